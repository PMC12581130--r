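## Stochastic dock-and-lock aggregation generator.
##
## An explicit stand-in for coarse-grained aggregation dynamics: the two
## docking channels (backbone-mediated and side-chain interlocking), the
## dock->lock conversion, and the dissociation of small unlocked oligomers
## are encoded as mass-action rates. Rates are illustrative, not physical;
## the Q16-like regime has fast small-cluster dissociation, the H16-like
## regime (N17-stabilized oligomers) has nearly none, which is what makes
## it accumulate midsized oligomers before t-half.

#' Dock-and-lock rate parameters
#'
#' All rates are per ns (mass-action propensities):
#' dimerization `k_dim * M(M-1)/2`; monomer addition
#' `(k_add_bb + k_add_sc) * M * C`; coagulation `k_coag * C(C-1)/2`;
#' dissociation `k_off_small` per eligible cluster (size 2..size_s with at
#' least one non-locked chain); locking `k_lock` per docked chain. M =
#' monomers, C = clusters of size >= 2.
#'
#' @param n_chains number of chains.
#' @param k_dim,k_add_bb,k_add_sc,k_coag,k_off_small,k_lock rates (>= 0).
#' @param size_s largest cluster size subject to dissociation (>= 2).
#' @param seed RNG seed.
#' @return object of class `dock_lock_params`.
#' @export
dock_lock_params <- function(n_chains, k_dim = 0, k_add_bb = 0, k_add_sc = 0,
                             k_coag = 0, k_off_small = 0, k_lock = 0,
                             size_s = 13L, seed = 1L) {
  rates <- c(k_dim, k_add_bb, k_add_sc, k_coag, k_off_small, k_lock)
  stopifnot(n_chains >= 1L, all(rates >= 0), size_s >= 2L)
  structure(list(n_chains = as.integer(n_chains), k_dim = k_dim,
                 k_add_bb = k_add_bb, k_add_sc = k_add_sc, k_coag = k_coag,
                 k_off_small = k_off_small, k_lock = k_lock,
                 size_s = as.integer(size_s), seed = as.integer(seed)),
            class = "dock_lock_params")
}

#' Illustrative Q16-like and H16-like kinetic regimes
#'
#' The regimes share addition, coagulation and locking rates and differ in
#' (i) small-oligomer dissociation - fast for Q16, absent for the H16-like
#' regime whose N17-stabilized oligomers do not dissolve - and (ii) the
#' dimerization rate, fast for Q16 whose monomers readily engage in initial
#' binding events. Together these reproduce the qualitative kinetics
#' contrast: Q16 depletes monomers faster into a dimer-dominated early
#' population, while the H16-like regime converts more slowly but
#' accumulates midsized (5-13 chain) oligomers before t-half. Rates are
#' illustrative, not physical.
#'
#' @param n_chains chains per simulation.
#' @param seed RNG seed.
#' @return named list of two [dock_lock_params()]: `Q16` and `H16`.
#' @export
dock_lock_regimes <- function(n_chains = 100L, seed = 1L) {
  base <- list(n_chains = n_chains, k_add_bb = 5e-4, k_add_sc = 5e-4,
               k_coag = 2e-3, k_lock = 0.05, size_s = 13L, seed = seed)
  list(Q16 = do.call(dock_lock_params,
                     c(base, k_dim = 3e-3, k_off_small = 1.0)),
       H16 = do.call(dock_lock_params,
                     c(base, k_dim = 2e-4, k_off_small = 0)))
}

#' Simulate the dock-and-lock model (exact Gillespie)
#'
#' @param params a [dock_lock_params()].
#' @param t_end simulation end time (ns, > 0).
#' @param sample_dt sampling interval for state snapshots (ns).
#' @return object of class `dock_lock_trajectory`: list with `params`,
#'   `events` (data.frame time / reaction / participants), `times` (sample
#'   times), `cluster` (samples x chains integer matrix of cluster ids) and
#'   `state` (samples x chains matrix, COIL / DOCKED / LOCKED).
#' @export
simulate_dock_lock <- function(params, t_end, sample_dt = 1) {
  stopifnot(inherits(params, "dock_lock_params"))
  if (t_end <= 0) stop("t_end must be > 0")
  set.seed(params$seed)
  n <- params$n_chains
  cluster <- seq_len(n)          # cluster id per chain
  state <- rep("COIL", n)
  times <- seq(0, t_end, by = sample_dt)
  cl_mat <- matrix(NA_integer_, length(times), n)
  st_mat <- matrix(NA_character_, length(times), n)
  ev_time <- numeric(); ev_rxn <- character(); ev_part <- character()
  t <- 0
  next_sample <- 1L
  record_until <- function(tnow) {
    while (next_sample <= length(times) && times[next_sample] <= tnow) {
      cl_mat[next_sample, ] <<- match(cluster, unique(cluster))
      st_mat[next_sample, ] <<- state
      next_sample <<- next_sample + 1L
    }
  }
  repeat {
    sizes <- table(cluster)
    mono_ids <- as.integer(names(sizes)[sizes == 1L])
    clus_ids <- as.integer(names(sizes)[sizes >= 2L])
    M <- length(mono_ids); C <- length(clus_ids)
    elig <- clus_ids[vapply(clus_ids, function(cid) {
      sz <- sizes[[as.character(cid)]]
      sz <= params$size_s && any(state[cluster == cid] != "LOCKED")
    }, logical(1L))]
    docked <- which(state == "DOCKED")
    a <- c(dim = params$k_dim * M * (M - 1) / 2,
           add = (params$k_add_bb + params$k_add_sc) * M * C,
           coag = params$k_coag * C * (C - 1) / 2,
           off = params$k_off_small * length(elig),
           lock = params$k_lock * length(docked))
    a_tot <- sum(a)
    if (a_tot <= 0) { record_until(t_end); break }
    t <- t + stats::rexp(1L, a_tot)
    if (t > t_end) { record_until(t_end); break }
    record_until(t)
    rxn <- sample.int(5L, 1L, prob = a)
    if (rxn == 1L) {                               # monomer + monomer
      pick <- sample(mono_ids, 2L)
      cluster[cluster == pick[2L]] <- pick[1L]
      sel <- cluster == pick[1L] & state != "LOCKED"
      state[sel] <- "DOCKED"
      ev_rxn <- c(ev_rxn, "DIMERIZE")
      ev_part <- c(ev_part, paste(pick, collapse = ","))
    } else if (rxn == 2L) {                        # monomer -> cluster
      m <- if (M == 1L) mono_ids else sample(mono_ids, 1L)
      cid <- if (C == 1L) clus_ids else sample(clus_ids, 1L)
      channel <- if (stats::runif(1L) <
                     params$k_add_bb / (params$k_add_bb + params$k_add_sc))
        "ADD_BB" else "ADD_SC"
      cluster[m] <- cid
      if (state[m] != "LOCKED") state[m] <- "DOCKED"
      ev_rxn <- c(ev_rxn, channel)
      ev_part <- c(ev_part, paste(m, cid, sep = ","))
    } else if (rxn == 3L) {                        # cluster + cluster
      pick <- sample(clus_ids, 2L)
      cluster[cluster == pick[2L]] <- pick[1L]
      ev_rxn <- c(ev_rxn, "COAGULATE")
      ev_part <- c(ev_part, paste(pick, collapse = ","))
    } else if (rxn == 4L) {                        # chain leaves small cluster
      cid <- if (length(elig) == 1L) elig else sample(elig, 1L)
      members <- which(cluster == cid & state != "LOCKED")
      leaver <- if (length(members) == 1L) members else sample(members, 1L)
      cluster[leaver] <- leaver
      state[leaver] <- "COIL"
      rest <- which(cluster == cid)
      if (length(rest) == 1L && state[rest] != "LOCKED") state[rest] <- "COIL"
      ev_rxn <- c(ev_rxn, "DISSOCIATE")
      ev_part <- c(ev_part, paste(leaver, cid, sep = ","))
    } else {                                       # dock -> lock
      ch <- if (length(docked) == 1L) docked else sample(docked, 1L)
      state[ch] <- "LOCKED"
      ev_rxn <- c(ev_rxn, "LOCK")
      ev_part <- c(ev_part, as.character(ch))
    }
    ev_time <- c(ev_time, t)
  }
  structure(list(params = params,
                 events = data.frame(time = ev_time, reaction = ev_rxn,
                                     participants = ev_part,
                                     stringsAsFactors = FALSE),
                 times = times, cluster = cl_mat, state = st_mat),
            class = "dock_lock_trajectory")
}

#' Bookkeeping statistics from a dock-and-lock trajectory
#'
#' Monomer and largest-cluster fractions computed directly from the sampled
#' cluster assignments (no coordinates involved) - the ground-truth side of
#' the generator/analyzer closure.
#'
#' @param dlt a `dock_lock_trajectory`.
#' @return data.frame with `time`, `monomer_fraction`,
#'   `largest_cluster_fraction`.
#' @export
dock_lock_series <- function(dlt) {
  stopifnot(inherits(dlt, "dock_lock_trajectory"))
  n <- dlt$params$n_chains
  rows <- lapply(seq_along(dlt$times), function(k) {
    sizes <- table(dlt$cluster[k, ])
    data.frame(time = dlt$times[k],
               monomer_fraction = sum(sizes == 1L) / n,
               largest_cluster_fraction = max(sizes) / n)
  })
  do.call(rbind, rows)
}

#' Cluster-size vectors per sample from a dock-and-lock trajectory
#'
#' @param dlt a `dock_lock_trajectory`.
#' @return list (one per sample time) of integer cluster-size vectors.
#' @export
dock_lock_sizes <- function(dlt) {
  lapply(seq_along(dlt$times), function(k) {
    as.integer(table(dlt$cluster[k, ]))
  })
}

#' Oligomer distribution directly from dock-and-lock samples
#'
#' Event-log/bookkeeping analogue of [oligomer_distribution()].
#'
#' @param dlts list of `dock_lock_trajectory` replicates (or one).
#' @param t_half_value half-time(s), recycled over replicates.
#' @param window window length after t-half (ns).
#' @param weighting,include_monomers as in [oligomer_distribution()].
#' @return data.frame as in [oligomer_distribution()].
#' @export
dock_lock_oligomer_distribution <- function(dlts, t_half_value, window = 200,
                                            weighting = c("oligomer", "chain"),
                                            include_monomers = FALSE) {
  weighting <- match.arg(weighting)
  if (inherits(dlts, "dock_lock_trajectory")) dlts <- list(dlts)
  th <- rep_len(t_half_value, length(dlts))
  size_hist <- function(sz) {
    if (!include_monomers) sz <- sz[sz >= 2L]
    if (length(sz) == 0L) return(NULL)
    w <- if (weighting == "chain") sz else rep(1L, length(sz))
    tapply(w, sz, sum) / sum(w)
  }
  out <- list()
  for (w in c("BEFORE_THALF", "AFTER_THALF")) {
    reps <- lapply(seq_along(dlts), function(r) {
      tt <- dlts[[r]]$times
      sel <- if (w == "BEFORE_THALF") tt < th[r] else
        tt >= th[r] & tt <= th[r] + window
      size_hist(unlist(dock_lock_sizes(dlts[[r]])[sel]))
    })
    reps <- Filter(Negate(is.null), reps)
    if (length(reps) == 0L) next
    sizes <- sort(unique(as.integer(unlist(lapply(reps, names)))))
    fr <- vapply(reps, function(h) {
      v <- rep(0, length(sizes))
      v[match(as.integer(names(h)), sizes)] <- h
      v
    }, numeric(length(sizes)))
    fr <- matrix(fr, nrow = length(sizes))
    mean_fr <- rowMeans(fr)
    out[[w]] <- data.frame(window = w, size = sizes,
                           fraction = mean_fr / sum(mean_fr),
                           sem = if (ncol(fr) >= 2L)
                             apply(fr, 1L, stats::sd) / sqrt(ncol(fr))
                           else rep(NA_real_, length(sizes)))
  }
  if (length(out) == 0L) {
    return(data.frame(window = character(), size = integer(),
                      fraction = numeric(), sem = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Realize 3D coordinates for a dock-and-lock state
#'
#' Renders one sampled state as a frame that the geometric clustering
#' pipeline can analyze: each cluster of size m becomes m copies of a
#' template chain stacked at `strand_spacing` (so consecutive chains are
#' within the clustering cutoff), and every cluster/monomer is placed on a
#' coarse grid whose spacing keeps distinct groups at least twice the
#' cutoff apart. [cluster_frame()] on the result recovers the generator's
#' partition exactly.
#'
#' @param cluster integer cluster id per chain (one row of `dlt$cluster`).
#' @param template a `list(topology=, coords=)` chain template; default is
#'   an 8-residue extended glutamine strand.
#' @param cutoff the clustering cutoff the realization must respect.
#' @param stack_spacing intra-cluster chain spacing (Angstrom).
#' @return list with `topologies`, `frame` (non-periodic).
#' @export
realize_coordinates <- function(cluster, template = NULL, cutoff = 10,
                                stack_spacing = 4.8) {
  n <- length(cluster)
  if (is.null(template)) {
    template <- suppressWarnings(build_glutamine_chain(
      8L, data.frame(phi = -150, psi = 136, chi1 = -65, chi2 = 180)))
  }
  txyz <- sweep(template$coords, 2L, colMeans(template$coords))
  ext <- max(apply(txyz, 2L, function(v) diff(range(v))))
  groups <- split(seq_len(n), cluster)
  max_size <- max(lengths(groups))
  pitch <- ext + max_size * stack_spacing + 2 * cutoff + 5
  side <- ceiling(length(groups)^(1 / 3))
  coords <- matrix(NA_real_, n * nrow(txyz), 3L)
  na <- nrow(txyz)
  for (g in seq_along(groups)) {
    cell <- c(g %% side, (g %/% side) %% side, g %/% side^2)
    origin <- cell * pitch
    members <- groups[[g]]
    for (m in seq_along(members)) {
      idx <- (members[m] - 1L) * na + seq_len(na)
      coords[idx, ] <- sweep(txyz, 2L,
                             origin + c(0, (m - 1L) * stack_spacing, 0), "+")
    }
  }
  tops <- lapply(seq_len(n), function(ci) {
    chain_topology(chain_letters(ci), template$topology$atoms)
  })
  list(topologies = tops, frame = new_frame(coords, time = 0))
}

#' Estimate k_dim from replicate dimerization-only runs
#'
#' Least-squares fit of the mean monomer count against the closed-form
#' solution of `dM/dt = -k M(M-1)` over the early decay (down to 20% of the
#' initial count).
#'
#' @param dlts list of `dock_lock_trajectory` replicates (>= 1; the
#'   contract expects ~10+ for a stable estimate) generated with only
#'   `k_dim` active.
#' @return estimated k_dim (per ns).
#' @export
recover_rates <- function(dlts) {
  if (inherits(dlts, "dock_lock_trajectory")) dlts <- list(dlts)
  if (length(dlts) == 0L) stop("no trajectories supplied")
  times <- dlts[[1L]]$times
  n0 <- dlts[[1L]]$params$n_chains
  M <- vapply(dlts, function(d) {
    vapply(seq_along(d$times), function(k) {
      sum(table(d$cluster[k, ]) == 1L)
    }, numeric(1L))
  }, numeric(length(times)))
  Mbar <- rowMeans(matrix(M, nrow = length(times)))
  if (stats::sd(Mbar) == 0) return(0)
  sel <- Mbar >= 0.2 * n0
  if (sum(sel) < 3L) sel <- seq_len(min(3L, length(times)))
  u0 <- 1 - 1 / n0
  model <- function(k, t) 1 / (1 - u0 * exp(-k * t))
  obj <- function(k) sum((Mbar[sel] - model(k, times[sel]))^2)
  ## bracket the rate from the crude initial slope
  slope <- (Mbar[1L] - Mbar[min(5L, length(Mbar))]) /
    (times[min(5L, length(times))] - times[1L])
  k0 <- max(slope / (n0 * (n0 - 1)), 1e-9)
  stats::optimize(obj, c(k0 / 100, k0 * 100))$minimum
}
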