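## Aggregation statistics: chain clustering, monomer / largest-cluster
## fractions, t-half, oligomer-order distributions.

## chain -> CA coordinate list for one frame
chain_ca_coords <- function(tab, xyz) {
  ca <- tab[tab$atom_name == "CA", ]
  if (nrow(ca) == 0L) stop("no CA atoms in topology")
  miss <- setdiff(unique(tab$chain), unique(ca$chain))
  if (length(miss) > 0L) stop("chain without CA atoms: ", paste(miss, collapse = ","))
  lapply(split(ca$atom, ca$chain), function(idx) xyz[idx, , drop = FALSE])
}

#' Cluster chains in one frame
#'
#' Two chains are connected when their nearest CA-CA minimum-image distance
#' is within the cutoff ("nearest" linkage, the default, matching
#' nearest-neighbour identification) or when their CA-centroid distance is
#' ("centroid" linkage). Clusters are the transitive closure (connected
#' components).
#'
#' @param frame a [new_frame()].
#' @param topologies list of [chain_topology()] (or a [trajectory()], whose
#'   topologies are used).
#' @param cutoff CA-CA distance cutoff in Angstrom (default 10).
#' @param linkage `"nearest"` or `"centroid"`.
#' @return object of class `cluster_labels`: list with `labels` (integer
#'   cluster id per chain, 1-based, in chain order) and `sizes` (cluster
#'   sizes, indexed by cluster id).
#' @export
cluster_frame <- function(frame, topologies, cutoff = 10,
                          linkage = c("nearest", "centroid")) {
  linkage <- match.arg(linkage)
  if (inherits(topologies, "trajectory")) topologies <- topologies$topologies
  tab <- atom_table(topologies)
  cas <- chain_ca_coords(tab, frame$coords)
  ## keep chain order as in the topologies, not alphabetical
  ord <- match(unique(tab$chain), names(cas))
  cas <- cas[ord]
  n <- length(cas)
  if (linkage == "centroid") {
    cas <- lapply(cas, function(x) rbind(colMeans(x)))
  }
  ## union-find over chain pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      A <- cas[[i]]; B <- cas[[j]]
      linked <- FALSE
      for (k in seq_len(nrow(A))) {
        d2 <- rowSums(min_image_disp(B, A[rep(k, nrow(B)), , drop = FALSE],
                                     frame)^2)
        if (any(d2 <= cutoff^2)) { linked <- TRUE; break }
      }
      if (linked) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  labels <- match(roots, unique(roots))
  structure(list(labels = labels,
                 sizes = as.integer(table(factor(labels,
                                                 seq_len(max(labels)))))),
            class = "cluster_labels")
}

#' Largest-cluster fraction
#'
#' Size of the largest cluster divided by the number of chains.
#'
#' @param labels a `cluster_labels` (or an integer label vector).
#' @param n_chains total chain count (defaults to the label count).
#' @return fraction in [1/n_chains, 1].
#' @export
largest_cluster_fraction <- function(labels, n_chains = NULL) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  n_chains <- n_chains %||% length(lab)
  max(table(lab)) / n_chains
}

#' Kinetics series over a trajectory
#'
#' Per-frame monomer fraction (clusters of size 1), largest-cluster
#' fraction, and optionally the beta-sheet fraction.
#'
#' @param traj a [trajectory()].
#' @param cutoff clustering cutoff (Angstrom, default 10).
#' @param beta also compute the DSSP-style beta fraction (slower).
#' @param linkage passed to [cluster_frame()].
#' @return data.frame with `time`, `monomer_fraction`,
#'   `largest_cluster_fraction` (and `beta_fraction`).
#' @export
kinetics_series <- function(traj, cutoff = 10, beta = FALSE,
                            linkage = "nearest") {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$topologies)
  rows <- lapply(seq_along(traj$frames), function(f) {
    cl <- cluster_frame(traj$frames[[f]], traj$topologies, cutoff, linkage)
    data.frame(time = traj$frames[[f]]$time,
               monomer_fraction = sum(cl$sizes == 1L) / n,
               largest_cluster_fraction = max(cl$sizes) / n)
  })
  out <- do.call(rbind, rows)
  if (beta) out$beta_fraction <- beta_fraction_series(traj)$beta_fraction
  out
}

#' @rdname kinetics_series
#' @export
monomer_fraction_series <- function(traj, cutoff = 10) {
  kinetics_series(traj, cutoff)[, c("time", "monomer_fraction")]
}

#' Aggregation half-time
#'
#' First time at which the monomer fraction falls to half its initial
#' value, linearly interpolated between bracketing frames. `NA` (with a
#' warning) when the series never crosses.
#'
#' @param series data.frame with `time` and `monomer_fraction` (or two
#'   numeric vectors via `time`).
#' @param time optional time vector when `series` is numeric.
#' @return time (ns), or `NA_real_` flagged by a warning.
#' @export
t_half <- function(series, time = NULL) {
  if (is.data.frame(series)) {
    f <- series$monomer_fraction
    t <- series$time
  } else {
    f <- series
    t <- time %||% seq_along(series) - 1
  }
  if (length(f) < 2L || f[1L] <= 0) stop("series must start at fraction > 0")
  target <- f[1L] / 2
  below <- which(f <= target)
  if (length(below) == 0L) {
    warning("monomer fraction never reaches half its initial value")
    return(NA_real_)
  }
  k <- below[1L]
  if (k == 1L) return(t[1L])
  t[k - 1L] + (f[k - 1L] - target) / (f[k - 1L] - f[k]) * (t[k] - t[k - 1L])
}

#' Oligomer-order distributions before and after t-half
#'
#' Cluster-size histograms pooled over frames in [0, t_half) and
#' [t_half, t_half + window]; with several replicate trajectories the
#' fractions are averaged and the SEM across replicates reported.
#'
#' @param trajs one [trajectory()] or a list of replicates. Alternatively a
#'   list of per-frame `cluster_labels` lists via `labels_list` semantics
#'   (each element: list(times=, sizes=list of size vectors)).
#' @param t_half_value the half-time (ns); one value applied to all
#'   replicates, or a vector (one per replicate).
#' @param window window length after t_half in ns (default 200); truncated
#'   with a warning when it extends past the trajectory end.
#' @param cutoff clustering cutoff (Angstrom).
#' @param weighting `"oligomer"` (each cluster counts once, default) or
#'   `"chain"` (clusters weighted by size).
#' @param include_monomers include size-1 clusters in the normalization.
#' @return data.frame with `window` (BEFORE_THALF / AFTER_THALF), `size`,
#'   `fraction`, `sem` (NA with < 2 replicates); fractions sum to 1 within
#'   each window.
#' @export
oligomer_distribution <- function(trajs, t_half_value, window = 200,
                                  cutoff = 10, weighting = c("oligomer", "chain"),
                                  include_monomers = FALSE) {
  weighting <- match.arg(weighting)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (any(!is.finite(t_half_value))) stop("t_half must be defined")
  th <- rep_len(t_half_value, length(trajs))
  per_rep <- lapply(seq_along(trajs), function(r) {
    traj <- trajs[[r]]
    times <- vapply(traj$frames, function(f) f$time, numeric(1L))
    if (max(times) < th[r] + window) {
      warning("window extends past trajectory end; truncated")
    }
    sizes_by_frame <- lapply(seq_along(traj$frames), function(f) {
      cluster_frame(traj$frames[[f]], traj$topologies, cutoff)$sizes
    })
    list(times = times, sizes = sizes_by_frame)
  })
  size_hist <- function(sizes_pooled) {
    if (!include_monomers) sizes_pooled <- sizes_pooled[sizes_pooled >= 2L]
    if (length(sizes_pooled) == 0L) return(NULL)
    w <- if (weighting == "chain") sizes_pooled else rep(1L, length(sizes_pooled))
    tapply(w, sizes_pooled, sum) / sum(w)
  }
  windows <- list(BEFORE_THALF = function(t, r) t < th[r],
                  AFTER_THALF = function(t, r) t >= th[r] & t <= th[r] + window)
  out <- list()
  for (w in names(windows)) {
    reps <- lapply(seq_along(per_rep), function(r) {
      sel <- windows[[w]](per_rep[[r]]$times, r)
      size_hist(unlist(per_rep[[r]]$sizes[sel]))
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
    sem <- if (ncol(fr) >= 2L) {
      apply(fr, 1L, stats::sd) / sqrt(ncol(fr))
    } else rep(NA_real_, length(sizes))
    out[[w]] <- data.frame(window = w, size = sizes,
                           fraction = mean_fr / sum(mean_fr), sem = sem)
  }
  if (length(out) == 0L) {
    return(data.frame(window = character(), size = integer(),
                      fraction = numeric(), sem = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Midsize-oligomer fraction
#'
#' Sum of distribution fractions over the given oligomer-size range
#' (default 5-13, the midsized-oligomer band).
#'
#' @param distribution an [oligomer_distribution()] data.frame (one window,
#'   or filtered by `window`).
#' @param range inclusive size range.
#' @param window optional window tag to filter on.
#' @return fraction in [0, 1]; 0 with a warning on an empty distribution.
#' @export
midsize_fraction <- function(distribution, range = c(5, 13), window = NULL) {
  d <- distribution
  if (!is.null(window)) d <- d[d$window == window, ]
  if (nrow(d) == 0L) {
    warning("empty oligomer distribution")
    return(0)
  }
  sum(d$fraction[d$size >= range[1L] & d$size <= range[2L]])
}
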