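## Hydrogen-bond-based secondary structure (Kabsch-Sander style, 4 states).
##
## Backbone amide hydrogens are reconstructed geometrically (bisector of the
## C(i-1)->N and CA->N directions), since built and coarse-grained
## structures carry no hydrogens. The H-bond energy is the Kabsch-Sander
## electrostatic approximation,
##   E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
## with a bond assigned below -0.5 kcal/mol. States: H (alpha-helix, runs of
## i,i+4 bonds), E (beta via parallel/antiparallel bridges), T (n-turns),
## C otherwise; priority H > E > T > C.

KS_Q <- 27.888      # kcal/mol * A, = 332 * 0.42 * 0.20
KS_CUTOFF <- -0.5   # kcal/mol
KS_CA_PREFILTER <- 9.0

## backbone bookkeeping: one row per residue with atom rows or NA
backbone_index <- function(tab) {
  key <- paste(tab$chain, tab$residue_index)
  res <- !duplicated(key)
  bb <- data.frame(chain = tab$chain[res], residue_index = tab$residue_index[res])
  for (nm in c("N", "CA", "C", "O")) {
    sel <- tab$atom_name == nm
    bb[[nm]] <- tab$atom[sel][match(paste(bb$chain, bb$residue_index),
                                    key[sel])]
  }
  bb
}

## reconstructed H positions (NA rows where undefined: chain start or
## missing atoms)
amide_hydrogens <- function(bb, xyz) {
  n <- nrow(bb)
  H <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    if (i == 1L || bb$chain[i] != bb$chain[i - 1L] ||
        bb$residue_index[i] != bb$residue_index[i - 1L] + 1L) next
    if (anyNA(c(bb$N[i], bb$CA[i], bb$C[i - 1L]))) next
    Np <- xyz[bb$N[i], ]
    d <- unit(unit(Np - xyz[bb$C[i - 1L], ]) + unit(Np - xyz[bb$CA[i], ]))
    H[i, ] <- Np + 1.01 * d
  }
  H
}

## H-bond matrix: hb[i, j] = TRUE when NH of residue i donates to CO of j.
ks_hbonds <- function(bb, xyz, frame) {
  n <- nrow(bb)
  H <- amide_hydrogens(bb, xyz)
  hb <- matrix(FALSE, n, n)
  has_acc <- !is.na(bb$C) & !is.na(bb$O)
  has_don <- !is.na(bb$N) & is.finite(H[, 1L])
  ca_ok <- !is.na(bb$CA)
  CA <- matrix(NA_real_, n, 3L)
  CA[ca_ok, ] <- xyz[bb$CA[ca_ok], , drop = FALSE]
  for (i in which(has_don)) {
    if (!ca_ok[i]) next
    dca <- min_image_disp(CA, CA[rep(i, n), , drop = FALSE], frame)
    near <- which(has_acc & ca_ok & sqrt(rowSums(dca^2)) < KS_CA_PREFILTER)
    for (j in near) {
      if (bb$chain[i] == bb$chain[j] &&
          abs(bb$residue_index[i] - bb$residue_index[j]) <= 1L) next
      Ni <- xyz[bb$N[i], ]; Hi <- H[i, ]
      Cj <- xyz[bb$C[j], ]; Oj <- xyz[bb$O[j], ]
      ## apply the same image shift to the whole acceptor group
      shift <- min_image_disp(rbind(Cj), rbind(Ni), frame)[1L, ] - (Cj - Ni)
      Cj <- Cj + shift; Oj <- Oj + shift
      e <- KS_Q * (1 / vnorm(Oj - Ni) + 1 / vnorm(Cj - Hi) -
                     1 / vnorm(Oj - Hi) - 1 / vnorm(Cj - Ni))
      if (e < KS_CUTOFF) hb[i, j] <- TRUE
    }
  }
  hb
}

## 4-state assignment for one frame; bb rows define residue order.
ks_assign <- function(bb, xyz, frame) {
  n <- nrow(bb)
  state <- rep("C", n)
  if (n == 0L) return(state)
  hb <- ks_hbonds(bb, xyz, frame)
  same_chain_offset <- function(i, k) {
    j <- i + k
    ok <- j >= 1L & j <= n
    ok[ok] <- bb$chain[i[ok]] == bb$chain[j[ok]] &
      bb$residue_index[j[ok]] == bb$residue_index[i[ok]] + k
    ok
  }
  ## n-turns: turn_n[i] <=> HB(i+n -> i)
  turns <- list()
  for (k in 3:5) {
    t <- rep(FALSE, n)
    i <- seq_len(n)
    ok <- same_chain_offset(i, k)
    t[ok] <- hb[cbind(i[ok] + k, i[ok])]
    turns[[as.character(k)]] <- t
  }
  ## alpha helix: residues i..i+3 where turn4(i-1) and turn4(i)
  t4 <- turns[["4"]]
  helix <- rep(FALSE, n)
  for (i in which(t4)) {
    if (i > 1L && t4[i - 1L]) helix[i:min(n, i + 3L)] <- TRUE
  }
  ## bridges; i-1 / i+1 references must stay within the same chain
  ok_prev <- c(FALSE, bb$chain[-1L] == bb$chain[-n] &
                 bb$residue_index[-1L] == bb$residue_index[-n] + 1L)
  ok_next <- c(ok_prev[-1L], FALSE)
  bridge <- rep(FALSE, n)
  HB <- function(a, b) hb[a, b]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (bb$chain[i] == bb$chain[j] &&
          abs(bb$residue_index[i] - bb$residue_index[j]) < 3L) next
      ## Kabsch-Sander bridge rules with Hbond(a, b) = CO(a) accepting from
      ## NH(b); HB(d, a) here is donor-first, hence the swapped indices.
      para <- (ok_prev[i] && ok_next[i] && HB(j, i - 1L) && HB(i + 1L, j)) ||
        (ok_prev[j] && ok_next[j] && HB(i, j - 1L) && HB(j + 1L, i))
      anti <- (HB(i, j) && HB(j, i)) ||
        (ok_prev[i] && ok_next[i] && ok_prev[j] && ok_next[j] &&
           HB(j + 1L, i - 1L) && HB(i + 1L, j - 1L))
      if (para || anti) bridge[i] <- TRUE
    }
  }
  turn_flag <- rep(FALSE, n)
  for (k in 3:5) {
    for (i in which(turns[[as.character(k)]])) {
      turn_flag[(i + 1L):min(n, i + k - 1L)] <- TRUE
    }
  }
  state[turn_flag] <- "T"
  state[bridge] <- "E"
  state[helix] <- "H"
  ## chains shorter than 3 residues are all coil
  for (ch in unique(bb$chain)) {
    sel <- bb$chain == ch
    if (sum(sel) < 3L) state[sel] <- "C"
  }
  state
}

#' Assign secondary structure (Kabsch-Sander, 4 states)
#'
#' @param traj a [trajectory()] (backbone N, CA, C, O required; amide H is
#'   reconstructed).
#' @return object of class `ss_series`: list with `states` (frames x
#'   residues character matrix), `residues` (data.frame chain /
#'   residue_index), `times`.
#' @export
assign_secondary_structure <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  tab <- atom_table(traj$topologies)
  bb <- backbone_index(tab)
  states <- matrix("C", length(traj$frames), nrow(bb))
  for (f in seq_along(traj$frames)) {
    states[f, ] <- ks_assign(bb, traj$frames[[f]]$coords, traj$frames[[f]])
  }
  structure(list(states = states,
                 residues = bb[, c("chain", "residue_index")],
                 times = vapply(traj$frames, function(x) x$time, numeric(1L))),
            class = "ss_series")
}

#' Secondary-structure fractions
#'
#' @param ss an `ss_series`.
#' @param by `"frame"` (fraction of residues in each state per frame) or
#'   `"residue"` (fraction of frames per residue).
#' @return data.frame of fractions; states sum to 1 within each unit.
#' @export
ss_fractions <- function(ss, by = c("frame", "residue")) {
  by <- match.arg(by)
  sts <- c("H", "E", "T", "C")
  if (by == "frame") {
    out <- t(apply(ss$states, 1L, function(r) {
      tabulate(factor(r, sts), nbins = 4L) / length(r)
    }))
    colnames(out) <- sts
    data.frame(time = ss$times, out)
  } else {
    out <- t(apply(ss$states, 2L, function(r) {
      tabulate(factor(r, sts), nbins = 4L) / length(r)
    }))
    colnames(out) <- sts
    data.frame(ss$residues, out)
  }
}

#' Beta-sheet fraction time series
#'
#' Fraction of residues (over all chains) assigned E, per frame.
#'
#' @param traj a [trajectory()] or an `ss_series`.
#' @return data.frame with `time` and `beta_fraction`.
#' @export
beta_fraction_series <- function(traj) {
  ss <- if (inherits(traj, "ss_series")) traj else
    assign_secondary_structure(traj)
  data.frame(time = ss$times,
             beta_fraction = rowMeans(ss$states == "E"))
}

#' Per-residue helicity profile
#'
#' Average fraction of frames (pooled over chains at the same residue
#' position) in state H, with block-averaged standard deviations over four
#' blocks of frames.
#'
#' @param traj a [trajectory()] or `ss_series`.
#' @param n_blocks blocks for the error estimate (default 4).
#' @return data.frame with `residue_index`, `helicity`, `sd_block` (NA with
#'   a warning when fewer than `n_blocks` frames).
#' @export
helicity_profile <- function(traj, n_blocks = 4L) {
  ss <- if (inherits(traj, "ss_series")) traj else
    assign_secondary_structure(traj)
  resi <- ss$residues$residue_index
  positions <- sort(unique(resi))
  helmat <- ss$states == "H"
  nf <- nrow(helmat)
  prof <- vapply(positions, function(p) mean(helmat[, resi == p]), numeric(1L))
  if (nf < n_blocks) {
    warning("fewer than ", n_blocks, " frames: block averaging skipped")
    sdb <- rep(NA_real_, length(positions))
  } else {
    blk <- cut(seq_len(nf), n_blocks, labels = FALSE)
    sdb <- vapply(positions, function(p) {
      bm <- vapply(seq_len(n_blocks), function(b) {
        mean(helmat[blk == b, resi == p])
      }, numeric(1L))
      stats::sd(bm)
    }, numeric(1L))
  }
  data.frame(residue_index = positions, helicity = prof, sd_block = sdb)
}
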