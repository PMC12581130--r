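## Lattice spacings, end-to-end conformer classification, radius of gyration.

ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                 P = 30.974, D = 2.014)

## CA coordinates per (chain, strand) from a strand assignment table
strand_ca_sets <- function(tab, xyz, strands, spans) {
  lapply(seq_len(nrow(strands)), function(k) {
    rng <- if (strands$strand[k] == 1L) spans$strand1 else spans$strand2
    sel <- tab$chain == strands$chain[k] & tab$atom_name == "CA" &
      tab$residue_index >= rng[1L] & tab$residue_index <= rng[2L]
    xyz[tab$atom[sel], , drop = FALSE]
  })
}

#' Sheet and strand spacing of a fibril lattice or trajectory
#'
#' Strand spacing: mean nearest inter-strand CA-CA distance over adjacent
#' strand pairs within a sheet, averaged over interior CA atoms (strand-end
#' CAs are excluded: in a finite lattice their nearest partner lies beyond
#' the strand end, which would bias the estimate upward). Sheet spacing: mean distance between
#' least-squares planes fitted to the CA atoms of adjacent sheets. Both are
#' minimum-image aware and averaged over frames.
#'
#' @param x a [build_lattice()] result or a [trajectory()].
#' @param assignment for a trajectory: the `meta$strands` table and
#'   `meta$chain_spans` of the generating lattice, as
#'   `list(strands=, chain_spans=)`.
#' @return list with `strand_spacing`, `sheet_spacing` (NA and
#'   `strand_defined`/`sheet_defined` FALSE when fewer than 2 strands or
#'   sheets), `strand_sd`, `sheet_sd` (per-pair variation).
#' @export
spacing_metrics <- function(x, assignment = NULL) {
  if (inherits(x, "fibril_lattice")) {
    assignment <- list(strands = x$meta$strands,
                       chain_spans = x$meta$chain_spans)
    x <- trajectory(x$topologies, list(x$frame))
  }
  stopifnot(inherits(x, "trajectory"), !is.null(assignment))
  strands <- assignment$strands
  spans <- assignment$chain_spans
  tab <- atom_table(x$topologies)
  strand_vals <- c(); sheet_vals <- c()
  for (f in seq_along(x$frames)) {
    frame <- x$frames[[f]]
    cas <- strand_ca_sets(tab, frame$coords, strands, spans)
    ## adjacent strands within each sheet, by slot order
    for (sh in unique(strands$sheet)) {
      idx <- which(strands$sheet == sh)
      idx <- idx[order(strands$slot[idx])]
      if (length(idx) < 2L) next
      for (k in seq_len(length(idx) - 1L)) {
        a <- cas[[idx[k]]]; b <- cas[[idx[k + 1L]]]
        src <- if (nrow(a) > 2L) 2L:(nrow(a) - 1L) else seq_len(nrow(a))
        nn <- vapply(src, function(i) {
          min(sqrt(rowSums(min_image_disp(b, a[rep(i, nrow(b)), ,
                                                drop = FALSE], frame)^2)))
        }, numeric(1L))
        strand_vals <- c(strand_vals, mean(nn))
      }
    }
    ## least-squares plane per sheet: centroid + normal from SVD
    sheets <- sort(unique(strands$sheet))
    if (length(sheets) >= 2L) {
      planes <- lapply(sheets, function(sh) {
        pts <- do.call(rbind, cas[strands$sheet == sh])
        ctr <- colMeans(pts)
        nrm <- svd(sweep(pts, 2L, ctr))$v[, 3L]
        list(ctr = ctr, nrm = nrm)
      })
      for (k in seq_len(length(sheets) - 1L)) {
        nbar <- unit(planes[[k]]$nrm *
                       sign(sum(planes[[k]]$nrm * planes[[k + 1L]]$nrm)) +
                       planes[[k + 1L]]$nrm)
        sheet_vals <- c(sheet_vals,
                        abs(sum((planes[[k + 1L]]$ctr - planes[[k]]$ctr) * nbar)))
      }
    }
  }
  list(strand_spacing = if (length(strand_vals)) mean(strand_vals) else NA_real_,
       strand_sd = if (length(strand_vals) > 1L) stats::sd(strand_vals) else NA_real_,
       strand_defined = length(strand_vals) > 0L,
       sheet_spacing = if (length(sheet_vals)) mean(sheet_vals) else NA_real_,
       sheet_sd = if (length(sheet_vals) > 1L) stats::sd(sheet_vals) else NA_real_,
       sheet_defined = length(sheet_vals) > 0L)
}

#' End-to-end distance classification of chain conformers
#'
#' CA(first)-CA(last) distance of the declared residue span on unwrapped
#' coordinates; chains above the upper cutoff are EXTENDED (beta-strand
#' configuration), below the lower cutoff COMPACT (beta-turn or beta-arc),
#' in between UNASSIGNED. Default cutoffs suit a 16-residue span: an ideal
#' extended strand reaches ~50 A, an ideal hairpin stays under ~15 A.
#'
#' @param traj a [trajectory()] or [build_lattice()] result.
#' @param span residue index range `c(first, last)`, e.g. `c(18, 33)` for
#'   the polyQ domain of H16.
#' @param cutoffs `c(compact, extended)` in Angstrom.
#' @return data.frame with `frame`, `chain`, `distance`, `class`.
#' @export
end_to_end_classify <- function(traj, span, cutoffs = c(15, 30)) {
  if (inherits(traj, "fibril_lattice")) {
    traj <- trajectory(traj$topologies, list(traj$frame))
  }
  stopifnot(inherits(traj, "trajectory"), length(span) == 2L,
            cutoffs[1L] <= cutoffs[2L])
  tab <- atom_table(traj$topologies)
  out <- list()
  for (ch in unique(tab$chain)) {
    sub <- tab[tab$chain == ch, ]
    if (!all(span %in% sub$residue_index)) {
      stop("span ", span[1L], ":", span[2L], " outside chain ", ch)
    }
    i1 <- sub$atom[sub$residue_index == span[1L] & sub$atom_name == "CA"]
    i2 <- sub$atom[sub$residue_index == span[2L] & sub$atom_name == "CA"]
    if (length(i1) != 1L || length(i2) != 1L) {
      stop("span endpoints missing CA in chain ", ch)
    }
    for (f in seq_along(traj$frames)) {
      xyz <- unwrap_coords(traj$frames[[f]], tab)
      d <- vnorm(xyz[i2, ] - xyz[i1, ])
      cls <- if (d > cutoffs[2L]) "EXTENDED" else if (d < cutoffs[1L])
        "COMPACT" else "UNASSIGNED"
      out[[length(out) + 1L]] <- data.frame(frame = f, chain = ch,
                                            distance = d, class = cls,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Radius of gyration per frame
#'
#' Mass-weighted over heavy atoms, on unwrapped coordinates.
#'
#' @param traj a [trajectory()].
#' @param per_chain if `TRUE`, one value per chain per frame; otherwise the
#'   whole system.
#' @return data.frame with `frame`, `time`, (`chain`,) `rg` (Angstrom).
#' @export
radius_of_gyration <- function(traj, per_chain = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  tab <- atom_table(traj$topologies)
  heavy <- tab[is_heavy(tab), ]
  mass <- ATOMIC_MASS[heavy$element]
  mass[is.na(mass)] <- 12.0
  groups <- if (per_chain) split(seq_len(nrow(heavy)), heavy$chain) else
    list(all = seq_len(nrow(heavy)))
  out <- list()
  for (f in seq_along(traj$frames)) {
    xyz <- unwrap_coords(traj$frames[[f]], tab)
    for (g in names(groups)) {
      sel <- groups[[g]]
      x <- xyz[heavy$atom[sel], , drop = FALSE]
      m <- mass[sel]
      com <- colSums(x * m) / sum(m)
      rg <- sqrt(sum(m * rowSums(sweep(x, 2L, com)^2)) / sum(m))
      row <- data.frame(frame = f, time = traj$frames[[f]]$time, rg = rg)
      if (per_chain) row$chain <- g
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
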