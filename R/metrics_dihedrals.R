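## Dihedral measurement and circular statistics.
##
## Angles are averaged with circular statistics throughout: fibril psi/chi
## targets sit near the +-180 wrap, where naive means are badly biased.

#' Measure backbone and side-chain dihedrals
#'
#' Computes phi, psi (IUPAC convention) and Gln chi1/chi2 for every residue
#' of every chain and frame. Terminal residues have undefined phi (first) or
#' psi (last) and are reported as `NA`; residues missing a required atom are
#' skipped with a message.
#'
#' @param x a [trajectory()], a [build_lattice()] result, or a
#'   `list(topology=, coords=)` pair from [build_glutamine_chain()].
#' @return data.frame with columns `frame`, `time`, `chain`, `residue_index`,
#'   `name` (phi/psi/chi1/chi2), `value` (deg). For lattice input, columns
#'   `conformer` ("a"/"b"/"none") and `interior` (logical: interior strand
#'   residue) are attached from the builder metadata.
#' @export
measure_dihedrals <- function(x) {
  lattice_meta <- NULL
  if (inherits(x, "fibril_lattice")) {
    lattice_meta <- x$meta
    x <- trajectory(x$topologies, list(x$frame))
  } else if (!inherits(x, "trajectory") && is.list(x) &&
             !is.null(x$topology)) {
    x <- trajectory(list(x$topology), list(new_frame(x$coords)))
  }
  stopifnot(inherits(x, "trajectory"))
  tab <- atom_table(x$topologies)
  quads <- dihedral_quads(tab)
  out <- vector("list", length(x$frames))
  for (f in seq_along(x$frames)) {
    xyz <- x$frames[[f]]$coords
    vals <- torsion_rows(xyz, as.matrix(quads[, c("a1", "a2", "a3", "a4")]))
    out[[f]] <- data.frame(frame = f, time = x$frames[[f]]$time,
                           chain = quads$chain,
                           residue_index = quads$residue_index,
                           name = quads$name, value = vals,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(lattice_meta)) {
    lab <- lattice_residue_labels(lattice_meta)
    m <- match(paste(res$chain, res$residue_index),
               paste(lab$chain, lab$residue_index))
    res$conformer <- lab$conformer[m]
    res$interior <- lab$interior[m]
  }
  res
}

## index quadruplets for all measurable dihedrals
dihedral_quads <- function(tab) {
  rows <- list()
  skipped <- 0L
  for (ch in unique(tab$chain)) {
    sub <- tab[tab$chain == ch, ]
    res <- unique(sub$residue_index)
    at <- function(ri, nm) {
      i <- sub$atom[sub$residue_index == ri & sub$atom_name == nm]
      if (length(i) == 1L) i else NA_integer_
    }
    for (k in seq_along(res)) {
      ri <- res[k]
      N <- at(ri, "N"); CA <- at(ri, "CA"); C <- at(ri, "C")
      if (anyNA(c(N, CA, C))) { skipped <- skipped + 1L; next }
      if (k > 1L && res[k - 1L] == ri - 1L) {
        Cp <- at(ri - 1L, "C")
        if (!is.na(Cp)) {
          rows[[length(rows) + 1L]] <- list(ch, ri, "phi", Cp, N, CA, C)
        }
      }
      if (k < length(res) && res[k + 1L] == ri + 1L) {
        Nn <- at(ri + 1L, "N")
        if (!is.na(Nn)) {
          rows[[length(rows) + 1L]] <- list(ch, ri, "psi", N, CA, C, Nn)
        }
      }
      CB <- at(ri, "CB"); CG <- at(ri, "CG"); CD <- at(ri, "CD")
      if (!anyNA(c(CB, CG))) {
        rows[[length(rows) + 1L]] <- list(ch, ri, "chi1", N, CA, CB, CG)
        if (!is.na(CD)) {
          rows[[length(rows) + 1L]] <- list(ch, ri, "chi2", CA, CB, CG, CD)
        }
      }
    }
  }
  if (skipped > 0L) message(skipped, " residues skipped (missing backbone atoms)")
  q <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r[[1L]], residue_index = r[[2L]], name = r[[3L]],
               a1 = r[[4L]], a2 = r[[5L]], a3 = r[[6L]], a4 = r[[7L]],
               stringsAsFactors = FALSE)
  }))
  q
}

## conformer / interior labels per residue from lattice metadata
lattice_residue_labels <- function(meta) {
  sp <- meta$chain_spans
  chains <- unique(meta$strands$chain)
  out <- list()
  for (ci in chains) {
    sm <- meta$strands[meta$strands$chain == ci, ]
    n_res <- sp$strand2[2L]
    conf <- rep("none", n_res)
    interior <- rep(FALSE, n_res)
    for (snum in c(1L, 2L)) {
      rng <- if (snum == 1L) sp$strand1 else sp$strand2
      conf[rng[1L]:rng[2L]] <- sm$conformer[sm$strand == snum]
      if (rng[2L] - rng[1L] >= 2L) {
        interior[(rng[1L] + 1L):(rng[2L] - 1L)] <- TRUE
      }
    }
    out[[length(out) + 1L]] <- data.frame(chain = ci,
                                          residue_index = seq_len(n_res),
                                          conformer = conf,
                                          interior = interior)
  }
  do.call(rbind, out)
}

#' Circular statistics for angle samples
#'
#' @param values angles in degrees (length >= 1).
#' @param bin_width histogram bin width (deg) for the mode.
#' @return list with `mean` (circular mean, deg in (-180, 180]), `sd`
#'   (circular SD, deg), `mode` (center of the most populated bin; ties
#'   resolved toward the bin nearest the mean), `n`.
#' @export
circular_stats <- function(values, bin_width = 5) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite angle values")
  rad <- values * DEG
  s <- mean(sin(rad)); c <- mean(cos(rad))
  mu <- wrap_angle(atan2(s, c) / DEG)
  R <- sqrt(s^2 + c^2)
  sd <- if (R >= 1) 0 else sqrt(-2 * log(R)) / DEG
  breaks <- seq(-180, 180, by = bin_width)
  h <- hist(wrap_angle(values), breaks = breaks, plot = FALSE)
  top <- which(h$counts == max(h$counts))
  if (length(top) > 1L) {
    dmu <- abs(wrap_angle(h$mids[top] - mu))
    top <- top[which.min(dmu)]
  }
  list(mean = mu, sd = sd, mode = h$mids[top], n = length(values))
}

#' Per-conformer dihedral summary of a built lattice
#'
#' Circular means of psi/chi1/chi2 over interior strand residues, split by
#' conformer label - the quantities validated against the ssNMR-derived
#' targets.
#'
#' @param lattice a [build_lattice()] result (or a `measure_dihedrals()`
#'   data.frame carrying `conformer`/`interior` columns).
#' @return data.frame with columns `name`, `conformer`, `mean`, `sd`, `n`.
#' @export
conformer_dihedral_summary <- function(lattice) {
  dh <- if (is.data.frame(lattice)) lattice else measure_dihedrals(lattice)
  if (is.null(dh$conformer)) stop("input carries no conformer labels")
  dh <- dh[dh$interior & dh$conformer %in% c("a", "b") & is.finite(dh$value), ]
  agg <- expand.grid(name = c("phi", "psi", "chi1", "chi2"),
                     conformer = c("a", "b"), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(agg)), function(k) {
    v <- dh$value[dh$name == agg$name[k] & dh$conformer == agg$conformer[k]]
    if (length(v) == 0L) return(NULL)
    cs <- circular_stats(v)
    data.frame(name = agg$name[k], conformer = agg$conformer[k],
               mean = cs$mean, sd = cs$sd, n = cs$n)
  })
  do.call(rbind, res)
}
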