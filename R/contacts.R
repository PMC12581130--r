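## Residue contact maps and the multi-state interaction table.
##
## Analysis convention: two residues are in contact when any heavy-atom
## pair is within 6 A (minimum-image aware); contact probability is the
## fraction of frames (and, for INTER scope, chain pairs) in contact.

## per-chain list of heavy-atom coordinates grouped by residue
residue_atom_groups <- function(tab) {
  heavy <- tab[is_heavy(tab), ]
  lapply(split(heavy, heavy$chain), function(sub) {
    split(sub$atom, sub$residue_index)
  })
}

## residue-residue contact indicator for two atom-group lists in one frame
contact_block <- function(groups_a, groups_b, xyz, frame, cutoff) {
  ra <- as.integer(names(groups_a))
  rb <- as.integer(names(groups_b))
  out <- matrix(FALSE, length(ra), length(rb),
                dimnames = list(ra, rb))
  for (i in seq_along(ra)) {
    A <- xyz[groups_a[[i]], , drop = FALSE]
    for (j in seq_along(rb)) {
      B <- xyz[groups_b[[j]], , drop = FALSE]
      ## min over all heavy-atom pairs
      hit <- FALSE
      for (k in seq_len(nrow(A))) {
        d2 <- rowSums(min_image_disp(B, A[rep(k, nrow(B)), , drop = FALSE],
                                     frame)^2)
        if (any(d2 <= cutoff^2)) { hit <- TRUE; break }
      }
      out[i, j] <- hit
    }
  }
  out
}

#' Extract a residue contact-probability map from a trajectory
#'
#' @param traj a [trajectory()] (>= 1 frame).
#' @param scope `"INTRA"` (within chains, averaged over chains) or `"INTER"`
#'   (between chains, aggregated over all chain pairs).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 6).
#' @param min_seq_sep for INTRA scope, exclude pairs with |i-j| below this
#'   (default 3, dropping trivially bonded neighbours).
#' @param source provenance tag: `"MONOMER"`, `"DENSE"` or `"FIBRIL"`.
#' @return object of class `contact_map`: data.frame `(i, j, probability)`
#'   with i < j, plus attributes `scope`, `source`, `cutoff`, `n_residues`.
#' @export
extract_contacts <- function(traj, scope = c("INTRA", "INTER"), cutoff = 6,
                             min_seq_sep = 3L,
                             source = c("MONOMER", "DENSE", "FIBRIL")) {
  scope <- match.arg(toupper(scope), c("INTRA", "INTER"))
  source <- match.arg(toupper(source), c("MONOMER", "DENSE", "FIBRIL"))
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  if (length(traj$frames) == 0L) stop("empty trajectory")
  mat <- residue_contact_map(traj, scope, cutoff, min_seq_sep)
  idx <- which(upper.tri(mat, diag = FALSE), arr.ind = TRUE)
  res <- as.integer(rownames(mat))
  df <- data.frame(i = res[idx[, 1L]], j = res[idx[, 2L]],
                   probability = mat[idx])
  if (scope == "INTRA") df <- df[abs(df$i - df$j) >= min_seq_sep, ]
  df <- df[df$probability > 0, ]
  rownames(df) <- NULL
  structure(df, class = c("contact_map", "data.frame"),
            scope = scope, source = source, cutoff = cutoff,
            n_residues = length(res))
}

#' Full residue contact-frequency matrix
#'
#' Same contact definition as [extract_contacts()] but returning the dense
#' matrix (residue position x residue position) for plotting and direct
#' comparison.
#'
#' @inheritParams extract_contacts
#' @return symmetric numeric matrix with values in [0, 1], residue indices
#'   as dimnames.
#' @export
residue_contact_map <- function(traj, scope = c("INTRA", "INTER"), cutoff = 6,
                                min_seq_sep = 0L) {
  scope <- match.arg(toupper(scope), c("INTRA", "INTER"))
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) == 0L) stop("empty trajectory")
  tab <- atom_table(traj$topologies)
  groups <- residue_atom_groups(tab)
  ## residue positions pooled across chains (homologous chains assumed)
  res <- sort(unique(tab$residue_index[is_heavy(tab)]))
  acc <- matrix(0, length(res), length(res), dimnames = list(res, res))
  nobs <- 0L
  chains <- names(groups)
  for (f in seq_along(traj$frames)) {
    frame <- traj$frames[[f]]
    xyz <- frame$coords
    if (scope == "INTRA") {
      for (ch in chains) {
        blk <- contact_block(groups[[ch]], groups[[ch]], xyz, frame, cutoff)
        acc[rownames(blk), colnames(blk)] <-
          acc[rownames(blk), colnames(blk)] + blk
        nobs <- nobs + 1L
      }
    } else {
      if (length(chains) < 2L) stop("INTER scope needs >= 2 chains")
      for (a in seq_along(chains)) {
        for (b in seq_along(chains)) {
          if (b <= a) next
          blk <- contact_block(groups[[chains[a]]], groups[[chains[b]]],
                               xyz, frame, cutoff)
          sym <- blk | t(blk)
          acc[rownames(blk), colnames(blk)] <-
            acc[rownames(blk), colnames(blk)] + sym
          nobs <- nobs + 1L
        }
      }
    }
  }
  mat <- acc / nobs
  if (scope == "INTRA") {
    ridx <- as.integer(res)
    sep <- abs(outer(ridx, ridx, "-"))
    mat[sep < min_seq_sep] <- 0
    diag(mat) <- 0
  }
  mat
}

#' Merge per-state contact maps into a multi-state interaction table
#'
#' Implements the multi-state native-contact logic: polyQ-core (QCORE) pairs
#' above the inclusion threshold become ATTRACTIVE with the configured
#' epsilon (intermolecular strength equal to intramolecular); flanking-domain
#' pairs (N17-N17, P5-P5, N17-P5) are sourced from the dense-phase map;
#' every flanking-QCORE cross pair is REPULSIVE (excluded volume) regardless
#' of the input maps; all remaining non-native pairs are REPULSIVE.
#'
#' @param monomer_map,fibril_map [extract_contacts()] results (fibril takes
#'   precedence for QCORE provenance).
#' @param dense_map dense-phase map, or `NULL` for constructs without
#'   flanking domains.
#' @param topology a [chain_topology()] carrying domain labels.
#' @param epsilon attractive interaction strength in kJ/mol (0.4 for Q16,
#'   0.325 for H16).
#' @param threshold native-contact inclusion threshold on the contact
#'   probability (default 0.05).
#' @return object of class `model_parameters`: data.frame
#'   `(i, j, kind, epsilon, provenance)` with i < j covering all residue
#'   pairs, plus attribute `epsilon`.
#' @export
merge_multistate <- function(monomer_map, fibril_map, dense_map = NULL,
                             topology, epsilon, threshold = 0.05) {
  stopifnot(inherits(topology, "chain_topology"), epsilon > 0)
  ridx <- unique(topology$atoms$residue_index)
  dom <- topology$domains
  has_flank <- any(dom %in% c("N17", "P5"))
  if (has_flank && is.null(dense_map)) {
    stop("topology has flanking domains but no dense-phase map was given")
  }
  check_map <- function(m) {
    if (is.null(m)) return(invisible(NULL))
    if (!all(c(m$i, m$j) %in% ridx)) {
      stop("contact map residue indices collide with the declared topology")
    }
  }
  check_map(monomer_map); check_map(fibril_map); check_map(dense_map)
  lookup <- function(m, i, j) {
    if (is.null(m) || nrow(m) == 0L) return(0)
    hit <- m$probability[(m$i == i & m$j == j) | (m$i == j & m$j == i)]
    if (length(hit) == 0L) 0 else max(hit)
  }
  pairs <- which(upper.tri(diag(length(ridx))), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- ridx[pairs[k, 1L]]; j <- ridx[pairs[k, 2L]]
    di <- dom[pairs[k, 1L]]; dj <- dom[pairs[k, 2L]]
    flank_i <- di %in% c("N17", "P5"); flank_j <- dj %in% c("N17", "P5")
    if ((flank_i && dj == "QCORE") || (flank_j && di == "QCORE")) {
      return(data.frame(i = i, j = j, kind = "REPULSIVE", epsilon = NA_real_,
                        provenance = "excluded_volume"))
    }
    if (di == "QCORE" && dj == "QCORE") {
      pf <- lookup(fibril_map, i, j); pm <- lookup(monomer_map, i, j)
      if (pf >= threshold) {
        return(data.frame(i = i, j = j, kind = "ATTRACTIVE", epsilon = epsilon,
                          provenance = "fibril"))
      }
      if (pm >= threshold) {
        return(data.frame(i = i, j = j, kind = "ATTRACTIVE", epsilon = epsilon,
                          provenance = "monomer"))
      }
      return(data.frame(i = i, j = j, kind = "REPULSIVE", epsilon = NA_real_,
                        provenance = "non_native"))
    }
    if (flank_i && flank_j) {
      if (lookup(dense_map, i, j) >= threshold) {
        return(data.frame(i = i, j = j, kind = "ATTRACTIVE", epsilon = epsilon,
                          provenance = "dense"))
      }
      return(data.frame(i = i, j = j, kind = "REPULSIVE", epsilon = NA_real_,
                        provenance = "non_native"))
    }
    data.frame(i = i, j = j, kind = "REPULSIVE", epsilon = NA_real_,
               provenance = "non_native")
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("model_parameters", "data.frame"),
            epsilon = epsilon)
}

#' Write / read a model-parameter table
#'
#' Tab-separated with header `i j kind epsilon provenance`;
#' `read_params(write_params(x))` is the identity.
#'
#' @param params a `model_parameters` table.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "character",
                                         "numeric", "character"))
  if (!all(df$kind %in% c("ATTRACTIVE", "REPULSIVE"))) {
    stop("unknown kind token in ", path)
  }
  key <- paste(pmin(df$i, df$j), pmax(df$i, df$j))
  if (anyDuplicated(key) > 0L) stop("duplicate (i, j) pair in ", path)
  eps <- df$epsilon[df$kind == "ATTRACTIVE"]
  structure(df, class = c("model_parameters", "data.frame"),
            epsilon = if (length(eps)) eps[1L] else NA_real_)
}
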