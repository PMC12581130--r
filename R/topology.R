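## io_core data model: ChainTopology, Frame, Trajectory.
##
## Conventions: coordinates in Angstrom, times in ns, residue indices 1-based.
## A Frame stores one global N x 3 coordinate matrix covering all chains in
## topology order; chain_topology$atoms maps rows of that matrix to atoms.

#' Chain topology
#'
#' Describes one polypeptide chain: ordered residues, their atoms, and a
#' per-residue domain label used to mark flanking domains of huntingtin
#' exon-1-like constructs (N17 / QCORE / P5 / NONE).
#'
#' @param chain_id single character chain identifier.
#' @param atoms data.frame with columns `residue_index` (1-based int,
#'   non-decreasing by block), `residue_name` (3-letter code), `atom_name`,
#'   `element`.
#' @param domains optional named assignment of domain labels: a character
#'   vector with one entry per residue, values in
#'   `c("N17", "QCORE", "P5", "NONE")`. Defaults to `"NONE"`.
#' @return object of class `chain_topology`.
#' @export
chain_topology <- function(chain_id, atoms, domains = NULL) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("residue_index", "residue_name", "atom_name", "element")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  ridx <- unique(atoms$residue_index)
  if (any(diff(ridx) <= 0)) stop("residue indices must be strictly increasing")
  ## atom names unique within each residue
  dup <- tapply(atoms$atom_name, atoms$residue_index,
                function(x) anyDuplicated(x) > 0L)
  if (any(dup)) stop("duplicate atom names within a residue")
  if (is.null(domains)) domains <- rep("NONE", length(ridx))
  domains <- as.character(domains)
  if (length(domains) != length(ridx)) {
    stop("domains must have one label per residue")
  }
  if (!all(domains %in% c("N17", "QCORE", "P5", "NONE"))) {
    stop("domain labels must be N17, QCORE, P5 or NONE")
  }
  ## contiguity: each label occupies one contiguous block
  r <- rle(domains)
  if (anyDuplicated(r$values[r$values != "NONE"]) > 0L) {
    stop("domain labels must form contiguous blocks along the chain")
  }
  structure(list(chain_id = chain_id, atoms = atoms, domains = domains),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology %s: %d residues, %d atoms>\n",
              x$chain_id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

n_residues <- function(topology) length(unique(topology$atoms$residue_index))

#' Assign domain labels from spans
#'
#' Domain labels come from configuration (sequence spans), never from residue
#' identity, so arbitrary flanking sequences work.
#'
#' @param topology a `chain_topology`.
#' @param spans named list like `list(N17 = c(1, 17), QCORE = c(18, 33))`,
#'   residue indices inclusive.
#' @return the topology with updated domain labels.
#' @export
assign_domains <- function(topology, spans) {
  ridx <- unique(topology$atoms$residue_index)
  lab <- rep("NONE", length(ridx))
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    lab[ridx >= sp[1L] & ridx <= sp[2L]] <- nm
  }
  chain_topology(topology$chain_id, topology$atoms, lab)
}

#' Coordinate frame
#'
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param time time in ns.
#' @param box orthorhombic box edge lengths (Angstrom), length 3, or `NULL`
#'   for a non-periodic frame.
#' @param periodic_axes character subset of `c("X","Y","Z")`; axes on which
#'   the system interacts with its periodic image. Semi-infinite fibril
#'   setups are periodic in X and Y only.
#' @return object of class `frame`.
#' @export
new_frame <- function(coords, time = 0, box = NULL, periodic_axes = character()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  periodic_axes <- toupper(periodic_axes)
  if (!all(periodic_axes %in% c("X", "Y", "Z"))) {
    stop("periodic_axes must be a subset of X, Y, Z")
  }
  if (length(periodic_axes) > 0L) {
    if (is.null(box)) stop("periodic frame requires a box")
    ax <- match(periodic_axes, c("X", "Y", "Z"))
    if (any(!is.finite(box[ax])) || any(box[ax] <= 0)) {
      stop("box edges must be > 0 on periodic axes")
    }
  }
  structure(list(time = time, coords = coords, box = box,
                 periodic_axes = periodic_axes),
            class = "frame")
}

#' Trajectory: shared topology plus ordered frames
#'
#' @param topologies list of `chain_topology` (one per chain).
#' @param frames list of `frame`s; all must match the total atom count and
#'   have non-decreasing times.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topologies, frames) {
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  natom <- sum(vapply(topologies, function(t) nrow(t$atoms), integer(1L)))
  times <- vapply(frames, function(f) f$time, numeric(1L))
  for (f in frames) {
    if (nrow(f$coords) != natom) {
      stop("frame coordinate count (", nrow(f$coords),
           ") does not match topology atom count (", natom, ")")
    }
  }
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  structure(list(topologies = topologies, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d chains, %d frames, %d atoms>\n",
              length(x$topologies), length(x$frames),
              nrow(x$frames[[1L]]$coords)))
  invisible(x)
}

#' Flat atom table across all chains
#'
#' @param topologies list of `chain_topology` or a `trajectory`.
#' @return data.frame with columns chain_id, chain (integer), residue_index,
#'   residue_name, atom_name, element, domain, and `atom` (row in the global
#'   coordinate matrix).
#' @export
atom_table <- function(topologies) {
  if (inherits(topologies, "trajectory")) topologies <- topologies$topologies
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  out <- vector("list", length(topologies))
  for (i in seq_along(topologies)) {
    tp <- topologies[[i]]
    ridx <- unique(tp$atoms$residue_index)
    dom <- tp$domains[match(tp$atoms$residue_index, ridx)]
    out[[i]] <- data.frame(chain_id = tp$chain_id, chain = i,
                           tp$atoms, domain = dom,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$atom <- seq_len(nrow(tab))
  tab
}

## Heavy-atom mask (everything but hydrogen).
is_heavy <- function(tab) !(tab$element %in% c("H", "D"))

#' Minimum-image displacement and distance
#'
#' Euclidean distance minimized over periodic images on the frame's periodic
#' axes only; non-periodic axes use the plain difference.
#'
#' @param p1,p2 xyz vectors or N x 3 matrices (paired rows).
#' @param frame a `frame` carrying box and periodic axes (or `NULL` box for
#'   fully non-periodic).
#' @return distances (Angstrom), one per row.
#' @export
min_image_distance <- function(p1, p2, frame) {
  d <- min_image_disp(rbind(p2), rbind(p1), frame)
  unname(sqrt(rowSums(d * d)))
}

## Displacement p - q with minimum-image convention applied per periodic axis.
min_image_disp <- function(p, q, frame) {
  d <- p - q
  ax <- match(frame$periodic_axes, c("X", "Y", "Z"))
  for (a in ax) {
    L <- frame$box[a]
    if (!is.finite(L) || L <= 0) stop("zero or invalid box edge on periodic axis")
    d[, a] <- d[, a] - L * round(d[, a] / L)
  }
  d
}

#' Unwrap chain coordinates across periodic boundaries
#'
#' Makes each chain whole by walking its atoms in order and applying the
#' minimum-image displacement relative to the previous atom. Used by shape
#' metrics (end-to-end distance, radius of gyration) which are meaningless
#' on wrapped coordinates.
#'
#' @param frame a `frame`.
#' @param tab atom table (from [atom_table()]).
#' @return N x 3 matrix of unwrapped coordinates.
#' @export
unwrap_coords <- function(frame, tab) {
  xyz <- frame$coords
  if (length(frame$periodic_axes) == 0L) return(xyz)
  out <- xyz
  for (ch in unique(tab$chain)) {
    idx <- tab$atom[tab$chain == ch]
    for (k in seq_along(idx)[-1L]) {
      d <- min_image_disp(rbind(xyz[idx[k], ]), rbind(out[idx[k - 1L], ]), frame)
      out[idx[k], ] <- out[idx[k - 1L], ] + d[1L, ]
    }
  }
  out
}
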