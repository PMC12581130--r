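## Standard-format structure I/O: PDB (single and multi-model) and GRO.
## Internally everything is Angstrom; GRO files are nm on disk.

KNOWN_ELEMENTS <- c("C", "N", "O", "S", "H", "P", "D", "FE", "ZN", "NA", "CL", "MG", "K")

infer_element <- function(atom_name) {
  s <- gsub("[0-9' ]", "", atom_name)
  two <- toupper(substr(s, 1L, 2L))
  one <- toupper(substr(s, 1L, 1L))
  ifelse(two %in% c("FE", "ZN", "NA", "CL", "MG"), two, one)
}

#' Read a structure file
#'
#' @param path file path.
#' @param format `"PDB"` or `"GRO"`; default guessed from the extension.
#' @return list with `topologies` (list of [chain_topology()]) and `frame`
#'   (a [new_frame()]). A missing box yields a non-periodic frame.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- toupper(format %||% tools::file_ext(path))
  switch(format,
         PDB = read_pdb(path),
         GRO = read_gro(path),
         stop("unknown structure format: ", format))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1L, 6L)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0L) stop("no ATOM records in ", path)
  ln <- lines[sel]
  x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0L) {
    stop("malformed ATOM record at line ", sel[bad[1L]], " of ", path)
  }
  resseq <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
  if (anyNA(resseq)) {
    stop("malformed residue number at line ", sel[which(is.na(resseq))[1L]],
         " of ", path)
  }
  elem <- trimws(substr(ln, 77L, 78L))
  name <- trimws(substr(ln, 13L, 16L))
  noel <- !nzchar(elem) | !(toupper(elem) %in% KNOWN_ELEMENTS)
  if (any(noel)) {
    warning("element missing/unknown for ", sum(noel),
            " atoms; inferred from atom names")
    elem[noel] <- infer_element(name[noel])
  }
  data.frame(chain_id = substr(ln, 22L, 22L),
             residue_index = resseq,
             residue_name = trimws(substr(ln, 18L, 20L)),
             atom_name = name,
             element = toupper(elem),
             x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

split_chains <- function(tab) {
  ## blank chain ids become "A"; chains split on id change (not value) so
  ## re-used ids in weird files still split.
  id <- ifelse(tab$chain_id == " ", "A", tab$chain_id)
  brk <- cumsum(c(1L, as.integer(id[-1L] != id[-length(id)])))
  tops <- list()
  for (b in unique(brk)) {
    sub <- tab[brk == b, , drop = FALSE]
    tops[[length(tops) + 1L]] <- chain_topology(
      id[brk == b][1L],
      sub[, c("residue_index", "residue_name", "atom_name", "element")])
  }
  tops
}

read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) > 0L) {
    b <- suppressWarnings(as.numeric(c(substr(cry[1L], 7L, 15L),
                                       substr(cry[1L], 16L, 24L),
                                       substr(cry[1L], 25L, 33L))))
    if (all(is.finite(b)) && all(b > 0)) box <- b
  }
  mstart <- grep("^MODEL", lines)
  if (length(mstart) <= 1L) {
    tab <- parse_pdb_atoms(lines, path)
    tops <- split_chains(tab)
    frame <- new_frame(as.matrix(tab[, c("x", "y", "z")]), time = 0, box = box)
    return(list(topologies = tops, frame = frame))
  }
  ## multi-model: frames share topology of the first model
  mend <- grep("^ENDMDL", lines)
  if (length(mend) != length(mstart)) stop("unbalanced MODEL/ENDMDL in ", path)
  frames <- vector("list", length(mstart))
  tops <- NULL
  for (k in seq_along(mstart)) {
    tab <- parse_pdb_atoms(lines[(mstart[k] + 1L):(mend[k] - 1L)], path)
    if (k == 1L) tops <- split_chains(tab)
    frames[[k]] <- new_frame(as.matrix(tab[, c("x", "y", "z")]),
                             time = k - 1, box = box)
  }
  list(topologies = tops, frame = frames[[1L]], frames = frames)
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  natom <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natom)) stop("malformed atom-count line (line 2) of ", path)
  if (length(lines) < 2L + natom + 1L) stop("truncated GRO file: ", path)
  ln <- lines[3L:(2L + natom)]
  resseq <- suppressWarnings(as.integer(substr(ln, 1L, 5L)))
  x <- suppressWarnings(as.numeric(substr(ln, 21L, 28L))) * 10
  y <- suppressWarnings(as.numeric(substr(ln, 29L, 36L))) * 10
  z <- suppressWarnings(as.numeric(substr(ln, 37L, 44L))) * 10
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resseq))
  if (length(bad) > 0L) stop("malformed GRO record at line ", 2L + bad[1L],
                             " of ", path)
  name <- trimws(substr(ln, 11L, 15L))
  tab <- data.frame(chain_id = "A",
                    residue_index = resseq,
                    residue_name = trimws(substr(ln, 6L, 10L)),
                    atom_name = name,
                    element = infer_element(name),
                    x = x, y = y, z = z, stringsAsFactors = FALSE)
  ## GRO has no chain column: start a new chain whenever resid decreases
  n <- length(resseq)
  newc <- cumsum(c(0L, as.integer(diff(resseq) < 0L)))
  tab$chain_id <- LETTERS[(newc %% 26L) + 1L]
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + natom + 1L]),
                                               "\\s+")[[1L]]))
  box <- if (length(boxv) >= 3L && all(is.finite(boxv[1:3])) &&
             all(boxv[1:3] > 0)) boxv[1:3] * 10 else NULL
  list(topologies = split_chains(tab),
       frame = new_frame(as.matrix(tab[, c("x", "y", "z")]), box = box))
}

## hybrid-36 encoding for PDB serial numbers > 99999
hy36_encode <- function(n, width = 5L) {
  if (n < 10^width) return(formatC(n, width = width))
  digits <- c(0:9, LETTERS)
  m <- n - 10^width + 26 * 36^(width - 1L)
  out <- character(width)
  for (i in width:1) {
    out[i] <- digits[(m %% 36) + 1L]
    m <- m %/% 36
  }
  paste(out, collapse = "")
}

#' Write a structure file
#'
#' Multi-chain PDB output uses distinct chain identifiers and TER records and
#' round-trips through [read_structure()] with lossless residue/atom ordering
#' (coordinates to 1e-3 Angstrom, the PDB field precision).
#'
#' @param topologies list of [chain_topology()] (or one).
#' @param frame a [new_frame()] (or, for `"PDB"`, a list of frames written as
#'   MODEL blocks).
#' @param path output path.
#' @param format `"PDB"` or `"GRO"`.
#' @param allow_hybrid36 if `TRUE`, atom serials beyond 99999 use hybrid-36
#'   encoding; otherwise such systems are an error.
#' @export
write_structure <- function(topologies, frame, path, format = NULL,
                            allow_hybrid36 = TRUE) {
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  if (length(topologies) == 0L) stop("empty chain list")
  format <- toupper(format %||% tools::file_ext(path))
  frames <- if (inherits(frame, "frame")) list(frame) else frame
  for (f in frames) {
    if (!all(is.finite(f$coords))) stop("non-finite coordinates")
  }
  tab <- atom_table(topologies)
  if (format == "PDB") {
    write_pdb(tab, frames, path, allow_hybrid36)
  } else if (format == "GRO") {
    write_gro(tab, frames[[1L]], path)
  } else stop("unknown structure format: ", format)
  invisible(path)
}

write_pdb <- function(tab, frames, path, allow_hybrid36) {
  n <- nrow(tab)
  if (n > 99999L && !allow_hybrid36) {
    stop("more than 99,999 atoms; enable allow_hybrid36 or split the system")
  }
  serial <- vapply(seq_len(n), hy36_encode, character(1L))
  multi <- length(frames) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1L]]$box
  if (!is.null(box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1L], box[2L], box[3L], 90, 90, 90), con)
  }
  name4 <- ifelse(nchar(tab$atom_name) < 4L,
                  sprintf(" %-3s", tab$atom_name), tab$atom_name)
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frames[[k]]$coords
    lines <- sprintf("ATOM  %5s %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     serial, name4, tab$residue_name,
                     substr(tab$chain_id, 1L, 1L), tab$residue_index,
                     xyz[, 1L], xyz[, 2L], xyz[, 3L], tab$element)
    ## insert TER after each chain
    out <- split(lines, tab$chain)
    for (ch in out) {
      writeLines(ch, con)
      writeLines("TER", con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_gro <- function(tab, frame, path) {
  xyz <- frame$coords / 10
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   tab$residue_index %% 100000L, tab$residue_name,
                   tab$atom_name, tab$atom %% 100000L,
                   xyz[, 1L], xyz[, 2L], xyz[, 3L])
  box <- (frame$box %||% c(0, 0, 0)) / 10
  writeLines(c("generated by qzipper", sprintf("%5d", nrow(tab)), lines,
               sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L])),
             path)
}

#' Read a trajectory from a multi-model PDB
#'
#' @param path multi-model PDB file.
#' @param times optional vector of frame times (ns); defaults to 0,1,2,...
#' @param periodic_axes axes on which frames are periodic (requires a CRYST1
#'   box in the file).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, times = NULL, periodic_axes = character()) {
  s <- read_pdb(path)
  frames <- s$frames %||% list(s$frame)
  if (!is.null(times)) {
    if (length(times) != length(frames)) stop("times length != frame count")
    for (k in seq_along(frames)) frames[[k]]$time <- times[k]
  }
  if (length(periodic_axes) > 0L) {
    for (k in seq_along(frames)) {
      frames[[k]] <- new_frame(frames[[k]]$coords, frames[[k]]$time,
                               frames[[k]]$box, periodic_axes)
    }
  }
  trajectory(s$topologies, frames)
}

#' Read a JSON run configuration
#'
#' Structured configs (sequence, domain spans, box, periodic axes, rates)
#' are JSON files; see the vignette for the schema of each stage.
#'
#' @param path JSON file.
#' @return named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
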