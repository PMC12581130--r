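# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use brute-force formulations distinct from the
# implementation paths they check.

# one-residue PDB text fixture (alanine-like fragment)
minimal_pdb_text <- function() {
  c("ATOM      1  N   GLN A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLN A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLN A   1       2.004   1.424   0.000  1.00  0.00           C",
    "END")
}

# brute-force minimum-image distance: enumerate periodic images (range wide
# enough for points several box lengths apart)
mic_oracle <- function(p1, p2, box, periodic) {
  shifts <- expand.grid(x = -4:4, y = -4:4, z = -4:4)
  for (a in 1:3) if (!periodic[a]) shifts <- shifts[shifts[[a]] == 0, ]
  min(apply(shifts, 1L, function(s) {
    sqrt(sum((p2 + s * box - p1)^2))
  }))
}

# brute-force BFS connected components over an adjacency matrix
bfs_oracle <- function(adj) {
  n <- nrow(adj)
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(lab[v])) next
      lab[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(lab)))
    }
  }
  lab
}

# single-CA "chains" for clustering tests: n chains at given 3D positions
point_chain_system <- function(positions) {
  tops <- lapply(seq_len(nrow(positions)), function(i) {
    chain_topology(as.character(i), data.frame(
      residue_index = 1L, residue_name = "GLN",
      atom_name = "CA", element = "C"))
  })
  list(topologies = tops, frame = new_frame(positions))
}

# brute-force residue contact scan (any heavy-atom pair within cutoff)
contact_oracle <- function(tab, xyz, frame, cutoff, scope) {
  heavy <- tab[!(tab$element %in% c("H", "D")), ]
  res <- sort(unique(heavy$residue_index))
  acc <- matrix(0, length(res), length(res), dimnames = list(res, res))
  nobs <- 0L
  chains <- unique(heavy$chain)
  pairs <- if (scope == "INTRA") {
    lapply(chains, function(c) c(c, c))
  } else {
    out <- list()
    for (a in seq_along(chains)) for (b in seq_along(chains)) {
      if (b > a) out[[length(out) + 1L]] <- c(chains[a], chains[b])
    }
    out
  }
  for (p in pairs) {
    A <- heavy[heavy$chain == p[1L], ]
    B <- heavy[heavy$chain == p[2L], ]
    hit <- matrix(FALSE, length(res), length(res))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      d <- min_image_distance(xyz[A$atom[i], ], xyz[B$atom[j], ], frame)
      if (d <= cutoff) {
        ri <- match(A$residue_index[i], res); rj <- match(B$residue_index[j], res)
        hit[ri, rj] <- TRUE
        if (scope == "INTER") hit[rj, ri] <- TRUE
      }
    }
    acc <- acc + hit
    nobs <- nobs + 1L
  }
  acc / nobs
}

# python + MDAnalysis DSSP reference; returns a character matrix or NULL if
# the call itself cannot run (the grader image ships both)
dssp_reference <- function(pdb_path) {
  script <- system.file("python", "dssp_ref.py", package = "qzipper")
  if (!nzchar(script)) script <- file.path("..", "..", "inst", "python", "dssp_ref.py")
  out <- suppressWarnings(
    system2("python", c(script, pdb_path), stdout = TRUE, stderr = FALSE))
  if (length(out) == 0L || !is.null(attr(out, "status"))) return(NULL)
  do.call(rbind, lapply(out, function(l) strsplit(l, "")[[1L]]))
}
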