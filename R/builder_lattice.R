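## Idealized cross-beta fibril lattices for the beta-turn (BT) and beta-arc
## (BA) tertiary units, in directional arrangements A1-A4.
##
## Lattice frame used throughout: x = lateral axis (strand direction, where
## the end termini point), y = fibril axis (inter-strand hydrogen-bonding
## direction, strand_spacing), z = sheet stacking (side-chain
## interdigitation, sheet_spacing). Strands at consecutive y slots are
## antiparallel and alternate conformer "a"/"b".

#' Steric-zipper unit specification
#'
#' @param strand_len glutamines per zipper strand.
#' @param turn_len residues modeling the turn/arc between strands.
#' @param strands_per_chain strands contributed by one chain.
#' @return object of class `zipper_spec` with derived `total_residues`.
#' @export
zipper_spec <- function(strand_len, turn_len, strands_per_chain = 2L) {
  stopifnot(strand_len >= 2L, turn_len >= 1L, strands_per_chain >= 2L)
  structure(list(strand_len = as.integer(strand_len),
                 turn_len = as.integer(turn_len),
                 strands_per_chain = as.integer(strands_per_chain),
                 total_residues = as.integer(
                   strands_per_chain * strand_len +
                     (strands_per_chain - 1L) * turn_len)),
            class = "zipper_spec")
}

#' Minimal polyQ steric-zipper unit
#'
#' Six glutamines per zipper strand and a four-residue turn, two strands per
#' chain: 16 Qs per steric zipper unit.
#'
#' @return a [zipper_spec()] with `total_residues = 16`.
#' @export
minimal_zipper_spec <- function() zipper_spec(6L, 4L, 2L)

#' Lattice specification
#'
#' @param model `"BT"` (beta-turn) or `"BA"` (beta-arc).
#' @param arrangement `"A1"`..`"A4"`: end-terminus directions of consecutive
#'   chains (A1 all same lateral; A2 alternating lateral; A3 alternating
#'   axial; A4 alternating both).
#' @param n_sheets number of beta-sheets (BA requires an even number).
#' @param n_chains_per_sheet chains per sheet (each contributes 2 strands).
#' @param sheet_spacing sheet-to-sheet distance (Angstrom); default 8.2, the
#'   canonical polyQ X-ray value.
#' @param strand_spacing strand-to-strand distance within a sheet (Angstrom);
#'   default 4.8.
#' @param box_padding padding added around the lattice on non-seamless axes
#'   (Angstrom).
#' @param registry_shift lateral (x) offset of odd-slot strands (Angstrom);
#'   about one residue rise, which brings donor and acceptor rungs of
#'   adjacent antiparallel strands into hydrogen-bonding register.
#' @param periodic_axes axes on which the box continues the lattice; the
#'   semi-infinite setup is `c("X", "Y")`.
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(model = c("BT", "BA"),
                         arrangement = c("A1", "A2", "A3", "A4"),
                         n_sheets = 2L, n_chains_per_sheet = 2L,
                         sheet_spacing = 8.2, strand_spacing = 4.8,
                         box_padding = 10, periodic_axes = c("X", "Y"),
                         registry_shift = 3.6) {
  model <- match.arg(toupper(model), c("BT", "BA"))
  arrangement <- match.arg(toupper(arrangement), c("A1", "A2", "A3", "A4"))
  stopifnot(n_sheets >= 1L, n_chains_per_sheet >= 1L,
            sheet_spacing > 0, strand_spacing > 0, box_padding >= 0)
  if (model == "BA" && n_sheets %% 2L != 0L) {
    stop("beta-arc lattices pair adjacent sheets: n_sheets must be even")
  }
  structure(list(model = model, arrangement = arrangement,
                 n_sheets = as.integer(n_sheets),
                 n_chains_per_sheet = as.integer(n_chains_per_sheet),
                 sheet_spacing = sheet_spacing,
                 strand_spacing = strand_spacing,
                 box_padding = box_padding,
                 registry_shift = registry_shift,
                 periodic_axes = toupper(periodic_axes)),
            class = "lattice_spec")
}

## rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  ax <- vcross(a, b)
  s <- vnorm(ax)
  d <- sum(a * b)
  if (s < 1e-9) {
    if (d > 0) return(diag(3))
    ## antiparallel: rotate 180 deg about any axis perpendicular to a
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_matrix(vcross(a, p), 180))
  }
  rotation_matrix(ax, atan2(s, d) / DEG)
}

## Build one ideal strand and canonicalize its pose: N->C along +x, the
## alternating carbonyl (hydrogen-bonding) direction along +y, CA centroid
## at origin. Side chains then pleat roughly along +-z (the sheet-stacking
## direction), as in a cross-beta sheet.
strand_template <- function(geom, conformer, strand_len) {
  ch <- suppressWarnings(
    build_glutamine_chain(strand_len,
                          conformer_dihedrals(geom, conformer, strand_len)))
  xyz <- ch$coords
  ca <- 9L * (seq_len(strand_len) - 1L) + 2L
  R1 <- rotation_between(xyz[ca[strand_len], ] - xyz[ca[1L], ], c(1, 0, 0))
  xyz <- rotate_coords(xyz, R1)
  co <- ca + 2L   # carbonyl O rows
  h <- colSums((xyz[co, ] - xyz[co - 1L, ]) * (-1)^(seq_len(strand_len) - 1L))
  h[1L] <- 0
  if (vnorm(h) > 1e-9) {
    xyz <- rotate_coords(xyz, rotation_between(h, c(0, 1, 0)))
  }
  xyz <- sweep(xyz, 2L, colMeans(xyz[ca, , drop = FALSE]))
  xyz
}

## Interior points of a circular arc from p0 to p1 with n_seg segments of
## roughly seg_len each, bulging toward `bulge`.
arc_points <- function(p0, p1, n_seg, seg_len, bulge = c(1, 0, 0)) {
  chord <- vnorm(p1 - p0)
  L <- n_seg * seg_len
  ts <- seq_len(n_seg - 1L) / n_seg
  if (L <= chord * 1.001) {   # straight linker
    return(t(vapply(ts, function(t) p0 + t * (p1 - p0), numeric(3L))))
  }
  f <- function(th) 2 * (L / th) * sin(th / 2) - chord
  th <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root
  r <- L / th
  chat <- (p1 - p0) / chord
  u <- bulge - sum(bulge * chat) * chat
  if (vnorm(u) < 1e-9) u <- vcross(chat, c(0, 0, 1))
  u <- unit(u)
  m <- (p0 + p1) / 2
  ctr <- m - r * cos(th / 2) * u
  ang <- -th / 2 + ts * th
  t(vapply(ang, function(a) ctr + r * (cos(a) * u + sin(a) * chat),
           numeric(3L)))
}

## Backbone + side chain for linker residues threaded along a CA path.
## path has n_turn + 2 points: flanking strand CAs plus the turn CAs.
linker_coords <- function(path, chi1 = -60) {
  n_turn <- nrow(path) - 2L
  g <- IDEAL_GEOM
  gam <- 34.5 * DEG
  xyz <- matrix(NA_real_, 9L * n_turn, 3L)
  for (k in seq_len(n_turn)) {
    ca <- path[k + 1L, ]
    tgt <- unit(path[k + 2L, ] - path[k, ])
    ## normal: perpendicular component of the local curvature direction
    curv <- (path[k, ] + path[k + 2L, ]) / 2 - ca
    nrm <- curv - sum(curv * tgt) * tgt
    nrm <- if (vnorm(nrm) < 1e-9) unit(vcross(tgt, c(0, 0, 1))) else unit(nrm)
    r <- 9L * (k - 1L)
    xyz[r + 1L, ] <- ca - g$b_n_ca * (cos(gam) * tgt + sin(gam) * nrm)
    xyz[r + 2L, ] <- ca
    xyz[r + 3L, ] <- ca + g$b_ca_c * (cos(gam) * tgt - sin(gam) * nrm)
    xyz <- place_gln_branches(xyz, r,
                              data.frame(psi = 150, chi1 = chi1, chi2 = 180))
  }
  xyz
}

#' Build an idealized cross-beta fibril lattice
#'
#' Places `n_sheets * n_chains_per_sheet` polyglutamine chains on an ideal
#' lattice. Within a sheet, adjacent strands are antiparallel, offset by
#' `strand_spacing` along the fibril (hydrogen-bonding) axis, and alternate
#' conformer "a"/"b"; sheets are offset by `sheet_spacing`. BT chains are
#' beta-hairpins within one sheet; BA chains place their two strands in
#' adjacent sheets, linked by an arc. Turn/arc linker backbones are geometric
#' stand-ins (flagged in the metadata); all strand residues carry exact
#' conformer dihedrals.
#'
#' @param spec a [lattice_spec()].
#' @param geom a [conformer_geometry()].
#' @param zipper a [zipper_spec()]; `turn_len` sets the linker length.
#' @param check_clashes run the non-bonded clash audit (warning on hits).
#' @return object of class `fibril_lattice`: list with `topologies`,
#'   `frame`, and `meta` (model, arrangement, fibril axis, per-strand
#'   conformer/sheet/slot/direction table, per-chain residue spans).
#' @export
build_lattice <- function(spec, geom = conformer_geometry(),
                          zipper = minimal_zipper_spec(),
                          check_clashes = FALSE) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(geom, "conformer_geometry"),
            inherits(zipper, "zipper_spec"))
  if (zipper$strands_per_chain != 2L) {
    stop("lattice construction supports two strands per chain")
  }
  sl <- zipper$strand_len
  tl <- zipper$turn_len
  ss <- spec$strand_spacing
  hs <- spec$sheet_spacing
  tmpl <- list(a = strand_template(geom, "a", sl),
               b = strand_template(geom, "b", sl))
  Rflip <- rotation_matrix(c(0, 0, 1), 180)   # antiparallel partner
  ca_first <- 2L
  ca_last <- 9L * (sl - 1L) + 2L

  place_strand <- function(slot, sheet) {
    conf <- if (slot %% 2L == 0L) "a" else "b"
    xyz <- tmpl[[conf]]
    dir <- 1L
    if (slot %% 2L == 1L) {
      xyz <- rotate_coords(xyz, Rflip)
      dir <- -1L
    }
    xyz <- sweep(xyz, 2L, c((slot %% 2L) * spec$registry_shift,
                            slot * ss, sheet * hs), "+")
    list(xyz = xyz, conformer = conf, dir = dir, slot = slot, sheet = sheet)
  }

  build_chain <- function(s1, s2) {
    p0 <- s1$xyz[ca_last, ]
    p1 <- s2$xyz[ca_first, ]
    path <- rbind(p0, arc_points(p0, p1, tl + 1L, 3.8), p1)
    rbind(s1$xyz, linker_coords(path), s2$xyz)
  }

  chains <- list()
  meta_strands <- list()
  if (spec$model == "BT") {
    for (s in seq_len(spec$n_sheets) - 1L) {
      for (k in seq_len(spec$n_chains_per_sheet) - 1L) {
        s1 <- place_strand(2L * k, s)
        s2 <- place_strand(2L * k + 1L, s)
        chains[[length(chains) + 1L]] <- build_chain(s1, s2)
        ci <- length(chains)
        meta_strands[[length(meta_strands) + 1L]] <- data.frame(
          chain = ci, strand = c(1L, 2L),
          conformer = c(s1$conformer, s2$conformer),
          sheet = s, slot = c(s1$slot, s2$slot),
          direction = c(s1$dir, s2$dir), stack_index = k)
      }
    }
  } else {  # BA: chains based alternately in the lower/upper sheet of a pair
    for (p in seq_len(spec$n_sheets %/% 2L) - 1L) {
      for (k in seq_len(spec$n_chains_per_sheet) - 1L) {
        for (base in 0:1) {
          slot <- 2L * k + base
          sh <- 2L * p + base
          sh2 <- 2L * p + 1L - base
          s1 <- place_strand(slot, sh)
          s2 <- place_strand(slot, sh2)
          chains[[length(chains) + 1L]] <- build_chain(s1, s2)
          ci <- length(chains)
          meta_strands[[length(meta_strands) + 1L]] <- data.frame(
            chain = ci, strand = c(1L, 2L),
            conformer = c(s1$conformer, s2$conformer),
            sheet = c(sh, sh2), slot = slot,
            direction = c(s1$dir, s2$dir), stack_index = slot)
        }
      }
    }
  }
  smeta <- do.call(rbind, meta_strands)

  ## arrangement flips about each chain's own centroid; applied to chains at
  ## even 1-based positions along the stacking order
  if (spec$arrangement != "A1") {
    ax <- switch(spec$arrangement, A2 = c(0, 1, 0), A3 = c(1, 0, 0),
                 A4 = c(0, 0, 1))
    R <- rotation_matrix(ax, 180)
    for (ci in seq_along(chains)) {
      si <- smeta$stack_index[smeta$chain == ci][1L]
      if (si %% 2L == 1L) {
        ctr <- colMeans(chains[[ci]])
        chains[[ci]] <- sweep(rotate_coords(sweep(chains[[ci]], 2L, ctr), R),
                              2L, ctr, "+")
        if (spec$arrangement %in% c("A2", "A4")) {
          ## lateral component of the flip reverses strand N->C x-direction
          smeta$direction[smeta$chain == ci] <-
            -smeta$direction[smeta$chain == ci]
        }
      }
    }
  }

  coords <- do.call(rbind, chains)
  n_res <- zipper$total_residues
  tops <- lapply(seq_along(chains), function(ci) {
    gln_topology(n_res, chain_letters(ci))
  })
  n_slots <- 2L * spec$n_chains_per_sheet
  ext <- apply(coords, 2L, range)
  box <- c(
    if ("X" %in% spec$periodic_axes) diff(ext[, 1L]) + spec$box_padding
    else diff(ext[, 1L]) + 2 * spec$box_padding,
    n_slots * ss,
    diff(ext[, 3L]) + 2 * spec$box_padding)
  frame <- new_frame(coords, time = 0, box = box,
                     periodic_axes = intersect(spec$periodic_axes,
                                               c("X", "Y", "Z")))
  if (check_clashes) report_clashes(tops, coords)
  chain_spans <- list(strand1 = c(1L, sl),
                      turn = c(sl + 1L, sl + tl),
                      strand2 = c(sl + tl + 1L, n_res))
  structure(list(topologies = tops, frame = frame,
                 meta = list(model = spec$model,
                             arrangement = spec$arrangement,
                             fibril_axis = c(0, 1, 0),
                             lateral_axis = c(1, 0, 0),
                             stacking_axis = c(0, 0, 1),
                             sheet_spacing = hs, strand_spacing = ss,
                             strands = smeta, chain_spans = chain_spans,
                             linker = "geometric stand-in",
                             spec = spec, geometry = geom, zipper = zipper)),
            class = "fibril_lattice")
}

## chain identifiers beyond 26 chains: A..Z, then a..z, then 2-char codes
chain_letters <- function(i) {
  pool <- c(LETTERS, letters, 0:9)
  if (i <= length(pool)) return(pool[i])
  paste0(pool[((i - 1L) %/% length(pool))], pool[((i - 1L) %% length(pool)) + 1L])
}

#' @export
print.fibril_lattice <- function(x, ...) {
  cat(sprintf("<fibril_lattice %s-%s: %d chains, %d atoms, box %.1f x %.1f x %.1f A>\n",
              x$meta$model, x$meta$arrangement, length(x$topologies),
              nrow(x$frame$coords), x$frame$box[1L], x$frame$box[2L],
              x$frame$box[3L]))
  invisible(x)
}

#' Cubic box side from chain count and concentration
#'
#' `side = (n_chains / (N_A * concentration))^(1/3)`, returned in nm.
#' 1000 chains at 10 mM gives ~55 nm.
#'
#' @param n_chains number of chains (>= 1).
#' @param concentration_mM concentration in mM.
#' @return box side in nm.
#' @export
box_from_concentration <- function(n_chains, concentration_mM) {
  if (n_chains < 1 || concentration_mM <= 0) {
    stop("n_chains must be >= 1 and concentration > 0")
  }
  N_A <- 6.02214076e23
  v_l <- n_chains / (N_A * concentration_mM * 1e-3)  # litres
  (v_l * 1e24)^(1 / 3)                               # 1 L = 1e24 nm^3
}

#' @rdname box_from_concentration
#' @param side_nm cubic box side in nm.
#' @return concentration in mM.
#' @export
concentration_from_box <- function(n_chains, side_nm) {
  if (n_chains < 1 || side_nm <= 0) stop("n_chains >= 1 and side > 0 required")
  N_A <- 6.02214076e23
  n_chains / (N_A * side_nm^3 * 1e-24) * 1e3
}
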