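## Internal-coordinate construction of polyglutamine chains.
##
## Ideal covalent geometry follows standard peptide stereochemistry
## (Engh-Huber-like values); the experimental constraints live entirely in
## the dihedral angles, which is where the ssNMR-derived conformer targets
## enter. Atom order within each Gln is fixed: N, CA, C, O, CB, CG, CD,
## OE1, NE2.

GLN_ATOMS <- c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2")
GLN_ELEMENTS <- c("N", "C", "C", "O", "C", "C", "C", "O", "N")

## ideal bond lengths (Angstrom) and angles (degrees)
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_cb_cg = 1.520, b_cg_cd = 1.516,
  b_cd_oe1 = 1.231, b_cd_ne2 = 1.328,
  a_c_n_ca = 121.7, a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, a_ca_cb_cg = 114.1, a_cb_cg_cd = 112.6,
  a_cg_cd_oe1 = 120.8, a_cg_cd_ne2 = 116.4,
  t_cb = 122.6   # torsion C-N-CA-CB fixing L-chirality
)

#' Strand conformer geometry
#'
#' The two dominant glutamine conformers ("a"/"b") seen by ssNMR in
#' antiparallel polyQ beta-sheets. Defaults for psi, chi1 and chi2 are the
#' published ssNMR-derived targets (psi 136/150 deg, chi1 -65/55 deg,
#' chi2 180 deg). phi has no printed target; the defaults are the unique
#' beta-region values that give each strand an exact two-fold screw (zero
#' twist) at the target psi, so idealized sheets are strictly periodic.
#'
#' @param phi_a,phi_b backbone phi per conformer (deg).
#' @param psi_a,psi_b backbone psi per conformer (deg).
#' @param chi1_a,chi1_b side-chain chi1 per conformer (deg).
#' @param chi2 side-chain chi2, shared by both conformers (deg).
#' @param omega peptide-bond omega, shared (deg).
#' @return object of class `conformer_geometry`.
#' @export
conformer_geometry <- function(phi_a = -138.6, phi_b = -151.8,
                               psi_a = 136, psi_b = 150,
                               chi1_a = -65, chi1_b = 55,
                               chi2 = 180, omega = 180) {
  vals <- c(phi_a, phi_b, psi_a, psi_b, chi1_a, chi1_b, chi2, omega)
  if (any(vals <= -180 | vals > 180)) stop("angles must lie in (-180, 180]")
  if (psi_a == psi_b && chi1_a == chi1_b) {
    stop("conformers a and b must differ in psi or chi1")
  }
  structure(list(phi = c(a = phi_a, b = phi_b), psi = c(a = psi_a, b = psi_b),
                 chi1 = c(a = chi1_a, b = chi1_b), chi2 = chi2, omega = omega),
            class = "conformer_geometry")
}

## per-residue dihedral row block for one conformer
conformer_dihedrals <- function(geom, conformer, n) {
  data.frame(phi = rep(geom$phi[[conformer]], n),
             psi = rep(geom$psi[[conformer]], n),
             chi1 = rep(geom$chi1[[conformer]], n),
             chi2 = rep(geom$chi2, n),
             omega = rep(geom$omega, n))
}

#' Stand-in dihedral libraries for hairpin turns and arcs
#'
#' The source figures show turn geometry but print no dihedrals, so these
#' tables are replaceable stand-ins: a type-II'-like 4-residue turn for the
#' beta-turn model and a 6-residue arc for the beta-arc model.
#'
#' @return data.frame of per-residue phi/psi/chi1/chi2/omega.
#' @export
turn_library_bt <- function() {
  data.frame(phi = c(-135, 60, -90, -120),
             psi = c(135, -120, 0, 140),
             chi1 = -60, chi2 = 180, omega = 180)
}

#' @rdname turn_library_bt
#' @export
arc_library_ba <- function() {
  data.frame(phi = c(-100, 55, -90, -120, 60, -100),
             psi = c(120, 40, 0, 130, 30, 120),
             chi1 = -60, chi2 = 180, omega = 180)
}

gln_topology <- function(n_res, chain_id = "A", start_res = 1L) {
  chain_topology(chain_id, data.frame(
    residue_index = rep(seq.int(start_res, length.out = n_res), each = 9L),
    residue_name = "GLN",
    atom_name = rep(GLN_ATOMS, n_res),
    element = rep(GLN_ELEMENTS, n_res),
    stringsAsFactors = FALSE))
}

## Place the full Gln side chain plus carbonyl O for residue at rows r
## (N, CA, C already in xyz). d = one dihedral row.
place_gln_branches <- function(xyz, r, d, g = IDEAL_GEOM) {
  N <- xyz[r + 1L, ]; CA <- xyz[r + 2L, ]; C <- xyz[r + 3L, ]
  xyz[r + 4L, ] <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o,
                              wrap_angle(d$psi + 180))           # O
  xyz[r + 5L, ] <- place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_cb)  # CB
  CB <- xyz[r + 5L, ]
  xyz[r + 6L, ] <- place_atom(N, CA, CB, g$b_cb_cg, g$a_ca_cb_cg, d$chi1) # CG
  CG <- xyz[r + 6L, ]
  xyz[r + 7L, ] <- place_atom(CA, CB, CG, g$b_cg_cd, g$a_cb_cg_cd, d$chi2) # CD
  CD <- xyz[r + 7L, ]
  xyz[r + 8L, ] <- place_atom(CB, CG, CD, g$b_cd_oe1, g$a_cg_cd_oe1, 0)    # OE1
  xyz[r + 9L, ] <- place_atom(CB, CG, CD, g$b_cd_ne2, g$a_cg_cd_ne2, 180)  # NE2
  xyz
}

#' Build a polyglutamine chain from per-residue dihedrals
#'
#' All backbone and side-chain heavy atoms are placed by internal-coordinate
#' (Z-matrix) chaining with ideal bond lengths and angles; measured dihedrals
#' of interior residues reproduce the requested values to numerical
#' precision (well within 0.5 deg).
#'
#' @param n_res number of residues (>= 2).
#' @param dihedrals data.frame with columns `phi`, `psi`, `chi1`, `chi2`
#'   (optionally `omega`), one row per residue (rows recycled if fewer).
#' @param chain_id chain identifier.
#' @param clash_cutoff non-bonded heavy-atom pairs closer than this (Angstrom)
#'   trigger a warning listing the clashes.
#' @return list with `topology` ([chain_topology()]) and `coords`
#'   (9*n_res x 3 matrix, Angstrom).
#' @export
build_glutamine_chain <- function(n_res, dihedrals, chain_id = "A",
                                  clash_cutoff = 1.8) {
  if (n_res < 2L) stop("n_res must be >= 2")
  dihedrals <- as.data.frame(dihedrals)
  if (!all(c("phi", "psi", "chi1", "chi2") %in% names(dihedrals))) {
    stop("dihedrals needs columns phi, psi, chi1, chi2")
  }
  if (is.null(dihedrals$omega)) dihedrals$omega <- 180
  if (nrow(dihedrals) == 1L) dihedrals <- dihedrals[rep(1L, n_res), ]
  if (nrow(dihedrals) != n_res) stop("dihedral table must have n_res rows")
  g <- IDEAL_GEOM
  xyz <- matrix(NA_real_, nrow = 9L * n_res, ncol = 3L)
  ## residue 1 seeded directly (its phi is undefined by convention)
  xyz[1L, ] <- c(0, 0, 0)
  xyz[2L, ] <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  xyz[3L, ] <- xyz[2L, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  xyz <- place_gln_branches(xyz, 0L, dihedrals[1L, ])
  for (i in seq_len(n_res)[-1L]) {
    r <- 9L * (i - 1L)
    p <- r - 9L
    d <- dihedrals[i, ]
    xyz[r + 1L, ] <- place_atom(xyz[p + 1L, ], xyz[p + 2L, ], xyz[p + 3L, ],
                                g$b_c_n, g$a_ca_c_n, dihedrals$psi[i - 1L])
    xyz[r + 2L, ] <- place_atom(xyz[p + 2L, ], xyz[p + 3L, ], xyz[r + 1L, ],
                                g$b_n_ca, g$a_c_n_ca, d$omega)
    xyz[r + 3L, ] <- place_atom(xyz[p + 3L, ], xyz[r + 1L, ], xyz[r + 2L, ],
                                g$b_ca_c, g$a_n_ca_c, d$phi)
    xyz <- place_gln_branches(xyz, r, d)
  }
  top <- gln_topology(n_res, chain_id)
  report_clashes(top, xyz, clash_cutoff)
  list(topology = top, coords = xyz)
}

## Warn about non-bonded heavy-atom pairs below cutoff.
report_clashes <- function(topologies, xyz, cutoff = 1.8) {
  if (inherits(topologies, "chain_topology")) topologies <- list(topologies)
  tab <- atom_table(topologies)
  heavy <- which(is_heavy(tab))
  if (length(heavy) < 2L) return(invisible(NULL))
  xy <- xyz[tab$atom[heavy], , drop = FALSE]
  d <- as.matrix(stats::dist(xy))
  close <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(close) == 0L) return(invisible(NULL))
  a1 <- tab[heavy[close[, 1L]], ]
  a2 <- tab[heavy[close[, 2L]], ]
  bonded <- (a1$chain == a2$chain) &
    ((a1$residue_index == a2$residue_index) |
       (abs(a1$residue_index - a2$residue_index) == 1L &
          ((a1$atom_name == "C" & a2$atom_name == "N") |
             (a1$atom_name == "N" & a2$atom_name == "C"))))
  if (all(bonded)) return(invisible(NULL))
  k <- which(!bonded)
  msg <- paste(sprintf("%s%d:%s-%s%d:%s (%.2f A)",
                       a1$chain_id[k], a1$residue_index[k], a1$atom_name[k],
                       a2$chain_id[k], a2$residue_index[k], a2$atom_name[k],
                       d[cbind(close[k, 1L], close[k, 2L])]),
               collapse = ", ")
  warning("steric clash between non-bonded heavy atoms: ", msg)
  invisible(k)
}
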