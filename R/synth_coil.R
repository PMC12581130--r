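## Synthetic conformational ensembles: random-coil monomers (optionally
## with a partially helical span, emulating the N17 residual helicity) and
## Gaussian-perturbed fibril lattices.

#' Coil-ensemble specification
#'
#' @param n_chains chains per frame.
#' @param n_res residues per chain.
#' @param n_frames frames in the ensemble.
#' @param persistence persistence (residues): expected run length of
#'   extended/PPII backbone states; larger values give straighter chains.
#' @param helical_span optional `c(first, last)` residue range that adopts
#'   ideal alpha-helix dihedrals in a fraction of frames.
#' @param helicity fraction of frames in which the span is helical, in
#'   [0, 1].
#' @param seed RNG seed.
#' @return object of class `coil_ensemble_spec`.
#' @export
coil_ensemble_spec <- function(n_chains = 1L, n_res = 16L, n_frames = 50L,
                               persistence = 3, helical_span = NULL,
                               helicity = 0, seed = 1L) {
  stopifnot(n_chains >= 1L, n_res >= 2L, n_frames >= 1L, persistence >= 1,
            helicity >= 0, helicity <= 1)
  if (!is.null(helical_span)) {
    stopifnot(length(helical_span) == 2L, helical_span[1L] >= 1L,
              helical_span[2L] <= n_res)
  }
  structure(list(n_chains = as.integer(n_chains), n_res = as.integer(n_res),
                 n_frames = as.integer(n_frames), persistence = persistence,
                 helical_span = helical_span, helicity = helicity,
                 seed = as.integer(seed)),
            class = "coil_ensemble_spec")
}

## coil phi/psi basins: extended beta, PPII, alpha-R, alpha-L
COIL_BASINS <- data.frame(
  name = c("ext", "ppii", "aR", "aL"),
  phi = c(-120, -75, -60, 60), psi = c(135, 150, -45, 45),
  sd_phi = c(25, 15, 12, 15), sd_psi = c(25, 15, 12, 15),
  weight = c(0.35, 0.30, 0.25, 0.10))

sample_coil_dihedrals <- function(n_res, persistence) {
  p_stay <- 1 - 1 / max(1, persistence)
  basins <- integer(n_res)
  basins[1L] <- sample.int(4L, 1L, prob = COIL_BASINS$weight)
  for (i in seq_len(n_res)[-1L]) {
    ## persistence applies to the extended/PPII basins only: a random coil
    ## is locally stiff but must not grow spontaneous helical runs
    stay <- basins[i - 1L] <= 2L && stats::runif(1L) < p_stay
    basins[i] <- if (stay) basins[i - 1L] else
      sample.int(4L, 1L, prob = COIL_BASINS$weight)
    ## cap alpha-basin runs at two residues: a coil ensemble must not grow
    ## spontaneous helical hydrogen-bond runs (those are injected only via
    ## the helical_span machinery)
    if (i >= 3L && basins[i] == basins[i - 1L] && basins[i] == basins[i - 2L] &&
        basins[i] >= 3L) {
      basins[i] <- sample.int(2L, 1L)
    }
  }
  data.frame(
    phi = wrap_angle(stats::rnorm(n_res, COIL_BASINS$phi[basins],
                                  COIL_BASINS$sd_phi[basins])),
    psi = wrap_angle(stats::rnorm(n_res, COIL_BASINS$psi[basins],
                                  COIL_BASINS$sd_psi[basins])),
    chi1 = wrap_angle(sample(c(-60, 60, 180), n_res, replace = TRUE) +
                        stats::rnorm(n_res, 0, 10)),
    chi2 = wrap_angle(stats::rnorm(n_res, 180, 15)))
}

## true when the chain self-intersects (CA pairs |i-j| >= 3 closer than 3.5 A)
self_clash <- function(coords, n_res) {
  ca <- coords[9L * (seq_len(n_res) - 1L) + 2L, , drop = FALSE]
  d <- as.matrix(stats::dist(ca))
  sep <- abs(outer(seq_len(n_res), seq_len(n_res), "-"))
  any(d[sep >= 3L] < 3.5)
}

#' Generate a random-coil ensemble
#'
#' Chains are built residue-by-residue from dihedrals sampled from coil
#' basins (extended/PPII/alpha) with a persistence-controlled stay
#' probability, rejected and resampled on self-intersection. When a helical
#' span is configured, a deterministic fraction of frames (randomly placed)
#' adopts ideal helix dihedrals (-57, -47) over the span. Fully seeded and
#' reproducible. Chains are glutamine homopolymers; domain labels are
#' assigned by configuration, not sequence.
#'
#' @param spec a [coil_ensemble_spec()].
#' @param domains optional domain spans passed to [assign_domains()].
#' @param retry_budget resampling attempts per chain before giving up.
#' @return a [trajectory()] with `n_frames` frames (times 0,1,2,... ns) and
#'   chains separated by 100 A so they do not interact.
#' @export
gen_coil_ensemble <- function(spec, domains = NULL, retry_budget = 100L) {
  stopifnot(inherits(spec, "coil_ensemble_spec"))
  set.seed(spec$seed)
  n_hel <- round(spec$helicity * spec$n_frames)
  helical_frames <- if (n_hel > 0L) {
    sort(sample.int(spec$n_frames, n_hel))
  } else integer()
  tops <- lapply(seq_len(spec$n_chains), function(ci) {
    tp <- gln_topology(spec$n_res, chain_letters(ci))
    if (!is.null(domains)) tp <- assign_domains(tp, domains) else tp
  })
  offsets <- (seq_len(spec$n_chains) - 1L) * 100
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    per_chain <- lapply(seq_len(spec$n_chains), function(ci) {
      for (try in seq_len(retry_budget)) {
        dh <- sample_coil_dihedrals(spec$n_res, spec$persistence)
        if (f %in% helical_frames && !is.null(spec$helical_span)) {
          sp <- spec$helical_span[1L]:spec$helical_span[2L]
          dh$phi[sp] <- -57 + stats::rnorm(length(sp), 0, 3)
          dh$psi[sp] <- -47 + stats::rnorm(length(sp), 0, 3)
        }
        ch <- suppressWarnings(build_glutamine_chain(spec$n_res, dh))
        if (!self_clash(ch$coords, spec$n_res)) {
          return(sweep(ch$coords, 2L, c(offsets[ci], 0, 0), "+"))
        }
      }
      stop("self-avoidance unsatisfiable after ", retry_budget, " attempts")
    })
    frames[[f]] <- new_frame(do.call(rbind, per_chain), time = f - 1)
  }
  trajectory(tops, frames)
}

#' Perturb a fibril lattice into a noisy ensemble
#'
#' Adds i.i.d. Gaussian displacements (sd `sigma` per coordinate) to every
#' atom in every frame; `sigma = 0` reproduces the input exactly. Used as
#' the stand-in for fibril-state MD when testing spacing and dihedral
#' distribution metrics.
#'
#' @param lattice a [build_lattice()] result.
#' @param sigma displacement standard deviation (Angstrom, >= 0).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a [trajectory()] (times 0,1,2,... ns), same box/periodicity as
#'   the lattice frame.
#' @export
perturb_fibril <- function(lattice, sigma, n_frames = 10L, seed = 1L) {
  stopifnot(inherits(lattice, "fibril_lattice"), sigma >= 0, n_frames >= 1L)
  set.seed(seed)
  base <- lattice$frame
  frames <- lapply(seq_len(n_frames), function(f) {
    noise <- matrix(stats::rnorm(length(base$coords), 0, sigma),
                    ncol = 3L)
    new_frame(base$coords + noise, time = f - 1, box = base$box,
              periodic_axes = base$periodic_axes)
  })
  trajectory(lattice$topologies, frames)
}
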