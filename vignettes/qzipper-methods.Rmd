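---
title: "qzipper: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qzipper: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind each part of the package,
the tunable parameters with their defaults and rationale, what the
synthetic-data generators do and do not emulate, and the numerical choices
a maintainer would want to know. It states no empirical result that the
test suite or `scripts/acceptance.R` do not themselves compute.

## 1. The idealized cross-β lattice

### Geometry and frame conventions

Coordinates are Angstrom, times ns, residue indices 1-based. The lattice
frame is fixed: **x** is the lateral axis (strand direction, where the end
termini point), **y** the fibril axis (inter-strand hydrogen bonding,
`strand_spacing`, default 4.8 Å), **z** the sheet-stacking axis
(side-chain interdigitation, `sheet_spacing`, default 8.2 Å). The two
spacing defaults are the canonical polyQ X-ray values; both are
config-exposed because the source constraints are stated qualitatively.

Chains are built atom-by-atom by internal-coordinate (NeRF) placement with
standard peptide stereochemistry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
tetrahedral side-chain angles; L-chirality fixed by the C–N–CA–CB torsion
of +122.6°). All experimental information enters through dihedrals only, so
a built structure reproduces requested dihedrals to numerical precision —
this is what makes the dihedral validation a meaningful round trip rather
than a fit.

### Conformer dihedrals: what is measured and what is chosen

ψ, χ1 and χ2 defaults are exactly the ssNMR-derived conformer targets
(ψ 136/150°, χ1 −65/55°, χ2 180° for conformers a/b in alternating
antiparallel strands). φ has no published target. We do **not** use generic
β-region values: an ideal strand built with an arbitrary (φ, ψ) is a helix
with a residual twist, its carbonyls de-align within a few residues, and no
periodic hydrogen-bonded sheet exists — which would defeat the purpose of
an idealized lattice. Instead φ defaults to the unique β-region value that
gives the strand an exact two-fold screw (zero twist) at the fixed ψ:
φ_a = −138.6° (ψ = 136°) and φ_b = −151.8° (ψ = 150°), found by
minimizing the misalignment of carbonyls two residues apart. Both remain
arguments of `conformer_geometry()`.

Adjacent antiparallel strands are related by a 180° rotation about the
sheet normal plus a lateral **registry shift** of 3.6 Å (≈ one residue
rise) applied to odd strand slots. The shift was chosen by scanning the
Kabsch–Sander hydrogen-bond count of a two-strand system: without it the
donor and acceptor rungs face each other out of register and no H-bonded
ladder forms. It is exposed as `lattice_spec(registry_shift=)`. Because the
shift alternates (rather than accumulating as a screw), the lattice stays
strictly periodic along y and the box edge `n_slots * strand_spacing`
continues it seamlessly.

### Chains, linkers, arrangements

BT chains are β-hairpins: both strands in one sheet at consecutive slots
(intra-chain lateral H-bonds; interdigitation with chains of the adjacent
sheet). BA chains put their two strands at the same slot of two adjacent
sheets (intra-chain axial interdigitation; H-bonds to neighbouring chains),
which is why BA lattices require an even sheet count. Strand slots
alternate conformer a/b along y in both models.

The 4-residue turn (BT) and arc (BA) linkers are geometric stand-ins,
flagged as such in the lattice metadata: their CA atoms are threaded along
a circular arc between the strand ends, the backbone is framed locally and
the side chains grown by the same internal-coordinate machinery. Dihedral
libraries for free-standing hairpins (`turn_library_bt()`,
`arc_library_ba()`) are provided and replaceable, but the lattice uses the
geometric linker so that strand placement — the quantity the validation
targets — is exact. Consequences: measured dihedrals of linker residues
are unconstrained, the spec-level guarantee covers interior strand
residues, and DSSP-style assignment gives linker residues T/C.

Arrangements A1–A4 flip every second chain along the stacking order
(A2: 180° about y, reversing the lateral termini direction; A3: about x,
reversing the axial order; A4: about z, both). All flips are proper
rotations, so chirality and built dihedrals are preserved. The arrangement
symmetry property ("A2 maps onto itself under lateral mirror + one-chain
shift") is asserted on the strand direction pattern rather than on raw
coordinates: the stand-in linkers and the registry shift break exact
point-set symmetry for every arrangement, so a coordinate-level test
cannot discriminate A1 from A2, while the pattern-level test can.

### Box from concentration

`box_from_concentration(n, c)` is the closed form
`side = (n / (N_A c))^{1/3}`: 1000 chains at 10 mM give 55.0 nm. The
inverse for 170 chains in a 13 nm box is 128.5 mM; the source rounds this
to "∼100 mM" and we treat that as rounding, not something to correct for.

## 2. Structure metrics

* **Dihedrals** follow the IUPAC convention; terminal residues report NA
  for the undefined angle. All angle averaging uses circular statistics
  (mean via `atan2`, SD `sqrt(-2 log R)`), since the χ2 target sits exactly
  on the ±180° wrap where naive means are meaningless. Histogram modes use
  5° bins with ties resolved toward the circular mean.
* **Secondary structure** is a 4-state (H/E/T/C) Kabsch–Sander
  implementation: amide hydrogens rebuilt on the C(i−1)/CA bisector
  (1.01 Å), electrostatic H-bond energy with the −0.5 kcal/mol cutoff,
  helix from consecutive i,i+4 turns, strand from parallel/antiparallel
  bridges (acceptor-first index convention), turn from n-turn coverage.
  Minimum-image aware, with a 9 Å Cα prefilter. The independent reference
  used by the agreement tests is the MDAnalysis DSSP module (3-state);
  residual disagreement is confined to single marginal strand-edge
  residues where the two bridge formulations differ.
* **Spacings**: strand spacing is the mean nearest inter-strand Cα–Cα
  distance over *interior* CAs (strand-end CAs excluded — in a finite
  lattice their nearest partner lies beyond the strand end and biases the
  estimate upward; the modeled situation is semi-infinite). Sheet spacing
  is the distance between least-squares planes of adjacent sheets.
* **End-to-end classification** uses Cα(first)–Cα(last) of the declared
  span on unwrapped coordinates with cutoffs COMPACT < 15 Å,
  EXTENDED > 30 Å for a 16-residue span. These derive from construction:
  an ideal extended 16-mer spans ≈ 50 Å, an ideal hairpin < 10 Å. The
  published distributions print no thresholds, so both cutoffs are
  arguments. Distance alone cannot separate β-turn from β-arc compact
  states; no sub-classification is claimed.
* **Unwrapping** walks each chain and applies minimum-image displacements
  between consecutive atoms. Shape metrics (end-to-end, Rg) always unwrap;
  contact and clustering metrics use minimum-image distances directly, so
  the wrapped/unwrapped question the source leaves open does not affect
  them.

## 3. Contact maps and the multi-state interaction table

A residue pair is in contact when any heavy-atom pair is within 6 Å
(minimum-image aware); the probability is the fraction of frames (and, for
inter-chain scope, chain pairs) in contact. `min_seq_sep` defaults to 3
for intramolecular maps to drop trivially bonded neighbours.

`merge_multistate()` builds the residue-level interaction table: polyQ-core
pairs above the inclusion threshold are ATTRACTIVE with a single ε
(0.4 kJ/mol for Q16, 0.325 kJ/mol for H16 — supplied, not fitted, and
identical for intra- and intermolecular contacts); core contacts prefer the
fibril-state map over the monomer map for provenance; flanking-domain
pairs (N17–N17, P5–P5, N17–P5) come from the dense-phase map; every
flanking↔core cross pair is REPULSIVE (excluded volume) regardless of the
input maps; everything else is REPULSIVE. The inclusion threshold defaults
to probability ≥ 0.05 — the source never states its learning cutoff, so it
is an argument, and the tests assert the monotonicity that raising it can
only remove attractive entries. Granularity is residue-level, not
atom-pair-level: the table feeds the analysis pipeline and the kinetic
generator, not a simulation engine.

## 4. Aggregation kinetics

Chains cluster by single-linkage transitive closure with the 10 Å
nearest-Cα rule ("Cα–Cα distance between two molecules" is read as the
minimum over Cα pairs — the reading that matches nearest-neighbour
identification; centroid linkage is available as an option). t½ is the
first linear-interpolated crossing of half the initial monomer fraction;
a non-crossing series yields NA with a warning. Oligomer distributions
pool cluster sizes over [0, t½) and [t½, t½ + 200 ns], are normalized over
oligomers of size ≥ 2 by default (count-weighted; chain weighting and
monomer inclusion are options, since the published normalization is
unstated), and report the SEM across ≥ 2 replicates. The midsize band is
5–13 chains.

## 5. Synthetic data: what it emulates, what it does not

The generators replace molecular dynamics wholesale; a green test
establishes that the *analysis* is correct against ground truth, not that
any physical prediction is reproduced.

* **Coil ensembles** sample per-residue φ/ψ from four basins
  (extended/PPII/α_R/α_L) with a persistence-controlled stay probability
  restricted to the extended basins, α-runs hard-capped at two residues
  (a coil must not grow spontaneous helical H-bond runs), self-avoidance
  enforced by Cα rejection (3.5 Å, |i−j| ≥ 3) with a retry budget.
  Residual helicity is injected deterministically: a `helicity` fraction
  of frames adopts ideal helix dihedrals over the configured span,
  emulating the partial N17 helicity of H16. Chains are glutamine
  homopolymers; domain labels come from configuration, so "N17"/"P5" here
  means a labeled span, not the real sequence.
* **Perturbed fibrils** add i.i.d. Gaussian noise per atom per frame; they
  emulate thermal spread around the ideal lattice, not anharmonic or
  collective motion.
* **Dock-and-lock kinetics** is an exact Gillespie simulation over
  mass-action propensities: dimerization k_dim·M(M−1)/2, monomer addition
  (k_add_bb + k_add_sc)·M·C through the two docking channels, coagulation
  k_coag·C(C−1)/2, dissociation k_off_small per eligible cluster (size
  2..size_s with ≥ 1 non-locked chain; the leaving chain returns to COIL,
  and a size-2 remainder dissolves unless locked), locking k_lock per
  docked chain. LOCKED is absorbing. Propensities are size-independent
  (simplest mass-action closure; no diffusion kernel is published).
  `realize_coordinates()` renders any sampled state as 3D chains — cluster
  members stacked at 4.8 Å, groups separated by > 2 × the clustering
  cutoff on a grid — so the geometric pipeline provably recovers the
  generator's partition.

### The two regimes

`dock_lock_regimes()` encodes Q16-like and H16-like parameter sets. The
defining contrast is oligomer stability: k_off_small = 1.0/ns for Q16
versus 0 for H16 (N17-stabilized oligomers do not dissolve). They also
differ in dimerization: k_dim = 3×10⁻³ (Q16) versus 2×10⁻⁴ (H16) per ns.
The second knob is deliberate. With dissociation alone, the Q16-like run
reaches t½ much later and its pre-t½ window accumulates *more* midsized
clusters — the opposite of the published contrast — because dissociation
retains clusters inside the 5–13 band while delaying monomer depletion.
The source kinetics themselves report that Q16 monomers engage in initial
binding faster; encoding that as a faster k_dim reproduces every
qualitative ordering at once: earlier Q16 t½, a dimer-dominated Q16
early population, and a strictly larger H16 midsize fraction before t½.
All rates are illustrative, clearly non-physical, and config-exposed.

## 6. Numerical and interface choices

* Configs are JSON (`read_config()`): the target environment ships no R
  YAML parser, and the schema (spans, axes, rates) is structure-identical.
* PDB fields give 10⁻³ Å precision; round-trip tests assert exactly that.
  Systems beyond 99,999 atoms use hybrid-36 serials (or error if
  disabled). Multi-frame trajectories are multi-model PDB.
* The PDB/GRO readers are fixed-column parsers implemented here because no
  pre-installed R package reads these formats; they cover the documented
  subset (orthorhombic CRYST1, ATOM/HETATM, MODEL blocks) and fail with
  line-numbered errors on malformed records.
* All stochastic functions take explicit seeds and are bitwise
  reproducible; the CLI writes a manifest (config echo, version, seed)
  even on failure.
* Clash auditing warns on non-bonded heavy-atom pairs < 1.8 Å. The ideal
  b-conformer strand itself carries a genuine 1.67 Å O(i)–CG(i+1) contact
  — a consequence of rigid ideal geometry at χ1 = +55°, reported, not
  hidden.

## 7. Known limitations

* Linker geometry is a stand-in; only strand-interior dihedrals are
  guaranteed.
* The lattice is rigid and unrelaxed: no energy minimization, solvent or
  flanking-domain placement.
* The β-sheet fraction normalization is per residue over all chains; the
  per-chain alternative is not implemented.
* The kinetic generator has no nucleation phase, no fragmentation or
  secondary nucleation, and no concentration dependence beyond the rate
  constants themselves.
* Large-scale coarse-grained outcomes (β-fraction plateaus, 500–1000-chain
  morphologies, published dimer-share percentages) are out of scope by
  design; the property suites stand in for them.
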