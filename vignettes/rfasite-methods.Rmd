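---
title: "Methods: mapping RFamide binding sites on ASIC1a and quantifying channel modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping RFamide binding sites on ASIC1a and quantifying channel modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfasite)
```

## The scientific problem

Acid-sensing ion channels (ASICs) are trimeric, proton-gated Na$^+$ channels
that open transiently on extracellular acidification and then desensitize.
Neuropeptides ending in an Arg-Phe-NH$_2$ motif (RFamide peptides, e.g.
FRRFa = Phe-Arg-Arg-Phe-amide) modulate this behaviour: they induce a
sustained current during acidification and shift the pH dependence of
steady-state desensitization (SSD). `rfasite` implements the computational
side of locating where such peptides bind on ASIC1a and of quantifying their
functional effects:

1. post-processing of rigid-receptor docking ensembles into a small set of
   *consensus* binding modes compatible with both a short and a long RFamide
   peptide;
2. grid-based detection of candidate binding cavities (acidic pocket, thumb
   base pocket, central vestibule and its side cavities) with
   probe-accessible volumes;
3. typed protein-peptide interaction fingerprints for the selected modes;
4. analysis of two-electrode voltage-clamp recordings: sustained/peak
   current ratios, SSD Hill fits, concentration-response and kinetic fits,
   and classification of mutant-versus-wild-type effects.

Seeded generators produce synthetic inputs with known ground truth for every
stage, so the full pipeline is testable without any external download.

## Pose consensus selection

Both peptides are docked to the *same rigid receptor*, so all poses share one
coordinate frame. The selection rule is:

- keep poses of the short peptide scoring within 1 kcal/mol of its best pose
  (`energy_window()`; the window is inclusive and the best pose always
  survives);
- for each surviving pose, compute the RMSD over the nine heavy atoms of the
  Arg-Phe-amide moiety (backbone N and C$\alpha$, side-chain C$\gamma$ and
  C$\zeta$ of the C-terminal-most Arg and Phe, plus the amide nitrogen)
  against every pose of the longer peptide, and keep the pose if its best
  partner lies strictly below 1 Å (`match_consensus()`).

Design choices worth noting:

- **No superposition before the RMSD.** Complexes docked to one rigid
  receptor already share a frame; a fitting step would alter the meaning of
  the 1 Å criterion. For inputs in different frames,
  `superpose_transform()` provides a receptor-C$\alpha$ Kabsch fit to apply
  first.
- **Positional atom correspondence.** The nine frame atoms are chemically
  unambiguous, so no permutation optimization is performed.
- **Windowing is applied to the short peptide only** by default; whether the
  long-peptide ensemble should also be windowed is genuinely ambiguous, so
  it is exposed as `window_b` (default `FALSE`).
- **Amide nitrogen aliases.** Builders name the C-terminal amide nitrogen
  `NT`, `NXT` or `NH2`; all are recognized, and an `NH2` atom belonging to
  an Arg side chain is never mistaken for it.
- Ties between equally good partners are broken by (RMSD, then pose id), so
  results are invariant to input pose order.

The orientation criterion — relevant poses must leave the peptide N-terminus
pointing towards the pocket entrance, since longer RFamide peptides extend
from there — has no unique geometric definition. This package
operationalizes it on the cavity grid: the *burial depth* of an atom is the
breadth-first path length through solvent-accessible voxels from the atom's
nearest accessible voxel to bulk solvent, and `nterm_orientation_ok()`
accepts a pose when its N-terminal amine nitrogen is no more buried than its
C-terminal amide nitrogen.

## Cavity detection and volumes

`probe_accessible_cavities()` approximates probe-accessible cavity volumes on
a rectilinear voxel grid (default spacing 0.5 Å, solvent probe 1.4 Å,
Bondi-style united-atom radii C 1.70, N 1.55, O 1.52, S 1.80 Å; hydrogens are
ignored). A voxel is occupied when its center lies within (vdW + probe) of a
heavy atom; bulk solvent is flood-filled from the grid boundary with
6-connectivity (so the fill cannot leak diagonally through an occupied
wall), and cavity regions are 26-connected components of the remaining
accessible space.

Two refinements depart from the bare algorithm, both for defensible
numerical reasons:

- **Open pockets.** A pocket with a mouth is, by definition, connected to
  bulk, so a plain flood fill would absorb it. A second, larger "sealing"
  probe (default 4.0 Å) is therefore used only to close mouths: accessible
  voxels that the large probe cannot reach, and that lie deeper than the
  thin surface skin it leaves, are pocket voxels even when a small-probe
  path to bulk exists. A region is `sealed` when the small probe has no
  path from it to bulk. This is the standard two-probe trick of grid-based
  pocket finders. Regions smaller than `min_volume` (default 25 Å$^3$,
  about two water volumes) are suppressed as surface dimples.
- **Volume antialiasing.** Counting voxel centers has an origin-dependent
  lattice error that does *not* shrink smoothly with the spacing: on a
  sealed spherical phantom of analytic volume 523.6 Å$^3$ the plain count
  is off by $+2.2$ to $+2.4$ Å$^3$ at 0.8, 0.4 *and* 0.2 Å spacing, with
  the sign and size set by where the lattice happens to sit. The reported
  `volume` therefore re-weights every region voxel facing an occupied wall
  (and every occupied voxel facing the region) by the unoccupied fraction
  of 128 quasi-random sub-points (a Halton(2,3,5) pattern, rotated per
  voxel by a hash so patterns are decorrelated). This brings the sphere
  phantom error below 0.1% at 0.4 Å. The raw voxel-count estimate is kept
  in `volume_voxel` = voxel_count $\times$ spacing$^3$.

A caveat the test suite makes explicit: even the antialiased estimator
cannot exhibit *strictly* decreasing error against the idealized sphere
volume across 0.8 → 0.4 → 0.2 Å, because the atom-shell phantom's true
accessible volume differs from the ideal $\tfrac{4}{3}\pi r^3$ by a small
sphere-packing corrugation term (about $+0.3$ Å$^3$ at the default shell
density, confirmed by an independent closed-form ray oracle), and a finer
grid resolves *more* of that true-but-unwanted volume. The corresponding
convergence assertion in the test suite documents this saturation;
the estimator is accurate to $\sim 0.002$ Å$^3$ against the phantom's true
volume already at 0.4 Å spacing.

Named pocket labels (`acidic_pocket`, `thumb_base`, `central_vestibule`,
`side_cavity`) are attached by matching each region's lining residues
(heavy atoms within vdW + probe + spacing of a region voxel) against
landmark residue sets; a default set in human ASIC1a numbering ships in
`inst/extdata/landmarks_asic1a.json`.

Poses are assigned to the cavity containing the most pose heavy atoms
within 2 Å of a cavity voxel center, requiring at least 25% of the atoms;
ties go to the larger cavity, then label order.

## Interaction fingerprints

`detect_interactions()` reports hydrogen bonds (donor-acceptor heavy atoms
$\le$ 3.5 Å; D-H···A $\ge$ 120° when a hydrogen is present), hydrophobic
contacts (apolar C···C $\le$ 4.0 Å), aromatic stacking (ring centroids
$\le$ 5.0 Å, inter-plane angle $\le$ 30° parallel or 60-90° T-shaped),
cation-$\pi$ contacts (Arg C$\zeta$ / Lys N$\zeta$ to ring centroid $\le$
6.0 Å) and salt bridges (opposite-charge heavy atoms $\le$ 4.0 Å). The 2-D
interaction-diagram tools used in the field apply slightly different
stringencies to the same complexes, so none of these thresholds is treated
as canonical: all are fields of `interaction_criteria()`. One interaction
is kept per (peptide atom or ring, receptor residue, type) at the shortest
distance; the result is deterministic and invariant under global rigid
motion of the complex.

## Electrophysiology analysis

**Trace metrics.** Currents are inward-negative; ratios are reported
positive. The baseline is the mean current over the 2 s before acid onset;
the peak is the largest baseline-subtracted magnitude in the acid window;
the sustained current is the mean magnitude over the last 2 s of the acid
application (the acid window must be at least that long). Peaks below a
configurable noise floor flag the trace unusable rather than erroring.

**SSD Hill fit.** The conditioning-pH dependence of the pH-5-evoked current
follows

$$ I(\mathrm{pH}) \;=\; I_{max}\left(1 - \frac{1}{1 + \left(10^{-\mathrm{pHD}_{50}}/10^{-\mathrm{pH}}\right)^{n_H}}\right), $$

which passes exactly through $I_{max}/2$ at $\mathrm{pHD}_{50}$.
`fit_ssd()` fits it by Levenberg-Marquardt least squares with three
deterministic initializations (the data-driven midpoint and $\pm$0.5 pH
units) to avoid local minima; raw amplitudes are accepted because $I_{max}$
is fitted.

**Concentration-response.** `fit_dose_response()` fits the Hill-Langmuir
form $r(c) = r_0 + (r_{max}-r_0)\,c^h/(EC_{50}^h + c^h)$ with $EC_{50}$
parameterized on the log scale, again with three midpoint initializations.

**Kinetics.** `fit_exponential_kinetics()` fits mono-exponential decay
(washout of the sustained current, giving $k_{off}$) or rise (appearance
during pre-application). For a rise at ligand concentration $[L]$ the
association constant defaults to the pseudo-first-order form
$k_{on} = k_{obs}/[L]$; the two-state variant
$k_{on} = (k_{obs}-k_{off})/[L]$ is available via `kon_model = "with_koff"`.
Neither model is asserted as the true scheme: published rise and washout
rates for this system are mutually inconsistent under a simple two-state
interpretation ($k_{on}[L] \approx 0.008\ \mathrm{s^{-1}}$ at 50 µM vs
$k_{off} = 0.025\ \mathrm{s^{-1}}$), so both are provided and the choice is
the analyst's.

**Wild-type vs mutant classification.** `compare_modulation()` derives, per
cell, the modulator-induced fold change of $I_{sust}/I_{peak}$, the pHD$_{50}$
shift, and the SSD Hill-coefficient ratio, and annotates each mutant with
`<`, `=`, `>` per parameter: significantly different from wild type in the
stated direction, or not. Mutants are compared against wild type with
Welch's t-test, Holm-corrected across mutants within each parameter. This
approximates the many-to-one (Dunnett-style) post-hoc comparisons used in
practice without reimplementing multivariate-t tables; for the symbol
semantics only rejection at $\alpha$ matters. For the pHD$_{50}$ shift,
`<` means a smaller *magnitude* of the modulator-induced shift than wild
type.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their spec (seed included) and restore
the caller's RNG state.

- `gen_pose_ensembles()` plants a chosen number of cross-peptide frame
  matches at an exact RMSD (a rigid translation of the partner pose, so the
  planted RMSD is exact by the translation law) among decoys kept at least
  `decoy_margin` apart by rejection sampling with a retry cap. The truth
  table is therefore exact and consensus tests are non-flaky. Peptide
  templates are idealized extended chains: correct atom names and topology
  for frame extraction and interaction typing, not realistic conformers or
  energies.
- `gen_cavity_structure()` builds pseudo-atom shells (Fibonacci lattices,
  default point separation 0.25 Å, dense enough that shell corrugation is
  negligible against the 5% volume tolerance) with analytically known
  interior volume: a sealed sphere, an open pocket with a mouth of given
  accessible aperture along $+z$, or two disjoint voids.
- `gen_current_traces()` produces baseline + instant peak + mono-exponential
  desensitization to a sustained plateau + Gaussian noise; defaults emulate
  a wild-type-like oocyte recording (5 µA peak, 10 s acid application,
  desensitization $\tau$ 0.5 s). `gen_ssd_series()`,
  `gen_dose_response_series()` and `gen_kinetic_series()` sample the exact
  closed forms the fitters assume, plus seeded Gaussian noise.
- `gen_modulation_dataset()` draws per-cell replicate tables around stated
  effect means. Effects the mutant leaves unchanged reuse the wild-type
  effect realizations cell-for-cell, so "no difference" classifications
  hold by construction rather than at the mercy of $\alpha$-level false
  positives. The wild-type SSD midpoint is not a published number; the
  generator default (pHD$_{50}$ 7.2, $n_H$ 3) is a field-typical choice for
  ASIC1a and is documented as arbitrary.

Because the trace generator uses the same functional forms the fitters
assume, parameter-recovery tests validate the *estimation machinery*
(identifiability, optimizer robustness, bias under noise), not the
biological adequacy of those forms; passing them says nothing about model
misspecification on real recordings, rundown, series-resistance artifacts
or day-to-day variability, which are out of scope.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10-50 pose-ensemble draws
of 20-26 poses per peptide; cavity grids at 0.8/0.5/0.4/0.2 Å spacing on
phantoms of radius 4-11 Å (about $10^5$-$10^7$ voxels); 50-100 seeded
replicates for the noisy fit-recovery studies; and n = 10 cells per
genotype for the classification datasets. These sizes were chosen so that
every stochastic check has comfortable statistical margin while the whole
suite remains quick to run on a single core.

Fitting tolerances follow `minpack.lm` defaults with a 200-iteration cap;
multi-start selection is by lowest residual sum of squares; degenerate
inputs (constant responses, too few distinct points, windows shorter than
the sustained-current interval) error early with explicit messages.

## Known limitations

- The cavity volumes are grid approximations, not alpha-shape (CASTp-exact)
  volumes; how alpha-shape software partitions connected cavities can
  differ, especially where pockets merge at small probe radii.
- The `.dock4`-style reader is written against AutoDock-family MODEL/USER
  result text generally, since the exact internal layout of such files
  varies; files whose per-model score lines match neither the
  `REMARK VINA RESULT` nor the `USER` energy conventions are rejected with
  the pose named.
- The orientation filter depends on the grid (spacing, sealing probe); it is
  a coarse topological criterion, not a free-energy statement.
- Welch-plus-Holm is an approximation to Dunnett-style post-hoc testing;
  with many mutants and small n the two can disagree near the significance
  boundary.
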