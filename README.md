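# rfasite

Mapping RFamide neuropeptide binding sites on acid-sensing ion channels
(ASICs), and quantifying the channel modulation those peptides produce.

ASIC1a is a trimeric, proton-gated Na⁺ channel that desensitizes rapidly
during acidification. Neuropeptides carrying a C-terminal Arg-Phe-NH₂
(RFamide) motif — such as FRRFa (Phe-Arg-Arg-Phe-amide) — induce a sustained
current and shift the pH dependence of steady-state desensitization (SSD).
Locating their binding site combines two lines of evidence: rigid-receptor
docking of a short and a long RFamide peptide, post-processed into consensus
binding modes, and electrophysiological comparison of wild-type and mutant
channels. `rfasite` implements both, plus seeded synthetic-data generators
that make every stage testable offline.

## What it computes

**Docking post-processing**

- Pose ensembles are read from multi-MODEL PDB (`REMARK VINA RESULT`
  scores) or AutoDock-style result text (`USER` energy lines), sorted
  best-score-first.
- Consensus selection keeps poses of the short peptide within 1 kcal/mol of
  its best docking score whose RFa moiety — nine heavy atoms: backbone N
  and Cα, side-chain Cγ and Cζ of the C-terminal Arg and Phe, and the amide
  nitrogen — lies within 1 Å RMSD of some pose of the longer peptide
  (strict inequality, no superposition: both peptides share the rigid
  receptor's frame).
- Cavities are detected on a voxel grid (probe 1.4 Å, Bondi-style radii)
  with a two-probe scheme so open pockets are reported too; volumes are
  probe-accessible volumes with sub-voxel boundary antialiasing; poses are
  assigned to named pockets (acidic pocket, thumb base, central vestibule,
  side cavities) via landmark residues, filtered by an N-terminus
  orientation criterion based on grid burial depth, and fingerprinted
  (H-bonds, hydrophobic, stacking, cation-π, salt bridges).

**Electrophysiology**

- Sustained/peak current ratios (I_sust/I_peak; sustained = last 2 s of the
  acid application), SSD Hill fits
  `I = Imax * (1 - 1/(1 + (10^-pHD50 / 10^-pH)^nH))`,
  Hill-Langmuir concentration-response fits (EC₅₀), mono-exponential
  association/dissociation kinetics (k_off, k_obs, k_on = k_obs/[L]), and
  wild-type-versus-mutant effect classification with `<`/`=`/`>` symbols per
  parameter (Welch + Holm across mutants).

## Worked example

```r
library(rfasite)

# two planted consensus modes among 20 + 20 decoys, recovered exactly
sim <- gen_pose_ensembles(pose_gen_spec(seed = 42, n_planted = 2,
                                        n_decoys_a = 20, n_decoys_b = 20))
match_consensus(sim$ens_a, sim$ens_b, consensus_params(1.0, 1.0))
#>      pose_a      pose_b rmsd score_a
#> 1 FRRFa_p01 KNFLRFa_p01  0.5    -9.0
#> 2 FRRFa_p02 KNFLRFa_p02  0.5    -8.8

# a sealed spherical void of analytic volume 523.6 A^3
ph <- gen_cavity_structure("sealed_sphere", r = 5)
cav <- probe_accessible_cavities(ph$structure, grid_spec(spacing = 0.4))
cav[, c("label", "volume", "sealed")]
#>      label  volume sealed
#> 1 cavity_1 523.869   TRUE

# SSD and concentration-response fits on noisy synthetic series
s <- gen_ssd_series(pHD50 = 7.2, nH = 3, noise_sd = 0.05, seed = 9)
f <- fit_ssd(s$pH, s$I)
sprintf("pHD50 = %.3f, nH = %.2f, Imax = %.3f", f$pHD50, f$nH, f$Imax)
#> "pHD50 = 7.204, nH = 3.17, Imax = 0.997"

d <- gen_dose_response_series(EC50 = 37e-6, noise_sd = 0.05 * 0.035, seed = 9)
fd <- fit_dose_response(d$conc, d$ratio)
sprintf("EC50 = %.1f uM (Hill slope %.2f)", fd$EC50 * 1e6, fd$hill)
#> "EC50 = 38.0 uM (Hill slope 0.89)"
```

The consensus table lists each selected short-peptide pose with its best
long-peptide partner and their RFa-frame RMSD; the planted 0.5 Å pairs are
recovered with no spurious matches. The cavity volume is within 0.06% of
the analytic value, and the fits recover the generating parameters within
the noise.

End-to-end runs are one call: `run_site_mapping(run_config(...))` executes
energy window → consensus → cavity detection → pocket assignment →
orientation filter → fingerprints and writes TSV/JSON reports;
`run_ephys()` does the same for replicate tables, fit series and trace
CSVs.

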