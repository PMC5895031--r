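---
title: "Methods: variant triage and protein-stability analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage and protein-stability analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstab)
```

varstab implements the computational arm of a variant-effect study of a
small membrane protein — the 18 kDa translocator protein (TSPO, 169
residues) is the packaged worked system — as four analysis stages plus a
synthetic-data module. This vignette documents the models, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open.

## Consensus triage of missense variants

Each variant carries raw outputs from eight deleteriousness predictors.
The published tools disagree in output type (categorical labels, scores,
free-energy changes), so every output is first binarized under the tool's
own published rule:

| Tool       | damaging when                       | benign when |
|------------|-------------------------------------|-------------|
| PROVEAN    | "Deleterious"                       | "Neutral"   |
| SIFT       | "Damaging" / score < 0.05           | "Tolerated" |
| PolyPhen-2 | "probably damaging" / score > 0.85  | "benign", "possibly damaging" |
| PhD-SNP    | "Disease"                           | "Neutral"   |
| SNAP2      | "Effect"                            | "Neutral"   |
| SNPs&GO    | "Disease" / score > 0.5 (strict)    | "Neutral"   |
| FATHMM     | "Damaging"                          | "Tolerated" |
| I-Mutant 3 | "Large decrease …" / DDG < −0.5 kcal/mol | "Neutral", stabilizing |

A variant is deleterious (D) when **at least 5 of 8** calls are damaging.
Two boundary decisions deserve comment, both resolved by brute force
against the packaged 52-row panel (`tspo_panel_path()`):

* *The vote boundary.* The published table header leaves exactly 5 votes
  unaddressed ("1–4 = N, >5 = D"), but rows with exactly 5 damaging calls
  (e.g. A147T, W5R, G30D) are printed D, so the implemented rule is
  votes ≥ 5 ⇒ D. Row-level evidence outweighs header typography.
* *PolyPhen-2 "possibly damaging".* Counted as a benign vote. Scoring the
  panel under both assignments shows this is the only one consistent with
  the printed labels (the A94V row, "possibly damaging" plus four other
  damaging calls, is printed N); the test suite performs exactly this
  brute-force comparison.

Under these rules the re-derived label matches the printed one on 51 of
52 rows. The one exception, G63S, collects only 4 damaging votes under
*every* binarization consistent with the remaining 51 rows yet is printed
D; whether that is a transcription slip upstream is unknowable, so the
concordance report flags it and printed labels are never overwritten.
Region enrichment over residue ranges (default: the transmembrane
stretches aa 44–65 and 133–150) uses union semantics — a variant hit by
overlapping ranges counts once. The conservation overlay takes a
per-residue grade track (1 = variable … 9 = conserved) and a cutoff,
default `min_score = 8`, exposed as a parameter because no published
cutoff accompanies the "highly conserved" wording; reproducing any
particular conserved-fraction count therefore depends on the user's track
and cutoff.

## Catalog analytics

Coordinates are 1-based closed intervals throughout, matching residue
numbering conventions. Region classification translates the reference and
alternate codon at coding positions, so synonymous/non-synonymous status
is decided by the genetic code rather than trusted from the input; this
requires ref/alt alleles on coding records. 5' and 3' UTRs are kept
distinct internally but pooled as "utr" in summaries. Percentages are
rounded half-up to one decimal (base R's `round()` is half-to-even, which
would print 4.85 as 4.8); with the printed catalog counts
(674/52/52/40 of 818) this yields 82.4 / 6.4 / 6.4 / 4.9. Note that
100·40/818 = 4.889 rounds to 4.9 under any one-decimal convention.
Malformed rows are collected into a rejects table with reasons, never
dropped, because class counts are audit quantities.

## Codon usage

Relative adaptiveness is defined per synonymous family: the most frequent
codon is set to 100% and the rest scale linearly with frequency. The
embedded default table is a standard human codon-usage table (CUTG-style
occurrences per 1000 codons); computations keep full precision and
reports round to integer percent, so the leucine swap CTG→CTA reads
100 → 18 (7.2/39.6 = 18.18). Ties for a family maximum all receive 100
and are flagged, since the definition is silent on ties. Stop codons are
excluded from CDS profiles and cluster statistics.

Rare-codon clusters are maximal runs of codon positions whose centered
sliding-window mean falls below a threshold, expanded by half a window on
each side and merged when overlapping — the expansion makes a planted
low-adaptiveness block recoverable to within half a window rather than
systematically shrunk by the windowing. Defaults are `window = 15` codons
and `threshold = 40%`; no published windowing accompanies the cluster
concept, so both are parameters, and cluster boundaries should be read as
window-resolution estimates, not base-pair-exact calls. Which synonymous
deltas count as "significant" is likewise left to the user: the module
reports exact deltas.

## Trajectory statistics

Superposition uses the Kabsch algorithm: SVD of the weighted covariance
matrix with the determinant-corrected composition, so reflections are
excluded and the returned rotation is always proper. Degenerate
(collinear) geometries error rather than returning an arbitrary member of
the solution family. The test suite checks this route against an
independent orientation-search oracle (random unit quaternions plus
Nelder-Mead polish over the rotation vector) to 10⁻³ Å on small systems.

* **RMSD** series superpose every frame's selection onto a reference
  frame (default: the first frame, the common convention) before
  measuring deviation, so rigid-body motion never contributes. Presets:
  `backbone` = {N, CA, C, O}, `calpha` = {CA}; both backbone and Cα-only
  RMSD are available since summary tables conventionally print both.
* **RMSF** is computed about the time-averaged structure, iterated to
  self-consistency (tolerance 10⁻⁶ Å, max 20 iterations); a first-frame
  reference is available as an option because either convention appears
  in practice. For isotropic per-coordinate noise of SD σ the expected
  RMSF is σ√3, which is what the parameter-recovery tests assert.
* **Rg** is the mass-weighted RMS distance of atoms from their centre of
  mass; masses come from standard atomic masses by element.
* **Equilibrium statistics** are means ± SD over frames at or after a
  window start, default 12 ns (typical for a 30 ns membrane-protein run);
  the window is a parameter everywhere it is used.
* **Group comparison** pre-checks both samples for normality
  (Shapiro-Wilk at 0.05) and then applies Welch's t-test, or the unpaired
  Wilcoxon rank-sum test when either sample fails the gate; significance
  at p < 0.05. The rank-sum (not signed-rank) variant is used because the
  compared samples — post-equilibration frames of independent
  simulations — are unpaired. When trajectories of replicate simulations
  are supplied, post-equilibration frames are pooled per system and a
  per-system report is emitted, since no single pooling rule is canonical.
* The homology-model quality score is the fixed linear combination
  0.1456·Dihedrals + 0.3906·Packing1D + 0.4656·Packing3D of component
  Z-scores.

Multi-model PDB I/O is delegated to bio3d behind the package's reader and
writer; the reader pre-validates that every MODEL carries the same atom
set and names the first offending atom otherwise, because silently
misaligned atom tables corrupt every downstream statistic. Occupancy and
B-factor are ignored on read and written as 1.00/0.00.

## Degradation kinetics

Chase densitometry is normalized per replicate as
`100 · (target/loading)(t) / (target/loading)(0)`, so every replicate
starts at exactly 100% and arbitrary density units cancel; per-time
mean ± SEM uses n = replicate count. The decay model is first-order,
`N(t) = 100·e^(−kt)`, fitted by nonlinear least squares (Levenberg–
Marquardt) with the intercept pinned at 100 — the normalization pins
t₀, and fitting on the natural scale avoids the low-signal bias a
log-linear fit would introduce. An unconstrained-intercept variant sits
behind a flag. Rates below 10⁻⁴ /h are reported as no detectable decay
(half-life ∞) rather than as absurdly long finite half-lives: a 24 h
chase window cannot resolve them. Half-life changes are reported as
`100·(1 − t½_mut/t½_ref)` (positive = faster degradation). Because
percent-remaining endpoints and fitted half-life ratios are both in use
as effect measures, `percent_remaining()` and `compare_halflife()` expose
both routes.

## The synthetic-data module

Generators are seeded, bitwise-deterministic, and every one returns a
ground-truth manifest; recovery tests read truth only from the manifest.
Noise models are the simplest matching each assay's error structure:
categorical draws for predictor panels, isotropic per-coordinate Gaussian
fluctuations (optionally per-residue) composed with a smooth rigid-body
motion schedule for trajectories, and multiplicative lognormal noise for
densitometry. The trajectory reference is a generated 169-residue helical
dummy chain (ideal helix, 1.5 Å rise, 100° twist), so no structure
download is needed. Default study-condition parameters mirror the worked
system: catalog composition (0.824/0.064/0.064/0.048 over
intronic/UTR/nsSNP/sSNP), 169-residue protein, 25 ps frame spacing,
triplicate chase series over 0–24 h with 10% multiplicative noise.

What the generators deliberately do **not** emulate: real trajectories
have correlated, anisotropic fluctuations and slow collective modes, real
CDSs have sequence constraints beyond codon choice, and real blots have
spatially structured error. Passing the recovery tests therefore
demonstrates correctness of the estimators under their stated models, not
robustness to every artefact of real data.

## Problem sizes and numerical choices

The test suite exercises: 2000-frame, 169-residue trajectories for RMSF
parameter recovery at σ ∈ {0.5, 1, 2} Å (acceptance band 0.95–1.05 on the
per-residue-median ratio to σ√3); 100 seeded ≤6-atom instances for the
superposition oracle comparison at 10⁻³ Å; 200 noisy chase series for
half-life recovery (median within 10%) and 200 pairs for the 25%
reduction recovery (±3); and 2000 null simulations (n = 20 per group) for
the comparison gate's type-I error, accepted within [0.03, 0.07]. These
sizes keep sampling error comfortably inside each acceptance band at a
cost of seconds per check.

## Known limitations

* The consensus machinery consumes predictor outputs; it does not call
  the prediction services, so it can only be as current as its inputs.
* Region classification assumes a single plus-strand transcript and no
  liftover or genome-build handling.
* Absolute MD observables (RMSD/RMSF/Rg of a real protein) depend on the
  force field and simulation protocol upstream; this package only
  analyses trajectories, so its MD-facing guarantees are invariants and
  synthetic-parameter recovery, not reproduction of any particular
  simulation's values.
* First-order decay is a single-compartment model; multi-phase
  degradation or compartment-specific turnover is out of scope.
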