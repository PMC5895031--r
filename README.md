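# varstab

Variant triage and protein-stability analytics for a protein-coding gene,
built around the 18 kDa translocator protein (TSPO, 169 residues) as the
worked system. The package takes the outputs that a typical variant-effect
study produces — a variant catalog, per-variant calls from eight
deleteriousness predictors, a coding sequence, molecular-dynamics
trajectories of wild-type and mutant structures, and cycloheximide-chase
densitometry — and turns them into reproducible, testable numbers:

* **Consensus triage** of missense variants: each predictor's raw output
  (PROVEAN, SIFT, PolyPhen-2, PhD-SNP, SNAP2, SNPs&GO, FATHMM, I-Mutant 3)
  is binarized under its published threshold, and a variant is called
  deleterious when at least 5 of the 8 vote damaging. Re-derived labels are
  compared against any printed labels in a concordance report, never
  silently overwritten.
* **Catalog analytics**: region classification (intronic / UTR /
  synonymous / non-synonymous by codon translation), class distributions
  with one-decimal percentages, protein-variant mapping from tokens such as
  `A147T`, multi-allelic residue detection, MAF filtering, and residue-range
  enrichment (e.g. transmembrane stretches aa 44–65 and 133–150).
* **Codon usage**: relative adaptiveness *w* of a codon, defined per
  synonymous family as `w = 100 * f / f_max` (the most frequent synonymous
  codon scores 100), per-position CDS profiles, synonymous-variant deltas,
  and rare-codon cluster detection by windowed profile means.
* **Trajectory statistics**: weighted Kabsch superposition (SVD route,
  proper rotations only), RMSD time series, iterated-mean-structure
  per-residue Cα RMSF, mass-weighted radius of gyration
  `Rg = sqrt(Σ mᵢ|rᵢ − r_com|² / Σ mᵢ)`, post-equilibration means ± SD, and
  normality-gated group comparison (Welch t-test / Wilcoxon rank-sum,
  α = 0.05), plus the combined homology-model quality Z-score
  `0.1456·Dihedrals + 0.3906·Packing1D + 0.4656·Packing3D`.
* **Degradation kinetics**: loading-control normalization of chase series
  to percent-of-t₀, nonlinear least-squares fits of
  `N(t) = 100·exp(−kt)`, half-life `t½ = ln 2 / k`, and percent half-life
  change between genotypes.
* **Synthetic data**: seeded generators with ground-truth manifests for
  every stage (catalogs, predictor panels, CDSs with planted rare-codon
  blocks, trajectories with known per-residue fluctuation amplitudes,
  chase series with known half-life), so the whole pipeline runs and is
  validated without any download.

## Worked example

```r
library(varstab)

panel <- read.delim(tspo_panel_path(), stringsAsFactors = FALSE)
tri <- classify_table(panel)
sum(tri$results$label == "D")      # 20 re-derived deleterious calls
tri$concordance$n_match            # 51 of 52 agree with the printed labels
tri$concordance$mismatches
#>             id mutation votes label printed_label
#> 14 rs566547284     G63S     4     N             D

region_enrichment(tri$results, rbind(c(44, 65), c(133, 150)),
                  use_printed = TRUE)$per_range
#>   start end count                     mutations
#> 1    44  65     4           P44L,G63S,G63D,Y65F
#> 2   133 150     5 A133T,P139T,P139S,A147T,L150F

ad <- relative_adaptiveness(human_codon_usage())
ad[ad$codon %in% c("CTG", "CTA"), c("codon", "aa", "per1000", "value", "display")]
#>   codon aa per1000     value display
#> 7   CTA  L     7.2  18.18182      18
#> 8   CTG  L    39.6 100.00000     100

g <- gen_chase(half_life = 30, cv = 0.1, seed = 7)
fit_decay(normalize_chase(g$chase))
#> first-order decay: k = 0.01948 /h, half-life = 35.6 h
```

The 52-row panel classifies 20 variants as deleterious under the default
rules and matches the printed label on 51 of 52 rows; the single mismatch
(G63S, 4 damaging votes yet printed deleterious) is flagged in the
concordance report rather than corrected. Nine deleterious variants fall
in the two transmembrane stretches. The leucine codon swap CTG→CTA drops
relative adaptiveness from 100 to 18. The synthetic chase series, drawn
with a true half-life of 30 h and 10% multiplicative noise, fits to
35.6 h on this particular seed.

Stage orchestration (`run_triage`, `run_codons`, `run_traj`, `run_chase`)
writes TSV + JSON reports; a thin wrapper with subcommands lives at
`inst/scripts/varstab.R`:

```sh
Rscript inst/scripts/varstab.R triage --out-dir out/
Rscript inst/scripts/varstab.R simulate --stage trajectory --n 200 --out-dir sim/
```

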