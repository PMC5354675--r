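---
title: "Methods: quantifying melanoma cell-line fidelity"
author: "melafidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying melanoma cell-line fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melafidelity)
```

# The problem

Melanoma cell lines are the workhorse model of the field, yet a cultured
line differs from the tumour it was derived from in at least one systematic
way: a tumour biopsy contains immune and stromal cells whose transcripts are
absent from monoculture. `melafidelity` implements a pipeline that (i)
quantifies cell-line-versus-tumour transcriptional divergence while
explicitly attributing it to tumour purity, (ii) ranks individual cell lines
by their similarity to single malignant cells, so the comparison is not
confounded by the microenvironment at all, (iii) scores the two antagonistic
melanoma transcriptional programs (MITF-high proliferative versus AXL-high
invasive) in lines and single cells, (iv) classifies UV mutational
signatures from SNV catalogs, and (v) combines skin-specific expression with
UV status into tissue-of-origin calls and a per-line genomic summary.

Every stage runs on output of the bundled synthetic-cohort generator, so the
whole pipeline is testable end to end without any external download.

# Expression scales

All expression enters the statistics on `log2(TPM + 1)`. `rpkm_to_tpm()`
renormalises RPKM columns to sum to $10^6$; `to_log_tpm()` applies the
pseudo-count. For single-cell libraries, whose complexity is roughly an
order of magnitude below bulk (~100,000 transcripts), TPM is divided by 10
before the offset (`single_cell_scale = TRUE`), otherwise the pseudo-count
is negligible relative to inflated single-cell TPM values and the log values
are not comparable with bulk. Gene universes are matched by exact symbol
intersection (`intersect_universe()`); nothing is imputed.

# The synthetic cohort

The generator (`cohort_params()` + `simulate_*()`) encodes the structural
assumptions the analysis relies on, with defaults fixed at the conditions
the test-suite studies use:

* **Tumours as mixtures.** A tumour TPM profile is
  $\pi \cdot m + (1-\pi)\,[w \cdot i + (1-w)\, s]$ where $m$, $i$, $s$ are
  malignant, immune and stromal archetype profiles, $\pi \sim U(0.3, 0.7)$
  is tumour purity and $w \sim U(0.5, 0.9)$ — drawn once per cohort — makes
  immune contamination dominate stromal, mirroring the strong asymmetry
  between immune- and stromal-correlated divergent genes seen in real
  cohorts. Gene baselines are $\log_2$-normal ($\mu = 4$, $\sigma = 2$ on
  the log scale), a realistic span for expressed coding genes; immune and
  stromal block genes are shifted $\pm 3\ \log_2$ units between the
  archetypes. Multiplicative log-normal noise (default SD 0.3 log2 units)
  is applied before renormalisation to TPM.
* **Cell lines as pure malignant profiles**, plus the same noise — the core
  premise that culture removes the microenvironment.
* **Admixture scores.** The immune/stromal score tables are the mean
  log-expression of the true immune/stromal blocks per tumour. The pipeline
  only requires scores monotone in the respective cell fraction, which this
  construction guarantees (the generator's purity truth correlates with the
  immune score at $r > 0.99$ in the noiseless limit).
* **Single cells** are drawn 50/50 from MITF-high and AXL-high archetypes
  (program block elevated by `program_shift`, default 2 log2 units) and
  emitted at a ×10 TPM scale so the single-cell log path is exercised.
* **Graded cell-line panels** (`simulate_cell_line_panel()`) distort the
  malignant archetype by line-specific log-normal noise, giving a known
  fidelity ordering for validating the ranking.
* **Mutation catalogs**: each SNV of a UV-positive sample is a C>T at a
  dipyrimidine with probability `uv_fraction_pos` (default 0.75; 0.30 for
  negatives, bracketing the 0.6 decision threshold from both sides), else
  uniform over the remaining substitution/context classes; records are
  reported on a random strand so pyrimidine-strand collapse is exercised.
* **Survival**: exponential times with log-hazard linear in the
  standardized immune score, scaled so above/below-median groups differ by
  the requested hazard ratio; baseline median survival 60 months,
  administrative censoring at 120 months (the ten-year horizon).

What the generator deliberately does **not** model: read counts and library
size, single-cell dropout, copy-number segmentation, clonal structure, or
correlated gene modules beyond the planted blocks. Passing tests therefore
demonstrate that the statistics recover planted structure under realistic
noise — not that they are robust to every artefact of real RNA-seq.

# Immune divergence

`differential_expression()` computes per-gene Welch $t$ (unequal variances,
Welch–Satterthwaite df, two-sided $p$) between cell lines and tumours, with
Benjamini–Hochberg adjustment applied once over the full tested universe.
The top 5% of genes (`select_top_degs()`, `floor(0.05 m)` genes, ties broken
by raw $p$, then $|t|$, then gene id) are partitioned by their Pearson
correlation with the immune and stromal admixture scores across tumours:
`IMMUNE` if $r_{imm} > 0.4$, else `STROMAL` if $r_{str} > 0.4$, else
`NEITHER`. The thresholds are strict inequalities. Genes clearing both
thresholds are labelled `IMMUNE` — the published accounting does not define
the overlap rule, and immune precedence matches the biological focus on
immune admixture. Zero-variance genes get $r = 0$ plus a flag rather than
`NA`, so the partition is total.

The immune DEG value of a tumour is the sum over immune-labelled top genes
of that gene's Z-score across tumours ($n-1$ denominator; zero-SD genes
contribute 0). `survival_logrank()` dichotomizes at the median — strictly
above is `HIGH`, ties go `LOW` — censors events beyond the ten-year horizon,
and reports Kaplan–Meier curves plus the 1-df log-rank chi-square
(`survival::survdiff`). Samples lacking either a score or survival data are
dropped before the split.

# Fidelity ranking and MITF/AXL states

`rank_by_single_cell_correlation()` scores each line by the mean Pearson
correlation with every single malignant cell over all shared genes, on
`log2(TPM+1)` (the published analyses do not state the scale for these
correlations; the log scale is used consistently here since raw TPM
correlations are dominated by a handful of extreme genes). Zero-variance
pairs are skipped, not scored 0, to avoid biasing the mean.

Program cell scores follow the control-matched construction: per-gene
centering across cells, raw score = mean relative expression of program
genes, control = mean over a pool built by cutting all genes into 25
equal-frequency bins of average expression and drawing 100 control genes
from the bin of each program gene (with replacement — at the default 2,000
gene scale bins hold ~80 genes), score = raw − control. Cells are ordered
along the state axis by `score_MITF − score_AXL`: the difference rather
than a literal quotient, because control-subtracted scores can be zero or
negative, where a ratio is ill-defined; on the additive log scale the
difference is the monotone analogue. The `k` highest/lowest cells (default
400) define the MITF-top and AXL-top reference sets for the state-specific
rankings.

Per-line program enrichment is the one-sample $t$ of the set genes'
cross-sample Z-scores against zero (`gene_set_enrichment()`, single-sample
mode); the two-group mode compares a set's log-fold changes between two
sample groups to the all-gene background by Welch $t$. These explicit
statistics replace a black-box enrichment package so the pipeline is fully
reproducible from its own definitions.

`cluster_program_states()` runs Gaussian-kernel mean-shift on the 2-D
enrichment coordinates, with per-axis Silverman bandwidths
($h_j = \sigma_j n^{-1/6}$ for $d = 2$). Each line ascends the density to a
mode; modes closer than one (scaled) bandwidth merge. The cluster with the
highest mean MITF−AXL difference is `MITF`, the lowest is `AXL`, everything
else pools into `INTERMEDIATE`. With fewer than two modes the procedure
falls back to the sign of MITF−AXL with a warning. The procedure has no
internal randomness, so labels are deterministic and invariant to input
order.

# UV mutational signatures

`normalize_substitution()` collapses every SNV to the pyrimidine strand
(purine-reference records are reverse-complemented, flanks swapped and
complemented) yielding the six standard substitution classes; a site is a
dipyrimidine when at least one flank is C or T after collapse — the
standard UV-context convention; the source data do not state an adjacency
rule beyond this. A sample is UV-signature positive when the fraction of
its SNVs (all SNVs, not only C>T) that are C>T at dipyrimidines strictly
exceeds 0.6. `compare_alteration_frequencies()` is the exact binomial test
with the two-sided minimum-likelihood rule, stated explicitly because
two-sided conventions differ.

# Origin scoring and the genomic summary

Skin-origin scores weight each panel gene by its squared, normalised
tissue-enrichment score ($EE_g^2 / \sum EE^2$) and sum weight × expression
per sample. Panel genes missing from the universe are dropped and the
weights renormalised, keeping scores comparable across datasets with
different coverage. The score is linear in expression and invariant to
rescaling all EE values. The default calling threshold of 95 is tied to the
variance-stabilised scale of the original panels; on any other scale
(including the synthetic cohort) the threshold must be chosen from data,
which is why `call_probable_origin()` exposes it as a parameter. A sample
in the high-skin-score, UV-positive quadrant is flagged probable melanoma
origin; the published narrative combines the two axes informally, and the
conjunction is the conservative reading — `skin_high` alone remains visible
in the output as the candidate flag.

Hierarchical clustering uses Euclidean distance with `ward.D2` —
dissimilarities enter un-squared and are squared inside the Lance–Williams
update — pinned explicitly because "Ward" implementations differ. Copy
number events are `AMP` above +1 and `DEL` below −0.75 on ploidy-corrected
values, strict inequalities. `build_genomic_summary()` joins state, UV
flag, mean correlation, per-gene mutation status (`MUT`/`WT`/`NA`) and CN
calls into the per-line model-selection table.

# Numerical choices and degenerate inputs

* Variance ties in `top_variance_genes()` and rank ties everywhere else
  break lexicographically by identifier — determinism over elegance.
* PCA centers genes but does not scale them: scaling would undo the
  variance ranking that selects the input genes in the first place.
  Component signs are fixed (largest-magnitude loading positive).
* Welch on a gene constant in both groups with equal means is defined as
  $t = 0, p = 1$; with unequal means $p = 0$.
* Duplicate gene rows in expression input collapse by per-sample maximum,
  preserving detection of the expressed isoform; the collapse is
  idempotent.
* All generators restore the caller's RNG state; a seed argument is the
  only entry point for randomness.

# Problem sizes in the test suite

The bundled tests validate on cohorts of 2,000 genes × 120 tumours × 30
cell lines × 200 single cells, 500 mutation samples × 100 SNVs, and 1,000
null survival replicates of n = 200 — sizes at which every planted effect
is comfortably detectable yet the whole suite runs in well under a minute,
chosen so the tests can be re-run habitually during development.

# Known limitations

The admixture model is linear in TPM space with a single immune weight per
cohort; real tumours vary in composition continuously. The ESTIMATE-style
scores are stand-ins that are monotone in the true fractions by
construction; results on real ESTIMATE output depend on that algorithm's
own behaviour. The UV classifier uses only the single-base C>T fraction —
no CC>TT dinucleotide component and no signature deconvolution. Skin-score
thresholds do not transfer across normalisation scales. Mean-correlation
ranking is intentionally coarse: it guides model choice, it does not claim
a finely graduated ordering.
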