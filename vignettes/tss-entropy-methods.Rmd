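---
title: "Methods: bias-corrected TSS entropy and chromatin-feature model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-corrected TSS entropy and chromatin-feature model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssentropy)
```

## The model

Transcription at a mammalian promoter does not start at one fixed base but
at a distribution of positions within the core promoter, here the
strand-oriented window of ±1000 bp around the annotated TSS. `tssentropy`
assumes that distribution is Gaussian with unknown standard deviation σ (in
bp) and summarises its width as the differential entropy

$$H(\sigma) = \tfrac{1}{2}\,\ln(2\pi e \sigma^2),$$

in nats. Entropy rather than the sample standard deviation is used because
the SD is fragile: a handful of background tags far from the mode can move
it by an order of magnitude, while the entropy of the fitted Gaussian
scenario barely shifts (the `std_entropy_robustness()` harness quantifies
this; under 20% uniform background noise the entropy-based AUC for
separating σ = 5 from σ = 25 populations is near 1 while the SD-based AUC
collapses toward chance).

Assumptions worth stating plainly: one unimodal Gaussian per promoter (no
mixtures, no multi-modal shapes), tags independent given σ, and 1-bp bins
(CAGE resolves single nucleotides). Multi-modal promoters exist in real
data; for them the estimated σ̂ describes an effective width, not the shape.

## The estimation procedure

The plug-in histogram estimator
$U = -\sum_i p(i)\ln p(i)$, with $p(i)$ the fraction of the promoter's $k$
tags in 1-bp bin $i$, is bounded by $\ln k$ and therefore biased low
whenever the depth is small relative to the spread (at $k=20,\ \sigma=30$
the bias is about −1.9 nats). The correction works by simulation rather
than an analytic bias formula:

1. **Reference matrix (SDEM).** For every scenario (n tags, σ), n = 1…200
   and σ = 1…100, draw 50 independent samples of n points from
   Normal(0, σ²), round to integer bp, and record the mean and SD of the 50
   histogram entropies. `build_sdem()` returns this pair of 200 × 100
   matrices; `write_sdem()`/`read_sdem()` serialise them as TSV.
2. **Maximum-likelihood adjustment.** For a promoter with k tags and
   observed entropy U, score every column j of row k by the likelihood
   $L_j = \Phi\!\big(\tfrac{U+\alpha-m_{kj}}{s_{kj}}\big) -
   \Phi\!\big(\tfrac{U-\alpha-m_{kj}}{s_{kj}}\big)$ with α = 0.1, and pick
   the maximising σ. The adjusted TSS entropy is $H(\hat\sigma)$.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `window` | 1000 bp | core promoter half-width; tags outside `[-1000, 1000)` (strand-oriented) are dropped at load time |
| `min_reads` | 10 | strict depth filter (`k > 10`); below ~10 reads the estimator no longer converges usefully |
| `n_max` | 200 | largest simulated depth; deeper promoters clamp to the last row (the estimate is already stable well before 200 tags), with a warning |
| `sigma_max` | 100 | flat distributions beyond σ = 100 bp are not of interest |
| `B` | 50 | resamples per SDEM cell |
| `alpha` | 0.1 | likelihood half-window; σ-recovery error changes by <20% across α ∈ {0.05, 0.1, 0.2} (asserted in the tests), so the choice is not delicate |

### Numerical choices

* All internal entropy arithmetic is in **nats**; a `base = "log2"` output
  option only rescales. The differential-entropy closed form is natural in
  nats and every internal comparison is base-free.
* The σ grid is the **integers 1…100**: σ = 0 is a degenerate point mass
  with no differential entropy, so the grid starts at 1. A single tag
  (k = 1) always has U = 0, row 1 of the SDEM is identically (0, 0), and the
  tie rule maps such promoters to σ̂ = 1.
* **Degenerate cells**: where the cell SD is below 1e−9 the CDF difference
  is undefined; the likelihood becomes the indicator |U − mean| ≤ α.
* **Ties** in the likelihood scan resolve to the smallest σ —
  deterministic and conservative (narrow call).
* Simulated Gaussian draws are rounded with **round-half-to-even** (R's
  `round()`), matching the discretisation applied to real 1-bp tag
  positions.
* The likelihood integral is the exact normal-CDF difference, not
  quadrature.
* Adjacent SDEM columns differ in mean by roughly $\ln\frac{j+1}{j}$ nats,
  which near σ = 100 is below the Monte-Carlo jitter of a 50-resample cell;
  σ̂ is therefore reproducible to ±1–2 grid steps, not to the exact column,
  and downstream analyses treat it accordingly.

## Feature aggregation

Windows use 0-based half-open coordinates internally (BED-native; CTSS
1-based positions are converted at the boundary). Signal tracks are
aggregated as the overlap-weighted sum (interval value × bp of overlap) over
each window — summing raw signal, not depth-normalised, and splitting a
track interval at any point leaves every aggregate unchanged (a tested
invariant). Motif-cluster scores arrive as a precomputed per-promoter table;
scanning and motif clustering are upstream of this package. CpG-related and
non-CpG promoters are split before any model fitting and never mixed in one
fit; the CpG label is consumed, never computed.

## Model selection

Every k-feature subset is fit by OLS and scored by 5-fold cross-validation:
fit on 4/5 of promoters, predict the held-out fifth, record the Pearson
correlation between predicted and measured entropy, and average the five
fold PCCs. Coefficients are reported from a final fit on all data (the CV
fits only score). Fold assignment is a seeded uniform random permutation,
unstratified. A fold with zero-variance predictions scores 0 with a warning
rather than NA, so degenerate subsets rank last instead of poisoning the
ranking.

The BIC is the Gaussian-likelihood variant
$n\ln(\mathrm{RSS}/n) + (p+2)\ln n$, counting the intercept and the error
variance among the parameters; RSS = 0 maps to a −Inf sentinel with a
warning. Ranking is by mean CV PCC descending, ties by smaller BIC then
lexicographic feature names, so outputs are fully deterministic.

Enumeration is exhaustive up to `cap = 2e5` subsets (C(180, 3) ≈ 9.5e5 is
feasible but slow; the cap is configurable so a full exhaustive run remains
possible). Beyond the cap a greedy forward beam search (width 20) substitutes
with a message; on pools small enough to check, the beam and exhaustive
searches select the same best subsets (a tested equivalence).

"Best models" are those with mean CV PCC > 0.1. Transferred models keep
their frozen coefficients and are scored by PCC on the target cohort.
ROC analysis sweeps a threshold over predicted entropies with "broad" as the
positive class and integrates by trapezoid; in synthetic mode, ground-truth
labels derive from the true σ with a narrow/broad boundary at 10 bp.

## Mark classification and the bivalent comparison

Each histone mark's window-aggregated level is correlated **across
promoters** with the Pol II and H2A.Z levels (both established proxies for
promoter nucleosome organisation), giving a (PCC-with-Pol II,
PCC-with-H2A.Z) pair per mark. A per-promoter positional-profile correlation
would be an alternative reading; across-promoter correlation is the default
here because every other quantity in the package lives at promoter
resolution, and the pair (rather than its mean) is clustered to keep the two
references' information separate.

The pairs are clustered with `stats::kmeans()`, k = 2, 10 seeded random
restarts, lowest within-cluster SSE kept — the standard, well-tested
implementation; with the bimodal inputs the classification rests on, any
reasonable initialisation converges to the same partition, and the seeded
restarts make it reproducible. Cluster identity is made deterministic by
relabelling: the cluster with the higher centroid mean correlation is
Class I (nucleosome-correlated, active-type), the other Class II. With
exactly two marks, each is its own class by definition.

`bivalent_comparison()` partitions 2-feature models over classified marks
into cross-class and same-class groups and reports each group's count, mean
and SD of CV PCC, plus the difference of means. An `exclude` argument
removes named marks (e.g. Class II marks that signal activity in gene
bodies) as a bias control. On default synthetic data the cross-class
advantage is ≈0.2 PCC; with the planted repressive effect set to zero it
collapses (slightly negative, since two same-class active marks average
away noise).

## The synthetic-data generator

The generator is **latent-first**: per promoter it draws a nucleosome
signal N ~ N(0,1) and an independent repressive signal R ~ N(0,1), forms
the predictor η = c₁N + c₂R + ε (defaults c₁ = 0.8, c₂ = 0.5,
sd(ε) = 0.4), and maps η affinely onto log σ so that σ covers [2, 80] bp
(clamped at the edges; <5% of promoters touch a clamp at defaults). True
entropy is H(σ), so the linear model the selection stage must find exists by
construction, and the effective post-scaling coefficients are stored with
the truth table — the parameter-recovery gate checks OLS on (N, R) recovers
them within 10% at n ≥ 2000. CpG promoters get a +0.3 log-σ shift (CpG
promoters are broader), non-CpG −0.3.

Observed layers: depth k per promoter is negative-binomial (mean 50,
size 5 — overdispersed, as tag counts are); tags are Normal(0, σ²) rounded
to bp; optionally a Binomial(k, `noise_fraction`) subset is replaced by
background tags, uniform over the window or Normal(0, (5σ)²) for a wide
Gaussian background. Active marks and the NU/DNase features are N plus
Gaussian noise (sd 0.5 for marks; sd 1 for NU/DNase, which are noisier
proxies in practice), repressive marks are R plus noise, SEQ motif features
are pure noise, and the Pol II / H2A.Z references are N plus small noise
(sd 0.2), giving active marks reference correlations ≈0.9 and repressive
marks ≈0 — the bimodal structure the k-means stage needs.

What the generator does **not** emulate: multi-modal or skewed TSS shapes,
positional signal profiles within the window (features are scalar
aggregates by construction), mappability and GC artefacts, correlated noise
between marks, library-size differences between samples, and any sequence
realism (SEQ features are abstract scores). Passing tests therefore
demonstrate that the estimator and the selection machinery recover planted
structure of the assumed form — not that real promoters follow that form.

## Validation problem sizes

The test-suite simulations use 200–1000 replicates for estimator
properties (bias, σ recovery, α insensitivity), cohorts of 1000–3000
promoters for model selection and classification, 50 seeds for the
bivalent comparison, 100 seeds for planted-feature recovery and BIC
behaviour, and 20 paired cohorts for transfer; the acceptance script uses
the same sizes. These are large enough that the Monte-Carlo error of each
checked quantity is several-fold smaller than the margin being asserted.

## Known limitations

* The Gaussian single-component assumption is structural; σ̂ for genuinely
  multi-modal promoters is an effective width.
* σ̂ is quantised to an integer grid and reproducible only to ±1–2 grid
  steps where adjacent scenario means are within Monte-Carlo jitter.
* Depths above `n_max` clamp to the last SDEM row; for very deep CAGE
  libraries the correction is effectively that of 200 tags (where the bias
  is already small).
* CV folds are unstratified; with strong depth–entropy confounding a
  stratified scheme could differ slightly.
* Real-data mode consumes precomputed CpG labels and motif scores; it does
  not compute them.
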