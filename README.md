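# tssentropy

Quantifying the *shape* of transcription initiation: is a promoter's
transcription start site (TSS) a single sharp position, or a broad region of
many weakly used starts?

Cap Analysis Gene Expression (CAGE) sequencing gives single-base-pair counts
of where transcripts actually start. `tssentropy` treats a promoter's CAGE
tags as a finite sample from an unknown Gaussian distribution of initiation
positions and summarises the distribution's width as its Shannon entropy,

&nbsp;&nbsp;&nbsp;&nbsp;*H*(σ) = ½ ln(2π e σ²) &nbsp; (nats),

then asks which chromatin and sequence features of the core promoter
(±1000 bp around the annotated TSS) predict that entropy. The package is
aimed at regulatory genomicists working with CAGE-style 5′-end data and
promoter-window chromatin signal.

## What the package implements

1. **Bias-corrected entropy estimation.** The plug-in ("histogram")
   estimator −Σᵢ p(i) ln p(i) over 1-bp bins is strongly biased downward at
   realistic sequencing depths. The package builds a simulated reference
   matrix (the *SDEM*): for every sampling scenario of n = 1…200 tags drawn
   from a Gaussian with σ = 1…100 bp, the mean and standard deviation of the
   histogram entropy over 50 resamples. Given a promoter's observed entropy
   *U* from *k* tags, the σ whose scenario maximises the likelihood of *U*
   (normal-CDF mass on [*U* − α, *U* + α], α = 0.1) is selected, and the
   *adjusted* TSS entropy is *H*(σ̂). Promoters need more than 10 reads to be
   estimated.
2. **Feature aggregation.** Promoter windows from BED6(+1), tags from
   CTSS-style text, overlap-weighted sums of bedGraph signal per window, and
   precomputed motif-cluster score tables, assembled into a promoters ×
   features tibble (types HM / NU / SEQ / DNase); CpG-related and non-CpG
   promoters are analysed separately.
3. **Exhaustive linear-model selection.** All k-feature OLS models
   (k = 1, 2, 3, and the full pool) scored by 5-fold cross-validated Pearson
   correlation (PCC) between predicted and measured entropy, plus a
   Gaussian-likelihood BIC; "best models" are those with mean CV PCC > 0.1.
   Trained models can be transferred to a second cohort with frozen
   coefficients, and predicted entropies drive a narrow/broad ROC analysis.
4. **Histone-mark classes and the bivalent-like comparison.** Marks are
   correlated with the Pol II and H2A.Z nucleosome proxies across promoters
   and split by 2-means clustering into Class I (nucleosome-correlated,
   active-type) and Class II. The key comparison: 2-feature models pairing
   one Class I with one Class II mark (*cross-class*) versus pairs from a
   single class — a cross-class advantage is the signature of bivalent-like
   control of initiation shape.
5. **A synthetic-data generator** that plants exactly this structure (a
   latent nucleosome signal, an orthogonal repressive signal, and a linear
   entropy model on both) so the whole pipeline runs and is validated
   without any external data.

## Worked example

```r
library(tssentropy)
library(dplyr)

# 1. simulate a CAGE-like cohort with a planted bivalent chromatin code
ds <- simulate_dataset(sim_config(n_promoters = 1000, seed = 42))

# 2. build the bias-correction reference matrix and estimate TSS entropy
sdem <- build_sdem(n_max = 200, sigma_max = 100, B = 50, seed = 42)
entropy <- estimate_entropy(ds$tags, sdem, alpha = 0.1, min_reads = 10)
print(entropy, n = 3)
#> # A tibble: 993 × 6
#>   promoter_id     k     U sigma_hat H_adj likelihood
#>   <chr>       <int> <dbl>     <dbl> <dbl>      <dbl>
#> 1 p00001         37  3.06        10  3.72      0.686
#> 2 p00002        112  3.29         8  3.50      0.856
#> 3 p00003         39  3.40        28  4.75      0.824
#> # ℹ 990 more rows

# 3. enumerate 2-feature models predicting the entropy
dat <- inner_join(entropy[, c("promoter_id", "H_adj")], ds$features, "promoter_id")
m2 <- enumerate_models(dat, "H_adj", k = 2, seed = 1)
print(m2, n = 3)
#> <tss_models> 231 model(s), k = 2
#>   HM_active_05 + HM_repressive_03: mean CV PCC 0.739, BIC -777.8
#>   HM_active_05 + HM_repressive_06: mean CV PCC 0.735, BIC -763.6
#>   HM_active_05 + HM_repressive_05: mean CV PCC 0.733, BIC -758.0
#>   ... and 228 more

# 4. classify marks against the nucleosome proxies and compare
#    cross-class vs same-class 2-models
hm <- ds$feature_info$feature[ds$feature_info$type == "HM"]
classes <- kmeans_two_classes(
  mark_reference_pcc(ds$features, ds$references, marks = hm), seed = 1)
report <- bivalent_comparison(best_models(m2), classes)
print(report)
#> # A tibble: 2 × 4
#>   partition     n mean_pcc  sd_pcc
#>   <chr>     <int>    <dbl>   <dbl>
#> 1 cross        36    0.719 0.00925
#> 2 same         30    0.519 0.114
```

Reading the output: of 1000 simulated promoters, 993 pass the >10-read
filter. Promoter `p00001` has 37 tags whose raw histogram entropy (3.06
nats) is biased low; the maximum-likelihood scenario is σ̂ = 10 bp, giving an
adjusted entropy of 3.72 nats. Every one of the ten strongest 2-feature
models pairs an active mark with a repressive mark, and across all passing
2-models the cross-class pairs predict entropy substantially better (mean CV
PCC 0.72) than same-class pairs (0.52) — the bivalent-like signature the
generator planted and the analysis recovers.

The same stages run end-to-end, per CpG class, with TSV outputs and a JSON
manifest, via:

```r
run_pipeline(run_config(sim = sim_config(seed = 1), seed = 1), "run_out/")
```

`autoplot()` methods exist for SDEM objects, ROC curves and mark
classifications; `tidy()`/`glance()` methods summarise model sets.

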