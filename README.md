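# nucflow

Single-cell quantification of nucleocytoplasmic protein dynamics from
multi-channel time-lapse fluorescence movies.

## What it is for

Many regulatory proteins respond to stress by moving from the cytoplasm
into the nucleus. Measured in single cells with endogenously tagged
proteins, such responses show two robust features that population assays
miss: large cell-to-cell variability of expression (coefficients of
variation around 0.4) and tightly correlated dynamics of functionally
coupled proteins. `nucflow` is an R implementation of the complete
quantification chain for such experiments:

* a **synthetic movie generator** producing multi-channel time-lapse
  movies with full per-cell ground truth (lognormal expression with a
  Gaussian copula between channels, logit-normal nuclear fractions,
  persistent random-walk motility, cell cycle and divisions, saturating
  drug-induced nuclear accumulation, flat field, shot/read noise,
  photobleaching);
* **correction and segmentation**: flat-field and background correction,
  nuclear seed detection on a smoothed red reference channel, seeded
  partitioning of touching cells, fixed-threshold nucleus extraction per
  cell, per-cell fluorescence measurement (total, nuclear, cytoplasmic,
  nuclear enrichment);
* **tracking**: backward nearest-centroid linking, division detection by
  the twofold intensity drop plus a co-appearing sibling, track alignment
  on drug addition or on divisions (in-silico synchronization);
* **statistics**: CV and 90:10 percentile ratio, Spearman correlation
  with bootstrap CIs, per-cell response metrics (Fi, Fmax, T50), the
  normalized lag cross-correlation

  R(τ) = ⟨(c(t) − c̄(t)) (y(t+τ) − ȳ(t+τ))⟩ / √(⟨(c − c̄)²⟩ ⟨(y − ȳ)²⟩),

  averaged over cells and time, and its decorrelation time τ50 (first lag
  with R ≤ R(0)/2);
* an **in-silico artificial-exon tagging designer**: reading-frame
  cassettes (one per phase), intronic insertion and splicing arithmetic,
  in-frame checks, RT-PCR and nested 3'RACE amplicon prediction.

## Worked example

Simulate a small drug-response movie, quantify it, and measure the
population response:

```r
library(nucflow)

scene <- sceneParams(n_cells = 60, field_size = c(600, 600),
                     frame_interval = 30, n_frames = 20,
                     drug_frame = 5, rng_seed = 1)
sim   <- simulateMovie(scene)

meas   <- quantifyMovie(sim$stack,
                        flat_field = sim$stack@metadata$flatField)
tracks <- detectDivisions(linkTracks(meas))$tracks

f1 <- subset(tracks, frame == 1 & !border)
populationCV(f1$total_cyan)
#> [1] 0.3893279
ratio9010(f1$total_cyan)
#> [1] 2.601037
cor(f1$total_cyan, f1$total_yellow, method = "spearman")
#> [1] 0.5403168
```

The CV of ~0.39 and 90:10 ratio of ~2.6 are the generator's lognormal
cell-to-cell variability (CV set to 0.41) seen through segmentation and
camera noise at n = 60 cells; the rank correlation of ~0.53 estimates the
copula's 0.64 at this small n. Aligning the nuclear traces on the drug
frame and normalizing each cell to its pre-drug baseline gives the
mean fold accumulation and per-cell response times:

```r
tm   <- traceMatrix(tracks, "nuclear", "cyan")
time <- (as.numeric(colnames(tm)) - 5) * 0.5          # hours from drug
norm <- normalizeToBaseline(tm, time, 0)
resp <- responseMetrics(tm, time, drug_time = 0, window = 7.5)
```

`pipelineBenchmark()` runs this entire loop at full scale (200 cells, 60
frames) against the generator's ground truth and reports segmentation
Jaccard, link accuracy, division recall, and recovery of the CV, rank
correlation, nuclear fold change and T50.

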