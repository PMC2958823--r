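---
title: "Quantifying nucleocytoplasmic protein dynamics in single cells with nucflow"
author: "nucflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleocytoplasmic protein dynamics in single cells with nucflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucflow)
```

# The problem

Proteins that shuttle between cytoplasm and nucleus — for instance redox
regulators that accumulate in the nucleus under genotoxic or oxidative
stress — are best studied in individual living cells: population averages
hide both the large cell-to-cell variability of expression and the
correlated timing of each cell's response. The experimental design this
package supports is a multicolour time-lapse movie of endogenously tagged
proteins: a red reference channel (a tagged protein that is bright in the
nucleus and dimmer in the cytosol, expressed quite uniformly across cells)
drives segmentation, while two spectrally separated tags (cyan and yellow)
report the levels and localization of the two proteins of interest. Frames
are taken every 20 minutes for 30 hours or more; a drug may be added at a
known frame.

`nucflow` implements the complete quantification chain —

1. **synthetic movies** with exact ground truth, so every downstream stage
   is testable without any microscope data;
2. **image correction and segmentation** (flat field, background, seeded
   partitioning of cells, per-cell nucleus extraction);
3. **tracking** (nearest-centroid linking, division detection, in-silico
   synchronization);
4. **statistics** (variability, drug-response metrics, lag
   cross-correlation and decorrelation time);
5. an **in-silico artificial-exon tagging designer** that reproduces the
   validation arithmetic of intron tagging (reading frames, splicing,
   RT-PCR and 3'RACE products).

# The synthetic movie generator

The generator is first-class, tested code: its defaults define the study
conditions the rest of the package is validated against.

**Expression.** Per-cell total levels of the two tagged channels are
lognormal (long right tail, as measured protein distributions are) with
coefficients of variation 0.41 and 0.44, joined by a Gaussian copula so
that a requested Spearman correlation (default 0.64) is preserved exactly
under the monotone marginals. Nuclear fractions start at 0.43 / 0.39 of
the total and vary between cells on the logit scale (sd 0.9), which keeps
them in (0, 1) and reproduces the observation that nuclear levels are
roughly twice as variable as whole-cell levels; the per-cell deviations of
the two channels share a copula with rank correlation 0.85, so nuclear
enrichment is the most correlated measure. The red reference channel has
CV 0.15 ("relatively uniform") and a fixed 3:1 nucleus:cytoplasm intensity
contrast realized through each cell's actual geometry.

**Geometry.** Cells are ellipses with jittered axes (mean radius 12 µm at
0.8 µm/pixel) and a concentric nuclear ellipse at 0.55 of the cell axes.
Simple shapes are deliberate: the analysis operators make no use of shape
beyond masks, and crisp geometry makes conservation checks exact.

**Motion.** Cells take one step of `mean_speed × Δt` (default 8.5 µm/h)
per frame along a persistent heading with turning noise — migrating cells
keep direction over an hour or two — and neighbours exert soft volume
exclusion (centres are relaxed to at least 0.85 of their summed radii).
Exclusion matters: without it unrelated neighbours drift into full
overlap, which no real monolayer does, and any segmenter will merge them.
Cells may leave and re-enter the field; the truth records visibility per
frame.

**Cell cycle and division.** Each cell draws one cycle length from a
truncated normal (28 ± 4 h); its fluorescent content doubles exponentially
over the cycle, and at the end the cell divides: the two daughters split
every channel's signal as q and 1 − q with q ~ U(0.45, 0.55), so the sum
is conserved exactly. Cells entering mitosis pause migration for that
frame (mitotic rounding), daughters shrink to 0.75 of the mother's axes and are placed at ±0.7 of
her semi-major axis (roughly in contact) with opposite initial headings (cytokinesis pushes sisters
apart). Division is age-triggered, not signal-triggered.

**Drug response.** From the drug frame on, division and growth arrest (as
under a DNA-damaging drug) and each tagged channel's nuclear signal
relaxes as a saturating exponential (timescale 6 h) toward a per-cell
target, while the total stays constant — so the cytoplasmic signal falls
correspondingly. Two response modes are provided. In `absolute_target`
(the default) targets are common across cells up to a lognormal dispersion
(sd 0.1), so dim nuclei rise more in relative terms: nuclear CV falls
after the drug and the initial level anti-correlates with the fold rise.
In `fold_change` each target is a fold multiple of the cell's own initial
level. Targets are capped at 95 % of the cell's total (nuclear signal
cannot exceed the cell's content) and the common scale is calibrated on
the realized population at the drug frame, under that cap, so the mean
per-cell fold at 25 h equals the requested value (defaults 1.78 / 1.95) in
expectation.

**Rendering.** Cells are painted at uniform cytoplasmic and nuclear
densities chosen so the integral over the discretized mask equals the true
signal exactly; a parabolic flat-field vignette (corner drop 15 %),
a constant background offset (100 counts), Poisson shot noise and Gaussian
read noise (sd 2) follow, and pixels are quantized to 16-bit camera
counts. The true flat field and background are stored in the movie
metadata so correction can be verified. With noise off, a uniform flat
field and `quantize = FALSE`, per-cell integrated intensity equals the
true total to machine precision — the conservation oracle the tests use.
Photobleaching is a global exponential multiplicative decay totalling 3 %
over the movie, applied at render time; the truth table keeps unbleached
signals so division bookkeeping stays exact. There is no PSF convolution,
no z-dimension and no phase-contrast physics (the phase channel is a flat
placeholder): passing tests demonstrate correctness of the *operators*, not
photorealism, and real movies with strong blur or clumping will segment
worse than these synthetic ones.

```{r quick-movie, eval = FALSE}
sim <- simulateMovie(sceneParams(n_cells = 75, n_frames = 90,
                                 drug_frame = 15, rng_seed = 1))
writeMovie(sim$stack, "movie_dir")       # 16-bit TIFF per channel + YAML
writeGroundTruth(sim$truth, "movie_dir") # truth CSV + parameter sidecar
```

# Segmentation

Processing follows the classic red-channel recipe with a few robustness
choices worth documenting:

* **Correction.** `corrected = (raw − dark) / normalized flat field`,
  negatives clipped. The dark offset can be estimated per frame as the
  median of below-Otsu pixels.
* **Foreground.** A plain Otsu split is unreliable here for two reasons:
  the red histogram has *three* modes (background, cytoplasm, 3×-brighter
  nucleus) and with few or very clean cells the between-class criterion
  can prefer the cytoplasm/nucleus split; and after background
  subtraction the zero-clipped noise floor distorts the histogram (it also
  zeroes the MAD). The package therefore uses Otsu only to seed a
  background sample and thresholds at the background median plus 4 robust
  upper-quantile sigmas — on a noiseless image this degenerates to
  "anything above background", exactly the true mask.
* **Seeds.** The smoothed red image (Gaussian σ ≈ half the nuclear
  radius, default 4 px) is split nucleus-vs-cytoplasm *per connected
  foreground component* — a global split loses the seeds of dim cells,
  e.g. freshly divided daughters with half the content — and a watershed
  on the resulting relief separates touching nuclei.
* **Cells.** Foreground pixels are partitioned among seeds by seeded
  region growing on the smoothed intensity (`EBImage::propagate`, the
  seeded counterpart of the watershed transform; `EBImage::watershed`
  itself is unseeded). Foreground components without a seed are dropped by
  default as debris; `keep_seedless = TRUE` keeps them. A second pass then
  re-examines every segmented object with a tolerance watershed on its
  smoothed interior: an object holding two intensity maxima of sufficient
  prominence is an under-segmented pair — freshly divided sisters, or a
  dim cell pooled with a much brighter neighbour, which defeats any
  threshold rule but not maxima counting — and the watershed basins become
  the corrected labels.
* **Nuclei.** Within each cell the red intensity is min–max stretched to
  [0, 1] and thresholded at a fixed value (default 0.5, configurable);
  the largest connected component inherits the cell's label, so nuclei
  are nested inside cells by construction. A cell with no contrast gets
  an empty nucleus and a warning.
* **Measurement.** Totals are sums of corrected intensity over the cell
  mask, nuclear sums over the nucleus mask, cytoplasm their difference,
  enrichment the nuclear/total ratio; centroids are unweighted mask
  centroids. Cells touching the border are measured but flagged, and
  population statistics exclude them by default (partial cells bias
  totals). Coordinates are R's native 1-based pixel centres; areas are in
  pixels, converted to µm² only in reports.

The seeds-first ordering resolves the chicken-and-egg between "nuclei as
cell seeds" and per-cell nucleus refinement: bright smoothed blobs act as
seeds, and the definitive nucleus mask is recomputed per cell afterwards.

# Tracking and synchronization

Linking scans the movie from its last frame to its first, attaching each
cell to the closest centroid in the previous frame. Matching is one-to-one
and greedy by ascending distance with ties broken by the lower label pair
(deterministic). Links beyond `max_displacement` (default 15 µm) are
refused; the gate must cover both the per-frame migration step (~2.8 µm at
defaults) and the centroid jump from a mother to her daughters at division
(about one cell radius), while staying far below typical neighbour
spacing, and mostly protects against cells entering the field being
grafted onto unrelated tracks.

Division is detected as a drop of a track's total red fluorescence to at
most 0.6× its previous value — the nominal twofold split with noise
margin — *plus* a sibling track born at the same frame (or one frame
later, for a daughter briefly pooled with a touching neighbour) within two
cell diameters. The sibling requirement exists because an intensity drop
alone also fires on segmentation failures. Three further guards reject
drop events that halve the intensity without being divisions: drops of
border-flagged cells (a cell sliding off the field fades), transient
one-frame dips (merge/split flicker reverts immediately), and drops within
six frames of a ≥1.3× upward jump (only a merge with a neighbour produces
jumps — an unperturbed mother grows by a few percent per frame — and the
merged pair separating again mimics a division). The red channel is used
because every cell expresses the reference marker; the channel is
configurable. Each event splits the mother track into two daughter tracks
carrying `parent_track`.

`synchronizeTracks` re-indexes traces to hours relative to an event: the
drug frame, the track's own birth-by-division (in-silico synchronization —
the computational replacement for chemically synchronizing a culture), or
no event. Tracks lacking the event are excluded and counted.

# Statistics

* **Variability**: CV = sample sd / mean (n − 1 denominator throughout)
  and the 90:10 percentile ratio, with percentiles by linear interpolation
  (type 7; documented because percentile conventions differ). Both are
  invariant under positive rescaling, so they are unaffected by exposure
  or gain.
* **Correlation**: Spearman by default, with a percentile bootstrap CI
  over cells (1000 resamples) to report robustness.
* **Response metrics**: per cell, Fi (level at drug addition, baseline
  averaged), Fmax (max within the 25-h window), their difference and
  ratio, and T50 — the time to reach halfway between Fi and the level at
  25 h, by linear interpolation between frames. The half level uses the
  25-h value rather than Fmax, matching the definition "half of the
  nuclear level observed 25 h after addition". Flat traces get T50 = 0
  and a degenerate flag; traces that never reach the half level are
  flagged censored. Cells leaving the movie before the window ends are
  excluded and counted.
* **Cross-correlation**: for traces c(t), y(t) of the two channels in the
  same cells,
  R(τ) = ⟨(c(t) − c̄(t)) (y(t+τ) − ȳ(t+τ))⟩ / √(⟨(c − c̄)²⟩⟨(y − ȳ)²⟩),
  where c̄(t), ȳ(t) are the per-time-point cross-cell means and ⟨·⟩
  averages over cells and all valid time pairs at that lag. Subtracting
  the cross-sectional means removes population-wide trends (growth,
  bleaching, the shared drug response), so R measures *co-fluctuation of
  deviations*. The matched-sample Pearson normalization bounds |R| by 1
  (Cauchy–Schwarz) and gives R(0) = 1 for identical traces; the
  unnormalized covariance is also returned. Cross-cell means are global
  (not per-field) by default. The decorrelation time τ50 is the smallest
  positive lag at which R falls to half of R(0), linearly interpolated,
  with an option to average the two branches; if R never halves within
  the lag window the value is censored (Inf with the censoring bound
  attached) rather than extrapolated.

A note on what the generator can and cannot show here: per-cell expression
in the generator is static between divisions, so cross-cell heterogeneity
never mixes away and a movie-derived τ50 is typically censored. The τ50
estimator is therefore validated against closed forms (exponential decay
→ λ·ln 2) and constructed trace ensembles with known fast/slow dynamics,
not against the generator.

# The tagging designer

Directed intron tagging inserts an artificial exon — splice acceptor, a
fluorescent-tag coding sequence with no start or stop codons, splice
donor — into an intron of the target gene, one cassette per reading-frame
phase (enumerating the phases yields exactly three variants). After
splicing, the mRNA gains one exon of exactly the tag length, and the
fusion is in frame iff the cassette phase equals the phase at which the
upstream exon ends and the tag length is a multiple of 3. All operations
work on 1-based inclusive interval arithmetic (the convention of primer
catalogues) and optionally on real sequence via Biostrings; minus-strand
genomic input is reverse-complemented at load. Amplicons are predicted as
forward-primer 5' start to reverse-primer span end on the spliced
transcript; a primer whose reference is absent (a tag primer on wild-type
mRNA) yields "no product" rather than an error. Splice-site sequences
default to canonical consensus sites and are overridable. The designer
does not score splice-site strength or design genomic homology arms.

```{r tag, eval = FALSE}
gene <- geneModel("toy", starts = c(1, 131, 251, 401, 551),
                  ends = c(80, 200, 340, 500, 624))
cassette <- buildCassettes(tag_cds)[[1]]       # phase-0 variant
tagged <- insertExon(gene, intron_index = 3, cassette)
predictAmplicon(tagged, primerPair("E1", c(1, 20), "E5", c(55, 74)))
```

# Validation problem sizes and numerical choices

The test suite validates parameter recovery end-to-end on a rendered
60-frame, 200-cell movie on a 1000×1000 px field. For that benchmark the
movie is sampled every 30 minutes so the 60 frames span 30 h and leave a
complete 25-h response window after drug addition at frame 10; 20 minutes
remains the package default for routine use. Monte-Carlo checks of the
generator's distributional targets use 300–500 cells at a single frame.
Other choices: cell-cycle draws are truncated at 6 h; the response target
cap (95 % of total) is calibrated away by a one-dimensional root solve so
the requested mean fold survives the cap; percentile and CV conventions
are as above; greedy link ties and seed watershed tolerance (5 % of the
relief maximum) are fixed and deterministic; all stochastic stages accept
seeds, and identical parameters plus seeds give bit-identical movies.

# Limitations

* The renderer is deliberately non-photorealistic (no PSF, no
  z-structure); segmentation accuracy on real movies will be lower than on
  synthetic ones, and the reported recovery numbers should be read as
  validation of the operators, not as expected field performance.
* Tracking is greedy nearest-centroid with no gap closing or global
  optimization; prolonged segmentation dropouts fragment tracks.
* The generator's expression levels are static between divisions; movies
  it produces are not suitable for estimating decorrelation times.
* The tagging designer checks length and frame arithmetic only; it does
  not assess splicing efficiency.
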