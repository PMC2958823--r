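#' Scene parameters for a synthetic time-lapse field
#'
#' Describes the imaging geometry of a simulated field of cells: how many
#' cells, how large the field, the sampling in space and time, and when (if
#' ever) the stimulating drug is added.
#'
#' @param n_cells number of cells at the first frame.
#' @param field_size integer length-2, field size in pixels (rows, cols).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames.
#' @param drug_frame 1-based frame index at which the drug is added (the drug
#'   is present from this frame onward), or NULL for an unstimulated movie.
#' @param cell_radius mean cell radius in micrometres.
#' @param radius_jitter lognormal sd of the per-cell radius about its mean.
#' @param nucleus_fraction nucleus semi-axis as a fraction of the cell's.
#' @param spacing_factor minimum initial centre-to-centre distance, in units
#'   of the mean cell radius. Controls how many cells touch; the field's true
#'   overlap density is unknown, so this is exposed.
#' @param rng_seed integer seed used by the generator, or NULL to use the
#'   current RNG state.
#' @return a named list of validated scene parameters.
#' @export
sceneParams <- function(n_cells = 75L,
                        field_size = c(800L, 800L),
                        pixel_size = 0.8,
                        frame_interval = 20,
                        n_frames = 90L,
                        drug_frame = NULL,
                        cell_radius = 12,
                        radius_jitter = 0.12,
                        nucleus_fraction = 0.55,
                        spacing_factor = 2.2,
                        rng_seed = NULL) {
  stopifnot(n_cells >= 0, length(field_size) == 2L, all(field_size >= 16),
            pixel_size > 0, frame_interval > 0, n_frames >= 1,
            cell_radius > 0, nucleus_fraction > 0, nucleus_fraction < 1)
  if (!is.null(drug_frame)) {
    if (drug_frame < 1 || drug_frame > n_frames)
      stop("drug_frame must lie within 1..n_frames")
  }
  list(n_cells = as.integer(n_cells), field_size = as.integer(field_size),
       pixel_size = pixel_size, frame_interval = frame_interval,
       n_frames = as.integer(n_frames),
       drug_frame = if (is.null(drug_frame)) NULL else as.integer(drug_frame),
       cell_radius = cell_radius, radius_jitter = radius_jitter,
       nucleus_fraction = nucleus_fraction, spacing_factor = spacing_factor,
       rng_seed = rng_seed)
}

#' Expression parameters of the simulated channels
#'
#' Cell-to-cell expression variability follows the long-right-tailed pattern
#' typical of mammalian protein levels: lognormal marginals per channel with
#' a Gaussian copula linking the two tagged channels so a requested Spearman
#' rank correlation is preserved. Nuclear fractions vary between cells on the
#' logit scale, which keeps them inside (0, 1) and reproduces the observation
#' that nuclear levels are noisier than whole-cell levels.
#'
#' @param mean_level mean total signal per cell (photon counts), shared by
#'   all fluorescent channels.
#' @param cv_total length-2 coefficient of variation of total levels for the
#'   cyan and yellow channels.
#' @param rank_correlation Spearman correlation between the two tagged
#'   channels' total levels, in [-1, 1].
#' @param baseline_nuclear_fraction length-2 mean nuclear fraction (nuclear /
#'   total) of the cyan and yellow channels at baseline.
#' @param nuclear_fraction_sd sd of the per-cell nuclear-fraction deviation
#'   on the logit scale.
#' @param enrichment_correlation rank correlation between the two channels'
#'   per-cell nuclear-fraction deviations.
#' @param red_cv coefficient of variation of the red segmentation channel
#'   (kept small: its pattern is near-uniform across cells).
#' @param red_contrast nucleus:cytoplasm intensity ratio of the red channel.
#' @return a named list of validated expression parameters.
#' @export
expressionParams <- function(mean_level = 1e5,
                             cv_total = c(cyan = 0.41, yellow = 0.44),
                             rank_correlation = 0.64,
                             baseline_nuclear_fraction = c(cyan = 0.43, yellow = 0.39),
                             nuclear_fraction_sd = 0.9,
                             enrichment_correlation = 0.85,
                             red_cv = 0.15,
                             red_contrast = 3) {
  if (length(cv_total) == 1L) cv_total <- rep(cv_total, 2L)
  if (length(baseline_nuclear_fraction) == 1L)
    baseline_nuclear_fraction <- rep(baseline_nuclear_fraction, 2L)
  stopifnot(mean_level > 0, all(cv_total >= 0),
            abs(rank_correlation) <= 1, abs(enrichment_correlation) <= 1,
            all(baseline_nuclear_fraction > 0),
            all(baseline_nuclear_fraction < 1),
            nuclear_fraction_sd >= 0, red_cv >= 0, red_contrast > 0)
  list(mean_level = mean_level, cv_total = unname(cv_total),
       rank_correlation = rank_correlation,
       baseline_nuclear_fraction = unname(baseline_nuclear_fraction),
       nuclear_fraction_sd = nuclear_fraction_sd,
       enrichment_correlation = enrichment_correlation,
       red_cv = red_cv, red_contrast = red_contrast)
}

#' Drug-response parameters
#'
#' After drug addition the nuclear signal of each tagged channel approaches a
#' per-cell target level as a saturating exponential. In
#' \code{absolute_target} mode the targets are common across cells up to a
#' lognormal dispersion, so initially dim nuclei rise more in relative terms
#' and the population nuclear CV falls; in \code{fold_change} mode each
#' cell's target is a fold multiple of its own initial level, preserving
#' relative variability. \code{fold_nuclear_25h} is defined as the population
#' mean of per-cell nuclear fold changes evaluated \code{reference_hours}
#' after drug addition.
#'
#' @param fold_nuclear_25h length-2 mean nuclear fold change of the cyan and
#'   yellow channels at \code{reference_hours} after the drug.
#' @param response_timescale exponential approach timescale, hours.
#' @param response_mode "absolute_target" or "fold_change".
#' @param fold_dispersion lognormal sd of the per-cell target about its mean.
#' @param reference_hours hours after drug addition at which
#'   \code{fold_nuclear_25h} is defined.
#' @return a named list of validated response parameters.
#' @export
responseParams <- function(fold_nuclear_25h = c(cyan = 1.78, yellow = 1.95),
                           response_timescale = 6,
                           response_mode = c("absolute_target", "fold_change"),
                           fold_dispersion = 0.1,
                           reference_hours = 25) {
  response_mode <- match.arg(response_mode)
  if (length(fold_nuclear_25h) == 1L)
    fold_nuclear_25h <- rep(fold_nuclear_25h, 2L)
  stopifnot(all(fold_nuclear_25h >= 1), response_timescale > 0,
            fold_dispersion >= 0, reference_hours > 0)
  list(fold_nuclear_25h = unname(fold_nuclear_25h),
       response_timescale = response_timescale,
       response_mode = response_mode,
       fold_dispersion = fold_dispersion,
       reference_hours = reference_hours)
}

#' Motion, cell-cycle and bleaching parameters
#'
#' @param mean_speed centre-of-mass speed in micrometres per hour; each cell
#'   steps this distance per frame along a persistent heading.
#' @param turning_rate sd of the per-step heading change, radians per square
#'   root hour; migrating cells keep their direction over an hour or two, and
#'   freshly divided sisters start with opposite headings.
#' @param cell_cycle_mean,cell_cycle_sd cell-cycle duration (hours), drawn
#'   once per cell from a truncated normal.
#' @param bleaching_total total fractional loss of fluorescence over the
#'   whole movie from photobleaching, applied as a global exponential
#'   multiplicative decay at render time.
#' @return a named list of validated motion parameters.
#' @export
motionParams <- function(mean_speed = 8.5,
                         turning_rate = 1.2,
                         cell_cycle_mean = 28,
                         cell_cycle_sd = 4,
                         bleaching_total = 0.03) {
  stopifnot(mean_speed >= 0, turning_rate >= 0, cell_cycle_mean > 0,
            cell_cycle_sd >= 0, bleaching_total >= 0, bleaching_total < 1)
  list(mean_speed = mean_speed, turning_rate = turning_rate,
       cell_cycle_mean = cell_cycle_mean, cell_cycle_sd = cell_cycle_sd,
       bleaching_total = bleaching_total)
}

#' Optics and camera parameters of the renderer
#'
#' @param flat_field_strength relative intensity drop of the parabolic
#'   vignette at the field corner (0 = perfectly flat illumination).
#' @param background additive camera background offset, counts.
#' @param shot_noise logical, apply Poisson shot noise to expected counts.
#' @param read_noise_sd sd of additive Gaussian read noise, counts.
#' @param quantize logical; TRUE rounds pixels to integer camera counts and
#'   clips to the sensor bit depth (the on-disk representation), FALSE keeps
#'   exact expected intensities (useful for conservation checks).
#' @param bit_depth sensor bit depth (pixel values clip at 2^bit_depth - 1).
#' @param phase_level placeholder pixel value of cells in the phase channel.
#' @return a named list of validated optics parameters.
#' @export
opticsParams <- function(flat_field_strength = 0.15,
                         background = 100,
                         shot_noise = TRUE,
                         read_noise_sd = 2,
                         quantize = TRUE,
                         bit_depth = 16L,
                         phase_level = 300) {
  stopifnot(flat_field_strength >= 0, flat_field_strength < 1,
            background >= 0, read_noise_sd >= 0, bit_depth %in% c(8L, 16L))
  list(flat_field_strength = flat_field_strength, background = background,
       shot_noise = isTRUE(shot_noise), read_noise_sd = read_noise_sd,
       quantize = isTRUE(quantize), bit_depth = as.integer(bit_depth),
       phase_level = phase_level)
}
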