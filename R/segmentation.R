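#' @include AllClasses.R
NULL

## Otsu threshold on an arbitrary-range matrix.
otsuThreshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image(x), range = rng, levels = 512L)
}

## Foreground (cell vs background) threshold of a corrected fluorescence
## image. A plain Otsu split can fail in two ways here: on a trimodal
## histogram (background, cytoplasm, 3x-brighter nucleus) it may prefer the
## cytoplasm/nucleus split, and after background subtraction the zero-clipped
## noise floor confuses histogram shape. Instead the Otsu split only seeds a
## background sample, and the threshold is the robust background level plus
## k robust standard deviations -- the usual background + k*sigma rule. On a
## noiseless image this degenerates to > background exactly.
foregroundThreshold <- function(x, k = 4) {
  th0 <- otsuThreshold(x)
  bg <- x[x < th0]
  if (!length(bg)) return(th0)
  q <- stats::quantile(bg, c(0.5, 0.8413), names = FALSE)
  # upper-sided sigma estimate: background-subtracted images are clipped at
  # zero, which zeroes the lower tail (and the MAD with it)
  q[1] + k * (q[2] - q[1])
}

#' Flat-field and dark-offset correction
#'
#' Corrects a raw frame for the spatial illumination/sensitivity profile and
#' the camera offset: \code{corrected = (image - dark_offset) / (flat_field /
#' mean(flat_field))}, with negative results clipped to zero. Dividing by the
#' mean-normalized flat field preserves the overall intensity scale.
#'
#' @param image numeric matrix of raw intensities.
#' @param flat_field strictly positive matrix of the same size, the
#'   illumination profile (any scale; it is normalized to mean 1).
#' @param dark_offset scalar additive background/camera offset.
#' @return corrected matrix, same dimensions, non-negative.
#' @export
flatFieldCorrect <- function(image, flat_field = NULL, dark_offset = 0) {
  if (is.null(flat_field))
    flat_field <- matrix(1, nrow(image), ncol(image))
  if (!identical(dim(image), dim(flat_field)))
    stop("flat_field dimensions ", paste(dim(flat_field), collapse = "x"),
         " do not match image ", paste(dim(image), collapse = "x"))
  if (any(flat_field <= 0))
    stop("flat_field must be strictly positive everywhere")
  ff <- flat_field / mean(flat_field)
  pmax((image - dark_offset) / ff, 0)
}

#' Estimate the background (dark) offset of a frame
#'
#' Splits the frame at its Otsu threshold and returns the median of the
#' below-threshold (cell-free) pixels, a robust location estimate of the
#' additive background.
#'
#' @param image numeric matrix.
#' @param min_background_fraction minimum fraction of pixels that must fall
#'   below the threshold for the estimate to be trusted.
#' @return scalar background estimate.
#' @export
estimateBackground <- function(image, min_background_fraction = 0.05) {
  rng <- range(image, finite = TRUE)
  if (diff(rng) == 0) {
    if (rng[1] == 0) return(0)
    stop("image is constant (possibly saturated): no background/foreground ",
         "contrast to estimate from; supply the offset explicitly")
  }
  th <- otsuThreshold(image)
  bg <- image[image < th]
  if (length(bg) < min_background_fraction * length(image))
    stop("image appears to be almost entirely foreground (",
         length(bg), " background pixels); mask out cells or supply the ",
         "offset explicitly")
  stats::median(bg)
}

#' Detect nuclear seeds in the red segmentation channel
#'
#' Smooths the corrected red image with a Gaussian and labels its bright
#' nuclear blobs: foreground is split from background first, then within
#' each connected foreground component a second Otsu split separates the
#' bright nuclei from the dimmer cytoplasm (per component, so dim cells keep
#' their seeds), and an intensity watershed separates blobs that hold more
#' than one maximum. Components above a minimum area become seeds, one per
#' nucleus for reasonably separated cells.
#'
#' @param red_image corrected red-channel matrix.
#' @param smoothing_sigma Gaussian sigma in pixels; a good default is half
#'   the expected nuclear radius.
#' @param min_seed_area discard components smaller than this (pixels).
#' @return integer matrix of seed labels (0 = background).
#' @export
detectSeeds <- function(red_image, smoothing_sigma = 4, min_seed_area = 20) {
  sm <- gaussianSmooth(red_image, smoothing_sigma)
  if (diff(range(sm)) == 0) return(matrix(0L, nrow(red_image), ncol(red_image)))
  th1 <- foregroundThreshold(sm)
  fg <- sm > th1
  if (!any(fg)) return(matrix(0L, nrow(red_image), ncol(red_image)))
  # nucleus/cytoplasm split per connected foreground component: a global
  # split would miss the nuclei of dim cells (e.g. freshly divided
  # daughters) whose whole dynamic range sits below the population split
  comp <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(fg + 0)))), nrow(red_image))
  seedmask <- matrix(FALSE, nrow(red_image), ncol(red_image))
  relief <- matrix(0, nrow(red_image), ncol(red_image))
  for (k in seq_len(max(comp))) {
    px <- which(comp == k)
    if (length(px) < max(min_seed_area, 25)) next
    th2 <- otsuThreshold(matrix(sm[px]))
    hit <- px[sm[px] > th2]
    seedmask[hit] <- TRUE
    relief[hit] <- sm[hit] - th2
  }
  if (!any(seedmask)) return(matrix(0L, nrow(red_image), ncol(red_image)))
  splitSeedBlobs(relief, min_seed_area)
}

## Watershed split of a seed relief map: blobs holding two intensity maxima
## (e.g. freshly divided sisters whose nuclei still touch across a bright
## cytoplasmic bridge) are separated. The relief is normalized per blob so
## the split tolerance is relative to each blob's own peak, not to the
## brightest nucleus in the field; components below min_seed_area are
## dropped and labels are made consecutive.
splitSeedBlobs <- function(relief, min_seed_area = 20, tolerance = 0.1) {
  blob <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image((relief > 0) + 0)))), nrow(relief))
  if (max(blob) > 0L) {
    peak <- vapply(seq_len(max(blob)), function(k) max(relief[blob == k]),
                   numeric(1))
    pos <- blob > 0L
    relief[pos] <- relief[pos] / peak[blob[pos]]
  }
  lab <- EBImage::watershed(EBImage::Image(relief), tolerance = tolerance,
                            ext = 1L)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(relief))
  if (min_seed_area > 0 && any(lab > 0L)) {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_seed_area)
    if (length(small)) lab[lab %in% small] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  lab
}

gaussianSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  matrix(as.numeric(EBImage::imageData(
    EBImage::gblur(EBImage::Image(x), sigma = sigma))), nrow(x))
}

#' Partition the foreground into cells from nuclear seeds
#'
#' Foreground is the set of pixels above the Otsu threshold of the corrected
#' red image (cells vs background). The foreground is then partitioned among
#' the seeds by seeded region growing on the smoothed red intensity
#' (EBImage's \code{propagate}, the seeded counterpart of the watershed
#' transform), which splits touching cells along intensity valleys.
#' Foreground components containing no seed are dropped by default (likely
#' debris) or kept as their own labels.
#'
#' @param red_image corrected red-channel matrix.
#' @param seeds integer seed label matrix, e.g. from \code{\link{detectSeeds}}.
#' @param smoothing_sigma Gaussian sigma used for the growth potential.
#' @param keep_seedless keep foreground components without a seed as extra
#'   labels instead of dropping them.
#' @param lambda propagation regularizer passed to \code{EBImage::propagate};
#'   small values weight the intensity landscape, large values approach a
#'   plain distance (Voronoi) split.
#' @return integer matrix of cell labels (0 = background).
#' @export
segmentCells <- function(red_image, seeds, smoothing_sigma = 4,
                         keep_seedless = FALSE, lambda = 1e-4) {
  if (!identical(dim(red_image), dim(seeds)))
    stop("seed map dimensions must match the image")
  zero <- matrix(0L, nrow(red_image), ncol(red_image))
  if (diff(range(red_image)) == 0) return(zero)
  th <- foregroundThreshold(red_image)
  fg <- red_image > th
  if (!any(fg)) return(zero)
  if (any(seeds > 0L)) {
    sm <- gaussianSmooth(red_image, smoothing_sigma)
    lab <- EBImage::propagate(EBImage::Image(sm),
                              seeds = EBImage::Image(seeds),
                              mask = EBImage::Image(fg), lambda = lambda)
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(red_image))
  } else {
    if (!keep_seedless) return(zero)
    lab <- zero
  }
  if (keep_seedless) {
    orphan <- fg & lab == 0L
    if (any(orphan)) {
      extra <- EBImage::bwlabel(EBImage::Image(orphan + 0))
      extra <- matrix(as.integer(EBImage::imageData(extra)), nrow(red_image))
      off <- max(lab)
      lab[extra > 0L] <- extra[extra > 0L] + off
    }
  }
  lab
}

#' Segment the nucleus inside each cell
#'
#' Within each cell mask the red intensity is min-max stretched to [0, 1]
#' and pixels at or above a fixed threshold become the nucleus; only the
#' largest connected component is kept, and it inherits the cell's label.
#' Cells with no intensity contrast (max = min) get an empty nucleus with a
#' warning.
#'
#' @param red_image corrected red-channel matrix.
#' @param cell_labels integer cell label matrix.
#' @param fixed_threshold nucleus threshold on the per-cell stretched
#'   intensity, in [0, 1].
#' @return integer matrix of nucleus labels, nested inside \code{cell_labels}.
#' @export
segmentNuclei <- function(red_image, cell_labels, fixed_threshold = 0.5) {
  if (!identical(dim(red_image), dim(cell_labels)))
    stop("cell label dimensions must match the image")
  stopifnot(fixed_threshold >= 0, fixed_threshold <= 1)
  nl <- matrix(0L, nrow(red_image), ncol(red_image))
  ids <- setdiff(sort(unique(as.integer(cell_labels))), 0L)
  degenerate <- integer(0)
  for (id in ids) {
    idx <- which(cell_labels == id, arr.ind = TRUE)
    vals <- red_image[idx]
    rng <- range(vals)
    if (diff(rng) == 0) { degenerate <- c(degenerate, id); next }
    stretched <- (vals - rng[1]) / diff(rng)
    inNuc <- stretched >= fixed_threshold
    if (!any(inNuc)) next
    # largest connected component within the cell's bounding box
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(idx[inNuc, 1] - r0 + 1L, idx[inNuc, 2] - c0 + 1L)] <- 1
    comp <- matrix(as.integer(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(sub)))), nrow(sub))
    sizes <- tabulate(comp[comp > 0L])
    best <- which.max(sizes)
    hit <- which(comp == best, arr.ind = TRUE)
    nl[cbind(hit[, 1] + r0 - 1L, hit[, 2] + c0 - 1L)] <- id
  }
  if (length(degenerate))
    warning("cell(s) with uniform intensity got an empty nucleus: ",
            paste(degenerate, collapse = ", "))
  nl
}

#' Measure every cell of one segmented frame
#'
#' Sums the corrected intensity of each channel over the cell and nucleus
#' masks, derives the cytoplasmic signal and the nuclear enrichment
#' (nuclear / total), and records the unweighted mask centroid, area in
#' pixels and whether the cell touches the image border (border cells are
#' flagged so population statistics can exclude partially imaged cells).
#'
#' @param seg a \linkS4class{SegmentedFrame}, or a list with elements
#'   \code{cellLabels} and \code{nucleusLabels}.
#' @param channel_images named list of corrected intensity matrices, e.g.
#'   \code{list(red = ..., cyan = ..., yellow = ...)}.
#' @param frame frame index recorded in the output (default: taken from
#'   \code{seg} when available).
#' @return data.frame, one row per cell: \code{frame, cell_id, centroid_row,
#'   centroid_col, area, border} plus, per channel \code{ch}, columns
#'   \code{total_ch, nuclear_ch, cyto_ch, enrich_ch}. Coordinates are
#'   1-based pixel centers; areas are in pixels.
#' @export
measureCells <- function(seg, channel_images, frame = NULL) {
  if (is(seg, "SegmentedFrame")) {
    cl <- seg@cellLabels; nl <- seg@nucleusLabels
    if (is.null(frame)) frame <- seg@frame
  } else {
    cl <- seg$cellLabels; nl <- seg$nucleusLabels
    if (is.null(frame)) frame <- NA_integer_
  }
  stopifnot(is.list(channel_images), length(channel_images) > 0,
            !is.null(names(channel_images)))
  for (img in channel_images)
    if (!identical(dim(img), dim(cl)))
      stop("channel image dimensions must match the label maps")
  nz <- nl != 0L
  if (any(nl[nz] != cl[nz]))
    stop("nucleus label present outside (or mismatching) its cell: label maps",
         " are inconsistent")
  ids <- setdiff(sort(unique(as.integer(cl))), 0L)
  if (!length(ids)) {
    out <- data.frame(frame = integer(0), cell_id = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      area = integer(0), border = logical(0))
    for (ch in names(channel_images))
      out[paste0(c("total_", "nuclear_", "cyto_", "enrich_"), ch)] <-
        numeric(0)
    return(out)
  }
  cidx <- as.integer(cl)
  fidx <- factor(cidx[cidx > 0L], levels = ids)
  pos <- which(cidx > 0L)
  rows <- ((pos - 1L) %% nrow(cl)) + 1L
  colsp <- ((pos - 1L) %/% nrow(cl)) + 1L
  area <- as.integer(table(fidx))
  c_row <- as.numeric(tapply(rows, fidx, mean))
  c_col <- as.numeric(tapply(colsp, fidx, mean))
  border <- as.logical(tapply(rows == 1L | rows == nrow(cl) |
                                colsp == 1L | colsp == ncol(cl), fidx, any))
  nidx <- as.integer(nl)
  nfac <- factor(nidx[nidx > 0L], levels = ids)
  out <- data.frame(frame = as.integer(frame), cell_id = ids,
                    centroid_row = c_row, centroid_col = c_col,
                    area = area, border = border)
  for (ch in names(channel_images)) {
    v <- as.numeric(channel_images[[ch]])
    tot <- as.numeric(tapply(v[cidx > 0L], fidx, sum))
    nuc <- as.numeric(tapply(v[nidx > 0L], nfac, sum))
    nuc[is.na(nuc)] <- 0
    out[[paste0("total_", ch)]] <- tot
    out[[paste0("nuclear_", ch)]] <- nuc
    out[[paste0("cyto_", ch)]] <- tot - nuc
    out[[paste0("enrich_", ch)]] <- ifelse(tot > 0, nuc / tot, NA_real_)
  }
  out
}

## Second-pass splitting of under-segmented cells. Within each segmented
## object, a tolerance watershed on the smoothed red intensity counts
## regional maxima of sufficient relative prominence -- every nucleus is
## one, regardless of how dim its cell is next to a bright neighbour, which
## defeats any threshold-based rule. An object holding two maxima is a
## merged pair (freshly divided sisters, or a dim cell pooled with a bright
## neighbour) and the watershed basins themselves become the new labels.
splitMergedCells <- function(sm, cell_labels, tolerance = 0.07,
                             min_part_area = 120) {
  next_lab <- max(cell_labels)
  for (id in setdiff(sort(unique(as.integer(cell_labels))), 0L)) {
    idx <- which(cell_labels == id, arr.ind = TRUE)
    if (nrow(idx) < 2L * min_part_area) next
    vals <- sm[idx]
    rngv <- range(vals)
    if (diff(rngv) == 0) next
    r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
    sub <- matrix(0, max(idx[, 1]) - r0 + 1L, max(idx[, 2]) - c0 + 1L)
    sub[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <-
      (vals - rngv[1]) / diff(rngv) + 1e-6
    ws <- EBImage::watershed(EBImage::Image(sub), tolerance = tolerance,
                             ext = 1L)
    ws <- matrix(as.integer(EBImage::imageData(ws)), nrow(sub))
    parts <- tabulate(ws[ws > 0L])
    big <- which(parts >= min_part_area)
    if (length(big) < 2L) next
    # keep the original id for the largest basin, new ids for the rest
    big <- big[order(-parts[big])]
    for (k in big[-1]) {
      next_lab <- next_lab + 1L
      kk <- which(ws == k, arr.ind = TRUE)
      cell_labels[cbind(kk[, 1] + r0 - 1L, kk[, 2] + c0 - 1L)] <- next_lab
    }
  }
  cell_labels
}

#' Segment one frame of the red channel
#'
#' Convenience wrapper chaining \code{\link{detectSeeds}},
#' \code{\link{segmentCells}}, a second-pass watershed split of objects
#' that still hold two nuclear intensity maxima (under-segmented touching
#' pairs) and \code{\link{segmentNuclei}}.
#'
#' @param red_image corrected red-channel matrix.
#' @param smoothing_sigma Gaussian sigma for seeds and growth potential.
#' @param nucleus_threshold fixed per-cell nucleus threshold in [0, 1].
#' @param min_seed_area minimum seed component area in pixels.
#' @param keep_seedless keep seedless foreground components.
#' @param frame frame index stored in the result.
#' @return a \linkS4class{SegmentedFrame}.
#' @export
segmentFrame <- function(red_image, smoothing_sigma = 4,
                         nucleus_threshold = 0.5, min_seed_area = 20,
                         keep_seedless = FALSE, frame = 1L) {
  seeds <- detectSeeds(red_image, smoothing_sigma, min_seed_area)
  cl <- segmentCells(red_image, seeds, smoothing_sigma, keep_seedless)
  if (any(cl > 0L)) {
    sm <- gaussianSmooth(red_image, smoothing_sigma)
    cl <- splitMergedCells(sm, cl)
  }
  nl <- segmentNuclei(red_image, cl, nucleus_threshold)
  new("SegmentedFrame", cellLabels = cl, nucleusLabels = nl,
      frame = as.integer(frame))
}

#' Segment and measure a whole movie
#'
#' Runs background/flat-field correction, seeded segmentation on the red
#' channel, nucleus extraction and per-cell measurement on every frame of a
#' movie, producing the measurement table the tracking stage consumes.
#'
#' @param stack a \linkS4class{MovieStack} containing a \code{"red"} channel
#'   and any number of additional fluorescence channels to quantify.
#' @param flat_field known illumination profile matrix, or NULL to skip
#'   flat-field correction.
#' @param dark_offset known additive offset, or \code{"estimate"} to
#'   estimate it per frame from below-Otsu pixels.
#' @param channels channels to measure (default: all non-phase channels).
#' @param smoothing_sigma,nucleus_threshold,min_seed_area,keep_seedless
#'   passed to the per-frame segmentation.
#' @param verbose print a progress line every 10 frames.
#' @return data.frame of per-cell per-frame measurements (see
#'   \code{\link{measureCells}}).
#' @export
quantifyMovie <- function(stack, flat_field = NULL, dark_offset = "estimate",
                          channels = NULL, smoothing_sigma = 4,
                          nucleus_threshold = 0.5, min_seed_area = 20,
                          keep_seedless = FALSE, verbose = FALSE) {
  stopifnot(is(stack, "MovieStack"))
  if (!"red" %in% stack@channels)
    stop("movie must contain the red segmentation channel")
  if (is.null(channels)) channels <- setdiff(stack@channels, "phase")
  nf <- dim(stack@pixels)[4]
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    imgs <- lapply(channels, function(ch) getFrame(stack, f, ch))
    names(imgs) <- channels
    off <- if (identical(dark_offset, "estimate"))
      estimateBackground(imgs[["red"]]) else dark_offset
    imgs <- lapply(imgs, flatFieldCorrect, flat_field = flat_field,
                   dark_offset = off)
    seg <- segmentFrame(imgs[["red"]], smoothing_sigma, nucleus_threshold,
                        min_seed_area, keep_seedless, frame = f)
    res[[f]] <- measureCells(seg, imgs)
    if (verbose && f %% 10 == 0)
      message("segmented frame ", f, "/", nf, " (",
              nrow(res[[f]]), " cells)")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
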