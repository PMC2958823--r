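#' @include AllClasses.R
NULL

#' Construct a MovieStack
#'
#' @param pixels numeric 4-D array (row, col, channel, frame); a 3-D array
#'   is promoted to a single-frame movie.
#' @param channels character vector of channel names.
#' @param frameInterval minutes between frames.
#' @param pixelSize micrometres per pixel.
#' @param metadata optional list of extras.
#' @return a \linkS4class{MovieStack}.
#' @export
MovieStack <- function(pixels, channels, frameInterval = 20, pixelSize = 0.8,
                       metadata = list()) {
  if (length(dim(pixels)) == 3L)
    dim(pixels) <- c(dim(pixels), 1L)
  new("MovieStack", pixels = pixels, channels = channels,
      frameInterval = frameInterval, pixelSize = pixelSize,
      metadata = metadata)
}

#' Write a movie to disk as per-channel multi-page TIFF
#'
#' Each channel is written as one multi-page 16-bit TIFF (one page per
#' frame), the native format of a scientific camera, alongside a
#' \code{movie.yaml} sidecar holding the channel names, frame interval and
#' pixel size. Pixel values must be non-negative; non-integer values are
#' rounded and values above 65535 are clipped, both with a warning, so a
#' quantized rendered movie round-trips bit-identically.
#'
#' @param stack a \linkS4class{MovieStack}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory written.
#' @seealso \code{\link{readMovie}}
#' @export
writeMovie <- function(stack, dir) {
  stopifnot(is(stack, "MovieStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  px <- stack@pixels
  if (any(px < 0)) stop("movie pixels must be non-negative")
  if (any(px != round(px))) {
    warning("non-integer pixel values rounded to camera counts")
    px <- round(px)
  }
  if (any(px > 65535)) {
    warning("pixel values above 65535 clipped")
    px <- pmin(px, 65535)
  }
  nf <- dim(px)[4]
  for (k in seq_along(stack@channels)) {
    pages <- lapply(seq_len(nf), function(f) px[, , k, f] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(stack@channels[k], ".tif")),
                    bits.per.sample = 16L, compression = "deflate")
  }
  yaml::write_yaml(list(channels = as.list(stack@channels),
                        n_frames = nf,
                        frame_interval_min = stack@frameInterval,
                        pixel_size_um = stack@pixelSize),
                   file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' Read a movie written by writeMovie
#'
#' Reads the per-channel multi-page TIFFs and the \code{movie.yaml} sidecar
#' back into a \linkS4class{MovieStack}. Fails with an explicit message when
#' the sidecar is missing, a required channel file is absent (naming the
#' channels that were found), the movie has zero frames, or channels
#' disagree in frame count or image size.
#'
#' @param dir directory written by \code{\link{writeMovie}}.
#' @param channels channels that must be present; default: all channels
#'   listed in the sidecar.
#' @return a \linkS4class{MovieStack} with integer pixel counts.
#' @export
readMovie <- function(dir, channels = NULL) {
  side <- file.path(dir, "movie.yaml")
  if (!file.exists(side))
    stop("not a movie directory: missing sidecar ", side)
  meta <- yaml::read_yaml(side)
  found <- unlist(meta$channels)
  if (is.null(channels)) channels <- found
  missing <- setdiff(channels, found)
  if (length(missing))
    stop("channel(s) ", paste(missing, collapse = ", "),
         " required but movie contains only: ", paste(found, collapse = ", "))
  if (is.null(meta$n_frames) || meta$n_frames < 1)
    stop("movie has no frames")
  stacks <- lapply(channels, function(ch) {
    path <- file.path(dir, paste0(ch, ".tif"))
    if (!file.exists(path))
      stop("channel file missing: ", path, "; channels found on disk: ",
           paste(sub("\\.tif$", "", list.files(dir, pattern = "\\.tif$")),
                 collapse = ", "))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages
  })
  nf <- length(stacks[[1]])
  if (nf < 1) stop("movie has no frames")
  d <- dim(stacks[[1]][[1]])
  if (any(vapply(stacks, length, integer(1)) != nf))
    stop("channels disagree in frame count")
  arr <- array(0, dim = c(d[1], d[2], length(channels), nf))
  for (k in seq_along(channels)) for (f in seq_len(nf)) {
    pg <- stacks[[k]][[f]]
    if (!identical(dim(pg), d)) stop("frame size mismatch in channel ",
                                     channels[k], " frame ", f)
    arr[, , k, f] <- pg
  }
  new("MovieStack", pixels = arr, channels = channels,
      frameInterval = meta$frame_interval_min,
      pixelSize = meta$pixel_size_um, metadata = list())
}
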