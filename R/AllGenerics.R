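#' @include AllClasses.R
NULL

#' Accessors for MovieStack
#'
#' @param x a \linkS4class{MovieStack}.
#' @return \code{moviePixels}: the 4-D pixel array; \code{channelNames}: the
#'   channel names; \code{frameInterval}: minutes between frames;
#'   \code{pixelSize}: micrometres per pixel; \code{nFrames}: number of
#'   frames; \code{getFrame}: one channel of one frame as a matrix.
#' @name MovieStack-accessors
NULL

#' @rdname MovieStack-accessors
#' @export
setGeneric("moviePixels", function(x) standardGeneric("moviePixels"))
#' @rdname MovieStack-accessors
#' @export
setMethod("moviePixels", "MovieStack", function(x) x@pixels)

#' @rdname MovieStack-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname MovieStack-accessors
#' @export
setMethod("channelNames", "MovieStack", function(x) x@channels)

#' @rdname MovieStack-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname MovieStack-accessors
#' @export
setMethod("frameInterval", "MovieStack", function(x) x@frameInterval)

#' @rdname MovieStack-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname MovieStack-accessors
#' @export
setMethod("pixelSize", "MovieStack", function(x) x@pixelSize)

#' @rdname MovieStack-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname MovieStack-accessors
#' @export
setMethod("nFrames", "MovieStack", function(x) dim(x@pixels)[4])

#' Extract one channel of one frame
#'
#' @param x a \linkS4class{MovieStack}.
#' @param frame 1-based frame index.
#' @param channel channel name.
#' @return numeric matrix of pixel intensities.
#' @export
setGeneric("getFrame", function(x, frame, channel) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "MovieStack", function(x, frame, channel) {
  ci <- match(channel, x@channels)
  if (is.na(ci))
    stop("channel '", channel, "' not found; available: ",
         paste(x@channels, collapse = ", "))
  if (frame < 1L || frame > dim(x@pixels)[4])
    stop("frame index out of range")
  x@pixels[, , ci, frame]
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@pixels)
  cat("MovieStack:", d[4], "frames of", d[1], "x", d[2], "pixels,",
      d[3], "channels (", paste(object@channels, collapse = ", "), ")\n")
  cat("  frame interval:", object@frameInterval, "min;  pixel size:",
      object@pixelSize, "um\n")
})

#' Accessors for GroundTruth
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return \code{truthCells}: the per-cell per-frame truth table;
#'   \code{truthScene}: the scene parameter list; \code{bleachFactor}: the
#'   per-frame multiplicative bleaching factor applied at render time.
#' @name GroundTruth-accessors
NULL

#' @rdname GroundTruth-accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("truthCells", "GroundTruth", function(x) x@cells)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("truthScene", function(x) standardGeneric("truthScene"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("truthScene", "GroundTruth", function(x) x@scene)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("bleachFactor", function(x) standardGeneric("bleachFactor"))
#' @rdname GroundTruth-accessors
#' @export
setMethod("bleachFactor", "GroundTruth", function(x) x@bleachFactor)

setMethod("show", "GroundTruth", function(object) {
  cf <- object@cells
  nf <- if (nrow(cf)) max(cf$frame) else 0L
  cat("GroundTruth:", length(unique(cf$cell_id)), "cells over", nf, "frames\n")
  cat("  field:", paste(object@scene$field_size, collapse = " x "),
      "px;  pixel size:", object@scene$pixel_size, "um;  frame interval:",
      object@scene$frame_interval, "min\n")
  if (!is.null(object@scene$drug_frame))
    cat("  drug added at frame", object@scene$drug_frame, "\n")
})

#' Accessors for SegmentedFrame
#'
#' @param x a \linkS4class{SegmentedFrame}.
#' @return integer label matrix.
#' @name SegmentedFrame-accessors
NULL

#' @rdname SegmentedFrame-accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname SegmentedFrame-accessors
#' @export
setMethod("cellLabels", "SegmentedFrame", function(x) x@cellLabels)

#' @rdname SegmentedFrame-accessors
#' @export
setGeneric("nucleusLabels", function(x) standardGeneric("nucleusLabels"))
#' @rdname SegmentedFrame-accessors
#' @export
setMethod("nucleusLabels", "SegmentedFrame", function(x) x@nucleusLabels)

setMethod("show", "SegmentedFrame", function(object) {
  cat("SegmentedFrame (frame", object@frame, "):",
      length(setdiff(unique(as.integer(object@cellLabels)), 0L)), "cells,",
      length(setdiff(unique(as.integer(object@nucleusLabels)), 0L)),
      "nuclei\n")
})

setMethod("show", "CrossCorrResult", function(object) {
  cat("CrossCorrResult (", object@measure, "): ", length(object@lag),
      " lags in [", min(object@lag), ", ", max(object@lag), "] h, ",
      object@nCells, " cells\n", sep = "")
  i0 <- which.min(abs(object@lag))
  cat("  R(0) =", round(object@R[i0], 3), "\n")
})

setMethod("show", "AlignedTraceSet", function(object) {
  cat("AlignedTraceSet (", object@alignment, "-aligned): ",
      nrow(object@traces), " traces x ", ncol(object@traces),
      " time points, t in [", round(min(object@time), 2), ", ",
      round(max(object@time), 2), "] h\n", sep = "")
})

#' Accessors for AlignedTraceSet
#'
#' @param x an \linkS4class{AlignedTraceSet}.
#' @return \code{alignedTraces}: the trace matrix (tracks x time);
#'   \code{alignedTime}: hours relative to the alignment event.
#' @name AlignedTraceSet-accessors
NULL

#' @rdname AlignedTraceSet-accessors
#' @export
setGeneric("alignedTraces", function(x) standardGeneric("alignedTraces"))
#' @rdname AlignedTraceSet-accessors
#' @export
setMethod("alignedTraces", "AlignedTraceSet", function(x) x@traces)

#' @rdname AlignedTraceSet-accessors
#' @export
setGeneric("alignedTime", function(x) standardGeneric("alignedTime"))
#' @rdname AlignedTraceSet-accessors
#' @export
setMethod("alignedTime", "AlignedTraceSet", function(x) x@time)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "with", nrow(object@exons), "exons,",
      "transcript length", sum(object@exons$end - object@exons$start + 1L),
      "bp", if (nchar(object@sequence)) "(sequence attached)" else
        "(interval arithmetic only)", "\n")
})

setMethod("show", "ArtificialExon", function(object) {
  cat("ArtificialExon: ", nchar(object@tagCds), " bp tag CDS, phase ",
      object@phase, " (acceptor ", nchar(object@acceptor), " nt / donor ",
      nchar(object@donor), " nt)\n", sep = "")
})

setMethod("show", "TaggedTranscript", function(object) {
  cat("TaggedTranscript", object@geneId, ":", object@splicedLength,
      "bp spliced mRNA,", nrow(object@exons), "exons,",
      if (isTRUE(object@inFrame)) "in frame" else "OUT of frame", "\n")
})
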