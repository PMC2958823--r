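#' @import methods
NULL

#' MovieStack: a multi-channel time-lapse movie
#'
#' Container for a 4-D pixel array (row, col, channel, frame) together with
#' the acquisition metadata needed downstream: named channels, frame interval
#' in minutes and pixel size in micrometres.
#'
#' @slot pixels numeric 4-D array, dimensions row x col x channel x frame.
#' @slot channels character vector of unique channel names, one per slice of
#'   the third dimension. Conventionally \code{c("phase","red","yellow","cyan")}.
#' @slot frameInterval numeric, minutes between consecutive frames.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot metadata list of free-form extras (e.g. the true flat field and
#'   background of a rendered synthetic movie).
#' @exportClass MovieStack
setClass("MovieStack",
  slots = c(
    pixels        = "array",
    channels      = "character",
    frameInterval = "numeric",
    pixelSize     = "numeric",
    metadata      = "list"
  )
)

setValidity("MovieStack", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 4L)
    return("pixels must be a 4-D array (row, col, channel, frame)")
  if (d[4] < 1L)
    return("movie must contain at least one frame")
  if (length(object@channels) != d[3])
    return(sprintf("channels has length %d but pixels has %d channel slices",
                   length(object@channels), d[3]))
  if (anyDuplicated(object@channels))
    return("channel names must be unique")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number (minutes)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number (micrometres)")
  TRUE
})

#' SegmentedFrame: paired cell and nucleus label maps for one time point
#'
#' Integer label images for cells and nuclei of a single frame. Background is
#' 0; each nucleus pixel carries the label of the cell containing it, so the
#' nucleus map is nested inside the cell map by construction.
#'
#' @slot cellLabels integer matrix of cell labels (0 = background).
#' @slot nucleusLabels integer matrix of nucleus labels, nested in cellLabels.
#' @slot frame integer frame index (1-based).
#' @exportClass SegmentedFrame
setClass("SegmentedFrame",
  slots = c(
    cellLabels    = "matrix",
    nucleusLabels = "matrix",
    frame         = "integer"
  )
)

setValidity("SegmentedFrame", function(object) {
  if (!identical(dim(object@cellLabels), dim(object@nucleusLabels)))
    return("cell and nucleus label maps must share dimensions")
  nz <- object@nucleusLabels != 0L
  if (any(object@nucleusLabels[nz] != object@cellLabels[nz]))
    return("every nucleus pixel must lie inside the cell of the same label")
  if (any(object@cellLabels < 0L) || any(object@nucleusLabels < 0L))
    return("labels must be non-negative integers")
  TRUE
})

#' GroundTruth: fully annotated state of a synthetic movie
#'
#' Per-cell, per-frame truth of a simulated field: geometry (elliptical cell
#' and concentric nucleus), centroid, lineage (parent id and division frame),
#' visibility, and the true total and nuclear signal of each fluorescent
#' channel before noise. Signals are stored unbleached; the per-frame
#' photobleaching factor applied at render time lives in \code{bleachFactor}.
#'
#' @slot cells data.frame, one row per visible-or-not cell per frame.
#' @slot scene list of scene parameters (see \code{\link{sceneParams}}).
#' @slot params list with elements \code{expr}, \code{response}, \code{motion}
#'   as passed to the generator (possibly NULL before dynamics are simulated).
#' @slot bleachFactor numeric vector, one multiplicative factor per frame.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(
    cells        = "data.frame",
    scene        = "list",
    params       = "list",
    bleachFactor = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  need <- c("frame", "cell_id", "parent_id", "row", "col",
            "a", "b", "theta", "nuc_a", "nuc_b", "visible")
  miss <- setdiff(need, names(object@cells))
  if (length(miss))
    return(paste("cells table is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@cells)) {
    if (any(object@cells$nuc_a > object@cells$a + 1e-9) ||
        any(object@cells$nuc_b > object@cells$b + 1e-9))
      return("nucleus axes must not exceed cell axes (nucleus inside cell)")
  }
  TRUE
})

#' AlignedTraceSet: single-cell traces on a shared event-relative time axis
#'
#' @slot traces numeric matrix, one row per track, columns on a common time
#'   grid; missing values are NA.
#' @slot time numeric vector of times in hours relative to the alignment event.
#' @slot alignment character, one of "drug", "division", "none".
#' @slot trackIds integer vector of track identifiers (rownames of traces).
#' @exportClass AlignedTraceSet
setClass("AlignedTraceSet",
  slots = c(
    traces    = "matrix",
    time      = "numeric",
    alignment = "character",
    trackIds  = "integer"
  )
)

setValidity("AlignedTraceSet", function(object) {
  if (ncol(object@traces) != length(object@time))
    return("time axis length must equal number of trace columns")
  if (nrow(object@traces) != length(object@trackIds))
    return("one track id per trace row required")
  if (!object@alignment %in% c("drug", "division", "none"))
    return("alignment must be one of 'drug', 'division', 'none'")
  TRUE
})

#' CrossCorrResult: normalized lag cross-correlation between two channels
#'
#' Holds the symmetric lag grid tau (hours), the Pearson-normalized
#' cross-correlation R(tau) between the cyan-like and yellow-like traces, the
#' unnormalized cross-covariance, and the number of cell-time pairs entering
#' each lag. The decorrelation time tau50 is computed from this object by
#' \code{\link{tau50}}.
#'
#' @slot lag numeric vector of lags in hours, symmetric about 0.
#' @slot R numeric vector, normalized cross-correlation per lag (|R| <= 1).
#' @slot cov numeric vector, unnormalized cross-covariance per lag.
#' @slot nPairs integer vector, valid (cell, time) pairs per lag.
#' @slot nCells integer, number of cells contributing.
#' @slot measure character, which per-cell measure was correlated.
#' @exportClass CrossCorrResult
setClass("CrossCorrResult",
  slots = c(
    lag     = "numeric",
    R       = "numeric",
    cov     = "numeric",
    nPairs  = "integer",
    nCells  = "integer",
    measure = "character"
  )
)

setValidity("CrossCorrResult", function(object) {
  n <- length(object@lag)
  if (length(object@R) != n || length(object@cov) != n || length(object@nPairs) != n)
    return("lag, R, cov and nPairs must have equal length")
  if (is.unsorted(object@lag))
    return("lag grid must be increasing")
  ok <- !is.na(object@R)
  if (any(abs(object@R[ok]) > 1 + 1e-8))
    return("|R| must not exceed 1 under Pearson normalization")
  TRUE
})

#' GeneModel: an exon structure for in-silico tagging
#'
#' Ordered exons as 1-based inclusive intervals on the transcript's strand,
#' with the reading-frame phase at which each exon starts. Minus-strand
#' genomic input is reverse-complemented at load so the stored model is
#' always transcript-oriented.
#'
#' @slot geneId character identifier.
#' @slot exons data.frame with columns name, start, end, phase.
#' @slot sequence character, the transcript-oriented genomic sequence spanning
#'   the model, or "" when operating on interval arithmetic alone.
#' @exportClass GeneModel
setClass("GeneModel",
  slots = c(
    geneId   = "character",
    exons    = "data.frame",
    sequence = "character"
  )
)

setValidity("GeneModel", function(object) {
  ex <- object@exons
  need <- c("name", "start", "end", "phase")
  miss <- setdiff(need, names(ex))
  if (length(miss))
    return(paste("exon table missing columns:", paste(miss, collapse = ", ")))
  if (nrow(ex) == 0L) return("gene model needs at least one exon")
  if (any(ex$end < ex$start)) return("exon end before start")
  if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)]))
    return("exons must be ordered and non-overlapping")
  if (!all(ex$phase %in% 0:2)) return("exon phases must be 0, 1 or 2")
  if (nchar(object@sequence) > 0 && nchar(object@sequence) < max(ex$end))
    return("sequence shorter than last exon end")
  TRUE
})

#' ArtificialExon: a splice-ready tagging cassette
#'
#' The cassette is a fluorescent-tag coding sequence without start or stop
#' codons, flanked by a splice acceptor and a splice donor, built in one of
#' the three reading-frame phases so that, once spliced into a transcript at
#' an intron of matching phase, the tag reads in frame with both flanking
#' exons.
#'
#' @slot acceptor character, splice-acceptor sequence (intronic side).
#' @slot tagCds character, the tag coding sequence (length divisible by 3).
#' @slot donor character, splice-donor sequence (intronic side).
#' @slot phase integer in 0:2, the intron phase the cassette is designed for.
#' @exportClass ArtificialExon
setClass("ArtificialExon",
  slots = c(
    acceptor = "character",
    tagCds   = "character",
    donor    = "character",
    phase    = "integer"
  )
)

#' TaggedTranscript: a spliced transcript, optionally carrying the tag exon
#'
#' @slot geneId character.
#' @slot exons data.frame with columns name, length and transcript-coordinate
#'   offsets (tx_start, tx_end) of each exon on the spliced mRNA.
#' @slot splicedLength integer, total mRNA length (sum of exon lengths).
#' @slot inFrame logical, TRUE when the cassette phase matches the insertion
#'   point phase and the tag length is a multiple of 3 (TRUE for wild type).
#' @slot fusionProteinLength numeric, fusion protein length in amino acids
#'   when in frame and the exons are coding, else NA.
#' @slot sequence character spliced mRNA sequence, or "".
#' @exportClass TaggedTranscript
setClass("TaggedTranscript",
  slots = c(
    geneId              = "character",
    exons               = "data.frame",
    splicedLength       = "integer",
    inFrame             = "logical",
    fusionProteinLength = "numeric",
    sequence            = "character"
  )
)

setValidity("TaggedTranscript", function(object) {
  if (object@splicedLength != sum(object@exons$length))
    return("spliced length must equal the sum of exon lengths")
  TRUE
})
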