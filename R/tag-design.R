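#' @include AllClasses.R
NULL

## canonical splice-site consensus defaults; overridable everywhere they are
## used. The acceptor carries the polypyrimidine tract + 3' AG, the donor
## the 5' GT context.
DEFAULT_ACCEPTOR <- "TTTTTTTTTTTCTTTCAG"
DEFAULT_DONOR <- "GTAAGTAT"

STOP_CODONS <- c("TAA", "TAG", "TGA")

codonsOf <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
}

#' Construct a GeneModel
#'
#' Exons are 1-based inclusive intervals on the transcript's strand. When a
#' genomic minus-strand model is supplied (\code{strand = "-"}), the
#' sequence is reverse-complemented and the exon coordinates flipped at
#' load, so the stored model is always transcript-oriented. Reading-frame
#' phases (the codon position at which each exon starts) are computed from
#' the exon lengths when not given, assuming the first exon starts in phase
#' 0 and the exons are coding -- adequate for the toy models this module
#' works on.
#'
#' @param gene_id character identifier.
#' @param starts,ends integer vectors of exon bounds (1-based inclusive).
#' @param names optional exon names (default E1, E2, ...).
#' @param phases optional integer vector in 0:2, one per exon.
#' @param sequence optional genomic sequence covering the model.
#' @param strand "+" or "-" (minus is reverse-complemented at load).
#' @return a \linkS4class{GeneModel}.
#' @export
geneModel <- function(gene_id, starts, ends, names = NULL, phases = NULL,
                      sequence = NULL, strand = "+") {
  stopifnot(length(starts) == length(ends), strand %in% c("+", "-"))
  n <- length(starts)
  if (is.null(names)) names <- paste0("E", seq_len(n))
  if (strand == "-") {
    if (is.null(sequence))
      stop("minus-strand input needs the sequence to orient against")
    L <- nchar(sequence)
    sequence <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    new_starts <- rev(L - ends + 1L)
    new_ends <- rev(L - starts + 1L)
    starts <- new_starts; ends <- new_ends
    names <- rev(names)
  }
  ord <- order(starts)
  starts <- as.integer(starts[ord]); ends <- as.integer(ends[ord])
  names <- names[ord]
  lens <- ends - starts + 1L
  if (is.null(phases)) {
    phases <- integer(n)
    for (i in seq_len(n - 1L)) phases[i + 1L] <- (phases[i] + lens[i]) %% 3L
  } else {
    phases <- as.integer(phases[ord])
  }
  new("GeneModel", geneId = gene_id,
      exons = data.frame(name = names, start = starts, end = ends,
                         phase = phases),
      sequence = if (is.null(sequence)) "" else toupper(sequence))
}

#' Read a gene model from an exon table and optional FASTA
#'
#' The exon table is a TSV with columns \code{name, start, end} and
#' optionally \code{phase}; the FASTA (read with Biostrings) supplies the
#' genomic sequence. All operations also work sequence-free on interval
#' arithmetic alone.
#'
#' @param exon_table path to the TSV.
#' @param fasta optional path to a single-record FASTA.
#' @param gene_id identifier (default: FASTA record name or file name).
#' @param strand "+" or "-".
#' @return a \linkS4class{GeneModel}.
#' @export
readGeneModel <- function(exon_table, fasta = NULL, gene_id = NULL,
                          strand = "+") {
  ex <- utils::read.delim(exon_table, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(ex)))
    stop("exon table must have columns name, start, end")
  seq <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) != 1L) stop("expected a single-record FASTA")
    seq <- as.character(ss[[1]])
    if (is.null(gene_id)) gene_id <- names(ss)[1]
  }
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(exon_table))
  geneModel(gene_id, ex$start, ex$end, names = ex$name,
            phases = if ("phase" %in% names(ex)) ex$phase else NULL,
            sequence = seq, strand = strand)
}

#' Build an artificial-exon tagging cassette in one reading frame
#'
#' Validates the tag coding sequence (length divisible by 3, no internal
#' stop codon in frame 0, no start or stop codon at its ends) and wraps it
#' between a splice acceptor and donor, marked with the intron phase the
#' cassette is designed for. One cassette per phase covers any insertion
#' point; \code{\link{buildCassettes}} enumerates all three.
#'
#' @param tag_cds tag coding sequence (character, A/C/G/T).
#' @param phase intron phase in 0:2 the cassette targets.
#' @param acceptor,donor splice-site sequences; defaults are canonical
#'   consensus sites and can be overridden with the experimentally used
#'   ones.
#' @return an \linkS4class{ArtificialExon}.
#' @export
buildCassette <- function(tag_cds, phase,
                          acceptor = DEFAULT_ACCEPTOR,
                          donor = DEFAULT_DONOR) {
  stopifnot(phase %in% 0:2)
  tag_cds <- toupper(tag_cds)
  if (!nchar(tag_cds))
    stop("empty tag coding sequence")
  if (nchar(tag_cds) %% 3L != 0L)
    stop("tag coding sequence length (", nchar(tag_cds),
         ") must be divisible by 3")
  if (grepl("[^ACGT]", tag_cds))
    stop("tag coding sequence contains non-ACGT characters")
  cod <- codonsOf(tag_cds)
  stops <- which(cod %in% STOP_CODONS)
  if (length(stops))
    stop("tag coding sequence contains a stop codon (", cod[stops[1]],
         ") at codon ", stops[1])
  if (cod[1] == "ATG")
    stop("tag coding sequence must not begin with a start codon")
  new("ArtificialExon", acceptor = toupper(acceptor), tagCds = tag_cds,
      donor = toupper(donor), phase = as.integer(phase))
}

#' Enumerate the three reading-frame variants of a cassette
#'
#' @inheritParams buildCassette
#' @return list of three \linkS4class{ArtificialExon} objects, phases 0, 1
#'   and 2.
#' @export
buildCassettes <- function(tag_cds, acceptor = DEFAULT_ACCEPTOR,
                           donor = DEFAULT_DONOR) {
  lapply(0:2, function(p) buildCassette(tag_cds, p, acceptor, donor))
}

spliceExonTable <- function(exons) {
  lens <- exons$end - exons$start + 1L
  tx_end <- cumsum(lens)
  data.frame(name = exons$name, length = lens,
             tx_start = tx_end - lens + 1L, tx_end = tx_end)
}

#' Splice a gene model, optionally inserting a tag cassette into an intron
#'
#' Models the splicing outcome of inserting the artificial exon into intron
#' \code{intron_index} (between exons \code{intron_index} and
#' \code{intron_index + 1}): the spliced mRNA gains one exon named
#' \code{"tag"} of the tag's length, so its length grows by exactly the tag
#' size. The fusion is in frame iff the cassette's phase equals the
#' insertion-point phase (the phase at which the upstream exon ends) and
#' the tag length is a multiple of 3. With \code{cassette = NULL} the
#' wild-type spliced transcript is returned.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param intron_index which intron receives the cassette (1-based; NULL or
#'   together with \code{cassette = NULL} for the wild type).
#' @param cassette an \linkS4class{ArtificialExon}, or NULL.
#' @return a \linkS4class{TaggedTranscript}.
#' @export
insertExon <- function(gene, intron_index = NULL, cassette = NULL) {
  stopifnot(is(gene, "GeneModel"))
  ex <- gene@exons
  n <- nrow(ex)
  hasSeq <- nchar(gene@sequence) > 0
  exonSeq <- function(i) substr(gene@sequence, ex$start[i], ex$end[i])
  if (is.null(cassette)) {
    tab <- spliceExonTable(ex)
    seq <- if (hasSeq)
      paste(vapply(seq_len(n), exonSeq, character(1)), collapse = "") else ""
    return(new("TaggedTranscript", geneId = gene@geneId, exons = tab,
               splicedLength = sum(tab$length), inFrame = TRUE,
               fusionProteinLength = sum(tab$length) / 3,
               sequence = seq))
  }
  stopifnot(is(cassette, "ArtificialExon"))
  if (is.null(intron_index) || intron_index < 1L || intron_index > n - 1L)
    stop("intron_index must be between 1 and ", n - 1L,
         " (gene has ", n, " exons)")
  i <- as.integer(intron_index)
  lens <- ex$end - ex$start + 1L
  insertion_phase <- (ex$phase[i] + lens[i]) %% 3L
  tagLen <- nchar(cassette@tagCds)
  in_frame <- insertion_phase == cassette@phase && tagLen %% 3L == 0L
  newex <- rbind(ex[seq_len(i), c("name", "start", "end")],
                 data.frame(name = "tag", start = NA_integer_,
                            end = NA_integer_),
                 ex[seq(i + 1L, n), c("name", "start", "end")])
  tab <- data.frame(name = newex$name,
                    length = c(lens[seq_len(i)], tagLen, lens[seq(i + 1L, n)]))
  tab$tx_end <- cumsum(tab$length)
  tab$tx_start <- tab$tx_end - tab$length + 1L
  seq <- ""
  if (hasSeq) {
    seq <- paste(c(vapply(seq_len(i), exonSeq, character(1)),
                   cassette@tagCds,
                   vapply(seq(i + 1L, n), exonSeq, character(1))),
                 collapse = "")
  }
  new("TaggedTranscript", geneId = gene@geneId,
      exons = tab[, c("name", "length", "tx_start", "tx_end")],
      splicedLength = sum(tab$length), inFrame = in_frame,
      fusionProteinLength = if (in_frame) sum(tab$length) / 3 else NA_real_,
      sequence = seq)
}

#' Define a PCR primer pair on transcript references
#'
#' Spans are 1-based inclusive intervals on a named reference: an exon name
#' of the gene model, or \code{"tag"} for the inserted cassette. The
#' reverse primer's span is given in the same (sense-strand) coordinates.
#'
#' @param forward_ref,forward_span reference name and c(start, end) of the
#'   forward primer.
#' @param reverse_ref,reverse_span reference name and c(start, end) of the
#'   reverse primer.
#' @return a list of class "primerPair".
#' @export
primerPair <- function(forward_ref, forward_span, reverse_ref, reverse_span) {
  stopifnot(length(forward_span) == 2L, length(reverse_span) == 2L,
            forward_span[1] <= forward_span[2],
            reverse_span[1] <= reverse_span[2],
            forward_span[1] >= 1L, reverse_span[1] >= 1L)
  structure(list(forward_ref = forward_ref,
                 forward_span = as.integer(forward_span),
                 reverse_ref = reverse_ref,
                 reverse_span = as.integer(reverse_span)),
            class = "primerPair")
}

mapSpan <- function(transcript, ref, span) {
  ex <- transcript@exons
  i <- which(ex$name == ref)
  if (!length(i)) return(NULL)
  i <- i[1]
  if (span[2] > ex$length[i])
    stop("primer span ", span[1], "-", span[2], " exceeds reference '", ref,
         "' of length ", ex$length[i])
  c(ex$tx_start[i] + span[1] - 1L, ex$tx_start[i] + span[2] - 1L)
}

#' Predict the RT-PCR product length on a spliced transcript
#'
#' Maps both primers onto the spliced transcript and returns the amplicon
#' length, from the forward primer's 5' end to the reverse primer's 5' end
#' (span end on the sense strand), inclusive. A primer whose reference is
#' absent from the transcript (e.g. a tag-specific primer on the wild-type
#' mRNA) yields no product: NA with attribute \code{reason}.
#'
#' @param transcript a \linkS4class{TaggedTranscript}.
#' @param primers a \code{\link{primerPair}}.
#' @return product length in bp, or NA (no product) with a \code{reason}
#'   attribute.
#' @export
predictAmplicon <- function(transcript, primers) {
  stopifnot(is(transcript, "TaggedTranscript"),
            inherits(primers, "primerPair"))
  fwd <- mapSpan(transcript, primers$forward_ref, primers$forward_span)
  rev <- mapSpan(transcript, primers$reverse_ref, primers$reverse_span)
  if (is.null(fwd) || is.null(rev)) {
    miss <- c(if (is.null(fwd)) primers$forward_ref,
              if (is.null(rev)) primers$reverse_ref)
    out <- NA_integer_
    attr(out, "reason") <- paste0("no product: reference '",
                                  paste(miss, collapse = "', '"),
                                  "' absent from transcript")
    return(out)
  }
  if (fwd[1] > rev[1])
    stop("forward primer (tx ", fwd[1], ") lies downstream of the reverse ",
         "primer (tx ", rev[1], "): no amplification geometry")
  rev[2] - fwd[1] + 1L
}

#' Nesting distance of a nested (3'RACE-style) PCR
#'
#' With an outer and an inner (nested) forward primer on the same reference
#' and a common reverse primer, the nested product is shorter than the
#' first-round product by the distance between the forward primers' 5'
#' starts. Returns that difference in bp.
#'
#' @param outer_forward,inner_forward c(start, end) spans of the two forward
#'   primers on the same reference (inner downstream of, or equal to, the
#'   outer).
#' @return length difference in bp (0 for identical primers).
#' @export
nestedRaceDistance <- function(outer_forward, inner_forward) {
  stopifnot(length(outer_forward) >= 1L, length(inner_forward) >= 1L)
  o <- as.integer(outer_forward[1]); i <- as.integer(inner_forward[1])
  if (i < o)
    stop("inner (nested) primer must not lie upstream of the outer primer")
  i - o
}

#' JSON report of a tagging design
#'
#' Summarizes a tagging design: wild-type and tagged spliced lengths, frame
#' status, fusion protein length, and predicted amplicons for a set of
#' primer pairs on both transcripts.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param intron_index intron receiving the cassette.
#' @param cassette an \linkS4class{ArtificialExon}.
#' @param primer_pairs named list of \code{\link{primerPair}} objects.
#' @param file optional path; when given the report is written as JSON.
#' @return the report as a list, invisibly when written to file.
#' @export
tagDesignReport <- function(gene, intron_index, cassette,
                            primer_pairs = list(), file = NULL) {
  wt <- insertExon(gene, NULL, NULL)
  tagged <- insertExon(gene, intron_index, cassette)
  amp <- function(tx) lapply(primer_pairs, function(p) {
    a <- predictAmplicon(tx, p)
    if (is.na(a)) list(reason = attr(a, "reason"))
    else list(product = as.integer(a))
  })
  rep <- list(gene = gene@geneId,
              intron_index = as.integer(intron_index),
              tag_length = nchar(cassette@tagCds),
              cassette_phase = cassette@phase,
              in_frame = tagged@inFrame,
              wildtype_spliced_length = wt@splicedLength,
              tagged_spliced_length = tagged@splicedLength,
              fusion_protein_aa = if (is.na(tagged@fusionProteinLength))
                NULL else tagged@fusionProteinLength,
              amplicons_wildtype = amp(wt),
              amplicons_tagged = amp(tagged))
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(rep))
  }
  rep
}
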