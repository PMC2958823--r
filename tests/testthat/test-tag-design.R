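# a toy 5-exon gene whose spliced mRNA is 414 bp, with a 714 bp tag CDS:
# the sizes of the wild-type amplicon and fluorescent-tag insert used
# throughout these tests
toyGene <- function(sequence = NULL) {
  # exon lengths 80, 70, 90, 100, 74 = 414; introns of 50 bp
  lens <- c(80L, 70L, 90L, 100L, 74L)
  starts <- cumsum(c(1L, head(lens, -1) + 50L))
  geneModel("toy", starts, starts + lens - 1L, sequence = sequence)
}

randomCds <- function(n_codons, seed) {
  set.seed(seed)
  ok <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste, collapse = ""),
                c("TAA", "TAG", "TGA", "ATG"))
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

tagCds714 <- randomCds(238, seed = 7)   # 714 bp, stop-free

test_that("cassette construction enumerates exactly the three reading frames", {
  cs <- buildCassettes(tagCds714)
  expect_length(cs, 3L)
  expect_equal(vapply(cs, function(c) c@phase, integer(1)), 0:2)
  expect_equal(length(unique(vapply(cs, function(c) c@phase, integer(1)))), 3L)
})

test_that("cassette validation rejects malformed tag sequences", {
  expect_error(buildCassette("", 0), "empty")
  expect_error(buildCassette("ACGTA", 0), "divisible by 3")
  expect_error(buildCassette("ACGTAAGGG", 0), "stop codon.*codon 2")
  expect_error(buildCassette("ATGCCCGGG", 0), "start codon")
  expect_error(buildCassette("ACGNNNGGG", 0), "non-ACGT")
})

test_that("inserting the tag exon grows the spliced mRNA by exactly the tag length", {
  g <- toyGene()
  wt <- insertExon(g)
  expect_equal(wt@splicedLength, 414L)
  for (intron in 1:4) {
    tg <- insertExon(g, intron, buildCassette(tagCds714, 0))
    expect_equal(tg@splicedLength, 414L + 714L)
    expect_equal(sum(tg@exons$length), tg@splicedLength)
  }
  expect_error(insertExon(g, 5, buildCassette(tagCds714, 0)), "intron_index")
})

test_that("frame algebra: fusion is in frame iff cassette phase matches the intron phase", {
  g <- toyGene()
  lens <- g@exons$end - g@exons$start + 1L
  for (intron in 1:4) {
    pt <- sum(lens[1:intron]) %% 3L
    for (ph in 0:2) {
      tg <- insertExon(g, intron, buildCassette(tagCds714, ph))
      expect_equal(tg@inFrame, ph == pt)
      if (ph != pt) expect_true(is.na(tg@fusionProteinLength))
    }
  }
})

test_that("the first-to-last-exon RT-PCR doublet is 414 vs 1128 bp", {
  g <- toyGene()
  # primers anchored at the transcript ends: full-length amplicon
  pp <- primerPair("E1", c(1, 20), "E5", c(55, 74))
  wt <- insertExon(g)
  expect_equal(predictAmplicon(wt, pp), 414L)
  phase3 <- sum((g@exons$end - g@exons$start + 1L)[1:3]) %% 3L
  tg <- insertExon(g, 3, buildCassette(tagCds714, phase3))
  expect_true(tg@inFrame)
  expect_equal(predictAmplicon(tg, pp), 1128L)
  expect_equal(predictAmplicon(tg, pp) - predictAmplicon(wt, pp), 714L)
})

test_that("tag-specific primers give no product on the wild-type transcript", {
  g <- toyGene()
  pp <- primerPair("tag", c(432, 451), "E5", c(55, 74))
  wt <- insertExon(g)
  out <- predictAmplicon(wt, pp)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "tag")
  tg <- insertExon(g, 3, buildCassette(tagCds714, 0))
  expect_false(is.na(predictAmplicon(tg, pp)))
})

test_that("reversed primer geometry is rejected", {
  g <- toyGene()
  pp <- primerPair("E5", c(55, 74), "E1", c(1, 20))
  expect_error(predictAmplicon(insertExon(g), pp), "downstream")
})

test_that("amplicon difference equals the tag length for random toy gene models", {
  set.seed(11)
  for (rep in 1:15) {
    n_ex <- sample(3:7, 1)
    lens <- sample(60:200, n_ex, replace = TRUE)
    starts <- cumsum(c(1L, head(lens, -1) + sample(40:120, n_ex - 1,
                                                   replace = TRUE)))
    g <- geneModel("rand", starts, starts + lens - 1L)
    tagLen <- 3L * sample(50:300, 1)
    cassette <- buildCassette(randomCds(tagLen / 3L, seed = rep), 0)
    pp <- primerPair("E1", c(1, 18), paste0("E", n_ex),
                     c(lens[n_ex] - 17L, lens[n_ex]))
    wt <- predictAmplicon(insertExon(g), pp)
    intron <- sample(n_ex - 1, 1)
    tg <- predictAmplicon(insertExon(g, intron, cassette), pp)
    expect_equal(tg - wt, tagLen)
  }
})

test_that("the nested 3'RACE product is shorter by the primer nesting distance", {
  # tag-internal forward primers at positions 432-451 and 606-626
  expect_equal(nestedRaceDistance(c(432, 451), c(606, 626)), 174L)
  expect_equal(nestedRaceDistance(c(432, 451), c(432, 451)), 0L)
  expect_error(nestedRaceDistance(c(606, 626), c(432, 451)), "upstream")
  # explicit-product oracle: build both products and subtract lengths
  g <- toyGene()
  tg <- insertExon(g, 3, buildCassette(tagCds714, 0))
  common_rev <- primerPair("tag", c(432, 451), "E5", c(55, 74))
  set.seed(12)
  for (rep in 1:10) {
    a <- sort(sample(1:600, 2))
    p1 <- predictAmplicon(tg, primerPair("tag", c(a[1], a[1] + 19),
                                         "E5", c(55, 74)))
    p2 <- predictAmplicon(tg, primerPair("tag", c(a[2], a[2] + 19),
                                         "E5", c(55, 74)))
    expect_equal(nestedRaceDistance(c(a[1], a[1] + 19), c(a[2], a[2] + 19)),
                 p1 - p2)
  }
})

test_that("sequence mode splices real sequence and honors minus-strand input", {
  set.seed(13)
  g0 <- toyGene()
  L <- max(g0@exons$end) + 50L
  seqchars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seq <- paste(seqchars, collapse = "")
  g <- toyGene(sequence = seq)
  wt <- insertExon(g)
  expect_equal(nchar(wt@sequence), 414L)
  ex1 <- substr(seq, g@exons$start[1], g@exons$end[1])
  expect_equal(substr(wt@sequence, 1, 80), ex1)
  tg <- insertExon(g, 2, buildCassette(tagCds714, 0))
  expect_equal(nchar(tg@sequence), 1128L)
  expect_equal(substr(tg@sequence, 151, 864), tagCds714)
  # minus-strand load: reverse-complement and flipped coordinates give the
  # same transcript-oriented model
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  gm <- geneModel("toy", L - g0@exons$end + 1L, L - g0@exons$start + 1L,
                  sequence = rc, strand = "-")
  expect_equal(gm@exons$start, g@exons$start)
  expect_equal(insertExon(gm)@sequence, wt@sequence)
})

test_that("gene models load from exon-table TSV plus FASTA", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "toy.tsv")
  write.table(data.frame(name = c("E1", "E2"), start = c(1L, 101L),
                         end = c(40L, 160L)),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  fa <- file.path(dir, "toy.fa")
  set.seed(14)
  writeLines(c(">toygene",
               paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                     collapse = "")), fa)
  g <- readGeneModel(tsv, fa)
  expect_s4_class(g, "GeneModel")
  expect_equal(g@geneId, "toygene")
  expect_equal(insertExon(g)@splicedLength, 100L)
  expect_error(readGeneModel(tsv, fa, gene_id = NULL, strand = "x"))
})

test_that("tag design report assembles lengths, frame and amplicons", {
  g <- toyGene()
  cassette <- buildCassette(tagCds714, 1)
  pp <- list(flanks = primerPair("E1", c(1, 20), "E5", c(55, 74)),
             tag_rev = primerPair("tag", c(1, 20), "E5", c(55, 74)))
  file <- withr::local_tempfile(fileext = ".json")
  rep <- tagDesignReport(g, 2, cassette, pp, file = file)
  back <- jsonlite::read_json(file)
  expect_equal(back$wildtype_spliced_length, 414L)
  expect_equal(back$tagged_spliced_length, 1128L)
  expect_equal(back$amplicons_wildtype$flanks$product, 414L)
  expect_equal(back$amplicons_tagged$flanks$product, 1128L)
  expect_null(back$amplicons_wildtype$tag_rev$product)
  expect_true(back$in_frame == (sum(80, 70) %% 3 == 1))
})
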