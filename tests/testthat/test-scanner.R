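test_that("consensus scanning follows the strand algebra on known sites", {
  # palindromic G-box: one hit, forward strand only
  gbox <- consensus_motif("BZR1_Gbox", "CACGTG")
  h <- scan_consensus("ATCACGTGAT", gbox)
  expect_identical(h[, c("start", "end", "strand")],
                   data.frame(start = 2L, end = 8L, strand = "+"))

  # TGTCTC and its reverse orientation GAGACA in one sequence
  auxre <- consensus_motif("AuxRE_TGTCTC", "TGTCTC")
  h <- scan_consensus("TGTCTCAAGAGACA", auxre)
  expect_identical(h$start, c(0L, 8L))
  expect_identical(h$end, c(6L, 14L))
  expect_identical(h$strand, c("+", "-"))

  # wildcard positions admit any base
  pif <- consensus_motif("ClassI_PIF5like", "CANNNNCATGTG")
  h <- scan_consensus("CATTTTCATGTG", pif)
  expect_identical(h[h$strand == "+", ]$start, 0L)
  expect_identical(h[h$strand == "+", ]$end, 12L)

  expect_identical(nrow(scan_consensus("", gbox)), 0L)
})

test_that("assembly N's never match, not even wildcard positions", {
  pif <- consensus_motif("pif", "CANNNNCATGTG")
  expect_identical(nrow(scan_consensus("CATTNTCATGTG", pif)), 0L)
  auxre <- consensus_motif("auxre", "TGTCTC")
  expect_identical(nrow(scan_consensus("TGTCNC", auxre)), 0L)
})

test_that("dyad scanning enforces the spacer range and reports spacer length", {
  auxre <- dyad_motif("AuxRE_combined", "TGTC", "GACA", 11, 13)
  h <- scan_dyad(paste0("TGTC", strrep("A", 11), "GACA"), auxre)
  expect_identical(h[, c("start", "end", "strand", "spacer_len")],
                   data.frame(start = 0L, end = 19L, strand = "+",
                              spacer_len = 11L))
  expect_identical(nrow(scan_dyad(paste0("TGTC", strrep("A", 10), "GACA"),
                                  auxre)), 0L)
  # a second downstream core does not create a second in-range window
  h <- scan_dyad(paste0("TGTC", strrep("A", 12), "GACAGACA"), auxre)
  expect_identical(h[, c("start", "end", "spacer_len")],
                   data.frame(start = 0L, end = 20L, spacer_len = 12L))
  # an N inside the spacer voids the match
  expect_identical(
    nrow(scan_dyad(paste0("TGTC", "AAAAANAAAAA", "GACA"), auxre)), 0L)
})

test_that("non-everted dyads are scanned in both orientations", {
  ggtc <- dyad_motif("relaxed", "GGTC", "GACA", 11, 11)
  seq <- paste0("GGTC", strrep("T", 11), "GACA")
  h <- scan_dyad(seq, ggtc)
  expect_identical(h$strand, "+")
  h_rc <- scan_dyad(reverse_complement(seq), ggtc)
  expect_identical(h_rc$strand, "-")
  expect_identical(h_rc$start, 0L)
})

test_that("scanners agree with the brute-force oracle on random sequences", {
  set.seed(411)
  motifs <- list(
    consensus_motif("auxre", "TGTCTC"),
    consensus_motif("gbox", "CACGTG"),
    consensus_motif("pif5", "CANNNNCATGTG"),
    consensus_motif("pif5alt", "CAMNNANGTG"),
    dyad_motif("combined", "TGTC", "GACA", 2, 4),
    dyad_motif("relaxed", "GGTC", "GACA", 1, 3)
  )
  for (i in 1:150) {
    # short alphabet-biased sequences make matches frequent
    seq <- random_dna(sample(10:200, 1), alphabet = c("A", "C", "G", "T",
                                                      "T", "G", "A", "C",
                                                      "N"))
    for (m in motifs) {
      got <- scan_motif(seq, m)[, c("start", "end", "strand")]
      rownames(got) <- NULL
      want <- if (inherits(m, "dyad_motif"))
        brute_dyad(seq, m$core5, m$core3, m$spacer_min,
                   m$spacer_max)[, c("start", "end", "strand")]
      else brute_consensus(seq, m$pattern)
      rownames(want) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("hits mirror under reverse complementation of the sequence", {
  set.seed(421)
  motifs <- list(consensus_motif("pif5", "CANNNNCATGTG"),
                 consensus_motif("auxre", "TGTCTC"),
                 dyad_motif("combined", "TGTC", "GACA", 3, 5))
  for (i in 1:40) {
    seq <- random_dna(sample(30:150, 1),
                      alphabet = c("A", "C", "G", "T", "T", "A"))
    L <- nchar(seq)
    for (m in motifs) {
      h <- scan_motif(seq, m)
      h_rc <- scan_motif(reverse_complement(seq), m)
      mirrored <- data.frame(start = L - h$end, end = L - h$start,
                             strand = if (is_self_reverse_complementary(m))
                               h$strand else chartr("+-", "-+", h$strand))
      mirrored <- mirrored[order(mirrored$start, mirrored$end,
                                 mirrored$strand), ]
      rownames(mirrored) <- NULL
      got <- h_rc[, c("start", "end", "strand")]
      rownames(got) <- NULL
      expect_identical(got, mirrored)
    }
  }
})

test_that("widening a dyad's spacer range never removes hits", {
  set.seed(431)
  for (i in 1:25) {
    seq <- random_dna(300, alphabet = c("A", "C", "G", "T", "T", "A"))
    narrow <- scan_dyad(seq, dyad_motif("d", "TGTC", "GACA", 3, 4))
    wide <- scan_dyad(seq, dyad_motif("d", "TGTC", "GACA", 1, 6))
    key <- function(h) paste(h$start, h$end, h$strand)
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("presence reduces hits to per-gene booleans", {
  cat2 <- motif_catalog(consensus_motif("gbox", "CACGTG"),
                        dyad_motif("combined", "TGTC", "GACA", 11, 13))
  # no hits anywhere
  pset <- promoter_set(c("a", "b", "c"),
                       c(strrep("AT", 20), strrep("AG", 20), strrep("AC", 20)))
  scan <- build_presence(pset, cat2)
  expect_identical(dim(scan$presence), c(3L, 2L))
  expect_false(any(scan$presence))

  # five hits of one motif still one TRUE cell
  seq5 <- paste(rep("CACGTGTT", 5), collapse = "")
  pset <- promoter_set("multi", seq5)
  scan <- build_presence(pset, cat2)
  expect_identical(sum(scan$hits$motif == "gbox"), 5L)
  expect_true(scan$presence["multi", "gbox"])
  expect_false(scan$presence["multi", "combined"])
})

test_that("planted ground truth drives presence column sums", {
  set.seed(441)
  cat1 <- motif_catalog(consensus_motif("pif5", "CANNNNCATGTG"))
  n <- 30; k <- 11L
  seqs <- replicate(n, random_dna(500, alphabet = c("A", "T")))  # no C/G: no chance hits
  for (i in seq_len(k)) {
    p <- plant_motif(seqs[i], cat1$pif5)
    seqs[i] <- p$sequence
  }
  pset <- promoter_set(sprintf("g%02d", 1:n), seqs)
  scan <- build_presence(pset, cat1)
  expect_identical(sum(scan$presence[, "pif5"]), k)

  # column sums are invariant under promoter permutation
  perm <- sample(n)
  pset2 <- promoter_set(pset$records$gene_id[perm],
                        pset$records$sequence[perm],
                        pset$records$class_label[perm])
  scan2 <- build_presence(pset2, cat1)
  expect_identical(colSums(scan$presence), colSums(scan2$presence))
})

test_that("hit tables and presence matrices round-trip through TSV", {
  set.seed(451)
  pset <- promoter_set(c("g1", "g2"),
                       c(paste0("AA", "CACGTG", random_dna(30)),
                         random_dna(38)))
  scan <- build_presence(pset, motif_catalog(consensus_motif("gbox", "CACGTG")))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits(scan, pset, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(back$start, scan$hits$start)
  expect_identical(back$tss_offset, scan$hits$start - 38L)

  ptsv <- withr::local_tempfile(fileext = ".tsv")
  write_presence(scan, ptsv)
  expect_identical(read_presence(ptsv), scan$presence)
})

test_that("genomic hit coordinates recover the motif from the genome", {
  set.seed(461)
  toy_len <- 3000
  # A/T-only backbone: the spliced G-boxes are the only C/G-containing sites
  genome_seq <- random_dna(toy_len, alphabet = c("A", "T"))
  # splice a G-box into both a plus- and a minus-strand promoter window
  substr(genome_seq, 501, 506) <- "CACGTG"    # inside [400, 1000) plus window
  substr(genome_seq, 2101, 2106) <- "CACGTG"  # inside [2000, 2600) minus window
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", genome_seq), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1001\t1400\t.\t+\t.\tID=gp",
               "chr1\ttoy\tgene\t1500\t2000\t.\t-\t.\tID=gm"), gff)
  pset <- extract_upstream(fa, gff, c("gp", "gm"), 600)
  scan <- build_presence(pset, motif_catalog(consensus_motif("gbox", "CACGTG")))
  gr <- hits_to_granges(scan, pset)
  expect_identical(length(gr), 2L)
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    expect_identical(substring(genome_seq, s, e), "CACGTG")
  }
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(scan, pset, bed)
  reread <- rtracklayer::import(bed)
  expect_identical(GenomicRanges::start(reread), GenomicRanges::start(gr))
})
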