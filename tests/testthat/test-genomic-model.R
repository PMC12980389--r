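# Data model, format round-trips, and coordinate algebra.

test_that("genome FASTA round-trips with case normalization", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "gggatgaaa", "cccGGGtttTAGGGGG",
               ">chr2", "ACGTN"), path)
  g <- read_genome(path)
  expect_named(g, c("chr1", "chr2"))
  expect_identical(g[["chr1"]], "GGGATGAAACCCGGGTTTTAGGGGG")
  expect_identical(g[["chr2"]], "ACGTN")
  out <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, out)
  expect_identical(read_genome(out), g)
})

test_that("invalid genome characters are rejected", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTRY"), path)
  expect_error(read_genome(path), "outside")
})

test_that("transcript_model enforces interval invariants", {
  expect_error(transcript_model("T", "G", "chr1", "+",
                                data.frame(start = c(1, 5), end = c(6, 9)),
                                data.frame(start = 2, end = 4)),
               "overlap")
  expect_error(transcript_model("T", "G", "chr1", "+",
                                data.frame(start = 1, end = 10),
                                data.frame(start = 5, end = 12)),
               "outside exons")
  # intervals get sorted by genomic start regardless of input order
  tx <- transcript_model("T", "G", "chr1", "-",
                         data.frame(start = c(40, 28), end = c(47, 36)),
                         data.frame(start = c(40, 30), end = c(45, 35)))
  expect_identical(tx$cds$start, c(30L, 40L))
})

test_that("GTF reading merges stop codons, skips non-coding, round-trips", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0('chr1\tx\texon\t1\t25\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    paste0('chr1\tx\tCDS\t4\t18\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    paste0('chr1\tx\tstop_codon\t19\t21\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    paste0('chr1\tx\texon\t50\t80\t.\t+\t.\tgene_id "G2"; transcript_id "T2";'),
    paste0('chr2\tx\texon\t30\t35\t.\t-\t.\tgene_id "G3"; transcript_id "T3";'),
    paste0('chr2\tx\texon\t40\t45\t.\t-\t.\tgene_id "G3"; transcript_id "T3";'),
    paste0('chr2\tx\tCDS\t30\t35\t.\t-\t.\tgene_id "G3"; transcript_id "T3";'),
    paste0('chr2\tx\tCDS\t40\t45\t.\t-\t.\tgene_id "G3"; transcript_id "T3";')),
    path)
  txs <- read_transcripts(path)
  expect_setequal(names(txs), c("T1", "T3"))     # T2 has no CDS
  expect_identical(txs$T1$cds, data.frame(start = 4L, end = 21L))
  # minus-strand CDS pieces stored sorted by genomic start
  expect_identical(txs$T3$cds$start, c(30L, 40L))
  out <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(txs, out)
  back <- read_transcripts(out)
  expect_identical(back$T3$cds, txs$T3$cds)
  expect_identical(back$T1$exons, txs$T1$exons)
  expect_identical(back$T1$strand, "+")
})

test_that("VCF reading maps GT/GQ/PS and flags multi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t7\t.\tA\tG\t.\t.\t.\tGT:GQ:PS\t1|0:40:4",
    "chr1\t13\t.\tG\tT\t.\t.\t.\tGT:GQ\t1/1:55",
    "chr1\t16\t.\tT\tG,C\t.\t.\t.\tGT:GQ\t1/2:30"), path)
  v <- read_phased_variants(path)
  expect_equal(nrow(v), 3L)
  expect_true(v$phased[1] && is_het(v)[1])
  expect_identical(v$phase_set[1], "4")
  expect_equal(v$gq, c(40, 55, 30))
  expect_false(v$phased[2])                       # hom 1/1 is not phased
  expect_false(is_het(v)[2])
  expect_true(v$multiallelic[3])
  out <- withr::local_tempfile(fileext = ".vcf")
  write_phased_variants(v[1:2, ], out)
  back <- read_phased_variants(out)
  expect_identical(back[, c("chrom", "pos", "ref", "alt", "gt1", "gt2",
                            "phased", "phase_set")],
                   v[1:2, c("chrom", "pos", "ref", "alt", "gt1", "gt2",
                            "phased", "phase_set")])
})

test_that("multi-sample VCF is rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t7\t.\tA\tG\t.\t.\t.\tGT\t1|0\t0|0"), path)
  expect_error(read_phased_variants(path), "multi-sample")
})

test_that("spliced CDS extraction matches manual substring on the toy", {
  expect_identical(spliced_cds_sequence(toy_genome(), toy_tx()),
                   "ATGAAACCCGGGTTTTAG")
})

test_that("minus-strand spliced CDS equals revcomp-ordered pieces", {
  g <- c(chrA = "TTTTTCTACCCGGGTTTCATGGGGG")
  # single-interval strand symmetry
  tx_plus <- transcript_model("P", "G", "chrA", "+",
                              data.frame(start = 1, end = 25),
                              data.frame(start = 4, end = 21))
  tx_minus <- transcript_model("M", "G", "chrA", "-",
                               data.frame(start = 1, end = 25),
                               data.frame(start = 4, end = 21))
  s_plus <- spliced_cds_sequence(g, tx_plus)
  s_minus <- spliced_cds_sequence(g, tx_minus)
  expect_identical(
    s_minus,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s_plus))))
  # two-interval minus strand: downstream-genomic piece comes first
  g2 <- c(chrB = "AAACATTCCGGGCTATTTGGG")
  txm <- transcript_model("M2", "G", "chrB", "-",
                          data.frame(start = c(4, 13), end = c(9, 18)),
                          data.frame(start = c(4, 13), end = c(9, 18)))
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_identical(spliced_cds_sequence(g2, txm),
                   paste0(rc("CTATTT"), rc("CATTCC")))
  # per-base enumeration oracle agrees
  expect_identical(spliced_cds_sequence(g2, txm), walk_cds_sequence(g2, txm))
})

test_that("genomic/CDS coordinate mapping matches the toy arithmetic", {
  tx <- toy_tx()
  expect_identical(genomic_to_cds_coord(tx, 7L), 4L)
  expect_true(is.na(genomic_to_cds_coord(tx, 2L)))
  expect_true(is.na(genomic_to_cds_coord(tx, 23L)))
  expect_identical(cds_interval_to_genomic(tx, 4L, 6L),
                   structure(data.frame(start = 7L, end = 9L), strand = "+"),
                   ignore_attr = TRUE)
  # full CDS range reproduces the annotated intervals
  full <- cds_interval_to_genomic(tx, 1L, cds_length(tx))
  expect_identical(full$start, tx$cds$start)
  expect_identical(full$end, tx$cds$end)
  expect_error(cds_interval_to_genomic(tx, 0L, 3L), "out of bounds")
})

test_that("CDS range spanning an intron yields blocks abutting the intron", {
  g2 <- c(chrB = "AAACATTCCGGGCTATTTGGG")
  txm <- transcript_model("M2", "G", "chrB", "-",
                          data.frame(start = c(4, 13), end = c(9, 18)),
                          data.frame(start = c(4, 13), end = c(9, 18)))
  iv <- cds_interval_to_genomic(txm, 5L, 8L)   # crosses the junction
  expect_equal(nrow(iv), 2L)
  expect_identical(iv$start, c(8L, 13L))
  expect_identical(iv$end, c(9L, 14L))
  # highest CDS base of a minus-strand transcript is CDS position 1
  expect_identical(genomic_to_cds_coord(txm, 18L), 1L)
})

test_that("round-trip property holds for every CDS base of random models", {
  set.seed(42)
  sim <- simulate_reference(42, n_genes = 6, exons_per_tx = 3)
  for (tx in sim$txs) {
    for (b in seq_len(cds_length(tx))) {
      iv <- cds_interval_to_genomic(tx, b, b)
      expect_equal(nrow(iv), 1L)
      expect_identical(genomic_to_cds_coord(tx, iv$start), b)
    }
    # spliced sequence agrees with the base-by-base walking oracle
    expect_identical(spliced_cds_sequence(sim$genome, tx),
                     walk_cds_sequence(sim$genome, tx))
  }
})
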