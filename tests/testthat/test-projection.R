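# Variant application, translation, effect flags, labels.

toy_applied <- function() {
  v <- toy_variants()
  haploproteo:::variants_to_cds_space(toy_tx(), v)
}

test_that("variant application edits the carried haplotype only", {
  app <- toy_applied()
  cds <- "ATGAAACCCGGGTTTTAG"
  v1 <- app[app$pos == 7L, ]
  expect_identical(apply_variants_to_cds(cds, v1, 1L), "ATGGAACCCGGGTTTTAG")
  expect_identical(apply_variants_to_cds(cds, v1, 2L), cds)
  # 1-nt deletion shortens the sequence at that offset
  del <- hp_variants("chr1", 8L, "AA", "A", 1L, 1L)
  del <- haploproteo:::variants_to_cds_space(toy_tx(), del)
  expect_identical(apply_variants_to_cds(cds, del, 1L), "ATGAACCCGGGTTTTAG")
  # reference mismatch is an error naming the variant
  bad <- v1; bad$ref_cds <- "C"
  expect_error(apply_variants_to_cds(cds, bad, 1L), "mismatch")
})

test_that("translation follows the standard code and stops at the first terminator", {
  tr <- translate_cds("ATGAAACCCGGGTTTTAG")
  expect_identical(tr$aa, "MKPGF")
  expect_true(tr$stop_observed)
  expect_equal(tr$stop_codon_index, 6L)
  tr2 <- translate_cds("ATGGAACCCTGGTTTTAG")
  expect_identical(tr2$aa, "MEPWF")
  # no terminator
  tr3 <- translate_cds("ATGAAA")
  expect_identical(tr3$aa, "MK")
  expect_false(tr3$stop_observed)
  # N codons yield X
  expect_identical(translate_cds("ATGANATAG")$aa, "MX")
  expect_error(translate_cds("AT"), "codon")
})

test_that("the toy transcript projects to MEPWF / MKPWL with diff K2E;G4W", {
  out <- project_transcript_haplotypes(toy_genome(), toy_tx(), toy_variants(),
                                       toy_th())
  expect_length(out, 2L)
  haps <- setNames(vapply(out, `[[`, character(1), "aa"),
                   vapply(out, function(e) as.character(e$haplotype), character(1)))
  expect_identical(unname(haps["1"]), "MEPWF")
  expect_identical(unname(haps["2"]), "MKPWL")
  e1 <- out[[which(names(haps) == "1")]]
  expect_identical(e1$diff, "K2E;G4W")
  expect_false(e1$flags$has_indel)
  expect_false(e1$flags$frameshift)
  expect_false(e1$flags$changed_stop)
  # two applied non-silent variants on hap 1 (V1 het + V2 hom)
  expect_equal(nrow(e1$applied), 2L)
})

test_that("hom-only and silent variants collapse to a single HOM product", {
  v_hom <- toy_variants()[2, ]
  out <- project_transcript_haplotypes(toy_genome(), toy_tx(), v_hom, toy_th())
  expect_length(out, 1L)
  expect_identical(out[[1]]$label, "HOM")
  expect_identical(out[[1]]$aa, "MKPWF")
  # silent third-base SNV: CCC -> CCG (both Pro), cds position 9 = genomic 12
  v_silent <- hp_variants("chr1", 12L, "C", "G", 1L, 1L, gq = 40)
  out2 <- project_transcript_haplotypes(toy_genome(), toy_tx(), v_silent,
                                        toy_th())
  expect_length(out2, 1L)
  expect_identical(out2[[1]]$label, "HOM")
  expect_identical(out2[[1]]$aa, "MKPGF")
  expect_equal(nrow(out2[[1]]$applied), 0L)   # silent excluded
  # zero variants project to exactly the reference protein
  out3 <- project_transcript_haplotypes(toy_genome(), toy_tx(),
                                        toy_variants()[0, ], toy_th())
  expect_identical(out3[[1]]$aa, "MKPGF")
  expect_identical(out3[[1]]$diff, "")
})

test_that("frameshift, resolved frameshift and stop flags are derived from edits", {
  g <- toy_genome(); tx <- toy_tx(); th <- toy_th()
  # 1-nt deletion mid-CDS: frameshift; translation runs into the 3' UTR
  del <- hp_variants("chr1", 8L, "AA", "A", 1L, 1L, gq = 40)
  out <- project_transcript_haplotypes(g, tx, del, th)
  expect_true(out[[1]]$flags$frameshift)
  expect_true(out[[1]]$flags$has_indel)
  expect_false(out[[1]]$flags$resolved_frameshift)
  expect_true(out[[1]]$flags$changed_stop)
  # deletion + downstream insertion restores the frame
  pair <- hp_variants("chr1", c(8L, 12L), c("AA", "C"), c("A", "CT"),
                      1L, 1L, gq = 40)
  out2 <- project_transcript_haplotypes(g, tx, pair, th)
  expect_true(out2[[1]]$flags$resolved_frameshift)
  expect_false(out2[[1]]$flags$frameshift)
  expect_true(out2[[1]]$flags$has_indel)
  # SNV destroying the stop codon: translation extends into the 3' UTR
  nostop <- hp_variants("chr1", 19L, "T", "C", 1L, 1L, gq = 40)
  out3 <- project_transcript_haplotypes(g, tx, nostop, th)
  expect_true(out3[[1]]$flags$changed_stop)
  expect_true(nchar(out3[[1]]$aa) > 5L)
})

test_that("diff strings for length-changing edits come from a minimal alignment", {
  # in-frame deletion of one codon
  eff <- characterize_effects("MKPGF", "MKGF",
                              data.frame(type = "indel", delta = -3L,
                                         cds_pos = 7L))
  expect_match(eff$diff, "^del3:P$")
  eff2 <- characterize_effects("MKPGF", "MKAPGF",
                               data.frame(type = "indel", delta = 3L,
                                          cds_pos = 7L))
  expect_match(eff2$diff, "ins2:A")
})

test_that("an indel spanning an intron boundary is skipped with a warning", {
  g2 <- c(chrB = "AAACATTCCGGGCTATTTGGG")
  txm <- transcript_model("M2", "G", "chrB", "+",
                          data.frame(start = c(4, 13), end = c(9, 18)),
                          data.frame(start = c(4, 13), end = c(9, 18)))
  v <- hp_variants("chrB", 8L, "CCGGGCT", "C", 1L, 1L, gq = 40)
  expect_warning(
    out <- project_transcript_haplotypes(g2, txm, v, toy_th()),
    "CDS boundary")
  expect_equal(nrow(out[[1]]$applied), 0L)
})

test_that("haplotype labels propagate allele assignments across isoforms", {
  g <- toy_genome()
  tx1 <- toy_tx()
  tx2 <- transcript_model("T2", "G1", "chr1", "+",
                          data.frame(start = 1, end = 25),
                          data.frame(start = 4, end = 21))
  # same het variant, opposite VCF order in the second isoform
  v1 <- hp_variants("chr1", 7L, "A", "G", 1L, 0L, phased = TRUE,
                    phase_set = "4", gq = 40)
  v2 <- v1; v2$gt1 <- 0L; v2$gt2 <- 1L
  e1 <- project_transcript_haplotypes(g, tx1, v1, toy_th())
  e2 <- project_transcript_haplotypes(g, tx2, v2, toy_th())
  labeled <- assign_haplotype_labels(c(e1, e2))
  ids <- vapply(labeled, `[[`, character(1), "entry_id")
  seqs <- setNames(vapply(labeled, `[[`, character(1), "aa"), ids)
  # the alt-carrying products of both isoforms share the same letter
  expect_identical(unname(seqs["T1.A"]), unname(seqs["T2.A"]))
  expect_identical(unname(seqs["T1.B"]), unname(seqs["T2.B"]))
  expect_identical(unname(seqs["T1.A"]), "MEPGF")
  # label assignment is invariant to input order
  labeled_rev <- assign_haplotype_labels(c(e2, e1))
  ids_rev <- vapply(labeled_rev, `[[`, character(1), "entry_id")
  expect_identical(sort(ids), sort(ids_rev))
  expect_identical(
    setNames(vapply(labeled_rev, `[[`, character(1), "aa"), ids_rev)[ids],
    seqs)
  # isoforms with disjoint het sets each default haplotype 1 to A
  v3 <- hp_variants("chr1", 16L, "T", "C", 0L, 1L, phased = TRUE,
                    phase_set = "4", gq = 40)
  e3 <- project_transcript_haplotypes(g, tx2, v3, toy_th())
  lab2 <- assign_haplotype_labels(c(e1, e3))
  hap1 <- Filter(function(e) identical(e$haplotype, 1L), lab2)
  expect_true(all(vapply(hap1, `[[`, character(1), "label") == "A"))
})

test_that("het-only haplotype pairs differ unless every variant is silent", {
  sim <- simulate_reference(5, n_genes = 5, exons_per_tx = 2)
  pv <- simulate_phased_variants(5, sim$genome, sim$txs,
                                 n_het_snv = 2, n_hom_snv = 0)
  for (tx in sim$txs) {
    out <- project_transcript_haplotypes(sim$genome, tx, pv$variants)
    if (length(out) == 2L) {
      expect_false(identical(out[[1]]$aa, out[[2]]$aa))
    } else {
      # collapsed: every planted het must have been silent
      expect_equal(nrow(out[[1]]$applied), 0L)
    }
  }
})
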