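# Peptide classification, haplotype calls, variant identification,
# protein groups, genes, browser-track projection.

# Two-gene toy: T1 (chr1) carries the three phased variants and projects to
# MEPWF (A) / MKPWL (B); T2 (chr2, "MTKWG") stays reference; N1 skips the
# middle of T2's CDS (novel junction product "MTG").
ps_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    genome <- c(toy_genome(), chr2 = "GGGATGACCAAATGGGGATAGGGGG")
    txs <- list(
      T1 = toy_tx(),
      T2 = transcript_model("T2", "G2", "chr2", "+",
                            data.frame(start = 1, end = 25),
                            data.frame(start = 4, end = 21)),
      N1 = transcript_model("N1", "G2", "chr2", "+",
                            data.frame(start = 1, end = 25),
                            data.frame(start = c(4, 16), end = c(9, 21))))
    th <- hp_thresholds(min_cds_nt = 9L, min_peptide_len = 4L)
    proc <- process_variants(toy_variants(), txs, th)
    projections <- project_all_transcripts(genome, txs, proc$variants, th,
                                           novel_ids = "N1")
    ref <- reference_proteome(genome, txs[c("T1", "T2")], th)
    is_novel <- vapply(projections, `[[`, logical(1), "is_novel_splice")
    with_var <- vapply(projections, function(e) nrow(e$applied) > 0L,
                       logical(1))
    db <- build_search_database(
      ref, unname(projections[with_var & !is_novel]),
      unname(projections[is_novel]),
      contaminants = c(CON_A = "KKWWKKWWKK"), th = th, seed = 1)
    cache <<- list(genome = genome, txs = txs, th = th,
                   variants = proc$variants, projections = projections,
                   db = db, ref = ref)
    cache
  }
})

test_that("the toy database holds the expected entries", {
  fx <- ps_fixture()
  tgt <- fx$db[fx$db$class != "decoy", ]
  expect_setequal(tgt$entry_id[tgt$class == "variant"], c("T1.A", "T1.B"))
  expect_identical(tgt$seq[tgt$entry_id == "T1.A"], "MEPWF")
  expect_identical(tgt$seq[tgt$entry_id == "T1.B"], "MKPWL")
  expect_identical(tgt$seq[tgt$entry_id == "N1"], "MTG")
  expect_identical(tgt$class[tgt$entry_id == "N1"], "novel_splice")
})

test_that("PSM filtering keeps sub-threshold target peptides only", {
  fx <- ps_fixture()
  psms <- data.frame(
    peptide = c("MEPWF", "MTKWG", "KKWWK", "MKPWL", "WGPKM"),
    q_value = c(0.005, 0.02, 0.001, 0.009, 0.002),
    proteins = c("T1.A", "T2", "CON_A", "T1.B", "XXX_T2"))
  acc <- filter_psms(psms, fx$db, fx$th)
  expect_setequal(acc, c("MEPWF", "MKPWL"))   # high-q, contaminant-only,
                                              # decoy-only all rejected
  bad <- psms; bad$proteins[1] <- "NOPE"
  expect_error(filter_psms(bad, fx$db, fx$th), "unknown database entry")
})

test_that("peptides classify as reference, variant, splice", {
  fx <- ps_fixture()
  expect_identical(classify_peptide("MTKWG", fx$db, fx$projections),
                   "reference")
  expect_identical(classify_peptide("KPG", fx$db, fx$projections),
                   "reference")                 # substring of reference T1
  expect_identical(classify_peptide("MEP", fx$db, fx$projections), "variant")
  expect_identical(classify_peptide("MTG", fx$db, fx$projections), "splice")
  # substring of a reference protein stays reference even when the
  # reference entry was displaced by its variant products
  expect_identical(classify_peptide("MK", fx$db, fx$projections,
                                    reference_seqs = fx$ref), "reference")
})

test_that("peptide haplotype calls require a unique single-haplotype match", {
  fx <- ps_fixture()
  expect_identical(assign_peptide_haplotype("MEPWF", fx$db), "A")
  expect_identical(assign_peptide_haplotype("MKPWL", fx$db), "B")
  expect_identical(assign_peptide_haplotype("PW", fx$db), "homozygous")
  expect_identical(assign_peptide_haplotype("MTG", fx$db), "homozygous")
})

test_that("direct identification needs span coverage and uniqueness", {
  fx <- ps_fixture()
  # MEPWF covers V1 (E2) and hom V2 (W4) on T1.A, uniquely
  d1 <- identify_direct_variants("MEPWF", fx$db, fx$projections)
  expect_setequal(d1$pos, c(7L, 13L))
  expect_setequal(d1$zygosity, c("heterozygous", "homozygous"))
  expect_true(all(d1$mode == "direct"))
  # PWF covers residues 3..5 only: V1 not direct, V2 (residue 4) is
  d2 <- identify_direct_variants("PWF", fx$db, fx$projections)
  expect_identical(d2$pos, 13L)
  # MK occurs in the reference protein (entry lacking the variants):
  # nothing is direct
  d3 <- identify_direct_variants("MK", fx$db, fx$projections)
  expect_equal(nrow(d3), 0L)
})

test_that("linked inference follows phase blocks and co-residence", {
  fx <- ps_fixture()
  direct <- identify_direct_variants("MEP", fx$db, fx$projections)
  expect_identical(direct$pos, 7L)           # V1 only
  linked <- infer_linked_variants(direct, fx$projections, fx$variants)
  expect_setequal(linked$pos, c(13L, 16L))
  expect_identical(
    linked$zygosity[order(linked$pos)], c("homozygous", "heterozygous"))
  expect_length(intersect(direct$key, linked$key), 0L)
  # no direct variants -> empty linked set
  none <- identify_direct_variants(character(0), fx$db, fx$projections)
  expect_equal(nrow(infer_linked_variants(none, fx$projections,
                                          fx$variants)), 0L)
})

test_that("greedy set cover picks maximal coverage with lexicographic ties", {
  db <- data.frame(entry_id = c("A", "B", "C"),
                   seq = c("AAAAXCCCC", "CCCCXDDDD", "XDDDDX"),
                   class = "reference",
                   members = c("A", "B", "C"))
  accepted <- c("AAAA", "CCCC", "DDDD")
  groups <- infer_protein_groups(accepted, db)
  expect_length(groups, 2L)
  expect_identical(groups[[1]]$members, "A")
  expect_identical(groups[[2]]$members, "B")   # tie on {DDDD}: B < C
  expect_setequal(unlist(lapply(groups, `[[`, "peptides")), accepted)
  # entries with identical peptide sets merge into one group
  db2 <- data.frame(entry_id = c("E1", "E2"),
                    seq = c("AAAAGGGG", "GGGGAAAA"), class = "reference",
                    members = c("E1", "E2"))
  g2 <- infer_protein_groups(c("AAAA", "GGGG"), db2)
  expect_length(g2, 1L)
  expect_identical(g2[[1]]$members, c("E1", "E2"))
})

test_that("gene identification requires single-gene protein groups", {
  fx <- ps_fixture()
  gm <- entry_gene_map(fx$db, fx$txs)
  expect_identical(unname(gm[c("T1.A", "T1.B", "T2", "N1")]),
                   c("G1", "G1", "G2", "G2"))
  expect_true(is.na(gm["CON_A"]))
  g_one <- identify_genes(list(list(members = c("T1.A", "T1.B"),
                                    peptides = "x")), gm)
  expect_identical(g_one, "G1")
  g_mixed <- identify_genes(list(list(members = c("T1.A", "T2"),
                                      peptides = "x")), gm)
  expect_length(g_mixed, 0L)
  expect_length(identify_genes(list(), gm), 0L)
})

test_that("peptides project back to genomic blocks through edits", {
  fx <- ps_fixture()
  # residues 2..4 of T1.A -> CDS 4..12 -> chr1:7-15 (SNVs preserve length)
  b <- project_peptide_to_genome("EPW", "T1.A", fx$projections, fx$txs)
  expect_equal(nrow(b), 1L)
  expect_identical(c(b$start, b$end), c(7L, 15L))
  expect_identical(attr(b, "chrom"), "chr1")
  # junction-spanning novel peptide yields two blocks around the skip
  b2 <- project_peptide_to_genome("MTG", "N1", fx$projections, fx$txs)
  expect_equal(nrow(b2), 2L)
  expect_identical(b2$start, c(4L, 16L))
  expect_identical(b2$end, c(9L, 18L))   # MTG covers 9 coding nt
  # HOM entry without indels projects identically to the reference
  b3 <- project_peptide_to_genome("TKW", "T2", fx$projections, fx$txs)
  expect_identical(c(b3$start, b3$end), c(7L, 15L))
  expect_error(project_peptide_to_genome("ZZZZ", "T2", fx$projections,
                                         fx$txs), "not found")
  # BED12 export: one line per peptide, block sizes match
  bed <- withr::local_tempfile(fileext = ".bed")
  write_peptide_bed(c("EPW", "MTG"), c("T1.A", "N1"), fx$projections,
                    fx$txs, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_length(lines, 2L)
  expect_identical(lines[[2]][c(1, 2, 3, 10, 11, 12)],
                   c("chr2", "3", "18", "2", "6,3,", "0,12,"))
})

test_that("peptide projection inverts indel offsets", {
  # 1-nt deletion at CDS 5 shifts downstream residues by one frame step
  g <- toy_genome(); tx <- toy_tx()
  th <- hp_thresholds(min_cds_nt = 9L)
  del <- hp_variants("chr1", 8L, "AA", "A", 1L, 1L, gq = 40)
  proc <- process_variants(del, list(T1 = tx), th)
  proj <- project_all_transcripts(g, list(T1 = tx), proc$variants, th)
  e <- proj[[1]]
  expect_true(e$flags$frameshift)
  # residue 1 (M) maps to the first codon regardless of the edit
  b <- project_peptide_to_genome(substr(e$aa, 1, 1), e$entry_id, proj,
                                 list(T1 = tx))
  expect_identical(c(b$start, b$end), c(4L, 6L))
})

test_that("annotation records tally variants by type and zygosity", {
  fx <- ps_fixture()
  ann <- build_annotation_records(fx$projections)
  a <- ann[ann$entry_id == "T1.A", ]
  expect_equal(a$n_snv_het, 1L)
  expect_equal(a$n_snv_hom, 1L)
  expect_equal(a$n_indel_het + a$n_indel_hom, 0L)
  expect_identical(a$diff, "K2E;G4W")
  expect_false(a$frameshift)
  r <- ann[ann$entry_id == "T2", ]
  expect_equal(r$n_snv_het + r$n_snv_hom + r$n_indel_het + r$n_indel_hom, 0L)
  expect_identical(r$diff, "")
  expect_true(ann$novel_splice[ann$entry_id == "N1"])
})

test_that("modification stripping leaves bare residue strings", {
  expect_identical(strip_peptide_mods("M[+15.995]EPWF"), "MEPWF")
  expect_identical(strip_peptide_mods("MEP(ox)WF"), "MEPWF")
  expect_identical(strip_peptide_mods("mEPWF2"), "EPWF")
})

test_that("end-to-end annotation on the toy picks up all planted variants", {
  fx <- ps_fixture()
  psms <- simulate_search_results(3, fx$db, coverage_fraction = 1,
                                  n_decoy_noise = 1, n_high_q = 1,
                                  th = fx$th)
  sr <- annotate_search_results(psms, fx$db, fx$projections, fx$txs,
                                fx$variants, fx$th)
  expect_true(all(c("MEPWF", "MKPWL", "MTKWG") %in% sr$accepted))
  expect_setequal(sr$variant_ids$pos, c(7L, 13L, 16L))
  expect_true(all(sr$variant_ids$mode == "direct"))
  expect_setequal(sr$genes, c("G1", "G2"))
  cov <- unique(unlist(lapply(sr$groups, `[[`, "peptides")))
  expect_setequal(cov, sr$accepted)
})
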