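## End-to-end orchestration: variant processing -> haplotype projection ->
## database assembly -> (optional) post-search annotation, with a manifest
## of checksummed outputs. External tools (aligner, caller, phaser, search
## engine) are consumed through their standard-format outputs, never run.

#' Project every transcript and label the products
#'
#' @param genome Named character vector.
#' @param txs Named list of \code{transcript_model}.
#' @param variants Processed variant data frame.
#' @param th \code{\link{hp_thresholds}}.
#' @param novel_ids Transcript ids to mark as novel-splice isoforms.
#' @return Named list (by entry id) of labeled \code{haplotype_protein}.
#' @export
project_all_transcripts <- function(genome, txs, variants,
                                    th = hp_thresholds(),
                                    novel_ids = character(0)) {
  entries <- list()
  for (tx in txs) {
    entries <- c(entries, project_transcript_haplotypes(
      genome, tx, variants, th,
      is_novel_splice = tx$transcript_id %in% novel_ids))
  }
  entries <- assign_haplotype_labels(entries)
  setNames(entries, vapply(entries, `[[`, character(1), "entry_id"))
}

#' Translate the reference proteome from genome + annotation
#'
#' Keeps transcripts whose CDS is at least \code{th$min_cds_nt} long and
#' divisible by 3; others are dropped (with a message), mirroring the
#' complete-CDS filtering applied to the input annotation.
#'
#' @inheritParams project_all_transcripts
#' @return Named character vector transcript_id -> protein sequence.
#' @export
reference_proteome <- function(genome, txs, th = hp_thresholds()) {
  keep <- vapply(txs, function(tx)
    cds_length(tx) >= th$min_cds_nt && cds_length(tx) %% 3L == 0L, logical(1))
  if (any(!keep))
    message("dropping ", sum(!keep), " transcript(s) with incomplete or short CDS")
  vapply(txs[keep], function(tx)
    translate_cds(spliced_cds_sequence(genome, tx))$aa, character(1))
}

#' Build a run configuration
#'
#' @param genome,gtf,vcf Input paths (required).
#' @param reference_proteome Optional protein FASTA; when NULL the
#'   reference proteome is translated from genome + annotation.
#' @param contaminants Optional contaminant FASTA.
#' @param psms Optional PSM TSV; post-search annotation runs when present.
#' @param out_dir Output directory.
#' @param th \code{\link{hp_thresholds}}.
#' @param seed Integer seed (decoy generation).
#' @param novel_ids Transcript ids to treat as novel-splice isoforms.
#' @return Validated config list.
#' @export
run_config <- function(genome, gtf, vcf, reference_proteome = NULL,
                       contaminants = NULL, psms = NULL,
                       out_dir = ".", th = hp_thresholds(), seed = 1L,
                       novel_ids = character(0)) {
  cfg <- list(genome = genome, gtf = gtf, vcf = vcf,
              reference_proteome = reference_proteome,
              contaminants = contaminants, psms = psms,
              out_dir = out_dir, th = th, seed = as.integer(seed),
              novel_ids = novel_ids)
  for (f in c("genome", "gtf", "vcf", "reference_proteome", "contaminants",
              "psms")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input path does not exist: ", f, " = ", cfg[[f]])
  }
  cfg
}

#' Run the pipeline stages
#'
#' Variant processing, haplotype projection, database construction, and --
#' when a PSM table is configured -- post-search annotation. All outputs
#' land in \code{config$out_dir}, listed with MD5 checksums in
#' \code{manifest.tsv}. Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param config From \code{\link{run_config}}.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  th <- config$th

  genome <- read_genome(config$genome)
  txs <- read_transcripts(config$gtf)
  raw <- read_phased_variants(config$vcf)
  proc <- process_variants(raw, txs, th)
  write_filter_report(proc$report, out("filter_report.json"))
  write_phased_variants(proc$variants, out("variants_processed.vcf"))

  ref <- if (is.null(config$reference_proteome))
    reference_proteome(genome, txs, th)
  else
    read_protein_fasta(config$reference_proteome)
  contam <- if (is.null(config$contaminants)) character(0)
            else read_protein_fasta(config$contaminants)

  projections <- project_all_transcripts(genome, txs, proc$variants, th,
                                         novel_ids = config$novel_ids)
  with_var <- vapply(projections, function(e) nrow(e$applied) > 0L, logical(1))
  is_novel <- vapply(projections, `[[`, logical(1), "is_novel_splice")
  db <- build_search_database(
    reference = ref,
    haplotype_proteins = unname(projections[with_var & !is_novel]),
    novel_proteins = unname(projections[is_novel]),
    contaminants = contam, th = th, seed = config$seed)
  write_database(db, out("database.fasta"), out("database_sidecar.tsv"))
  ann <- build_annotation_records(projections)
  utils::write.table(ann, out("protein_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  results <- list(variants = proc$variants, report = proc$report,
                  projections = projections, db = db, annotation = ann)

  if (!is.null(config$psms)) {
    psms <- read_psm_table(config$psms)
    sr <- annotate_search_results(psms, db, projections, txs,
                                  proc$variants, th,
                                  reference_seqs = unname(ref))
    utils::write.table(sr$peptide_annotations, out("peptide_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grp <- data.frame(
      group = seq_along(sr$groups),
      members = vapply(sr$groups, function(g)
        paste(g$members, collapse = ";"), character(1)),
      n_peptides = vapply(sr$groups, function(g)
        length(g$peptides), integer(1)))
    utils::write.table(grp, out("protein_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sr$variant_ids, out("variant_identifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sr$genes, out("identified_genes.txt"))
    results$search <- sr
  }

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   out("manifest.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$manifest <- manifest
  invisible(results)
}
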