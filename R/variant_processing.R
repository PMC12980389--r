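## Post-call variant filtering and phase-block post-processing.
##
## The guarantee established by the full chain: every CDS either contains no
## heterozygous variant, or all heterozygous variants it overlaps are phased
## and share a single phase set, so each CDS forms one contiguous phase
## block and haplotype projection is well defined.

new_filter_report <- function(n_input = 0L, n_removed_gq = 0L,
                              n_removed_multiallelic = 0L,
                              n_removed_phase_incomplete = 0L,
                              n_singleton_assigned = 0L, n_output = 0L) {
  structure(list(n_input = as.integer(n_input),
                 n_removed_gq = as.integer(n_removed_gq),
                 n_removed_multiallelic = as.integer(n_removed_multiallelic),
                 n_removed_phase_incomplete = as.integer(n_removed_phase_incomplete),
                 n_singleton_assigned = as.integer(n_singleton_assigned),
                 n_output = as.integer(n_output)),
            class = "hp_filter_report")
}

#' @export
print.hp_filter_report <- function(x, ...) {
  cat("variant filter report:\n")
  for (k in names(x)) cat(sprintf("  %-28s %d\n", k, x[[k]]))
  invisible(x)
}

#' Filter variants on genotype quality and allele count
#'
#' Retains biallelic variants with genotype quality at or above
#' \code{th$min_gq} (default 5); multi-allelic records, flagged by the VCF
#' reader, are removed. Input order is preserved.
#'
#' @param variants Variant data frame.
#' @param th \code{\link{hp_thresholds}}.
#' @return List with \code{variants} (filtered) and \code{report}.
#' @export
filter_variants <- function(variants, th = hp_thresholds()) {
  n <- nrow(variants)
  multi <- variants$multiallelic
  low_gq <- !multi & (is.na(variants$gq) | variants$gq < th$min_gq)
  keep <- !multi & !low_gq
  list(variants = variants[keep, , drop = FALSE],
       report = new_filter_report(
         n_input = n,
         n_removed_gq = sum(low_gq),
         n_removed_multiallelic = sum(multi),
         n_output = sum(keep)))
}

# For each transcript CDS, the row indices of heterozygous variants whose
# reference span overlaps it.
het_by_cds <- function(variants, txs) {
  het <- is_het(variants)
  lapply(txs, function(tx) {
    which(het & variant_overlaps_cds(variants, tx))
  })
}

#' Remove heterozygous variants from incompletely phased CDS regions
#'
#' Whenever a CDS overlaps two or more heterozygous variants that are not
#' all phased into one and the same phase set, the CDS cannot be projected
#' onto haplotypes, and every heterozygous variant overlapping that CDS is
#' removed. A variant overlapping several CDS regions is removed if it
#' fails the rule in any of them. Homozygous variants are never touched.
#'
#' @param variants Variant data frame (already quality-filtered).
#' @param txs List of \code{transcript_model}.
#' @return List with \code{variants} and \code{report}.
#' @export
enforce_cds_phase_completeness <- function(variants, txs) {
  n <- nrow(variants)
  drop <- rep(FALSE, n)
  for (idx in het_by_cds(variants, txs)) {
    if (length(idx) < 2L) next
    ps <- variants$phase_set[idx]
    ok <- all(variants$phased[idx]) && !anyNA(ps) && length(unique(ps)) == 1L
    if (!ok) drop[idx] <- TRUE
  }
  list(variants = variants[!drop, , drop = FALSE],
       report = new_filter_report(
         n_input = n,
         n_removed_phase_incomplete = sum(drop),
         n_output = n - sum(drop)))
}

#' Assign phase blocks to isolated heterozygous variants
#'
#' An unphased heterozygous variant that overlaps at least one CDS and is
#' the sole heterozygous variant in every CDS it overlaps gets an arbitrary
#' but deterministic phase: haplotype 1 carries the alternative allele, and
#' the variant's genomic position becomes its (fresh, collision-free) phase
#' set. Phasing is arbitrary for such singletons because no other
#' heterozygous variant in the region constrains it.
#'
#' @param variants Variant data frame (after
#'   \code{\link{enforce_cds_phase_completeness}}).
#' @param txs List of \code{transcript_model}.
#' @return List with \code{variants} and \code{report}.
#' @export
assign_singleton_phase_blocks <- function(variants, txs) {
  n <- nrow(variants)
  per_cds <- het_by_cds(variants, txs)
  n_overlapped <- integer(n)  # CDS regions each variant overlaps
  alone <- rep(TRUE, n)       # sole het in every overlapped CDS
  for (idx in per_cds) {
    n_overlapped[idx] <- n_overlapped[idx] + 1L
    if (length(idx) > 1L) alone[idx] <- FALSE
  }
  target <- which(is_het(variants) & !variants$phased &
                    n_overlapped > 0L & alone)
  if (length(target)) {
    variants$phased[target] <- TRUE
    variants$gt1[target] <- 1L
    variants$gt2[target] <- 0L
    variants$phase_set[target] <- as.character(variants$pos[target])
  }
  list(variants = variants,
       report = new_filter_report(
         n_input = n, n_singleton_assigned = length(target), n_output = n))
}

#' Run the full variant post-processing chain
#'
#' Quality/allele-count filtering, CDS phase-completeness enforcement, and
#' singleton phase-block assignment, with a merged report. The chain is
#' idempotent.
#'
#' @inheritParams enforce_cds_phase_completeness
#' @param th \code{\link{hp_thresholds}}.
#' @return List with \code{variants} and \code{report}.
#' @export
process_variants <- function(variants, txs, th = hp_thresholds()) {
  s1 <- filter_variants(variants, th)
  s2 <- enforce_cds_phase_completeness(s1$variants, txs)
  s3 <- assign_singleton_phase_blocks(s2$variants, txs)
  list(variants = s3$variants,
       report = new_filter_report(
         n_input = s1$report$n_input,
         n_removed_gq = s1$report$n_removed_gq,
         n_removed_multiallelic = s1$report$n_removed_multiallelic,
         n_removed_phase_incomplete = s2$report$n_removed_phase_incomplete,
         n_singleton_assigned = s3$report$n_singleton_assigned,
         n_output = nrow(s3$variants)))
}

#' Group phased heterozygous variants into phase blocks
#'
#' @param variants Variant data frame.
#' @return Data frame with one row per (chrom, phase_set) block:
#'   \code{chrom}, \code{phase_set}, \code{n_members}, and a list column
#'   \code{member_positions} (sorted).
#' @export
build_phase_blocks <- function(variants) {
  sel <- variants[is_het(variants) & variants$phased &
                    !is.na(variants$phase_set), , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(chrom = character(0), phase_set = character(0),
                      n_members = integer(0),
                      member_positions = I(list())))
  }
  key <- paste(sel$chrom, sel$phase_set, sep = "\r")
  sp <- split(sel$pos, key)
  ids <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(ids, `[`, character(1), 1L),
    phase_set = vapply(ids, `[`, character(1), 2L),
    n_members = lengths(sp),
    stringsAsFactors = FALSE)
  out$member_positions <- I(lapply(sp, sort))
  ord <- order(out$chrom, vapply(out$member_positions, min, numeric(1)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a filter report as key-value JSON
#' @param report An \code{hp_filter_report}.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
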