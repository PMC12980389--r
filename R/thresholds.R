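#' Analysis thresholds
#'
#' Bundle of the tunable cutoffs used across the workflow. The defaults are
#' the values used throughout: genotype-quality filtering at GQ >= 5,
#' a minimum CDS length of 100 nt (applied in codons, i.e. 33 residues, when
#' re-filtering translated haplotype proteins), PSM acceptance at q < 0.01,
#' and tryptic digestion with up to two missed cleavages and peptide lengths
#' of 5--100 residues. Decoy peptide collisions are re-shuffled for at most
#' \code{max_decoy_iterations} attempts.
#'
#' The \code{caller_*} fields record the upstream variant-caller settings
#' (minimum allele fraction 0.08 for SNVs / 0.15 for indels, coverage 3,
#' MAPQ 5) for provenance only; they act inside the caller and are not
#' re-applied here.
#'
#' @param min_gq Minimum genotype quality for a variant to be retained.
#' @param min_cds_nt Minimum CDS length in nucleotides.
#' @param psm_q_max PSMs with q-values at or above this are rejected.
#' @param max_missed_cleavages Maximum missed tryptic cleavages.
#' @param min_peptide_len,max_peptide_len Peptide length window (residues).
#' @param max_decoy_iterations Shuffle attempts per colliding decoy peptide.
#' @param caller_min_af_snv,caller_min_af_indel,caller_min_coverage,caller_min_mapq
#'   Upstream caller settings, informational.
#' @return An object of class \code{hp_thresholds} (a named list).
#' @export
hp_thresholds <- function(min_gq = 5,
                          min_cds_nt = 100L,
                          psm_q_max = 0.01,
                          max_missed_cleavages = 2L,
                          min_peptide_len = 5L,
                          max_peptide_len = 100L,
                          max_decoy_iterations = 100L,
                          caller_min_af_snv = 0.08,
                          caller_min_af_indel = 0.15,
                          caller_min_coverage = 3L,
                          caller_min_mapq = 5L) {
  th <- list(
    min_gq = min_gq,
    min_cds_nt = as.integer(min_cds_nt),
    psm_q_max = psm_q_max,
    max_missed_cleavages = as.integer(max_missed_cleavages),
    min_peptide_len = as.integer(min_peptide_len),
    max_peptide_len = as.integer(max_peptide_len),
    max_decoy_iterations = as.integer(max_decoy_iterations),
    caller_min_af_snv = caller_min_af_snv,
    caller_min_af_indel = caller_min_af_indel,
    caller_min_coverage = as.integer(caller_min_coverage),
    caller_min_mapq = as.integer(caller_min_mapq)
  )
  stopifnot(all(vapply(th, function(x) is.numeric(x) && x >= 0, logical(1))),
            th$min_peptide_len <= th$max_peptide_len)
  structure(th, class = "hp_thresholds")
}
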