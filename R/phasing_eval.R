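## Phasing accuracy (switch error rate) and completeness metrics at
## variant and CDS/transcript/gene resolution.

#' Switch error rate between a truth and a test phasing
#'
#' Comparison is restricted to heterozygous sites phased in both call sets
#' with identical REF/ALT alleles; sites that are heterozygous in one set
#' but homozygous in the other are excluded and counted in the
#' \code{n_excluded} attribute. Within each test phase block, shared sites
#' are ordered by position; each consecutive pair is assessed for relative
#' orientation (haplotype-1 alleles agreeing at both sites, or flipped at
#' both sites), and a switch is a change of orientation between the two
#' sites of a pair. Pairs spanning two test blocks are not assessed.
#' Phasing is relative, so a global haplotype flip leaves the rate
#' unchanged.
#'
#' @param truth,test Variant data frames.
#' @return List with \code{n_switches}, \code{n_assessed_pairs} and
#'   \code{rate} (0 when no pairs were assessed).
#' @export
switch_error_rate <- function(truth, test) {
  kt <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  ks <- paste(test$chrom, test$pos, test$ref, test$alt)
  truth_i <- match(ks, kt)
  n_excluded <- 0L
  shared <- which(!is.na(truth_i))
  use <- logical(length(shared))
  for (j in seq_along(shared)) {
    i <- shared[j]; ti <- truth_i[i]
    het_pair <- is_het(test[i, ]) && is_het(truth[ti, ])
    if (!het_pair && (is_het(test[i, ]) || is_het(truth[ti, ]))) {
      n_excluded <- n_excluded + 1L   # het/hom genotype mismatch
      next
    }
    use[j] <- het_pair && test$phased[i] && truth$phased[ti] &&
      !is.na(test$phase_set[i])
  }
  idx <- shared[use]
  n_switches <- 0L; n_pairs <- 0L
  if (length(idx) >= 2L) {
    block <- paste(test$chrom[idx], test$phase_set[idx])
    for (b in unique(block)) {
      bi <- idx[block == b]
      bi <- bi[order(test$pos[bi])]
      if (length(bi) < 2L) next
      orient <- test$gt1[bi] == truth$gt1[truth_i[bi]]
      n_pairs <- n_pairs + length(bi) - 1L
      n_switches <- n_switches + sum(orient[-1L] != orient[-length(orient)])
    }
  }
  out <- list(n_switches = n_switches, n_assessed_pairs = n_pairs,
              rate = if (n_pairs > 0L) n_switches / n_pairs else 0)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Phasing completeness counts
#'
#' @param test Variant data frame.
#' @return List with \code{n_phased_het} and \code{n_het_total}.
#' @export
completeness_counts <- function(test) {
  het <- is_het(test)
  list(n_phased_het = sum(het & test$phased), n_het_total = sum(het))
}

region_intervals <- function(txs, level = c("CDS", "transcript", "gene")) {
  level <- match.arg(level)
  if (level == "gene") {
    genes <- vapply(txs, `[[`, character(1), "gene_id")
    lapply(split(txs, genes), function(g) {
      iv <- do.call(rbind, lapply(g, `[[`, "cds"))
      r <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
      list(chrom = g[[1]]$chrom,
           iv = data.frame(start = IRanges::start(r), end = IRanges::end(r)))
    })
  } else {
    ivs <- lapply(txs, function(tx) {
      list(chrom = tx$chrom,
           iv = if (level == "CDS") tx$cds else tx$exons)
    })
    names(ivs) <- vapply(txs, `[[`, character(1), "transcript_id")
    ivs
  }
}

#' Fraction of fully phased regions
#'
#' A region (CDS, transcript exon span, or gene-level CDS union) is fully
#' phased when every heterozygous variant overlapping it is phased and all
#' of them share a single phase set. Regions with zero or one heterozygous
#' variant count as fully phased. Because the natural denominator is
#' ambiguous, three fractions are reported: over all regions, over regions
#' with at least one het, and over regions with at least two hets.
#'
#' @param test Variant data frame.
#' @param txs Named list of \code{transcript_model}.
#' @param level "CDS", "transcript" or "gene".
#' @return List with \code{fraction_all}, \code{fraction_het},
#'   \code{fraction_multi} and a per-region data frame \code{regions}.
#' @export
fully_phased_fraction <- function(test, txs, level = "CDS") {
  regs <- region_intervals(txs, level)
  het <- is_het(test)
  vs <- test$pos; ve <- test$pos + nchar(test$ref) - 1L
  tab <- lapply(names(regs), function(rn) {
    r <- regs[[rn]]
    hit <- rep(FALSE, nrow(test))
    for (i in seq_len(nrow(r$iv)))
      hit <- hit | (vs <= r$iv$end[i] & ve >= r$iv$start[i])
    idx <- which(het & hit & test$chrom == r$chrom)
    full <- length(idx) <= 1L ||
      (all(test$phased[idx]) && !anyNA(test$phase_set[idx]) &&
         length(unique(test$phase_set[idx])) == 1L)
    data.frame(region = rn, n_het = length(idx), fully_phased = full,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  frac <- function(sub) if (nrow(sub) == 0L) NA_real_ else mean(sub$fully_phased)
  list(fraction_all = frac(tab),
       fraction_het = frac(tab[tab$n_het >= 1L, , drop = FALSE]),
       fraction_multi = frac(tab[tab$n_het >= 2L, , drop = FALSE]),
       regions = tab)
}

#' Stratified phasing metrics
#'
#' Recomputes completeness (and, when transcript models / a truth set are
#' supplied, fully-phased fractions and the switch error rate) on the
#' variant subsets at each minimum-coverage cutoff, separately for SNVs
#' only and for SNVs plus indels. Sites missing from the coverage map are
#' treated as depth 0.
#'
#' @param variants Variant data frame.
#' @param coverage Named numeric vector, names "chrom:pos".
#' @param cutoffs Minimum-depth cutoffs (e.g. \code{c(5, 10, 25, 100)}).
#' @param txs Optional transcript models for fully-phased fractions.
#' @param truth Optional truth variants for the switch error rate.
#' @return Data frame, one row per cutoff and stratum.
#' @export
stratify_by_coverage <- function(variants, coverage,
                                 cutoffs = c(5, 10, 25, 100),
                                 txs = NULL, truth = NULL) {
  depth <- coverage[paste0(variants$chrom, ":", variants$pos)]
  depth[is.na(depth)] <- 0
  rows <- list()
  for (cut in cutoffs) {
    for (stratum in c("SNV", "SNV+indel")) {
      sel <- depth >= cut & (stratum == "SNV+indel" | variants$type == "SNV")
      sub <- variants[sel, , drop = FALSE]
      cc <- completeness_counts(sub)
      row <- data.frame(cutoff = cut, stratum = stratum,
                        n_variants = nrow(sub),
                        n_phased_het = cc$n_phased_het,
                        n_het_total = cc$n_het_total,
                        stringsAsFactors = FALSE)
      if (!is.null(txs)) {
        fp <- fully_phased_fraction(sub, txs, "CDS")
        row$fully_phased_cds_all <- fp$fraction_all
        row$fully_phased_cds_het <- fp$fraction_het
      }
      if (!is.null(truth)) {
        ser <- switch_error_rate(truth, sub)
        row$n_switches <- ser$n_switches
        row$n_assessed_pairs <- ser$n_assessed_pairs
        row$switch_error_rate <- ser$rate
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate phasing metrics for one call set
#'
#' @param test Variant data frame.
#' @param txs Named list of \code{transcript_model}.
#' @param truth Optional truth variant data frame.
#' @return List of class \code{hp_phasing_metrics}.
#' @export
phasing_metrics <- function(test, txs, truth = NULL) {
  cc <- completeness_counts(test)
  fp <- lapply(setNames(c("CDS", "transcript", "gene"),
                        c("CDS", "transcript", "gene")),
               function(lv) fully_phased_fraction(test, txs, lv))
  out <- list(n_phased_het = cc$n_phased_het,
              n_het_total = cc$n_het_total,
              fully_phased = lapply(fp, function(x)
                x[c("fraction_all", "fraction_het", "fraction_multi")]))
  if (!is.null(truth)) {
    ser <- switch_error_rate(truth, test)
    out$n_switches <- ser$n_switches
    out$n_assessed_pairs <- ser$n_assessed_pairs
    out$switch_error_rate <- ser$rate
  }
  structure(out, class = "hp_phasing_metrics")
}

#' @export
print.hp_phasing_metrics <- function(x, ...) {
  cat(sprintf("phased hets: %d / %d\n", x$n_phased_het, x$n_het_total))
  for (lv in names(x$fully_phased))
    cat(sprintf("fully phased %-10s all=%.3f het=%.3f multi=%.3f\n", lv,
                x$fully_phased[[lv]]$fraction_all,
                x$fully_phased[[lv]]$fraction_het,
                x$fully_phased[[lv]]$fraction_multi))
  if (!is.null(x$switch_error_rate))
    cat(sprintf("switch error rate: %d / %d = %.4f\n",
                x$n_switches, x$n_assessed_pairs, x$switch_error_rate))
  invisible(x)
}
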