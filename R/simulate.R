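## Seeded synthetic-fixture generators: genome + annotation, phased
## variants with independently edited ground-truth haplotype sequences,
## planted switch errors, and simulated search-result tables.
##
## The ground-truth haplotype sequences are built by a deliberately simple,
## self-contained string editor (plant_edits) and plain translation so that
## projection results can be checked against an independent construction.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_cds <- function(n_codons) {
  sense <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  sense <- setdiff(sense, STOP_CODONS)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Simulate a reference genome and coding annotation
#'
#' Generates \code{n_genes} single-isoform genes, one per chromosome, with
#' alternating strands and \code{exons_per_tx} exons. Every CDS starts with
#' ATG, contains no internal in-frame terminator, and ends with a stop
#' codon (included in the CDS); 5' and 3' UTRs flank it. Deterministic per
#' seed.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes/transcripts.
#' @param exons_per_tx Exons per transcript.
#' @param cds_len_range Range of CDS lengths in nt (rounded to codons).
#' @param utr_len_range,intron_len_range Length ranges for UTR ends and
#'   introns.
#' @return List with \code{genome} (named character vector) and \code{txs}
#'   (named list of \code{transcript_model}).
#' @export
simulate_reference <- function(seed = 1L, n_genes = 10L, exons_per_tx = 3L,
                               cds_len_range = c(150L, 450L),
                               utr_len_range = c(12L, 40L),
                               intron_len_range = c(20L, 60L)) {
  if (min(cds_len_range) < 9L) stop("CDS length range too small")
  set.seed(seed)
  genome <- character(0); txs <- list()
  for (g in seq_len(n_genes)) {
    chrom <- sprintf("chr%d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_cod <- sample(seq(min(cds_len_range) %/% 3L,
                        max(cds_len_range) %/% 3L), 1L)
    cds <- random_cds(n_cod)
    utr5 <- random_dna(sample(utr_len_range[1]:utr_len_range[2], 1L))
    utr3 <- random_dna(sample(utr_len_range[1]:utr_len_range[2], 1L))
    t_seq <- paste0(utr5, cds, utr3)      # transcript 5'->3'
    tlen <- nchar(t_seq)
    # split transcript into exon chunks
    if (exons_per_tx > 1L) {
      cuts <- sort(sample(seq_len(tlen - 1L), exons_per_tx - 1L))
    } else cuts <- integer(0)
    t_starts <- c(1L, cuts + 1L); t_ends <- c(cuts, tlen)
    introns <- if (exons_per_tx > 1L)
      vapply(seq_len(exons_per_tx - 1L), function(i)
        random_dna(sample(intron_len_range[1]:intron_len_range[2], 1L)),
        character(1)) else character(0)
    # lay out the forward region: exon1 intron1 exon2 ...
    r_pieces <- character(0); r_starts <- integer(exons_per_tx)
    r_ends <- integer(exons_per_tx); at <- 0L
    for (i in seq_len(exons_per_tx)) {
      chunk <- substr(t_seq, t_starts[i], t_ends[i])
      r_starts[i] <- at + 1L; r_ends[i] <- at + nchar(chunk)
      r_pieces <- c(r_pieces, chunk); at <- at + nchar(chunk)
      if (i < exons_per_tx) {
        r_pieces <- c(r_pieces, introns[i]); at <- at + nchar(introns[i])
      }
    }
    region <- paste(r_pieces, collapse = ""); rlen <- nchar(region)
    pad1 <- random_dna(sample(10:30, 1L)); pad2 <- random_dna(sample(10:30, 1L))
    # transcript-space range -> genomic intervals
    t_range_to_genomic <- function(ts, te) {
      out <- list()
      for (i in seq_len(exons_per_tx)) {
        s <- max(ts, t_starts[i]); e <- min(te, t_ends[i])
        if (s > e) next
        rs <- r_starts[i] + (s - t_starts[i]); re <- r_starts[i] + (e - t_starts[i])
        if (strand == "+") {
          out[[length(out) + 1L]] <- c(nchar(pad1) + rs, nchar(pad1) + re)
        } else {
          out[[length(out) + 1L]] <- c(nchar(pad1) + rlen - re + 1L,
                                       nchar(pad1) + rlen - rs + 1L)
        }
      }
      m <- do.call(rbind, out)
      df <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
      df[order(df$start), , drop = FALSE]
    }
    chrom_seq <- if (strand == "+") paste0(pad1, region, pad2)
                 else paste0(pad1, revcomp(region), pad2)
    cds_t <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds))
    tid <- sprintf("T%03d", g)
    tx <- transcript_model(
      transcript_id = tid, gene_id = sprintf("G%03d", g),
      chrom = chrom, strand = strand,
      exons = t_range_to_genomic(1L, tlen),
      cds = t_range_to_genomic(cds_t[1], cds_t[2]))
    genome[chrom] <- chrom_seq
    txs[[tid]] <- tx
  }
  list(genome = genome, txs = txs)
}

# Self-contained edit application for ground truth: substitute (pos, ref,
# alt) edits into a plain string, descending position order.
plant_edits <- function(seq, pos, ref, alt) {
  ord <- order(pos, decreasing = TRUE)
  for (i in ord) {
    stopifnot(substr(seq, pos[i], pos[i] + nchar(ref[i]) - 1L) == ref[i])
    seq <- paste0(substr(seq, 1L, pos[i] - 1L), alt[i],
                  substr(seq, pos[i] + nchar(ref[i]), nchar(seq)))
  }
  seq
}

# plain translation of a transcript-space sequence up to the first stop
truth_translate <- function(nt) {
  usable <- 3L * (nchar(nt) %/% 3L)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, usable)), no.init.codon = TRUE)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) substr(aa, 1L, stop_at - 1L) else aa
}

#' Simulate phased variants with ground-truth haplotype proteins
#'
#' Plants heterozygous/homozygous SNVs and short indels (1--6 nt, both
#' in-frame and frameshifting) inside each transcript's CDS, avoiding the
#' start and stop codons and keeping edits non-overlapping within a single
#' exon. All heterozygous variants of a chromosome share one phase set.
#' Ground truth is constructed independently of the projection engine: the
#' CDS + 3' UTR transcript sequence is edited directly per haplotype and
#' translated to the first terminator.
#'
#' @param seed Integer seed.
#' @param genome,txs Output of \code{\link{simulate_reference}}.
#' @param n_het_snv,n_hom_snv,n_het_indel,n_hom_indel Variants planted per
#'   transcript.
#' @param indel_max Maximum indel length in nt.
#' @param gq_range Range for simulated genotype qualities.
#' @return List with \code{variants} (phased variant data frame) and
#'   \code{truth}: per transcript, the planted rows, the two edited
#'   haplotype sequences and their translated proteins.
#' @export
simulate_phased_variants <- function(seed, genome, txs,
                                     n_het_snv = 2L, n_hom_snv = 1L,
                                     n_het_indel = 0L, n_hom_indel = 0L,
                                     indel_max = 6L,
                                     gq_range = c(20, 60)) {
  set.seed(seed)
  all_rows <- list(); truth <- list()
  for (tx in txs) {
    cds_seq <- spliced_cds_sequence(genome, tx)
    utr3 <- downstream_exonic_sequence(genome, tx)
    clen <- nchar(cds_seq)
    n_total <- n_het_snv + n_hom_snv + n_het_indel + n_hom_indel
    kinds <- c(rep("het_snv", n_het_snv), rep("hom_snv", n_hom_snv),
               rep("het_indel", n_het_indel), rep("hom_indel", n_hom_indel))
    used <- matrix(numeric(0), ncol = 2)  # claimed cds spans
    rows <- NULL
    for (kind in kinds) {
      placed <- FALSE
      for (try in 1:200) {
        is_indel <- grepl("indel", kind)
        k <- if (is_indel) sample(seq_len(indel_max), 1L) else 0L
        ins <- is_indel && stats::runif(1) < 0.5
        span_len <- if (!is_indel) 1L else if (ins) 1L else k + 1L
        p <- sample(seq(4L, clen - 3L - span_len), 1L)
        span <- c(p, p + span_len - 1L)
        if (nrow(used) && any(used[, 1] <= span[2] + 1 & used[, 2] >= span[1] - 1))
          next
        # the reference span must be contiguous on the genome (single exon)
        giv <- cds_interval_to_genomic(tx, span[1], span[2])
        if (nrow(giv) != 1L) next
        ref_cds <- substr(cds_seq, span[1], span[2])
        alt_cds <- if (!is_indel) {
          sample(setdiff(BASES, ref_cds), 1L)
        } else if (ins) {
          paste0(ref_cds, random_dna(k))
        } else {
          substr(ref_cds, 1L, 1L)
        }
        het <- grepl("het", kind)
        gt <- if (!het) c(1L, 1L) else if (stats::runif(1) < 0.5) c(1L, 0L) else c(0L, 1L)
        # genomic record
        if (tx$strand == "+") {
          gpos <- giv$start[1]; ref_g <- ref_cds; alt_g <- alt_cds
        } else {
          gpos <- giv$start[1]; ref_g <- revcomp(ref_cds); alt_g <- revcomp(alt_cds)
        }
        stopifnot(substr(genome[[tx$chrom]], gpos, gpos + nchar(ref_g) - 1L) == ref_g)
        rows <- rbind(rows, data.frame(
          chrom = tx$chrom, pos = gpos, ref = ref_g, alt = alt_g,
          gt1 = gt[1], gt2 = gt[2], het = het,
          cds_pos = span[1], ref_cds = ref_cds, alt_cds = alt_cds,
          stringsAsFactors = FALSE))
        used <- rbind(used, span)
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place a ", kind, " in ", tx$transcript_id)
    }
    full <- paste0(cds_seq, utr3)
    hap_seq <- function(h) {
      if (is.null(rows)) return(full)
      carry <- if (h == 1L) rows$gt1 == 1L else rows$gt2 == 1L
      sub <- rows[carry, , drop = FALSE]
      if (nrow(sub) == 0L) return(full)
      plant_edits(full, sub$cds_pos, sub$ref_cds, sub$alt_cds)
    }
    h1 <- hap_seq(1L); h2 <- hap_seq(2L)
    truth[[tx$transcript_id]] <- list(
      planted = rows,
      hap1_nt = h1, hap2_nt = h2,
      hap1_aa = truth_translate(h1), hap2_aa = truth_translate(h2),
      ref_aa = truth_translate(full))
    if (!is.null(rows)) {
      ps <- if (any(rows$het)) as.character(min(rows$pos[rows$het])) else NA_character_
      all_rows[[tx$transcript_id]] <- hp_variants(
        chrom = rows$chrom, pos = rows$pos, ref = rows$ref, alt = rows$alt,
        gt1 = rows$gt1, gt2 = rows$gt2,
        phased = rows$het,
        phase_set = ifelse(rows$het, ps, NA_character_),
        gq = round(stats::runif(nrow(rows), gq_range[1], gq_range[2])))
    }
  }
  variants <- if (length(all_rows)) do.call(rbind, all_rows) else empty_variants()
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, truth = truth)
}

#' Plant switch errors into a phased call set
#'
#' Within each phase block (ordered by position), flips the haplotype
#' orientation of all heterozygous sites from each chosen switch point
#' onward; each planted point contributes exactly one orientation switch
#' relative to the input.
#'
#' @param variants Phased variant data frame (the truth).
#' @param n_switches Number of switch points to plant (over all blocks).
#' @param seed Integer seed.
#' @return List with \code{test} (the perturbed call set) and
#'   \code{planted} (data frame of block / site-index switch points).
#' @export
plant_switch_errors <- function(variants, n_switches, seed = 1L) {
  set.seed(seed)
  test <- variants
  het <- which(is_het(test) & test$phased)
  blocks <- split(het, paste(test$chrom[het], test$phase_set[het]))
  blocks <- blocks[vapply(blocks, length, integer(1)) >= 2L]
  # candidate switch points: (block, site index >= 2)
  cand <- do.call(rbind, lapply(names(blocks), function(b) {
    idx <- blocks[[b]][order(test$pos[blocks[[b]]])]
    data.frame(block = b, site = seq_along(idx)[-1L],
               row = idx[-1L], first_row = idx[1L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < n_switches)
    stop("not enough assessable pairs to plant ", n_switches, " switches")
  pick <- cand[sort(sample(seq_len(nrow(cand)), n_switches)), , drop = FALSE]
  for (b in unique(pick$block)) {
    idx <- blocks[[b]][order(test$pos[blocks[[b]]])]
    flip <- rep(FALSE, length(idx))
    for (s in pick$site[pick$block == b]) {
      flip[s:length(idx)] <- !flip[s:length(idx)]
    }
    rows <- idx[flip]
    tmp <- test$gt1[rows]
    test$gt1[rows] <- test$gt2[rows]
    test$gt2[rows] <- tmp
  }
  list(test = test, planted = pick[, c("block", "site")])
}

#' Simulate a search-result (PSM) table from a database
#'
#' Samples tryptic peptides from the non-decoy, non-contaminant entries of
#' a database. A fraction \code{coverage_fraction} of the peptide universe
#' is reported with q-values drawn uniformly below 0.01; optionally,
#' decoy-matching rows below threshold and target rows above threshold are
#' added as noise. The \code{proteins} column lists every database entry
#' containing each peptide as a substring.
#'
#' @param seed Integer seed.
#' @param db Database data frame.
#' @param coverage_fraction Fraction of target tryptic peptides reported.
#' @param n_decoy_noise Decoy-only peptides reported below threshold.
#' @param n_high_q High-q-value (rejected) target rows added.
#' @param th \code{\link{hp_thresholds}} (digestion parameters).
#' @return PSM data frame (\code{peptide}, \code{q_value}, \code{proteins}).
#' @export
simulate_search_results <- function(seed, db, coverage_fraction = 1,
                                    n_decoy_noise = 0L, n_high_q = 0L,
                                    th = hp_thresholds()) {
  set.seed(seed)
  stopifnot(coverage_fraction >= 0, coverage_fraction <= 1)
  targets <- db[!db$class %in% c("decoy", "contaminant"), , drop = FALSE]
  universe <- sort(digest_with(targets$seq, th))
  n_take <- round(coverage_fraction * length(universe))
  take <- sort(sample(universe, n_take))
  match_col <- function(peps) {
    vapply(peps, function(p)
      paste(db$entry_id[grepl(p, db$seq, fixed = TRUE)], collapse = ";"),
      character(1), USE.NAMES = FALSE)
  }
  out <- data.frame(peptide = take,
                    q_value = stats::runif(length(take), 0, 0.009),
                    proteins = match_col(take), stringsAsFactors = FALSE)
  decoys <- db[db$class == "decoy", , drop = FALSE]
  if (n_decoy_noise > 0L && nrow(decoys) > 0L) {
    dpep <- setdiff(digest_with(decoys$seq, th), universe)
    dpep <- sample(dpep, min(n_decoy_noise, length(dpep)))
    if (length(dpep))
      out <- rbind(out, data.frame(
        peptide = dpep, q_value = stats::runif(length(dpep), 0, 0.009),
        proteins = match_col(dpep), stringsAsFactors = FALSE))
  }
  if (n_high_q > 0L && length(universe) > 0L) {
    hq <- sample(universe, min(n_high_q, length(universe)))
    out <- rbind(out, data.frame(
      peptide = hq, q_value = stats::runif(length(hq), 0.02, 0.2),
      proteins = match_col(hq), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
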