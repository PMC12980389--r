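## Haplotype projection: apply phased and homozygous variants to each
## transcript CDS per haplotype, translate, and characterize protein effects.
##
## All edits are performed in CDS space. A variant whose genomic reference
## span does not map to a contiguous CDS range (e.g. an indel crossing an
## intron boundary) cannot be projected and is skipped with a warning.

## ---- CDS-space transformation ----------------------------------------------

# Map variant rows onto a transcript's CDS coordinates. Adds cds_pos (start
# of the reference span in CDS coordinates), ref_cds / alt_cds (strand
# transformed) and delta (nt length change). Boundary-spanning variants are
# dropped with a warning.
variants_to_cds_space <- function(tx, variants) {
  if (nrow(variants) == 0L) {
    variants$cds_pos <- integer(0)
    variants$ref_cds <- variants$alt_cds <- character(0)
    variants$delta <- integer(0)
    return(variants)
  }
  n <- nrow(variants)
  cds_pos <- integer(n); ok <- rep(TRUE, n)
  ref_cds <- variants$ref; alt_cds <- variants$alt
  for (i in seq_len(n)) {
    L <- nchar(variants$ref[i])
    p1 <- variants$pos[i]; p2 <- p1 + L - 1L
    if (tx$strand == "+") {
      a <- genomic_to_cds_coord(tx, p1); b <- genomic_to_cds_coord(tx, p2)
    } else {
      a <- genomic_to_cds_coord(tx, p2); b <- genomic_to_cds_coord(tx, p1)
      ref_cds[i] <- revcomp(variants$ref[i])
      alt_cds[i] <- revcomp(variants$alt[i])
    }
    if (is.na(a) || is.na(b) || b - a + 1L != L) {
      ok[i] <- FALSE
      warning("variant ", variants$chrom[i], ":", variants$pos[i],
              " spans a CDS boundary of ", tx$transcript_id, "; skipped")
      next
    }
    cds_pos[i] <- a
  }
  variants$cds_pos <- cds_pos
  variants$ref_cds <- ref_cds
  variants$alt_cds <- alt_cds
  variants$delta <- nchar(alt_cds) - nchar(ref_cds)
  out <- variants[ok, , drop = FALSE]
  out[order(out$cds_pos), , drop = FALSE]
}

#' Apply variants to a CDS sequence for one haplotype
#'
#' Substitutes every variant carried by the chosen haplotype into the CDS
#' nucleotide sequence. Edits are applied in descending CDS position so
#' earlier coordinates remain valid. The variant table must be in CDS space
#' (columns \code{cds_pos}, \code{ref_cds}, \code{alt_cds}); carried means
#' \code{gt1 == 1} for haplotype 1 and \code{gt2 == 1} for haplotype 2.
#'
#' @param cds_seq Reference CDS nucleotide string.
#' @param applied CDS-space variant table (see
#'   \code{variants_to_cds_space}).
#' @param haplotype 1 or 2.
#' @return Edited nucleotide string.
#' @export
apply_variants_to_cds <- function(cds_seq, applied, haplotype) {
  stopifnot(haplotype %in% c(1L, 2L))
  carried <- if (haplotype == 1L) applied$gt1 == 1L else applied$gt2 == 1L
  ed <- applied[carried, , drop = FALSE]
  if (nrow(ed) == 0L) return(cds_seq)
  ed <- ed[order(ed$cds_pos), , drop = FALSE]
  ends <- ed$cds_pos + nchar(ed$ref_cds) - 1L
  if (nrow(ed) > 1L && any(ed$cds_pos[-1L] <= ends[-nrow(ed)]))
    stop("overlapping variant edits in CDS space")
  for (i in rev(seq_len(nrow(ed)))) {
    span <- substr(cds_seq, ed$cds_pos[i], ends[i])
    if (span != ed$ref_cds[i])
      stop("reference allele mismatch at CDS position ", ed$cds_pos[i],
           " (", ed$chrom[i], ":", ed$pos[i], "): expected ", ed$ref_cds[i],
           ", genome has ", span)
    cds_seq <- paste0(substr(cds_seq, 1L, ed$cds_pos[i] - 1L),
                      ed$alt_cds[i],
                      substr(cds_seq, ends[i] + 1L, nchar(cds_seq)))
  }
  cds_seq
}

## ---- translation ------------------------------------------------------------

#' Translate a CDS nucleotide sequence
#'
#' Standard genetic code; translation stops at the first terminator codon.
#' Codons containing N that cannot be resolved unambiguously translate to
#' 'X'. Trailing bases that do not fill a codon are ignored.
#'
#' @param nt_seq Nucleotide string, length >= 3.
#' @return List with \code{aa} (amino acids before the terminator),
#'   \code{stop_observed}, and \code{stop_codon_index} (1-based codon index
#'   of the terminator; NA when none was reached).
#' @export
translate_cds <- function(nt_seq) {
  if (nchar(nt_seq) < 3L) stop("sequence shorter than one codon")
  usable <- 3L * (nchar(nt_seq) %/% 3L)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(nt_seq, 1L, usable)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(aa = substr(aa, 1L, stop_at - 1L), stop_observed = TRUE,
         stop_codon_index = as.integer(stop_at))
  } else {
    list(aa = aa, stop_observed = FALSE, stop_codon_index = NA_integer_)
  }
}

## ---- effect characterization ------------------------------------------------

#' Characterize protein effects of applied variants
#'
#' Flags: \code{has_indel} (any applied variant is an indel);
#' \code{frameshift} (the cumulative nucleotide length offset over the
#' applied edits, scanned 5' to 3', ends at a value not divisible by 3);
#' \code{resolved_frameshift} (the running offset leaves frame mid-scan but
#' ends in frame); \code{changed_stop} (terminator codon index differs from
#' the reference); \code{changed_start} (first codon differs);
#' \code{truncated} (no terminator reached).
#'
#' The diff string lists substitutions as \code{refAA<pos>altAA} joined by
#' ';' when the two proteins have equal length; otherwise it reports the
#' edit operations of a minimal global alignment, with deletions as
#' \code{del<pos>:<residues>} and insertions as \code{ins<pos>:<residues>}
#' (positions on the reference protein).
#'
#' @param ref_protein Reference amino-acid string (no terminator).
#' @param alt_protein Variant amino-acid string (no terminator).
#' @param applied CDS-space table of the non-silent variants applied.
#' @param ref_stop,alt_stop Terminator codon indices (NA if none).
#' @param alt_stop_observed Whether the variant translation reached a stop.
#' @param ref_nt,alt_nt Reference and edited CDS nucleotide strings.
#' @return List with \code{flags} (named logical list) and \code{diff}.
#' @export
characterize_effects <- function(ref_protein, alt_protein, applied,
                                 ref_stop = NA_integer_,
                                 alt_stop = NA_integer_,
                                 alt_stop_observed = TRUE,
                                 ref_nt = "", alt_nt = "") {
  cum <- if (nrow(applied)) cumsum(applied$delta[order(applied$cds_pos)]) else integer(0)
  final_off <- if (length(cum)) cum[length(cum)] else 0L
  frameshift <- final_off %% 3L != 0L
  resolved <- !frameshift && any(cum %% 3L != 0L)
  flags <- list(
    has_indel = any(applied$type == "indel"),
    frameshift = frameshift,
    resolved_frameshift = resolved,
    changed_stop = !identical(as.integer(ref_stop), as.integer(alt_stop)),
    changed_start = nchar(ref_nt) >= 3L && nchar(alt_nt) >= 3L &&
      substr(ref_nt, 1L, 3L) != substr(alt_nt, 1L, 3L),
    truncated = !isTRUE(alt_stop_observed))
  list(flags = flags, diff = protein_diff_string(ref_protein, alt_protein))
}

protein_diff_string <- function(ref, alt) {
  if (identical(ref, alt)) return("")
  if (nchar(ref) == nchar(alt)) {
    r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
    i <- which(r != a)
    return(paste0(r[i], i, a[i], collapse = ";"))
  }
  if (nchar(ref) == 0L) return(paste0("ins0:", alt))
  if (nchar(alt) == 0L) return(paste0("del1:", ref))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(alt),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ops <- character(0)
  ref_pos <- 0L; i <- 1L
  while (i <= length(p)) {
    if (p[i] != "-" && s[i] != "-") {
      ref_pos <- ref_pos + 1L
      if (p[i] != s[i]) ops <- c(ops, paste0(p[i], ref_pos, s[i]))
      i <- i + 1L
    } else if (s[i] == "-") {            # deletion from reference
      run <- i
      while (run <= length(p) && s[run] == "-" && p[run] != "-") run <- run + 1L
      ops <- c(ops, paste0("del", ref_pos + 1L, ":",
                           paste(p[i:(run - 1L)], collapse = "")))
      ref_pos <- ref_pos + (run - i)
      i <- run
    } else {                              # insertion relative to reference
      run <- i
      while (run <= length(p) && p[run] == "-" && s[run] != "-") run <- run + 1L
      ops <- c(ops, paste0("ins", ref_pos, ":",
                           paste(s[i:(run - 1L)], collapse = "")))
      i <- run
    }
  }
  paste(ops, collapse = ";")
}

## ---- per-transcript projection ---------------------------------------------

# Translate an edited CDS, extending past a lost terminator into the
# spliced 3' UTR sequence of the transcript.
translate_with_extension <- function(cds_seq, utr3) {
  tr <- translate_cds(paste0(cds_seq, utr3))
  tr$within_cds <- tr$stop_observed && 3L * tr$stop_codon_index <= nchar(cds_seq)
  tr
}

# Alt-coordinate (edited CDS) spans of each applied edit for one haplotype,
# plus the protein residue span each edit touches.
alt_space_spans <- function(applied) {
  if (nrow(applied) == 0L) {
    applied$alt_start <- applied$alt_end <- integer(0)
    applied$aa_start <- applied$aa_end <- integer(0)
    return(applied)
  }
  applied <- applied[order(applied$cds_pos), , drop = FALSE]
  shift <- c(0L, cumsum(applied$delta))[seq_len(nrow(applied))]
  applied$alt_start <- applied$cds_pos + shift
  applied$alt_end <- applied$alt_start + pmax(nchar(applied$alt_cds), 1L) - 1L
  applied$aa_start <- (applied$alt_start + 2L) %/% 3L
  applied$aa_end <- (applied$alt_end + 2L) %/% 3L
  applied
}

#' Project a transcript's haplotype proteins
#'
#' Builds the two haplotype CDS sequences of a transcript from its
#' processed variants (homozygous-alternative variants on both haplotypes;
#' phased heterozygous variants per their phase), translates them (with
#' extension into the 3' UTR when a terminator is lost), discards products
#' shorter than \code{th$min_cds_nt / 3} codons, and drops silent variants
#' from the applied-variant lists. If the two haplotype proteins are
#' identical a single HOM product is returned.
#'
#' @param genome Named character vector from \code{\link{read_genome}}.
#' @param tx A \code{transcript_model}.
#' @param variants Processed variant data frame (all heterozygous variants
#'   overlapping the CDS must share one phase set).
#' @param th \code{\link{hp_thresholds}}.
#' @param is_novel_splice Mark products as novel-splice isoforms.
#' @return List of \code{haplotype_protein} objects (length 0, 1 or 2).
#' @export
project_transcript_haplotypes <- function(genome, tx, variants,
                                          th = hp_thresholds(),
                                          is_novel_splice = FALSE) {
  ov <- variant_overlaps_cds(variants, tx)
  rel <- variants[ov, , drop = FALSE]
  het <- is_het(rel)
  # only phased hets and hom-alt genotypes are projectable
  rel <- rel[(het & rel$phased) | (!het & rel$gt1 == 1L), , drop = FALSE]
  if (any(is_het(rel))) {
    ps <- unique(rel$phase_set[is_het(rel)])
    if (length(ps) != 1L || anyNA(ps))
      stop("heterozygous variants in CDS of ", tx$transcript_id,
           " do not share one phase set; run process_variants() first")
  }
  applied_all <- variants_to_cds_space(tx, rel)

  ref_cds <- spliced_cds_sequence(genome, tx)
  utr3 <- downstream_exonic_sequence(genome, tx)
  ref_tr <- translate_with_extension(ref_cds, utr3)

  build_hap <- function(hap) {
    nt <- apply_variants_to_cds(ref_cds, applied_all, hap)
    tr <- translate_with_extension(nt, utr3)
    carried <- if (hap == 1L) applied_all$gt1 == 1L else applied_all$gt2 == 1L
    ed <- applied_all[carried, , drop = FALSE]
    # leave-one-out silence test on this haplotype
    silent <- logical(nrow(ed))
    if (nrow(ed) > 0L) {
      for (i in seq_len(nrow(ed))) {
        nt_wo <- apply_variants_to_cds(ref_cds, ed[-i, , drop = FALSE],
                                       hap)
        silent[i] <- identical(translate_with_extension(nt_wo, utr3)$aa, tr$aa)
      }
    }
    list(nt = nt, tr = tr, applied = alt_space_spans(ed[!silent, , drop = FALSE]))
  }
  h1 <- build_hap(1L); h2 <- build_hap(2L)

  min_codons <- th$min_cds_nt %/% 3L
  make_entry <- function(hap, h, label) {
    eff <- characterize_effects(
      ref_protein = ref_tr$aa, alt_protein = h$tr$aa, applied = h$applied,
      ref_stop = ref_tr$stop_codon_index, alt_stop = h$tr$stop_codon_index,
      alt_stop_observed = h$tr$stop_observed,
      ref_nt = ref_cds, alt_nt = h$nt)
    structure(list(
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      haplotype = hap, label = label,
      aa = h$tr$aa, nt = h$nt,
      applied = h$applied,
      flags = eff$flags, diff = eff$diff,
      is_novel_splice = is_novel_splice),
      class = "haplotype_protein")
  }

  identical_products <- identical(h1$tr$aa, h2$tr$aa)
  out <- list()
  if (identical_products) {
    if (nchar(h1$tr$aa) >= min_codons)
      out <- list(make_entry(NA_integer_, h1, "HOM"))
  } else {
    if (nchar(h1$tr$aa) >= min_codons)
      out <- c(out, list(make_entry(1L, h1, "A")))
    if (nchar(h2$tr$aa) >= min_codons)
      out <- c(out, list(make_entry(2L, h2, "B")))
  }
  out
}

#' @export
print.haplotype_protein <- function(x, ...) {
  cat(sprintf("<haplotype_protein %s [%s] %d aa, %d applied variant(s)>\n",
              x$transcript_id, x$label, nchar(x$aa), nrow(x$applied)))
  invisible(x)
}

## ---- haplotype label assignment --------------------------------------------

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Assign A/B haplotype labels across a gene's isoforms
#'
#' Labels are assigned per gene, transcripts in lexicographic id order. The
#' first transcript's haplotype 1 gets A; each later transcript is oriented
#' so that, at the leftmost heterozygous variant it shares with an
#' already-labeled transcript, the allele-to-letter assignment agrees.
#' Transcripts sharing no heterozygous variant default to haplotype 1 = A.
#' HOM products keep the label "HOM". Entry ids become
#' \code{<transcript_id>.<A|B>} for haplotype-specific products and the
#' bare transcript id for HOM products.
#'
#' @param entries List of \code{haplotype_protein} (any genes, any order).
#' @return The same entries with \code{label} and \code{entry_id} set,
#'   in a deterministic order.
#' @export
assign_haplotype_labels <- function(entries) {
  if (length(entries) == 0L) return(entries)
  genes <- vapply(entries, `[[`, character(1), "gene_id")
  out <- list()
  for (g in sort(unique(genes))) {
    idx <- which(genes == g)
    tids <- vapply(entries[idx], `[[`, character(1), "transcript_id")
    assignment <- list()  # variant key -> letter carrying the ALT allele
    for (tid in sort(unique(tids))) {
      sub <- entries[idx[tids == tid]]
      is_hom <- vapply(sub, function(e) identical(e$label, "HOM"), logical(1))
      het_entries <- sub[!is_hom]
      if (length(het_entries) > 0L) {
        # het variants of this transcript, pooled over both haplotype
        # entries (each entry lists only the variants it carries)
        app <- do.call(rbind, lapply(het_entries, `[[`, "applied"))
        app <- app[!duplicated(variant_key(app)), , drop = FALSE]
        hets <- app[app$gt1 != app$gt2, , drop = FALSE]
        hap1_letter <- "A"
        if (nrow(hets) > 0L) {
          keys <- variant_key(hets)
          known <- which(keys %in% names(assignment))
          if (length(known) > 0L) {
            j <- known[which.min(hets$pos[known])]
            alt_letter <- assignment[[keys[j]]]
            hap1_carries_alt <- hets$gt1[j] == 1L
            hap1_letter <- if (hap1_carries_alt) alt_letter else
              setdiff(c("A", "B"), alt_letter)
          }
          for (j in seq_along(keys)) {
            if (is.null(assignment[[keys[j]]])) {
              assignment[[keys[j]]] <-
                if (hets$gt1[j] == 1L) hap1_letter else
                  setdiff(c("A", "B"), hap1_letter)
            }
          }
        }
        for (k in seq_along(het_entries)) {
          e <- het_entries[[k]]
          e$label <- if (e$haplotype == 1L) hap1_letter else
            setdiff(c("A", "B"), hap1_letter)
          e$entry_id <- paste0(e$transcript_id, ".", e$label)
          het_entries[[k]] <- e
        }
      }
      hom_entries <- lapply(sub[is_hom], function(e) {
        e$entry_id <- e$transcript_id
        e
      })
      merged <- c(het_entries, hom_entries)
      ord <- order(vapply(merged, `[[`, character(1), "entry_id"))
      out <- c(out, merged[ord])
    }
  }
  out
}
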