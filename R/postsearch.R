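## Post-search annotation: PSM filtering, peptide classification and
## haplotype assignment, direct and phase-linked variant identification,
## greedy set-cover protein inference, gene calls, browser-track
## projection, and the per-protein annotation table.

## ---- PSM table --------------------------------------------------------------

#' Strip modification annotations from peptide strings
#'
#' Removes bracketed mass tags (\code{[...]}, \code{(...)}) and any
#' character that is not an upper-case residue letter, so modified search
#' engine output matches database sequences.
#'
#' @param x Character vector of peptide strings.
#' @export
strip_peptide_mods <- function(x) {
  x <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x)
  gsub("[^A-Z]", "", x)
}

#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with columns \code{peptide}, \code{q_value} and
#' \code{proteins} (';'-separated matched entry ids) -- the minimal
#' projection of a search-engine results table. Modifications are stripped
#' from peptide strings.
#'
#' @param path TSV path.
#' @return Data frame with \code{peptide}, \code{q_value}, \code{proteins}.
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "q_value", "proteins")
  if (!all(need %in% names(df)))
    stop("PSM table must have columns: ", paste(need, collapse = ", "))
  df$peptide <- strip_peptide_mods(df$peptide)
  df[, need]
}

#' Write a PSM table
#' @param psms PSM data frame.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter PSMs on q-value and match class
#'
#' Retains peptides with \code{q_value < th$psm_q_max} whose reported
#' matches include at least one entry that is neither a decoy nor a
#' contaminant. Peptides explained only by decoys or contaminants are
#' rejected.
#'
#' @param psms PSM data frame.
#' @param db Database data frame (for resolving matches).
#' @param th \code{\link{hp_thresholds}}.
#' @return Character vector of accepted (unique) peptide sequences.
#' @export
filter_psms <- function(psms, db, th = hp_thresholds()) {
  if (nrow(psms) == 0L) return(character(0))
  cls <- setNames(db$class, db$entry_id)
  keep <- logical(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    if (psms$q_value[i] >= th$psm_q_max) next
    ids <- strsplit(psms$proteins[i], ";", fixed = TRUE)[[1]]
    unknown <- setdiff(ids, names(cls))
    if (length(unknown))
      stop("PSM references unknown database entry: ", unknown[1])
    keep[i] <- any(!cls[ids] %in% c("decoy", "contaminant"))
  }
  unique(psms$peptide[keep])
}

## ---- peptide/entry index ----------------------------------------------------

#' Match peptides to database entries by substring search
#'
#' @param peptides Character vector of peptide sequences.
#' @param db Database data frame.
#' @param include Classes to search (default: all non-decoy).
#' @return Named list: peptide -> character vector of entry ids.
#' @export
match_peptides <- function(peptides, db,
                           include = c("reference", "variant",
                                       "novel_splice", "contaminant")) {
  sub <- db[db$class %in% include, , drop = FALSE]
  setNames(lapply(peptides, function(p) {
    sub$entry_id[grepl(p, sub$seq, fixed = TRUE)]
  }), peptides)
}

entry_members <- function(db) {
  setNames(strsplit(db$members, ";", fixed = TRUE), db$entry_id)
}

# Protein-coordinate spans affected by variation in one projected entry.
# For a frameshifted product the span of the frame-breaking edit extends to
# the end of the protein (every downstream residue differs from reference).
entry_variant_spans <- function(proj) {
  app <- proj$applied
  if (nrow(app) == 0L)
    return(data.frame(key = character(0), aa_start = integer(0),
                      aa_end = integer(0), het = logical(0),
                      type = character(0)))
  app <- app[order(app$cds_pos), , drop = FALSE]
  aa_end <- pmin(app$aa_end, max(nchar(proj$aa), 1L))
  if (isTRUE(proj$flags$frameshift)) {
    cum <- cumsum(app$delta)
    brk <- which(cum %% 3L != 0L)[1L]
    if (!is.na(brk)) aa_end[brk:length(aa_end)] <- nchar(proj$aa)
  }
  data.frame(key = variant_key(app),
             aa_start = pmin(app$aa_start, nchar(proj$aa)),
             aa_end = aa_end,
             het = app$gt1 != app$gt2,
             type = app$type,
             stringsAsFactors = FALSE)
}

# variant keys carried by each db target entry (union over member
# accessions' projections)
db_variant_keys <- function(db, projections) {
  mem <- entry_members(db)
  lapply(mem, function(ms) {
    unique(unlist(lapply(ms, function(m) {
      p <- projections[[m]]
      if (is.null(p) || nrow(p$applied) == 0L) character(0)
      else variant_key(p$applied)
    })))
  })
}

## ---- peptide classification & haplotype call --------------------------------

peptide_hits_variant <- function(peptide, proj) {
  spans <- entry_variant_spans(proj)
  if (nrow(spans) == 0L) return(FALSE)
  occ <- gregexpr(peptide, proj$aa, fixed = TRUE)[[1]]
  if (occ[1] < 0L) return(FALSE)
  for (s in occ) {
    e <- s + nchar(peptide) - 1L
    if (any(spans$aa_start <= e & spans$aa_end >= s)) return(TRUE)
  }
  FALSE
}

#' Classify an accepted peptide
#'
#' A peptide is \emph{reference} when it occurs as a substring of any
#' reference protein -- a reference-class database entry or, when
#' \code{reference_seqs} is supplied, any sequence of the original
#' reference proteome (variant products displace their reference entry
#' from the database, but a peptide they share with the reference is still
#' a reference peptide); otherwise it is classified by the entries that
#' explain it: \emph{variant} when its explanations are variant products
#' and it overlaps an applied variant position, \emph{splice} when its
#' explanations are novel-splice products without variant overlap, and
#' \emph{variant_splice} when its only explanations are variant-carrying
#' novel-splice products and it overlaps a variant.
#'
#' @param peptide Peptide string.
#' @param db Database data frame.
#' @param projections Named list accession -> \code{haplotype_protein}.
#' @param matches Optional precomputed entry ids matching the peptide.
#' @param reference_seqs Optional character vector of reference proteome
#'   sequences to consult in addition to reference-class entries.
#' @return One of "reference", "variant", "splice", "variant_splice".
#' @export
classify_peptide <- function(peptide, db, projections, matches = NULL,
                             reference_seqs = NULL) {
  if (is.null(matches))
    matches <- match_peptides(peptide, db)[[1]]
  cls <- setNames(db$class, db$entry_id)[matches]
  if (any(cls == "reference")) return("reference")
  if (!is.null(reference_seqs) &&
      any(grepl(peptide, reference_seqs, fixed = TRUE)))
    return("reference")
  target <- matches[cls %in% c("variant", "novel_splice")]
  if (length(target) == 0L) return("reference")  # contaminant-only
  mem <- entry_members(db[db$entry_id %in% target, , drop = FALSE])
  accs <- unlist(mem, use.names = FALSE)
  hits_var <- any(vapply(accs, function(a) {
    p <- projections[[a]]
    !is.null(p) && peptide_hits_variant(peptide, p)
  }, logical(1)))
  all_novel <- all(cls[cls %in% c("variant", "novel_splice")] == "novel_splice")
  if (all_novel) {
    if (hits_var) "variant_splice" else "splice"
  } else if (hits_var) {
    "variant"
  } else if (any(cls == "novel_splice")) {
    "splice"
  } else {
    "variant"
  }
}

#' Assign an accepted peptide to a haplotype
#'
#' Returns "A" or "B" only when the peptide matches exactly one database
#' entry and that entry is a single-haplotype product (one member accession
#' with an A/B suffix); in every other case the peptide is called
#' homozygous.
#'
#' @inheritParams classify_peptide
#' @return "A", "B" or "homozygous".
#' @export
assign_peptide_haplotype <- function(peptide, db, matches = NULL) {
  if (is.null(matches))
    matches <- match_peptides(peptide, db)[[1]]
  if (length(matches) != 1L) return("homozygous")
  mem <- strsplit(db$members[db$entry_id == matches], ";", fixed = TRUE)[[1]]
  if (length(mem) != 1L) return("homozygous")
  m <- regmatches(mem, regexpr("\\.(A|B)$", mem))
  if (length(m) == 0L) return("homozygous")
  sub("^\\.", "", m)
}

## ---- variant identification -------------------------------------------------

empty_variant_ids <- function() {
  data.frame(key = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             transcript_id = character(0), mode = character(0),
             zygosity = character(0), peptide = character(0),
             stringsAsFactors = FALSE)
}

#' Identify variants directly supported by unique peptides
#'
#' A variant is directly identified when an accepted peptide (i) occurs in
#' an entry carrying the variant, (ii) covers the variant's full altered
#' residue span -- for indels the whole affected span plus one flanking
#' residue on each side -- and (iii) occurs in no target entry lacking the
#' variant.
#'
#' @param accepted Accepted peptide set.
#' @param db Database data frame.
#' @param projections Named list accession -> \code{haplotype_protein}.
#' @return Data frame of direct identifications (one row per variant and
#'   transcript).
#' @export
identify_direct_variants <- function(accepted, db, projections) {
  if (length(accepted) == 0L) return(empty_variant_ids())
  targets <- db[db$class != "decoy", , drop = FALSE]
  keys_by_entry <- db_variant_keys(targets, projections)
  matches <- match_peptides(accepted, db)
  rows <- list()
  for (acc in names(projections)) {
    proj <- projections[[acc]]
    app <- proj$applied
    if (nrow(app) == 0L) next
    spans <- entry_variant_spans(proj)
    for (v in seq_len(nrow(app))) {
      key <- spans$key[v]
      is_indel <- spans$type[v] == "indel"
      need_s <- spans$aa_start[v] - if (is_indel) 1L else 0L
      need_e <- spans$aa_end[v] + if (is_indel) 1L else 0L
      need_s <- max(1L, need_s); need_e <- min(nchar(proj$aa), need_e)
      lacking <- names(keys_by_entry)[!vapply(keys_by_entry, function(k)
        key %in% k, logical(1))]
      for (pep in accepted) {
        occ <- gregexpr(pep, proj$aa, fixed = TRUE)[[1]]
        if (occ[1] < 0L) next
        covers <- any(occ <= need_s & occ + nchar(pep) - 1L >= need_e)
        if (!covers) next
        if (any(matches[[pep]] %in% lacking)) next   # not unique to variant
        rows[[length(rows) + 1L]] <- data.frame(
          key = key, chrom = app$chrom[v], pos = app$pos[v],
          ref = app$ref[v], alt = app$alt[v],
          transcript_id = proj$transcript_id, mode = "direct",
          zygosity = if (spans$het[v]) "heterozygous" else "homozygous",
          peptide = pep, stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(rows) == 0L) return(empty_variant_ids())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("key", "transcript_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer variants linked to direct identifications
#'
#' Heterozygous linkage: a phased heterozygous variant is inferred when it
#' shares a phase block (chrom + phase set) with a directly identified
#' heterozygous variant. Homozygous linkage: a homozygous variant is
#' inferred when it resides on a protein entry that contains a directly
#' identified variant. Variants already identified directly are excluded.
#'
#' @param direct Output of \code{\link{identify_direct_variants}}.
#' @param projections Named list accession -> \code{haplotype_protein}.
#' @param variants Processed variant data frame (for phase-block lookup).
#' @return Data frame of linked identifications.
#' @export
infer_linked_variants <- function(direct, projections, variants) {
  if (nrow(direct) == 0L) return(empty_variant_ids())
  direct_keys <- unique(direct$key)
  # phase blocks holding a direct het
  vkeys <- variant_key(variants)
  het <- is_het(variants)
  direct_het <- vkeys %in% direct$key[direct$zygosity == "heterozygous"]
  hot_blocks <- unique(paste(variants$chrom, variants$phase_set)[
    het & variants$phased & direct_het])
  # accessions carrying a direct variant (for homozygous linkage)
  acc_keys <- lapply(projections, function(p)
    if (nrow(p$applied)) variant_key(p$applied) else character(0))
  hot_accs <- names(acc_keys)[vapply(acc_keys, function(k)
    any(k %in% direct_keys), logical(1))]
  rows <- list()
  for (acc in names(projections)) {
    proj <- projections[[acc]]
    app <- proj$applied
    if (nrow(app) == 0L) next
    for (v in seq_len(nrow(app))) {
      key <- variant_key(app[v, ])
      if (key %in% direct_keys) next
      vhet <- app$gt1[v] != app$gt2[v]
      linked <- if (vhet) {
        paste(app$chrom[v], app$phase_set[v]) %in% hot_blocks
      } else {
        acc %in% hot_accs
      }
      if (!linked) next
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, chrom = app$chrom[v], pos = app$pos[v],
        ref = app$ref[v], alt = app$alt[v],
        transcript_id = proj$transcript_id, mode = "linked",
        zygosity = if (vhet) "heterozygous" else "homozygous",
        peptide = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_variant_ids())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("key", "transcript_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- protein inference ------------------------------------------------------

#' Greedy set-cover protein inference
#'
#' Entries with identical accepted-peptide sets are merged into candidate
#' groups; the greedy loop then repeatedly picks the group covering the
#' most still-uncovered peptides (ties broken by the lexicographically
#' smallest member id) until every accepted peptide is covered.
#'
#' @param accepted Accepted peptide set.
#' @param db Database data frame.
#' @param matches Optional precomputed peptide -> entry-id list.
#' @return List of groups, each a list with \code{members} (sorted entry
#'   ids) and \code{peptides} (the group's full accepted-peptide set).
#' @export
infer_protein_groups <- function(accepted, db, matches = NULL) {
  if (length(accepted) == 0L) return(list())
  if (is.null(matches)) matches <- match_peptides(accepted, db)
  entries <- sort(unique(unlist(matches)))
  pepset <- lapply(setNames(entries, entries), function(e) {
    sort(accepted[vapply(matches[accepted], function(m) e %in% m, logical(1))])
  })
  sig <- vapply(pepset, paste, character(1), collapse = "\r")
  cand <- lapply(split(entries, sig), function(mem) {
    list(members = sort(mem), peptides = pepset[[mem[1]]])
  })
  uncovered <- sort(unique(accepted))
  chosen <- list()
  while (length(uncovered) > 0L && length(cand) > 0L) {
    gain <- vapply(cand, function(g) sum(g$peptides %in% uncovered), integer(1))
    best <- which(gain == max(gain))
    if (max(gain) == 0L) break
    first_member <- vapply(cand[best], function(g) g$members[1], character(1))
    pick <- best[order(first_member)][1L]
    chosen[[length(chosen) + 1L]] <- cand[[pick]]
    uncovered <- setdiff(uncovered, cand[[pick]]$peptides)
    cand <- cand[-pick]
  }
  chosen
}

#' Map database entries to gene ids
#'
#' Member accessions are stripped of their A/B haplotype suffix and mapped
#' to genes through the transcript models; contaminants map to NA.
#'
#' @param db Database data frame.
#' @param txs Named list of \code{transcript_model} (reference + novel).
#' @return Named character vector entry_id -> gene_id.
#' @export
entry_gene_map <- function(db, txs) {
  tx_gene <- vapply(txs, `[[`, character(1), "gene_id")
  names(tx_gene) <- vapply(txs, `[[`, character(1), "transcript_id")
  mem <- entry_members(db)
  vapply(mem, function(ms) {
    tids <- unique(sub("\\.(A|B)$", "", ms))
    g <- unique(tx_gene[tids])
    g <- g[!is.na(g)]
    if (length(g) == 1L) g else NA_character_
  }, character(1))
}

#' Gene-level identification
#'
#' A gene is identified when at least one protein group exists whose
#' members are all products of that gene (haplotype suffixes ignored).
#'
#' @param groups Output of \code{\link{infer_protein_groups}}.
#' @param gene_map Named vector entry_id -> gene_id.
#' @return Sorted character vector of identified gene ids.
#' @export
identify_genes <- function(groups, gene_map) {
  genes <- character(0)
  for (g in groups) {
    gg <- unique(gene_map[g$members])
    if (length(gg) == 1L && !is.na(gg)) genes <- c(genes, gg)
  }
  sort(unique(genes))
}

## ---- browser tracks ---------------------------------------------------------

# Invert the applied-edit offsets: map a position on the edited (alt) CDS
# back to reference CDS coordinates. Positions inside an inserted span clamp
# to the edit's reference anchor span.
alt_to_ref_cds <- function(x, applied) {
  if (nrow(applied) == 0L) return(x)
  applied <- applied[order(applied$cds_pos), , drop = FALSE]
  cum <- 0L
  for (i in seq_len(nrow(applied))) {
    if (x < applied$alt_start[i]) return(x - cum)
    if (x <= applied$alt_end[i]) {
      off <- x - applied$alt_start[i]
      return(applied$cds_pos[i] + min(off, nchar(applied$ref_cds[i]) - 1L))
    }
    cum <- cum + applied$delta[i]
  }
  x - cum
}

#' Project a peptide onto genomic coordinates
#'
#' Converts the peptide's residue span in a haplotype protein to the edited
#' CDS nucleotide span, inverts the applied indel offsets to reference CDS
#' coordinates, and maps those through the transcript model; spans crossing
#' introns yield multiple blocks. Residues translated past the reference
#' CDS end (after a lost stop codon) are clamped to the CDS.
#'
#' @param peptide Peptide string.
#' @param accession Member accession identifying the haplotype protein.
#' @param projections Named list accession -> \code{haplotype_protein}.
#' @param txs Named list of \code{transcript_model}.
#' @return Data frame of genomic blocks (\code{start}, \code{end}) with
#'   attributes \code{strand} and \code{chrom}.
#' @export
project_peptide_to_genome <- function(peptide, accession, projections, txs) {
  proj <- projections[[accession]]
  if (is.null(proj)) stop("unknown accession: ", accession)
  tx <- txs[[proj$transcript_id]]
  if (is.null(tx)) stop("no transcript model for ", proj$transcript_id)
  at <- regexpr(peptide, proj$aa, fixed = TRUE)
  if (at < 0L) stop("peptide not found in ", accession)
  a <- as.integer(at); b <- a + nchar(peptide) - 1L
  alt_s <- 3L * a - 2L; alt_e <- 3L * b
  ref_s <- alt_to_ref_cds(alt_s, proj$applied)
  ref_e <- alt_to_ref_cds(alt_e, proj$applied)
  len <- cds_length(tx)
  ref_s <- max(1L, min(ref_s, len)); ref_e <- max(1L, min(ref_e, len))
  out <- cds_interval_to_genomic(tx, min(ref_s, ref_e), max(ref_s, ref_e))
  attr(out, "chrom") <- tx$chrom
  out
}

#' Write peptide projections as a BED12 browser track
#'
#' @param peptides Character vector of peptides.
#' @param accessions Parallel vector of member accessions.
#' @param projections,txs As in \code{\link{project_peptide_to_genome}}.
#' @param path Output path.
#' @export
write_peptide_bed <- function(peptides, accessions, projections, txs, path) {
  lines <- character(0)
  for (i in seq_along(peptides)) {
    blocks <- project_peptide_to_genome(peptides[i], accessions[i],
                                        projections, txs)
    chrom <- attr(blocks, "chrom"); strand <- attr(blocks, "strand")
    chrom_start <- min(blocks$start) - 1L          # BED is 0-based half-open
    chrom_end <- max(blocks$end)
    sizes <- blocks$end - blocks$start + 1L
    starts <- blocks$start - 1L - chrom_start
    lines <- c(lines, paste(
      chrom, chrom_start, chrom_end, peptides[i], 0L, strand,
      chrom_start, chrom_end, "0,0,0", nrow(blocks),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(starts, collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- annotation records -----------------------------------------------------

#' Build the per-protein annotation table
#'
#' One row per haplotype-resolved protein: novelty flag, counts of
#' non-silent variants broken down by SNV/indel and zygosity, the variant
#' list, the diff string against the reference protein, and the protein
#' effect flags.
#'
#' @param entries Labeled \code{haplotype_protein} list.
#' @return Data frame.
#' @export
build_annotation_records <- function(entries) {
  rows <- lapply(entries, function(e) {
    app <- e$applied
    het <- if (nrow(app)) app$gt1 != app$gt2 else logical(0)
    vl <- if (nrow(app))
      paste(sprintf("%s:%d:%s>%s[%s]", app$chrom, app$pos, app$ref, app$alt,
                    ifelse(het, "het", "hom")), collapse = ";") else ""
    data.frame(
      entry_id = e$entry_id %||% e$transcript_id,
      transcript_id = e$transcript_id, gene_id = e$gene_id,
      haplotype = e$label, novel_splice = e$is_novel_splice,
      n_snv_het = sum(app$type == "SNV" & het),
      n_snv_hom = sum(app$type == "SNV" & !het),
      n_indel_het = sum(app$type == "indel" & het),
      n_indel_hom = sum(app$type == "indel" & !het),
      variants = vl, diff = e$diff,
      has_indel = e$flags$has_indel, frameshift = e$flags$frameshift,
      resolved_frameshift = e$flags$resolved_frameshift,
      changed_stop = e$flags$changed_stop,
      changed_start = e$flags$changed_start,
      truncated = e$flags$truncated,
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(entry_id = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- orchestration ----------------------------------------------------------

#' Annotate search results end to end
#'
#' Runs PSM filtering, peptide classification and haplotype assignment,
#' protein-group and gene inference, and direct plus linked variant
#' identification.
#'
#' @param psms PSM data frame.
#' @param db Database data frame.
#' @param projections Named list accession -> \code{haplotype_protein}.
#' @param txs Named list of \code{transcript_model}.
#' @param variants Processed variant data frame.
#' @param th \code{\link{hp_thresholds}}.
#' @param reference_seqs Optional reference proteome sequences for peptide
#'   classification (see \code{\link{classify_peptide}}).
#' @return List: \code{accepted}, \code{peptide_annotations} (data frame),
#'   \code{groups}, \code{genes}, \code{variant_ids} (direct + linked).
#' @export
annotate_search_results <- function(psms, db, projections, txs, variants,
                                    th = hp_thresholds(),
                                    reference_seqs = NULL) {
  accepted <- filter_psms(psms, db, th)
  matches <- match_peptides(accepted, db)
  pep_ann <- data.frame(
    peptide = accepted,
    category = vapply(accepted, function(p)
      classify_peptide(p, db, projections, matches[[p]], reference_seqs),
      character(1)),
    haplotype_call = vapply(accepted, function(p)
      assign_peptide_haplotype(p, db, matches[[p]]), character(1)),
    stringsAsFactors = FALSE)
  rownames(pep_ann) <- NULL
  groups <- infer_protein_groups(accepted, db, matches)
  genes <- identify_genes(groups, entry_gene_map(db, txs))
  direct <- identify_direct_variants(accepted, db, projections)
  linked <- infer_linked_variants(direct, projections, variants)
  list(accepted = accepted, peptide_annotations = pep_ann,
       groups = groups, genes = genes,
       variant_ids = rbind(direct, linked))
}
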