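## Search-database assembly: reference + variant-haplotype + novel protein
## merging, sequence deduplication with accession tracking, contaminant
## concatenation, and reversed-sequence decoy generation with tryptic
## collision resolution.

DECOY_PREFIX <- "XXX_"

new_db <- function(entry_id = character(0), seq = character(0),
                   class = character(0), members = character(0)) {
  n <- length(entry_id)
  data.frame(entry_id = entry_id, seq = rep_len(seq, n),
             class = rep_len(class, n), members = rep_len(members, n),
             stringsAsFactors = FALSE)
}

#' Assemble the sample-specific proteome
#'
#' Starts from the reference protein set (accessions are transcript ids),
#' replaces every transcript that carries at least one non-silent applied
#' variant with its haplotype products, and appends the novel-splice
#' products. Haplotype products must have been labeled with
#' \code{\link{assign_haplotype_labels}} so their \code{entry_id} is set.
#'
#' @param reference Named character vector of reference protein sequences
#'   (names are transcript ids).
#' @param haplotype_proteins Labeled \code{haplotype_protein} list for
#'   reference transcripts.
#' @param novel_proteins Labeled \code{haplotype_protein} list for novel
#'   isoforms (may carry variants; class stays novel_splice).
#' @return Database data frame: \code{entry_id}, \code{seq}, \code{class},
#'   \code{members}.
#' @export
assemble_sample_proteome <- function(reference, haplotype_proteins = list(),
                                     novel_proteins = list()) {
  hp_tids <- vapply(haplotype_proteins, `[[`, character(1), "transcript_id")
  unknown <- setdiff(hp_tids, names(reference))
  if (length(unknown))
    stop("haplotype protein references unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  has_var <- vapply(haplotype_proteins, function(e) nrow(e$applied) > 0L,
                    logical(1))
  replace_tids <- unique(hp_tids[has_var])
  keep_ref <- setdiff(names(reference), replace_tids)
  db <- new_db(entry_id = keep_ref, seq = unname(reference[keep_ref]),
               class = "reference", members = keep_ref)
  add_entries <- function(db, entries, class) {
    for (e in entries) {
      if (is.null(e$entry_id))
        stop("unlabeled haplotype protein for ", e$transcript_id,
             "; run assign_haplotype_labels() first")
      db <- rbind(db, new_db(e$entry_id, e$aa, class, e$entry_id))
    }
    db
  }
  db <- add_entries(db, haplotype_proteins[hp_tids %in% replace_tids], "variant")
  db <- add_entries(db, novel_proteins, "novel_splice")
  rownames(db) <- NULL
  db
}

#' Deduplicate database sequences, tracking member accessions
#'
#' Collapses entries with identical amino-acid sequence into one entry whose
#' id is the lexicographically smallest member accession and whose
#' \code{members} field lists all contributors (sorted, ';'-separated).
#' When members differ in class the merged entry keeps the highest-priority
#' class (reference > variant > novel_splice > contaminant).
#'
#' @param db Database data frame.
#' @return Deduplicated database data frame.
#' @export
deduplicate_sequences <- function(db) {
  if (nrow(db) == 0L) return(db)
  prio <- c(reference = 1L, variant = 2L, novel_splice = 3L,
            contaminant = 4L, decoy = 5L)
  sp <- split(seq_len(nrow(db)), db$seq)
  rows <- lapply(sp, function(i) {
    members <- sort(unique(unlist(strsplit(db$members[i], ";", fixed = TRUE))))
    new_db(entry_id = min(db$entry_id[i]),
           seq = db$seq[i[1]],
           class = names(prio)[min(prio[db$class[i]])],
           members = paste(members, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$entry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tryptic in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P, and emits every
#' fragment carrying 0 to \code{max_missed} internal (missed) cleavage
#' sites, filtered to the requested length window. Returns the peptide set
#' (unique strings).
#'
#' @param aa_sequence Amino-acid string.
#' @param max_missed Maximum missed cleavages.
#' @param min_len,max_len Peptide length window (residues).
#' @return Character vector of unique peptides.
#' @export
tryptic_digest <- function(aa_sequence, max_missed = 2L, min_len = 5L,
                           max_len = 100L) {
  n <- nchar(aa_sequence)
  if (n == 0L) return(character(0))
  res <- strsplit(aa_sequence, "")[[1]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nf <- length(starts)
  peps <- character(0)
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + max_missed)
    for (j in i:jmax) {
      w <- ends[j] - starts[i] + 1L
      if (w > max_len) break
      if (w >= min_len)
        peps <- c(peps, substr(aa_sequence, starts[i], ends[j]))
    }
  }
  unique(peps)
}

digest_with <- function(seqs, th) {
  unique(unlist(lapply(seqs, tryptic_digest,
                       max_missed = th$max_missed_cleavages,
                       min_len = th$min_peptide_len,
                       max_len = th$max_peptide_len)))
}

reverse_string <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Generate reversed-sequence decoys
#'
#' One decoy per target entry: the whole sequence reversed, with the id
#' prefixed \code{XXX_}. Decoy tryptic peptides that collide with the
#' target peptide universe (same digestion parameters) are resolved by
#' randomly shuffling the colliding peptide in place and re-checking, for at
#' most \code{th$max_decoy_iterations} rounds; entries still colliding after
#' that are emitted anyway and counted in the \code{n_residual_collisions}
#' attribute (with a warning). Deterministic given \code{seed}.
#'
#' @param targets Database data frame containing no decoy entries.
#' @param th \code{\link{hp_thresholds}}.
#' @param seed Integer seed.
#' @return Decoy database data frame (one row per target), with attribute
#'   \code{n_residual_collisions}.
#' @export
generate_decoys <- function(targets, th = hp_thresholds(), seed = 1L) {
  stopifnot(!any(targets$class == "decoy"))
  set.seed(seed)
  universe <- digest_with(targets$seq, th)
  n_residual <- 0L
  decoy_seqs <- character(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    dseq <- reverse_string(targets$seq[i])
    for (iter in seq_len(th$max_decoy_iterations)) {
      coll <- intersect(tryptic_digest(dseq, th$max_missed_cleavages,
                                       th$min_peptide_len, th$max_peptide_len),
                        universe)
      if (length(coll) == 0L) break
      for (pep in coll) {
        at <- regexpr(pep, dseq, fixed = TRUE)
        if (at < 0L) next
        shuffled <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
        dseq <- paste0(substr(dseq, 1L, at - 1L), shuffled,
                       substr(dseq, at + nchar(pep), nchar(dseq)))
      }
    }
    resid <- length(intersect(
      tryptic_digest(dseq, th$max_missed_cleavages,
                     th$min_peptide_len, th$max_peptide_len), universe))
    n_residual <- n_residual + resid
    decoy_seqs[i] <- dseq
  }
  if (n_residual > 0L)
    warning(n_residual, " decoy tryptic peptide(s) still collide with the ",
            "target peptide universe after ", th$max_decoy_iterations,
            " shuffling rounds")
  out <- new_db(entry_id = paste0(DECOY_PREFIX, targets$entry_id),
                seq = decoy_seqs, class = "decoy",
                members = paste0(DECOY_PREFIX, targets$entry_id))
  attr(out, "n_residual_collisions") <- n_residual
  out
}

#' Build the full search database
#'
#' Assembles the sample proteome, deduplicates it, concatenates the
#' contaminant proteins (so that contaminants also receive decoys), and
#' generates reversed decoys for the combined target set.
#'
#' @inheritParams assemble_sample_proteome
#' @param contaminants Named character vector of contaminant protein
#'   sequences (e.g. a cRAP-style FASTA read with
#'   \code{\link{read_protein_fasta}}).
#' @param th \code{\link{hp_thresholds}}.
#' @param seed Integer seed for decoy generation.
#' @return Database data frame including decoys.
#' @export
build_search_database <- function(reference, haplotype_proteins = list(),
                                  novel_proteins = list(),
                                  contaminants = character(0),
                                  th = hp_thresholds(), seed = 1L) {
  db <- assemble_sample_proteome(reference, haplotype_proteins, novel_proteins)
  db <- deduplicate_sequences(db)
  if (length(contaminants) > 0L) {
    db <- rbind(db, new_db(entry_id = names(contaminants),
                           seq = unname(contaminants),
                           class = "contaminant",
                           members = names(contaminants)))
  }
  decoys <- generate_decoys(db, th, seed)
  out <- rbind(db, decoys)
  rownames(out) <- NULL
  attr(out, "n_residual_collisions") <- attr(decoys, "n_residual_collisions")
  out
}

#' Read a protein FASTA as a named character vector
#' @param path FASTA path.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write the database FASTA and its sidecar table
#'
#' The sidecar TSV maps \code{entry_id} to its member accessions and entry
#' class, which downstream annotation needs to resolve deduplicated ids.
#'
#' @param db Database data frame.
#' @param fasta_path,sidecar_path Output paths.
#' @export
write_database <- function(db, fasta_path, sidecar_path) {
  ss <- Biostrings::AAStringSet(setNames(db$seq, db$entry_id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  utils::write.table(db[, c("entry_id", "class", "members")], sidecar_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a database back from FASTA + sidecar
#' @param fasta_path,sidecar_path Paths written by \code{\link{write_database}}.
#' @return Database data frame.
#' @export
read_database <- function(fasta_path, sidecar_path) {
  seqs <- read_protein_fasta(fasta_path)
  side <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!setequal(names(seqs), side$entry_id))
    stop("FASTA and sidecar entry ids disagree")
  side$seq <- unname(seqs[side$entry_id])
  side[, c("entry_id", "seq", "class", "members")]
}
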