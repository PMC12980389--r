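#' @importFrom Biostrings readDNAStringSet readAAStringSet writeXStringSet
#'   DNAString DNAStringSet AAStringSet reverseComplement translate subseq
#' @importFrom IRanges IRanges reduce start end
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

## ---- genome ----------------------------------------------------------------

#' Read a genome FASTA
#'
#' Loads a genome as a named character vector of chromosome sequences,
#' case-normalized to upper case. Only A, C, G, T and N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in FASTA: ", path)
  seqs <- toupper(as.character(ss))
  # first whitespace-delimited token of the header is the chromosome name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("genome sequence for ", names(seqs)[bad][1],
         " contains characters outside A/C/G/T/N")
  }
  seqs
}

#' Write a genome FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

## ---- transcript models ------------------------------------------------------

#' Construct a transcript model
#'
#' One coding isoform: its exon and CDS intervals on a chromosome strand.
#' Intervals are 1-based inclusive genomic coordinates, stored sorted by
#' start and pairwise non-overlapping; every CDS interval must lie inside an
#' exon. The CDS includes the stop codon.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons,cds Data frames with integer columns \code{start}, \code{end}.
#' @return Object of class \code{transcript_model}.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), is.data.frame(cds),
            all(c("start", "end") %in% names(exons)),
            all(c("start", "end") %in% names(cds)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  exons[] <- lapply(exons, as.integer)
  cds[] <- lapply(cds, as.integer)
  rownames(exons) <- rownames(cds) <- NULL
  check_disjoint <- function(iv, what) {
    if (nrow(iv) == 0L) return(invisible())
    if (any(iv$end < iv$start)) stop(what, " interval with end < start")
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)]))
      stop(what, " intervals overlap in ", transcript_id)
  }
  check_disjoint(exons, "exon")
  check_disjoint(cds, "CDS")
  if (nrow(cds) > 0L) {
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
    }, logical(1))
    if (!all(contained)) stop("CDS interval outside exons in ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' Total CDS length of a transcript model (nt)
#' @param tx A \code{transcript_model}.
#' @export
cds_length <- function(tx) {
  if (nrow(tx$cds) == 0L) return(0L)
  sum(tx$cds$end - tx$cds$start + 1L)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s%s, %d exon(s), CDS %d nt>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Read coding transcript models from a GTF file
#'
#' Parses exon, CDS and stop_codon features. stop_codon intervals are merged
#' into the CDS so the model's CDS ends at (and includes) the terminator.
#' Transcripts without any CDS feature are skipped.
#'
#' @param path Path to a GTF file.
#' @return Named list of \code{transcript_model} objects (by transcript id).
#' @export
read_transcripts <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(list())
  if (any(is.na(md$transcript_id)))
    stop("GTF feature without transcript_id attribute")
  df <- data.frame(
    type = as.character(md$type),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    stringsAsFactors = FALSE)
  out <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    cds_rows <- sub[sub$type %in% c("CDS", "stop_codon"), , drop = FALSE]
    if (!any(sub$type == "CDS")) next
    ex_rows <- sub[sub$type == "exon", , drop = FALSE]
    merge_iv <- function(rows) {
      if (nrow(rows) == 0L) return(data.frame(start = integer(), end = integer()))
      r <- IRanges::reduce(IRanges::IRanges(rows$start, rows$end))
      data.frame(start = IRanges::start(r), end = IRanges::end(r))
    }
    cds <- merge_iv(cds_rows)
    exons <- if (nrow(ex_rows)) merge_iv(ex_rows) else cds
    out[[tid]] <- transcript_model(
      transcript_id = tid, gene_id = sub$gene_id[1],
      chrom = sub$chrom[1], strand = sub$strand[1],
      exons = exons, cds = cds)
  }
  out
}

#' Write transcript models to a GTF file
#' @param txs List of \code{transcript_model}.
#' @param path Output path.
#' @export
write_transcripts_gtf <- function(txs, path) {
  lines <- character(0)
  for (tx in txs) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        tx$gene_id, tx$transcript_id)
    fmt <- function(type, iv) {
      if (nrow(iv) == 0L) return(character(0))
      sprintf("%s\thaploproteo\t%s\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom, type, iv$start, iv$end, tx$strand, attr_str)
    }
    lines <- c(lines, fmt("exon", tx$exons), fmt("CDS", tx$cds))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- variants ---------------------------------------------------------------

#' Construct a variant table
#'
#' Variants are kept as a data frame with one row per biallelic site:
#' \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt},
#' \code{gt1}/\code{gt2} (allele index on haplotype 1/2; 0 = ref, 1 = alt),
#' \code{phased}, \code{phase_set} (NA when unphased), \code{gq},
#' \code{multiallelic} and \code{type} ("SNV" or "indel").
#'
#' @param chrom,pos,ref,alt,gt1,gt2 Vectors, recycled to common length.
#' @param phased Logical; whether the genotype separator was "|".
#' @param phase_set Phase-set (PS) identifier, NA when absent.
#' @param gq Genotype quality.
#' @param multiallelic Flag set by the reader for records with >1 ALT.
#' @return A \code{data.frame} of variants.
#' @export
hp_variants <- function(chrom, pos, ref, alt, gt1, gt2,
                        phased = FALSE, phase_set = NA_character_,
                        gq = NA_real_, multiallelic = FALSE) {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.integer(pos),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   gt1 = rep_len(as.integer(gt1), n),
                   gt2 = rep_len(as.integer(gt2), n),
                   phased = rep_len(as.logical(phased), n),
                   phase_set = rep_len(as.character(phase_set), n),
                   gq = rep_len(as.numeric(gq), n),
                   multiallelic = rep_len(as.logical(multiallelic), n),
                   stringsAsFactors = FALSE)
  df$type <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "indel")
  df
}

empty_variants <- function() {
  hp_variants(character(0), integer(0), character(0), character(0),
              integer(0), integer(0))
}

#' Heterozygosity of variant rows
#' @param variants Variant data frame.
#' @return Logical vector.
#' @export
is_het <- function(variants) variants$gt1 != variants$gt2

#' Read phased variants from a single-sample VCF
#'
#' Requires GT and (for filtering) GQ in FORMAT; PS is read for phased
#' heterozygous records. Multi-allelic records are retained but flagged
#' \code{multiallelic} for downstream removal; multi-sample VCFs are
#' rejected because the workflow is sample-specific.
#'
#' @param path Path to a VCF file.
#' @return Variant data frame (see \code{\link{hp_variants}}).
#' @export
read_phased_variants <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(empty_variants())
  if (ncol(v@gt) > 2L) stop("multi-sample VCF not supported (", path, ")")
  if (ncol(v@gt) < 2L) stop("VCF has no sample column: ", path)
  fix <- v@fix
  fmt <- strsplit(v@gt[, 1L], ":", fixed = TRUE)
  smp <- strsplit(v@gt[, 2L], ":", fixed = TRUE)
  get_field <- function(i, key) {
    j <- match(key, fmt[[i]])
    if (is.na(j) || j > length(smp[[i]])) NA_character_ else smp[[i]][j]
  }
  n <- nrow(fix)
  gt <- vapply(seq_len(n), get_field, character(1), key = "GT")
  if (anyNA(gt) || any(gt %in% c(".", "./.", ".|.")))
    stop("VCF record without GT genotype")
  gq <- suppressWarnings(as.numeric(
    vapply(seq_len(n), get_field, character(1), key = "GQ")))
  ps <- vapply(seq_len(n), get_field, character(1), key = "PS")
  ps[ps %in% "."] <- NA_character_
  phased <- grepl("|", gt, fixed = TRUE)
  alleles <- strsplit(gt, "[|/]")
  if (any(lengths(alleles) != 2L)) stop("non-diploid GT in VCF")
  gt1 <- as.integer(vapply(alleles, `[`, character(1), 1L))
  gt2 <- as.integer(vapply(alleles, `[`, character(1), 2L))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  hp_variants(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
              ref = fix[, "REF"], alt = fix[, "ALT"],
              gt1 = gt1, gt2 = gt2,
              phased = phased & (gt1 != gt2),
              phase_set = ifelse(phased, ps, NA_character_),
              gq = gq, multiallelic = multi)
}

#' Write variants to a single-sample VCF
#' @param variants Variant data frame.
#' @param path Output path.
#' @param sample Sample name for the header.
#' @export
write_phased_variants <- function(variants, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=PS,Number=1,Type=String,Description="Phase set">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  body <- character(nrow(v))
  if (nrow(v)) {
    sep <- ifelse(v$phased, "|", "/")
    gt <- paste0(v$gt1, sep, v$gt2)
    gq <- ifelse(is.na(v$gq), ".", format(v$gq, trim = TRUE, scientific = FALSE))
    ps <- ifelse(is.na(v$phase_set), ".", v$phase_set)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:GQ:PS\t%s:%s:%s",
                    v$chrom, v$pos, v$ref, v$alt, gt, gq, ps)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- coordinate algebra ----------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Spliced CDS sequence of a transcript
#'
#' Concatenates the CDS interval sequences in translation order: ascending
#' genomic order for plus-strand transcripts; for minus-strand transcripts
#' the highest-coordinate interval comes first and every piece is
#' reverse-complemented.
#'
#' @param genome Named character vector from \code{\link{read_genome}}.
#' @param tx A \code{transcript_model}.
#' @return Nucleotide string of length \code{cds_length(tx)}.
#' @export
spliced_cds_sequence <- function(genome, tx) {
  spliced_interval_sequence(genome, tx, tx$cds)
}

spliced_interval_sequence <- function(genome, tx, iv) {
  chrom <- genome[[tx$chrom]]
  if (is.null(chrom)) stop("chromosome not in genome: ", tx$chrom)
  if (nrow(iv) == 0L) return("")
  if (any(iv$start < 1L) || any(iv$end > nchar(chrom)))
    stop("interval out of chromosome bounds in ", tx$transcript_id)
  pieces <- substring(chrom, iv$start, iv$end)
  fwd <- paste(pieces, collapse = "")
  if (tx$strand == "+") fwd else revcomp(fwd)
}

#' Map a genomic position into CDS coordinates
#'
#' @param tx A \code{transcript_model}.
#' @param gpos 1-based genomic position.
#' @return 1-based CDS coordinate, or \code{NA_integer_} if \code{gpos}
#'   falls outside the CDS.
#' @export
genomic_to_cds_coord <- function(tx, gpos) {
  iv <- tx$cds
  if (nrow(iv) == 0L) return(NA_integer_)
  hit <- which(iv$start <= gpos & iv$end >= gpos)
  if (length(hit) == 0L) return(NA_integer_)
  widths <- iv$end - iv$start + 1L
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    as.integer(before + (gpos - iv$start[hit] + 1L))
  } else {
    n <- nrow(iv)
    after <- if (hit < n) sum(widths[seq(hit + 1L, n)]) else 0L
    as.integer(after + (iv$end[hit] - gpos + 1L))
  }
}

#' Map a CDS coordinate range to genomic intervals
#'
#' Returns the minimal list of maximal genomic intervals whose union maps
#' exactly onto \code{[cds_start, cds_end]}; a range spanning an intron
#' yields two or more intervals. Intervals are returned sorted by genomic
#' start.
#'
#' @param tx A \code{transcript_model}.
#' @param cds_start,cds_end 1-based CDS coordinates, start <= end.
#' @return Data frame with columns \code{start}, \code{end} and attribute
#'   \code{strand}.
#' @export
cds_interval_to_genomic <- function(tx, cds_start, cds_end) {
  len <- cds_length(tx)
  if (cds_start < 1L || cds_end > len || cds_start > cds_end)
    stop("CDS range [", cds_start, ",", cds_end, "] out of bounds (len ", len, ")")
  iv <- tx$cds
  ord <- if (tx$strand == "+") seq_len(nrow(iv)) else rev(seq_len(nrow(iv)))
  out <- list(); cum <- 0L
  for (i in ord) {
    w <- iv$end[i] - iv$start[i] + 1L
    lo <- cum + 1L; hi <- cum + w          # CDS span of this interval
    s <- max(cds_start, lo); e <- min(cds_end, hi)
    if (s <= e) {
      if (tx$strand == "+") {
        out[[length(out) + 1L]] <- c(iv$start[i] + (s - lo), iv$start[i] + (e - lo))
      } else {
        out[[length(out) + 1L]] <- c(iv$end[i] - (e - lo), iv$end[i] - (s - lo))
      }
    }
    cum <- cum + w
  }
  m <- do.call(rbind, out)
  res <- data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "strand") <- tx$strand
  res
}

# Spliced exonic sequence downstream of the CDS in transcript orientation
# (the 3' UTR); used to extend translation past a lost stop codon.
downstream_exonic_sequence <- function(genome, tx) {
  if (nrow(tx$cds) == 0L || nrow(tx$exons) == 0L) return("")
  if (tx$strand == "+") {
    cds_end <- max(tx$cds$end)
    keep <- tx$exons[tx$exons$end > cds_end, , drop = FALSE]
    if (nrow(keep) == 0L) return("")
    keep$start <- pmax(keep$start, cds_end + 1L)
  } else {
    cds_end <- min(tx$cds$start)
    keep <- tx$exons[tx$exons$start < cds_end, , drop = FALSE]
    if (nrow(keep) == 0L) return("")
    keep$end <- pmin(keep$end, cds_end - 1L)
  }
  spliced_interval_sequence(genome, tx, keep)
}

# TRUE where the variant's reference span [pos, pos+nchar(ref)-1] intersects
# any CDS interval of tx (same chromosome).
variant_overlaps_cds <- function(variants, tx) {
  if (nrow(variants) == 0L) return(logical(0))
  vs <- variants$pos
  ve <- variants$pos + nchar(variants$ref) - 1L
  same <- variants$chrom == tx$chrom
  if (nrow(tx$cds) == 0L) return(rep(FALSE, nrow(variants)))
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(tx$cds))) {
    hit <- hit | (vs <= tx$cds$end[i] & ve >= tx$cds$start[i])
  }
  hit & same
}
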