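# Shared fixtures and independent oracles used across the suite.

# Toy single-exon plus-strand transcript on a 25 nt chromosome:
# CDS 4-21 codes for MKPGF followed by the terminator.
toy_genome <- function() {
  c(chr1 = "GGGATGAAACCCGGGTTTTAGGGGG")
}

toy_tx <- function() {
  transcript_model("T1", "G1", "chr1", "+",
                   exons = data.frame(start = 1L, end = 25L),
                   cds = data.frame(start = 4L, end = 21L))
}

# V1 het (alt on hap 1), V2 hom, V3 het (alt on hap 2), one phase block.
toy_variants <- function() {
  hp_variants(
    chrom = "chr1",
    pos = c(7L, 13L, 16L),
    ref = c("A", "G", "T"),
    alt = c("G", "T", "C"),
    gt1 = c(1L, 1L, 0L),
    gt2 = c(0L, 1L, 1L),
    phased = c(TRUE, FALSE, TRUE),
    phase_set = c("4", NA, "4"),
    gq = 40)
}

# thresholds scaled to toy proteins (a handful of residues long)
toy_th <- function() hp_thresholds(min_cds_nt = 9L, min_peptide_len = 1L)

# Brute-force tryptic digestion: enumerate every substring and keep those
# whose ends are valid cleavage boundaries with at most max_missed internal
# cleavage sites.
brute_force_digest <- function(seq, max_missed, min_len, max_len) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  res <- strsplit(seq, "")[[1]]
  is_cut <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1L] != "P"
  peps <- character(0)
  for (s in 1:n) for (e in s:n) {
    w <- e - s + 1L
    if (w < min_len || w > max_len) next
    if (!(s == 1L || is_cut(s - 1L))) next
    if (!(e == n || is_cut(e))) next
    internal <- if (e > s) sum(vapply(s:(e - 1L), is_cut, logical(1))) else 0L
    if (internal <= max_missed)
      peps <- c(peps, substr(seq, s, e))
  }
  unique(peps)
}

random_protein <- function(n, alphabet = c(LETTERS[1:20])) {
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Walk every CDS base through genomic_to_cds_coord to rebuild the spliced
# CDS one base at a time (brute-force oracle for spliced_cds_sequence).
walk_cds_sequence <- function(genome, tx) {
  n <- cds_length(tx)
  chrom <- genome[[tx$chrom]]
  out <- character(n)
  gpos_all <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
    tx$cds$start[i]:tx$cds$end[i]))
  for (g in gpos_all) {
    cpos <- genomic_to_cds_coord(tx, g)
    base <- substr(chrom, g, g)
    if (tx$strand == "-")
      base <- chartr("ACGT", "TGCA", base)
    out[cpos] <- base
  }
  paste(out, collapse = "")
}
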