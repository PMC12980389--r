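# haploproteo

Haplotype-resolved, sample-specific proteogenomics in R: build a protein
search database that carries both haplotypes of every variant coding
sequence, then annotate the search results to identify genetic variants at
the peptide level — directly, and by phase linkage.

Standard proteomic searches against a reference proteome cannot see
sample-specific variation: a peptide carrying an amino-acid variant simply
fails to match. Given a genome (FASTA), a coding annotation (GTF) and
phased variants (single-sample VCF with `GT`/`GQ`/`PS`), `haploproteo`

* filters variants (GQ ≥ 5, biallelic only) and post-processes phase
  blocks so that every coding sequence (CDS) is covered by a single
  contiguous phase block — heterozygous variants in incompletely phased
  CDSs are removed, and isolated heterozygous variants get an arbitrary
  deterministic phase, since no other variant constrains them;
* applies the variants to each transcript CDS per haplotype (SNVs and
  indels, including frameshifts and lost stop codons with translation
  extension into the 3' UTR), translates, flags protein effects (indel,
  frameshift, resolved frameshift, changed stop/start, truncation) and
  writes a diff string such as `K2E;G4W` against the reference protein;
* assembles the search database: reference proteins are replaced by their
  haplotype products (`<tx>.A` / `<tx>.B`, or a single unsuffixed entry
  when both haplotypes agree), novel-splice products are appended,
  sequences are deduplicated with accession tracking, contaminants are
  concatenated, and reversed decoys (`XXX_` prefix) are generated with
  tryptic-collision shuffling (trypsin, ≤2 missed cleavages, peptide
  length 5–100, ≤100 shuffle rounds);
* consumes a peptide–spectrum-match table (peptide, q-value, matched
  proteins), accepts peptides at q < 0.01 with a non-decoy,
  non-contaminant match, classifies them (reference / variant / splice /
  variant_splice), assigns haplotypes, infers protein groups by greedy set
  cover, calls genes whose groups are gene-pure, and identifies variants:
  **direct** when a unique peptide spans the altered residues, **linked**
  when a variant shares a phase block (heterozygous) or a protein
  (homozygous) with a directly identified variant;
* evaluates phasing quality: switch error rate over consecutive
  heterozygous pairs within phase blocks, phased-variant counts, and
  fully-phased fractions at CDS, transcript and gene level, stratified by
  coverage and SNV/indel class;
* simulates all of its inputs (genome, GTF, VCF, PSM tables) with seeded
  generators that also emit independently edited ground-truth haplotype
  sequences, so the whole workflow is testable without external data.

## Worked example

One 25 nt chromosome; transcript `T1` has its CDS at positions 4–21 and
codes for `MKPGF`. Three variants: a heterozygous A→G at position 7 (CDS
codon 2, haplotype 1), a homozygous G→T at 13 (codon 4), and a
heterozygous T→C at 16 (codon 5, haplotype 2); the heterozygous variants
share phase set 4.

```r
library(haploproteo)

genome <- c(chr1 = "GGGATGAAACCCGGGTTTTAGGGGG")
tx <- transcript_model("T1", "G1", "chr1", "+",
                       exons = data.frame(start = 1, end = 25),
                       cds   = data.frame(start = 4, end = 21))
v <- hp_variants("chr1", pos = c(7, 13, 16),
                 ref = c("A", "G", "T"), alt = c("G", "T", "C"),
                 gt1 = c(1, 1, 0), gt2 = c(0, 1, 1),
                 phased = c(TRUE, FALSE, TRUE),
                 phase_set = c("4", NA, "4"), gq = 40)

prots <- project_transcript_haplotypes(genome, tx, v,
                                       hp_thresholds(min_cds_nt = 9))
ann <- build_annotation_records(assign_haplotype_labels(prots))
ann[, c("entry_id", "haplotype", "n_snv_het", "n_snv_hom", "diff")]
#>   entry_id haplotype n_snv_het n_snv_hom    diff
#> 1     T1.A         A         1         1 K2E;G4W
#> 2     T1.B         B         1         1 G4W;F5L
```

Haplotype A is `MEPWF`, haplotype B is `MKPWL`: each product carries its
heterozygous variant plus the shared homozygous one, and the diff strings
give the residue changes against the reference `MKPGF`. A peptide
covering residue 2 only in `T1.A` identifies the A→G variant directly;
the T→C variant, phased into the same block, is then identified by
linkage even without a spanning peptide.

The same API scales to whole simulated studies — see
`vignettes/haplotype-resolved-proteogenomics.Rmd` for the model and the
generator design, and `inst/scripts/haploproteo` for the command-line
wrapper (`simulate`, `build-db`, `annotate`, `phase-eval`, `run`).

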