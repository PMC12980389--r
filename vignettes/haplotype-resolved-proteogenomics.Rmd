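---
title: "Haplotype-resolved proteogenomics: models and design choices"
author: "haploproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved proteogenomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploproteo)
```

# The problem

A diploid sample expresses two versions of every protein-coding locus.
Mass-spectrometry searches against a reference proteome are blind to this:
any peptide whose sequence is altered by a coding variant has no database
entry to match. `haploproteo` constructs a *sample-specific,
haplotype-resolved* protein database — each transcript contributes the
protein of haplotype A and of haplotype B, built from phased variants —
and then interprets search results at the variant level. The key payoff
of phasing is *linked identification*: once one heterozygous variant on a
haplotype is confirmed by a spanning peptide, every other variant phased
into the same block is attributable to that haplotype even without
peptide coverage of its own site.

# Variant post-processing

Input variants come from a single-sample VCF with `GT`, `GQ` and `PS`
fields. Two filters and one repair step run in a fixed order
(`process_variants()`):

1. **Quality/allele count** (`filter_variants`): keep biallelic records
   with `GQ >= min_gq`. Multi-allelic records are flagged by the reader
   and removed here; projection is defined only for one alternative
   allele per site.
2. **CDS phase completeness** (`enforce_cds_phase_completeness`): for
   each transcript CDS, if two or more heterozygous variants overlap it
   and they are not all phased into one phase set, *all* heterozygous
   variants in that CDS are removed. Removal (rather than demotion to
   unphased) is deliberate: an unphased heterozygous variant cannot be
   placed on either haplotype and would poison projection. A variant
   overlapping several CDSs is removed if it fails in any of them —
   conservative, because keeping it would break the guarantee for the
   failing CDS.
3. **Singleton phase assignment** (`assign_singleton_phase_blocks`): an
   unphased heterozygous variant that is the *only* heterozygous variant
   in every CDS it touches gets `phased = TRUE` with the alternative
   allele on haplotype 1 and a fresh phase set equal to its genomic
   position. The choice of haplotype is arbitrary by construction —
   there is no second variant with which it could be consistently or
   inconsistently phased — and the positional phase-set id can never
   collide with a caller-assigned one within a chromosome.

"Stretching across the full CDS" is interpreted as *all heterozygous
variants of the CDS belong to one phase block*. A stricter reading — the
block must physically span the CDS end points — would discard almost
every variant, because a block's extent is defined only by its member
variants. After the chain, every CDS is a single contiguous phase block;
the chain is idempotent, and homozygous variants pass through untouched.

# Haplotype projection

For each transcript the CDS sequence (stop codon included) is extracted
strand-aware, variants are transformed into CDS space (alleles
reverse-complemented on minus-strand transcripts), and each haplotype's
edits are applied in descending CDS order so earlier coordinates stay
valid. Non-overlapping edits are a precondition; overlapping edits and
reference-allele mismatches are hard errors, since they indicate
inconsistent inputs rather than biology.

Translation uses the standard code and stops at the first terminator.
Numerical/degenerate-input choices:

* Codons containing `N` translate to `X` rather than erroring; degenerate
  genome regions must not crash projection.
* A variant that destroys the stop codon (or a frameshift that runs past
  it) extends translation into the spliced 3' UTR of the transcript until
  the next in-frame terminator; if none exists, the product is flagged
  `truncated`.
* An indel whose reference span crosses an intron boundary has no defined
  projection and is skipped with a warning.
* A changed start codon is flagged (`changed_start`) but the protein is
  still emitted from the annotated start; start-codon re-annotation is
  out of scope and such cases are rare in real data.
* Products shorter than `min_cds_nt / 3` codons (33 at the default) are
  dropped, mirroring the minimum-CDS-length filter applied to the input
  annotation: after editing, a frameshift or premature stop can shrink a
  protein below what a search can meaningfully identify.
* A variant is *silent* on a haplotype if removing it (leave-one-out)
  leaves that haplotype's protein unchanged; silent variants stay in the
  sequence construction but are excluded from the applied-variant record,
  so downstream variant identification only ever reports non-silent
  variation.

Effect flags are computed from the applied edits: `frameshift` when the
cumulative length offset over the edits, scanned 5'→3', ends off-frame;
`resolved_frameshift` when the running offset leaves frame mid-scan but
returns; `changed_stop` when the terminator codon index moves. The diff
string lists substitutions as `refAA<pos>altAA` for length-preserving
changes; when lengths differ, a global protein alignment (BLOSUM62, gap
open 10 / extend 0.5) yields `del<pos>:<res>` / `ins<pos>:<res>`
operations. The format is a package convention; any unambiguous encoding
would do.

**Haplotype labels.** `A`/`B` are assigned per gene, transcripts in
lexicographic order; each later transcript orients its labels so that, at
the leftmost heterozygous variant shared with an already-labeled
transcript, the allele-to-letter assignment agrees. Transcripts with no
shared heterozygous variant default to haplotype 1 = A. This local,
forward-only rule can in principle label the same variant differently in
isoforms connected only through a chain of other variants; it is
deterministic and order-invariant, which matters more for reproducible
databases. When both haplotype proteins are identical the single product
keeps the bare transcript id (no `A`/`B` suffix) — an unsuffixed entry is
therefore always a homozygous-equivalent product.

# Database assembly

Reference entries whose transcript carries at least one non-silent
variant are replaced by the haplotype products; novel-splice products are
appended. Deduplication keeps one entry per distinct sequence, with the
lexicographically smallest accession as id and all contributors recorded
in a sidecar (`entry_id`, `class`, `members`) — search engines see a
sequence-unique FASTA while annotation can recover every accession.
Contaminants are concatenated *before* decoy generation so they also
receive decoys. Decoys are whole-sequence reversals (id prefix `XXX_`);
any decoy tryptic peptide that collides with the target peptide universe
is shuffled in place and re-checked for up to `max_decoy_iterations`
(100) rounds. Residual collisions are counted and warned about, never
silently ignored. I and L are treated as distinct residues in collision
checks. Decoys are generated from the deduplicated set: duplicated
targets would otherwise produce duplicated decoys.

Digestion is tryptic: cleave after K or R unless followed by P, up to
`max_missed_cleavages = 2`, peptide length 5–100. These digestion
parameters are shared between decoy generation and the search-result
simulator.

# Post-search annotation

Accepted peptides have `q_value < 0.01` and at least one non-decoy,
non-contaminant match. All peptide–entry relations are recomputed by
substring search against the database, so the annotation does not depend
on the completeness of the search engine's protein lists. Peptide
classification precedence: *reference* when the peptide occurs in any
reference protein (including reference proteins displaced from the
database by their variant products — pass `reference_seqs`); otherwise
*variant* / *splice* / *variant_splice* by the classes of the explaining
entries and whether the peptide overlaps an applied variant. When the
explanations mix variant and novel-splice entries, the peptide is called
*variant* if it overlaps a variant somewhere and *splice* otherwise; the
choice is documented rather than canonical.

**Direct identification** requires a peptide that (i) occurs in an entry
carrying the variant, (ii) covers the full altered residue span — for
indels, the affected span plus one flanking residue on each side, since
an indel is only distinguishable when its boundaries are bracketed — and
(iii) occurs in no target entry lacking the variant (sequence-level
uniqueness). For frameshifted products the affected span extends from
the frame-breaking edit to the protein's end, because every downstream
residue differs from reference. **Linked identification**: heterozygous
variants sharing a phase block with a directly identified heterozygous
variant; homozygous variants residing on a protein entry that contains a
direct variant (homozygous variants have no phase block, so co-residence
is the natural analogue; this entry-level rule is a package definition).
Direct and linked sets are disjoint by construction.

**Protein inference** merges entries with identical accepted-peptide
sets, then greedily picks the group covering the most uncovered peptides
until all are covered. Ties break on the lexicographically smallest
member id — everywhere in the package, lexicographic order is the
tie-break, making all outputs order-invariant. A gene is identified when
some group's members all map to it (haplotype suffixes stripped).

Browser tracks back-translate peptides to the genome: residue span →
edited-CDS nucleotide span → reference CDS coordinates by inverting the
applied indel offsets (positions inside an insertion clamp to the edit's
anchor) → genomic blocks, emitted as BED12 (0-based half-open, as the
format defines; VCF/GTF are 1-based inclusive internally).

# Phasing evaluation

The switch error rate compares a test phasing with a truth set on sites
that are heterozygous and phased in both, with identical alleles; a
het/hom genotype disagreement excludes the site (counted in an
attribute). Within each *test* phase block, consecutive shared sites are
assessed for relative orientation; a switch is an orientation change
between the two sites of a pair, and pairs spanning two blocks are not
assessed — no relative orientation is claimed across blocks. The rate is
invariant under a global haplotype flip, as phasing is relative.

Completeness is reported as phased/total heterozygous counts and as
fully-phased fractions at CDS, transcript (exon span) and gene (CDS
union) level. A region with zero or one heterozygous variant is fully
phased by convention, but since the natural denominator is debatable,
three fractions are emitted: over all regions, over regions with ≥1 het,
and over regions with ≥2 hets. Coverage stratification recomputes all
metrics at minimum-depth cutoffs (default 5/10/25/100; sites missing
from the depth map count as depth 0), separately for SNVs only and SNVs
plus indels.

# Synthetic studies

The generators are first-class, tested code. `simulate_reference` builds
one single-isoform gene per chromosome, alternating strands, with
multi-exon structure, 5'/3' UTRs, an ATG start, no internal in-frame
terminator, and the stop codon inside the CDS. Defaults — CDS 150–450 nt,
2–3 exons, UTRs 12–40 nt, introns 20–60 nt — are scaled-down but
structurally representative coding loci; chromosome-per-gene keeps phase
blocks and gene models independent. `simulate_phased_variants` plants
per-transcript variants (defaults: 2 heterozygous SNVs, 1 homozygous SNV;
indels of 1–6 nt, insertions and deletions equally likely, when
requested) inside the CDS, avoiding start/stop codons and intron
boundaries, with all heterozygous variants of a chromosome in one phase
set. Ground truth is built by a deliberately separate string editor: the
CDS + 3' UTR transcript sequence is edited directly per haplotype and
translated — projection is validated against this independent
construction, not against itself. `simulate_search_results` reports a
chosen fraction of the target tryptic peptide universe at q-values
uniformly below 0.01, plus optional decoy-only and high-q noise rows;
the two-component q model makes no claim of realism and exists to
exercise the filter.

What the simulations do *not* emulate: multi-isoform genes sharing
exons, realistic variant densities and allele-frequency spectra,
sequencing/caller error models, PTMs, and spectrum-level effects
(intensities, missed identifications biased by peptide chemistry).
Passing tests therefore demonstrate the correctness of the algorithms
under their stated contracts, not end-to-end performance on real data.
Problem sizes in the test-suite studies — 200 transcripts for the
projection oracle, 500 for the phase-completeness property, 1,000
sequences for the digestion oracle, 100 set-cover instances, 200
switch-planting replicates — were chosen as comfortably large for
property checks while keeping the default suite quick on a laptop.

# Known limitations

* Multi-allelic sites are dropped rather than decomposed.
* Variants overlapping CDS boundaries are skipped, not realigned.
* Haplotype labels are locally consistent per shared variant, not
  globally optimized across a gene.
* Uniqueness for direct identification is sequence-level substring
  uniqueness; peptides shared with an unrelated protein elsewhere in the
  database suppress identification even if that protein is unexpressed.
* Selenocysteine and non-standard genetic codes are not supported.
* q-values are consumed, never computed; FDR estimation belongs to the
  search engine.
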