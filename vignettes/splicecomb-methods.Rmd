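---
title: "Methods: splice-site combination analysis in splicecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-site combination analysis in splicecomb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecomb)
```

## The problem

Intron excision by the spliceosome is anchored on the terminal
dinucleotides of the intron: `GT` at the 5' (donor) and `AG` at the 3'
(acceptor) end in the canonical case, with the major non-canonical
combinations `GC-AG` and `AT-AC` and a tail of minor combinations.
Because annotation pipelines largely assume canonical borders,
non-canonical combinations in an annotation mix three things: genuine
non-canonical splicing, annotation artifacts (notably antisense
annotations, where a canonical `GT-AG` intron on the true strand
surfaces as its reverse complement `CT-AC` on the annotated strand), and
sequence variation. `splicecomb` implements the per-species pipeline to
separate these: strand-correct extraction and classification,
RNA-Seq-based validation, spectrum statistics, conservation scoring and
variant overlap, together with a synthetic-data generator that makes
every step testable against known ground truth.

## Coordinates and extraction

All internal coordinates are 0-based half-open; GFF3 input (1-based
inclusive) is converted once, at the parser boundary, so a single
round-trip test pins the convention. Exon lists are stored sorted by
genomic start regardless of strand; transcript orientation is recovered
where it matters (intron indices, donor/acceptor reading, flank
windows). On the minus strand the stored intron sequence is the reverse
complement of the genomic slice, which makes the donor the biological 5'
dinucleotide by construction. The whole extraction layer is checked by a
strand-flip invariance property: reverse-complementing the genome and
flipping every annotated strand must leave all combination tables
byte-identical.

One transcript per gene is used for counting ("representative"), chosen
as the longest total CDS, with ties broken by longest exonic span and
then lexicographically smallest transcript id. The rule is isolated in
`select_representative()` so an alternative convention can be swapped in
without touching extraction.

Two filters keep the tables honest. Introns shorter than 4 bases are
excluded (donor and acceptor would overlap; such annotated gaps are
almost always frame-preserving indel artifacts) and counted separately.
Any `N` in a border dinucleotide flags the record ambiguous and removes
it from frequency normalisation — otherwise assembly gaps would
materialise as phantom minor combinations.

## Flank profiles

Position frequency matrices are collected over 7 exonic and 7 intronic
positions at each splice site, in transcript orientation. The intronic
window *includes* the terminal dinucleotide (so 5 additional interior
bases); this makes the donor/acceptor columns a built-in consistency
check of the extraction (they must be 100% the stored dinucleotides),
and the window width is a parameter for users who prefer the other
reading. Windows truncated at sequence ends contribute only to the
columns they cover; per-column denominators are tracked rather than
padding with pseudo-counts.

## RNA-Seq validation and usage

A splice site is *supported* when (a) at least `min_reads = 3` reads
span the exact junction in a split alignment and (b) read depth drops by
at least `drop = 20%` when moving from the last exonic base into the
first intronic base, at both borders. Both comparisons are inclusive: a
drop of exactly 20% passes, because the threshold names the boundary of
acceptance, not a value to exceed. Junction reads are required on top of
the depth drop because per-base depth alone cannot distinguish a spliced
intron from a lowly covered retained one. A border with zero exonic
coverage can never support a site and is flagged rather than divided by.

Per-intron usage is the relative coverage drop per border, clamped to
the unit interval: `usage = max(0, 1 - intron_cov / exon_cov)`. The
clamp (rather than allowing negative usage) treats intron coverage above
exon coverage as no evidence of splicing, which is the conservative
reading under antisense transcription and mapping noise. The reported
`delta = usage_5 - usage_3` is antisymmetric under swapping the borders,
which the test suite checks as an invariant.

Expression comparisons use FPKM
(`read_count / ((length/1e3) * (total/1e6))`) on a consumed count table;
genes above the 99th FPKM percentile are excluded from binning by
default ("extremely high values" is otherwise unbounded), and the
cumulative relative bin sizes are compared across gene classes (only
GT-AG, has GC-AG, has AT-AC, has minor). The isoform-presence estimate
compares the mean depth of the two exonic bases flanking an intron with
`200 * read_count / transcript_length`, i.e. a fragment length of 200 bp
(2 × 100 nt reads) is assumed; a strongly negative difference marks an
intron carried by a minor isoform only.

## Spectrum statistics

Shannon diversity is computed in natural log units, both over the full
combination spectrum (`H_all`) and over the spectrum excluding GT-AG and
GC-AG with renormalisation (`H_excl`) — the two supports answer
different questions (overall spectrum entropy versus diversity among the
rarer combinations) and both are reported. Group comparisons use the
Mann–Whitney U test for two groups (normal approximation with tie and
continuity correction, i.e. the scipy default convention) and
Kruskal–Wallis for three or more; GC relationships use Pearson
correlation with two-sided p-values. All three are delegated to base R
(`wilcox.test`, `kruskal.test`, `cor.test`); the test suite checks the
closed forms (U = nm/2 for identical groups, U + U' = nm, H(uniform k) =
ln k, r = ±1 on exact linear data) rather than re-deriving the tests.

For retention tolerance, an intron qualifies when its length is
divisible by three *and* it contains no `TAA`/`TAG`/`TGA` read in the
frame continuing from the upstream CDS. The frame is anchored to the
upstream CDS phase — the codon grid starts `(3 - offset mod 3) mod 3`
bases into the intron — because that is the frame a retained intron
would actually be translated in; codons are scanned fully within the
intron. Introns outside the CDS span are not evaluated (flagged `NA`)
rather than silently counted. An independent brute-force scan is kept in
the test suite as the oracle.

## Conservation

Per-transcript combination strings are encoded with a fixed codebook:
GT-AG always maps to `G`; the next 18 globally most frequent
combinations (count-descending, ties lexicographic) map to fixed
distinct amino-acid letters; everything else maps to the rare symbol
`X`. Nineteen informative symbols plus one rare class is what a
peptide-alphabet encoding admits, and the fixed GT-AG symbol keeps
strings comparable across species. Alignment is global
Needleman–Wunsch with match +1, mismatch 0, gap −1 (configurable) and a
deterministic tie-break (diagonal over gap-in-query over gap-in-subject)
so results are reproducible to the byte. Alignment is pairwise per
query–homolog pair — the conservation counts are tallied per homolog
sequence, so a multiple alignment would add coupling without changing
the tally. At each non-canonical query position the aligned homolog
symbol is classified as identical combination, other non-canonical, or
canonical GT-AG; gap-only positions are excluded from this partition and
counted separately. Homology detection itself (sequence search,
best-hit selection) is out of scope; the module consumes a homolog
mapping.

## Variant overlap

Variant positions (one per VCF record, 0-based, non-PASS excluded by
default) are intersected with the four border bases of every intron and
with a background set. The default background is the exonic bases of
representative transcripts: exons share the selective context of splice
sites better than whole-genome background, which would conflate
intergenic mutation rates with splice-site constraint. The background is
a parameter, so whole-genome intervals can be supplied instead.

## The synthetic-data generator

`synthetic_spec()` fixes the study conditions; `generate_species()`,
`simulate_coverage()` and `simulate_variants()` emit standard formats
(FASTA, GFF3, interval-depth TSV, junction TSV, count TSV, VCF) plus a
truth manifest. Design choices:

- Gene structure: exon count `1 + Poisson(mean_introns)`; exon and
  intron lengths are shifted geometric distributions (minima 30 and
  20 bases; the intron minimum keeps donor/acceptor disjoint with
  margin). Kingdom presets encode typical published genome properties —
  fungi: 1.49 introns per gene, genomic GC 47.1%, shorter introns
  (mean 80); animals: 6.95 introns per gene, GC 39.4%, longer introns
  (mean 120).
- Bases are sampled i.i.d. with the GC target; intron borders are then
  overwritten with the sampled combination. Interior bases are *not*
  rejection-sampled against accidental border motifs: accidental
  dinucleotides in interior positions affect no consumer (extraction
  reads only the terminal positions; flank-profile assertions concern
  planted terminal/exonic-context columns), and rejection would bias
  the GC target.
- Antisense artifacts: a fraction of intron-bearing genes is annotated
  on the opposite strand of its true orientation; the manifest records
  both the true and the annotated-strand combination, so the
  extraction oracle remains exact while the apparent CT-AC excess can
  be measured.
- Coverage: exonic bases at `Poisson(depth × expression_multiplier)`
  (or exact, `noise = "none"`), spliced introns at zero, retained
  introns at exonic depth; junction reads proportional to the spliced
  fraction, zero for retained introns. Per-gene expression multipliers
  are log-normal; genes with non-canonical combinations get a
  configurable fold change, emulating the observed depletion of
  non-canonical sites among lowly expressed genes. A minor-isoform
  intron scales its junction and its two flanking exonic bases to the
  minor-isoform frequency (a local approximation: only the bases the
  isoform-presence estimator reads are modelled, not a full second
  transcript).
- Variants: independent Bernoulli per base at separate border and
  background rates.
- All sampling flows from the single integer seed in the spec; the
  emitted files are byte-identical across runs with equal specs.

What the generator does *not* emulate: alternative splice-site choice
within a gene, sequencing error and mapping ambiguity, stranded-library
information, GC-dependent coverage bias, and correlated variant
processes. Tests passing on synthetic data therefore demonstrate the
correctness of the computations and the recoverability of planted
effects — not robustness to every artifact of real libraries.

## Problem sizes and numerical choices

The test and acceptance runs use: one animal-like species with 2,000
genes (≈14,000 introns) for the extraction oracle and mixture recovery
(recovery asserted within 3 binomial standard errors); 300 genes with
30% planted retention and noise-free coverage for the validation
contract (sensitivity = specificity = 1 is required, as no stochastic
element remains); 1,000 genes for the antisense fraction; 1,000 null
replicates at n = 50 per group for the Mann–Whitney type-I rate; 250–350
genes per condition for the frame analysis; 50 homologs with 60%
planted conservation; and 500 genes with a 3× planted border variant
enrichment. These sizes put every binomial check several standard
errors away from its alternative while keeping a full run in the order
of a minute. Closed-form identities are asserted to 1e−12; frequency
sums to 1e−9. Degenerate inputs (empty tables, zero exonic coverage,
all-ambiguous borders, empty groups) return flagged `NA`s or warnings
rather than propagating `NaN`s, and hard errors are reserved for
contract violations (missing files, reference mismatches, zero-length
backgrounds).

## Known limitations

- The representative-transcript rule is one conventional reading; CDS
  annotations with programmed frameshifts or partial CDS are taken at
  face value.
- BAM support filters on NM/NH tags when present; aligners that omit
  them are effectively unfiltered (TSV input is always taken as
  pre-filtered).
- The usage metric is coverage-based and conflates intron retention
  with overlapping antisense transcription on unstranded data.
- Conservation counts depend on the supplied homolog mapping and on
  alignment quality of the symbol strings; positions aligned to gaps
  are reported but not interpreted.
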