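---
title: "Methods: TE calling, haplotype grouping and CSSL mapping in awnloci"
author: "awnloci authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE calling, haplotype grouping and CSSL mapping in awnloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awnloci)
```

## The problem

Awns — the needle-like extensions of the grass spikelet — were selected
against during rice domestication. In the AA-genome *Oryza* group, two genes
dominate the genetics of awn loss: *RAE1*, a bHLH transcription factor whose
dysfunctional alleles carry a ~4.4-kb transposable element (TE) in the
promoter and/or a 1-bp deletion in the second exon, and *RAE2*, an
EPFL-family small secreted peptide whose function requires exactly six
cysteines in the mature peptide to form its disulfide bonds. Frameshift
indels in *RAE2* shift that count to 4 or 7 and abolish function.

`awnloci` implements three analyses around these genes, each exercisable at
desk scale on synthetic data produced by the package's own generator:

1. **TE presence/absence calling** from short-read breadth of coverage over
   the TE insertion boundaries (`call_te_accession()`).
2. **Haplotype and functional-group classification** of accessions from
   diagnostic variants (`classify_profiles()`, `summarize_groups()`).
3. **Awn-locus mapping** from chromosome-segment substitution line (CSSL)
   marker genotypes and multi-year phenotypes (`infer_segments()`,
   `candidate_loci()`).

## TE calling from boundary breadth

A structural insertion cannot be genotyped from a single position with
substitution-only read placement, but it leaves a clean breadth signature
on a TE-*containing* reference: an accession carrying the TE covers both
the TE edges and the flanks; an accession without it covers the flanks
seamlessly while the TE edges stay bare.

Four 200-bp windows are anchored at the two TE/flank junctions: for a TE
occupying `[s, e]`, `inside_left = [s, s+199]`, `outside_left =
[s-200, s-1]`, `inside_right = [e-199, e]`, `outside_right = [e+1, e+200]`.
**Breadth** is the fraction of window positions overlapped by at least one
*uniquely* placed read. The call rules are:

* **present** — breadth > 0.80 in the inside windows *and* > 0.80 in the
  outside windows;
* **absent** — breadth < 0.20 inside *and* > 0.80 outside;
* **no_call** — anything between the two rules.

Three numerical choices deserve note. The inequalities are strict
(breadth of exactly 160/200 does not qualify), matching the published form
of the rule; at 20-fold coverage breadths sit far from the thresholds, so
the choice is immaterial in practice but is pinned down for
reproducibility. Outcomes between the two rules are *emitted as `no_call`*
rather than forced into a class, because only the two extreme rules are
defined; a half-covered TE edge is evidence of something the model does not
describe (structural variation, contamination) and should be surfaced, not
hidden. Finally, both edges must satisfy the rule (the conservative
reading); `edges = "either"` relaxes this for callers who prefer recall
over precision.

### Read placement and multi-map exclusion

The TE's sequence recurs elsewhere in the genome, so reads placed equally
well at several loci carry no evidence about *this* insertion site and are
excluded. The placer is deliberately simple, because breadth needs only
substitution-level placement, not gapped alignment:

* an exact k-mer index (k = 31, odd so a k-mer never equals its own
  reverse complement) over the forward strand;
* three seed k-mers per read (both ends and the middle), so a single
  sequencing error cannot hide every seed — with 100-bp reads at 1% error
  the probability that all three seeds are hit is ~2%, which costs depth
  but not breadth at 20-fold coverage;
* full-length verification of each candidate locus allowing at most
  `max_mismatch = 5` substitutions (the expected error count per 100-bp
  read at 1% error is 1; five gives a generous margin without admitting
  spurious loci);
* `n_best_hits` counts all loci tied at the minimal mismatch count; ties
  count every tied locus, and any read with `n_best_hits > 1` contributes
  to no window.

Reads are simulated, and placed, on the forward strand only: generator and
caller are a consistent pair, and breadth statistics are unaffected by
strand (a real library would simply contribute both orientations to the
same windows). Externally aligned data enter through `ingest_sam()`, where
secondary/supplementary flags or MAPQ 0 mark a read multi-mapped.

For taxa whose flank has diverged from the reference (so that flank reads
fail to place at all, which would otherwise look like `no_call`), the
package follows the alternative-reference route: place the taxon's reads
on its own TE-free assembly and require seamless breadth across the
insertion point (`flank_continuity()`).

## Haplotypes, cysteine arithmetic and groups

*RAE1* haplotypes are a 2×2 code: hap1 (no TE, intact exon 2, functional),
hap2 (exon-2 deletion), hap3 (TE), hap4 (both). *RAE2* haplotypes hap1–hap6
are keyed by five diagnostic second-exon indels: none, a 6-bp in-frame
deletion, a 1-bp deletion, two distinct 2-bp deletions, and a 1-bp
insertion. Function is decided by translation, not by table lookup: the
allele's CDS is rebuilt from its variants (`reconstruct_cds()`, applied
right-to-left so coordinates stay valid), translated with stop-at-first-stop
semantics (`translate_cds()`), and the mature-peptide cysteines counted.
`rae2_functional` is *defined* as `cys_count == 6`, which coincides with
hap1/hap2; the 4C truncation (hap3) and the 7C frameshifts (hap4–hap6) are
dysfunctional. The four functional groups follow: I (RAE1+, RAE2+),
II (RAE1+, rae2−), III (rae1−, RAE2+), IV (rae1−, rae2−).

The exact CDS positions of the diagnostic indels are not part of the public
record, so they are *configuration*, packaged as a fixture
(`rae2_cds_fixture()`) and overridable for real data. The fixture's 138-bp
CDS was designed so that every documented consequence holds exactly and is
re-verified at construction time: six mature cysteines unedited; the hap3
deletion sits between the 4th and 5th cysteine codons and its frameshift
stops immediately, destroying cysteines 5 and 6 (4C); the hap2 deletion is
in-frame and neutral (6C); each of hap4/hap5/hap6 shifts frame after the
6th cysteine and gains exactly one frame-shifted cysteine before the new
stop (7C).

Two smaller decisions: accessions are treated as inbred/haploid (the
species panel is), so a heterozygous diagnostic site warns and yields
`unresolved` rather than guessing; and group percentages are rounded half
up to one decimal *with the exact counts always emitted alongside*, because
one-decimal roundings are lossy and published roundings of such tables are
not always internally consistent (1/16 is reported here as 6.3).
Unresolved calls are excluded from the percentage denominator and reported
in their own column. The published rae1 *indica* lesion is implemented as a
1-bp deletion (the hap2 definition) throughout.

## CSSL locus mapping

A CSSL panel tiles a donor genome across lines as single (occasionally
double) substituted segments in a recurrent background. From ordered marker
calls (`D`/`R`/`H`), maximal same-call runs become segments
(`infer_segments()`). The breakpoint between two adjacent runs is only
known to lie *between* the flanking markers, so segments carry a core
interval (outermost same-call markers) plus uncertainty bounds (the
inter-marker gaps) rather than a midpoint split — the conservative
representation loses no information and any narrower convention can be
derived from it. Missing calls are bridged with a logged count; a
chromosome with no informative marker is reported untyped.

A line is **awned** when at least `min_years = 2` years qualify, a year
qualifying when mean awn length strictly exceeds 3 mm and at least one
awned spikelet was seen. "Two or more years" is the chosen reading of the
scoring rule because several panels were only observed in two years, making
a stricter reading unsatisfiable for them; the threshold is configurable.

Candidate loci are the maximal intervals supported by at least
`min_support` donor core segments of awned lines, computed as coverage
slices over the candidate set — i.e. overlapping candidates are
intersected rather than unioned (`combine = "union"` is available, since
the narrowing convention admits both readings). Het segments are excluded
by default, matching the homozygous-substitution design of CSSL panels.
Non-awned lines whose donor segments overlap an emitted locus are reported
as *conflicts* rather than subtracted: a carrier segment can genuinely miss
the causal gene inside a broad locus (the known counterexample is a set of
lines whose chromosome-4 fragments miss *RAE1*), so naive subtraction would
delete true loci. Loci are annotated against a packaged catalogue: the
three cloned genes with published coordinates (*RAE1/An-1*, *LABA1/An-2*,
*RAE2/GAD1*) and five marker-mapped loci as chromosome-level tags; loci
overlapping nothing are flagged novel.

## What the generator emulates — and what it does not

`build_reference()` draws chromosomes from a seeded uniform nucleotide
model, embeds the gene fixtures, and inserts the TE (the reference carries
the TE allele, as the reference genome of the emulated study does).
Defaults: a 100-kb TE chromosome, a 4.4-kb TE at position 50,001, a 60-kb
second chromosome for *RAE2*. Because the real TE recurs in the genome, a
400-bp interior chunk of the TE is planted at a second locus (plus one
unrelated 400-bp repeat pair): with 100-bp reads a repeat must exceed the
read length to make whole reads ambiguous, so a 400-bp unit guarantees the
multi-map exclusion path is actually exercised while staying ≥300 bp clear
of the boundary windows. `simulate_reads()` draws
`round(depth × length / read_length)` reads per chromosome, uniform starts,
independent substitution errors; defaults 100 bp, 20-fold, 1% — ordinary
resequencing conditions under which the boundary windows are covered with
large margins. An optional flank-divergence route is *not* defaulted: the
degree of flank divergence in the diverged-taxon case is not quantified in
the public record, so the package exposes the alternative-reference
mechanism instead of inventing a divergence rate.

CSSL panels (`make_cssl_panel()`) tile the marker map across lines in
consecutive blocks (1–2 contiguous donor segments per line, second segments
arising at chromosome boundaries), and draw per-year phenotypes: a line
overlapping a causal locus is awned each year with probability equal to the
locus penetrance, otherwise with a false-positive rate (default 0). Awned
years draw 80–150 spikelets, awned fractions from 7–100% (the span observed
in the emulated panels), and awn lengths 5–80 mm; non-awned years draw
lengths below 1 mm. The default panel shape, 35 lines over 149 markers on
12 chromosomes, mirrors a published panel.

The generator deliberately omits: quality-score models and indel sequencing
errors, paired-end structure, reverse-strand reads, linkage/coalescent
population structure, and heterozygous CSSL segments (available only via
explicit `H` calls). Passing tests therefore demonstrate that the
*algorithms* recover what the model plants — TE status at realistic depth
and error, groups from diagnostic variants, loci from tiling panels — not
that they are robust to alignment artefacts, indel-rich divergence, or
structural variation beyond the single catalogued insertion, none of which
the generator produces.

## Problem sizes and determinism

Every generator routes randomness through an internal seeded-RNG scope, so
identical seeds give byte-identical FASTA/FASTQ/VCF outputs and
`run_pipeline()` manifests with identical digests. The test suite runs the
TE-recovery property on 20 accessions of a 100-kb single-chromosome
reference at 20-fold coverage and 1% error (~20,000 reads per accession),
the breadth oracle on 100 randomized windows, the haplotype round-trip on
all 24 haplotype combinations, and locus recovery on a 35-line/149-marker
panel — sizes chosen so the full suite completes in a couple of minutes
while leaving the calling margins (breadth vs. threshold, support vs.
minimum) essentially at their asymptotic values.

## Known limitations

* The placer is substitution-only; indel-containing reads near window
  edges are unplaced rather than soft-clipped, which slightly depresses
  outside-window breadth around a deletion junction (harmless at the
  default margins, visible at very low depth).
* Diagnostic indel positions, the mature-peptide start, and the gene
  catalogue are configuration; results on real data are only as good as
  those tables.
* `candidate_loci()` reports support and conflicts but no likelihoods; it
  is a deterministic interval method, not QTL interval mapping.
* The real-scale analyses of the emulated study (175 SRA accessions, its
  exact SNP/indel inventories, and sub-megabase narrowed regions that
  depend on external SSR marker maps) are out of desk-scale reach and are
  replaced here by the property suites above.
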