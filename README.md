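# awnloci

Genetics of awn development in AA-genome rice, at desk scale.

Awns — the bristles on the tips of grass spikelets — were selected against
during rice domestication, largely through two genes: **RAE1** (a bHLH
transcription factor, also known as *An-1*) and **RAE2** (an EPFL-family
secreted peptide, also known as *GAD1*). Dysfunctional *rae1* alleles carry
a ~4.4-kb transposable element (TE) in the promoter and/or a 1-bp deletion
in the second exon; dysfunctional *rae2* alleles carry frameshift indels
that change the mature peptide's cysteine count away from the six required
for its disulfide-bonded fold (4C truncations, 7C read-throughs).

`awnloci` is for geneticists who want to run this style of analysis — or
teach it, or stress-test it — without a cluster. It provides:

* **TE insertion calling** from short reads: breadth of coverage over four
  200-bp windows at the TE boundaries on a TE-containing reference, with
  multi-mapped reads excluded. Present when breadth > 0.80 inside *and*
  outside the TE; absent when < 0.20 inside and > 0.80 outside; `no_call`
  between the rules.
* **Haplotype and group classification**: *RAE1*-hap1–4 from TE status ×
  exon-2 deletion; *RAE2*-hap1–6 from five diagnostic indels;
  frameshift-aware translation and cysteine counting; the four functional
  groups I–IV (functional/functional … dysfunctional/dysfunctional) and
  per-species frequency tables.
* **CSSL locus mapping**: graphical genotypes from marker calls
  (donor/recurrent/het segment cores with inter-marker uncertainty), awn
  scoring across 2–3 years (> 3 mm in ≥ 2 years), candidate loci as
  intervals supported by ≥ *k* donor segments of awned lines, annotated
  against the known awn-gene catalogue.
* **A seeded synthetic-data generator** for every input the pipeline
  consumes: reference and accession FASTA (with or without the TE, with
  haplotype-defining edits), FASTQ reads at configurable depth/error,
  truth VCFs, CSSL marker-genotype and phenotype tables.

## Worked example

Simulate a TE-carrying *japonica*-like accession, call the TE from its
reads, and classify a small panel:

```r
library(awnloci)

ref <- build_reference(synthetic_genome_spec())   # 100-kb chr4 + 4.4-kb TE, 60-kb chr8
idx <- index_reference(ref)

acc   <- make_accession_genome(ref, accession_profile("ACC001", "japonica",
                                                      te_present = TRUE,
                                                      rae2_edit = "del1"))
reads <- simulate_reads(acc, read_sim_params(seed = 42))  # 100 bp, 20x, 1% error
call_te_accession(reads, idx, ref$windows, "ACC001")
#>  accession_id breadth_inside_left breadth_outside_left breadth_inside_right
#>        ACC001                   1                    1                    1
#>  breadth_outside_right  status
#>                      1 present
```

All four boundary windows are fully covered, so the TE is called
`present` — at 20-fold depth the breadths sit far from the 0.80/0.20
thresholds. Haplotype/group classification of a three-accession panel:

```r
calls <- classify_profiles(list(
  accession_profile("ACC001", "japonica",  TRUE,  FALSE, "del1"),
  accession_profile("ACC002", "japonica",  TRUE,  FALSE, "none"),
  accession_profile("ACC003", "rufipogon", FALSE, FALSE, "none")))
calls
#>  accession_id species_label rae1_hap rae2_hap cys_count rae1_functional
#>        ACC001      japonica     hap3     hap3         4           FALSE
#>        ACC002      japonica     hap3     hap1         6           FALSE
#>        ACC003     rufipogon     hap1     hap1         6            TRUE
#>  rae2_functional group
#>            FALSE    IV
#>             TRUE   III
#>             TRUE     I
```

ACC001 carries the promoter TE (*rae1*-hap3, dysfunctional) and the 1-bp
*RAE2* deletion whose frameshift truncates the peptide to 4 cysteines
(*rae2*-hap3, dysfunctional) — group IV, the typical domesticated awnless
combination. ACC003 is the wild-type: both genes functional, group I.
`summarize_groups(calls)` then tabulates counts and half-up one-decimal
percentages per species.

For CSSL mapping, `make_cssl_panel()` simulates a tiling panel with causal
loci and penetrance, `infer_segments()` + `classify_awned()` +
`candidate_loci()` map the loci, and `annotate_known()` labels them
against the catalogue (RAE1/An-1, LABA1/An-2, RAE2/GAD1, An7, An9, An10,
qAWL2, RAE3). A thin command-line wrapper with `simulate`, `call-te`,
`haplotype`, `classify-groups`, `map-loci` and `run-all` subcommands is
installed at `inst/scripts/awnloci.R`.

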