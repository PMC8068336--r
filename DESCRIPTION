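Package: awnloci
Title: Awn-Development Genetics: TE Insertion Calling, RAE1/RAE2 Haplotype
    Grouping and CSSL Locus Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the genetics of awn development in AA-genome rice.
    Calls a catalogued promoter transposable-element (TE) insertion from
    short-read breadth of coverage over 200-bp boundary windows with
    multi-mapped-read exclusion; classifies RAE1/RAE2 haplotypes from
    diagnostic variants, translates alleles through frameshifts, counts
    mature-peptide cysteines and assigns the four functional groups with
    per-species frequency summaries; infers chromosome-segment substitution
    line (CSSL) graphical genotypes from marker calls and localizes awn loci
    by donor-segment overlap against a catalogue of known awn genes. A
    seeded synthetic-data generator produces every input the pipeline
    consumes (reference and accession FASTA, FASTQ reads, truth VCF, marker
    and phenotype tables) so the whole analysis is exercisable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
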