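#' Pipeline configuration
#'
#' Collects the tunable thresholds and simulation settings for a
#' reproducible end-to-end run. Thresholds are validated against their
#' documented ranges.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_accessions Accessions to simulate (half TE-present).
#' @param depth,error_rate,read_length Read-simulation settings.
#' @param present_th,absent_th TE-caller breadth thresholds.
#' @param min_years,min_support,min_awn_mm CSSL-mapping thresholds.
#' @param n_lines,years CSSL panel size and observation years.
#' @param run_cssl Also simulate and map a CSSL panel.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_accessions = 8L, depth = 20,
                       error_rate = 0.01, read_length = 100L,
                       present_th = 0.80, absent_th = 0.20,
                       min_years = 2L, min_support = 2L, min_awn_mm = 3,
                       n_lines = 35L, years = 3L, run_cssl = TRUE) {
  stopifnot(present_th > 0, present_th < 1, absent_th > 0,
            absent_th < present_th, min_years >= 1L, min_support >= 1L,
            min_awn_mm >= 0, n_accessions >= 1L)
  structure(list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
                 depth = depth, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 present_th = present_th, absent_th = absent_th,
                 min_years = as.integer(min_years),
                 min_support = as.integer(min_support), min_awn_mm = min_awn_mm,
                 n_lines = as.integer(n_lines), years = as.integer(years),
                 run_cssl = isTRUE(run_cssl)),
            class = "run_config")
}

# a deterministic demo accession panel: alternating TE status, assorted
# RAE2 edits so all four groups appear
demo_profiles <- function(n) {
  edits <- rep(c("none", "del1", "none", "ins1", "del6", "del2a", "none", "del2b"),
               length.out = n)
  lapply(seq_len(n), function(i)
    accession_profile(sprintf("ACC%03d", i),
                      species_label = ifelse(i %% 2L == 0L, "speciesA", "speciesB"),
                      te_present = i %% 2L == 0L,
                      rae1_exon2_del = i %% 5L == 0L,
                      rae2_edit = edits[i]))
}

#' Run the whole pipeline on synthetic data
#'
#' Simulates a reference and a panel of accessions, sequences each
#' accession, calls the TE from boundary-window breadths, classifies
#' RAE1/RAE2 haplotypes and groups from the truth variants plus the
#' *measured* TE status, summarizes group frequencies per species, and
#' (optionally) simulates and maps a CSSL panel. Writes TSV/BED/VCF/FASTA
#' outputs plus a JSON manifest with the seed, configuration and md5
#' digests of every output, so identical config and seed give identical
#' digests.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param spec Optional [synthetic_genome_spec()]; by default one is built
#'   from the config seed with a marker map and one causal locus over the
#'   RAE1 region for the CSSL stage.
#' @return List with `te_calls`, `haplotype_calls`, `group_freq`, `loci`
#'   (or `NULL`), and `manifest` (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, outdir, spec = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (missing(outdir) || is.null(outdir))
    stop("usage error: 'outdir' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) {
    cl <- c(chr4 = 100000L, chr8 = 60000L)
    spec <- synthetic_genome_spec(
      chrom_lengths = cl,
      marker_map = make_marker_map(cl, 24L),
      causal_loci = data.frame(chrom = "chr4", start = 50301L, end = 50450L,
                               penetrance = 1.0, stringsAsFactors = FALSE),
      seed = config$seed)
  }
  reference <- build_reference(spec)
  write_fasta(reference, file.path(outdir, "reference.fasta"))
  write_bed(reference$annotation, file.path(outdir, "annotation.bed"))
  idx <- index_reference(reference)

  profiles <- demo_profiles(config$n_accessions)
  te_calls <- list(); truth_vcfs <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    acc <- make_accession_genome(reference, p)
    reads <- simulate_reads(acc, read_sim_params(
      read_length = config$read_length, depth = config$depth,
      error_rate = config$error_rate, seed = config$seed + i))
    te_calls[[i]] <- call_te_accession(
      reads, idx, reference$windows, accession_id = p$accession_id,
      present_threshold = config$present_th,
      absent_threshold = config$absent_th)
    truth_vcfs[[i]] <- acc$variants
  }
  te_calls <- do.call(rbind, te_calls)
  write_tsv_file(te_calls, file.path(outdir, "te_calls.tsv"))
  write_vcf(do.call(rbind, truth_vcfs), file.path(outdir, "truth_variants.vcf"),
            contigs = nchar(reference$sequences))

  calls <- classify_profiles(profiles, te_status = te_calls$status)
  write_tsv_file(calls, file.path(outdir, "haplotype_calls.tsv"))
  freq <- summarize_groups(calls)
  write_tsv_file(freq, file.path(outdir, "group_frequencies.tsv"))

  loci <- NULL
  if (config$run_cssl && !is.null(spec$marker_map)) {
    panel <- make_cssl_panel(spec, n_lines = min(config$n_lines,
                                                 nrow(spec$marker_map)),
                             seed = config$seed, years = config$years)
    write_tsv_file(panel$genotypes, file.path(outdir, "cssl_genotypes.tsv"))
    write_tsv_file(panel$phenotypes, file.path(outdir, "cssl_phenotypes.tsv"))
    segs <- infer_segments(panel$genotypes, spec$chrom_lengths)
    aw <- classify_awned(panel$phenotypes, min_years = config$min_years,
                         min_length_mm = config$min_awn_mm)
    loci <- annotate_known(candidate_loci(segs, aw,
                                          min_support = config$min_support))
    write_tsv_file(loci, file.path(outdir, "awn_loci.tsv"))
  }

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "awnloci",
    version = as.character(utils::packageVersion("awnloci")),
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(outputs))),
                                      basename(sort(outputs)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(te_calls = te_calls, haplotype_calls = calls,
                 group_freq = freq, loci = loci, manifest = manifest))
}
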