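#' Assign the RAE1 haplotype
#'
#' RAE1 haplotypes are defined by two lesions: the ~4.4-kb promoter TE
#' insertion (reduces expression) and the second-exon 1-bp deletion
#' (premature stop). hap1 carries neither and is the functional allele;
#' hap2 carries only the deletion, hap3 only the TE, hap4 both. A `no_call`
#' TE status propagates to `unresolved`.
#'
#' @param te_status `"present"`, `"absent"` or `"no_call"` (vectorized).
#' @param exon2_del Logical: carries the second-exon 1-bp deletion.
#' @return Character vector in `hap1`..`hap4`/`unresolved`.
#' @export
assign_rae1_hap <- function(te_status, exon2_del) {
  stopifnot(all(te_status %in% c("present", "absent", "no_call")))
  ifelse(te_status == "no_call", "unresolved",
         ifelse(te_status == "absent",
                ifelse(exon2_del, "hap2", "hap1"),
                ifelse(exon2_del, "hap4", "hap3")))
}

#' Assign the RAE2 haplotype from diagnostic indels
#'
#' Matches an accession's RAE2 variants against the configured diagnostic
#' indel table: no diagnostic indel is hap1; the 6-bp deletion hap2; the
#' 1-bp deletion hap3; the two distinct 2-bp deletions hap4/hap5; the 1-bp
#' insertion hap6. An indel not in the table that shifts the reading frame
#' yields `unresolved` (with a warning); an unconfigured in-frame indel or
#' any SNP is ignored. Two diagnostic indels in one (inbred) accession is a
#' data conflict and errors.
#'
#' @param variants Data frame of the accession's RAE2 variants: `pos`
#'   (1-based CDS), `ref`, `alt`. May include a `gene` column, in which case
#'   only `RAE2` rows are used.
#' @param diagnostics Diagnostic table ([rae2_diagnostics()] by default).
#' @return One of `hap1`..`hap6` or `"unresolved"`.
#' @export
assign_rae2_hap <- function(variants, diagnostics = rae2_diagnostics()) {
  if (!is.null(variants$gene))
    variants <- variants[variants$gene == "RAE2", , drop = FALSE]
  if (is.null(variants) || nrow(variants) == 0L) return("hap1")
  if (!is.null(variants$gt) && any(variants$gt == "het")) {
    warning("heterozygous diagnostic site in an inbred accession; unresolved")
    return("unresolved")
  }
  is_indel <- nchar(variants$ref) != nchar(variants$alt)
  ind <- variants[is_indel, , drop = FALSE]
  if (nrow(ind) == 0L) return("hap1")
  key <- paste(ind$pos, toupper(ind$ref), toupper(ind$alt))
  dkey <- paste(diagnostics$pos, toupper(diagnostics$ref), toupper(diagnostics$alt))
  hit <- diagnostics$hap[match(key, dkey)]
  matched <- unique(hit[!is.na(hit)])
  if (length(matched) > 1L)
    stop("conflicting RAE2 diagnostic indels: ", paste(matched, collapse = " and "))
  unmatched <- ind[is.na(hit), , drop = FALSE]
  if (nrow(unmatched) > 0L) {
    frameshift <- (abs(nchar(unmatched$ref) - nchar(unmatched$alt)) %% 3L) != 0L
    if (any(frameshift)) {
      warning("unconfigured frameshifting indel at CDS position ",
              paste(unmatched$pos[frameshift], collapse = ", "),
              "; haplotype unresolved")
      return("unresolved")
    }
  }
  if (length(matched) == 1L) matched else "hap1"
}

#' Functional flags from haplotype and cysteine count
#'
#' RAE1 is functional only as hap1 (no promoter TE, intact second exon).
#' RAE2 is functional exactly when the mature peptide keeps 6 cysteines
#' (hap1/hap2); 4C and 7C alleles are dysfunctional. Unresolved haplotypes
#' propagate as `NA` flags.
#'
#' @param rae1_hap,rae2_hap Haplotype labels (possibly `"unresolved"`).
#' @param cys_count Mature-peptide cysteine count for the RAE2 allele.
#' @return List with logical `rae1_functional` and `rae2_functional`.
#' @export
call_function <- function(rae1_hap, rae2_hap, cys_count) {
  r1 <- if (rae1_hap == "unresolved") NA else rae1_hap == "hap1"
  r2 <- if (rae2_hap == "unresolved") NA else cys_count == 6L
  list(rae1_functional = r1, rae2_functional = r2)
}

#' Assign the functional group
#'
#' The four combinations of RAE1/RAE2 functionality: I (both functional),
#' II (RAE1 functional, rae2 dysfunctional), III (rae1 dysfunctional, RAE2
#' functional), IV (neither functional). `NA` flags give `"unresolved"`.
#'
#' @param rae1_functional,rae2_functional Logical flags (may be `NA`).
#' @return `"I"`, `"II"`, `"III"`, `"IV"` or `"unresolved"`.
#' @export
assign_group <- function(rae1_functional, rae2_functional) {
  if (is.na(rae1_functional) || is.na(rae2_functional)) return("unresolved")
  if (rae1_functional && rae2_functional) "I"
  else if (rae1_functional) "II"
  else if (rae2_functional) "III"
  else "IV"
}

#' Classify one accession end to end
#'
#' From TE status and a variant table to a full haplotype call: RAE1
#' haplotype from TE status and the second-exon deletion, RAE2 haplotype
#' from diagnostic indels, allele reconstruction and translation through
#' any frameshift, mature-cysteine count, functional flags and group.
#'
#' @param accession_id,species_label Identifiers carried into the result.
#' @param te_status `"present"`, `"absent"` or `"no_call"`.
#' @param variants Data frame `gene` (`RAE1`/`RAE2`), `pos` (1-based CDS),
#'   `ref`, `alt`; may be empty or `NULL`.
#' @param rae1_fixture,rae2_fixture CDS fixtures supplying reference CDS,
#'   mature start and diagnostic positions.
#' @return One-row data frame: accession, species, `rae1_hap`, `rae2_hap`,
#'   `cys_count`, `rae1_functional`, `rae2_functional`, `group`.
#' @export
classify_accession <- function(accession_id, species_label, te_status,
                               variants = NULL,
                               rae1_fixture = rae1_cds_fixture(),
                               rae2_fixture = rae2_cds_fixture()) {
  if (is.null(variants))
    variants <- data.frame(gene = character(), pos = integer(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
  v1 <- variants[variants$gene == "RAE1", , drop = FALSE]
  v2 <- variants[variants$gene == "RAE2", , drop = FALSE]
  d1 <- rae1_diagnostics(rae1_fixture)
  exon2_del <- any(paste(v1$pos, toupper(v1$ref), toupper(v1$alt)) %in%
                     paste(d1$pos, toupper(d1$ref), toupper(d1$alt)))
  rae1_hap <- assign_rae1_hap(te_status, exon2_del)
  rae2_hap <- assign_rae2_hap(v2, rae2_diagnostics(rae2_fixture))
  alt_cds <- reconstruct_cds(rae2_fixture$cds_sequence,
                             v2[order(v2$pos), c("pos", "ref", "alt"), drop = FALSE])
  cys <- count_cysteines(translate_cds(alt_cds), rae2_fixture$mature_start)
  fn <- call_function(rae1_hap, rae2_hap, cys)
  data.frame(accession_id = accession_id, species_label = species_label,
             rae1_hap = rae1_hap, rae2_hap = rae2_hap, cys_count = cys,
             rae1_functional = fn$rae1_functional,
             rae2_functional = fn$rae2_functional,
             group = assign_group(fn$rae1_functional, fn$rae2_functional),
             stringsAsFactors = FALSE)
}

# variants implied by an accession_profile, in CDS space (used when
# classifying straight from generator truth)
profile_variants <- function(profile, rae1_fixture = rae1_cds_fixture(),
                             rae2_fixture = rae2_cds_fixture()) {
  out <- list()
  if (profile$rae1_exon2_del)
    out[[length(out) + 1L]] <- cbind(gene = "RAE1",
                                     fixture_variant(rae1_fixture, "exon2_del"))
  if (profile$rae2_edit != "none")
    out[[length(out) + 1L]] <- cbind(gene = "RAE2",
                                     fixture_variant(rae2_fixture,
                                                     .RAE2_EDIT_HAP[[profile$rae2_edit]]))
  if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
}

#' Classify a table of accession profiles
#'
#' Convenience wrapper running [classify_accession()] over generator
#' profiles (or any data frame in the same shape), using each profile's
#' `te_present` as a clean TE status.
#'
#' @param profiles Data frame with columns `accession_id`, `species_label`,
#'   `te_present`, `rae1_exon2_del`, `rae2_edit` — or a list of
#'   [accession_profile()] objects.
#' @param te_status Optional character vector overriding the TE status per
#'   accession (e.g. measured calls from [call_te_accession()]).
#' @return Data frame of haplotype calls, one row per accession.
#' @export
classify_profiles <- function(profiles, te_status = NULL) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, lapply(profiles, function(p)
      data.frame(accession_id = p$accession_id, species_label = p$species_label,
                 te_present = p$te_present, rae1_exon2_del = p$rae1_exon2_del,
                 rae2_edit = p$rae2_edit, stringsAsFactors = FALSE)))
  if (is.null(te_status))
    te_status <- ifelse(profiles$te_present, "present", "absent")
  rf1 <- rae1_cds_fixture(); rf2 <- rae2_cds_fixture()
  do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    pr <- accession_profile(p$accession_id, p$species_label, p$te_present,
                            p$rae1_exon2_del, p$rae2_edit)
    classify_accession(p$accession_id, p$species_label, te_status[i],
                       profile_variants(pr, rf1, rf2), rf1, rf2)
  }))
}

#' Per-species group-frequency table
#'
#' Counts accessions per functional group within each species and converts
#' to percentages of the classified total, rounded half-up to one decimal.
#' Counts are always emitted alongside percentages because one-decimal
#' rounding is lossy; unresolved calls are counted separately and excluded
#' from the percentage denominator.
#'
#' @param calls Data frame with `species_label` and `group` columns
#'   ([classify_profiles()] output).
#' @param by Grouping column name (default `"species_label"`).
#' @return Data frame, one row per species: `n_I`..`n_IV`, `n_unresolved`,
#'   `n_total` (classified accessions), `pct_I`..`pct_IV`.
#' @export
summarize_groups <- function(calls, by = "species_label") {
  if (nrow(calls) == 0L)
    return(data.frame(species_label = character(), n_I = integer(),
                      n_II = integer(), n_III = integer(), n_IV = integer(),
                      n_unresolved = integer(), n_total = integer(),
                      pct_I = numeric(), pct_II = numeric(),
                      pct_III = numeric(), pct_IV = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(calls, calls[[by]]), function(d) {
    n <- vapply(c("I", "II", "III", "IV"), function(g) sum(d$group == g),
                integer(1L))
    nu <- sum(d$group == "unresolved")
    nt <- sum(n)
    pct <- if (nt > 0L) round_half_up(100 * n / nt, 1L) else rep(NA_real_, 4L)
    data.frame(species_label = d[[by]][1L], n_I = n[1L], n_II = n[2L],
               n_III = n[3L], n_IV = n[4L], n_unresolved = nu, n_total = nt,
               pct_I = pct[1L], pct_II = pct[2L], pct_III = pct[3L],
               pct_IV = pct[4L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
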