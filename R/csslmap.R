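#' Infer graphical-genotype segments from marker calls
#'
#' Maximal runs of identical marker calls become segments. The segment
#' *core* spans the outermost same-call markers of the run; the flanking
#' inter-marker gaps, where the recombination breakpoint must lie, are kept
#' as uncertainty bounds rather than split at midpoints. Missing calls are
#' bridged (skipped) and counted; a chromosome with no non-missing marker is
#' reported untyped via a message and contributes no segments.
#'
#' @param calls Data frame `line`, `marker`, `chrom`, `pos` (1-based bp),
#'   `call` in `D`/`R`/`H` (`NA` or `"missing"` for missing).
#' @param chrom_lengths Optional named vector; when given, the outer bounds
#'   of terminal segments extend to the chromosome ends.
#' @return Data frame of segments: `line`, `chrom`, `state`
#'   (donor/recurrent/het), `core_start`, `core_end`, `lower_bound`,
#'   `upper_bound` (the interval certainly containing the true segment
#'   boundary region: core plus flanking gaps).
#' @export
infer_segments <- function(calls, chrom_lengths = NULL) {
  state_of <- c(D = "donor", R = "recurrent", H = "het")
  out <- list()
  for (ln in unique(calls$line)) {
    for (ch in unique(calls$chrom[calls$line == ln])) {
      d <- calls[calls$line == ln & calls$chrom == ch, , drop = FALSE]
      d <- d[order(d$pos), , drop = FALSE]
      miss <- is.na(d$call) | d$call == "missing"
      if (sum(miss) > 0L)
        message("line ", ln, " ", ch, ": ", sum(miss), " missing call(s) bridged")
      d <- d[!miss, , drop = FALSE]
      if (nrow(d) == 0L) {
        message("line ", ln, " ", ch, ": no informative markers; untyped")
        next
      }
      r <- rle(d$call)
      hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
      chrom_end <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else NA_integer_
      for (j in seq_along(r$values)) {
        core_start <- d$pos[lo[j]]; core_end <- d$pos[hi[j]]
        lower <- if (j == 1L) 1L else d$pos[hi[j - 1L]] + 1L
        upper <- if (j == length(r$values)) chrom_end else d$pos[lo[j + 1L]] - 1L
        out[[length(out) + 1L]] <- data.frame(
          line = ln, chrom = ch, state = unname(state_of[r$values[j]]),
          core_start = core_start, core_end = core_end,
          lower_bound = lower, upper_bound = upper, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      state = character(), core_start = integer(),
                      core_end = integer(), lower_bound = integer(),
                      upper_bound = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Awned-spikelet ratio
#'
#' Percentage of spikelets on the main-stem panicle bearing an awn.
#'
#' @param awned_spikelets,total_spikelets Counts (vectorized).
#' @return Percentages; `NA` (with a message) where the total is zero.
#' @export
awned_spikelet_ratio <- function(awned_spikelets, total_spikelets) {
  if (any(awned_spikelets > total_spikelets, na.rm = TRUE))
    stop("awned_spikelets exceeds total_spikelets")
  zero <- !is.na(total_spikelets) & total_spikelets == 0L
  if (any(zero)) message(sum(zero), " observation(s) with zero spikelets: ratio undefined")
  ifelse(zero, NA_real_, 100 * awned_spikelets / total_spikelets)
}

#' Classify lines as awned across years
#'
#' A year counts as awned when the mean awn length exceeds `min_length_mm`
#' (strictly; awns must exceed 3 mm on mature grains to count) and at least
#' one awned spikelet was seen. A line is awned when enough years qualify —
#' by default two, because awns are a labile, environment-dependent
#' phenotype scored over a 2-to-3-year period.
#'
#' @param observations Data frame `line`, `year`, `awned_spikelets`,
#'   `total_spikelets`, `mean_awn_length_mm`.
#' @param min_years Minimum qualifying years (default 2).
#' @param min_length_mm Awn-length threshold in mm (default 3, strict `>`).
#' @return Data frame `line`, `n_years`, `n_awned_years`, `awned`.
#' @export
classify_awned <- function(observations, min_years = 2L, min_length_mm = 3) {
  yr_awned <- observations$mean_awn_length_mm > min_length_mm &
    observations$awned_spikelets > 0L
  agg <- stats::aggregate(yr_awned, by = list(line = observations$line), FUN = sum)
  nyr <- stats::aggregate(yr_awned, by = list(line = observations$line), FUN = length)
  data.frame(line = agg$line, n_years = nyr$x, n_awned_years = agg$x,
             awned = agg$x >= min_years, stringsAsFactors = FALSE)
}

#' Candidate awn loci from donor segments of awned lines
#'
#' Every donor core segment of an awned line is a candidate; where
#' candidates from different lines/panels overlap they are intersected, and
#' the emitted loci are the maximal intervals supported by at least
#' `min_support` candidate segments (computed as coverage slices over the
#' candidate set). Heterozygous segments are excluded by default (CSSL
#' panels are scored on donor homozygotes). Non-awned lines whose donor
#' segments overlap an emitted locus are reported as conflicts rather than
#' subtracted, since a carrier segment can miss the causal gene inside the
#' locus.
#'
#' @param segments Segment table from [infer_segments()]; an optional
#'   `panel` column is carried into the support listing.
#' @param awned Data frame `line`, `awned` ([classify_awned()] output).
#' @param min_support Minimum number of supporting candidate segments.
#' @param include_het Also treat het segments of awned lines as candidates.
#' @param combine `"intersect"` (default): emit coverage slices >=
#'   `min_support`; `"union"`: merge overlapping candidates and keep merged
#'   intervals whose distinct supporting lines reach `min_support`.
#' @return Data frame of loci: `chrom`, `start`, `end`, `n_support`,
#'   `lines` (comma-separated), `conflicts` (non-awned carrier lines).
#' @export
candidate_loci <- function(segments, awned, min_support = 2L,
                           include_het = FALSE,
                           combine = c("intersect", "union")) {
  combine <- match.arg(combine)
  states <- if (include_het) c("donor", "het") else "donor"
  awned_lines <- awned$line[awned$awned]
  cand <- segments[segments$state %in% states &
                     segments$line %in% awned_lines, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_support = integer(), lines = character(),
                      conflicts = character(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$core_start, cand$core_end))
  loci <- if (combine == "intersect") {
    cov <- GenomicRanges::coverage(gr)
    sl <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    GenomicRanges::GRanges(sl)
  } else {
    GenomicRanges::reduce(gr)
  }
  if (length(loci) == 0L) return(empty)
  ov <- GenomicRanges::findOverlaps(loci, gr)
  sup_lines <- split(cand$line[S4Vectors::subjectHits(ov)],
                     S4Vectors::queryHits(ov))
  n_support <- integer(length(loci)); lines <- character(length(loci))
  for (i in seq_along(loci)) {
    ls <- unique(sup_lines[[as.character(i)]])
    n_support[i] <- sum(S4Vectors::queryHits(ov) == i)  # segments, not lines
    lines[i] <- paste(sort(ls), collapse = ",")
  }
  keep <- if (combine == "union")
    vapply(seq_along(loci), function(i)
      length(unique(sup_lines[[as.character(i)]])) >= min_support, logical(1L))
  else rep(TRUE, length(loci))
  loci <- loci[keep]; n_support <- n_support[keep]; lines <- lines[keep]
  if (length(loci) == 0L) return(empty)
  # non-awned carriers overlapping each locus, reported not subtracted
  non <- segments[segments$state == "donor" &
                    !(segments$line %in% awned_lines), , drop = FALSE]
  conflicts <- character(length(loci))
  if (nrow(non) > 0L) {
    ngr <- GenomicRanges::GRanges(non$chrom,
                                  IRanges::IRanges(non$core_start, non$core_end))
    nov <- GenomicRanges::findOverlaps(loci, ngr)
    cl <- split(non$line[S4Vectors::subjectHits(nov)], S4Vectors::queryHits(nov))
    for (i in seq_along(loci)) {
      x <- unique(cl[[as.character(i)]])
      conflicts[i] <- if (is.null(x)) "" else paste(sort(x), collapse = ",")
    }
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
             start = GenomicRanges::start(loci), end = GenomicRanges::end(loci),
             n_support = n_support, lines = lines, conflicts = conflicts,
             stringsAsFactors = FALSE)
}

#' Catalogue of known awn genes and loci
#'
#' The three cloned genes with published coordinates — RAE1/An-1
#' (chr4:16731738-16735336), LABA1/An-2 (chr4:25959399-25963504) and
#' RAE2/GAD1 (chr8:23998787-24000176) — plus marker-mapped loci recorded as
#' chromosome-level tags (An9/An10 on chr1, qAWL2 on chr2, An7 on chr5,
#' RAE3 on chr6) whose base-pair intervals are not published.
#'
#' @return Data frame `name`, `chrom`, `start`, `end`, `level`
#'   (`gene`/`chromosome`).
#' @export
known_awn_genes <- function() {
  data.frame(
    name = c("RAE1/An-1", "LABA1/An-2", "RAE2/GAD1",
             "An9", "An10", "qAWL2", "An7", "RAE3"),
    chrom = c("chr4", "chr4", "chr8", "chr1", "chr1", "chr2", "chr5", "chr6"),
    start = c(16731738L, 25959399L, 23998787L, NA, NA, NA, NA, NA),
    end = c(16735336L, 25963504L, 24000176L, NA, NA, NA, NA, NA),
    level = c("gene", "gene", "gene", "chromosome", "chromosome",
              "chromosome", "chromosome", "chromosome"),
    stringsAsFactors = FALSE)
}

#' Annotate loci against the known-gene catalogue
#'
#' Labels each candidate locus with every overlapping catalogued gene;
#' chromosome-level tags match any locus on their chromosome. Loci with no
#' overlap are flagged novel.
#'
#' @param loci Locus table from [candidate_loci()] (`chrom`, `start`,
#'   `end`).
#' @param genes Gene catalogue in the [known_awn_genes()] schema.
#' @return `loci` with added `known_overlaps` (comma-separated) and `novel`.
#' @export
annotate_known <- function(loci, genes = known_awn_genes()) {
  if (!all(c("name", "chrom") %in% names(genes)))
    stop("malformed gene table: need columns name, chrom, start, end")
  labels <- vapply(seq_len(nrow(loci)), function(i) {
    hit <- genes$chrom == loci$chrom[i] &
      (is.na(genes$start) |
         (genes$start <= loci$end[i] & genes$end >= loci$start[i]))
    paste(genes$name[hit], collapse = ",")
  }, character(1L))
  loci$known_overlaps <- labels
  loci$novel <- labels == ""
  loci
}
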