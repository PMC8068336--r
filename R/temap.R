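#' Build an exact k-mer index of a reference
#'
#' Indexes every k-mer of every chromosome (forward strand) for exact
#' lookup of genomic positions. K-mers never span chromosome boundaries.
#'
#' @param sequences Named character vector of chromosome sequences, or an
#'   `awn_reference`.
#' @param k Odd k-mer length (default 31); must not exceed every
#'   chromosome's length.
#' @return An object of class `kmer_index`.
#' @export
index_reference <- function(sequences, k = 31L) {
  if (inherits(sequences, "awn_reference")) sequences <- sequences$sequences
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  lens <- nchar(sequences)
  if (all(k > lens)) stop("k larger than every chromosome")
  offsets <- c(0L, cumsum(lens))[seq_along(lens)]
  names(offsets) <- names(sequences)
  all_kmers <- vector("list", length(sequences))
  all_pos <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    L <- lens[i]
    if (k > L) next
    all_kmers[[i]] <- substring(sequences[[i]], 1:(L - k + 1L), k:L)
    all_pos[[i]] <- seq_len(L - k + 1L) + offsets[i]
  }
  env <- list2env(split(unlist(all_pos), unlist(all_kmers)),
                  hash = TRUE, parent = emptyenv())
  structure(list(k = k, env = env, chrom_names = names(sequences),
                 chrom_lengths = lens, offsets = offsets,
                 genome_raw = charToRaw(paste(sequences, collapse = ""))),
            class = "kmer_index")
}

# candidate verification for one read; returns placement row or NULL
.place_one <- function(seq_chars_raw, L, index, max_mismatch) {
  k <- index$k
  seq <- rawToChar(seq_chars_raw)
  offs <- unique(c(1L, (L - k) %/% 2L + 1L, L - k + 1L))
  cand <- integer(0)
  for (o in offs) {
    hits <- index$env[[substr(seq, o, o + k - 1L)]]
    if (!is.null(hits)) cand <- c(cand, hits - o + 1L)
  }
  if (!length(cand)) return(NULL)
  cand <- unique(cand)
  cand <- cand[cand >= 1L & cand + L - 1L <= length(index$genome_raw)]
  if (!length(cand)) return(NULL)
  ci <- findInterval(cand, index$offsets + 1L)
  ok <- cand >= index$offsets[ci] + 1L &
    cand + L - 1L <= index$offsets[ci] + index$chrom_lengths[ci]
  cand <- cand[ok]; ci <- ci[ok]
  if (!length(cand)) return(NULL)
  mm <- vapply(cand, function(g)
    sum(index$genome_raw[g:(g + L - 1L)] != seq_chars_raw), integer(1L))
  keep <- mm <= max_mismatch
  if (!any(keep)) return(NULL)
  mm <- mm[keep]; cand <- cand[keep]; ci <- ci[keep]
  best <- min(mm)
  bi <- which(mm == best)
  g <- cand[bi[1L]]; chrom_i <- ci[bi[1L]]
  list(chrom = index$chrom_names[chrom_i],
       start = g - index$offsets[chrom_i] - 1L,   # 0-based
       end = g - index$offsets[chrom_i] - 1L + L, # half-open
       n_best_hits = length(bi), mismatches = best)
}

#' Place reads on an indexed reference
#'
#' Candidate loci are seeded from up to three k-mers per read (both ends and
#' the middle, so one sequencing error cannot hide every seed), then
#' verified by full-length comparison allowing at most `max_mismatch`
#' substitutions. `n_best_hits` counts the loci tied at the minimal mismatch
#' count; reads with `n_best_hits > 1` are multi-mapped and contribute to no
#' coverage window. Reads shorter than k are skipped and counted.
#'
#' @param reads Data frame with `read_id` and `seq` (e.g. from
#'   [simulate_reads()] or [read_fastq()]), or a character vector.
#' @param index A [index_reference()] result.
#' @param max_mismatch Maximum substitutions for a valid placement.
#' @return Data frame of placements: `read_id`, `chrom`, `start` (0-based),
#'   `end` (half-open), `n_best_hits`, `mismatches`. Unplaced reads are
#'   absent; counts of unplaced and skipped reads are attached as
#'   attributes `n_unplaced` and `n_skipped`.
#' @export
place_reads <- function(reads, index, max_mismatch = 5L) {
  if (is.character(reads))
    reads <- data.frame(read_id = if (is.null(names(reads)))
      paste0("r", seq_along(reads)) else names(reads),
      seq = unname(reads), stringsAsFactors = FALSE)
  stopifnot(inherits(index, "kmer_index"))
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  skip <- lens < index$k
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (skip[i]) next
    res <- .place_one(charToRaw(reads$seq[i]), lens[i], index, max_mismatch)
    if (!is.null(res)) rows[[i]] <- res  # [[<- NULL would shrink the list
  }
  placed <- !vapply(rows, is.null, logical(1L)) & !skip
  out <- data.frame(
    read_id = reads$read_id[placed],
    chrom = vapply(rows[placed], `[[`, character(1L), "chrom"),
    start = vapply(rows[placed], `[[`, numeric(1L), "start"),
    end = vapply(rows[placed], `[[`, numeric(1L), "end"),
    n_best_hits = vapply(rows[placed], `[[`, integer(1L), "n_best_hits"),
    mismatches = vapply(rows[placed], `[[`, integer(1L), "mismatches"),
    stringsAsFactors = FALSE)
  if (any(skip))
    message(sum(skip), " read(s) shorter than k = ", index$k, " skipped")
  attr(out, "n_skipped") <- sum(skip)
  attr(out, "n_unplaced") <- sum(!placed & !skip)
  out
}

#' Place a single read
#'
#' @inheritParams place_reads
#' @param read Single read sequence (character scalar).
#' @return One-row placement data frame, or `NULL` when the read has no
#'   acceptable placement. A multi-mapped read is returned with
#'   `n_best_hits > 1` (excluded from coverage downstream).
#' @export
place_read <- function(read, index, max_mismatch = 5L) {
  p <- place_reads(read, index, max_mismatch = max_mismatch)
  if (nrow(p) == 0L) NULL else p
}

# reference-consumed length of a CIGAR string (M/D/N/=/X advance)
.cigar_reflen <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops)) return(NA_integer_)
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Ingest alignments from a SAM file
#'
#' Alternative entry point when reads were aligned externally. Unmapped
#' records (FLAG 0x4 or CIGAR `*`) are dropped. Secondary (0x100) and
#' supplementary (0x800) records, and primary records with mapping quality
#' 0, mark the read multi-mapped (`n_best_hits = 2`).
#'
#' @param path SAM file, with or without header.
#' @return Placement data frame as from [place_reads()].
#' @export
ingest_sam <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "@")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(read_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_best_hits = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad))
    stop("malformed SAM line ", lineno[bad[1L]], ": fewer than 11 fields")
  flag <- as.integer(vapply(fields, `[[`, character(1L), 2L))
  if (anyNA(flag))
    stop("malformed SAM line ", lineno[which(is.na(flag))[1L]],
         ": non-numeric FLAG")
  cigar <- vapply(fields, `[[`, character(1L), 6L)
  mapped <- bitwAnd(flag, 4L) == 0L & cigar != "*"
  fields <- fields[mapped]; flag <- flag[mapped]; cigar <- cigar[mapped]
  pos <- as.integer(vapply(fields, `[[`, character(1L), 4L))
  mapq <- as.integer(vapply(fields, `[[`, character(1L), 5L))
  multi <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L | mapq == 0L
  reflen <- vapply(cigar, .cigar_reflen, integer(1L), USE.NAMES = FALSE)
  data.frame(read_id = vapply(fields, `[[`, character(1L), 1L),
             chrom = vapply(fields, `[[`, character(1L), 3L),
             start = pos - 1L, end = pos - 1L + reflen,
             n_best_hits = ifelse(multi, 2L, 1L),
             mismatches = NA_integer_, stringsAsFactors = FALSE)
}

#' Breadth of coverage over a window
#'
#' Counts window positions overlapped by at least one uniquely placed read
#' (placements with `n_best_hits > 1` are ignored). Breadth — the fraction
#' of covered positions — is the statistic the TE caller thresholds, in
#' contrast to depth.
#'
#' @param placements Placement data frame ([place_reads()]/[ingest_sam()]).
#' @param window One-row data frame or list with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return List with `covered_bp` and `fraction`.
#' @export
breadth <- function(placements, window) {
  wlen <- window$end - window$start + 1L
  p <- placements[placements$n_best_hits == 1L &
                    placements$chrom == window$chrom, , drop = FALSE]
  if (nrow(p) == 0L) return(list(covered_bp = 0L, fraction = 0))
  ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))  # to 1-based
  ir <- IRanges::restrict(ir, start = window$start, end = window$end)
  covered <- sum(IRanges::width(ir))
  list(covered_bp = as.integer(covered), fraction = covered / wlen)
}

#' Call TE presence/absence from boundary-window breadths
#'
#' Implements the breadth rules: the insertion is *present* when breadth
#' exceeds the present threshold both inside the TE (> 160/200 bp at the
#' default 0.80) and outside it (> 160/200 bp); *absent* when breadth inside
#' stays below the absent threshold (< 40/200 bp at the default 0.20) while
#' outside still exceeds the present threshold. Anything between the two
#' rules is a `no_call`. Inequalities are strict, as the rules are stated.
#' By default both TE edges must satisfy the rule (conservative);
#' `edges = "either"` relaxes to one edge.
#'
#' @param breadths Named numeric vector of the four breadth fractions:
#'   `inside_left`, `outside_left`, `inside_right`, `outside_right`.
#' @param present_threshold,absent_threshold Breadth thresholds.
#' @param edges `"both"` (default) or `"either"`.
#' @param accession_id Optional id carried into the result.
#' @param covered_bp Optional named integer vector (same names) of covered
#'   positions per window.
#' @return One-row data frame (`TECallResult`): accession id, four breadth
#'   fractions, optional covered bp, and `status` in
#'   present/absent/no_call.
#' @export
call_te <- function(breadths, present_threshold = 0.80, absent_threshold = 0.20,
                    edges = c("both", "either"), accession_id = NA_character_,
                    covered_bp = NULL) {
  edges <- match.arg(edges)
  need <- c("inside_left", "outside_left", "inside_right", "outside_right")
  if (!all(need %in% names(breadths)))
    stop("breadths must be named: ", paste(need, collapse = ", "))
  b <- breadths[need]
  if (any(b < 0) || any(b > 1)) stop("breadth outside [0, 1]")
  edge_status <- function(inside, outside) {
    if (inside > present_threshold && outside > present_threshold) "present"
    else if (inside < absent_threshold && outside > present_threshold) "absent"
    else "no_call"
  }
  left <- edge_status(b[["inside_left"]], b[["outside_left"]])
  right <- edge_status(b[["inside_right"]], b[["outside_right"]])
  status <- if (edges == "both") {
    if (left == "present" && right == "present") "present"
    else if (left == "absent" && right == "absent") "absent"
    else "no_call"
  } else {
    if (left == "present" || right == "present") "present"
    else if (left == "absent" || right == "absent") "absent"
    else "no_call"
  }
  out <- data.frame(accession_id = accession_id,
                    breadth_inside_left = b[["inside_left"]],
                    breadth_outside_left = b[["outside_left"]],
                    breadth_inside_right = b[["inside_right"]],
                    breadth_outside_right = b[["outside_right"]],
                    status = status, stringsAsFactors = FALSE)
  if (!is.null(covered_bp))
    for (w in need) out[[paste0("covered_", w)]] <- covered_bp[[w]]
  out
}

#' Breadths over the four boundary windows
#'
#' @param placements Placement data frame.
#' @param windows Data frame of the four windows (`awn_reference$windows`).
#' @return List with `fractions` and `covered_bp`, both named by window.
#' @export
window_breadths <- function(placements, windows) {
  res <- lapply(seq_len(nrow(windows)), function(i)
    breadth(placements, windows[i, ]))
  names(res) <- windows$name
  list(fractions = vapply(res, `[[`, numeric(1L), "fraction"),
       covered_bp = vapply(res, `[[`, integer(1L), "covered_bp"))
}

#' End-to-end TE call for one accession's reads
#'
#' Places the reads on the TE-containing reference, computes breadth over
#' the four boundary windows, and applies the calling rules.
#'
#' @param reads Read data frame (or character vector of sequences).
#' @param index [index_reference()] of the TE-containing reference.
#' @param windows Boundary-window table (`awn_reference$windows`).
#' @param accession_id Id for the result row.
#' @param max_mismatch Passed to [place_reads()].
#' @param ... Passed to [call_te()].
#' @return One-row `TECallResult` data frame.
#' @export
call_te_accession <- function(reads, index, windows,
                              accession_id = NA_character_,
                              max_mismatch = 5L, ...) {
  pl <- place_reads(reads, index, max_mismatch = max_mismatch)
  wb <- window_breadths(pl, windows)
  call_te(wb$fractions, accession_id = accession_id,
          covered_bp = wb$covered_bp, ...)
}

#' Seamless flank coverage at an insertion site
#'
#' For taxa whose flanking sequence diverges from the TE-containing
#' reference, reads can instead be placed on an alternative (TE-free)
#' reference of their own taxon; seamless breadth across the insertion
#' point then indicates no insertion. This helper measures breadth over the
#' window spanning `flank` bp either side of the site.
#'
#' @param placements Placements on the alternative reference.
#' @param chrom,site Chromosome and 1-based insertion point on that
#'   reference.
#' @param flank Half-window size in bp (default 200).
#' @return List with `covered_bp`, `fraction` and `seamless` (fraction
#'   equal to 1).
#' @export
flank_continuity <- function(placements, chrom, site, flank = 200L) {
  b <- breadth(placements, list(chrom = chrom, start = site - flank,
                                end = site + flank - 1L))
  c(b, list(seamless = b$fraction == 1))
}
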