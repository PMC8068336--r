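test_that("k-mer index reports exact positions and respects chromosome bounds", {
  idx <- index_reference(c(chrA = "ACGTACGT"), k = 5L)
  expect_equal(idx$env[["ACGTA"]], 1L)
  expect_equal(idx$env[["CGTAC"]], 2L)
  expect_null(idx$env[["AAAAA"]])

  # no k-mer spans the junction of concatenated chromosomes
  idx2 <- index_reference(c(chrA = "AAAAAA", chrB = "CCCCCC"), k = 5L)
  expect_null(idx2$env[["AAACC"]])
  expect_null(idx2$env[["AACCC"]])

  expect_error(index_reference(c(chrA = "ACGT"), k = 7L), "larger than every")
  expect_error(index_reference(c(chrA = "ACGTACGT"), k = 4L), "odd")
})

test_that("read placement is unique, excluded on ties, and skips short reads", {
  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 3000L, replace = TRUE),
                collapse = "")
  # plant the same 100-mer at two loci
  unit <- substr(base, 501L, 600L)
  genome <- paste0(substr(base, 1L, 2000L), unit,
                   substr(base, 2101L, 3000L))
  idx <- index_reference(c(chr1 = genome), k = 31L)

  uniq_read <- substr(genome, 1001L, 1100L)
  p <- place_read(uniq_read, idx)
  expect_equal(p$start, 1000L)       # 0-based
  expect_equal(p$end, 1100L)         # half-open
  expect_equal(p$n_best_hits, 1L)
  expect_equal(p$mismatches, 0L)

  # read equal to the repeat unit: two equally good loci, excluded
  p2 <- place_read(unit, idx)
  expect_equal(p2$n_best_hits, 2L)

  # and excluded reads contribute to no window
  win <- list(chrom = "chr1", start = 501L, end = 600L)
  expect_equal(breadth(p2, win)$covered_bp, 0L)

  expect_message(p3 <- place_reads(data.frame(read_id = "tiny", seq = "ACGT"),
                                   idx), "skipped")
  expect_equal(nrow(p3), 0L)
  expect_equal(attr(p3, "n_skipped"), 1L)

  # one substitution is tolerated and still placed at the truth locus
  mut <- paste0("T", substr(uniq_read, 2L, 100L))
  if (substr(uniq_read, 1L, 1L) == "T") mut <- paste0("A", substr(uniq_read, 2L, 100L))
  p4 <- place_read(mut, idx)
  expect_equal(p4$start, 1000L)
  expect_equal(p4$mismatches, 1L)
})

test_that("SAM ingestion applies flag, MAPQ and CIGAR semantics", {
  sam <- c("@HD\tVN:1.6",
           "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
           "r2\t256\tchr1\t201\t60\t50M\t*\t0\t0\t*\t*",
           "r3\t0\tchr1\t301\t0\t50M\t*\t0\t0\t*\t*",
           "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
           "r5\t0\tchr1\t401\t60\t10M5D10M\t*\t0\t0\t*\t*")
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  p <- ingest_sam(f)
  expect_equal(nrow(p), 4L)                       # unmapped r4 dropped
  expect_equal(p$n_best_hits[p$read_id == "r1"], 1L)
  expect_equal(p$n_best_hits[p$read_id == "r2"], 2L)  # secondary
  expect_equal(p$n_best_hits[p$read_id == "r3"], 2L)  # MAPQ 0
  expect_equal(p$start[p$read_id == "r1"], 100L)
  expect_equal(p$end[p$read_id == "r5"], 400L + 25L)  # 10M5D10M consumes 25

  empty <- tempfile(fileext = ".sam")
  writeLines(character(0), empty)
  expect_equal(nrow(ingest_sam(empty)), 0L)

  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "broken\tline"), bad)
  expect_error(ingest_sam(bad), "line 2")
})

test_that("breadth matches hand-computed and brute-force values", {
  win <- list(chrom = "c", start = 1001L, end = 1200L)
  empty <- data.frame(read_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_best_hits = integer(), mismatches = integer())
  expect_equal(breadth(empty, win), list(covered_bp = 0L, fraction = 0))

  one <- data.frame(read_id = "a", chrom = "c", start = 1000, end = 1200,
                    n_best_hits = 1L, mismatches = 0L)
  expect_equal(breadth(one, win), list(covered_bp = 200L, fraction = 1))

  # two 120-bp reads at window offsets 0 and 100 -> full cover
  two <- data.frame(read_id = c("a", "b"), chrom = "c",
                    start = c(1000, 1100), end = c(1120, 1220),
                    n_best_hits = 1L, mismatches = 0L)
  expect_equal(breadth(two, win)$fraction, 1)
  # at offsets 0 and 130 -> gap 120..129 within the window
  gap <- data.frame(read_id = c("a", "b"), chrom = "c",
                    start = c(1000, 1130), end = c(1120, 1250),
                    n_best_hits = 1L, mismatches = 0L)
  expect_equal(breadth(gap, win), list(covered_bp = 190L, fraction = 0.95))

  # property: equality with the per-position oracle on random instances
  set.seed(42)
  for (i in 1:30) {
    n <- sample(0:15, 1L)
    pl <- data.frame(read_id = as.character(seq_len(n)),
                     chrom = sample(c("c", "d"), n, replace = TRUE),
                     start = sample(900:1300, n, replace = TRUE),
                     n_best_hits = sample(1:2, n, replace = TRUE,
                                          prob = c(0.8, 0.2)),
                     mismatches = rep(0L, n))
    pl$end <- pl$start + sample(20:150, n, replace = TRUE)
    expect_equal(breadth(pl, win), oracle_breadth(pl, win))
  }
})

test_that("breadth never decreases when reads are added", {
  win <- list(chrom = "c", start = 101L, end = 300L)
  set.seed(7)
  pl <- data.frame(read_id = as.character(1:20), chrom = "c",
                   start = sample(1:400, 20L, replace = TRUE),
                   n_best_hits = 1L, mismatches = 0L)
  pl$end <- pl$start + 50L
  fractions <- vapply(1:20, function(n)
    breadth(pl[seq_len(n), ], win)$fraction, numeric(1L))
  expect_true(all(diff(fractions) >= 0))
})

test_that("TE calling follows the 80/20 breadth rules with strict inequalities", {
  b <- function(il, ol, ir, or) c(inside_left = il, outside_left = ol,
                                  inside_right = ir, outside_right = or)
  expect_equal(call_te(b(0.90, 0.90, 0.95, 0.90))$status, "present")
  expect_equal(call_te(b(0.05, 0.90, 0.10, 0.85))$status, "absent")
  expect_equal(call_te(b(0.50, 0.90, 0.50, 0.90))$status, "no_call")
  # strict: exactly 160/200 on an inside window is not enough for present
  expect_equal(call_te(b(0.80, 0.90, 0.90, 0.90))$status, "no_call")
  # absent requires outside breadth strictly above the present threshold
  expect_equal(call_te(b(0.05, 0.75, 0.05, 0.75))$status, "no_call")
  # both edges must agree by default; either-edge mode relaxes
  mixed <- b(0.90, 0.90, 0.50, 0.90)
  expect_equal(call_te(mixed)$status, "no_call")
  expect_equal(call_te(mixed, edges = "either")$status, "present")
  expect_error(call_te(b(1.2, 0.9, 0.9, 0.9)), "outside \\[0, 1\\]")
  expect_error(call_te(c(a = 1)), "named")
})

test_that("a planted TE-edge repeat cannot flip a truth-absent accession", {
  spec <- small_spec(seed = 21L)
  ref <- build_reference(spec)
  s <- spec$te_site
  # plant the left TE edge (first 400 bp of the TE) at a second locus on
  # chr8, in reference and accession alike: a genuine genomic repeat
  edge <- substr(ref$sequences[["chr4"]], s, s + 399L)
  plant <- function(seqs) {
    substr(seqs[["chr8"]], 15001L, 15400L) <- edge
    seqs
  }
  ref$sequences <- plant(ref$sequences)
  acc <- make_accession_genome(ref, accession_profile("x", te_present = FALSE))
  # (profile has no chr8 edits, so the accession keeps the planted copy)
  expect_equal(substr(acc$sequences[["chr8"]], 15001L, 15400L), edge)

  idx <- index_reference(ref)
  reads <- simulate_reads(acc, read_sim_params(depth = 20, error_rate = 0,
                                               seed = 22L))
  res <- call_te_accession(reads, idx, ref$windows, "x")
  expect_equal(res$status, "absent")
  expect_lt(res$breadth_inside_left, 0.2)
  expect_lt(res$breadth_inside_right, 0.2)
})

test_that("seamless flank coverage is detected on an alternative reference", {
  # a TE-free reference of the accession's own taxon: reads across the
  # insertion point cover it seamlessly
  spec <- small_spec(seed = 31L, embed_repeats = FALSE)
  ref <- build_reference(spec)
  acc <- make_accession_genome(ref, accession_profile("y", te_present = FALSE))
  alt_idx <- index_reference(acc$sequences)
  reads <- simulate_reads(acc, read_sim_params(depth = 20, error_rate = 0,
                                               seed = 32L))
  pl <- place_reads(reads, alt_idx)
  fc <- flank_continuity(pl, "chr4", spec$te_site)
  expect_true(fc$seamless)
  expect_equal(fc$fraction, 1)
})
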