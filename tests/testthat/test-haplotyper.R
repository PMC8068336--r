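test_that("RAE1 haplotypes follow TE status and the exon-2 deletion", {
  expect_equal(assign_rae1_hap("absent", FALSE), "hap1")
  expect_equal(assign_rae1_hap("absent", TRUE), "hap2")
  expect_equal(assign_rae1_hap("present", FALSE), "hap3")
  expect_equal(assign_rae1_hap("present", TRUE), "hap4")
  expect_equal(assign_rae1_hap("no_call", FALSE), "unresolved")
  expect_equal(assign_rae1_hap(c("absent", "present"), c(TRUE, FALSE)),
               c("hap2", "hap3"))
  expect_error(assign_rae1_hap("maybe", FALSE))
})

test_that("RAE2 haplotypes are read off the diagnostic indel table", {
  fx <- rae2_cds_fixture()
  diag <- rae2_diagnostics(fx)
  no_var <- data.frame(pos = integer(), ref = character(), alt = character())
  expect_equal(assign_rae2_hap(no_var, diag), "hap1")

  for (h in paste0("hap", 2:6)) {
    v <- fixture_variant(fx, h)
    expect_equal(assign_rae2_hap(v, diag), h)
  }

  # a SNP alone is not diagnostic
  snp <- data.frame(pos = 50L, ref = "G", alt = "A")
  expect_equal(assign_rae2_hap(snp, diag), "hap1")

  # two conflicting diagnostic indels name both haplotypes
  both <- rbind(fixture_variant(fx, "hap2"), fixture_variant(fx, "hap3"))
  expect_error(assign_rae2_hap(both, diag), "hap2 and hap3")

  # an unconfigured frameshifting indel cannot be classified
  odd <- data.frame(pos = 40L, ref = "GA", alt = "G")
  expect_warning(h <- assign_rae2_hap(odd, diag), "unconfigured")
  expect_equal(h, "unresolved")

  # a heterozygous diagnostic site in an inbred accession is unresolved
  het <- cbind(fixture_variant(fx, "hap3"), gt = "het")
  expect_warning(hh <- assign_rae2_hap(het, diag), "heterozygous")
  expect_equal(hh, "unresolved")
})

test_that("CDS reconstruction matches an independent string-edit oracle", {
  cds <- rae2_cds_fixture()$cds_sequence
  expect_identical(reconstruct_cds(cds, NULL), cds)

  del6 <- fixture_variant(rae2_cds_fixture(), "hap2")
  out <- reconstruct_cds(cds, del6)
  expect_equal(nchar(out), nchar(cds) - 6L)
  expect_equal(nchar(out) %% 3L, 0L)

  # 1-bp deletion then SNP downstream equals the oracle's coordinate-order edit
  v <- rbind(data.frame(pos = 75L, ref = substr(cds, 75, 76),
                        alt = substr(cds, 75, 75)),
             data.frame(pos = 100L, ref = substr(cds, 100, 100), alt = "A"))
  expect_identical(reconstruct_cds(cds, v), oracle_apply_variants(cds, v))

  # property: random edits on random CDSs
  set.seed(99)
  for (i in 1:20) {
    s <- random_cds(60L)
    picks <- sort(sample(5:(nchar(s) - 10L), 3L))
    picks <- picks[c(TRUE, diff(picks) > 5L)]  # keep edits disjoint
    v <- do.call(rbind, lapply(picks, function(p) {
      type <- sample(c("snp", "del", "ins"), 1L)
      if (type == "snp") data.frame(pos = p, ref = substr(s, p, p),
                                    alt = setdiff(c("A", "C", "G", "T"),
                                                  substr(s, p, p))[1L])
      else if (type == "del") data.frame(pos = p, ref = substr(s, p, p + 2L),
                                         alt = substr(s, p, p))
      else data.frame(pos = p, ref = substr(s, p, p),
                      alt = paste0(substr(s, p, p), "GT"))
    }))
    expect_identical(reconstruct_cds(s, v), oracle_apply_variants(s, v))
  }

  expect_error(reconstruct_cds(cds, data.frame(pos = 10L, ref = "TTTT",
                                               alt = "T")), "mismatch")
  expect_error(reconstruct_cds(cds, rbind(
    data.frame(pos = 10L, ref = substr(cds, 10, 13), alt = substr(cds, 10, 10)),
    data.frame(pos = 12L, ref = substr(cds, 12, 12), alt = "A"))), "overlap")
})

test_that("translation halts at the first stop and matches Biostrings", {
  expect_equal(translate_cds("ATGTGTTAA"), "MC")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGTGTTAACCC"), "MC")   # post-stop ignored
  expect_equal(translate_cds("ATGTGTTA"), "MC")       # trailing partial dropped
  expect_error(translate_cds("TTGTGTTAA"), "ATG")
  expect_error(translate_cds("ATGNNNTAA"), "ambiguity")

  set.seed(123)
  for (i in 1:10) {
    cds <- random_cds(300L)
    expect_identical(translate_cds(cds), oracle_translate(cds))
  }
  # frame-shifted suffixes too (stop may appear anywhere or not at all)
  for (i in 1:10) {
    cds <- paste0("ATG", substr(random_cds(100L), sample(2:50, 1L), 250L))
    expect_identical(translate_cds(cds), oracle_translate(cds))
  }
})

test_that("the RAE2 fixture yields the documented cysteine classes", {
  fx <- rae2_cds_fixture()
  ms <- fx$mature_start
  cys <- function(label = NULL) {
    cds <- fx$cds_sequence
    if (!is.null(label)) cds <- reconstruct_cds(cds, fixture_variant(fx, label))
    count_cysteines(translate_cds(cds), ms)
  }
  expect_equal(cys(), 6L)          # functional 6C peptide
  expect_equal(cys("hap2"), 6L)    # in-frame deletion keeps 6C
  expect_equal(cys("hap3"), 4L)    # truncation destroys Cys 5 and 6
  expect_equal(cys("hap4"), 7L)
  expect_equal(cys("hap5"), 7L)
  expect_equal(cys("hap6"), 7L)
})

test_that("functional flags and groups enumerate the 2x2 combinations", {
  expect_equal(call_function("hap1", "hap1", 6L),
               list(rae1_functional = TRUE, rae2_functional = TRUE))
  expect_equal(call_function("hap3", "hap2", 6L)$rae1_functional, FALSE)
  expect_equal(call_function("hap2", "hap3", 4L),
               list(rae1_functional = FALSE, rae2_functional = FALSE))
  expect_true(is.na(call_function("unresolved", "hap1", 6L)$rae1_functional))

  expect_equal(assign_group(TRUE, TRUE), "I")
  expect_equal(assign_group(TRUE, FALSE), "II")
  expect_equal(assign_group(FALSE, TRUE), "III")
  expect_equal(assign_group(FALSE, FALSE), "IV")
  combos <- expand.grid(r1 = c(TRUE, FALSE), r2 = c(TRUE, FALSE))
  expect_setequal(mapply(assign_group, combos$r1, combos$r2),
                  c("I", "II", "III", "IV"))
  expect_equal(assign_group(NA, TRUE), "unresolved")
})

test_that("pipeline group output equals the truth group for every profile", {
  edits <- c("none", "del6", "del1", "del2a", "del2b", "ins1")
  grid <- expand.grid(te = c(TRUE, FALSE), del = c(TRUE, FALSE),
                      edit = edits, stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(grid)), function(i)
    accession_profile(sprintf("G%02d", i), "grid", grid$te[i], grid$del[i],
                      grid$edit[i]))
  calls <- classify_profiles(profiles)

  truth_r1 <- !grid$te & !grid$del
  truth_r2 <- grid$edit %in% c("none", "del6")
  truth_group <- ifelse(truth_r1 & truth_r2, "I",
                        ifelse(truth_r1, "II", ifelse(truth_r2, "III", "IV")))
  expect_equal(calls$group, truth_group)
  # and the cysteine counts behind the flags
  expect_equal(calls$cys_count %in% c(4L, 6L, 7L), rep(TRUE, nrow(grid)))
  expect_equal(calls$cys_count == 6L, truth_r2)

  # group assignment is invariant to the order of variants
  fx1 <- rae1_cds_fixture(); fx2 <- rae2_cds_fixture()
  p <- accession_profile("ord", "s", FALSE, TRUE, "del1")
  v <- awnloci:::profile_variants(p, fx1, fx2)
  fwd <- classify_accession("ord", "s", "absent", v, fx1, fx2)
  bwd <- classify_accession("ord", "s", "absent", v[rev(seq_len(nrow(v))), ],
                            fx1, fx2)
  expect_equal(fwd$group, bwd$group)
  expect_equal(fwd$rae2_hap, bwd$rae2_hap)

  # a no_call TE status propagates to an unresolved group
  unres <- classify_accession("u", "s", "no_call", NULL, fx1, fx2)
  expect_equal(unres$rae1_hap, "unresolved")
  expect_equal(unres$group, "unresolved")
})

test_that("group frequencies use half-up one-decimal percentages", {
  mk <- function(groups, species = "sp") data.frame(
    species_label = rep(species, length(groups)), group = groups,
    stringsAsFactors = FALSE)

  tab <- summarize_groups(mk(rep(c("I", "II", "III", "IV"), c(1, 1, 4, 15))))
  expect_equal(tab$n_total, 21L)
  expect_equal(tab$pct_IV, 71.4)
  expect_equal(tab$pct_III, 19.0)

  tab2 <- summarize_groups(mk(rep(c("I", "II", "III", "IV"), c(3, 3, 1, 5))))
  expect_equal(tab2$pct_I, 25.0)
  expect_equal(tab2$pct_IV, 41.7)
  expect_equal(tab2$pct_III, 8.3)

  # half-up at the boundary: 1/16 = 6.25 -> 6.3
  tab3 <- summarize_groups(mk(rep(c("II", "I"), c(1, 15))))
  expect_equal(tab3$pct_II, 6.3)

  single <- summarize_groups(mk("III"))
  expect_equal(single$pct_III, 100.0)

  expect_equal(nrow(summarize_groups(mk(character(0)))), 0L)

  # percentages sum to 100 within rounding slack, species by species
  set.seed(17)
  for (i in 1:15) {
    g <- sample(c("I", "II", "III", "IV"), sample(3:40, 1L), replace = TRUE)
    t <- summarize_groups(mk(g))
    expect_lt(abs(t$pct_I + t$pct_II + t$pct_III + t$pct_IV - 100), 0.2 + 1e-9)
  }

  # unresolved calls are counted but excluded from the denominator
  t4 <- summarize_groups(mk(c("I", "I", "unresolved")))
  expect_equal(t4$n_unresolved, 1L)
  expect_equal(t4$n_total, 2L)
  expect_equal(t4$pct_I, 100.0)
})
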