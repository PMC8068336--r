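# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation it checks.

# translation via Biostrings (codon table owned by Biostrings, not ours)
oracle_translate <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  pep <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)))))
  sub("\\*.*$", "", pep)
}

# variant application by left-to-right piecewise assembly (implementation
# edits right-to-left in place)
oracle_apply_variants <- function(seq, variants) {
  if (nrow(variants) == 0L) return(seq)
  v <- variants[order(variants$pos), , drop = FALSE]
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(v))) {
    pieces <- c(pieces, substr(seq, cursor, v$pos[i] - 1L), v$alt[i])
    cursor <- v$pos[i] + nchar(v$ref[i])
  }
  paste0(paste(pieces, collapse = ""), substr(seq, cursor, nchar(seq)))
}

# per-position brute-force breadth
oracle_breadth <- function(placements, window) {
  p <- placements[placements$n_best_hits == 1L &
                    placements$chrom == window$chrom, , drop = FALSE]
  covered <- 0L
  for (pos in window$start:window$end) {
    if (any(p$start + 1L <= pos & p$end >= pos)) covered <- covered + 1L
  }
  list(covered_bp = covered,
       fraction = covered / (window$end - window$start + 1L))
}

# a compact genome spec for fast end-to-end tests
small_spec <- function(seed = 1L, ...) {
  synthetic_genome_spec(chrom_lengths = c(chr4 = 30000L, chr8 = 20000L),
                        te_site = 15001L, rae2_start = 10001L, seed = seed, ...)
}

# random CDS of n codons (no internal stop, ATG start, TAA end)
random_cds <- function(n_codons) {
  codons <- names(awnloci:::.CODON_TABLE)
  body <- sample(codons[awnloci:::.CODON_TABLE != "*"], n_codons - 2L,
                 replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}
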