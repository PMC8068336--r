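# Standard genetic code, hard-coded so that translation semantics
# (halt at first in-frame stop, ignore trailing partial codon) are
# owned by this package and can be cross-checked against
# Biostrings::translate in the test suite.
.CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a coding sequence
#'
#' Standard-code translation of a CDS, terminating at the first in-frame
#' stop codon (the stop itself is not emitted). A trailing partial codon is
#' ignored, so frame-shifted alleles whose reading frame runs off the end of
#' the sequence translate cleanly. This models the biology of frameshift
#' alleles: a premature stop truncates the peptide, an abolished stop reads
#' through into downstream sequence.
#'
#' @param cds Nucleotide string (A/C/G/T only). Must begin with `ATG`.
#' @return Single amino-acid string (one-letter code), possibly empty.
#' @examples
#' translate_cds("ATGTGTTAA")  # "MC"
#' translate_cds("ATGTAA")     # "M"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    stop("CDS contains ambiguity or non-nucleotide codes; only A/C/G/T are translated")
  if (substr(cds, 1L, 3L) != "ATG")
    stop("CDS does not start with ATG")
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(.CODON_TABLE[codons])
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Apply variants to a coding sequence
#'
#' Rebuilds an alternate CDS from a reference CDS and a set of anchored
#' substitutions/indels given in 1-based CDS coordinates. Variants are
#' applied right-to-left so that earlier coordinates stay valid while later
#' edits change the sequence length.
#'
#' @param ref_cds Reference nucleotide string.
#' @param variants Data frame with columns `pos` (1-based CDS position of the
#'   first ref base), `ref` (reference bases, length >= 1) and `alt`
#'   (alternate bases, length >= 1); VCF-style anchored representation for
#'   indels. May have zero rows.
#' @return The edited nucleotide string.
#' @export
reconstruct_cds <- function(ref_cds, variants) {
  stopifnot(is.character(ref_cds), length(ref_cds) == 1L)
  if (is.null(variants) || nrow(variants) == 0L) return(ref_cds)
  v <- variants[order(variants$pos), , drop = FALSE]
  ends <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos < 1L) || any(ends > nchar(ref_cds)))
    stop("variant outside CDS bounds")
  if (nrow(v) > 1L && any(v$pos[-1L] <= ends[-nrow(v)]))
    stop("overlapping variants: ",
         paste(v$pos[c(which(v$pos[-1L] <= ends[-nrow(v)]), which(v$pos[-1L] <= ends[-nrow(v)]) + 1L)],
               collapse = ", "))
  out <- ref_cds
  for (i in rev(seq_len(nrow(v)))) {
    if (substr(out, v$pos[i], ends[i]) != toupper(v$ref[i]))
      stop("reference allele mismatch at CDS position ", v$pos[i],
           ": expected ", v$ref[i], ", found ", substr(out, v$pos[i], ends[i]))
    out <- paste0(substr(out, 1L, v$pos[i] - 1L), toupper(v$alt[i]),
                  substr(out, ends[i] + 1L, nchar(out)))
  }
  out
}

#' Count mature-peptide cysteines
#'
#' Counts cysteine residues at or after the mature-peptide start. Six mature
#' cysteines are required for a functional RAE2 peptide (they form the
#' disulfide bonds of the EPFL fold); frameshift alleles shift the count to
#' 4 or 7.
#'
#' @param peptide Amino-acid string (one-letter code).
#' @param mature_start 1-based residue index where the mature peptide begins
#'   (everything before it is signal peptide).
#' @return Integer cysteine count.
#' @export
count_cysteines <- function(peptide, mature_start) {
  stopifnot(length(peptide) == 1L, mature_start >= 1L,
            mature_start <= nchar(peptide) + 1L)
  mature <- substr(peptide, mature_start, nchar(peptide))
  lengths(regmatches(mature, gregexpr("C", mature, fixed = TRUE)))
}

# Round half away from zero to `digits` decimals. base::round() rounds half
# to even; frequency tables here follow the convention that e.g. 6.25 -> 6.3.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All generators route randomness through
# this so that identical seeds give byte-identical outputs regardless of the
# surrounding session.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
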