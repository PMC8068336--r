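#' Construct a CDS fixture
#'
#' A CDS fixture bundles a coding sequence with the 1-based position of the
#' mature-peptide start and a catalogue of named haplotype-defining edits.
#' Edits are stored in plain (position, deletion-length | inserted-bases)
#' form and converted to VCF-style anchored variants on demand with
#' [fixture_variant()].
#'
#' @param cds_sequence Nucleotide string; must start with `ATG`, have length
#'   divisible by 3, and end with a stop codon.
#' @param mature_start 1-based amino-acid index of the first mature-peptide
#'   residue.
#' @param hap_edits Named list; each element is `list(pos =, del =)` for a
#'   deletion of `del` bases starting at CDS position `pos`, or
#'   `list(pos =, ins =)` for an insertion of the given bases after `pos`.
#' @return An object of class `cds_fixture`.
#' @export
cds_fixture <- function(cds_sequence, mature_start, hap_edits = list()) {
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  if (substr(cds_sequence, 1L, 3L) != "ATG") stop("CDS does not start with ATG")
  if (!substr(cds_sequence, n - 2L, n) %in% c("TAA", "TAG", "TGA"))
    stop("CDS does not end with a stop codon")
  for (lab in names(hap_edits)) {
    e <- hap_edits[[lab]]
    if (is.null(e$pos) || (is.null(e$del) && is.null(e$ins)))
      stop("edit '", lab, "' must give pos and one of del/ins")
    if (e$pos < 2L || e$pos > n) stop("edit '", lab, "' position outside CDS")
  }
  structure(list(cds_sequence = cds_sequence, mature_start = mature_start,
                 hap_edits = hap_edits),
            class = "cds_fixture")
}

#' Anchored variant for a named fixture edit
#'
#' @param fixture A [cds_fixture()].
#' @param label Edit name as listed in the fixture's `hap_edits`.
#' @return One-row data frame with columns `pos`, `ref`, `alt` in anchored
#'   (VCF-style) representation, 1-based CDS coordinates.
#' @export
fixture_variant <- function(fixture, label) {
  e <- fixture$hap_edits[[label]]
  if (is.null(e)) stop("no edit named '", label, "' in fixture")
  cds <- fixture$cds_sequence
  if (!is.null(e$del)) {
    a <- e$pos - 1L                        # anchor base before the deletion
    data.frame(pos = a,
               ref = substr(cds, a, e$pos + e$del - 1L),
               alt = substr(cds, a, a),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = e$pos,
               ref = substr(cds, e$pos, e$pos),
               alt = paste0(substr(cds, e$pos, e$pos), toupper(e$ins)),
               stringsAsFactors = FALSE)
  }
}

# Translation of a fixture allele after applying one named edit (or none).
fixture_peptide <- function(fixture, label = NULL) {
  cds <- fixture$cds_sequence
  if (!is.null(label)) cds <- reconstruct_cds(cds, fixture_variant(fixture, label))
  translate_cds(cds)
}

#' Packaged RAE2 coding-sequence fixture
#'
#' A 138-bp synthetic CDS standing in for the RAE2 (EPFL-family peptide)
#' coding sequence. The real gene's indel positions are not part of the
#' public record, so the fixture fixes canonical positions engineered to
#' reproduce the documented cysteine arithmetic exactly:
#'
#' * unedited and `hap2` (6-bp in-frame deletion): 6 mature cysteines
#'   (functional);
#' * `hap3` (1-bp deletion between the 4th and 5th cysteine codons):
#'   immediate premature stop, destroying cysteines 5 and 6 (4C);
#' * `hap4`/`hap5` (two distinct 2-bp deletions) and `hap6` (1-bp
#'   insertion): frameshifts past the 6th cysteine adding exactly one
#'   frame-shifted cysteine before the new stop (7C).
#'
#' The fixture is validated at construction; see
#' [validate_rae2_fixture()].
#'
#' @return A `cds_fixture` with `mature_start = 11`.
#' @export
rae2_cds_fixture <- function() {
  cds <- paste0(
    "ATGGAGCTGAAACTGCTGGTGCTGGCAGCA",                # signal peptide, aa 1-10
    "GGAGGATGCGGAGGAGGATGCGGAGGAGGATGCGGAGGAGGATGC", # mature, Cys at aa 13/17/21/25
    "GTAAGG",                                        # aa 26-27: hap3 frameshift trap
    "GGAGGAGGATGCGGAGGAGGATGC",                      # Cys at aa 31/35
    "ACAATGAGAAGAGCCTATGCATCGTATAGC",                # aa 36-45 frameshift cassette
    "TAA")
  fx <- cds_fixture(cds, mature_start = 11L, hap_edits = list(
    hap2 = list(pos = 82L,  del = 6L),   # in-frame Gly-Gly deletion
    hap3 = list(pos = 76L,  del = 1L),   # GTA -> TAA premature stop
    hap4 = list(pos = 106L, del = 2L),
    hap5 = list(pos = 112L, del = 2L),
    hap6 = list(pos = 117L, ins = "A")))
  validate_rae2_fixture(fx)
  fx
}

#' Validate the RAE2 fixture's cysteine invariants
#'
#' Asserts, by translating every allele, that the full-length mature peptide
#' carries exactly 6 cysteines, that the `hap3` edit removes cysteines 5 and
#' 6 (4C), that `hap2` preserves 6C, and that `hap4`, `hap5` and `hap6` each
#' yield 7C via exactly one extra frame-shifted cysteine before the new
#' stop. Called automatically by [rae2_cds_fixture()].
#'
#' @param fixture A `cds_fixture` carrying RAE2-style `hap2`..`hap6` edits.
#' @return The fixture, invisibly; errors if any invariant fails.
#' @export
validate_rae2_fixture <- function(fixture) {
  ms <- fixture$mature_start
  cys <- function(label = NULL) count_cysteines(fixture_peptide(fixture, label), ms)
  want <- c(6L, 6L, 4L, 7L, 7L, 7L)
  got <- c(cys(), cys("hap2"), cys("hap3"), cys("hap4"), cys("hap5"), cys("hap6"))
  if (!all(got == want))
    stop("RAE2 fixture cysteine invariants violated: expected ",
         paste(want, collapse = "/"), ", got ", paste(got, collapse = "/"))
  # hap3 must fall strictly between the codons of the 4th and 5th cysteine
  pep <- fixture_peptide(fixture)
  cpos <- ms - 1L + which(strsplit(substr(pep, ms, nchar(pep)), "")[[1]] == "C")
  c4_end <- 3L * cpos[4L]; c5_start <- 3L * cpos[5L] - 2L
  p3 <- fixture$hap_edits$hap3$pos
  if (!(p3 > c4_end && p3 < c5_start))
    stop("hap3 edit not between the 4th and 5th cysteine codons")
  invisible(fixture)
}

#' Packaged RAE1 coding-sequence fixture
#'
#' A 150-bp synthetic CDS standing in for the RAE1 (bHLH transcription
#' factor) coding sequence. RAE1 haplotype classification is driven by the
#' promoter TE status and the presence of the second-exon 1-bp deletion, so
#' the only catalogued edit is `exon2_del`, a 1-bp deletion that creates an
#' immediate premature stop (modelling the translational truncation of the
#' indica dysfunctional allele).
#'
#' @return A `cds_fixture` with `mature_start = 1`.
#' @export
rae1_cds_fixture <- function() {
  spacer <- c("GAA", "GGT", "CTT", "GCA", "GAT", "GTG", "AAG", "CTG")
  cds <- paste0("ATG",
                paste(rep(spacer, length.out = 28L), collapse = ""),
                "GTAAGG",                 # aa 30-31: deletion of the G -> TAA
                paste(rep(spacer, length.out = 18L), collapse = ""),
                "TAA")
  fx <- cds_fixture(cds, mature_start = 1L,
                    hap_edits = list(exon2_del = list(pos = 88L, del = 1L)))
  # self-check: the deletion truncates the protein
  stopifnot(nchar(fixture_peptide(fx, "exon2_del")) < nchar(fixture_peptide(fx)))
  fx
}

#' Diagnostic RAE2 indels in CDS coordinates
#'
#' The packaged table mapping anchored indels to RAE2 haplotypes hap2..hap6
#' (hap1 is the absence of any diagnostic indel). Positions follow the
#' packaged fixture; for real data supply your own table in the same schema.
#'
#' @param fixture RAE2 fixture whose edit catalogue defines the positions.
#' @return Data frame with columns `hap`, `pos`, `ref`, `alt`.
#' @export
rae2_diagnostics <- function(fixture = rae2_cds_fixture()) {
  haps <- paste0("hap", 2:6)
  do.call(rbind, lapply(haps, function(h)
    cbind(hap = h, fixture_variant(fixture, h))))
}

#' Diagnostic RAE1 second-exon deletion in CDS coordinates
#'
#' @param fixture RAE1 fixture whose `exon2_del` edit defines the position.
#' @return One-row data frame with columns `hap`, `pos`, `ref`, `alt`
#'   (`hap` is `"exon2_del"`, a flag rather than a full haplotype: RAE1
#'   haplotypes also depend on promoter TE status).
#' @export
rae1_diagnostics <- function(fixture = rae1_cds_fixture()) {
  cbind(hap = "exon2_del", fixture_variant(fixture, "exon2_del"))
}
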