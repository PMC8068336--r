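#' Write sequences to FASTA
#'
#' @param sequences Named character vector, or an object with a `sequences`
#'   element (`awn_reference`, `accession_genome`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, c("awn_reference", "accession_genome")))
    sequences <- sequences$sequences
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write simulated reads to FASTQ
#'
#' Base qualities are uniform (`I`, Q40): the simulator models substitution
#' errors directly and carries no quality model.
#'
#' @param reads Data frame from [simulate_reads()] (`read_id`, `seq`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return Data frame `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write a minimal VCF v4.2
#'
#' @param variants Data frame `chrom`, `pos`, `id`, `ref`, `alt` (1-based,
#'   anchored indel representation).
#' @param path Output file.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=awnloci-%s",
                       as.character(utils::packageVersion("awnloci")))), con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                       variants$chrom, as.integer(variants$pos),
                       if (is.null(variants$id)) "." else variants$id,
                       variants$ref, variants$alt), con)
  invisible(path)
}

#' Read a VCF into a plain variant table
#' @param path VCF file (plain text).
#' @return Data frame `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
             id = fx[, "ID"], ref = fx[, "REF"], alt = fx[, "ALT"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write intervals to BED (0-based half-open)
#'
#' @param intervals Data frame `chrom`, `start`, `end` (1-based inclusive)
#'   with optional `name`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start, intervals$end,
                     names = if (!is.null(intervals$name)) intervals$name))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#' @param path BED file.
#' @return Data frame `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

# plain TSV helpers used by the pipeline surface
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
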