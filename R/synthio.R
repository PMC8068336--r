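#' Specification of a synthetic genome
#'
#' Describes everything the generator needs: chromosome lengths (without the
#' TE), the TE sequence and its 1-based insertion site on the RAE1
#' chromosome, the RAE1/RAE2 CDS fixtures and where they sit, an optional
#' marker map and causal-locus table for CSSL simulation, and a seed.
#'
#' Default geometry: a 100-kb RAE1 chromosome (`chr4`) receiving a 4.4-kb
#' TE at position 50,001 with the RAE1 CDS 300 bp downstream of the TE, and
#' a 60-kb RAE2 chromosome (`chr8`) with the RAE2 CDS at 30,001. Unless
#' `embed_repeats = FALSE`, a 400-bp interior chunk of the TE is also
#' planted at a second locus (plus one unrelated 400-bp repeat pair) so the
#' multi-mapped-read exclusion path is exercised; repeats are kept clear of
#' the TE boundary windows.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp,
#'   *before* TE insertion. The first chromosome carries the TE.
#' @param te_length TE length in bp (ignored when `te_sequence` given).
#' @param te_sequence Optional explicit TE nucleotide string.
#' @param te_site 1-based coordinate of the first TE base on the
#'   TE-containing reference chromosome.
#' @param rae1_offset Distance (bp) from the TE 3' end to the RAE1 CDS start.
#' @param rae1_cds_model,rae2_cds_model CDS fixtures ([cds_fixture()]).
#' @param rae2_chrom,rae2_start Placement of the RAE2 CDS.
#' @param marker_map Optional data frame `marker`, `chrom`, `pos` (1-based),
#'   strictly increasing per chromosome.
#' @param causal_loci Optional data frame `chrom`, `start`, `end`,
#'   `penetrance` (in `[0, 1]`).
#' @param embed_repeats Plant repeated sequence as described above.
#' @param seed Integer seed driving all sequence generation.
#' @return An object of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chr4 = 100000L, chr8 = 60000L),
                                  te_length = 4400L,
                                  te_sequence = NULL,
                                  te_site = 50001L,
                                  rae1_offset = 300L,
                                  rae1_cds_model = rae1_cds_fixture(),
                                  rae2_cds_model = rae2_cds_fixture(),
                                  rae2_chrom = names(chrom_lengths)[min(2L, length(chrom_lengths))],
                                  rae2_start = 30001L,
                                  marker_map = NULL,
                                  causal_loci = NULL,
                                  embed_repeats = TRUE,
                                  seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)))
  if (!is.null(te_sequence)) te_length <- nchar(te_sequence)
  te_chrom <- names(chrom_lengths)[1L]
  if (te_site < 1L || te_site > chrom_lengths[[1L]])
    stop("te_site ", te_site, " outside chromosome ", te_chrom,
         " (length ", chrom_lengths[[1L]], ")")
  if (!is.null(marker_map)) {
    sp <- split(marker_map$pos, marker_map$chrom)
    if (!all(vapply(sp, function(p) all(diff(p) > 0), logical(1L))))
      stop("marker positions must be strictly increasing within a chromosome")
  }
  if (!is.null(causal_loci) &&
      (any(causal_loci$penetrance < 0) || any(causal_loci$penetrance > 1)))
    stop("penetrance must lie in [0, 1]")
  structure(list(chrom_lengths = chrom_lengths, te_length = as.integer(te_length),
                 te_sequence = te_sequence, te_chrom = te_chrom,
                 te_site = as.integer(te_site), rae1_offset = as.integer(rae1_offset),
                 rae1_cds_model = rae1_cds_model, rae2_cds_model = rae2_cds_model,
                 rae2_chrom = rae2_chrom, rae2_start = as.integer(rae2_start),
                 marker_map = marker_map, causal_loci = causal_loci,
                 embed_repeats = isTRUE(embed_repeats), seed = as.integer(seed)),
            class = "genome_spec")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

str_overwrite <- function(s, at, piece) {
  paste0(substr(s, 1L, at - 1L), piece, substr(s, at + nchar(piece), nchar(s)))
}

#' Build the synthetic TE-containing reference
#'
#' Generates all chromosomes from a seeded uniform nucleotide model, embeds
#' the gene fixtures, inserts the TE at `te_site` on the first chromosome,
#' and returns the sequences together with annotation of the TE body, the
#' four 200-bp boundary windows, the gene CDSs and any markers. The
#' reference carries the TE allele (as the japonica reference genome does),
#' so "present" is the reference state.
#'
#' All coordinates in the returned annotation are 1-based inclusive on the
#' TE-containing reference; [write_bed()] converts to 0-based half-open on
#' export.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return An object of class `awn_reference`: list with `sequences` (named
#'   character vector), `annotation` (data frame `chrom`, `start`, `end`,
#'   `name`, `type`), `windows` (the four boundary windows), `te_sequence`,
#'   and the originating `spec`.
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    te <- spec$te_sequence
    if (is.null(te)) te <- random_dna(spec$te_length)
    chroms <- vapply(spec$chrom_lengths, random_dna, character(1L))

    s <- spec$te_site
    te_chrom <- spec$te_chrom
    if (spec$embed_repeats) {
      # interior TE chunk planted upstream on the TE chromosome; one
      # unrelated repeat pair shared between chromosomes when possible
      if (spec$te_length >= 2400L && s > 20800L) {
        chunk <- substr(te, 2001L, 2400L)
        chroms[te_chrom] <- str_overwrite(chroms[te_chrom], 20001L, chunk)
      }
      if (length(chroms) >= 2L) {
        rep2 <- substr(chroms[[1L]], 10001L, 10400L)
        chroms[[2L]] <- str_overwrite(chroms[[2L]], 10001L, rep2)
      }
    }

    # gene fixtures sit on the base (TE-less) coordinates, then shift with
    # the insertion
    rae1_cds <- spec$rae1_cds_model$cds_sequence
    rae1_base_start <- s + spec$rae1_offset
    if (rae1_base_start + nchar(rae1_cds) - 1L > nchar(chroms[te_chrom]))
      stop("RAE1 CDS does not fit downstream of te_site")
    chroms[te_chrom] <- str_overwrite(chroms[te_chrom], rae1_base_start, rae1_cds)

    rae2_cds <- spec$rae2_cds_model$cds_sequence
    if (spec$rae2_start + nchar(rae2_cds) - 1L > nchar(chroms[spec$rae2_chrom]))
      stop("RAE2 CDS does not fit on ", spec$rae2_chrom)
    chroms[spec$rae2_chrom] <- str_overwrite(chroms[spec$rae2_chrom],
                                             spec$rae2_start, rae2_cds)

    # insert the TE before base position s
    chroms[te_chrom] <- paste0(substr(chroms[te_chrom], 1L, s - 1L), te,
                               substr(chroms[te_chrom], s, nchar(chroms[te_chrom])))

    L <- spec$te_length
    e <- s + L - 1L                       # last TE base, 1-based
    windows <- data.frame(
      chrom = te_chrom,
      start = c(s, s - 200L, e - 199L, e + 1L),
      end   = c(s + 199L, s - 1L, e, e + 200L),
      name  = c("inside_left", "outside_left", "inside_right", "outside_right"),
      type  = "boundary_window", stringsAsFactors = FALSE)

    rae1_start <- rae1_base_start + L     # shifted by the insertion
    ann <- rbind(
      data.frame(chrom = te_chrom, start = s, end = e, name = "te_body",
                 type = "te", stringsAsFactors = FALSE),
      windows,
      data.frame(chrom = te_chrom, start = rae1_start,
                 end = rae1_start + nchar(rae1_cds) - 1L,
                 name = "RAE1", type = "cds", stringsAsFactors = FALSE),
      data.frame(chrom = spec$rae2_chrom, start = spec$rae2_start,
                 end = spec$rae2_start + nchar(rae2_cds) - 1L,
                 name = "RAE2", type = "cds", stringsAsFactors = FALSE))
    if (!is.null(spec$marker_map)) {
      mpos <- spec$marker_map$pos +
        ifelse(spec$marker_map$chrom == te_chrom & spec$marker_map$pos >= s, L, 0L)
      ann <- rbind(ann, data.frame(chrom = spec$marker_map$chrom, start = mpos,
                                   end = mpos, name = spec$marker_map$marker,
                                   type = "marker", stringsAsFactors = FALSE))
    }
    structure(list(sequences = chroms, annotation = ann, windows = windows,
                   te_sequence = te, spec = spec),
              class = "awn_reference")
  })
}

#' Describe one synthetic accession
#'
#' @param accession_id,species_label Identifiers.
#' @param te_present Does the accession carry the promoter TE insertion?
#' @param rae1_exon2_del Does it carry the RAE1 second-exon 1-bp deletion?
#' @param rae2_edit One of `"none"`, `"del6"`, `"del1"`, `"del2a"`,
#'   `"del2b"`, `"ins1"` — the RAE2 diagnostic indels defining hap2..hap6.
#' @param extra_snps Optional data frame `chrom`, `pos`, `alt` of additional
#'   substitutions (TE-containing reference coordinates).
#' @return An object of class `accession_profile`.
#' @export
accession_profile <- function(accession_id, species_label = "synthetic",
                              te_present = TRUE, rae1_exon2_del = FALSE,
                              rae2_edit = c("none", "del6", "del1", "del2a",
                                            "del2b", "ins1"),
                              extra_snps = NULL) {
  rae2_edit <- match.arg(rae2_edit)
  structure(list(accession_id = accession_id, species_label = species_label,
                 te_present = isTRUE(te_present),
                 rae1_exon2_del = isTRUE(rae1_exon2_del),
                 rae2_edit = rae2_edit, extra_snps = extra_snps),
            class = "accession_profile")
}

# RAE2 edit label -> fixture edit name (hap1 carries none)
.RAE2_EDIT_HAP <- c(del6 = "hap2", del1 = "hap3", del2a = "hap4",
                    del2b = "hap5", ins1 = "hap6")

# 1-based gene start coordinates on the TE-containing reference
gene_coords <- function(reference) {
  a <- reference$annotation
  g <- a[a$type == "cds", , drop = FALSE]
  stats::setNames(split(g[c("chrom", "start", "end")], g$name), g$name)
}

#' Realize an accession genome from a profile
#'
#' Applies the profile's edits to the TE-containing reference: deletes the
#' TE body when `te_present` is `FALSE`, introduces the RAE1/RAE2 diagnostic
#' indels inside the modelled genes, and any extra SNPs. Returns the edited
#' sequences together with a truth VCF (1-based, anchored indels) against
#' the TE-containing reference; applying the VCF to the reference
#' reproduces the accession genome exactly.
#'
#' @param reference An `awn_reference` from [build_reference()].
#' @param profile An [accession_profile()].
#' @return List of class `accession_genome`: `sequences`, `variants` (data
#'   frame `chrom`, `pos`, `id`, `ref`, `alt`), `profile`.
#' @export
make_accession_genome <- function(reference, profile) {
  stopifnot(inherits(reference, "awn_reference"),
            inherits(profile, "accession_profile"))
  spec <- reference$spec
  seqs <- reference$sequences
  genes <- gene_coords(reference)
  vv <- list()

  if (!profile$te_present) {
    s <- spec$te_site; L <- spec$te_length
    a <- s - 1L
    if (a < 1L) stop("TE at chromosome start cannot be left-anchored")
    vv[[length(vv) + 1L]] <- data.frame(
      chrom = spec$te_chrom, pos = a, id = "te_del",
      ref = substr(seqs[spec$te_chrom], a, s + L - 1L),
      alt = substr(seqs[spec$te_chrom], a, a), stringsAsFactors = FALSE)
  }
  if (profile$rae1_exon2_del) {
    v <- fixture_variant(spec$rae1_cds_model, "exon2_del")
    g <- genes$RAE1
    vv[[length(vv) + 1L]] <- data.frame(
      chrom = g$chrom, pos = g$start + v$pos - 1L, id = "rae1_exon2_del",
      ref = v$ref, alt = v$alt, stringsAsFactors = FALSE)
  }
  if (profile$rae2_edit != "none") {
    v <- fixture_variant(spec$rae2_cds_model, .RAE2_EDIT_HAP[[profile$rae2_edit]])
    g <- genes$RAE2
    vv[[length(vv) + 1L]] <- data.frame(
      chrom = g$chrom, pos = g$start + v$pos - 1L,
      id = paste0("rae2_", profile$rae2_edit),
      ref = v$ref, alt = v$alt, stringsAsFactors = FALSE)
  }
  if (!is.null(profile$extra_snps) && nrow(profile$extra_snps) > 0L) {
    es <- profile$extra_snps
    vv[[length(vv) + 1L]] <- data.frame(
      chrom = es$chrom, pos = es$pos,
      id = paste0("snp", seq_len(nrow(es))),
      ref = substr(seqs[es$chrom], es$pos, es$pos),
      alt = es$alt, stringsAsFactors = FALSE)
  }
  variants <- if (length(vv)) do.call(rbind, vv) else
    data.frame(chrom = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)

  # conflict check + right-to-left application per chromosome
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    ends <- v$pos + nchar(v$ref) - 1L
    if (nrow(v) > 1L && any(v$pos[-1L] <= ends[-nrow(v)]))
      stop("overlapping edits on ", ch, " (",
           paste(v$id[c(FALSE, v$pos[-1L] <= ends[-nrow(v)])], collapse = ", "), ")")
    for (i in rev(seq_len(nrow(v)))) {
      if (substr(seqs[ch], v$pos[i], ends[i]) != v$ref[i])
        stop("internal error: ref mismatch for ", v$id[i])
      seqs[ch] <- paste0(substr(seqs[ch], 1L, v$pos[i] - 1L), v$alt[i],
                         substr(seqs[ch], ends[i] + 1L, nchar(seqs[ch])))
    }
  }
  structure(list(sequences = seqs, variants = variants, profile = profile),
            class = "accession_genome")
}

#' Read-simulation parameters
#'
#' @param read_length Read length in bp.
#' @param depth Mean fold coverage (> 0).
#' @param error_rate Per-base substitution probability, in `[0, 0.2)`.
#' @param seed Integer seed.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100L, depth = 20, error_rate = 0.01,
                            seed = 1L) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.2, read_length >= 1L)
  structure(list(read_length = as.integer(read_length), depth = depth,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

.BASE_ALTS <- matrix(c("C", "G", "T",   # alternatives for A
                       "A", "G", "T",   # C
                       "A", "C", "T",   # G
                       "A", "C", "G"),  # T
                     nrow = 4L, byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"), NULL))

#' Simulate single-end reads
#'
#' Draws `round(depth * length / read_length)` reads per chromosome with
#' uniform start positions and independent per-base substitution errors.
#' Reads are forward-strand only (the companion placer searches the forward
#' strand only, so generator and caller are consistent). Read ids encode the
#' truth chromosome and 1-based start position.
#'
#' @param genome Named character vector of sequences, or an
#'   `accession_genome`/`awn_reference`.
#' @param params A [read_sim_params()].
#' @return Data frame `read_id`, `seq`, `chrom`, `start` (`chrom`/`start`
#'   are the simulation truth; [write_fastq()] keeps them only inside the id).
#' @export
simulate_reads <- function(genome, params) {
  if (inherits(genome, c("accession_genome", "awn_reference")))
    genome <- genome$sequences
  stopifnot(inherits(params, "read_sim_params"))
  rl <- params$read_length
  if (any(nchar(genome) < rl)) stop("read_length exceeds a chromosome length")
  with_seed(params$seed, {
    out <- lapply(names(genome), function(ch) {
      glen <- nchar(genome[[ch]])
      n <- round(params$depth * glen / rl)
      starts <- sample.int(glen - rl + 1L, n, replace = TRUE)
      reads <- substring(genome[[ch]], starts, starts + rl - 1L)
      if (params$error_rate > 0) {
        flat <- strsplit(paste(reads, collapse = ""), "")[[1L]]
        hit <- which(stats::runif(length(flat)) < params$error_rate)
        if (length(hit)) {
          pick <- sample.int(3L, length(hit), replace = TRUE)
          flat[hit] <- .BASE_ALTS[cbind(match(flat[hit], rownames(.BASE_ALTS)), pick)]
          reads <- substring(paste(flat, collapse = ""),
                             (seq_len(n) - 1L) * rl + 1L, seq_len(n) * rl)
        }
      }
      data.frame(read_id = sprintf("r%06d|%s|%d", seq_len(n), ch, starts),
                 seq = reads, chrom = ch, start = starts,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Build a marker map with even spacing
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_markers Total number of markers, allocated to chromosomes
#'   proportionally to length (each chromosome gets at least one).
#' @return Data frame `marker`, `chrom`, `pos`.
#' @export
make_marker_map <- function(chrom_lengths, n_markers) {
  stopifnot(n_markers >= length(chrom_lengths))
  alloc <- stats::setNames(
    pmax(1L, round(n_markers * as.numeric(chrom_lengths) /
                     sum(as.numeric(chrom_lengths)))),
    names(chrom_lengths))
  # trim/pad to hit n_markers exactly
  while (sum(alloc) > n_markers) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_markers) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    k <- alloc[[ch]]
    pos <- round(seq(1, chrom_lengths[[ch]], length.out = k + 2L))[2:(k + 1L)]
    data.frame(marker = sprintf("M_%s_%02d", ch, seq_len(k)), chrom = ch,
               pos = as.integer(pos), stringsAsFactors = FALSE)
  }))
}

#' Simulate a CSSL panel
#'
#' Generates a chromosome-segment substitution line panel: each line carries
#' one or two contiguous donor segments, and across lines the segments tile
#' the marker map (consecutive marker blocks; a block spanning a chromosome
#' boundary yields the line's second segment). Awn phenotypes are drawn per
#' line and year: awned with probability equal to the causal locus's
#' penetrance if any donor segment overlaps a causal locus, otherwise with
#' the false-positive rate.
#'
#' @param spec A [synthetic_genome_spec()] whose `marker_map` is set.
#' @param n_lines Number of lines (default 35, matching a published
#'   35-line, 149-marker panel when combined with a 149-marker map).
#' @param seed Integer seed.
#' @param years Number of observation years (2-3 in the emulated study).
#' @param fp_rate Probability that a non-carrier line is awned in a year.
#' @return List with `genotypes` (data frame `line`, `marker`, `chrom`,
#'   `pos`, `call` with calls in D/R), `phenotypes` (data frame `line`,
#'   `year`, `awned_spikelets`, `total_spikelets`, `mean_awn_length_mm`) and
#'   `truth` (`segments`, `carriers`).
#' @export
make_cssl_panel <- function(spec, n_lines = 35L, seed = spec$seed, years = 3L,
                            fp_rate = 0) {
  mm <- spec$marker_map
  if (is.null(mm) || nrow(mm) == 0L) stop("spec has an empty marker map")
  if (n_lines < 1L) stop("n_lines must be >= 1")
  if (nrow(mm) < n_lines)
    stop("need at least as many markers as lines for a tiling panel")
  mm <- mm[order(match(mm$chrom, unique(mm$chrom)), mm$pos), , drop = FALSE]
  M <- nrow(mm)
  cuts <- floor(seq(0, M, length.out = n_lines + 1L))
  with_seed(seed, {
    lines <- sprintf("L%03d", seq_len(n_lines))
    geno <- list(); segs <- list(); carrier <- logical(n_lines)
    cl <- spec$causal_loci
    pen <- numeric(n_lines)
    for (i in seq_len(n_lines)) {
      idx <- (cuts[i] + 1L):cuts[i + 1L]
      call <- rep("R", M)
      call[idx] <- "D"
      geno[[i]] <- data.frame(line = lines[i], marker = mm$marker,
                              chrom = mm$chrom, pos = mm$pos, call = call,
                              stringsAsFactors = FALSE)
      # contiguous donor runs (split at chromosome boundaries), keep <= 2
      pieces <- split(idx, mm$chrom[idx])
      pieces <- pieces[order(vapply(pieces, min, integer(1L)))]
      if (length(pieces) > 2L) {  # rare with realistic maps; drop extras to R
        drop <- unlist(pieces[-(1:2)])
        geno[[i]]$call[drop] <- "R"
        pieces <- pieces[1:2]
      }
      segs[[i]] <- do.call(rbind, lapply(pieces, function(p)
        data.frame(line = lines[i], chrom = mm$chrom[p[1L]],
                   start = mm$pos[min(p)], end = mm$pos[max(p)],
                   stringsAsFactors = FALSE)))
      p_awn <- fp_rate
      if (!is.null(cl) && nrow(cl) > 0L) {
        for (j in seq_len(nrow(cl))) {
          hit <- any(segs[[i]]$chrom == cl$chrom[j] &
                     segs[[i]]$start <= cl$end[j] & segs[[i]]$end >= cl$start[j])
          if (hit) p_awn <- max(p_awn, cl$penetrance[j])
        }
      }
      carrier[i] <- !is.null(cl) && nrow(cl) > 0L && p_awn > fp_rate
      pen[i] <- p_awn
    }
    pheno <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
      awned_yr <- stats::runif(years) < pen[i]
      total <- sample(80:150, years, replace = TRUE)
      awned <- ifelse(awned_yr,
                      pmax(1L, stats::rbinom(years, total,
                                             stats::runif(years, 0.07, 1))),
                      0L)
      len <- ifelse(awned_yr, stats::runif(years, 5, 80), stats::runif(years, 0, 1))
      data.frame(line = lines[i], year = 2015L + seq_len(years),
                 awned_spikelets = awned, total_spikelets = total,
                 mean_awn_length_mm = round(len, 1), stringsAsFactors = FALSE)
    }))
    list(genotypes = do.call(rbind, geno), phenotypes = pheno,
         truth = list(segments = do.call(rbind, segs),
                      carriers = data.frame(line = lines, carrier = carrier,
                                            penetrance = pen,
                                            stringsAsFactors = FALSE)))
  })
}
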