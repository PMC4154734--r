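#' Find restriction sites in a genome
#'
#' Scans the top strand of every contig for exact matches to the enzyme's
#' recognition sequence. Only palindromic enzymes are supported: a
#' palindromic top-strand match is its own reverse-complement match, so a
#' single scan covers both strands. Recognition sites never match across
#' an N.
#'
#' @param genome See [as_genome()].
#' @param enz Enzyme name or [enzyme()] object.
#' @return Tibble with columns `contig`, `pos` (0-based recognition start),
#'   `enzyme`, sorted by contig then position.
#' @examples
#' find_cut_sites(c(chr1 = "AACCTGCAGGTT"), "SbfI")
#' @export
find_cut_sites <- function(genome, enz) {
  genome <- as_genome(genome)
  enz <- enzyme(enz)
  if (!enz$palindromic) {
    stop("Enzyme '", enz$name, "' has a non-palindromic recognition sequence; ",
         "only palindromic enzymes are supported.", call. = FALSE)
  }
  res <- purrr::map(names(genome), function(ctg) {
    m <- Biostrings::matchPattern(enz$recognition,
                                  Biostrings::DNAString(genome[[ctg]]),
                                  fixed = TRUE)
    tibble::tibble(contig = ctg, pos = BiocGenerics::start(m) - 1L)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(contig = character(), pos = integer())
  }
  out$enzyme <- rep(enz$name, nrow(out))
  dplyr::arrange(out, .data$contig, .data$pos)
}

#' In silico double digestion
#'
#' Pools the recognition-site matches of two enzymes per contig and reports
#' the fragments between consecutive sites. Fragment coordinates span from
#' the first base of the left site to the last base of the right site, so
#' overlapping sites legitimately produce fragments down to
#' `|recA| + |recB| - 1` bp. Chromosome-end fragments are reported with an
#' `NA` enzyme on the open end.
#'
#' @param genome See [as_genome()].
#' @param enzA,enzB The two enzymes (names or [enzyme()] objects); must
#'   differ by recognition sequence.
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open),
#'   `length_bp`, `left_enzyme`, `right_enzyme`.
#' @examples
#' double_digest(c(chr1 = "CCTGCAGGAATTC"), "SbfI", "EcoRI")
#' @export
double_digest <- function(genome, enzA, enzB) {
  genome <- as_genome(genome)
  enzA <- enzyme(enzA); enzB <- enzyme(enzB)
  if (identical(enzA$recognition, enzB$recognition)) {
    stop("The two enzymes must have different recognition sequences.",
         call. = FALSE)
  }
  sites <- dplyr::bind_rows(
    find_cut_sites(genome, enzA),
    find_cut_sites(genome, enzB)
  )
  sites$site_len <- ifelse(sites$enzyme == enzA$name,
                           nchar(enzA$recognition), nchar(enzB$recognition))
  frags <- sites |>
    dplyr::arrange(.data$contig, .data$pos, .data$pos + .data$site_len) |>
    dplyr::group_by(.data$contig) |>
    dplyr::reframe(
      start        = c(0L, .data$pos),
      end          = c(.data$pos + .data$site_len, nchar(genome[[.data$contig[1]]])),
      left_enzyme  = c(NA_character_, .data$enzyme),
      right_enzyme = c(.data$enzyme, NA_character_)
    )
  frags$length_bp <- frags$end - frags$start
  dplyr::select(frags, "contig", "start", "end", "length_bp",
                "left_enzyme", "right_enzyme")
}

#' Predict ddRAD loci for an enzyme pair and size window
#'
#' Keeps double-digest fragments with one site of each enzyme at either
#' end (both orientations) whose total length, inclusive of both
#' recognition sites, falls inside the window. Minus-orientation loci
#' (enzyme-A site rightmost on the top strand) are reported with the
#' reverse-complemented sequence so the A site always leads, matching the
#' structure of sequencing reads. Loci containing N are flagged but
#' retained.
#'
#' @param genome See [as_genome()].
#' @param enzA Rare cutter; its site leads every reported sequence.
#' @param enzB Frequent cutter.
#' @param min_bp,max_bp Inclusive bounds on locus length.
#' @return Tibble sorted by (contig, start) with columns `locus_id`,
#'   `contig`, `start`, `end`, `orientation` ("+"/"-"), `length_bp`,
#'   `gc_fraction`, `sequence`, `contains_n`, `single_copy` (NA until
#'   [annotate_single_copy()] is run).
#' @examples
#' predict_ddrad_loci(c(chr1 = "CCTGCAGGAATTC"), "SbfI", "EcoRI", 13, 328)
#' @export
predict_ddrad_loci <- function(genome, enzA, enzB, min_bp = 38L, max_bp = 328L) {
  stopifnot(min_bp > 0, min_bp <= max_bp)
  genome <- as_genome(genome)
  enzA <- enzyme(enzA); enzB <- enzyme(enzB)
  frags <- double_digest(genome, enzA, enzB)
  ab <- frags |>
    dplyr::filter(
      (!is.na(.data$left_enzyme) & !is.na(.data$right_enzyme)) &
        ((.data$left_enzyme == enzA$name & .data$right_enzyme == enzB$name) |
         (.data$left_enzyme == enzB$name & .data$right_enzyme == enzA$name)),
      .data$length_bp >= min_bp, .data$length_bp <= max_bp
    )
  if (nrow(ab) == 0L) {
    return(tibble::tibble(
      locus_id = character(), contig = character(), start = integer(),
      end = integer(), orientation = character(), length_bp = integer(),
      gc_fraction = double(), sequence = character(), contains_n = logical(),
      single_copy = logical()
    ))
  }
  ab$orientation <- ifelse(ab$left_enzyme == enzA$name, "+", "-")
  seqs <- purrr::pmap_chr(
    list(ab$contig, ab$start, ab$end),
    function(ctg, s, e) genome_subseq(genome, ctg, s, e)
  )
  seqs[ab$orientation == "-"] <- revcomp(seqs[ab$orientation == "-"])
  out <- tibble::tibble(
    contig = ab$contig, start = ab$start, end = ab$end,
    orientation = ab$orientation, length_bp = ab$length_bp,
    gc_fraction = vapply(seqs, gc_fraction, numeric(1), USE.NAMES = FALSE),
    sequence = seqs,
    contains_n = grepl("N", seqs, fixed = TRUE),
    single_copy = NA
  ) |>
    dplyr::arrange(.data$contig, .data$start)
  out <- tibble::add_column(
    out,
    locus_id = sprintf("%s:%d-%d", out$contig, out$start, out$end),
    .before = 1
  )
  out
}

#' GC fraction of a sequence
#'
#' `(#G + #C) / (length - #N)`. Errors on an empty or all-N sequence.
#'
#' @param sequence A single nucleotide string.
#' @return Fraction in \[0, 1\].
#' @examples
#' gc_fraction("CCTGCAGG") # 0.75
#' @export
gc_fraction <- function(sequence) {
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("gc_fraction() needs a single non-empty sequence.", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n_n <- sum(chars == "N")
  denom <- length(chars) - n_n
  if (denom == 0L) stop("Sequence is all N; GC fraction undefined.", call. = FALSE)
  sum(chars %in% c("G", "C")) / denom
}

#' Annotate predicted loci with single-copy status
#'
#' The leading tag of each locus (its first `tag_len` bases, or the entire
#' sequence when shorter) is counted against the genome on both strands;
#' a locus is single copy iff the tag occurs exactly once. This is a
#' deterministic exact-occurrence criterion standing in for a unique
#' high-quality alignment hit.
#'
#' @param loci Tibble from [predict_ddrad_loci()].
#' @param genome See [as_genome()].
#' @param tag_len Tag length (default 100, the read length).
#' @return `loci` with `single_copy` filled in.
#' @export
annotate_single_copy <- function(loci, genome, tag_len = 100L) {
  genome <- as_genome(genome)
  if (nrow(loci) == 0L) return(loci)
  subjects <- Biostrings::DNAStringSet(unclass(genome))
  tags <- substr(loci$sequence, 1L, pmin(tag_len, nchar(loci$sequence)))
  loci$single_copy <- vapply(tags, function(tag) {
    fwd <- sum(Biostrings::vcountPattern(tag, subjects, fixed = TRUE))
    rc <- revcomp(tag)
    rev <- if (identical(rc, tag)) 0L else
      sum(Biostrings::vcountPattern(rc, subjects, fixed = TRUE))
    (fwd + rev) == 1L
  }, logical(1), USE.NAMES = FALSE)
  loci
}

#' Restrict predicted loci to the stringent single-copy set
#'
#' @inheritParams annotate_single_copy
#' @return The subset of `loci` with a unique leading tag.
#' @export
single_copy_filter <- function(loci, genome, tag_len = 100L) {
  loci <- annotate_single_copy(loci, genome, tag_len)
  dplyr::filter(loci, .data$single_copy)
}

#' Expected fragment count for single-enzyme RAD-seq
#'
#' With a single enzyme and random shearing, each cut site contributes one
#' sequenced fragment upstream and one downstream, so the expected number
#' of fragments is twice the site count.
#'
#' @param genome See [as_genome()].
#' @param enz Enzyme.
#' @return List with `n_sites` and `n_fragments` (= 2 * n_sites).
#' @export
rad_fragment_count <- function(genome, enz) {
  n <- nrow(find_cut_sites(genome, enz))
  list(n_sites = n, n_fragments = 2L * n)
}

#' Digest summary counts for a bird-sized reference assembly
#'
#' Convenience wrapper recomputing, for any assembly FASTA, the four
#' headline digest counts used to characterise genome reduction for the
#' zebra finch genome: the number of SbfI sites, SbfI-EcoRI loci in the
#' realised 38-328 bp window, SbfI-EcoRI loci in a narrow 206-254 bp
#' window, and EcoRI-MspI loci in 206-254 bp. Counts are
#' assembly-version sensitive.
#'
#' @param fasta Path to the assembly FASTA (may be gzipped), or anything
#'   [as_genome()] accepts.
#' @return Tibble with columns `quantity` and `value`.
#' @export
zebra_finch_digest_counts <- function(fasta) {
  genome <- as_genome(fasta)
  tibble::tibble(
    quantity = c("sbfi_sites",
                 "sbfi_ecori_loci_38_328",
                 "sbfi_ecori_loci_206_254",
                 "ecori_mspi_loci_206_254"),
    value = c(
      nrow(find_cut_sites(genome, "SbfI")),
      nrow(predict_ddrad_loci(genome, "SbfI", "EcoRI", 38L, 328L)),
      nrow(predict_ddrad_loci(genome, "SbfI", "EcoRI", 206L, 254L)),
      nrow(predict_ddrad_loci(genome, "EcoRI", "MspI", 206L, 254L))
    )
  )
}

#' Write predicted loci as TSV and FASTA
#'
#' @param loci Tibble from [predict_ddrad_loci()].
#' @param tsv,fasta Output paths (either may be NULL to skip).
#' @return `loci`, invisibly.
#' @export
write_loci <- function(loci, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(
      dplyr::select(loci, -"sequence"),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(loci$sequence)
    names(dss) <- loci$locus_id
    Biostrings::writeXStringSet(dss, fasta)
  }
  invisible(loci)
}
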