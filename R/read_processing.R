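#' Demultiplex raw reads by inline barcode
#'
#' A read is assigned to a sample iff its first `L` bases exactly match a
#' barcode (`L` = barcode length). Distance-2 barcode sets detect single
#' sequencing errors but cannot correct them, so no mismatch tolerance is
#' offered. Assigned reads have the barcode removed and `"CC"` prepended,
#' reconstructing the 8-base SbfI recognition sequence at the read start;
#' the two synthesized bases carry sentinel quality 40.
#'
#' @param reads Tibble with `id`, `sequence`, `qual` (see [read_fastq()]).
#' @param barcode_map Tibble with `barcode`, `sample_id` (see
#'   [read_barcode_map()]).
#' @return List with elements `reads` (assigned, with `sample_id`,
#'   `adapter_trimmed`, `internal_trimmed` flag columns), `unassigned`,
#'   and `counts` (per-sample read counts including an "(unassigned)"
#'   row).
#' @export
demultiplex <- function(reads, barcode_map) {
  barcode_map <- check_barcode_map(barcode_map)
  L <- nchar(barcode_map$barcode[1])
  bc <- substr(reads$sequence, 1L, L)
  idx <- match(bc, barcode_map$barcode)
  assigned <- reads[!is.na(idx), , drop = FALSE]
  unassigned <- reads[is.na(idx), , drop = FALSE]
  sample_id <- barcode_map$sample_id[idx[!is.na(idx)]]
  out <- tibble::tibble(
    sample_id = sample_id,
    id = assigned$id,
    sequence = paste0("CC", substr(assigned$sequence, L + 1L, nchar(assigned$sequence))),
    qual = paste0(strrep(SENTINEL_CHAR, 2L),
                  substr(assigned$qual, L + 1L, nchar(assigned$qual))),
    adapter_trimmed = FALSE,
    internal_trimmed = FALSE
  )
  counts <- dplyr::count(out, .data$sample_id, name = "n_reads")
  counts <- dplyr::bind_rows(
    counts,
    tibble::tibble(sample_id = "(unassigned)", n_reads = nrow(unassigned))
  )
  list(reads = out, unassigned = tibble::as_tibble(unassigned), counts = counts)
}

# Best ungapped placement of the adapter prefix against the 3' region of
# one sequence. Returns the 1-based start of the adapter in the read, or
# NA when no placement meets the overlap/error constraints.
find_adapter_start <- function(sequence, adapter, min_overlap, max_err) {
  L <- nchar(sequence)
  if (L < min_overlap) return(NA_integer_)
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ad_chars <- strsplit(adapter, "", fixed = TRUE)[[1]]
  best_s <- NA_integer_
  best_err <- Inf
  for (s in seq_len(L - min_overlap + 1L)) {
    len <- min(L - s + 1L, length(ad_chars))
    if (len < min_overlap) break
    mism <- sum(seq_chars[s:(s + len - 1L)] != ad_chars[seq_len(len)])
    err <- mism / len
    if (err <= max_err && err < best_err) {
      best_err <- err
      best_s <- s
    }
  }
  best_s
}

#' Trim P2 adapter read-through
#'
#' Reads from fragments shorter than the read length run through the
#' EcoRI site into the P2 adapter. The adapter prefix is placed against
#' every 3' start position of the read (ungapped, unit mismatch cost);
#' if the best placement covers at least `min_overlap` bases with an
#' error rate at most `max_err`, the read is truncated at the placement
#' start and a single `"C"` appended (completing the `GAATTC` site cut
#' during digestion).
#'
#' @param reads Tibble of processed reads (from [demultiplex()]).
#' @param adapter P2 adapter sequence as read through (5'->3' on the read).
#' @param min_overlap Minimum adapter overlap in bases.
#' @param max_err Maximum mismatch fraction within the overlap.
#' @return `reads` with trimmed sequences/qualities and the
#'   `adapter_trimmed` flag set.
#' @export
trim_p2_adapter <- function(reads, adapter = default_p2_adapter(),
                            min_overlap = 8L, max_err = 0.2) {
  stopifnot(nzchar(adapter))
  adapter <- toupper(adapter)
  starts <- vapply(reads$sequence, find_adapter_start, integer(1),
                   adapter = adapter, min_overlap = min_overlap,
                   max_err = max_err, USE.NAMES = FALSE)
  hit <- !is.na(starts)
  reads$sequence[hit] <- paste0(substr(reads$sequence[hit], 1L, starts[hit] - 1L), "C")
  reads$qual[hit] <- paste0(substr(reads$qual[hit], 1L, starts[hit] - 1L),
                            SENTINEL_CHAR)
  reads$adapter_trimmed <- hit
  reads
}

#' Default P2 adapter sequence (as it appears at the 3' end of a read)
#'
#' A TruSeq-style reverse adapter start; configurable everywhere it is
#' used.
#' @return Character scalar.
#' @export
default_p2_adapter <- function() {
  "AGATCGGAAGAGCGAGAACAAGGTCTTCAGCATACGGCAGG"
}

#' Screen reads for internal restriction sites (concatemers)
#'
#' After the leading reconstructed SbfI site, any complete internal SbfI
#' recognition sequence marks a chimera of two SbfI fragments and the
#' read is discarded. Otherwise the first internal EcoRI site is treated
#' as the legitimate locus terminus and the read is truncated immediately
#' after it (the EcoRI site may overlap the final base of the leading
#' SbfI site, which is how the 13-bp minimum locus arises). Clean reads
#' pass unchanged.
#'
#' @param reads Tibble of processed reads starting with `CCTGCAGG`.
#' @return List with `reads` (kept reads, possibly truncated, with
#'   `internal_trimmed` set) and `discarded`.
#' @export
screen_internal_sites <- function(reads) {
  sbfi <- "CCTGCAGG"; ecori <- "GAATTC"
  n <- nrow(reads)
  keep <- rep(TRUE, n)
  if (n > 0L) {
    # internal SbfI: any occurrence starting after the leading site
    tails <- substr(reads$sequence, 2L, nchar(reads$sequence))
    keep <- !grepl(sbfi, tails, fixed = TRUE)
  }
  kept <- reads[keep, , drop = FALSE]
  if (nrow(kept) > 0L) {
    # terminal/internal EcoRI may share the final G of the leading SbfI
    # site, so the search starts at read position 8
    region <- substr(kept$sequence, 8L, nchar(kept$sequence))
    hit <- regexpr(ecori, region, fixed = TRUE)
    found <- hit > 0L
    cut_at <- 7L + as.integer(hit) + nchar(ecori) - 1L  # read coordinate of site end
    trim <- found & cut_at < nchar(kept$sequence)
    kept$sequence[trim] <- substr(kept$sequence[trim], 1L, cut_at[trim])
    kept$qual[trim] <- substr(kept$qual[trim], 1L, cut_at[trim])
    kept$internal_trimmed <- kept$internal_trimmed | trim
  }
  list(reads = kept, discarded = reads[!keep, , drop = FALSE])
}

#' Condense identical reads per sample
#'
#' One row per distinct (sample, sequence), carrying the multiplicity and
#' the position-wise maximum quality over the collapsed reads (retaining
#' the maximum is conservative: several independent observations of the
#' same base only increase confidence).
#'
#' @param reads Tibble with `sample_id`, `sequence`, `qual`.
#' @return Tibble with `sample_id`, `sequence`, `count`, `qual`
#'   (position-wise maximum, Phred+33), `mean_qual`.
#' @export
condense_reads <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble::tibble(sample_id = character(), sequence = character(),
                          count = integer(), qual = character(),
                          mean_qual = double()))
  }
  out <- reads |>
    dplyr::group_by(.data$sample_id, .data$sequence) |>
    dplyr::summarise(
      count = dplyr::n(),
      qual = max_qual_string(.data$qual),
      .groups = "drop"
    )
  out$mean_qual <- vapply(out$qual, function(q) mean(utf8ToInt(q) - 33L),
                          numeric(1), USE.NAMES = FALSE)
  dplyr::arrange(out, .data$sample_id, dplyr::desc(.data$count), .data$sequence)
}

# Position-wise maximum of Phred+33 strings of equal length. ASCII order
# equals quality order, so the maximum can be taken on raw bytes.
max_qual_string <- function(quals) {
  if (length(quals) == 1L) return(quals[[1]])
  m <- vapply(quals, utf8ToInt, integer(nchar(quals[[1]])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  intToUtf8(apply(m, 1L, max))
}

#' Within-sample quality filter for condensed reads
#'
#' Drops condensed reads that are simultaneously low quality (mean Phred
#' below `min_mean_q`), singletons (count 1), and isolated (no other
#' condensed read from the same sample within the identity threshold).
#' Everything else is retained.
#'
#' @param condensed Tibble from [condense_reads()].
#' @param identity Identity threshold for the neighbour search.
#' @param min_mean_q Mean-quality threshold.
#' @return Filtered tibble.
#' @export
within_sample_quality_filter <- function(condensed, identity = 0.90,
                                         min_mean_q = 20) {
  if (nrow(condensed) == 0L) return(condensed)
  drop <- rep(FALSE, nrow(condensed))
  cand <- which(condensed$mean_qual < min_mean_q & condensed$count == 1L)
  for (i in cand) {
    others <- condensed$sequence[condensed$sample_id == condensed$sample_id[i]]
    others <- setdiff(others, condensed$sequence[i])
    if (length(others) == 0L) {
      drop[i] <- TRUE
    } else {
      ids <- seq_identity_many(condensed$sequence[i], others)
      drop[i] <- all(ids < identity)
    }
  }
  condensed[!drop, , drop = FALSE]
}

#' Full read-processing stage
#'
#' Demultiplex, adapter-trim, concatemer-screen, condense, and
#' quality-filter a set of raw reads.
#'
#' @inheritParams demultiplex
#' @inheritParams trim_p2_adapter
#' @inheritParams within_sample_quality_filter
#' @return List with `condensed` (the filtered condensed reads), `stats`
#'   (per-sample accounting tibble), and `discarded`.
#' @export
process_reads <- function(reads, barcode_map, adapter = default_p2_adapter(),
                          min_overlap = 8L, max_err = 0.2,
                          identity = 0.90, min_mean_q = 20) {
  dm <- demultiplex(reads, barcode_map)
  trimmed <- trim_p2_adapter(dm$reads, adapter, min_overlap, max_err)
  scr <- screen_internal_sites(trimmed)
  condensed <- condense_reads(scr$reads)
  filtered <- within_sample_quality_filter(condensed, identity, min_mean_q)
  stats <- dm$counts |>
    dplyr::left_join(
      dplyr::count(scr$reads, .data$sample_id, name = "n_kept"),
      by = "sample_id"
    ) |>
    dplyr::left_join(
      dplyr::count(filtered, .data$sample_id, wt = .data$count,
                   name = "n_condensed_reads"),
      by = "sample_id"
    )
  list(condensed = filtered, stats = stats, discarded = scr$discarded)
}
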