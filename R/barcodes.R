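#' Generate an inline barcode set with Hamming-code separation
#'
#' Enumerates, in lexicographic order, all barcodes of the given length
#' with exactly `gc_count` G/C bases and no run of more than `max_run`
#' identical bases; retains the subset whose GF(4) digit sum is zero
#' (a single parity check over the alphabet A=0, C=1, G=2, T=3 under
#' addition in GF(4), which guarantees any two retained words differ at
#' two or more positions); then greedily adds any remaining candidates
#' that keep the minimum pairwise Hamming distance. The construction is
#' fully deterministic.
#'
#' @param length Barcode length (default 6).
#' @param gc_count Required number of G/C bases (default 3, i.e. 50% GC).
#' @param max_run Maximum run of identical bases (default 2).
#' @param min_dist Minimum pairwise Hamming distance (default 2).
#' @return Tibble with columns `barcode` and `gc`, one row per barcode.
#'   Infeasible constraints produce an empty tibble with a warning.
#' @examples
#' nrow(generate_barcode_set()) # >= 128
#' @export
generate_barcode_set <- function(length = 6L, gc_count = 3L, max_run = 2L,
                                 min_dist = 2L) {
  stopifnot(length >= 1L, gc_count >= 0L, max_run >= 1L, min_dist >= 1L)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), length), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; flip so column 1 is the
  # most significant digit and the enumeration is lexicographic
  grid <- grid[, rev(seq_len(length)), drop = FALSE]
  seqs <- do.call(paste0, grid)
  seqs <- sort(seqs)

  gc_ok <- stringr::str_count(seqs, "[GC]") == gc_count
  run_ok <- !grepl(sprintf("(.)\\1{%d,}", max_run), seqs)
  cand <- seqs[gc_ok & run_ok]
  if (length(cand) == 0L) {
    warning("Barcode constraints are infeasible; returning an empty set.")
    return(tibble::tibble(barcode = character(), gc = double()))
  }

  mat <- do.call(rbind, strsplit(cand, "", fixed = TRUE))
  digits <- matrix(match(mat, bases) - 1L, nrow = nrow(mat))
  # GF(4) = (Z/2)^2: addition is XOR on the 2-bit representation
  gf4_sum <- Reduce(bitwXor, asplit(digits, 2))
  code <- cand[gf4_sum == 0L]
  rest <- cand[gf4_sum != 0L]

  keep <- code
  keep_mat <- do.call(rbind, strsplit(keep, "", fixed = TRUE))
  for (s in rest) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(keep) == 0L ||
        min(rowSums(keep_mat != matrix(v, nrow = nrow(keep_mat),
                                       ncol = length, byrow = TRUE))) >= min_dist) {
      keep <- c(keep, s)
      keep_mat <- rbind(keep_mat, v)
    }
  }
  if (length(keep) == 0L) {
    warning("Barcode constraints are infeasible; returning an empty set.")
    return(tibble::tibble(barcode = character(), gc = double()))
  }
  tibble::tibble(
    barcode = keep,
    gc = stringr::str_count(keep, "[GC]") / length
  )
}

#' Pairwise Hamming distances of equal-length barcodes
#'
#' @param barcodes Character vector of equal-length sequences.
#' @return Integer matrix of pairwise distances.
#' @export
barcode_distances <- function(barcodes) {
  stopifnot(length(unique(nchar(barcodes))) <= 1L)
  m <- do.call(rbind, strsplit(barcodes, "", fixed = TRUE))
  n <- length(barcodes)
  d <- matrix(0L, n, n, dimnames = list(barcodes, barcodes))
  for (i in seq_len(n)) {
    d[i, ] <- as.integer(colSums(t(m) != m[i, ]))
  }
  d
}

#' Read a barcode-to-sample map
#'
#' @param path TSV with columns `barcode` and `sample_id` (header
#'   optional; two unnamed columns are taken in that order).
#' @return Tibble with `barcode`, `sample_id`.
#' @export
read_barcode_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("barcode", "sample_id") %in% names(df))) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    names(df)[1:2] <- c("barcode", "sample_id")
  }
  check_barcode_map(tibble::as_tibble(df[, c("barcode", "sample_id")]))
}

check_barcode_map <- function(map) {
  map$barcode <- toupper(map$barcode)
  if (anyDuplicated(map$barcode)) {
    stop("Duplicate barcode -> sample mappings in barcode map.", call. = FALSE)
  }
  if (length(unique(nchar(map$barcode))) > 1L) {
    stop("All barcodes must have the same length.", call. = FALSE)
  }
  map
}
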