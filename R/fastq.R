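#' Read a FASTQ file into a tibble
#'
#' Qualities are kept as Phred+33 encoded strings; see [phred_ints()] to
#' decode.
#'
#' @param path FASTQ file (may be gzipped).
#' @return Tibble with columns `id`, `sequence`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = unname(sub("\\s.*$", "", names(x))),
    sequence = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with `id`, `sequence`, `qual` (Phred+33 strings).
#' @param path Output path; a ".gz" suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$qual)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$qual),
             con)
  invisible(path)
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual Character vector of Phred+33 strings.
#' @return For `phred_ints()`, a list of integer vectors; for
#'   `phred_string()`, a character vector.
#' @export
phred_ints <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' @param ints List of integer vectors (or a single vector) of Phred scores.
#' @rdname phred_ints
#' @export
phred_string <- function(ints) {
  if (!is.list(ints)) ints <- list(ints)
  vapply(ints, function(v) intToUtf8(v + 33L), character(1))
}

# Sentinel quality for bases synthesized during restriction-site
# reconstruction ("CC" prefix, trailing "C"): Q40.
SENTINEL_QUAL <- 40L
SENTINEL_CHAR <- "I"
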