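#' Coerce to a reference genome
#'
#' A reference genome is represented as a named character vector of
#' uppercase contig sequences (A/C/G/T/N). Accepts a named character
#' vector, a `Biostrings::DNAStringSet`, or a path to a (optionally
#' gzipped) FASTA file.
#'
#' @param x Genome input.
#' @return Named character vector of class `ddrad_genome`.
#' @examples
#' g <- as_genome(c(chr1 = "AACCTGCAGGTT"))
#' @export
as_genome <- function(x) {
  if (inherits(x, "ddrad_genome")) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
    # FASTA headers may carry descriptions after the first token
    names(seqs) <- sub("\\s.*$", "", names(x))
    x <- seqs
  }
  if (!is.character(x) || is.null(names(x))) {
    stop("Genome must be a named character vector, DNAStringSet, or FASTA path.",
         call. = FALSE)
  }
  x <- toupper(x)
  if (anyDuplicated(names(x))) stop("Contig names must be unique.", call. = FALSE)
  if (any(!nzchar(x))) stop("Empty contigs are not allowed.", call. = FALSE)
  if (any(grepl("[^ACGTN]", x))) {
    stop("Genome sequences may contain only A/C/G/T/N.", call. = FALSE)
  }
  structure(x, class = "ddrad_genome")
}

#' @export
print.ddrad_genome <- function(x, ...) {
  cat(sprintf("<genome: %d contig(s), %s bp>\n", length(x),
              format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome See [as_genome()].
#' @param path Output file path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

genome_subseq <- function(genome, contig, start0, end0) {
  # 0-based half-open coordinates on the top strand
  substr(genome[[contig]], start0 + 1L, end0)
}
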