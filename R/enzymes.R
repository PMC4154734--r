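#' Built-in restriction enzyme table
#'
#' The five enzymes supported out of the box. All have palindromic
#' recognition sequences, so a top-strand scan finds every site on both
#' strands. `cut_offset_top` is the distance in bases from the start of the
#' recognition sequence to the top-strand cut; it is carried for
#' documentation only, because sequencing of ddRAD fragments reconstructs
#' the full recognition site and all fragment coordinates in this package
#' are defined on recognition-site boundaries.
#'
#' @return A tibble with columns `name`, `recognition`, `cut_offset_top`,
#'   `palindromic`.
#' @examples
#' restriction_enzymes()
#' @export
restriction_enzymes <- function() {
  tibble::tibble(
    name           = c("SbfI", "EcoRI", "MspI", "MseI", "PstI"),
    recognition    = c("CCTGCAGG", "GAATTC", "CCGG", "TTAA", "CTGCAG"),
    cut_offset_top = c(6L, 1L, 1L, 1L, 5L),
    palindromic    = TRUE
  )
}

#' Look up or construct a restriction enzyme
#'
#' @param name Enzyme name. One of the built-ins (see
#'   [restriction_enzymes()]) or any name when `recognition` is supplied.
#' @param recognition Optional recognition sequence over A/C/G/T for a
#'   custom enzyme.
#' @param cut_offset_top Optional top-strand cut offset (bases from the
#'   recognition start). Defaults to 0 for custom enzymes.
#' @return A list of class `ddrad_enzyme` with fields `name`,
#'   `recognition`, `cut_offset_top`, `palindromic`.
#' @examples
#' enzyme("SbfI")
#' @export
enzyme <- function(name, recognition = NULL, cut_offset_top = NULL) {
  if (inherits(name, "ddrad_enzyme")) {
    return(name)
  }
  if (is.null(recognition)) {
    tab <- restriction_enzymes()
    hit <- tab[tab$name == name, ]
    if (nrow(hit) != 1L) {
      stop("Unknown enzyme '", name, "'; supply `recognition` for a custom enzyme.",
           call. = FALSE)
    }
    recognition <- hit$recognition
    cut_offset_top <- hit$cut_offset_top
  }
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L || grepl("[^ACGT]", recognition)) {
    stop("Recognition sequence must be >= 4 bases over A/C/G/T.", call. = FALSE)
  }
  if (is.null(cut_offset_top)) cut_offset_top <- 0L
  if (cut_offset_top < 0L || cut_offset_top > nchar(recognition)) {
    stop("cut_offset_top must lie within the recognition sequence.", call. = FALSE)
  }
  structure(
    list(
      name = name,
      recognition = recognition,
      cut_offset_top = as.integer(cut_offset_top),
      palindromic = identical(recognition, revcomp(recognition))
    ),
    class = "ddrad_enzyme"
  )
}

#' @export
print.ddrad_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at +%d%s>\n", x$name, x$recognition,
              x$cut_offset_top, if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' Vectorised; accepts A/C/G/T/N.
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
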