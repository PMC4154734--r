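# Pairwise alignment utilities shared by the quality filter, the
# clusterer and the center-star MSA. Scoring: unit match, -1 mismatch,
# affine gaps (open 2, extend 1). Identity is matching columns divided by
# alignment columns, with end gaps free: the shorter sequence must be
# aligned in full, the longer may overhang (this accommodates length
# differences from short adapter-trimmed loci without rewarding spurious
# tiny overlaps).

ddrad_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE, type = "DNA")
}

hamming_frac <- function(a, b) {
  # equal-length ungapped mismatch fraction on raw bytes
  av <- utf8ToInt(a)
  mean(av != utf8ToInt(b))
}

#' Pairwise identity of one query against many targets
#'
#' Equal-length pairs are screened gaplessly first: pairs within 15%
#' ungapped mismatches are accepted at their gapless identity (their
#' optimal alignment is gapless), and pairs below 50% gapless identity
#' are reported at it without consulting the aligner (no biologically
#' meaningful gapped alignment rescues such a pair). Only the
#' inconclusive band and length-mismatched pairs go through the
#' affine-gap aligner.
#'
#' @param query A single sequence.
#' @param targets Character vector of sequences.
#' @return Numeric vector of identities in \[0, 1\], one per target.
#' @export
seq_identity_many <- function(query, targets) {
  out <- rep(NA_real_, length(targets))
  if (length(targets) == 0L) return(numeric(0))
  qlen <- nchar(query)
  same_len <- nchar(targets) == qlen
  if (any(same_len)) {
    hf <- vapply(targets[same_len], hamming_frac, numeric(1), a = query,
                 USE.NAMES = FALSE)
    fast <- hf <= 0.15 | hf >= 0.5
    out[same_len][fast] <- 1 - hf[fast]
  }
  todo <- is.na(out)
  if (!any(todo)) return(out)
  targets_slow <- targets[todo]
  slow <- numeric(length(targets_slow))
  sm <- ddrad_submat()
  shorter <- nchar(targets_slow) <= qlen
  # targets no longer than the query: align each target in full
  if (any(shorter)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(targets_slow[shorter]),
      subject = Biostrings::DNAString(query),
      type = "global-local", substitutionMatrix = sm,
      gapOpening = 2, gapExtension = 1
    )
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    slow[shorter] <- Biostrings::nmatch(aln) / cols
  }
  # targets longer than the query: align the query (subject) in full
  if (any(!shorter)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(targets_slow[!shorter]),
      subject = Biostrings::DNAString(query),
      type = "local-global", substitutionMatrix = sm,
      gapOpening = 2, gapExtension = 1
    )
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    slow[!shorter] <- Biostrings::nmatch(aln) / cols
  }
  out[todo] <- slow
  out
}

#' Pairwise identity of two sequences
#'
#' @param a,b Sequences.
#' @return Identity in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  seq_identity_many(a, b)
}

# Align one member against the centroid and return the pair padded to
# full coverage of both sequences (explicit end gaps), as two
# equal-length character vectors. Equal-length near-identical pairs are
# gapless and skip the aligner.
padded_pair <- function(member, centroid) {
  if (nchar(member) == nchar(centroid) &&
      hamming_frac(member, centroid) <= 0.15) {
    return(list(member = strsplit(member, "")[[1]],
                centroid = strsplit(centroid, "")[[1]]))
  }
  sm <- ddrad_submat()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(member),
    subject = Biostrings::DNAString(centroid),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 2, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pr <- IRanges::ranges(Biostrings::pattern(aln))
  sr <- IRanges::ranges(Biostrings::subject(aln))
  p_pre <- substr(member, 1L, BiocGenerics::start(pr) - 1L)
  p_suf <- substr(member, BiocGenerics::end(pr) + 1L, nchar(member))
  s_pre <- substr(centroid, 1L, BiocGenerics::start(sr) - 1L)
  s_suf <- substr(centroid, BiocGenerics::end(sr) + 1L, nchar(centroid))
  split1 <- function(x) if (nzchar(x)) strsplit(x, "")[[1]] else character(0)
  p_pre <- split1(p_pre); p_suf <- split1(p_suf)
  s_pre <- split1(s_pre); s_suf <- split1(s_suf)
  # unaligned overhangs become end-gap columns; centroid columns first
  pad_p <- c(rep("-", length(s_pre)), p_pre, p,
             rep("-", length(s_suf)), p_suf)
  pad_s <- c(s_pre, rep("-", length(p_pre)), s,
             s_suf, rep("-", length(p_suf)))
  list(member = pad_p, centroid = pad_s)
}

# Decompose a padded pair into, per centroid slot i in 0..L, the member
# characters inserted before centroid base i+1 (`ins`), and the member
# character aligned to each centroid base (`at`).
decompose_on_centroid <- function(pair, L) {
  ins <- vector("list", L + 1L)
  for (i in seq_len(L + 1L)) ins[[i]] <- character(0)
  at <- rep("-", L)
  cpos <- 0L
  for (j in seq_along(pair$centroid)) {
    if (pair$centroid[j] == "-") {
      ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], pair$member[j])
    } else {
      cpos <- cpos + 1L
      at[cpos] <- pair$member[j]
    }
  }
  list(ins = ins, at = at)
}

#' Center-star multiple alignment of a sequence cluster
#'
#' Each member is pairwise-aligned against the centroid (affine gaps, end
#' gaps free) and the pairwise alignments are merged column-wise on
#' centroid coordinates: at each centroid slot the insertion width is the
#' maximum over members, shorter insertions are right-padded with gaps.
#' Adequate for clusters whose members are >= 85% identical, and fully
#' deterministic.
#'
#' @param sequences Character vector of member sequences; the first
#'   element is taken as the centroid.
#' @param quals Optional list of per-base integer quality vectors,
#'   parallel to `sequences`.
#' @return List with `rows` (gapped sequences, same order as input),
#'   `qual_rows` (gapped qualities, `NA` at gaps; NULL if `quals`
#'   missing), and `ncol`.
#' @export
center_star_align <- function(sequences, quals = NULL) {
  stopifnot(length(sequences) >= 1L)
  centroid <- sequences[[1]]
  L <- nchar(centroid)
  decomps <- lapply(sequences, function(s) {
    if (identical(s, centroid)) {
      decompose_on_centroid(
        list(member = strsplit(s, "")[[1]], centroid = strsplit(centroid, "")[[1]]), L)
    } else {
      decompose_on_centroid(padded_pair(s, centroid), L)
    }
  })
  widths <- vapply(seq_len(L + 1L), function(i) {
    max(vapply(decomps, function(d) length(d$ins[[i]]), integer(1)))
  }, integer(1))
  rows <- vapply(decomps, function(d) {
    parts <- character(0)
    for (i in seq_len(L + 1L)) {
      insert <- d$ins[[i]]
      parts <- c(parts, insert, rep("-", widths[i] - length(insert)))
      if (i <= L) parts <- c(parts, d$at[i])
    }
    paste(parts, collapse = "")
  }, character(1))
  qual_rows <- NULL
  if (!is.null(quals)) {
    qual_rows <- purrr::map2(rows, quals, function(row, q) {
      chars <- strsplit(row, "")[[1]]
      out <- rep(NA_integer_, length(chars))
      out[chars != "-"] <- q
      out
    })
  }
  list(rows = rows, qual_rows = qual_rows, ncol = sum(widths) + L)
}
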