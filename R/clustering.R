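#' Greedy identity clustering of condensed reads across samples
#'
#' Reads are processed in descending mean quality (ties broken by
#' descending count, then lexicographic sequence). Each read joins the
#' first existing centroid whose pairwise identity reaches the threshold,
#' otherwise it founds a new cluster with itself as centroid. Identity is
#' matching columns over alignment columns, end gaps free (see
#' [seq_identity()]).
#'
#' @param condensed Condensed reads pooled across samples (see
#'   [condense_reads()]).
#' @param identity Identity threshold (default 0.85).
#' @return `condensed` with `cluster_id` (integer, in centroid-founding
#'   order) and `is_centroid` columns, ordered by processing order.
#' @export
cluster_across_samples <- function(condensed, identity = 0.85) {
  if (nrow(condensed) == 0L) {
    return(dplyr::mutate(condensed, cluster_id = integer(), is_centroid = logical()))
  }
  condensed <- dplyr::arrange(
    condensed, dplyr::desc(.data$mean_qual), dplyr::desc(.data$count),
    .data$sequence
  )
  n <- nrow(condensed)
  cluster_id <- integer(n)
  centroid_seqs <- character(0)
  seq_to_cluster <- new.env(parent = emptyenv())  # exact-match shortcut
  for (i in seq_len(n)) {
    s <- condensed$sequence[i]
    hit <- get0(s, envir = seq_to_cluster)
    if (!is.null(hit)) {
      cluster_id[i] <- hit
      next
    }
    assigned <- 0L
    if (length(centroid_seqs) > 0L) {
      ids <- seq_identity_many(s, centroid_seqs)
      ok <- which(ids >= identity)
      if (length(ok) > 0L) assigned <- ok[1]
    }
    if (assigned == 0L) {
      centroid_seqs <- c(centroid_seqs, s)
      assigned <- length(centroid_seqs)
    }
    cluster_id[i] <- assigned
    assign(s, assigned, envir = seq_to_cluster)
  }
  condensed$cluster_id <- cluster_id
  condensed$is_centroid <- !duplicated(cluster_id)
  condensed
}

#' Build a reference mapper from a genome
#'
#' Returns a function `(sequence) -> tibble(contig, start, end, strand,
#' identity)` listing match locations of the sequence in the genome on
#' both strands, exact first and then allowing up to `max_mismatch`
#' substitutions. A minimal deterministic stand-in for an external
#' aligner, adequate for synthetic genomes; any function with the same
#' signature can be supplied to [map_clusters()] instead.
#'
#' @param genome See [as_genome()].
#' @param max_mismatch Maximum substitutions tolerated when no exact
#'   match exists.
#' @return A mapper function.
#' @export
genome_mapper <- function(genome, max_mismatch = 5L) {
  genome <- as_genome(genome)
  subjects <- lapply(unclass(genome), Biostrings::DNAString)
  function(sequence) {
    hits <- list()
    # escalate the allowance until something matches (substitutions
    # first for stable coordinates, then indel-tolerant), so the
    # reported identity reflects the minimal distance
    plan <- rbind(data.frame(mm = 0:max_mismatch, indels = FALSE),
                  data.frame(mm = seq_len(max_mismatch), indels = TRUE))
    for (step in seq_len(nrow(plan))) {
      mm <- plan$mm[step]
      for (ctg in names(subjects)) {
        for (strand in c("+", "-")) {
          query <- if (strand == "+") sequence else revcomp(sequence)
          m <- Biostrings::matchPattern(query, subjects[[ctg]],
                                        max.mismatch = mm,
                                        with.indels = plan$indels[step],
                                        fixed = TRUE)
          if (length(m) > 0L) {
            hits[[length(hits) + 1L]] <- tibble::tibble(
              contig = ctg,
              start = BiocGenerics::start(m) - 1L,
              end = BiocGenerics::end(m),
              strand = strand,
              identity = 1 - mm / nchar(sequence)
            )
          }
        }
      }
      if (length(hits) > 0L) break
    }
    if (length(hits) == 0L) {
      # local-alignment fallback for sequences separated from the
      # reference by a long indel: infer the locus start from the best
      # local block, requiring at least 40% of the query to match
      sm <- ddrad_submat()
      best <- NULL
      for (ctg in names(subjects)) {
        for (strand in c("+", "-")) {
          query <- if (strand == "+") sequence else revcomp(sequence)
          aln <- Biostrings::pairwiseAlignment(
            pattern = Biostrings::DNAString(query), subject = subjects[[ctg]],
            type = "local", substitutionMatrix = sm,
            gapOpening = 5, gapExtension = 2
          )
          nm <- Biostrings::nmatch(aln)
          if (nm >= max(30L, ceiling(0.4 * nchar(sequence))) &&
              (is.null(best) || nm > best$nm)) {
            p0 <- BiocGenerics::start(IRanges::ranges(Biostrings::pattern(aln)))
            s0 <- BiocGenerics::start(IRanges::ranges(Biostrings::subject(aln)))
            start <- max(s0 - p0, 0L)
            best <- list(nm = nm, contig = ctg, start = start,
                         end = start + nchar(sequence), strand = strand,
                         identity = nm / nchar(sequence))
          }
        }
      }
      if (!is.null(best)) {
        hits[[1L]] <- tibble::tibble(
          contig = best$contig, start = best$start, end = best$end,
          strand = best$strand, identity = best$identity
        )
      }
    }
    if (length(hits) == 0L) {
      return(tibble::tibble(contig = character(), start = integer(),
                            end = integer(), strand = character(),
                            identity = double()))
    }
    dplyr::distinct(dplyr::arrange(dplyr::bind_rows(hits),
                                   dplyr::desc(.data$identity),
                                   .data$contig, .data$start))
  }
}

#' Map cluster centroids to a reference
#'
#' The best hit (highest identity, ties by coordinate) is recorded per
#' cluster together with a uniqueness flag; clusters without any hit are
#' marked anonymous and retained. A mapper failure downgrades the cluster
#' to anonymous with a warning rather than failing the run.
#'
#' @param clustered Output of [cluster_across_samples()].
#' @param mapper A function `(sequence) -> hit tibble`, e.g. from
#'   [genome_mapper()].
#' @return Tibble with one row per cluster: `cluster_id`, `centroid`,
#'   `n_reads`, `n_samples`, `contig`, `pos`, `end`, `strand`,
#'   `identity`, `unique`, `anonymous`.
#' @export
map_clusters <- function(clustered, mapper) {
  cl <- cluster_summary(clustered)
  hits <- purrr::map(cl$centroid, function(s) {
    tryCatch(mapper(s), error = function(e) {
      warning("Mapper failed for a centroid (", conditionMessage(e),
              "); cluster kept as anonymous.", call. = FALSE)
      NULL
    })
  })
  cl$contig <- NA_character_; cl$pos <- NA_integer_; cl$end <- NA_integer_
  cl$strand <- NA_character_; cl$identity <- NA_real_; cl$unique <- NA
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (!is.null(h) && nrow(h) > 0L) {
      cl$contig[i] <- h$contig[1]; cl$pos[i] <- h$start[1]
      cl$end[i] <- h$end[1]; cl$strand[i] <- h$strand[1]
      cl$identity[i] <- h$identity[1]
      cl$unique[i] <- nrow(h) == 1L
    }
  }
  cl$anonymous <- is.na(cl$contig)
  cl
}

#' Per-cluster summary of a clustered read table
#'
#' @param clustered Output of [cluster_across_samples()].
#' @return Tibble with `cluster_id`, `centroid`, `n_reads` (summed
#'   multiplicities), `n_samples`, `centroid_mean_qual`.
#' @export
cluster_summary <- function(clustered) {
  clustered |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      centroid = .data$sequence[.data$is_centroid][1],
      n_reads = sum(.data$count),
      n_samples = dplyr::n_distinct(.data$sample_id),
      centroid_mean_qual = .data$mean_qual[.data$is_centroid][1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster_id)
}

#' Merge mapped clusters by genomic position
#'
#' Clusters whose best hits share contig and strand and whose start
#' positions lie within `tol_bp` are merged. Merging is single-link: the
#' closure is chained, so a run of hits each within `tol_bp` of the next
#' collapses into one locus (disable with `chain = FALSE` to require all
#' pairwise distances within `tol_bp`). The merged cluster keeps the id
#' and centroid of the member with the highest centroid quality.
#' Anonymous clusters never merge. This is what reunites alleles split by
#' a long indel.
#'
#' @param mapped Output of [map_clusters()].
#' @param clustered The clustered read table (its `cluster_id` column is
#'   rewritten).
#' @param tol_bp Position tolerance in bp (default 50).
#' @param chain Single-link chaining (default TRUE).
#' @return List with `mapped` (merged cluster table) and `clustered`
#'   (reads relabelled to merged cluster ids).
#' @export
merge_by_position <- function(mapped, clustered, tol_bp = 50L, chain = TRUE) {
  mp <- dplyr::arrange(mapped, .data$contig, .data$strand, .data$pos)
  merge_into <- stats::setNames(mapped$cluster_id, mapped$cluster_id)
  grp <- mp |> dplyr::filter(!.data$anonymous) |>
    dplyr::group_by(.data$contig, .data$strand)
  for (g in dplyr::group_split(grp)) {
    if (nrow(g) < 2L) next
    gap_ok <- diff(g$pos) <= tol_bp
    comp <- cumsum(c(TRUE, !gap_ok))
    if (!chain) {
      # greedily split chained runs so each merged group spans <= tol_bp
      sub <- integer(nrow(g))
      for (cc in unique(comp)) {
        idx <- which(comp == cc)
        anchor <- g$pos[idx[1]]; k <- 0L
        for (j in idx) {
          if (g$pos[j] - anchor > tol_bp) { k <- k + 1L; anchor <- g$pos[j] }
          sub[j] <- k
        }
      }
      comp <- comp * (max(sub) + 1L) + sub
    }
    for (cc in unique(comp)) {
      members <- g$cluster_id[comp == cc]
      if (length(members) < 2L) next
      quals <- g$centroid_mean_qual[comp == cc]
      keep_id <- members[order(-quals, members)][1]
      merge_into[as.character(members)] <- keep_id
    }
  }
  clustered$cluster_id <- unname(merge_into[as.character(clustered$cluster_id)])
  merged <- mapped
  merged$cluster_id <- unname(merge_into[as.character(mapped$cluster_id)])
  merged <- merged |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::slice_max(.data$centroid_mean_qual, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  # recompute membership counts after relabelling
  sizes <- clustered |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(n_reads = sum(.data$count),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
  merged <- merged |>
    dplyr::select(-"n_reads", -"n_samples") |>
    dplyr::left_join(sizes, by = "cluster_id") |>
    dplyr::arrange(.data$cluster_id)
  list(mapped = merged, clustered = clustered)
}

#' Align every cluster with the center-star aligner
#'
#' Within each cluster the member with the highest mean quality (ties:
#' count, then sequence) is the alignment center.
#'
#' @param clustered Clustered (and possibly merged) condensed reads.
#' @return Tibble with one row per cluster member: `cluster_id`,
#'   `member_id`, `sample_id`, `count`, `mean_qual`, `row` (gapped
#'   sequence) and `quals` (list of gapped integer qualities, `NA` at
#'   gaps).
#' @export
align_clusters <- function(clustered) {
  clustered <- dplyr::arrange(
    clustered, .data$cluster_id, dplyr::desc(.data$mean_qual),
    dplyr::desc(.data$count), .data$sequence
  )
  out <- clustered |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_map(function(g, key) {
      msa <- center_star_align(g$sequence, phred_ints(g$qual))
      tibble::tibble(
        cluster_id = key$cluster_id,
        member_id = seq_len(nrow(g)),
        sample_id = g$sample_id,
        count = g$count,
        mean_qual = g$mean_qual,
        row = msa$rows,
        quals = msa$qual_rows
      )
    }) |>
    dplyr::bind_rows()
  out
}
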