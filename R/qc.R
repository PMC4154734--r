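#' Missingness and flagged-genotype accounting
#'
#' Partitions loci into constant vs variable and complete vs partial
#' (complete = every sample genotyped cleanly at or above `min_depth`;
#' partial = at least `min_samples_frac` of samples with data), then
#' counts genotype cells by outcome within each category, with
#' percentages of the grand total.
#'
#' @param calls Tibble with `locus_id`, `sample_id`, `status`, `depth`
#'   and a logical `variable` column (per locus); missing
#'   (sample, locus) combinations are treated as MISSING cells.
#' @param min_depth Depth below which a cell counts as low depth
#'   (default 5).
#' @param min_samples_frac Minimum fraction of samples with at least one
#'   read for a locus to enter the partial category (default 42/46).
#' @return List of class `ddrad_missingness`: `by_category` tibble,
#'   `totals` one-row tibble (`n_loci`, `total_cells`, `n_low_depth`,
#'   `n_missing`, `n_bad_ratio`, `n_extra_reads`, and `pct_*`
#'   percentages of total cells, one decimal).
#' @export
missingness_summary <- function(calls, min_depth = 5L,
                                min_samples_frac = 42 / 46) {
  samples <- sort(unique(calls$sample_id))
  n_samples <- length(samples)
  full <- tidyr::complete(
    calls, locus_id = unique(calls$locus_id), sample_id = samples,
    fill = list(status = "MISSING", depth = 0L)
  )
  full <- full |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::mutate(variable = any(.data$variable, na.rm = TRUE)) |>
    dplyr::ungroup()
  full$low_depth <- full$status == "LOW_DEPTH" |
    (full$depth > 0L & full$depth < min_depth)
  full$missing <- full$status == "MISSING" | full$depth == 0L
  per_locus <- full |>
    dplyr::group_by(.data$locus_id, .data$variable) |>
    dplyr::summarise(
      n_with_data = sum(!.data$missing),
      clean = all(!.data$missing & !.data$low_depth &
                    !.data$status %in% c("BAD_RATIO", "EXTRA_READS")),
      .groups = "drop"
    )
  per_locus$completeness <- ifelse(per_locus$clean, "complete",
                                   ifelse(per_locus$n_with_data >=
                                            ceiling(min_samples_frac * n_samples),
                                          "partial", "below_threshold"))
  full <- dplyr::left_join(
    full, dplyr::select(per_locus, "locus_id", "completeness"), by = "locus_id"
  ) |>
    dplyr::filter(.data$completeness != "below_threshold")
  by_cat <- full |>
    dplyr::group_by(variability = ifelse(.data$variable, "variable", "constant"),
                    completeness = .data$completeness) |>
    dplyr::summarise(
      n_loci = dplyr::n_distinct(.data$locus_id),
      cells = dplyr::n(),
      n_low_depth = sum(.data$low_depth & !.data$missing),
      n_missing = sum(.data$missing),
      n_bad_ratio = sum(.data$status == "BAD_RATIO"),
      n_extra_reads = sum(.data$status == "EXTRA_READS"),
      .groups = "drop"
    )
  tot <- dplyr::summarise(
    by_cat,
    n_loci = sum(.data$n_loci), total_cells = sum(.data$cells),
    n_low_depth = sum(.data$n_low_depth), n_missing = sum(.data$n_missing),
    n_bad_ratio = sum(.data$n_bad_ratio),
    n_extra_reads = sum(.data$n_extra_reads)
  )
  for (col in c("n_low_depth", "n_missing", "n_bad_ratio", "n_extra_reads")) {
    tot[[sub("^n_", "pct_", col)]] <-
      round(100 * tot[[col]] / tot$total_cells, 1)
  }
  structure(list(by_category = by_cat, totals = tot, n_samples = n_samples),
            class = "ddrad_missingness")
}

#' @export
print.ddrad_missingness <- function(x, ...) {
  cat(sprintf("<missingness: %d loci, %s cells; low depth %.1f%%, missing %.1f%%>\n",
              x$totals$n_loci, format(x$totals$total_cells, big.mark = ","),
              x$totals$pct_low_depth, x$totals$pct_missing))
  print(x$by_category)
  invisible(x)
}

#' Exact binomial test of heterozygote allele balance
#'
#' Two-sided exact test of the two allele depths against Binomial(a+b,
#' 0.5): the p-value sums the probabilities of all outcomes no more
#' likely than the observed one. Vectorised.
#'
#' @param a,b Read depths of the two alleles.
#' @return Numeric vector of p-values.
#' @examples
#' heterozygote_balance_test(14, 14) # 1
#' @export
heterozygote_balance_test <- function(a, b) {
  stopifnot(length(a) == length(b), all(a + b >= 1))
  purrr::map2_dbl(a, b, function(x, y) {
    stats::binom.test(x, x + y, p = 0.5)$p.value
  })
}

#' Depth variance components by two-way ANOVA
#'
#' Fits `depth ~ locus + sample` (no interaction: one observation per
#' cell) and reports the partial eta-squared of each factor,
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param depths Either a numeric matrix (loci x samples) or a long
#'   tibble with `locus_id`, `sample_id`, `depth`.
#' @return Object of class `ddrad_anova` with `table` (tibble `term`,
#'   `df`, `sumsq`, `partial_eta_sq`) and the underlying `aov` fit.
#' @export
depth_variance_components <- function(depths) {
  if (is.matrix(depths)) {
    if (is.null(rownames(depths))) {
      rownames(depths) <- sprintf("L%d", seq_len(nrow(depths)))
    }
    if (is.null(colnames(depths))) {
      colnames(depths) <- sprintf("s%d", seq_len(ncol(depths)))
    }
    depths <- tibble::as_tibble(depths, rownames = "locus_id") |>
      tidyr::pivot_longer(-"locus_id", names_to = "sample_id",
                          values_to = "depth")
  }
  if (dplyr::n_distinct(depths$locus_id) < 2L ||
      dplyr::n_distinct(depths$sample_id) < 2L) {
    stop("Need at least 2 loci and 2 samples.", call. = FALSE)
  }
  fit <- stats::aov(depth ~ locus_id + sample_id,
                    data = dplyr::mutate(depths,
                                         locus_id = factor(.data$locus_id),
                                         sample_id = factor(.data$sample_id)))
  ss <- summary(fit)[[1]]
  terms <- trimws(rownames(ss))
  resid_ss <- ss[terms == "Residuals", "Sum Sq"]
  tab <- tibble::tibble(
    term = c("locus", "sample", "residual"),
    df = ss[c(which(terms == "locus_id"), which(terms == "sample_id"),
              which(terms == "Residuals")), "Df"],
    sumsq = ss[c(which(terms == "locus_id"), which(terms == "sample_id"),
                 which(terms == "Residuals")), "Sum Sq"]
  )
  tab$partial_eta_sq <- c(
    tab$sumsq[1] / (tab$sumsq[1] + resid_ss),
    tab$sumsq[2] / (tab$sumsq[2] + resid_ss),
    NA_real_
  )
  structure(list(table = tab, fit = fit), class = "ddrad_anova")
}

#' @export
print.ddrad_anova <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Per-locus coefficient of variation in depth
#'
#' CV = sd/mean of each locus's depth across samples; loci with zero
#' mean are reported with NA and excluded from the summary.
#'
#' @param depths Matrix (loci x samples) or long tibble with `locus_id`,
#'   `sample_id`, `depth`.
#' @return List: `per_locus` tibble (`locus_id`, `mean`, `sd`, `cv`) and
#'   `summary` one-row tibble (`mean_cv`, `sd_cv`, `n_loci`).
#' @export
per_locus_depth_cv <- function(depths) {
  if (is.matrix(depths)) {
    stopifnot(ncol(depths) >= 2L)
    per <- tibble::tibble(
      locus_id = if (is.null(rownames(depths)))
        as.character(seq_len(nrow(depths))) else rownames(depths),
      mean = unname(rowMeans(depths)),
      sd = unname(apply(depths, 1L, stats::sd))
    )
  } else {
    stopifnot(dplyr::n_distinct(depths$sample_id) >= 2L)
    per <- depths |>
      dplyr::group_by(.data$locus_id) |>
      dplyr::summarise(mean = mean(.data$depth), sd = stats::sd(.data$depth),
                       .groups = "drop")
  }
  per$cv <- ifelse(per$mean > 0, per$sd / per$mean, NA_real_)
  ok <- !is.na(per$cv)
  list(
    per_locus = per,
    summary = tibble::tibble(mean_cv = mean(per$cv[ok]),
                             sd_cv = stats::sd(per$cv[ok]),
                             n_loci = sum(ok))
  )
}

#' Site frequency spectrum with constant-size neutral expectation
#'
#' Given per-locus minor/derived allele counts over `n_chrom`
#' chromosomes, tabulates the observed spectrum and the neutral
#' expectation proportional to `1/i`, normalised over the spectrum's
#' frequency classes. `folded = TRUE` collapses class `i` with
#' `n_chrom - i`.
#'
#' @param allele_counts Integer vector, one allele count per polymorphic
#'   locus (each in `1 .. n_chrom - 1`).
#' @param n_chrom Number of sampled chromosomes (2 x individuals).
#' @param folded Fold the spectrum?
#' @return Tibble of class `ddrad_sfs`: `count_class`, `observed`,
#'   `expected` (same total as observed). Monomorphic input yields an
#'   empty spectrum.
#' @export
site_frequency_spectrum <- function(allele_counts, n_chrom, folded = FALSE) {
  allele_counts <- allele_counts[allele_counts > 0L &
                                   allele_counts < n_chrom]
  classes <- seq_len(n_chrom - 1L)
  expected_w <- 1 / classes
  if (folded) {
    fold <- pmin(classes, n_chrom - classes)
    allele_counts <- pmin(allele_counts, n_chrom - allele_counts)
    expected_w <- vapply(sort(unique(fold)), function(k) {
      sum(1 / classes[fold == k])
    }, numeric(1))
    classes <- sort(unique(fold))
  }
  if (length(allele_counts) == 0L) {
    out <- tibble::tibble(count_class = integer(), observed = integer(),
                          expected = double())
    class(out) <- c("ddrad_sfs", class(out))
    return(out)
  }
  obs <- vapply(classes, function(k) sum(allele_counts == k), integer(1))
  expected <- expected_w / sum(expected_w) * sum(obs)
  out <- tibble::tibble(count_class = classes, observed = obs,
                        expected = expected)
  class(out) <- c("ddrad_sfs", class(out))
  out
}

#' Minor-allele counts from biallelic genotype calls
#'
#' @param calls Calls tibble (`locus_id`, `sample_id`, `status`,
#'   `allele1`, `allele2`); only cleanly called biallelic loci are used.
#' @return Tibble `locus_id`, `minor_count`, `n_chrom`.
#' @export
allele_counts_from_calls <- function(calls) {
  called <- calls[calls$status %in% c("HOM", "HET", "HET_PROVISIONAL_PASSED"), ,
                  drop = FALSE]
  called |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_alleles = dplyr::n_distinct(.data$allele),
      minor_count = if (dplyr::n_distinct(.data$allele) == 2L)
        min(table(.data$allele)) else NA_integer_,
      n_chrom = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_alleles == 2L) |>
    dplyr::select("locus_id", "minor_count", "n_chrom")
}

#' Classify a recovered locus against the reference digest
#'
#' Reproduces the four-way diagnosis of where sequenced loci come from,
#' in priority order: (1) the locus starts at the leading SbfI site of a
#' predicted in-range SbfI-EcoRI fragment (CANONICAL_AB); (2) the
#' genomic 8-mer at the locus start differs from the canonical SbfI
#' recognition sequence at 1-4 positions (NEAR_CANONICAL, star-activity
#' substrate, mismatch positions recorded 1-based in read orientation);
#' (3) the start is a true SbfI site with no EcoRI site within
#' `max_insert` downstream (NO_ECORI_NEARBY); (4) the start falls inside
#' a predicted SbfI-SbfI fragment no longer than `max_insert`
#' (SBFI_SBFI). Anything else is OTHER.
#'
#' @param mapped Mapped cluster table (non-anonymous rows are
#'   classified; unmapped input is an error).
#' @param genome See [as_genome()].
#' @param predicted_ab In-range loci from [predict_ddrad_loci()].
#' @param predicted_bb Optional tibble of SbfI-SbfI fragments (from
#'   [double_digest()], both ends SbfI); computed from the genome when
#'   NULL.
#' @param max_insert Maximum insert length (default 328).
#' @return `mapped` with `category` and `mismatch_positions`
#'   (comma-separated) columns.
#' @export
classify_recovered_loci <- function(mapped, genome, predicted_ab,
                                    predicted_bb = NULL, max_insert = 328L) {
  genome <- as_genome(genome)
  if (any(mapped$anonymous)) {
    stop("Only mapped (non-anonymous) loci can be classified.", call. = FALSE)
  }
  if (is.null(predicted_bb)) {
    dd <- double_digest(genome, "SbfI", "EcoRI")
    predicted_bb <- dd[!is.na(dd$left_enzyme) & !is.na(dd$right_enzyme) &
                         dd$left_enzyme == "SbfI" & dd$right_enzyme == "SbfI", ,
                       drop = FALSE]
  }
  ab_a_start <- ifelse(predicted_ab$orientation == "+", predicted_ab$start,
                       predicted_ab$end - 8L)
  sbfi_sites <- find_cut_sites(genome, "SbfI")
  ecori_sites <- find_cut_sites(genome, "EcoRI")
  cat <- character(nrow(mapped)); mm <- character(nrow(mapped))
  for (i in seq_len(nrow(mapped))) {
    ctg <- mapped$contig[i]
    a_start <- if (mapped$strand[i] == "+") mapped$pos[i] else
      mapped$end[i] - 8L
    clen <- nchar(genome[[ctg]])
    eight <- if (mapped$strand[i] == "+") {
      genome_subseq(genome, ctg, a_start, min(a_start + 8L, clen))
    } else {
      revcomp(genome_subseq(genome, ctg, max(a_start, 0L), a_start + 8L))
    }
    n_mis <- if (nchar(eight) == 8L) {
      sum(strsplit(eight, "")[[1]] != strsplit(SBFI, "")[[1]])
    } else NA_integer_
    is_ab <- any(predicted_ab$contig == ctg & ab_a_start == a_start &
                   predicted_ab$orientation == mapped$strand[i])
    if (is_ab) {
      cat[i] <- "CANONICAL_AB"; mm[i] <- ""
    } else if (!is.na(n_mis) && n_mis >= 1L && n_mis <= 4L) {
      cat[i] <- "NEAR_CANONICAL"
      mm[i] <- paste(which(strsplit(eight, "")[[1]] !=
                             strsplit(SBFI, "")[[1]]), collapse = ",")
    } else {
      inside_bb <- any(predicted_bb$contig == ctg &
                         predicted_bb$length_bp <= max_insert &
                         predicted_bb$start <= a_start &
                         predicted_bb$end > a_start)
      mm[i] <- ""
      if (!is.na(n_mis) && n_mis == 0L) {
        # a start inside a short SbfI-SbfI fragment is diagnostic of a
        # chimera regardless of distant EcoRI sites
        near_e <- if (mapped$strand[i] == "+") {
          any(ecori_sites$contig == ctg & ecori_sites$pos >= a_start &
                ecori_sites$pos <= a_start + max_insert)
        } else {
          any(ecori_sites$contig == ctg & ecori_sites$pos + 6L <= a_start + 8L &
                ecori_sites$pos + 6L >= a_start + 8L - max_insert)
        }
        cat[i] <- if (inside_bb) "SBFI_SBFI" else
          if (!near_e) "NO_ECORI_NEARBY" else "OTHER"
      } else {
        cat[i] <- if (inside_bb) "SBFI_SBFI" else "OTHER"
      }
    }
  }
  mapped$category <- cat
  mapped$mismatch_positions <- mm
  mapped
}
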