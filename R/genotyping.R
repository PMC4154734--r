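#' Genotype-calling thresholds
#'
#' The Mendelian ratio bands used by the haplotype-count caller, with the
#' band edges resolved as: homozygote requires the top haplotype fraction
#' strictly above `hom_min_frac`; heterozygote requires the second
#' haplotype fraction strictly above `het_min_frac`; the provisional
#' heterozygote band is inclusive on both sides (`[prov_low, prov_high]`);
#' the bad-ratio band is `[ambig_low, prov_low)`; a third haplotype
#' strictly above `third_hap_max` flags extra reads; homozygotes at
#' variable loci with depth below `min_hom_depth` are low depth; a
#' variant column whose mean quality drops below `trunc_mean_q` truncates
#' the locus; loci with more than `flagged_locus_max` flagged genotypes
#' are screened out.
#'
#' @param hom_min_frac,het_min_frac,prov_low,prov_high,ambig_low,third_hap_max
#'   Fraction thresholds.
#' @param min_hom_depth Minimum reads for a homozygote call at a variable
#'   locus.
#' @param trunc_mean_q Mean-quality truncation threshold for variant
#'   columns.
#' @param flagged_locus_max Maximum flagged genotypes a locus may carry.
#' @return List of class `ddrad_thresholds`.
#' @export
genotype_thresholds <- function(hom_min_frac = 0.93, het_min_frac = 0.29,
                                prov_low = 0.20, prov_high = 0.29,
                                ambig_low = 0.07, third_hap_max = 0.10,
                                min_hom_depth = 5L, trunc_mean_q = 25,
                                flagged_locus_max = 2L) {
  stopifnot(0 < ambig_low, ambig_low < prov_low, prov_low <= prov_high,
            prov_high < hom_min_frac, hom_min_frac <= 1)
  structure(
    list(hom_min_frac = hom_min_frac, het_min_frac = het_min_frac,
         prov_low = prov_low, prov_high = prov_high, ambig_low = ambig_low,
         third_hap_max = third_hap_max, min_hom_depth = min_hom_depth,
         trunc_mean_q = trunc_mean_q, flagged_locus_max = flagged_locus_max),
    class = "ddrad_thresholds"
  )
}

msa_char_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$row, "", fixed = TRUE))
}

#' Detect variant columns in a locus alignment, with quality truncation
#'
#' A column is variant when at least two states occur across all reads
#' (a gap counts as a state). Scanning left to right, the first variant
#' column whose read-weighted mean quality falls below `trunc_mean_q`
#' truncates the locus: that column and everything beyond it is
#' discarded.
#'
#' @param msa One cluster's rows from [align_clusters()].
#' @param thresholds See [genotype_thresholds()].
#' @return List with `columns` (tibble `col`, `kind` ("SNP"/"indel"),
#'   `states`, `mean_qual`) and `truncated_at` (number of columns kept).
#' @export
detect_variant_columns <- function(msa, thresholds = genotype_thresholds()) {
  if (nrow(msa) == 0L) stop("Empty alignment.", call. = FALSE)
  mat <- msa_char_matrix(msa)
  qmat <- do.call(rbind, msa$quals)
  counts <- msa$count
  ncol_full <- ncol(mat)
  cols <- list()
  trunc <- ncol_full
  for (j in seq_len(ncol_full)) {
    states <- unique(mat[, j])
    if (length(states) < 2L) next
    w <- counts[!is.na(qmat[, j])]
    q <- qmat[!is.na(qmat[, j]), j]
    mq <- if (length(q)) sum(w * q) / sum(w) else NA_real_
    if (!is.na(mq) && mq < thresholds$trunc_mean_q) {
      trunc <- j - 1L
      break
    }
    cols[[length(cols) + 1L]] <- tibble::tibble(
      col = j,
      kind = if ("-" %in% states) "indel" else "SNP",
      states = list(sort(states)),
      mean_qual = mq
    )
  }
  columns <- if (length(cols)) dplyr::bind_rows(cols) else
    tibble::tibble(col = integer(), kind = character(), states = list(),
                   mean_qual = double())
  list(columns = columns, truncated_at = trunc)
}

#' Count haplotypes over the variant columns
#'
#' Each read's states at the variant columns, in column order, form its
#' haplotype; counts accumulate condensed-read multiplicities. With no
#' variant columns every read carries the empty haplotype.
#'
#' @param msa One cluster's rows from [align_clusters()].
#' @param columns The `columns` tibble from [detect_variant_columns()].
#' @return Tibble `haplotype`, `sample_id`, `count`, ordered by total
#'   haplotype count descending (ties lexicographic).
#' @export
count_haplotypes <- function(msa, columns) {
  mat <- msa_char_matrix(msa)
  hap <- if (nrow(columns) == 0L) rep("", nrow(msa)) else
    apply(mat[, columns$col, drop = FALSE], 1L, paste, collapse = "")
  tab <- tibble::tibble(haplotype = hap, sample_id = msa$sample_id,
                        count = msa$count) |>
    dplyr::group_by(.data$haplotype, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  totals <- tab |>
    dplyr::group_by(.data$haplotype) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  tab |>
    dplyr::left_join(totals, by = "haplotype") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$haplotype, .data$sample_id) |>
    dplyr::select(-"total")
}

#' Call one genotype from per-sample haplotype counts
#'
#' Decision order on the fractions `f1 >= f2 >= f3` of the sample's top
#' haplotypes (denominator: all reads the sample has at the locus):
#' heterozygote when `f2` exceeds the het threshold, unless a third
#' haplotype above `third_hap_max` flags extra reads; provisional
#' heterozygotes (`f2` in the provisional band) pass only when both
#' haplotypes occur in at least one other sample; `f2` in the ambiguous
#' band is a bad ratio; otherwise homozygote, downgraded to low depth at
#' variable loci below `min_hom_depth` reads.
#'
#' @param counts Named numeric vector of haplotype counts for one sample
#'   (names = haplotypes), in any order.
#' @param population_haplotypes Character vector of haplotypes seen (>= 1
#'   read) in at least one other sample.
#' @param thresholds See [genotype_thresholds()].
#' @param locus_variable Does the locus segregate at all?
#' @return One-row tibble `status`, `allele1`, `allele2`, `depth`,
#'   `f1`, `f2`.
#' @export
call_genotype <- function(counts, population_haplotypes = character(),
                          thresholds = genotype_thresholds(),
                          locus_variable = TRUE) {
  if (any(counts < 0)) stop("Negative haplotype counts.", call. = FALSE)
  depth <- sum(counts)
  if (depth < 1) stop("call_genotype() requires depth >= 1.", call. = FALSE)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  f <- counts / depth
  f1 <- f[1]
  f2 <- if (length(f) >= 2L) f[2] else 0
  f3 <- if (length(f) >= 3L) f[3] else 0
  h1 <- names(counts)[1]
  h2 <- if (length(counts) >= 2L) names(counts)[2] else h1
  th <- thresholds
  if (f2 > th$het_min_frac) {
    status <- if (f3 > th$third_hap_max) "EXTRA_READS" else "HET"
  } else if (f2 >= th$prov_low && f2 <= th$prov_high) {
    both_seen <- all(c(h1, h2) %in% population_haplotypes)
    status <- if (both_seen) "HET_PROVISIONAL_PASSED" else "BAD_RATIO"
  } else if (f2 >= th$ambig_low) {
    status <- "BAD_RATIO"
  } else {
    status <- if (locus_variable && depth < th$min_hom_depth) "LOW_DEPTH" else "HOM"
  }
  het <- status %in% c("HET", "HET_PROVISIONAL_PASSED")
  tibble::tibble(
    status = status,
    allele1 = h1,
    allele2 = if (het) h2 else h1,
    depth = depth,
    f1 = unname(f1), f2 = unname(f2)
  )
}

#' Genotype every sample at every locus
#'
#' Runs variant detection (with quality truncation), haplotype counting
#' and the threshold caller for each cluster in an alignment table.
#' Samples in `samples` with no reads at a locus are reported MISSING.
#'
#' @param alignments Output of [align_clusters()].
#' @param samples Character vector of all sample ids (roster for MISSING
#'   calls); defaults to the samples present in `alignments`.
#' @param thresholds See [genotype_thresholds()].
#' @return List of class `ddrad_genotypes` with elements `calls` (tibble
#'   `locus_id`, `sample_id`, `status`, `allele1`, `allele2`, `depth`,
#'   `allele_depths` list), `haplotypes` (per-locus haplotype count
#'   table), `columns` (per-locus variant columns), `loci` (per-locus
#'   summary: `locus_id`, `n_variant_cols`, `variable`, `truncated_at`).
#' @export
call_genotypes <- function(alignments, samples = NULL,
                           thresholds = genotype_thresholds()) {
  if (is.null(samples)) samples <- sort(unique(alignments$sample_id))
  locus_ids <- unique(alignments$cluster_id)
  calls <- list(); haps <- list(); cols <- list(); loci <- list()
  for (lid in locus_ids) {
    msa <- alignments[alignments$cluster_id == lid, , drop = FALSE]
    vc <- detect_variant_columns(msa, thresholds)
    columns <- vc$columns[vc$columns$col <= vc$truncated_at, , drop = FALSE]
    hap_tab <- count_haplotypes(msa, columns)
    variable <- nrow(columns) > 0L
    hap_by_sample <- split(hap_tab, hap_tab$sample_id)
    sample_calls <- purrr::map(samples, function(sm) {
      tab <- hap_by_sample[[sm]]
      if (is.null(tab) || sum(tab$count) == 0L) {
        return(tibble::tibble(status = "MISSING", allele1 = NA_character_,
                              allele2 = NA_character_, depth = 0L,
                              f1 = NA_real_, f2 = NA_real_))
      }
      counts <- stats::setNames(tab$count, tab$haplotype)
      other <- hap_tab$haplotype[hap_tab$sample_id != sm & hap_tab$count > 0L]
      call_genotype(counts, unique(other), thresholds, variable)
    })
    call_tbl <- dplyr::bind_rows(sample_calls)
    call_tbl <- tibble::add_column(call_tbl, locus_id = lid, sample_id = samples,
                                   .before = 1)
    call_tbl$allele_depths <- purrr::map(samples, function(sm) {
      tab <- hap_by_sample[[sm]]
      if (is.null(tab)) integer(0) else stats::setNames(tab$count, tab$haplotype)
    })
    calls[[length(calls) + 1L]] <- call_tbl
    hap_tab$locus_id <- lid
    haps[[length(haps) + 1L]] <- hap_tab
    if (nrow(columns)) {
      columns$locus_id <- lid
      cols[[length(cols) + 1L]] <- columns
    }
    loci[[length(loci) + 1L]] <- tibble::tibble(
      locus_id = lid, n_variant_cols = nrow(columns), variable = variable,
      truncated_at = vc$truncated_at
    )
  }
  structure(
    list(
      calls = dplyr::bind_rows(calls),
      haplotypes = dplyr::bind_rows(haps),
      columns = if (length(cols)) dplyr::bind_rows(cols) else
        tibble::tibble(col = integer(), kind = character(), states = list(),
                       mean_qual = double(), locus_id = integer()),
      loci = dplyr::bind_rows(loci),
      thresholds = thresholds
    ),
    class = "ddrad_genotypes"
  )
}

#' @export
print.ddrad_genotypes <- function(x, ...) {
  cat(sprintf("<ddrad_genotypes: %d loci x %d samples>\n",
              length(unique(x$calls$locus_id)),
              length(unique(x$calls$sample_id))))
  print(table(x$calls$status))
  invisible(x)
}

#' Code each unique indel as one presence/absence character
#'
#' Maximal runs of adjacent gap columns with identical row support form
#' one indel event; each unique event (by start column and length)
#' becomes a single binary character regardless of its length.
#'
#' @param msa One cluster's rows from [align_clusters()].
#' @return Tibble `indel_id`, `start_col`, `n_cols`, plus a `presence`
#'   list-column holding the per-row logical vector (TRUE = gap, i.e.
#'   deletion present).
#' @export
gap_code_indels <- function(msa) {
  mat <- msa_char_matrix(msa)
  gap_cols <- which(apply(mat == "-", 2L, any))
  if (length(gap_cols) == 0L) {
    return(tibble::tibble(indel_id = integer(), start_col = integer(),
                          n_cols = integer(), presence = list()))
  }
  support <- apply(mat[, gap_cols, drop = FALSE] == "-", 2L, paste, collapse = "")
  run_break <- c(TRUE, diff(gap_cols) != 1L | support[-1] != support[-length(support)])
  run_id <- cumsum(run_break)
  events <- tibble::tibble(
    start_col = gap_cols[run_break],
    n_cols = as.integer(table(run_id)),
    presence = lapply(split(gap_cols, run_id), function(cc) mat[, cc[1]] == "-")
  )
  events <- dplyr::distinct(events, .data$start_col, .data$n_cols,
                            .keep_all = TRUE)
  tibble::add_column(events, indel_id = seq_len(nrow(events)), .before = 1)
}

#' One-sided exact test for heterozygote excess under Hardy-Weinberg
#'
#' Levene's exact distribution of the heterozygote count conditional on
#' the allele counts; the p-value sums the probabilities of heterozygote
#' counts at least as large as observed.
#'
#' @param n_het,n_hom1,n_hom2 Genotype counts for a biallelic locus.
#' @return p-value.
#' @export
hwe_exact_excess <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  nA <- 2L * n_hom1 + n_het
  if (n == 0L || nA == 0L || nA == 2L * n) return(1)
  hets <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (2 * n - nA - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  sum(p[hets >= n_het])
}

#' Screen loci for duplication artefacts
#'
#' A locus is excluded when any of the following hold: (a) more than
#' `flagged_locus_max` genotypes are flagged BAD_RATIO or EXTRA_READS;
#' (b) mean depth per sample exceeds `max_depth`; (c) a one-sided exact
#' test detects heterozygote excess against Hardy-Weinberg at
#' `hwe_alpha` (biallelic loci); (d) two called alleles differ at more
#' than `min_allele_divergence` of the variant columns; (e) mean
#' heterozygote depth exceeds `het_hom_depth_ratio` times mean
#' homozygote depth.
#'
#' @param genotypes A `ddrad_genotypes` object.
#' @param max_depth Mean-depth ceiling (default 500).
#' @param hwe_alpha Significance level for the heterozygote-excess test.
#' @param min_allele_divergence Maximum tolerated allele divergence
#'   (fraction of variant columns).
#' @param het_hom_depth_ratio Het/hom mean depth ratio ceiling.
#' @return Tibble `locus_id`, `keep`, `reasons` (comma-separated).
#' @export
screen_duplicate_loci <- function(genotypes, max_depth = 500,
                                  hwe_alpha = 0.05,
                                  min_allele_divergence = 0.1,
                                  het_hom_depth_ratio = 2.0) {
  th <- genotypes$thresholds
  calls <- genotypes$calls
  per_locus <- split(calls, calls$locus_id)
  out <- purrr::imap(per_locus, function(g, lid) {
    reasons <- character(0)
    flagged <- sum(g$status %in% c("BAD_RATIO", "EXTRA_READS"))
    if (flagged > th$flagged_locus_max) reasons <- c(reasons, "flagged_genotypes")
    present <- g[g$depth > 0L, , drop = FALSE]
    if (nrow(present) > 0L && mean(present$depth) > max_depth) {
      reasons <- c(reasons, "high_depth")
    }
    called <- g[g$status %in% c("HOM", "HET", "HET_PROVISIONAL_PASSED"), ,
                drop = FALSE]
    alleles <- sort(unique(c(called$allele1, called$allele2)))
    if (length(alleles) == 2L && nrow(called) > 0L) {
      het <- called$allele1 != called$allele2
      hom1 <- !het & called$allele1 == alleles[1]
      hom2 <- !het & called$allele1 == alleles[2]
      if (hwe_exact_excess(sum(het), sum(hom1), sum(hom2)) < hwe_alpha) {
        reasons <- c(reasons, "het_excess")
      }
    }
    if (length(alleles) >= 2L) {
      hap_len <- nchar(alleles[1])
      if (hap_len > 0L) {
        combs <- utils::combn(alleles, 2L)
        div <- apply(combs, 2L, function(pr) {
          a <- strsplit(pr[1], "")[[1]]; b <- strsplit(pr[2], "")[[1]]
          mean(a != b)
        })
        n_total <- genotypes$loci$truncated_at[
          match(lid, as.character(genotypes$loci$locus_id))]
        # divergence relative to locus length, not just variant columns
        if (any(div * hap_len / max(n_total, 1L) > min_allele_divergence)) {
          reasons <- c(reasons, "divergent_alleles")
        }
      }
    }
    if (nrow(called) > 0L) {
      het_d <- called$depth[called$allele1 != called$allele2]
      hom_d <- called$depth[called$allele1 == called$allele2]
      if (length(het_d) >= 2L && length(hom_d) >= 2L &&
          mean(het_d) > het_hom_depth_ratio * mean(hom_d)) {
        reasons <- c(reasons, "het_depth_excess")
      }
    }
    tibble::tibble(locus_id = g$locus_id[1], keep = length(reasons) == 0L,
                   reasons = paste(reasons, collapse = ","))
  })
  dplyr::bind_rows(out)
}
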