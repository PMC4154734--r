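#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a depth variance-components fit
#'
#' @param x A `ddrad_anova` from [depth_variance_components()].
#' @param ... Unused.
#' @return Tibble with one row per term (`term`, `df`, `sumsq`,
#'   `partial_eta_sq`).
#' @method tidy ddrad_anova
#' @export
tidy.ddrad_anova <- function(x, ...) {
  x$table
}

#' One-row summary of a depth variance-components fit
#'
#' @param x A `ddrad_anova`.
#' @param ... Unused.
#' @return Tibble with `eta_locus`, `eta_sample`, `df_residual`.
#' @method glance ddrad_anova
#' @export
glance.ddrad_anova <- function(x, ...) {
  tibble::tibble(
    eta_locus = x$table$partial_eta_sq[x$table$term == "locus"],
    eta_sample = x$table$partial_eta_sq[x$table$term == "sample"],
    df_residual = x$table$df[x$table$term == "residual"]
  )
}

#' Tidy genotype calls
#'
#' @param x A `ddrad_genotypes` from [call_genotypes()].
#' @param ... Unused.
#' @return The long calls tibble.
#' @method tidy ddrad_genotypes
#' @export
tidy.ddrad_genotypes <- function(x, ...) {
  x$calls
}

#' One-row summary of a genotype call set
#'
#' @param x A `ddrad_genotypes`.
#' @param ... Unused.
#' @return Tibble with locus/sample counts, per-status cell counts and
#'   the fraction of clean calls.
#' @method glance ddrad_genotypes
#' @export
glance.ddrad_genotypes <- function(x, ...) {
  st <- table(factor(x$calls$status,
                     levels = c("HOM", "HET", "HET_PROVISIONAL_PASSED",
                                "BAD_RATIO", "EXTRA_READS", "LOW_DEPTH",
                                "MISSING")))
  tibble::tibble(
    n_loci = dplyr::n_distinct(x$calls$locus_id),
    n_samples = dplyr::n_distinct(x$calls$sample_id),
    n_hom = as.integer(st[["HOM"]]),
    n_het = as.integer(st[["HET"]] + st[["HET_PROVISIONAL_PASSED"]]),
    n_flagged = as.integer(st[["BAD_RATIO"]] + st[["EXTRA_READS"]]),
    n_low_depth = as.integer(st[["LOW_DEPTH"]]),
    n_missing = as.integer(st[["MISSING"]]),
    frac_called = (.data$n_hom + .data$n_het) / nrow(x$calls)
  )
}

#' Tidy a missingness summary
#'
#' @param x A `ddrad_missingness` from [missingness_summary()].
#' @param ... Unused.
#' @return The per-category tibble.
#' @method tidy ddrad_missingness
#' @export
tidy.ddrad_missingness <- function(x, ...) {
  x$by_category
}

#' One-row totals of a missingness summary
#'
#' @param x A `ddrad_missingness`.
#' @param ... Unused.
#' @return The totals tibble (counts and percentages).
#' @method glance ddrad_missingness
#' @export
glance.ddrad_missingness <- function(x, ...) {
  x$totals
}
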