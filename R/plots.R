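#' Depth versus fragment length and GC
#'
#' Log-scaled realized depth against fragment length, coloured by GC
#' fraction, for in-range fragments; the signature pattern of
#' amplification bias plus tapered size selection.
#'
#' @param depths Tibble from [simulate_depths()] (or any tibble with
#'   `length`, `gc`, `realized`).
#' @return A ggplot.
#' @export
plot_depth_bias <- function(depths) {
  d <- depths[!is.na(depths$length) & depths$realized > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$realized,
                                  colour = .data$gc)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(name = "GC") +
    ggplot2::labs(x = "Fragment length (bp)", y = "Read depth",
                  title = "Sequencing depth vs fragment length and GC") +
    ggplot2::theme_minimal()
}

#' Heterozygote allele-balance plot
#'
#' Allele-1 versus allele-2 read depth for heterozygous calls; under
#' Mendelian sampling the cloud straddles the 1:1 line binomially.
#'
#' @param calls Calls tibble with `status`, `allele_depths`.
#' @return A ggplot.
#' @export
plot_allele_balance <- function(calls) {
  het <- calls[calls$status %in% c("HET", "HET_PROVISIONAL_PASSED"), ,
               drop = FALSE]
  d <- tibble::tibble(
    a = vapply(het$allele_depths, function(x)
      if (length(x) >= 1L) as.numeric(sort(x, decreasing = TRUE)[1]) else NA_real_,
      numeric(1)),
    b = vapply(het$allele_depths, function(x)
      if (length(x) >= 2L) as.numeric(sort(x, decreasing = TRUE)[2]) else NA_real_,
      numeric(1))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Major allele depth", y = "Minor allele depth",
                  title = "Heterozygote allele balance") +
    ggplot2::theme_minimal()
}

#' Plot a site frequency spectrum against its neutral expectation
#'
#' @param object A `ddrad_sfs` tibble from [site_frequency_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ddrad_sfs
#' @export
autoplot.ddrad_sfs <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("observed", "expected"),
                              names_to = "series", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$count_class),
                                     y = .data$n, fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Minor/derived allele count", y = "Loci",
                  title = "Site frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Depth by locus-origin category
#'
#' Boxplot of cluster read depth by classification category
#' (canonical, star-activity, chimera, ...), mirroring the diagnostic
#' that star loci sit at low depth.
#'
#' @param classified Output of [classify_recovered_loci()] (needs
#'   `category` and `n_reads`).
#' @return A ggplot.
#' @export
plot_locus_classification <- function(classified) {
  ggplot2::ggplot(classified, ggplot2::aes(x = .data$category,
                                           y = .data$n_reads)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Cluster read depth",
                  title = "Read depth by locus origin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
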