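test_that("missingness accounting matches hand counts on a toy matrix", {
  # 3 loci x 4 samples; locus L1 clean, L2 has 2 low-depth cells,
  # L3 has 1 missing cell
  calls <- tidyr::expand_grid(locus_id = c("L1", "L2", "L3"),
                              sample_id = sprintf("s%d", 1:4))
  calls$status <- "HOM"
  calls$depth <- 20L
  calls$variable <- calls$locus_id != "L1"
  calls$status[calls$locus_id == "L2" & calls$sample_id %in% c("s1", "s2")] <-
    "LOW_DEPTH"
  calls$depth[calls$locus_id == "L2" & calls$sample_id %in% c("s1", "s2")] <- 3L
  calls$status[calls$locus_id == "L3" & calls$sample_id == "s4"] <- "MISSING"
  calls$depth[calls$locus_id == "L3" & calls$sample_id == "s4"] <- 0L
  ms <- missingness_summary(calls, min_depth = 5L, min_samples_frac = 0.75)
  expect_equal(ms$totals$total_cells, 12L)
  expect_equal(ms$totals$n_low_depth, 2L)
  expect_equal(ms$totals$n_missing, 1L)
  expect_equal(ms$totals$pct_low_depth, round(100 * 2 / 12, 1))
  expect_equal(ms$totals$pct_missing, round(100 * 1 / 12, 1))
  # cells = loci x samples within each category
  expect_equal(ms$by_category$cells, ms$by_category$n_loci * 4L)

  # an all-clean matrix has nothing missing
  clean <- calls
  clean$status <- "HOM"; clean$depth <- 20L
  ms2 <- missingness_summary(clean, min_depth = 5L)
  expect_equal(ms2$totals$n_missing + ms2$totals$n_low_depth, 0L)
})

test_that("exact binomial balance test gives textbook p-values", {
  expect_equal(heterozygote_balance_test(14, 14), 1)
  expect_equal(heterozygote_balance_test(0, 30), 2 * 2^-30, tolerance = 1e-12)
  expect_equal(heterozygote_balance_test(c(5, 10), c(5, 10)), c(1, 1))
})

test_that("binomial rejection rate at alpha 0.05 sits inside its sampling band", {
  set.seed(42)
  n <- 300L; depth <- 40L
  a <- stats::rbinom(n, depth, 0.5)
  p <- heterozygote_balance_test(a, depth - a)
  obs <- mean(p <= 0.05)
  half_width <- 1.96 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(obs - 0.05), half_width)
})

test_that("depth variance components recover designed effects", {
  # pure locus effect: partial eta^2 exactly 1
  m <- matrix(rep(c(10, 40, 90), each = 4), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3), paste0("s", 1:4)))
  vc <- depth_variance_components(m)
  expect_equal(tidy(vc)$partial_eta_sq[1], 1)

  # hand-computed 3x3 two-way ANOVA
  m2 <- matrix(c(1, 2, 3,
                 2, 4, 6,
                 3, 6, 9), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("L", 1:3), paste0("s", 1:3)))
  vc2 <- depth_variance_components(m2)
  grand <- mean(m2)
  ss_locus <- 3 * sum((rowMeans(m2) - grand)^2)
  ss_sample <- 3 * sum((colMeans(m2) - grand)^2)
  ss_total <- sum((m2 - grand)^2)
  ss_res <- ss_total - ss_locus - ss_sample
  tab <- tidy(vc2)
  expect_equal(tab$sumsq[tab$term == "locus"], ss_locus, tolerance = 1e-8)
  expect_equal(tab$sumsq[tab$term == "sample"], ss_sample, tolerance = 1e-8)
  expect_equal(tab$partial_eta_sq[1], ss_locus / (ss_locus + ss_res),
               tolerance = 1e-8)

  # i.i.d. noise: both effects near zero
  set.seed(9)
  m3 <- matrix(rnorm(4000), nrow = 80)
  g <- glance(depth_variance_components(m3))
  expect_lt(g$eta_locus, 0.1)
  expect_lt(g$eta_sample, 0.1)

  expect_error(depth_variance_components(m2[1, , drop = FALSE]), "at least 2")
})

test_that("per-locus depth CV matches direct arithmetic", {
  m <- matrix(c(7, 7, 7,
                10, 20, 30,
                0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3), paste0("s", 1:3)))
  cv <- per_locus_depth_cv(m)
  expect_equal(cv$per_locus$cv[1], 0)
  expect_equal(cv$per_locus$cv[2], stats::sd(c(10, 20, 30)) / 20)
  expect_true(is.na(cv$per_locus$cv[3]))
  expect_equal(cv$summary$n_loci, 2L)
  expect_equal(cv$summary$mean_cv,
               mean(c(0, stats::sd(c(10, 20, 30)) / 20)))

  two <- per_locus_depth_cv(matrix(c(10, 20), nrow = 1,
                                   dimnames = list("L1", c("a", "b"))))
  expect_equal(two$per_locus$cv[1], (5 * sqrt(2)) / 15, tolerance = 1e-12)
})

test_that("site frequency spectrum matches the closed-form neutral expectation", {
  sfs <- site_frequency_spectrum(c(1L, 1L, 2L, 3L), n_chrom = 4L)
  expect_equal(sfs$count_class, 1:3)
  expect_equal(sfs$expected / sum(sfs$expected),
               c(6 / 11, 3 / 11, 2 / 11), tolerance = 1e-12)
  expect_equal(sum(sfs$observed), 4L)

  # flat construction is visibly non-neutral
  flat <- site_frequency_spectrum(rep(1:9, each = 20), n_chrom = 10L)
  expect_equal(sum(flat$observed), 180L)
  expect_gt(flat$expected[1], flat$observed[1])

  empty <- site_frequency_spectrum(integer(0), n_chrom = 10L)
  expect_equal(nrow(empty), 0L)

  folded <- site_frequency_spectrum(c(1L, 3L), n_chrom = 4L, folded = TRUE)
  expect_equal(folded$count_class, 1:2)
  expect_equal(folded$observed, c(2L, 0L))
})

test_that("recovered loci are classified into the four origin categories", {
  star_run <- shared_run_star()
  toy <- star_run$toy; sim <- star_run$sim; res <- star_run$res
  predicted_ab <- predict_ddrad_loci(sim$genome, "SbfI", "EcoRI", 13L, 328L)
  mapped <- res$mapped[!res$mapped$anonymous, ]
  cls <- classify_recovered_loci(mapped, sim$genome, predicted_ab)
  expect_true(all(cls$category %in% c("CANONICAL_AB", "NEAR_CANONICAL",
                                      "NO_ECORI_NEARBY", "SBFI_SBFI", "OTHER")))
  # planted canonical loci classify as such
  expect_gt(sum(cls$category == "CANONICAL_AB"), 5L)
  # star loci carry their planted mismatch positions
  near <- cls[cls$category == "NEAR_CANONICAL", ]
  expect_gt(nrow(near), 0L)
  feats <- toy$features
  for (i in seq_len(nrow(near))) {
    truth_pos <- feats$mismatch_pos[feats$start == near$pos[i]]
    if (length(truth_pos) == 1L) {
      expect_equal(near$mismatch_positions[i], as.character(truth_pos))
    }
  }
  # star loci sit at lower depth than canonical loci
  if (nrow(near) >= 3L) {
    expect_lt(stats::median(near$n_reads),
              stats::median(cls$n_reads[cls$category == "CANONICAL_AB"]))
  }
})

test_that("hand-planted star and chimera features classify by construction", {
  toy <- shared_toy()
  feats <- toy$features
  predicted_ab <- predict_ddrad_loci(toy$genome, "SbfI", "EcoRI", 13L, 328L)
  g <- unclass(toy$genome)[[1]]
  mk_mapped <- function(start0, len) {
    tibble::tibble(cluster_id = 1L, centroid = "x", n_reads = 5L,
                   n_samples = 1L, centroid_mean_qual = 40,
                   contig = "chr1", pos = start0, end = start0 + len,
                   strand = "+", identity = 1, unique = TRUE,
                   anonymous = FALSE)
  }
  ab <- feats[feats$type == "ab_in", ][1, ]
  expect_equal(classify_recovered_loci(mk_mapped(ab$start, 96L), toy$genome,
                                       predicted_ab)$category, "CANONICAL_AB")
  star <- feats[feats$type == "star", ][1, ]
  out <- classify_recovered_loci(mk_mapped(star$start, 96L), toy$genome,
                                 predicted_ab)
  expect_equal(out$category, "NEAR_CANONICAL")
  expect_equal(out$mismatch_positions, as.character(star$mismatch_pos))
  bb <- feats[feats$type == "bb", ][1, ]
  expect_equal(classify_recovered_loci(mk_mapped(bb$start, 96L), toy$genome,
                                       predicted_ab)$category, "SBFI_SBFI")
  expect_error(classify_recovered_loci(
    dplyr::mutate(mk_mapped(0L, 10L), anonymous = TRUE),
    toy$genome, predicted_ab), "anonymous")
})
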