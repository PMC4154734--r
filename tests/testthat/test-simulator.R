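test_that("toy genomes plant exactly the requested features and nothing else", {
  toy <- shared_toy()
  loci <- predict_ddrad_loci(toy$genome, "SbfI", "EcoRI", 178L, 328L)
  expect_equal(nrow(loci), 8L)  # the planted in-range fragments

  # deterministic per seed
  toy2 <- make_toy_genome(n_in_range = 8L, n_short = 3L, n_long = 1L,
                          n_star = 4L, n_bb = 2L, n_duplications = 1L,
                          seed = 42L)
  expect_identical(unclass(toy$genome), unclass(toy2$genome))
  expect_identical(toy$features, toy2$features)

  # exhaustive scan: every recognition site lies inside a planted feature
  g <- unclass(toy$genome)[[1]]
  feats <- toy$features
  for (pat in c("CCTGCAGG", "GAATTC")) {
    hits <- oracle_find_sites(g, pat)
    for (h in hits) {
      expect_true(any(h >= feats$start & h + nchar(pat) <= feats$end),
                  label = sprintf("site %s at %d is planted", pat, h))
    }
  }
})

test_that("population simulation respects its rate parameters", {
  toy <- shared_toy()
  # zero rates: every individual is the same homozygote everywhere
  pop0 <- simulate_population(
    toy$genome, population_config(n_individuals = 6L, snp_rate = 0,
                                  indel_rate = 0, site_poly_rate = 0),
    seed = 3L)
  expect_true(all(pop0$genotypes$allele1 == "A1" &
                    pop0$genotypes$allele2 == "A1"))
  expect_true(all(pop0$alleles$sequence == pop0$loci$sequence[
    match(pop0$alleles$locus_id, pop0$loci$locus_id)]))

  # site-polymorphism rate 1: every locus is a fixed null
  pop1 <- simulate_population(
    toy$genome, population_config(n_individuals = 4L, snp_rate = 0,
                                  indel_rate = 0, site_poly_rate = 1),
    seed = 3L)
  expect_true(all(pop1$genotypes$allele1 == "NULL"))
  d1 <- simulate_depths(pop1, reads_per_individual = 100L, seed = 4L)
  expect_true(all(d1$realized == 0L))

  # allele frequencies follow the neutral 1/i law within sampling error
  pop <- simulate_population(
    toy$genome, population_config(n_individuals = 10L, snp_rate = 0.05,
                                  indel_rate = 0, site_poly_rate = 0),
    seed = 5L)
  counts <- pop$alleles$n_chrom[pop$alleles$allele != "A1"]
  expect_gt(length(counts), 10L)
  # singleton-class share should dominate as 1/i predicts
  expect_gt(mean(counts <= 3), 0.4)
})

test_that("depth model: flat parameters equalize, defaults favour short GC-rich fragments", {
  toy <- shared_toy()
  pop <- simulate_population(
    toy$genome, population_config(n_individuals = 2L, snp_rate = 0,
                                  indel_rate = 0, site_poly_rate = 0),
    seed = 3L)
  flat <- simulate_depths(
    pop, bias_model(beta_len = 0, beta_gc = 0, carryover_prob = 1,
                    carryover_gc_coeff = 0),
    size_selection_model(taper_min = 1), reads_per_individual = 1000L,
    seed = 8L)
  in_range <- flat[!is.na(flat$length) & flat$length >= 178 &
                     flat$length <= 328, ]
  expect_equal(length(unique(round(in_range$expected, 6))), 1L)

  # defaults: expected depth strictly higher at 250 bp than 300 bp, same GC
  b <- bias_model(); s <- size_selection_model()
  w <- function(len) exp(b$beta_len * (len - 253)) *
    (s$taper_min + 0.5 * (len - s$min_bp) / 150)
  expect_gt(w(250), w(300))

  # above-window fragments get nothing
  d <- simulate_depths(pop, reads_per_individual = 1000L, seed = 9L)
  expect_true(all(d$realized[!is.na(d$length) & d$length > 328] == 0L))
})

test_that("realized log depth regresses on length and GC at the calibrated strength", {
  sv <- depth_bias_survey(2000L, seed = 1L)
  expect_gt(sv$r_squared, 0.33)
  expect_lt(sv$r_squared, 0.53)
  expect_lt(coef(sv$fit)[["length"]], 0)
  expect_gt(coef(sv$fit)[["gc"]], 0)
  expect_gt(sv$partial_length, 0.1)
  expect_gt(sv$partial_gc, 0.1)
})

test_that("fastq emission is deterministic and conserves truth counts", {
  run <- shared_run0()
  sim <- run$sim
  expect_equal(nrow(sim$reads), nrow(sim$provenance))
  emitted <- sim$depths$realized[!sim$depths$null]
  expect_equal(sum(emitted), sum(sim$provenance$origin == "allele"))
  expect_true(all(nchar(sim$reads$sequence) == 100L))
  expect_true(all(nchar(sim$reads$qual) == 100L))

  toy <- shared_toy()
  sim_b <- simulate_ddrad(
    toy, cfg = population_config(n_individuals = 8L),
    reads_per_individual = 600L, error_rate = 0, seed = 7L,
    star = star_activity_model(rate_edge = 0, rate_internal = 0,
                               chimera_rate = 0))
  expect_identical(sim$reads, sim_b$reads)

  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, sim$reads$sequence)
  expect_equal(back$qual, sim$reads$qual)
})

test_that("star reads concentrate at edge-mismatch sites at the configured share", {
  star_run <- shared_run_star()
  sim <- star_run$sim
  star_prov <- sim$provenance[sim$provenance$origin == "star", ]
  expect_gt(nrow(star_prov), 40L)
  mm_pos <- star_run$toy$features$mismatch_pos[
    match(star_prov$locus_id, star_run$toy$features$feature_id)]
  edge_share <- mean(mm_pos %in% c(1L, 8L))
  configured <- 2 * 0.8 / (2 * 0.8 + 6 * 0.8 / 28.87)
  expect_lt(abs(edge_share - configured), 0.08)
})

test_that("null alleles halve the depth of carrier heterozygotes and are called HOM", {
  toy <- shared_toy()
  sim <- simulate_ddrad(
    toy, cfg = population_config(n_individuals = 20L, snp_rate = 0.013,
                                 indel_rate = 0, site_poly_rate = 0.6),
    reads_per_individual = 1500L, error_rate = 0, seed = 21L,
    star = star_activity_model(rate_edge = 0, rate_internal = 0,
                               chimera_rate = 0))
  gn <- sim$genotypes
  gn$has_null <- (gn$allele1 == "NULL") != (gn$allele2 == "NULL")
  gn$both_real <- gn$allele1 != "NULL" & gn$allele2 != "NULL"
  dp <- sim$depths |>
    dplyr::group_by(locus_id, sample_id) |>
    dplyr::summarise(depth = sum(realized), .groups = "drop")
  gn <- dplyr::left_join(gn, dp, by = c("locus_id", "sample_id"))
  gn$depth[is.na(gn$depth)] <- 0L
  ratios <- gn |>
    dplyr::group_by(locus_id) |>
    dplyr::summarise(
      null_het = mean(depth[has_null]),
      full = mean(depth[both_real]),
      n1 = sum(has_null), n2 = sum(both_real), .groups = "drop") |>
    dplyr::filter(n1 >= 3, n2 >= 3, full > 10)
  expect_gt(nrow(ratios), 2L)
  r <- mean(ratios$null_het / ratios$full)
  expect_gt(r, 0.3); expect_lt(r, 0.7)

  # carriers are scored HOM by the pipeline (the null allele is invisible)
  res <- run_ddrad_pipeline(sim$reads, sim$barcode_map, genome = sim$genome,
                            screen = FALSE)
  conc <- genotype_concordance(res$genotypes, res$mapped, res$alignments,
                               sim, min_allele_depth = 10L)
  hom_cells <- conc$cells[conc$cells$truth == "HOM", ]
  expect_gt(nrow(hom_cells), 50L)
  expect_gte(mean(hom_cells$agree), 0.99)
})
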