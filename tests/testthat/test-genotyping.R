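mk_msa <- function(rows, counts, samples, quals = NULL) {
  n <- length(rows)
  if (is.null(quals)) {
    quals <- lapply(rows, function(r) {
      q <- rep(38L, nchar(r))
      q[strsplit(r, "")[[1]] == "-"] <- NA_integer_
      q
    })
  }
  tibble::tibble(
    cluster_id = 1L, member_id = seq_len(n),
    sample_id = rep_len(samples, n),
    count = as.integer(counts),
    mean_qual = vapply(quals, function(q) mean(q, na.rm = TRUE), numeric(1)),
    row = rows, quals = quals
  )
}

test_that("variant columns are detected and low-quality columns truncate the locus", {
  msa <- mk_msa(c("ACGTA", "ACGTA", "ACCTA"), c(30, 28, 25), c("a", "b", "c"))
  vc <- detect_variant_columns(msa)
  expect_equal(vc$columns$col, 3L)
  expect_equal(vc$columns$kind, "SNP")
  expect_equal(vc$truncated_at, 5L)

  # gap state counts as a variant state
  msa_g <- mk_msa(c("ACGTA", "AC-TA"), c(10, 10), c("a", "b"))
  expect_equal(detect_variant_columns(msa_g)$columns$kind, "indel")

  # a variant column with mean quality below 25 truncates there
  q1 <- rep(38L, 5L); q2 <- rep(38L, 5L)
  q1[4] <- 20L; q2[4] <- 20L
  msa_t <- mk_msa(c("ACGTA", "ACGAA"), c(10, 10), c("a", "b"),
                  quals = list(q1, q2))
  vc_t <- detect_variant_columns(msa_t)
  expect_equal(vc_t$truncated_at, 3L)
  expect_equal(nrow(vc_t$columns), 0L)

  # invariant alignment: nothing to report
  inv <- detect_variant_columns(mk_msa(c("ACGT", "ACGT"), c(5, 5), c("a", "b")))
  expect_equal(nrow(inv$columns), 0L)
  expect_equal(inv$truncated_at, 4L)
  expect_error(detect_variant_columns(mk_msa(character(0), integer(0),
                                             character(0))), "Empty")
})

test_that("haplotype counting accumulates multiplicities in column order", {
  msa <- mk_msa(c("AAGA", "AAGA", "CAGT", "CAGT"), c(25, 15, 20, 18),
                c("a", "b", "a", "b"))
  vc <- detect_variant_columns(msa)
  expect_equal(vc$columns$col, c(1L, 4L))
  hap <- count_haplotypes(msa, vc$columns)
  expect_equal(sum(hap$count), 78L)
  tot <- tapply(hap$count, hap$haplotype, sum)
  expect_equal(as.integer(tot[["AA"]]), 40L)
  expect_equal(as.integer(tot[["CT"]]), 38L)

  # zero variant columns: one empty haplotype holding everything
  inv <- mk_msa(c("ACGT", "ACGT"), c(7, 3), c("a", "a"))
  hap0 <- count_haplotypes(inv, detect_variant_columns(inv)$columns)
  expect_equal(hap0$haplotype, "")
  expect_equal(hap0$count, 10L)
})

test_that("genotype calls follow the Mendelian ratio decision order", {
  th <- genotype_thresholds()
  call <- function(counts, pop = c("A", "C", "G", "T"), variable = TRUE) {
    call_genotype(counts, pop, th, variable)$status
  }
  expect_equal(call(c(A = 94, C = 6)), "HOM")
  expect_equal(call(c(A = 60, C = 40)), "HET")
  expect_equal(call(c(A = 75, C = 25)), "HET_PROVISIONAL_PASSED")
  expect_equal(call(c(A = 75, C = 25), pop = character(0)), "BAD_RATIO")
  expect_equal(call(c(A = 50, C = 39, G = 11)), "EXTRA_READS")
  expect_equal(call(c(A = 4)), "LOW_DEPTH")
  expect_equal(call(c(A = 4), variable = FALSE), "HOM")
  expect_equal(call(c(A = 100)), "HOM")
  expect_error(call_genotype(c(A = -1)), "Negative")
})

test_that("threshold band edges behave exactly as specified", {
  th <- genotype_thresholds()
  f2_status <- function(f2) {
    counts <- c(A = 1000 - round(1000 * f2), C = round(1000 * f2))
    call_genotype(counts, c("A", "C"), th, TRUE)$status
  }
  expect_equal(f2_status(0.069), "HOM")                     # below ambiguity band
  expect_equal(f2_status(0.07), "BAD_RATIO")                # band is inclusive
  expect_equal(f2_status(0.20), "HET_PROVISIONAL_PASSED")   # provisional, inclusive
  expect_equal(f2_status(0.29), "HET_PROVISIONAL_PASSED")   # provisional, inclusive
  expect_equal(f2_status(0.291), "HET")                     # strictly above 29%

  f1_status <- function(f1) {
    counts <- c(A = round(1000 * f1), C = 1000 - round(1000 * f1))
    call_genotype(counts, c("A", "C"), th, TRUE)$status
  }
  expect_equal(f1_status(0.93), "BAD_RATIO")  # "more than 93%" is strict
  expect_equal(f1_status(0.931), "HOM")
})

test_that("statuses partition all sample-locus cells with data", {
  run <- shared_run0()
  calls <- run$res$genotypes$calls
  expect_false(any(is.na(calls$status)))
  expect_true(all(calls$status[calls$depth == 0] == "MISSING"))
  expect_true(all(calls$status[calls$depth > 0] != "MISSING"))
  expect_equal(nrow(dplyr::distinct(calls, locus_id, sample_id)), nrow(calls))
  het <- calls[calls$status == "HET", ]
  expect_true(all(het$allele1 != het$allele2))
})

test_that("gap coding turns each unique indel into one binary character", {
  # one 3-column deletion shared by two rows
  msa <- mk_msa(c("ACGTTTACG", "ACG---ACG", "ACG---ACG"), c(10, 8, 7),
                c("a", "b", "c"))
  ev <- gap_code_indels(msa)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_col, 4L)
  expect_equal(ev$n_cols, 3L)
  expect_equal(ev$presence[[1]], c(FALSE, TRUE, TRUE))

  # two different deletions (lengths 1 and 4) -> two characters
  msa2 <- mk_msa(c("ACGTTTACGGAA", "ACG-TTACGGAA", "ACGTTT----AA"), c(5, 5, 5),
                 c("a", "b", "c"))
  ev2 <- gap_code_indels(msa2)
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$n_cols, c(1L, 4L))

  expect_equal(nrow(gap_code_indels(mk_msa(c("ACGT", "ACGT"), c(1, 1),
                                           c("a", "b")))), 0L)
})

test_that("heterozygote-excess exact test matches enumeration of random pairings", {
  # conditional distribution of het count given allele counts, by
  # exhaustive enumeration of equally likely multiset arrangements
  enum_p <- function(n_het, n, nA) {
    arr <- utils::combn(2 * n, nA)
    hets <- apply(arr, 2L, function(ones) {
      v <- integer(2 * n); v[ones] <- 1L
      sum(v[seq(1, 2 * n, 2)] != v[seq(2, 2 * n, 2)])
    })
    mean(hets >= n_het)
  }
  for (case in list(c(2, 5, 4), c(4, 5, 4), c(3, 6, 5))) {
    n_het <- case[1]; n <- case[2]; nA <- case[3]
    n_hom1 <- (nA - n_het) / 2
    if (n_hom1 != floor(n_hom1)) next
    expect_equal(
      hwe_exact_excess(n_het, n_hom1, n - n_het - n_hom1),
      enum_p(n_het, n, nA),
      tolerance = 1e-10
    )
  }
  # every sample heterozygous for the same two alleles: detected
  expect_lt(hwe_exact_excess(46, 0, 0), 1e-6)
})

test_that("duplicate-locus screens exclude for the stated reasons", {
  run <- shared_run0()
  gt <- run$res$genotypes
  scr <- run$res$screened
  expect_true(all(c("locus_id", "keep", "reasons") %in% names(scr)))
  # well-behaved simulated loci are retained
  expect_gte(mean(scr$keep), 0.8)

  # (a) three flagged genotypes
  gt2 <- gt
  bad <- gt2$calls$locus_id == gt2$calls$locus_id[1] &
    gt2$calls$sample_id %in% unique(gt2$calls$sample_id)[1:3]
  gt2$calls$status[bad] <- "BAD_RATIO"
  scr2 <- screen_duplicate_loci(gt2)
  expect_false(scr2$keep[scr2$locus_id == gt2$calls$locus_id[1]])
  expect_match(scr2$reasons[scr2$locus_id == gt2$calls$locus_id[1]],
               "flagged_genotypes")

  # (b) absurd depth
  gt3 <- gt
  lid <- gt3$calls$locus_id[1]
  gt3$calls$depth[gt3$calls$locus_id == lid] <- 10000L
  scr3 <- screen_duplicate_loci(gt3)
  expect_match(scr3$reasons[scr3$locus_id == lid], "high_depth")

  # (c) universal heterozygosity
  gt4 <- gt
  sel <- gt4$calls$locus_id == lid
  gt4$calls$status[sel] <- "HET"
  gt4$calls$allele1[sel] <- "A"
  gt4$calls$allele2[sel] <- "C"
  gt4$calls$depth[sel] <- 50L
  scr4 <- screen_duplicate_loci(gt4)
  expect_match(scr4$reasons[scr4$locus_id == lid], "het_excess")
})

test_that("genotype matrices and writers round-trip", {
  run <- shared_run0()
  gt <- run$res$genotypes
  gm <- genotype_matrix(gt)
  expect_equal(nrow(gm), dplyr::n_distinct(gt$calls$sample_id))
  expect_equal(ncol(gm) - 1L, dplyr::n_distinct(gt$calls$locus_id))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(gt, tsv)
  back <- read_genotypes_tsv(tsv)
  expect_equal(nrow(back), nrow(gt$calls))
  expect_equal(back$status, gt$calls$status)
  expect_equal(back$depth, gt$calls$depth)
  i <- which(back$depth > 0)[1]
  expect_equal(back$allele_depths[[i]], gt$calls$allele_depths[[i]])

  st <- snp_table(gt)
  expect_true(all(st$base1[!is.na(st$base1)] %in% c("A", "C", "G", "T", "-")))
  it <- indel_table(gt, run$res$alignments)
  expect_true(all(stats::na.omit(it$copies) %in% 0:2))
})

test_that("VCF output is valid VCF 4.2", {
  run <- shared_run0()
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(run$res$genotypes, vcf_path, mapped = run$res$mapped)
  lines <- readLines(vcf_path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_gt(sum(!startsWith(lines, "#")), 0L)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  expect_gt(length(vcf), 0L)
  expect_equal(sort(colnames(vcf)),
               sort(unique(run$res$genotypes$calls$sample_id)))
})
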