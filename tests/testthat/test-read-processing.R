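mk_reads <- function(seqs, q = 38L) {
  tibble::tibble(
    id = sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    qual = vapply(nchar(seqs), function(n) intToUtf8(rep(q + 33L, n)),
                  character(1))
  )
}

bc_map <- tibble::tibble(barcode = c("ACGTAG", "TGCATC"),
                         sample_id = c("s1", "s2"))

test_that("demultiplexing is exact-match only and reconstructs the SbfI site", {
  reads <- mk_reads(c(
    paste0("ACGTAG", "TGCAGG", strrep("A", 30)),   # s1
    paste0("ACTTAG", "TGCAGG", strrep("A", 30)),   # one mismatch -> unassigned
    paste0("TGCATC", "TGCAGG", strrep("C", 30))    # s2
  ))
  dm <- demultiplex(reads, bc_map)
  expect_equal(nrow(dm$reads), 2L)
  expect_equal(nrow(dm$unassigned), 1L)
  expect_true(all(startsWith(dm$reads$sequence, "CCTGCAGG")))
  expect_equal(dm$reads$sample_id, c("s1", "s2"))
  # synthesized CC carries sentinel quality 40
  expect_true(all(substr(dm$reads$qual, 1, 2) == "II"))
  # conservation: assigned + unassigned = input
  expect_equal(sum(dm$counts$n_reads), nrow(reads))
  expect_error(
    demultiplex(reads, tibble::tibble(barcode = c("ACGTAG", "ACGTAG"),
                                      sample_id = c("a", "b"))),
    "Duplicate")
})

test_that("adapter trimming truncates at the placement and completes the EcoRI site", {
  ad <- default_p2_adapter()
  core <- paste0("CCTGCAGG", strrep("T", 40), "GAATT")
  reads <- tibble::tibble(
    sample_id = "s1", id = "r1",
    sequence = paste0(core, substr(ad, 1, 20)),
    qual = strrep("G", nchar(core) + 20L),
    adapter_trimmed = FALSE, internal_trimmed = FALSE
  )
  tr <- trim_p2_adapter(reads, ad)
  expect_true(tr$adapter_trimmed)
  expect_equal(tr$sequence, paste0(core, "C"))
  expect_true(endsWith(tr$sequence, "GAATTC"))
  expect_equal(nchar(tr$qual), nchar(tr$sequence))

  # no adapter -> untouched
  clean <- reads
  clean$sequence <- paste0("CCTGCAGG", strrep("T", 60))
  clean$qual <- strrep("G", 68L)
  expect_false(trim_p2_adapter(clean, ad)$adapter_trimmed)

  # two mismatches in a 20-base overlap (10% error) still trims
  ad20 <- strsplit(substr(ad, 1, 20), "")[[1]]
  ad20[c(5, 12)] <- c("T", "T")
  noisy <- reads
  noisy$sequence <- paste0(core, paste(ad20, collapse = ""))
  tr2 <- trim_p2_adapter(noisy, ad)
  expect_true(tr2$adapter_trimmed)
  expect_equal(tr2$sequence, paste0(core, "C"))
})

test_that("internal restriction sites discard (SbfI) or truncate (EcoRI)", {
  base <- function(s) tibble::tibble(sample_id = "s1", id = "r", sequence = s,
                                     qual = strrep("G", nchar(s)),
                                     adapter_trimmed = FALSE,
                                     internal_trimmed = FALSE)
  # internal SbfI -> chimera, discarded
  sc <- screen_internal_sites(
    base(paste0("CCTGCAGG", strrep("A", 20), "CCTGCAGG", strrep("T", 20))))
  expect_equal(nrow(sc$reads), 0L)
  expect_equal(nrow(sc$discarded), 1L)

  # internal EcoRI -> truncated right after the site
  s <- paste0("CCTGCAGG", strrep("A", 20), "GAATTC", strrep("T", 20))
  sc2 <- screen_internal_sites(base(s))
  expect_equal(sc2$reads$sequence, paste0("CCTGCAGG", strrep("A", 20), "GAATTC"))
  expect_true(sc2$reads$internal_trimmed)
  expect_equal(nchar(sc2$reads$qual), nchar(sc2$reads$sequence))

  # the minimum locus: EcoRI overlapping the leading site's final G survives
  sc3 <- screen_internal_sites(base(paste0("CCTGCAGGAATTC", strrep("T", 10))))
  expect_equal(sc3$reads$sequence, "CCTGCAGGAATTC")

  # clean read unchanged
  sc4 <- screen_internal_sites(base(paste0("CCTGCAGG", strrep("A", 40))))
  expect_equal(sc4$reads$sequence, paste0("CCTGCAGG", strrep("A", 40)))
  expect_false(sc4$reads$internal_trimmed)
})

test_that("condensation keeps multiplicities and position-wise maximum qualities", {
  reads <- tibble::tibble(
    sample_id = "s1",
    sequence = rep("ACGT", 3L),
    qual = phred_string(list(c(30, 10, 10, 10), c(20, 35, 10, 10),
                             c(40, 10, 12, 10)))
  )
  cd <- condense_reads(reads)
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$count, 3L)
  expect_equal(phred_ints(cd$qual)[[1]], c(40, 35, 12, 10))

  distinct <- tibble::tibble(sample_id = "s1",
                             sequence = c("AAAA", "CCCC", "GGGG"),
                             qual = rep("IIII", 3L))
  expect_true(all(condense_reads(distinct)$count == 1L))

  set.seed(5)
  rnd <- tibble::tibble(
    sample_id = sample(c("a", "b"), 50L, replace = TRUE),
    sequence = sample(c("ACGTAC", "ACGTAA", "TTTTTT"), 50L, replace = TRUE),
    qual = strrep("E", 6L)
  )
  expect_equal(sum(condense_reads(rnd)$count), 50L)
})

test_that("within-sample filter drops only isolated low-quality singletons", {
  s100 <- strrep("ACGTTGCAAC", 10L)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(1L, by = ceiling(100 / k), length.out = k)
    ch[idx] <- ifelse(ch[idx] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  neighbor85 <- mut(s100, 15L)  # 85% identity (just under 0.90)
  neighbor92 <- mut(s100, 8L)   # 92% identity
  lowq <- phred_string(list(rep(15L, 100L)))
  highq <- phred_string(list(rep(38L, 100L)))
  cd <- tibble::tibble(
    sample_id = "s1",
    sequence = c(s100, neighbor85),
    count = c(5L, 1L),
    qual = c(highq, lowq),
    mean_qual = c(38, 15)
  )
  kept <- within_sample_quality_filter(cd)
  expect_equal(kept$sequence, s100)  # isolated low-quality singleton removed

  cd$sequence[2] <- neighbor92
  expect_equal(nrow(within_sample_quality_filter(cd)), 2L)

  solo <- tibble::tibble(sample_id = "s1", sequence = s100, count = 1L,
                         qual = highq, mean_qual = 25)
  expect_equal(nrow(within_sample_quality_filter(solo)), 1L)
})

test_that("zero-error simulator reads round-trip to the truth locus sequences", {
  run <- shared_run0()
  sim <- run$sim
  proc <- run$res$processed
  # every condensed sequence must equal the observable form of a truth allele
  obs <- unique(observable_allele(stats::na.omit(sim$alleles$sequence)))
  expect_true(all(proc$condensed$sequence %in% obs))
  # and demultiplex + condense conserve read counts
  expect_equal(sum(proc$stats$n_reads), nrow(sim$reads))
  assigned <- proc$stats$n_reads[proc$stats$sample_id != "(unassigned)"]
  expect_equal(sum(assigned), nrow(sim$reads))  # barcodes all known
})
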