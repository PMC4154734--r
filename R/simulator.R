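# Bias-aware ddRAD library simulator. Emits multiplexed single-end FASTQ
# plus truth tables (loci, alleles, genotypes, per-read provenance) so the
# whole pipeline is testable on toy genomes with no external data.

SBFI <- "CCTGCAGG"
ECORI <- "GAATTC"

#' Population model configuration
#'
#' @param n_individuals Diploid individuals (default 46, one sequencing
#'   lane's worth).
#' @param snp_rate Per-interior-site probability a position segregates.
#' @param indel_rate Per-interior-site probability of a segregating
#'   deletion (lengths 1-4, short-biased).
#' @param site_poly_rate Per-locus probability of a segregating mutation
#'   inside a terminal recognition site; carrier chromosomes are null
#'   alleles and emit no reads.
#' @return List of class `ddrad_popcfg`.
#' @export
population_config <- function(n_individuals = 46L, snp_rate = 0.013,
                              indel_rate = 0.0015, site_poly_rate = 0.02) {
  stopifnot(n_individuals >= 1L, snp_rate >= 0, snp_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            site_poly_rate >= 0, site_poly_rate <= 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 site_poly_rate = site_poly_rate),
            class = "ddrad_popcfg")
}

#' Amplification-bias depth model
#'
#' Log-linear mean depth in fragment length and GC for in-window
#' fragments, with negative-binomial dispersion; fragments below the
#' size window are carried over with a single inclusion probability and
#' a weaker GC effect, fragments above it get no reads. Defaults are
#' calibrated so that regressing realized log depth on (length, GC) over
#' a few thousand in-range loci yields R-squared near 0.43, with the
#' length:GC signal split near 0.20:0.23.
#'
#' @param beta_len Per-bp log-depth slope in length (negative: shorter
#'   fragments amplify better).
#' @param beta_gc Log-depth slope in GC fraction (positive).
#' @param dispersion Negative-binomial size parameter.
#' @param carryover_prob Relative inclusion weight of below-window
#'   fragments.
#' @param carryover_gc_coeff GC slope below the window (weaker).
#' @return List of class `ddrad_bias`.
#' @export
bias_model <- function(beta_len = -0.011, beta_gc = 4.2, dispersion = 6,
                       carryover_prob = 0.35, carryover_gc_coeff = 1.5) {
  stopifnot(dispersion > 0, carryover_prob >= 0, carryover_prob <= 1)
  structure(list(beta_len = beta_len, beta_gc = beta_gc,
                 dispersion = dispersion, carryover_prob = carryover_prob,
                 carryover_gc_coeff = carryover_gc_coeff),
            class = "ddrad_bias")
}

#' Tapered size-selection model
#'
#' Inclusion weight rises linearly from `taper_min` at the window minimum
#' to 1 at the window maximum, emulating a tapered gel slice (full lane
#' width at the large-fragment edge, half width at the small-fragment
#' edge) that counteracts PCR bias toward short fragments.
#'
#' @param min_bp,max_bp Genomic insert window (default 178-328 bp).
#' @param taper_min Weight at the window minimum (default 0.5).
#' @return List of class `ddrad_sizesel`.
#' @export
size_selection_model <- function(min_bp = 178L, max_bp = 328L,
                                 taper_min = 0.5) {
  stopifnot(min_bp > 0, min_bp <= max_bp, taper_min > 0, taper_min <= 1)
  structure(list(min_bp = min_bp, max_bp = max_bp, taper_min = taper_min),
            class = "ddrad_sizesel")
}

taper_weight <- function(len, size) {
  ifelse(len < size$min_bp | len > size$max_bp, 0,
         size$taper_min + (1 - size$taper_min) *
           (len - size$min_bp) / max(size$max_bp - size$min_bp, 1L))
}

#' Star-activity and chimera model
#'
#' Non-specific cutting at near-canonical SbfI sites, concentrated at
#' recognition positions 1 and 8; the default edge:internal rate ratio
#' (about 29:1) puts roughly 90% of star reads at edge-mismatch sites
#' when sites are planted uniformly across positions. Chimera reads
#' originate inside SbfI-SbfI fragments ligated to a genuine fragment.
#'
#' @param rate_edge Expected star reads per individual per 1-mismatch
#'   site with the mismatch at recognition position 1 or 8.
#' @param rate_internal Same for mismatches at positions 2-7.
#' @param chimera_rate Probability per individual per SbfI-SbfI fragment
#'   of emitting a chimera read.
#' @return List of class `ddrad_star`.
#' @export
star_activity_model <- function(rate_edge = 0.08,
                                rate_internal = 0.08 / 28.87,
                                chimera_rate = 0.02) {
  stopifnot(rate_edge >= 0, rate_internal >= 0,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(rate_edge = rate_edge, rate_internal = rate_internal,
                 chimera_rate = chimera_rate),
            class = "ddrad_star")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Mutate positions inside `protect_free` until `block` contains the two
# patterns only at the expected terminal positions.
scrub_block <- function(block, patterns, allowed_starts, mutable) {
  chars <- strsplit(block, "")[[1]]
  repeat {
    bad <- integer(0)
    blk <- paste(chars, collapse = "")
    for (p in patterns) {
      hits <- gregexpr(p, blk, fixed = TRUE)[[1]]
      hits <- hits[hits > 0L]
      for (h in hits) {
        if (!h %in% allowed_starts[[p]]) {
          span <- intersect(h:(h + nchar(p) - 1L), mutable)
          if (length(span) == 0L) stop("Cannot scrub planted block.", call. = FALSE)
          bad <- c(bad, span[ceiling(length(span) / 2)])
        }
      }
    }
    if (length(bad) == 0L) return(paste(chars, collapse = ""))
    for (b in unique(bad)) {
      chars[b] <- sample(setdiff(c("A", "C", "G", "T"), chars[b]), 1L)
    }
  }
}

make_ab_block <- function(len, gc) {
  interior <- random_dna(len - 14L, gc)
  block <- paste0(SBFI, interior, ECORI)
  scrub_block(block, c(SBFI, ECORI),
              stats::setNames(list(1L, len - 5L), c(SBFI, ECORI)),
              mutable = 9L:(len - 6L))
}

make_star_block <- function(len, gc, mismatch_pos) {
  site <- strsplit(SBFI, "")[[1]]
  site[mismatch_pos] <- sample(setdiff(c("A", "C", "G", "T"), site[mismatch_pos]), 1L)
  interior <- random_dna(len - 14L, gc)
  block <- paste0(paste(site, collapse = ""), interior, ECORI)
  scrub_block(block, c(SBFI, ECORI),
              stats::setNames(list(integer(0), len - 5L), c(SBFI, ECORI)),
              mutable = 9L:(len - 6L))
}

make_bb_block <- function(len, gc) {
  interior <- random_dna(len - 16L, gc)
  block <- paste0(SBFI, interior, SBFI)
  scrub_block(block, c(SBFI, ECORI),
              stats::setNames(list(c(1L, len - 7L), integer(0)), c(SBFI, ECORI)),
              mutable = 9L:(len - 8L))
}

#' Build a toy genome with planted ddRAD features
#'
#' A single contig of random background, guaranteed free of SbfI and
#' EcoRI recognition sequences except at planted features: SbfI-EcoRI
#' fragments at controlled lengths and GC (in-range, below-range,
#' above-range), near-canonical SbfI sites with chosen mismatch
#' positions (star-activity substrate), SbfI-SbfI fragments (chimera
#' substrate), and duplicated leading tags (multicopy substrate).
#' Spacers are long enough that no unplanned in-range fragment can form
#' between features. Deterministic per seed.
#'
#' @param n_in_range,n_short,n_long Numbers of planted SbfI-EcoRI
#'   fragments inside, below, and above the 178-328 bp window.
#' @param n_star Near-canonical SbfI sites; mismatch positions cycle
#'   through 1..8, so 2/8 of planted sites are edge-mismatch sites.
#' @param n_bb SbfI-SbfI fragments (<= 328 bp).
#' @param n_duplications In-range fragments whose first 100 bp are
#'   copied elsewhere in the genome.
#' @param gc Mean GC of planted fragments (per-fragment GC is jittered
#'   around this).
#' @param seed Random seed.
#' @return List of class `ddrad_toygenome`: `genome` (see
#'   [as_genome()]) and `features` (tibble `feature_id`, `type`,
#'   `start`, `end`, `length`, `mismatch_pos`, `source_id`).
#' @export
make_toy_genome <- function(n_in_range = 24L, n_short = 6L, n_long = 3L,
                            n_star = 8L, n_bb = 3L, n_duplications = 2L,
                            gc = 0.5, seed = 1L) {
  set.seed(seed)
  spacer <- function() random_dna(sample(600:800, 1L), 0.45)
  gc_jitter <- function(n) pmin(0.68, pmax(0.32, stats::rnorm(n, gc, 0.075)))
  specs <- dplyr::bind_rows(
    tibble::tibble(type = "ab_in", len = sample(178:328, n_in_range, replace = TRUE)),
    tibble::tibble(type = "ab_short", len = sample(38:170, max(n_short, 0L), replace = TRUE)),
    tibble::tibble(type = "ab_long", len = sample(360:450, max(n_long, 0L), replace = TRUE)),
    tibble::tibble(type = "star", len = sample(178:300, max(n_star, 0L), replace = TRUE)),
    tibble::tibble(type = "bb", len = sample(120:300, max(n_bb, 0L), replace = TRUE))
  )
  specs$gc <- gc_jitter(nrow(specs))
  specs$mismatch_pos <- NA_integer_
  if (n_star > 0L) {
    specs$mismatch_pos[specs$type == "star"] <- rep(1:8, length.out = n_star)
  }
  specs <- specs[sample(nrow(specs)), , drop = FALSE]
  specs$feature_id <- sprintf("f%02d", seq_len(nrow(specs)))
  blocks <- purrr::pmap_chr(
    list(specs$type, specs$len, specs$gc, specs$mismatch_pos),
    function(type, len, g, mp) {
      switch(type,
             ab_in = , ab_short = , ab_long = make_ab_block(len, g),
             star = make_star_block(len, g, mp),
             bb = make_bb_block(len, g))
    }
  )
  # duplications: copy the leading 100 bp of the first in-range fragments
  dup_src <- utils::head(specs$feature_id[specs$type == "ab_in" & specs$len >= 150L],
                         n_duplications)
  dup_seqs <- substr(blocks[match(dup_src, specs$feature_id)], 1L, 100L)
  parts <- character(0); feats <- list(); pos <- 0L
  add_spacer <- function() {
    s <- spacer(); parts <<- c(parts, s); pos <<- pos + nchar(s)
  }
  add_spacer()
  for (i in seq_len(nrow(specs))) {
    feats[[length(feats) + 1L]] <- tibble::tibble(
      feature_id = specs$feature_id[i], type = specs$type[i], start = pos,
      end = pos + nchar(blocks[i]), length = nchar(blocks[i]),
      mismatch_pos = specs$mismatch_pos[i], source_id = NA_character_
    )
    parts <- c(parts, blocks[i]); pos <- pos + nchar(blocks[i])
    add_spacer()
  }
  for (d in seq_along(dup_seqs)) {
    feats[[length(feats) + 1L]] <- tibble::tibble(
      feature_id = sprintf("dup%02d", d), type = "dup", start = pos,
      end = pos + nchar(dup_seqs[d]), length = nchar(dup_seqs[d]),
      mismatch_pos = NA_integer_, source_id = dup_src[d]
    )
    parts <- c(parts, dup_seqs[d]); pos <- pos + nchar(dup_seqs[d])
    add_spacer()
  }
  genome_str <- paste(parts, collapse = "")
  features <- dplyr::bind_rows(feats)
  # scrub stray sites created inside spacers (block junctions are
  # impossible by construction, but the random spacers can contain sites)
  in_feature <- function(p, width) {
    any(p <= features$end & p + width - 1L > features$start)
  }
  repeat {
    stray <- integer(0)
    for (p in c(SBFI, ECORI)) {
      hits <- gregexpr(p, genome_str, fixed = TRUE)[[1]]
      hits <- hits[hits > 0L]
      for (h in hits) {
        if (!in_feature(h - 1L, nchar(p))) stray <- c(stray, h + 3L)
      }
    }
    if (length(stray) == 0L) break
    chars <- strsplit(genome_str, "")[[1]]
    for (b in unique(stray)) {
      chars[b] <- sample(setdiff(c("A", "C", "G", "T"), chars[b]), 1L)
    }
    genome_str <- paste(chars, collapse = "")
  }
  structure(
    list(genome = as_genome(c(chr1 = genome_str)), features = features),
    class = "ddrad_toygenome"
  )
}

neutral_count <- function(n_chrom) {
  i <- seq_len(n_chrom - 1L)
  sample(i, 1L, prob = 1 / i)
}

#' Simulate a diploid population over predicted loci
#'
#' For each predicted locus, segregating SNPs and short deletions are
#' placed in the interior (derived-allele counts drawn from the neutral
#' 1/i spectrum, carriers assigned to random chromosomes), and with
#' probability `site_poly_rate` a terminal recognition-site mutation
#' makes carrier chromosomes null (they emit no reads). Chromosomes are
#' paired at random into individuals, i.e. Hardy-Weinberg sampling.
#'
#' @param genome See [as_genome()]; loci are predicted over a wide 13-500
#'   bp window so below- and above-window fragments stay visible to the
#'   depth model.
#' @param cfg See [population_config()].
#' @param seed Random seed.
#' @return List of class `ddrad_population`: `loci` (truth loci),
#'   `alleles` (tibble `locus_id`, `allele`, `sequence`, `length`, `gc`,
#'   `null`, `n_chrom`), `genotypes` (tibble `locus_id`, `sample_id`,
#'   `allele1`, `allele2`), `samples`.
#' @export
simulate_population <- function(genome, cfg = population_config(), seed = 1L) {
  set.seed(seed)
  genome <- as_genome(genome)
  loci <- predict_ddrad_loci(genome, "SbfI", "EcoRI", 13L, 500L)
  n <- cfg$n_individuals
  samples <- sprintf("ind%02d", seq_len(n))
  n_chrom <- 2L * n
  alleles <- list(); genos <- list()
  for (r in seq_len(nrow(loci))) {
    ref <- loci$sequence[r]
    len <- nchar(ref)
    chrom_seq <- rep(ref, n_chrom)
    chrom_null <- rep(FALSE, n_chrom)
    interior <- if (len >= 15L) 9L:(len - 6L) else integer(0)
    # SNPs (applied before deletions so positions do not shift)
    n_snp <- stats::rbinom(1L, length(interior), cfg$snp_rate)
    snp_pos <- sort(sample(interior, min(n_snp, length(interior))))
    for (p in snp_pos) {
      carriers <- sample(n_chrom, neutral_count(n_chrom))
      derived <- sample(setdiff(c("A", "C", "G", "T"), substr(ref, p, p)), 1L)
      substr(chrom_seq[carriers], p, p) <- derived
    }
    # deletions, longest position first
    n_ind <- stats::rbinom(1L, length(interior), cfg$indel_rate)
    if (n_ind > 0L && length(interior) > 6L) {
      for (k in seq_len(n_ind)) {
        dlen <- sample(1:4, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
        pmax_ <- len - 6L - dlen
        if (pmax_ < 9L) next
        p <- sample(9L:pmax_, 1L)
        carriers <- sample(n_chrom, neutral_count(n_chrom))
        chrom_seq[carriers] <- paste0(substr(chrom_seq[carriers], 1L, p - 1L),
                                      substr(chrom_seq[carriers], p + dlen, len))
      }
    }
    # restriction-site polymorphism -> null allele; rate 1 models a
    # fixed site difference (every chromosome null)
    if (cfg$site_poly_rate >= 1 || stats::runif(1L) < cfg$site_poly_rate) {
      carriers <- if (cfg$site_poly_rate >= 1) seq_len(n_chrom) else
        sample(n_chrom, neutral_count(n_chrom))
      chrom_null[carriers] <- TRUE
    }
    uniq <- unique(chrom_seq[!chrom_null])
    if (length(uniq) > 0L) {
      uniq <- uniq[order(-tabulate(match(chrom_seq[!chrom_null], uniq),
                                   nbins = length(uniq)), uniq)]
    }
    allele_of <- function(j) {
      if (chrom_null[j]) "NULL" else paste0("A", match(chrom_seq[j], uniq))
    }
    allele_ids <- vapply(seq_len(n_chrom), allele_of, character(1))
    tab <- table(allele_ids[allele_ids != "NULL"])
    if (length(uniq) > 0L) {
      alleles[[length(alleles) + 1L]] <- tibble::tibble(
        locus_id = loci$locus_id[r],
        allele = paste0("A", seq_along(uniq)),
        sequence = uniq,
        length = nchar(uniq),
        gc = vapply(uniq, gc_fraction, numeric(1), USE.NAMES = FALSE),
        null = FALSE,
        n_chrom = as.integer(tab[paste0("A", seq_along(uniq))])
      )
    }
    if (any(chrom_null)) {
      alleles[[length(alleles) + 1L]] <- tibble::tibble(
        locus_id = loci$locus_id[r], allele = "NULL", sequence = NA_character_,
        length = NA_integer_, gc = NA_real_, null = TRUE,
        n_chrom = sum(chrom_null)
      )
    }
    perm <- sample(n_chrom)
    genos[[length(genos) + 1L]] <- tibble::tibble(
      locus_id = loci$locus_id[r],
      sample_id = samples,
      allele1 = allele_ids[perm[seq(1L, n_chrom, by = 2L)]],
      allele2 = allele_ids[perm[seq(2L, n_chrom, by = 2L)]]
    )
  }
  structure(
    list(loci = loci, alleles = dplyr::bind_rows(alleles),
         genotypes = dplyr::bind_rows(genos), samples = samples,
         cfg = cfg),
    class = "ddrad_population"
  )
}

#' Simulate per-allele sequencing depths under the bias model
#'
#' Each allele copy an individual carries gets weight
#' `exp(beta_len * (len - 253) + beta_gc * (gc - 0.5)) * taper(len)`
#' inside the size window, `carryover_prob * exp(carryover_gc_coeff *
#' (gc - 0.5))` below it, and 0 above it (null alleles always 0); the
#' individual's read budget is shared in proportion. Each
#' (individual, locus) draws one negative-binomial total, split between
#' the two allele copies binomially by relative weight, so heterozygote
#' allele-depth pairs follow Binomial(depth, 1/2) for equivalent
#' alleles.
#'
#' @param pop A `ddrad_population`.
#' @param bias See [bias_model()].
#' @param size See [size_selection_model()].
#' @param reads_per_individual Expected total reads per individual
#'   (locus-derived reads; star/chimera reads come on top).
#' @param seed Random seed.
#' @return Tibble `sample_id`, `locus_id`, `allele`, `copies`, `length`,
#'   `gc`, `expected`, `realized`.
#' @export
simulate_depths <- function(pop, bias = bias_model(),
                            size = size_selection_model(),
                            reads_per_individual = 2000L, seed = 1L) {
  set.seed(seed)
  stopifnot(reads_per_individual >= 1L)
  mid <- (size$min_bp + size$max_bp) / 2
  gcopy <- pop$genotypes |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::count(.data$sample_id, .data$locus_id, .data$allele,
                 name = "copies") |>
    dplyr::left_join(pop$alleles, by = c("locus_id", "allele"))
  w_in <- exp(bias$beta_len * (gcopy$length - mid) +
                bias$beta_gc * (gcopy$gc - 0.5)) *
    taper_weight(gcopy$length, size)
  w_below <- bias$carryover_prob *
    exp(bias$carryover_gc_coeff * (gcopy$gc - 0.5))
  w <- dplyr::case_when(
    gcopy$null ~ 0,
    gcopy$length > size$max_bp ~ 0,
    gcopy$length < size$min_bp ~ w_below,
    TRUE ~ w_in
  )
  gcopy$w <- w * gcopy$copies
  gcopy$expected <- 0
  for (sm in unique(gcopy$sample_id)) {
    idx <- gcopy$sample_id == sm
    tot <- sum(gcopy$w[idx])
    if (tot > 0) gcopy$expected[idx] <- reads_per_individual * gcopy$w[idx] / tot
  }
  # Per (individual, locus): one overdispersed total, split between the
  # two allele copies binomially by relative weight -- heterozygote
  # allele-depth pairs are Binomial(total, 1/2) for alleles of equal
  # length and GC, matching Mendelian sampling.
  gcopy$realized <- 0L
  grp <- paste(gcopy$sample_id, gcopy$locus_id)
  for (g in split(seq_len(nrow(gcopy)), grp)) {
    mu <- sum(gcopy$expected[g])
    if (mu <= 0) next
    total <- stats::rnbinom(1L, mu = mu, size = bias$dispersion)
    if (total == 0L) next
    if (length(g) == 1L) {
      gcopy$realized[g] <- total
    } else {
      p <- gcopy$expected[g] / mu
      gcopy$realized[g] <- as.integer(stats::rmultinom(1L, total, p))
    }
  }
  dplyr::select(gcopy, "sample_id", "locus_id", "allele", "copies",
                "length", "gc", "null", "expected", "realized")
}

#' Survey the depth-bias law over many synthetic in-range loci
#'
#' Draws `n_loci` fragment lengths uniformly over the size window and GC
#' fractions from the toy-genome GC law (normal around 0.5, sd 0.075,
#' clipped), realizes depths for a single homozygous individual under
#' the bias model, and regresses realized log depth on length and GC.
#' This is the calibration view of the simulator: with default
#' coefficients the regression R-squared lands near 0.43.
#'
#' @param n_loci Number of surveyed loci (default 2000).
#' @param bias,size See [bias_model()], [size_selection_model()].
#' @param mean_depth Target mean depth per locus.
#' @param seed Random seed.
#' @return List: `depths` (tibble `locus_id`, `length`, `gc`,
#'   `realized`), `fit` (the lm), `r_squared`, `partial_length`,
#'   `partial_gc`.
#' @export
depth_bias_survey <- function(n_loci = 2000L, bias = bias_model(),
                              size = size_selection_model(),
                              mean_depth = 40L, seed = 1L) {
  set.seed(seed)
  lens <- sample(size$min_bp:size$max_bp, n_loci, replace = TRUE)
  gcs <- pmin(0.68, pmax(0.32, stats::rnorm(n_loci, 0.5, 0.075)))
  ids <- sprintf("L%05d", seq_len(n_loci))
  pop <- list(
    alleles = tibble::tibble(locus_id = ids, allele = "A1",
                             sequence = NA_character_, length = lens,
                             gc = gcs, null = FALSE, n_chrom = 2L),
    genotypes = tibble::tibble(locus_id = ids, sample_id = "ind01",
                               allele1 = "A1", allele2 = "A1")
  )
  d <- simulate_depths(pop, bias, size,
                       reads_per_individual = n_loci * mean_depth,
                       seed = seed + 1L)
  d <- d[d$realized > 0L, , drop = FALSE]
  fit <- stats::lm(log(realized) ~ length + gc, data = d)
  red_len <- stats::lm(log(realized) ~ gc, data = d)
  red_gc <- stats::lm(log(realized) ~ length, data = d)
  sse <- function(m) sum(stats::residuals(m)^2)
  list(
    depths = d, fit = fit,
    r_squared = summary(fit)$r.squared,
    partial_length = (sse(red_len) - sse(fit)) / sse(red_len),
    partial_gc = (sse(red_gc) - sse(fit)) / sse(red_gc)
  )
}

# Build the sequenced read body (after the barcode) for a fragment whose
# full sequence is `frag` (starting with the canonical SbfI site): the
# read begins at recognition position 3 (TGCA overhang + GG); fragments
# shorter than the read capacity continue through ...GAATT into the P2
# adapter.
read_body <- function(frag, cap, adapter) {
  body <- substr(frag, 3L, nchar(frag) - 1L)
  if (nchar(body) < cap) {
    body <- paste0(body, strrep(adapter, ceiling(cap / nchar(adapter))))
  }
  substr(body, 1L, cap)
}

apply_errors <- function(seqs, error_rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  quals <- character(length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    q <- sample(33:41, L, replace = TRUE,
                prob = c(1, 1, 2, 3, 5, 8, 12, 16, 12))
    if (n_err[i] > 0L) {
      pos <- sample(L, n_err[i])
      chars <- strsplit(seqs[i], "")[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
      q[pos] <- sample(3:20, n_err[i], replace = TRUE)
    }
    quals[i] <- intToUtf8(q + 33L)
  }
  list(sequence = seqs, qual = quals, n_err = n_err)
}

#' Emit multiplexed FASTQ reads with per-read truth
#'
#' Locus reads follow the realized depths; star reads are drawn per
#' near-canonical site at the model rates (the ligated overhang is
#' regenerated as canonical sequence, so the mismatch is visible only in
#' the genome, exactly as star loci are detected in practice); chimera
#' reads originate inside SbfI-SbfI fragments and run across the
#' reconstituted SbfI junction into a genuine fragment. Per-base errors
#' occur at `error_rate` with low quality scores; correct bases draw
#' from a high-quality distribution.
#'
#' @param pop A `ddrad_population`.
#' @param depths Tibble from [simulate_depths()].
#' @param toy The `ddrad_toygenome` (for star/chimera substrates); may be
#'   NULL to disable artifact reads.
#' @param star See [star_activity_model()].
#' @param error_rate Per-base error probability.
#' @param read_len Raw read length (default 100).
#' @param barcode_map Tibble `barcode`, `sample_id`; defaults to the
#'   first barcodes of [generate_barcode_set()].
#' @param adapter P2 adapter (read-through continuation).
#' @param seed Random seed.
#' @return List: `reads` (tibble `id`, `sequence`, `qual`),
#'   `provenance` (tibble `id`, `sample_id`, `origin`, `locus_id`,
#'   `allele`, `n_errors`), `barcode_map`.
#' @export
emit_fastq <- function(pop, depths, toy = NULL,
                       star = star_activity_model(), error_rate = 0.001,
                       read_len = 100L, barcode_map = NULL,
                       adapter = default_p2_adapter(), seed = 1L) {
  set.seed(seed)
  if (is.null(barcode_map)) {
    bcs <- generate_barcode_set()
    stopifnot(nrow(bcs) >= length(pop$samples))
    barcode_map <- tibble::tibble(barcode = bcs$barcode[seq_along(pop$samples)],
                                  sample_id = pop$samples)
  }
  bc_of <- stats::setNames(barcode_map$barcode, barcode_map$sample_id)
  cap <- read_len - nchar(barcode_map$barcode[1])
  seq_of_allele <- stats::setNames(
    pop$alleles$sequence, paste(pop$alleles$locus_id, pop$alleles$allele))
  emit <- depths[depths$realized > 0L & !depths$null, , drop = FALSE]
  src <- tibble::tibble(
    sample_id = rep(emit$sample_id, emit$realized),
    origin = "allele",
    locus_id = rep(emit$locus_id, emit$realized),
    allele = rep(emit$allele, emit$realized),
    frag = rep(seq_of_allele[paste(emit$locus_id, emit$allele)],
               emit$realized)
  )
  if (!is.null(toy)) {
    feats <- toy$features
    genome_str <- unclass(toy$genome)[[1]]
    stars <- feats[feats$type == "star", , drop = FALSE]
    if (nrow(stars) > 0L) {
      for (i in seq_len(nrow(stars))) {
        rate <- if (stars$mismatch_pos[i] %in% c(1L, 8L)) star$rate_edge else
          star$rate_internal
        n_by_sample <- stats::rpois(length(pop$samples), rate)
        if (sum(n_by_sample) == 0L) next
        # canonical head restored by ligation; genomic tail as-is
        frag <- paste0(SBFI,
                       substr(genome_str, stars$start[i] + 9L, stars$end[i]))
        src <- dplyr::bind_rows(src, tibble::tibble(
          sample_id = rep(pop$samples, n_by_sample),
          origin = "star",
          locus_id = stars$feature_id[i],
          allele = NA_character_,
          frag = frag
        ))
      }
    }
    bbs <- feats[feats$type == "bb", , drop = FALSE]
    ab_in <- feats[feats$type == "ab_in", , drop = FALSE]
    if (nrow(bbs) > 0L && nrow(ab_in) > 0L) {
      for (i in seq_len(nrow(bbs))) {
        hit <- stats::runif(length(pop$samples)) < star$chimera_rate
        if (!any(hit)) next
        partner <- ab_in[sample(nrow(ab_in), 1L), ]
        bb_seq <- substr(genome_str, bbs$start[i] + 1L, bbs$end[i])
        partner_seq <- substr(genome_str, partner$start + 1L, partner$end)
        frag <- paste0(bb_seq, substr(partner_seq, 9L, nchar(partner_seq)))
        src <- dplyr::bind_rows(src, tibble::tibble(
          sample_id = pop$samples[hit],
          origin = "chimera",
          locus_id = bbs$feature_id[i],
          allele = NA_character_,
          frag = frag
        ))
      }
    }
  }
  if (nrow(src) == 0L) {
    return(list(reads = tibble::tibble(id = character(), sequence = character(),
                                       qual = character()),
                provenance = tibble::tibble(id = character(),
                                            sample_id = character(),
                                            origin = character(),
                                            locus_id = character(),
                                            allele = character(),
                                            n_errors = integer()),
                barcode_map = barcode_map))
  }
  bodies <- vapply(src$frag, read_body, character(1), cap = cap,
                   adapter = adapter, USE.NAMES = FALSE)
  raw <- paste0(bc_of[src$sample_id], bodies)
  err <- apply_errors(raw, error_rate)
  ids <- sprintf("read%06d", seq_along(raw))
  list(
    reads = tibble::tibble(id = ids, sequence = err$sequence, qual = err$qual),
    provenance = tibble::tibble(
      id = ids, sample_id = src$sample_id, origin = src$origin,
      locus_id = src$locus_id, allele = src$allele, n_errors = err$n_err
    ),
    barcode_map = barcode_map
  )
}

#' One-call ddRAD library simulation
#'
#' Builds (or accepts) a toy genome, simulates the population, the
#' biased depths and the reads, and bundles every truth table.
#'
#' @param toy A `ddrad_toygenome` from [make_toy_genome()], or NULL to
#'   build one with defaults.
#' @param cfg,bias,size,star Model components (see
#'   [population_config()], [bias_model()], [size_selection_model()],
#'   [star_activity_model()]).
#' @param reads_per_individual,error_rate,read_len,adapter See
#'   [simulate_depths()] and [emit_fastq()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `ddrad_sim` with `toy`, `genome`, `loci`,
#'   `alleles`, `genotypes`, `depths`, `reads`, `provenance`,
#'   `barcode_map`, `params`.
#' @export
simulate_ddrad <- function(toy = NULL, cfg = population_config(),
                           bias = bias_model(),
                           size = size_selection_model(),
                           star = star_activity_model(),
                           reads_per_individual = 2000L, error_rate = 0.001,
                           read_len = 100L, adapter = default_p2_adapter(),
                           seed = 1L) {
  if (is.null(toy)) toy <- make_toy_genome(seed = seed)
  pop <- simulate_population(toy$genome, cfg, seed = seed + 1L)
  depths <- simulate_depths(pop, bias, size, reads_per_individual,
                            seed = seed + 2L)
  fq <- emit_fastq(pop, depths, toy, star, error_rate, read_len,
                   barcode_map = NULL, adapter = adapter, seed = seed + 3L)
  structure(
    list(toy = toy, genome = toy$genome, loci = pop$loci,
         alleles = pop$alleles, genotypes = pop$genotypes, depths = depths,
         reads = fq$reads, provenance = fq$provenance,
         barcode_map = fq$barcode_map,
         params = list(cfg = cfg, bias = bias, size = size, star = star,
                       reads_per_individual = reads_per_individual,
                       error_rate = error_rate, read_len = read_len,
                       adapter = adapter, seed = seed)),
    class = "ddrad_sim"
  )
}

#' @export
print.ddrad_sim <- function(x, ...) {
  cat(sprintf("<ddrad_sim: %d individuals, %d truth loci, %d reads>\n",
              length(unique(x$genotypes$sample_id)), nrow(x$loci),
              nrow(x$reads)))
  invisible(x)
}

#' The observable (read-level) representation of an allele sequence
#'
#' What the processing pipeline reconstructs of an allele of length `L`
#' with processed-read capacity `cap = read_len - barcode_len + 2`:
#' the full fragment when the adapter read-through is long enough to be
#' recognised and trimmed back (`L <= cap - min_overlap + 1`); the
#' leading `cap` bases when the fragment fills the read (`L > cap`);
#' and, in the narrow boundary zone in between, the fragment minus its
#' final base plus the few unrecognisably-short adapter bases that
#' remain untrimmed.
#'
#' @param sequence Allele (fragment) sequences.
#' @param read_len Raw read length.
#' @param barcode_len Barcode length.
#' @param adapter P2 adapter continuation.
#' @param min_overlap Adapter-trim minimum overlap.
#' @return Character vector.
#' @export
observable_allele <- function(sequence, read_len = 100L, barcode_len = 6L,
                              adapter = default_p2_adapter(),
                              min_overlap = 8L) {
  cap <- read_len - barcode_len + 2L
  L <- nchar(sequence)
  overlap <- cap + 1L - L  # adapter bases present in the processed read
  dplyr::case_when(
    L > cap ~ substr(sequence, 1L, cap),
    overlap >= min_overlap ~ sequence,
    TRUE ~ paste0(substr(sequence, 1L, L - 1L), substr(adapter, 1L, overlap))
  )
}

#' Concordance of pipeline genotype calls with simulator truth
#'
#' Matches merged, mapped clusters to truth loci by the genomic start of
#' the leading SbfI site, derives each cell's expected zygosity from the
#' reads the simulator actually emitted (so null alleles and dropout are
#' judged by what was observable), and compares status class and, for
#' both-called cells, the reconstructed allele sequences.
#'
#' @param genotypes A `ddrad_genotypes` from the pipeline.
#' @param mapped Merged cluster table ([map_clusters()] /
#'   [merge_by_position()]).
#' @param alignments Alignment table the calls were made from.
#' @param sim A `ddrad_sim`.
#' @param min_allele_depth Only cells where every emitting allele
#'   reached this many reads are scored.
#' @return List: `cells` (per-cell tibble with `agree`), `concordance`
#'   (fraction agreeing).
#' @export
genotype_concordance <- function(genotypes, mapped, alignments, sim,
                                 min_allele_depth = 1L) {
  read_len <- sim$params$read_len
  bc_len <- nchar(sim$barcode_map$barcode[1])
  truth_loci <- sim$loci
  a_start <- ifelse(truth_loci$orientation == "+", truth_loci$start,
                    truth_loci$end - nchar(SBFI))
  m <- mapped[!mapped$anonymous, , drop = FALSE]
  m_a_start <- ifelse(m$strand == "+", m$pos, m$end - nchar(SBFI))
  cluster_of_locus <- m$cluster_id[match(a_start, m_a_start)]
  allele_seqs <- stats::setNames(
    sim$alleles$sequence, paste(sim$alleles$locus_id, sim$alleles$allele))
  # reconstruct called allele sequences: commonest member sequence per
  # haplotype per cluster
  emitted <- sim$provenance[sim$provenance$origin == "allele", , drop = FALSE]
  cells <- list()
  for (r in seq_len(nrow(truth_loci))) {
    lid <- truth_loci$locus_id[r]
    cl <- cluster_of_locus[r]
    for (sm in sim$barcode_map$sample_id) {
      em <- emitted[emitted$locus_id == lid & emitted$sample_id == sm, ,
                    drop = FALSE]
      if (nrow(em) == 0L) {
        truth_z <- "MISSING"; truth_seqs <- character(0)
      } else {
        per_allele <- table(em$allele)
        if (min(per_allele) < min_allele_depth) next
        obs <- unique(observable_allele(
          allele_seqs[paste(lid, names(per_allele))], read_len, bc_len,
          adapter = sim$params$adapter))
        truth_seqs <- sort(unname(obs))
        truth_z <- if (length(truth_seqs) >= 2L) "HET" else "HOM"
      }
      if (is.na(cl)) {
        call_z <- "MISSING"; call_seqs <- character(0); status <- NA_character_
      } else {
        g <- genotypes$calls[genotypes$calls$locus_id == cl &
                               genotypes$calls$sample_id == sm, , drop = FALSE]
        status <- if (nrow(g)) g$status[1] else "MISSING"
        call_z <- switch(status,
                         HOM = "HOM", HET = "HET",
                         HET_PROVISIONAL_PASSED = "HET",
                         MISSING = "MISSING", status)
        call_seqs <- character(0)
        if (call_z %in% c("HOM", "HET") && nrow(g)) {
          msa <- alignments[alignments$cluster_id == cl, , drop = FALSE]
          cols <- genotypes$columns[genotypes$columns$locus_id == cl, ,
                                    drop = FALSE]
          hap_of_row <- if (nrow(cols) == 0L) rep("", nrow(msa)) else
            apply(msa_char_matrix(msa)[, cols$col, drop = FALSE], 1L,
                  paste, collapse = "")
          seq_of_hap <- function(h) {
            rows <- which(hap_of_row == h)
            if (!length(rows)) return(NA_character_)
            best <- rows[order(-msa$count[rows])][1]
            gsub("-", "", msa$row[best], fixed = TRUE)
          }
          call_seqs <- sort(unique(vapply(
            unique(c(g$allele1[1], g$allele2[1])), seq_of_hap, character(1))))
        }
      }
      agree <- (truth_z == call_z) &&
        (!(truth_z %in% c("HOM", "HET")) || identical(truth_seqs, call_seqs))
      cells[[length(cells) + 1L]] <- tibble::tibble(
        locus_id = lid, sample_id = sm, truth = truth_z, call = call_z,
        status = status, agree = agree
      )
    }
  }
  cells <- dplyr::bind_rows(cells)
  list(cells = cells, concordance = mean(cells$agree))
}
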