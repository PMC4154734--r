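#' Samples-by-loci genotype matrix
#'
#' @param genotypes A `ddrad_genotypes` object.
#' @param screened Optional output of [screen_duplicate_loci()]; excluded
#'   loci are dropped.
#' @return Wide tibble: one row per sample, one column per retained
#'   locus, cells `"allele1/allele2"` for called genotypes and the status
#'   string otherwise.
#' @export
genotype_matrix <- function(genotypes, screened = NULL) {
  calls <- genotypes$calls
  if (!is.null(screened)) {
    calls <- calls[calls$locus_id %in% screened$locus_id[screened$keep], ,
                   drop = FALSE]
  }
  calls |>
    dplyr::mutate(cell = dplyr::if_else(
      .data$status %in% c("HOM", "HET", "HET_PROVISIONAL_PASSED"),
      paste0(.data$allele1, "/", .data$allele2),
      .data$status
    )) |>
    dplyr::select("sample_id", "locus_id", "cell") |>
    tidyr::pivot_wider(names_from = "locus_id", values_from = "cell")
}

#' Write genotype calls as TSV
#'
#' Long format: sample, locus, status, alleles, depth, per-haplotype
#' depths encoded `hap:count` comma-separated.
#'
#' @param genotypes A `ddrad_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  calls <- genotypes$calls
  calls$allele_depths <- vapply(calls$allele_depths, function(d) {
    if (length(d) == 0L) return("")
    paste(paste0(ifelse(names(d) == "", ".", names(d)), ":", d), collapse = ",")
  }, character(1))
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype calls written by [write_genotypes_tsv()]
#'
#' @param path TSV path.
#' @return Tibble of calls with `allele_depths` decoded to a list-column.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  df$depth <- as.integer(df$depth)
  df$f1 <- as.numeric(df$f1); df$f2 <- as.numeric(df$f2)
  df$allele_depths <- lapply(df$allele_depths, function(x) {
    if (is.na(x) || !nzchar(x)) return(integer(0))
    parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(
      as.integer(vapply(parts, `[`, character(1), 2L)),
      vapply(parts, function(p) if (p[1] == ".") "" else p[1], character(1))
    )
  })
  tibble::as_tibble(df)
}

#' Per-sample SNP table
#'
#' One row per sample x locus x SNP column, with the two called bases.
#' Uncalled genotypes yield NA bases.
#'
#' @param genotypes A `ddrad_genotypes` object.
#' @return Tibble `locus_id`, `col`, `sample_id`, `base1`, `base2`.
#' @export
snp_table <- function(genotypes) {
  cols <- genotypes$columns
  snp_cols <- cols[cols$kind == "SNP", , drop = FALSE]
  if (nrow(snp_cols) == 0L) {
    return(tibble::tibble(locus_id = integer(), col = integer(),
                          sample_id = character(), base1 = character(),
                          base2 = character()))
  }
  # position of each variant column within the haplotype string
  cols_by_locus <- split(cols, cols$locus_id)
  out <- list()
  for (i in seq_len(nrow(snp_cols))) {
    lid <- snp_cols$locus_id[i]
    hap_pos <- match(snp_cols$col[i], cols_by_locus[[as.character(lid)]]$col)
    g <- genotypes$calls[genotypes$calls$locus_id == lid, , drop = FALSE]
    called <- g$status %in% c("HOM", "HET", "HET_PROVISIONAL_PASSED")
    out[[length(out) + 1L]] <- tibble::tibble(
      locus_id = lid, col = snp_cols$col[i], sample_id = g$sample_id,
      base1 = ifelse(called, substr(g$allele1, hap_pos, hap_pos), NA),
      base2 = ifelse(called, substr(g$allele2, hap_pos, hap_pos), NA)
    )
  }
  dplyr::bind_rows(out)
}

#' Per-sample binary indel table
#'
#' Counts indel-allele copies (0/1/2) per sample for each gap-coded
#' indel character.
#'
#' @param genotypes A `ddrad_genotypes` object.
#' @param alignments The alignment table the genotypes were called from.
#' @return Tibble `locus_id`, `indel_id`, `start_col`, `sample_id`,
#'   `copies`.
#' @export
indel_table <- function(genotypes, alignments) {
  out <- list()
  for (lid in unique(genotypes$calls$locus_id)) {
    msa <- alignments[alignments$cluster_id == lid, , drop = FALSE]
    events <- gap_code_indels(msa)
    if (nrow(events) == 0L) next
    cols <- genotypes$columns[genotypes$columns$locus_id == lid, , drop = FALSE]
    g <- genotypes$calls[genotypes$calls$locus_id == lid, , drop = FALSE]
    for (e in seq_len(nrow(events))) {
      # an allele carries the indel iff its haplotype has a gap at the
      # event's first column
      hap_pos <- match(events$start_col[e], cols$col)
      if (is.na(hap_pos)) next  # event column not variant (e.g. all rows gapped)
      called <- g$status %in% c("HOM", "HET", "HET_PROVISIONAL_PASSED")
      copies <- ifelse(called,
                       (substr(g$allele1, hap_pos, hap_pos) == "-") +
                         (substr(g$allele2, hap_pos, hap_pos) == "-"),
                       NA_integer_)
      out[[length(out) + 1L]] <- tibble::tibble(
        locus_id = lid, indel_id = events$indel_id[e],
        start_col = events$start_col[e], sample_id = g$sample_id,
        copies = copies
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(locus_id = integer(), indel_id = integer(),
                          start_col = integer(), sample_id = character(),
                          copies = integer()))
  }
  dplyr::bind_rows(out)
}

#' Write SNP genotypes as VCF 4.2
#'
#' SNP columns only; indels are emitted as symbolic `<DEL>` records.
#' Loci mapped to a reference use its contig and position; anonymous
#' loci use `locus<id>` as the contig with the alignment column as
#' position.
#'
#' @param genotypes A `ddrad_genotypes` object.
#' @param path Output path.
#' @param mapped Optional cluster table from [map_clusters()] providing
#'   contig/pos per locus.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, mapped = NULL) {
  samples <- sort(unique(genotypes$calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ddradkit",
    "##ALT=<ID=DEL,Description=\"Deletion (gap-coded indel)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- character(0)
  cols <- genotypes$columns
  for (lid in unique(cols$locus_id)) {
    lcols <- cols[cols$locus_id == lid, , drop = FALSE]
    g <- genotypes$calls[genotypes$calls$locus_id == lid, , drop = FALSE]
    g <- g[match(samples, g$sample_id), , drop = FALSE]
    chrom <- paste0("locus", lid); offset <- 0L
    if (!is.null(mapped)) {
      m <- mapped[mapped$cluster_id == lid, , drop = FALSE]
      if (nrow(m) == 1L && !m$anonymous[1]) {
        chrom <- m$contig[1]; offset <- m$pos[1]
      }
    }
    for (k in seq_len(nrow(lcols))) {
      hap_pos <- k
      states <- lcols$states[[k]]
      bases <- setdiff(states, "-")
      ref <- bases[1]
      alt <- c(setdiff(bases, ref), if ("-" %in% states) "<DEL>")
      if (length(alt) == 0L) next
      allele_code <- function(a) {
        ch <- substr(a, hap_pos, hap_pos)
        if (is.na(ch) || ch == "") return(".")
        if (ch == ref) return("0")
        idx <- match(if (ch == "-") "<DEL>" else ch, alt)
        if (is.na(idx)) "." else as.character(idx)
      }
      gt <- vapply(seq_len(nrow(g)), function(r) {
        if (!g$status[r] %in% c("HOM", "HET", "HET_PROVISIONAL_PASSED")) {
          return(paste0("./.:", g$depth[r]))
        }
        paste0(allele_code(g$allele1[r]), "/", allele_code(g$allele2[r]),
               ":", g$depth[r])
      }, character(1))
      rows <- c(rows, paste(c(
        chrom, offset + lcols$col[k], paste0("locus", lid, "_c", lcols$col[k]),
        ref, paste(alt, collapse = ","), ".", "PASS", ".", "GT:DP", gt
      ), collapse = "\t"))
    }
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
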