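#' Run the full ddRAD pipeline on raw reads
#'
#' Demultiplex, reconstruct and trim, screen concatemers, condense and
#' quality-filter; cluster across samples; optionally map to a reference
#' and merge clusters by position; align each cluster; call genotypes
#' and screen duplicate loci.
#'
#' @param reads Raw read tibble (see [read_fastq()]) or a FASTQ path.
#' @param barcode_map Tibble `barcode`, `sample_id`.
#' @param genome Optional reference ([as_genome()]); enables mapping,
#'   merging and classification.
#' @param adapter P2 adapter sequence.
#' @param identity Clustering identity threshold (default 0.85).
#' @param merge_tol Position-merge tolerance in bp (default 50).
#' @param thresholds See [genotype_thresholds()].
#' @param screen Run [screen_duplicate_loci()]?
#' @return List of class `ddrad_pipeline`: `processed` (processing
#'   output), `clustered`, `mapped` (NULL without a genome),
#'   `alignments`, `genotypes`, `screened`.
#' @export
run_ddrad_pipeline <- function(reads, barcode_map, genome = NULL,
                               adapter = default_p2_adapter(),
                               identity = 0.85, merge_tol = 50L,
                               thresholds = genotype_thresholds(),
                               screen = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  proc <- process_reads(reads, barcode_map, adapter)
  clustered <- cluster_across_samples(proc$condensed, identity)
  mapped <- NULL
  if (!is.null(genome)) {
    mapped <- map_clusters(clustered, genome_mapper(genome))
    merged <- merge_by_position(mapped, clustered, merge_tol)
    mapped <- merged$mapped
    clustered <- merged$clustered
  }
  alignments <- align_clusters(clustered)
  genotypes <- call_genotypes(alignments, samples = sort(unique(barcode_map$sample_id)),
                              thresholds = thresholds)
  screened <- if (screen) screen_duplicate_loci(genotypes) else NULL
  structure(
    list(processed = proc, clustered = clustered, mapped = mapped,
         alignments = alignments, genotypes = genotypes, screened = screened),
    class = "ddrad_pipeline"
  )
}

#' @export
print.ddrad_pipeline <- function(x, ...) {
  cat(sprintf("<ddrad_pipeline: %d clusters, %d samples>\n",
              dplyr::n_distinct(x$clustered$cluster_id),
              dplyr::n_distinct(x$clustered$sample_id)))
  invisible(x)
}
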