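# End-to-end convenience wrappers tying the modules together on one dataset.

# precompute reference-space mate ends once per pair table (hot path)
add_mate_ends <- function(aln) {
  aln$end1 <- aln$pos1 + cigar_ref_width(aln$cigar1) - 1L
  aln$end2 <- aln$pos2 + cigar_ref_width(aln$cigar2) - 1L
  aln
}

#' Per-variant allelic ratios after filtering
#'
#' For every heterozygous (variant, sample) combination inside the given
#' regions, tallies fragment-level allele-specific counts and the share of
#' reads assigned to the reference allele — the quality-control statistic
#' expected to centre on 0.5 when no true imbalance exists.
#'
#' @param aln_by_sample Named list of pair tables.
#' @param panel A [phased_panel()].
#' @param regions data.frame `chrom`, `start`, `end` (1-based inclusive).
#' @param base_qual_min Base-quality floor for allele calls.
#' @param genome Optional reference for indel context calling
#'   (see [count_alleles()]).
#' @return data.frame: `variant_id`, `sample`, `n_ref`, `n_alt`, `ratio`.
#' @export
allelic_ratio_table <- function(aln_by_sample, panel, regions,
                                base_qual_min = 10L, genome = NULL) {
  rows <- list()
  for (sm in names(aln_by_sample)) {
    for (r in seq_len(nrow(regions))) {
      ca <- count_alleles(aln_by_sample[[sm]], panel, sm, regions$chrom[r],
                          regions$start[r], regions$end[r], base_qual_min,
                          genome = genome)
      pv <- ca$per_variant
      pv <- pv[pv$n_ref + pv$n_alt > 0L, , drop = FALSE]
      if (nrow(pv))
        rows[[length(rows) + 1L]] <-
          data.frame(variant_id = pv$variant_id, sample = sm,
                     n_ref = pv$n_ref, n_alt = pv$n_alt,
                     ratio = pv$n_ref / (pv$n_ref + pv$n_alt),
                     stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), sample = character(),
               n_ref = integer(), n_alt = integer(), ratio = numeric())
  rownames(out) <- NULL
  out
}

#' Run the full allele-specific pipeline on a simulated dataset
#'
#' Simulates genome, panel and reads ([simulate_dataset()]), applies the
#' indel-aware bias filter with random de-duplication per sample, builds the
#' region count table and fits the combined haplotype test.
#'
#' @param cfg A [sim_config()].
#' @param radius Target-region radius (default `cfg$radius`).
#' @param min_read_count,min_as_count Count filters (see [region_counts()]).
#' @param dispersions Optional dispersions for [cht()].
#' @param permute Run the CHT with permuted genotypes.
#' @param work_dir Scratch directory.
#' @return List: `dataset`, `filtered` (pair tables after filtering),
#'   `filter_summaries`, `counts`, `scan` (a `cht_scan`), `ratios`
#'   (from [allelic_ratio_table()] over the target regions).
#' @export
run_pipeline <- function(cfg, radius = NULL, min_read_count = 400L,
                         min_as_count = 50L, dispersions = NULL,
                         permute = FALSE, work_dir = tempfile("aschip_run_")) {
  radius <- radius %||% cfg$radius
  ds <- simulate_dataset(cfg, work_dir = work_dir)
  filtered <- list(); summaries <- list()
  for (sm in names(ds$aln_by_sample)) {
    bf <- bias_filter(ds$aln_by_sample[[sm]], ds$sim$genome, ds$sim$panel,
                      aligner = ds$aligner, seed = child_seed(cfg$seed, sm))
    filtered[[sm]] <- add_mate_ends(bf$aln)
    summaries[[sm]] <- bf$summary
  }
  regions <- data.frame(chrom = ds$sim$peaks$chrom,
                        start = ds$sim$peaks$summit - radius,
                        end = ds$sim$peaks$summit + radius)
  ratios <- allelic_ratio_table(filtered, ds$sim$panel, regions,
                                genome = ds$sim$genome)
  counts <- region_counts(filtered, ds$sim$panel, ds$sim$peaks,
                          genome = ds$sim$genome, radius = radius,
                          min_read_count = min_read_count,
                          min_as_count = min_as_count)
  scan <- cht(counts, dispersions = dispersions, permute = permute,
              seed = cfg$seed)
  list(dataset = ds, filtered = filtered, filter_summaries = summaries,
       counts = counts, scan = scan, ratios = ratios)
}
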