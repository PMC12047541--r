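# Synthetic-data generator: a small diploid genome, a dense SNP+indel panel
# homozygous in the parents, F1 crosses sharing one maternal line, and
# paired-end reads drawn from the two haplotypes with configurable per-region
# allelic imbalance. All randomness flows from one seed via named child
# streams (panel / reads / dedup / permute).

#' Simulation configuration
#'
#' Defaults emulate the genetic structure of a dense F1-hybrid panel: one
#' variant per 230 bp with an 18% indel fraction (geometric indel lengths,
#' max 20 bp), eight F1 lines sharing a maternal line, 75 bp paired-end reads
#' from 300 bp fragments.
#'
#' @param seed Master seed; all streams derive from it.
#' @param n_peaks Number of binding regions (default 20).
#' @param radius Target-region radius around summits, bp (default 2500).
#' @param peak_spacing Distance between summits (default `2 * radius + 1000`).
#' @param n_f1_lines Number of F1 crosses (default 8).
#' @param variant_density Variants per bp (default 1/230).
#' @param indel_fraction Fraction of variants that are indels (default 0.18).
#' @param indel_geom_p Geometric parameter for indel lengths (default 0.21,
#'   i.e. about 69% of indels at 5 bp or less); lengths capped at
#'   `indel_max_len`.
#' @param indel_max_len Maximum indel length (default 20).
#' @param maternal_alt_rate Probability the maternal line carries ALT
#'   (default 0.3); paternal lines carry ALT with probability 0.5.
#' @param fragment_length,read_length Library geometry (defaults 300 / 75).
#' @param depth Fragments per region, pooled across samples (default 1000).
#' @param spread Half-width of fragment placement around the summit
#'   (default 900).
#' @param error_rate Per-base sequencing error rate (default 0).
#' @param imbalance List: `mode` one of `"null"`, `"fixed"`, `"motif"`; `p`
#'   the true ALT-haplotype read probability for `"fixed"` (scalar or
#'   per-region); `pwm` and `lambda` for `"motif"` (occupancy, and hence p,
#'   derived from toy-predictor energies of the two haplotypes).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_peaks = 20L, radius = 2500L,
                       peak_spacing = 2L * radius + 1000L, n_f1_lines = 8L,
                       variant_density = 1 / 230, indel_fraction = 0.18,
                       indel_geom_p = 0.21, indel_max_len = 20L,
                       maternal_alt_rate = 0.3,
                       fragment_length = 300L, read_length = 75L,
                       depth = 1000L, spread = 900L, error_rate = 0,
                       imbalance = list(mode = "null", p = 0.5,
                                        pwm = NULL, lambda = 0.7)) {
  stopifnot(variant_density > 0, variant_density < 0.04,
            indel_fraction >= 0, indel_fraction <= 1,
            fragment_length > 2L * read_length - 50L,
            spread + fragment_length < radius,
            imbalance$mode %in% c("null", "fixed", "motif"))
  if (imbalance$mode == "motif" && is.null(imbalance$pwm))
    stopf("imbalance mode 'motif' needs a pwm")
  structure(list(seed = as.integer(seed), n_peaks = as.integer(n_peaks),
                 radius = as.integer(radius),
                 peak_spacing = as.integer(peak_spacing),
                 n_f1_lines = as.integer(n_f1_lines),
                 variant_density = variant_density,
                 indel_fraction = indel_fraction,
                 indel_geom_p = indel_geom_p,
                 indel_max_len = as.integer(indel_max_len),
                 maternal_alt_rate = maternal_alt_rate,
                 fragment_length = as.integer(fragment_length),
                 read_length = as.integer(read_length),
                 depth = as.integer(depth), spread = as.integer(spread),
                 error_rate = error_rate, imbalance = imbalance),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "simulation config: %d peaks, %d F1 lines, density 1/%d bp (%.0f%% indels), depth %d, imbalance '%s'\n",
    x$n_peaks, x$n_f1_lines, round(1 / x$variant_density),
    100 * x$indel_fraction, x$depth, x$imbalance$mode))
  invisible(x)
}

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate genome, variant panel and phased F1 crosses
#'
#' Generates a uniform-random genome with `n_peaks` evenly spaced summits
#' (planting the motif consensus at each summit in `"motif"` mode), places a
#' non-overlapping SNP+indel panel at the configured density, assigns
#' homozygous parental alleles (one shared maternal line, one paternal line
#' per cross) and phases the F1s. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `aschip_sim`: `genome` (named vector), `contigs`,
#'   `peaks` (chrom/summit/region bounds), `panel` (a [phased_panel()]),
#'   `truth` (per-region `true_p`, `causal_id`, motif interval).
#' @export
simulate_panel <- function(cfg) {
  with_seed(child_seed(cfg$seed, "panel"), {
    chrom <- "chrS"
    L <- cfg$n_peaks * cfg$peak_spacing + cfg$peak_spacing
    gseq <- rand_dna(L)
    summits <- as.integer(cfg$peak_spacing * (seq_len(cfg$n_peaks) - 0.5) +
                            cfg$peak_spacing / 2)
    motif_iv <- NULL
    mode <- cfg$imbalance$mode
    if (mode == "motif") {
      pw <- cfg$imbalance$pwm
      cons <- pwm_consensus(pw)
      ms <- summits - (pw$width %/% 2L)
      for (s in ms) substr(gseq, s, s + pw$width - 1L) <- cons
      motif_iv <- data.frame(start = ms, end = ms + pw$width - 1L)
    }

    # non-overlapping variant placement at the target density
    gap <- cfg$indel_max_len + 5L
    n_target <- stats::rpois(1L, L * cfg$variant_density)
    cand <- sort(sample.int(L - gap, min(n_target * 2L, L %/% gap), replace = FALSE))
    keep <- logical(length(cand)); last_end <- -gap
    for (i in seq_along(cand)) {
      if (cand[i] - last_end > gap) { keep[i] <- TRUE; last_end <- cand[i] }
    }
    pos <- cand[keep]
    if (length(pos) > n_target) pos <- sort(sample(pos, n_target))
    # keep planted motifs (and their causal variant slot) clean
    if (!is.null(motif_iv)) {
      inmot <- vapply(pos, function(p)
        any(p >= motif_iv$start - gap & p <= motif_iv$end + 2L), logical(1))
      pos <- pos[!inmot]
    }
    n <- length(pos)
    is_indel <- stats::runif(n) < cfg$indel_fraction
    is_ins <- is_indel & stats::runif(n) < 0.5
    ilen <- pmin(1L + stats::rgeom(n, cfg$indel_geom_p), cfg$indel_max_len)
    ref <- substring(gseq, pos, pos)
    alt <- vapply(seq_len(n), function(i) {
      if (!is_indel[i]) sample(setdiff(BASES, ref[i]), 1L)
      else if (is_ins[i]) paste0(ref[i], rand_dna(ilen[i]))
      else ref[i]
    }, character(1))
    ref <- ifelse(is_indel & !is_ins,
                  substring(gseq, pos, pos + ilen), ref)
    v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)

    causal_id <- rep(NA_character_, cfg$n_peaks)
    if (mode == "motif") {
      pw <- cfg$imbalance$pwm
      ic <- pwm_ic(pw$prob)
      off <- which.max(ic)                     # most informative motif position
      worst <- BASES[which.min(pw$prob[, off])]
      cp <- motif_iv$start + off - 1L
      cv <- data.frame(chrom = chrom, pos = cp,
                       ref = substring(gseq, cp, cp), alt = worst,
                       stringsAsFactors = FALSE)
      causal_id <- variant_id(cv$chrom, cv$pos, cv$ref, cv$alt)
      v <- rbind(v, cv)
      v <- v[order(v$pos), , drop = FALSE]
    }
    v <- validate_variants(v)

    lines <- sprintf("F1_%02d", seq_len(cfg$n_f1_lines))
    nv <- nrow(v)
    m_allele <- stats::rbinom(nv, 1L, cfg$maternal_alt_rate)
    p_allele <- matrix(stats::rbinom(nv * cfg$n_f1_lines, 1L, 0.5), nv,
                       dimnames = list(NULL, lines))
    if (mode == "motif") {                     # causal site het in every line
      ci <- match(causal_id, v$id)
      m_allele[ci] <- 0L
      p_allele[ci, ] <- 1L
    }
    panel <- phased_panel(v, lines,
                          matrix(rep(m_allele, cfg$n_f1_lines), nv),
                          p_allele)

    genome <- load_genome(stats::setNames(gseq, chrom))
    true_p <- rep(0.5, cfg$n_peaks)
    if (mode == "fixed") {
      true_p <- rep(cfg$imbalance$p, length.out = cfg$n_peaks)
      # designate the variant nearest each summit as the causal anchor
      for (r in seq_len(cfg$n_peaks))
        causal_id[r] <- v$id[which.min(abs(v$pos - summits[r]))]
    } else if (mode == "motif") {
      pred <- pwm_energy_predictor(cfg$imbalance$pwm,
                                   lambda = cfg$imbalance$lambda %||% 0.7)
      for (r in seq_len(cfg$n_peaks)) {
        ci <- match(causal_id[r], v$id)
        occ_ref <- pred$predict(allele_window(genome, v[ci, ], 0L, pred$window))
        occ_alt <- pred$predict(allele_window(genome, v[ci, ], 1L, pred$window))
        true_p[r] <- occ_alt / (occ_ref + occ_alt)
      }
    } else {
      for (r in seq_len(cfg$n_peaks))
        causal_id[r] <- v$id[which.min(abs(v$pos - summits[r]))]
    }

    structure(list(cfg = cfg, genome = genome,
                   contigs = stats::setNames(L, chrom),
                   peaks = data.frame(chrom = chrom, summit = summits,
                                      start = summits - cfg$radius,
                                      end = summits + cfg$radius,
                                      stringsAsFactors = FALSE),
                   truth = list(true_p = true_p, causal_id = causal_id,
                                motif = motif_iv),
                   panel = panel),
              class = "aschip_sim")
  })
}

#' @export
print.aschip_sim <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d bp genome, %d peaks, ", x$contigs[[1]],
              nrow(x$peaks)))
  print(x$panel)
  invisible(x)
}

# fill NA gaps in a ref->hap coordinate map with the next mapped position
fill_next <- function(m) {
  ok <- which(!is.na(m))
  if (!length(ok)) return(m)
  stats::approx(ok, m[ok], xout = seq_along(m), method = "constant",
                f = 1, rule = 2)$y
}

#' Simulate paired-end reads from the two haplotypes
#'
#' For each region and sample, the number of fragments follows the sample's
#' genotype-weighted share of the pooled region depth, each fragment's
#' haplotype of origin is drawn according to the causal allele it carries
#' (probability `true_p` for the ALT-carrying haplotype; 0.5 everywhere under
#' the null), and mate sequences are cut from the chosen haplotype
#' (indel-aware). Every read's haplotype of origin is recorded.
#'
#' @param sim An `aschip_sim` from [simulate_panel()].
#' @return List: `reads` (data.frame `qname`, `sample`, `region`, `hap`,
#'   `seq1`, `seq2` in sequencing orientation), `truth` alias of the same.
#' @export
simulate_reads <- function(sim) {
  cfg <- sim$cfg
  with_seed(child_seed(cfg$seed, "reads"), {
    g <- sim$genome
    chrom <- names(g)[1L]
    v <- sim$panel$variants
    out <- list()
    for (r in seq_len(nrow(sim$peaks))) {
      summit <- sim$peaks$summit[r]
      p_alt <- sim$truth$true_p[r]
      ci <- match(sim$truth$causal_id[r], v$id)
      ws <- max(1L, summit - cfg$spread - 80L)
      we <- min(sim$contigs[[1L]], summit + cfg$spread + cfg$fragment_length + 80L)
      vin <- which(v$pos >= ws & (v$pos + nchar(v$ref) - 1L) <= we)
      vtab <- v[vin, c("pos", "ref", "alt"), drop = FALSE]

      # genotype-weighted depth allocation across samples
      gdose <- if (!is.na(ci)) dosage_matrix(sim$panel)[ci, ] else
        rep(1L, length(sim$panel$samples))
      wts <- (2 - gdose) * (1 - p_alt) + gdose * p_alt
      if (is.na(ci)) wts <- rep(1, length(sim$panel$samples))
      nfr <- stats::rmultinom(1L, cfg$depth, wts / sum(wts))[, 1L]

      for (sj in seq_along(sim$panel$samples)) {
        n_i <- nfr[sj]
        if (n_i == 0L) next
        sm <- sim$panel$samples[sj]
        haps <- lapply(c(M = "gt_m", P = "gt_p"), function(slot) {
          hs <- haplotype_sequence(g, chrom, ws, we, vtab,
                                   sim$panel[[slot]][vin, sj])
          hs$map <- fill_next(hs$ref_to_hap)
          hs
        })
        # haplotype weights from the causal allele each haplotype carries
        wm <- wp <- 0.5
        if (!is.na(ci)) {
          am <- sim$panel$gt_m[ci, sj]; ap <- sim$panel$gt_p[ci, sj]
          wm <- if (am == 1L) p_alt else 1 - p_alt
          wp <- if (ap == 1L) p_alt else 1 - p_alt
        }
        hap <- ifelse(stats::runif(n_i) < wm / (wm + wp), "M", "P")
        fs <- summit - cfg$spread +
          sample.int(2L * cfg$spread - cfg$fragment_length, n_i, replace = TRUE)
        seq1 <- seq2 <- character(n_i)
        for (k in seq_len(n_i)) {
          hh <- haps[[hap[k]]]
          hstart <- hh$map[fs[k] - ws + 1L]
          frag <- substr(hh$seq, hstart, hstart + cfg$fragment_length - 1L)
          if (nchar(frag) < cfg$fragment_length) {   # clipped at window edge
            hstart <- max(1L, nchar(hh$seq) - cfg$fragment_length + 1L)
            frag <- substr(hh$seq, hstart, hstart + cfg$fragment_length - 1L)
          }
          seq1[k] <- substr(frag, 1L, cfg$read_length)
          seq2[k] <- revcomp(substr(frag, nchar(frag) - cfg$read_length + 1L,
                                    nchar(frag)))
        }
        if (cfg$error_rate > 0) {
          seq1 <- add_seq_errors(seq1, cfg$error_rate)
          seq2 <- add_seq_errors(seq2, cfg$error_rate)
        }
        out[[length(out) + 1L]] <- data.frame(
          qname = sprintf("%s.r%02d.%05d", sm, r, seq_len(n_i)),
          sample = sm, region = r, hap = hap, seq1 = seq1, seq2 = seq2,
          stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    list(reads = reads, truth = reads[, c("qname", "sample", "region", "hap")])
  })
}

add_seq_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(BASES, b[i]), 1L)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a complete aligned dataset
#'
#' Runs [simulate_panel()] and [simulate_reads()], writes the genome FASTA,
#' and maps the simulated reads with the given aligner (default
#' [bwa_aligner()]), yielding per-sample pair tables ready for the bias
#' filter.
#'
#' @param cfg A [sim_config()].
#' @param aligner Optional `aschip_aligner`; default bwa on the simulated
#'   genome.
#' @param work_dir Scratch directory.
#' @return List: `sim`, `reads`, `aln_by_sample` (named list of pair tables),
#'   `aligner`, `fasta`.
#' @export
simulate_dataset <- function(cfg, aligner = NULL,
                             work_dir = tempfile("aschip_sim_")) {
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(cfg)
  rd <- simulate_reads(sim)
  fasta <- file.path(work_dir, "genome.fa")
  write_fasta(sim$genome, fasta)
  if (is.null(aligner)) aligner <- bwa_aligner(fasta, file.path(work_dir, "bwa"))
  aln_by_sample <- lapply(split(rd$reads, rd$reads$sample), function(d) {
    a <- aligner$align_pairs(d[, c("qname", "seq1", "seq2")])
    # store sequences in SAM orientation (reference strand)
    a$seq1 <- ifelse(!is.na(a$strand1) & a$strand1 == "-", revcomp(d$seq1), d$seq1)
    a$seq2 <- ifelse(!is.na(a$strand2) & a$strand2 == "-", revcomp(d$seq2), d$seq2)
    a$qual1 <- strrep("I", nchar(a$seq1))
    a$qual2 <- strrep("I", nchar(a$seq2))
    a$sample <- d$sample[1L]
    a[a$mapped1 & a$mapped2, , drop = FALSE]
  })
  list(sim = sim, reads = rd, aln_by_sample = aln_by_sample,
       aligner = aligner, fasta = fasta)
}

rbetabinom <- function(n, size, p, rho) {
  if (rho == 0) return(stats::rbinom(n, size, p))
  a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate a CHT count table directly (no reads)
#'
#' Counts-level generator used for calibration, dispersion-recovery and power
#' analysis of the combined haplotype test: genotypes from a Hardy-Weinberg
#' draw, depths from the (beta-)negative-binomial depth model, and
#' allele-specific counts from the beta-binomial with the configured true
#' effect.
#'
#' @param n_regions Number of regions (one test variant each).
#' @param n_samples Samples per region.
#' @param depth Expected total count per sample (`E`).
#' @param as_depth Expected allele-specific reads per het sample.
#' @param p_true True ALT-haplotype probability (scalar or per-region).
#' @param rho_as,phi_bnb Generating dispersions.
#' @param allele_freq ALT allele frequency for genotypes (default 0.5).
#' @param seed Seed.
#' @return Count table as accepted by [cht()], with the generating `p` in
#'   `attr(, "true_p")`.
#' @export
simulate_region_counts <- function(n_regions = 100L, n_samples = 8L,
                                   depth = 500, as_depth = 100,
                                   p_true = 0.5, rho_as = 0.01, phi_bnb = 20,
                                   allele_freq = 0.5, seed = 1L) {
  p_true <- rep(p_true, length.out = n_regions)
  with_seed(child_seed(seed, "counts"), {
    rows <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      g <- stats::rbinom(n_samples, 2L, allele_freq)
      if (!any(g == 1L)) g[sample.int(n_samples, 1L)] <- 1L
      p <- p_true[r]
      T_ <- rbnb(n_samples, mu_depth(rep(depth, n_samples), g, p), phi_bnb)
      n_as <- ifelse(g == 1L, stats::rpois(n_samples, as_depth), 0L)
      k <- integer(n_samples)
      k[g == 1L] <- rbetabinom(sum(g == 1L), n_as[g == 1L], p, rho_as)
      rows[[r]] <- data.frame(
        region_id = sprintf("region%04d", r),
        variant_id = sprintf("sim:%d:A:T", r),
        sample = sprintf("S%02d", seq_len(n_samples)),
        g = g, T = T_, E = depth,
        as_ref = n_as - k, as_alt = k, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "true_p") <- p_true
    out
  })
}

#' Evaluate pipeline output against simulation ground truth
#'
#' @param sim An `aschip_sim`.
#' @param scan Optional `cht_scan` from the pipeline run on the simulation.
#' @param ranks Optional ranked pAI table ([rank_variants()]).
#' @param radius Region radius used when building counts (default from cfg).
#' @param fdr_threshold,min_ai Significance gates.
#' @param json_path Optional path: write the metrics as JSON.
#' @return Named list of metrics (`type1_rate`, `power`, `ai_rmse`,
#'   `rank1_recovery`, each `NA` when not measurable).
#' @export
truth_eval <- function(sim, scan = NULL, ranks = NULL, radius = NULL,
                       fdr_threshold = 0.01, min_ai = 0.1, json_path = NULL) {
  cfg <- sim$cfg
  radius <- radius %||% cfg$radius
  region_ids <- sprintf("%s:%d-%d", sim$peaks$chrom,
                        sim$peaks$summit - radius, sim$peaks$summit + radius)
  null_r <- sim$truth$true_p == 0.5
  metrics <- list(type1_rate = NA_real_, power = NA_real_,
                  ai_rmse = NA_real_, rank1_recovery = NA_real_)
  if (!is.null(scan)) {
    res <- if (inherits(scan, "cht_scan")) scan$results else scan
    res$truth_region <- match(res$region_id, region_ids)
    if (anyNA(res$truth_region)) stopf("result region ids do not match the simulation")
    sig <- !is.na(res$fdr) & res$fdr < fdr_threshold & res$AI > min_ai
    isnull <- null_r[res$truth_region]
    if (any(isnull)) metrics$type1_rate <- mean(sig[isnull])
    if (any(!null_r)) {
      det <- vapply(which(!null_r), function(r)
        any(sig[res$truth_region == r]), logical(1))
      metrics$power <- mean(det)
    }
    ci <- match(sim$truth$causal_id, res$variant_id)
    ok <- !is.na(ci)
    if (any(ok & !null_r)) {
      est <- res$AI[ci[ok & !null_r]]
      tru <- abs(0.5 - sim$truth$true_p[ok & !null_r])
      metrics$ai_rmse <- sqrt(mean((est - tru)^2))
    }
  }
  if (!is.null(ranks)) {
    top <- ranks[ranks$rank == 1L, , drop = FALSE]
    tr <- match(top$region_id, region_ids)
    ok <- !is.na(tr) & !is.na(sim$truth$causal_id[tr])
    if (any(ok))
      metrics$rank1_recovery <-
        mean(top$variant_id[ok] == sim$truth$causal_id[tr][ok])
  }
  if (!is.null(json_path))
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA)
  metrics
}
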