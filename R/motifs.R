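#' Scan a PWM over variant-centered windows on both alleles
#'
#' For each variant, builds a `window`-bp sequence centered on the variant for
#' the reference allele and for the alternative allele (the alternative window
#' is rebuilt through the haplotype machinery and re-centered on the variant,
#' so indels shift the flanks, not the center), scores every offset on both
#' strands, and records the best hit per allele.
#'
#' @param x A [pwm()].
#' @param genome See [load_genome()].
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (and `id`;
#'   created if absent).
#' @param window Window size in bp (default 30); must be >= motif width.
#' @return data.frame, one row per variant: best score/strand/offset per
#'   allele, called flags, `score_change` (ref - alt), the variant's position
#'   inside the best ref-allele motif (`NA` if outside), and a `truncated`
#'   flag for windows clipped at contig ends.
#' @export
scan_variants <- function(x, genome, variants, window = 30L) {
  g <- load_genome(genome)
  if (window < x$width) stopf("window (%d) smaller than motif width (%d)",
                              window, x$width)
  variants <- validate_variants(variants)
  half <- window %/% 2L
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    L <- nchar(g[[v$chrom]])
    ws <- v$pos - half + 1L
    we <- ws + window - 1L
    trunc <- ws < 1L || we > L
    ws_c <- max(1L, ws)
    # pad the build window so indel shifts cannot starve the centered extract
    pad <- nchar(v$ref) + nchar(v$alt) + window
    bs <- max(1L, ws - pad); be <- min(L, we + pad)
    ref_seq <- substr(g[[v$chrom]], ws_c, min(L, we))

    hap <- haplotype_sequence(g, v$chrom, bs, be,
                              variants = v[, c("pos", "ref", "alt")],
                              alleles = 1L)
    vc <- hap$ref_to_hap[v$pos - bs + 1L]   # variant anchor in hap coords
    as_ <- vc - (v$pos - ws)                # keep same left offset as ref window
    ae_ <- as_ + window - 1L
    alt_seq <- substr(hap$seq, max(1L, as_), min(nchar(hap$seq), ae_))

    best <- function(seq) {
      sc <- pwm_score_all(x, seq)
      sc <- sc[!is.na(sc$score), , drop = FALSE]
      if (!nrow(sc)) return(list(score = NA_real_, strand = NA_character_,
                                 offset = NA_integer_))
      j <- order(-sc$score, sc$offset)[1L]
      list(score = sc$score[j], strand = sc$strand[j], offset = sc$offset[j])
    }
    br <- best(ref_seq); ba <- best(alt_seq)
    var_idx <- v$pos - ws_c + 1L            # variant position inside ref window
    pim <- if (!is.na(br$offset) &&
               var_idx >= br$offset && var_idx <= br$offset + x$width - 1L) {
      p <- var_idx - br$offset + 1L
      if (identical(br$strand, "-")) x$width - p + 1L else p
    } else NA_integer_
    out[[i]] <- data.frame(
      variant_id = v$id, chrom = v$chrom, pos = v$pos, motif = x$name,
      score_ref = br$score, strand_ref = br$strand,
      motif_start_ref = if (is.na(br$offset)) NA_integer_ else ws_c + br$offset - 1L,
      called_ref = !is.na(br$score) && br$score >= x$threshold,
      score_alt = ba$score, strand_alt = ba$strand,
      called_alt = !is.na(ba$score) && ba$score >= x$threshold,
      score_change = br$score - ba$score,
      position_in_motif = pim, truncated = trunc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Concordance between motif score change and allelic-imbalance direction
#'
#' Restricted to variants where the motif is called on both alleles; a variant
#' is concordant when the sign of the motif score change (reference minus
#' alternative) agrees with the direction of the fitted reference-allele bias.
#' Variants with `|score_change| <` `min_abs_score_change` are excluded.
#'
#' @param scan Output of [scan_variants()].
#' @param results CHT result table (needs `variant_id`, `ref_bias`).
#' @param min_abs_score_change Exclusion threshold on `|score_change|`
#'   (default 1).
#' @return List: `fraction` concordant (NA if no usable variants), `n`, and
#'   the per-variant table.
#' @export
disruption_concordance <- function(scan, results, min_abs_score_change = 1) {
  m <- merge(scan, results[, c("variant_id", "ref_bias")], by = "variant_id")
  m <- m[m$called_ref & m$called_alt &
           abs(m$score_change) >= min_abs_score_change &
           m$ref_bias != 0.5, , drop = FALSE]
  if (!nrow(m)) return(list(fraction = NA_real_, n = 0L, table = m))
  m$concordant <- sign(m$score_change) == sign(m$ref_bias - 0.5)
  list(fraction = mean(m$concordant), n = nrow(m), table = m)
}

#' Preferred-allele table for allelic-imbalance motif reconstruction
#'
#' For each significant SNP inside a motif, the preferred allele is the one
#' carried by the haplotype with higher fitted occupancy (REF if
#' `ref_bias > 0.5`, else ALT). Base and motif position are normalised to the
#' PWM strand: hits on the minus strand are complemented and position-flipped.
#'
#' @param scan Output of [scan_variants()].
#' @param results CHT result table (`variant_id`, `ref_bias`); pre-filter to
#'   the significant set before calling.
#' @param variants Variant table (`id`, `ref`, `alt`, `kind`).
#' @param width Motif width.
#' @return data.frame with `variant_id`, `position` (motif coordinate),
#'   `base` (preferred allele base on the PWM strand).
#' @export
preferred_alleles <- function(scan, results, variants, width) {
  m <- merge(scan, results[, c("variant_id", "ref_bias")], by = "variant_id")
  m <- merge(m, variants[, c("id", "ref", "alt", "kind")],
             by.x = "variant_id", by.y = "id")
  m <- m[!is.na(m$position_in_motif) & m$kind == "snp" &
           m$ref_bias != 0.5, , drop = FALSE]
  if (!nrow(m)) return(data.frame(variant_id = character(), position = integer(),
                                  base = character()))
  base <- ifelse(m$ref_bias > 0.5, m$ref, m$alt)
  minus <- !is.na(m$strand_ref) & m$strand_ref == "-"
  base[minus] <- chartr("ACGT", "TGCA", base[minus])
  data.frame(variant_id = m$variant_id,
             position = m$position_in_motif,
             base = base, stringsAsFactors = FALSE)
}

#' Build an allelic-imbalance-based count and information-content matrix
#'
#' The count matrix tallies, per motif position, the preferred bases of
#' significant motif-overlapping variants ([preferred_alleles()]). It is then
#' turned into an information content matrix: with a pseudocount of 0.25 per
#' base, per-position frequencies `f_b` give `IC = 2 + sum_b f_b log2 f_b`
#' bits, and letter heights `f_b * IC`. Positions without any variant stay as
#' zero count columns (IC ~ 0 after pseudocounts).
#'
#' @param pref Output of [preferred_alleles()].
#' @param width Motif width.
#' @param pseudocount Per-base pseudocount (default 0.25).
#' @return List: `counts` (4 x width), `freq`, `ic` (per position, bits),
#'   `icm` (letter heights `freq * ic`).
#' @export
build_ai_pwm <- function(pref, width, pseudocount = 0.25) {
  counts <- matrix(0, nrow = 4L, ncol = width, dimnames = list(BASES, NULL))
  if (nrow(pref)) {
    tab <- table(factor(pref$base, levels = BASES),
                 factor(pref$position, levels = seq_len(width)))
    counts <- counts + as.matrix(tab)
  }
  freq <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  ic <- pwm_ic(freq)
  icm <- sweep(freq, 2, ic, "*")
  list(counts = counts, freq = freq, ic = ic, icm = icm)
}

#' Annotate motif hits with distance to peak summit and inside/outside flag
#'
#' @param scan Output of [scan_variants()] (uses the reference-allele hit).
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `summit` (absolute position).
#' @param width Motif width.
#' @return `scan` with `summit_distance` (|motif midpoint - nearest summit|)
#'   and `in_peak` (motif interval contained in the peak).
#' @export
motif_distance_annotation <- function(scan, peaks, width) {
  scan$summit_distance <- NA_real_
  scan$in_peak <- FALSE
  for (i in seq_len(nrow(scan))) {
    if (is.na(scan$motif_start_ref[i])) next
    pk <- peaks[peaks$chrom == scan$chrom[i], , drop = FALSE]
    if (!nrow(pk)) next
    ms <- scan$motif_start_ref[i]                 # 1-based
    me <- ms + width - 1L
    mid <- (ms + me) / 2
    d <- abs(mid - pk$summit)
    j <- which.min(d)
    scan$summit_distance[i] <- d[j]
    # containment against 0-based half-open peak interval
    scan$in_peak[i] <- (ms - 1L) >= pk$start[j] && me <= pk$end[j]
  }
  scan
}
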