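# Consensus peaks, target regions, and per-sample total / allele-specific
# count tables — the CHT's input.

#' Per-base pooled fragment coverage
#'
#' @param aln Pair table (possibly concatenated across samples).
#' @param contigs Named integer vector of contig lengths.
#' @return Named list of integer vectors (per-base counts, index = position).
#' @export
coverage_from_alignments <- function(aln, contigs) {
  sp <- fragment_spans(aln)
  out <- lapply(names(contigs), function(ch) {
    s <- sp[sp$chrom == ch, , drop = FALSE]
    cov <- integer(contigs[[ch]])
    if (nrow(s)) {
      ir <- IRanges::IRanges(pmax(1L, s$start), pmin(contigs[[ch]], s$end))
      cov <- as.integer(IRanges::coverage(ir, width = contigs[[ch]]))
    }
    cov
  })
  names(out) <- names(contigs)
  out
}

fragment_spans <- function(aln) {
  e1 <- if ("end1" %in% names(aln)) aln$end1 else
    aln$pos1 + cigar_ref_width(aln$cigar1) - 1L
  e2 <- if ("end2" %in% names(aln)) aln$end2 else
    aln$pos2 + cigar_ref_width(aln$cigar2) - 1L
  data.frame(chrom = aln$chrom1,
             start = pmin(aln$pos1, aln$pos2, na.rm = TRUE),
             end = pmax(e1, e2, na.rm = TRUE))
}

#' Build consensus peaks from per-line peak sets
#'
#' Overlapping (>= 1 bp, transitively merged) peak intervals across lines are
#' merged; a merged interval is retained when supported by at least
#' `min_lines` distinct lines; its summit is recomputed as the position of
#' maximum pooled coverage inside the interval (leftmost on ties).
#'
#' @param per_line_peaks Named list of data.frames (`chrom`, `start`, `end`;
#'   0-based half-open), one per line.
#' @param pooled_coverage Output of [coverage_from_alignments()] over all
#'   samples.
#' @param min_lines Minimum supporting lines (default 3).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open), `summit`
#'   (1-based position), `n_lines`.
#' @export
consensus_peaks <- function(per_line_peaks, pooled_coverage, min_lines = 3L) {
  if (!length(per_line_peaks) || !any(vapply(per_line_peaks, nrow, 1L) > 0)) {
    warnf("no input peaks; returning empty consensus set")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), n_lines = integer()))
  }
  if (length(per_line_peaks) < min_lines)
    warnf("fewer peak sets (%d) than min_lines (%d); nothing can pass",
          length(per_line_peaks), min_lines)
  if (is.null(names(per_line_peaks)))
    names(per_line_peaks) <- paste0("line", seq_along(per_line_peaks))
  all_gr <- do.call(c, lapply(names(per_line_peaks), function(ln) {
    p <- per_line_peaks[[ln]]
    gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
    S4Vectors::mcols(gr)$line <- rep(ln, length(gr))
    gr
  }))
  merged <- GenomicRanges::reduce(all_gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(merged, all_gr)
  support <- tapply(S4Vectors::mcols(all_gr)$line[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) length(unique(x)))
  n_lines <- integer(length(merged))
  n_lines[as.integer(names(support))] <- as.integer(support)
  keep <- n_lines >= min_lines
  merged <- merged[keep]
  n_lines <- n_lines[keep]
  summit <- integer(length(merged))
  for (i in seq_along(merged)) {
    ch <- as.character(GenomicRanges::seqnames(merged)[i])
    s <- GenomicRanges::start(merged)[i]; e <- GenomicRanges::end(merged)[i]
    cov <- pooled_coverage[[ch]][s:e]
    summit[i] <- s + which.max(cov) - 1L      # leftmost maximum
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1L,
             end = GenomicRanges::end(merged),
             summit = summit, n_lines = n_lines, stringsAsFactors = FALSE)
}

#' Read narrowPeak/BED peak calls
#' @param path BED or narrowPeak file.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), and
#'   `summit` (absolute 1-based) when a narrowPeak summit offset is present.
#' @export
read_peaks <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = d[[1]], start = as.integer(d[[2]]),
                    end = as.integer(d[[3]]), stringsAsFactors = FALSE)
  if (ncol(d) >= 10L && all(d[[10]] >= 0)) out$summit <- out$start + d[[10]] + 1L
  out
}

phred <- function(qual_chr) as.integer(charToRaw(qual_chr)) - 33L

# parse a CIGAR into per-op (op, len) data.frame
cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Observed allele of one mate at one variant.
# Returns list(allele = 0 (REF) / 1 (ALT) / NA (other or undetermined),
#              qual = Phred at the variant anchor base).
mate_allele_at <- function(seq, qual, pos, cigar, vpos, vref, valt) {
  ops <- cigar_ops(cigar)
  nr <- nchar(vref); na_ <- nchar(valt)
  kind <- variant_kind(vref, valt)
  ref_at <- pos; read_at <- 1L
  anchor_read <- NA_integer_   # read position aligned to vpos
  ins_seq <- ""                # bases inserted immediately after vpos
  del_len <- 0L                # deletion length starting at vpos+1
  ref_seg <- ""                # read bases aligned across [vpos, vpos+nr-1]
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      # aligned block [ref_at, ref_at+len-1]
      if (vpos >= ref_at && vpos <= ref_at + len - 1L)
        anchor_read <- read_at + (vpos - ref_at)
      ov_s <- max(ref_at, vpos); ov_e <- min(ref_at + len - 1L, vpos + nr - 1L)
      if (ov_s <= ov_e)
        ref_seg <- paste0(ref_seg, substr(seq, read_at + (ov_s - ref_at),
                                          read_at + (ov_e - ref_at)))
      ref_at <- ref_at + len; read_at <- read_at + len
    } else if (op == "I") {
      if (ref_at == vpos + 1L)
        ins_seq <- substr(seq, read_at, read_at + len - 1L)
      read_at <- read_at + len
    } else if (op %in% c("D", "N")) {
      if (ref_at == vpos + 1L) del_len <- len
      ref_at <- ref_at + len
    } else if (op == "S") {
      read_at <- read_at + len
    }
    # H and P consume nothing we track
  }
  if (is.na(anchor_read)) return(list(allele = NA_integer_, qual = NA_integer_))
  q <- phred(substr(qual, anchor_read, anchor_read))
  allele <- NA_integer_
  if (kind == "snp") {
    b <- substr(seq, anchor_read, anchor_read)
    allele <- if (b == vref) 0L else if (b == valt) 1L else NA_integer_
  } else if (kind == "deletion") {
    if (del_len == nr - na_ && nchar(ref_seg) >= 1L &&
        substr(ref_seg, 1L, 1L) == substr(valt, 1L, 1L)) allele <- 1L
    else if (del_len == 0L && nchar(ref_seg) == nr && ref_seg == vref) allele <- 0L
  } else {  # insertion
    if (nchar(ins_seq) == na_ - nr && ins_seq == substr(valt, nr + 1L, na_) &&
        !is.na(anchor_read)) allele <- 1L
    else if (nchar(ins_seq) == 0L && nchar(ref_seg) == nr && ref_seg == vref)
      allele <- 0L
  }
  list(allele = allele, qual = q)
}

# Indel alleles are called by exact presence of the local haplotype context
# (flank + allele + flank) in the read sequence: placement-invariant, so
# left-shifted or soft-clipped gapped alignments cannot bias the call toward
# the reference allele. Ambiguous reads (both or neither context) are "other".
call_indel_context <- function(seq, qual, flank, ctx_ref, ctx_alt) {
  pr <- regexpr(ctx_ref, seq, fixed = TRUE)[1L]
  pa <- regexpr(ctx_alt, seq, fixed = TRUE)[1L]
  if (pr > 0L && pa > 0L) return(list(allele = NA_integer_, qual = NA_integer_))
  if (pa > 0L) return(list(allele = 1L,
                           qual = phred(substr(qual, pa + flank, pa + flank))))
  if (pr > 0L) return(list(allele = 0L,
                           qual = phred(substr(qual, pr + flank, pr + flank))))
  list(allele = NA_integer_, qual = NA_integer_)
}

#' Haplotype-resolved allele-specific counts for one sample over one region
#'
#' Each fragment contributes at most one allele-specific observation: among
#' the heterozygous sites it covers with base quality at or above
#' `base_qual_min`, the site with the highest base quality (then leftmost) is
#' used, its observed allele is mapped through the phase to the maternal or
#' paternal haplotype, and reads whose allele matches neither REF nor ALT are
#' counted as "other" and excluded.
#'
#' @param aln Pair table for one sample (bias-filtered, de-duplicated).
#' @param panel A [phased_panel()].
#' @param sample Sample name (a column of the panel).
#' @param chrom,start,end Region (1-based inclusive).
#' @param base_qual_min Minimum base quality for an allele call (default 10).
#' @param genome Optional reference ([load_genome()]); enables
#'   placement-invariant context calling of indel alleles (recommended —
#'   without it indel calls fall back to CIGAR walking, which is sensitive to
#'   how the mapper placed the gap).
#' @return List: `fragments` (data.frame: row index of the fragment, chosen
#'   variant id, `hap` "M"/"P"), `per_variant` (data.frame: variant id,
#'   `n_ref`, `n_alt`, `n_other`), `n_fragments` (total fragments overlapping
#'   the region).
#' @export
count_alleles <- function(aln, panel, sample, chrom, start, end,
                          base_qual_min = 10L, genome = NULL) {
  sp <- fragment_spans(aln)
  in_reg <- which(sp$chrom == chrom & sp$start <= end & sp$end >= start)
  v <- panel$variants
  si <- match(sample, panel$samples)
  if (is.na(si)) stopf("unknown sample '%s'", sample)
  het <- which(het_matrix(panel)[, si] & v$chrom == chrom &
                 v$pos <= end & (v$pos + nchar(v$ref) - 1L) >= start)
  empty <- list(fragments = data.frame(frag = integer(), variant_id = character(),
                                       hap = character()),
                per_variant = data.frame(variant_id = character(),
                                         n_ref = integer(), n_alt = integer(),
                                         n_other = integer()),
                n_fragments = length(in_reg))
  if (!length(in_reg) || !length(het)) return(empty)

  mate_end <- cbind(
    if ("end1" %in% names(aln)) aln$end1 else
      aln$pos1 + cigar_ref_width(aln$cigar1) - 1L,
    if ("end2" %in% names(aln)) aln$end2 else
      aln$pos2 + cigar_ref_width(aln$cigar2) - 1L)
  vpos_all <- v$pos; vend_all <- v$pos + nchar(v$ref) - 1L
  X <- as.list(aln)
  if (is.null(X$qual1)) X$qual1 <- strrep("I", nchar(X$seq1))
  if (is.null(X$qual2)) X$qual2 <- strrep("I", nchar(X$seq2))
  g <- if (!is.null(genome)) load_genome(genome) else NULL
  ctx <- vector("list", length(het))          # indel context strings
  if (!is.null(g)) {
    for (j in seq_along(het)) {
      hv <- het[j]
      if (v$kind[hv] == "snp") next
      vp <- v$pos[hv]; ve <- vp + nchar(v$ref[hv]) - 1L
      pre <- substr(g[[chrom]], max(1L, vp - 5L), vp - 1L)
      post <- substr(g[[chrom]], ve + 1L, min(nchar(g[[chrom]]), ve + 5L))
      ctx[[j]] <- list(ref = paste0(pre, v$ref[hv], post),
                       alt = paste0(pre, v$alt[hv], post),
                       flank = nchar(pre))
    }
  }
  calls <- list()
  for (fi in in_reg) {
    cands <- list()
    other_hit <- FALSE
    for (j in seq_along(het)) {
      hv <- het[j]
      vpos <- vpos_all[hv]; vend <- vend_all[hv]
      for (mate in 1:2) {
        mp <- X[[paste0("pos", mate)]][fi]
        mc <- X[[paste0("cigar", mate)]][fi]
        if (is.na(mp) || is.na(mc)) next
        mend <- mate_end[fi, mate]
        if (!is.null(ctx[[j]])) {
          # indel: loose span gate, placement-invariant context call
          if (mend + 20L < vpos || mp - 20L > vend) next
          ca <- call_indel_context(X[[paste0("seq", mate)]][fi],
                                   X[[paste0("qual", mate)]][fi],
                                   ctx[[j]]$flank, ctx[[j]]$ref, ctx[[j]]$alt)
          if (is.na(ca$allele)) next         # undetermined, not "other"
        } else {
          if (vpos < mp || vend > mend) next  # need the full REF span in the mate
          ca <- mate_allele_at(X[[paste0("seq", mate)]][fi],
                               X[[paste0("qual", mate)]][fi],
                               mp, mc, vpos, v$ref[hv], v$alt[hv])
        }
        if (is.na(ca$qual) || ca$qual < base_qual_min) next
        if (is.na(ca$allele)) { other_hit <- TRUE; next }
        cands[[length(cands) + 1L]] <-
          data.frame(variant = hv, allele = ca$allele, qual = ca$qual,
                     pos = vpos)
      }
    }
    if (length(cands)) {
      cd <- do.call(rbind, cands)
      # overlapping mates over the same site count once; pick the site with
      # the highest base quality, then leftmost
      cd <- cd[order(-cd$qual, cd$pos), , drop = FALSE]
      cd <- cd[!duplicated(cd$variant), , drop = FALSE]
      best <- cd[1L, ]
      hap <- if (best$allele == panel$gt_m[best$variant, si]) "M" else "P"
      calls[[length(calls) + 1L]] <-
        data.frame(frag = fi, variant = best$variant, allele = best$allele,
                   hap = hap)
    } else if (other_hit) {
      calls[[length(calls) + 1L]] <-
        data.frame(frag = fi, variant = NA_integer_, allele = NA_integer_,
                   hap = NA_character_)
    }
  }
  if (!length(calls)) return(empty)
  cl <- do.call(rbind, calls)
  pv <- do.call(rbind, lapply(het, function(hv) {
    sel <- !is.na(cl$variant) & cl$variant == hv
    data.frame(variant_id = v$id[hv],
               n_ref = sum(cl$allele[sel] == 0L),
               n_alt = sum(cl$allele[sel] == 1L),
               n_other = 0L, stringsAsFactors = FALSE)
  }))
  pv$n_other[1L] <- sum(is.na(cl$variant))
  ok <- !is.na(cl$variant)
  list(fragments = data.frame(frag = cl$frag[ok],
                              variant_id = v$id[cl$variant[ok]],
                              hap = cl$hap[ok], stringsAsFactors = FALSE),
       per_variant = pv, n_fragments = length(in_reg))
}

#' Build the CHT count table: one row per (region, test variant, sample)
#'
#' Target regions are consensus-peak summits +/- `radius`; every panel variant
#' inside a region is a candidate test variant. Candidates must pass four
#' inclusive filters: total reads across samples (`min_read_count`), summed
#' allele-specific reads over het samples (`min_as_count`), het sample count
#' (`min_het_count`), and minor-allele copies across sample genotypes
#' (`min_minor_allele_count`). Expected counts are fitted with
#' [adjust_expected_counts()].
#'
#' @param aln_by_sample Named list of pair tables (bias-filtered), one per
#'   sample.
#' @param panel A [phased_panel()].
#' @param peaks Consensus peaks ([consensus_peaks()]): needs `chrom`, `summit`.
#' @param genome Genome for the GC adjustment ([load_genome()]); `NULL` skips GC.
#' @param radius Region radius around the summit in bp (default 2500).
#' @param min_read_count,min_as_count,min_het_count,min_minor_allele_count
#'   Inclusion filters (defaults 400 / 50 / 1 / 1, applied as >=).
#' @param base_qual_min Base-quality floor for allele calls.
#' @param frip Optional named per-sample fraction-of-reads-in-peaks weights.
#' @return data.frame with columns `region_id`, `variant_id`, `chrom`, `pos`,
#'   `sample`, `g`, `T`, `E`, `as_ref`, `as_alt`; filter attrition counts in
#'   `attr(, "attrition")`.
#' @export
region_counts <- function(aln_by_sample, panel, peaks, genome = NULL,
                          radius = 2500L, min_read_count = 400L,
                          min_as_count = 50L, min_het_count = 1L,
                          min_minor_allele_count = 1L, base_qual_min = 10L,
                          frip = NULL) {
  samples <- names(aln_by_sample)
  stopifnot(!is.null(samples), all(samples %in% panel$samples))
  v <- panel$variants
  hm <- het_matrix(panel)[, match(samples, panel$samples), drop = FALSE]
  dm <- dosage_matrix(panel)[, match(samples, panel$samples), drop = FALSE]

  rows <- list()
  region_tot <- list()
  attrition <- c(candidates = 0L, fail_read_count = 0L, fail_as_count = 0L,
                 fail_het_count = 0L, fail_minor_allele = 0L, pass = 0L)
  for (pi in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[pi]
    rs <- peaks$summit[pi] - radius; re <- peaks$summit[pi] + radius
    region_id <- sprintf("%s:%d-%d", ch, rs, re)
    vin <- which(v$chrom == ch & v$pos >= rs & v$pos <= re)
    cnt <- lapply(samples, function(sm)
      count_alleles(aln_by_sample[[sm]], panel, sm, ch, rs, re, base_qual_min,
                    genome = genome))
    names(cnt) <- samples
    Tvec <- vapply(cnt, `[[`, 1L, "n_fragments")
    region_tot[[region_id]] <- Tvec
    if (!length(vin)) next
    for (tv in vin) {
      attrition["candidates"] <- attrition["candidates"] + 1L
      g <- dm[tv, ]
      het <- hm[tv, ]
      as_ref <- as_alt <- integer(length(samples))
      for (sj in seq_along(samples)) {
        if (!het[sj]) next
        fr <- cnt[[sj]]$fragments
        if (!nrow(fr)) next
        # haplotype carrying the test variant's REF allele for this sample
        ref_hap <- if (panel$gt_m[tv, match(samples[sj], panel$samples)] == 0L)
          "M" else "P"
        as_ref[sj] <- sum(fr$hap == ref_hap)
        as_alt[sj] <- sum(fr$hap != ref_hap)
      }
      tot <- sum(Tvec); as_tot <- sum(as_ref + as_alt)
      n_het <- sum(het)
      minor <- min(sum(g), 2L * length(g) - sum(g))
      if (tot < min_read_count) { attrition["fail_read_count"] <- attrition["fail_read_count"] + 1L; next }
      if (as_tot < min_as_count) { attrition["fail_as_count"] <- attrition["fail_as_count"] + 1L; next }
      if (n_het < min_het_count) { attrition["fail_het_count"] <- attrition["fail_het_count"] + 1L; next }
      if (minor < min_minor_allele_count) { attrition["fail_minor_allele"] <- attrition["fail_minor_allele"] + 1L; next }
      attrition["pass"] <- attrition["pass"] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = region_id, variant_id = v$id[tv], chrom = ch,
        pos = v$pos[tv], sample = samples, g = as.integer(g),
        T = Tvec, E = NA_real_, as_ref = as_ref, as_alt = as_alt,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no region test passed the count filters", call. = FALSE)

  # expected counts fitted on region totals (one row per region, not per test)
  tot_mat <- do.call(rbind, region_tot)
  gc <- if (!is.null(genome)) {
    g <- load_genome(genome)
    vapply(rownames(tot_mat), function(rid) {
      p <- strsplit(rid, "[:-]")[[1]]
      s <- substr(g[[p[1]]], max(1L, as.integer(p[2])),
                  min(nchar(g[[p[1]]]), as.integer(p[3])))
      b <- strsplit(s, "")[[1]]
      mean(b %in% c("G", "C"))
    }, numeric(1))
  } else NULL
  E_mat <- adjust_expected_counts(tot_mat, gc = gc, frip = frip)
  idx <- cbind(match(out$region_id, rownames(E_mat)),
               match(out$sample, colnames(E_mat)))
  out$E <- E_mat[idx]
  attr(out, "attrition") <- attrition
  rownames(out) <- NULL
  out
}

#' Fit expected per-sample region counts (library size, GC, FRiP)
#'
#' The baseline expectation allocates each region's pooled total to samples by
#' their library-size share (optionally reweighted by per-sample
#' fraction-of-reads-in-peaks). A per-sample GC correction then rescales
#' expectations by the median observed/expected ratio within GC-content
#' quartile bins, and expectations are renormalised so that
#' `sum_i E_i = sum_i T_i` holds exactly per region.
#'
#' @param tot Region x sample matrix of total counts.
#' @param gc Optional per-region GC fractions.
#' @param frip Optional named per-sample FRiP weights.
#' @param n_bins GC quantile bins (default 4).
#' @return Region x sample matrix of expected counts.
#' @export
adjust_expected_counts <- function(tot, gc = NULL, frip = NULL, n_bins = 4L) {
  tot <- as.matrix(tot)
  lib <- colSums(tot)
  w <- lib
  if (!is.null(frip)) {
    stopifnot(all(colnames(tot) %in% names(frip)))
    w <- w * frip[colnames(tot)]
  }
  share <- w / sum(w)
  E <- outer(rowSums(tot), share)
  dimnames(E) <- dimnames(tot)
  if (!is.null(gc) && nrow(tot) >= 20L) {
    br <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(br) < 3L) {
      warnf("degenerate GC distribution; GC factor fixed at 1")
    } else {
      bin <- cut(gc, br, include.lowest = TRUE)
      for (j in seq_len(ncol(E))) {
        f <- tapply(tot[, j] / pmax(E[, j], 1e-9), bin, stats::median)
        f[!is.finite(f) | is.na(f)] <- 1
        E[, j] <- E[, j] * f[bin]
      }
    }
  } else if (!is.null(gc)) {
    warnf("fewer than 20 regions; skipping GC adjustment")
  }
  # preserve per-region normalisation exactly
  E <- E * (rowSums(tot) / pmax(rowSums(E), 1e-9))
  E[E <= 0] <- 1e-6
  E
}

#' Export a count table as TSV
#' @param counts Count table from [region_counts()].
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
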