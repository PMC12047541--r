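# Indel-aware removal of reference-mapping bias: every read pair overlapping
# a variant is rewritten with all allele combinations, remapped, and kept only
# if every version maps uniquely (mapq > 10) back to the original 5' anchor
# of both mates.

variant_granges <- function(panel) {
  v <- panel$variants
  GenomicRanges::GRanges(v$chrom,
                         IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L))
}

#' Find read pairs whose aligned span intersects a variant
#'
#' A pair intersects when at least one mate's aligned reference span overlaps
#' at least one variant's REF span. Non-intersecting pairs pass through the
#' filter untouched.
#'
#' @param aln Pair table (see [read_alignments()]); mates must carry `pos` and
#'   `cigar`.
#' @param panel A [phased_panel()].
#' @return List: `intersecting` (pair table subset), `clean` (the rest), and
#'   `overlaps` (list, per intersecting pair, of panel variant indices).
#' @export
find_intersecting_reads <- function(aln, panel) {
  vgr <- variant_granges(panel)
  ov_idx <- vector("list", nrow(aln))
  for (mate in 1:2) {
    chrom <- aln[[paste0("chrom", mate)]]
    pos <- aln[[paste0("pos", mate)]]
    cg <- aln[[paste0("cigar", mate)]]
    ok <- !is.na(pos)
    if (!any(ok)) next
    w <- cigar_ref_width(cg[ok])
    gr <- GenomicRanges::GRanges(chrom[ok],
                                 IRanges::IRanges(pos[ok], pos[ok] + w - 1L))
    hits <- GenomicRanges::findOverlaps(gr, vgr)
    if (length(hits)) {
      qi <- which(ok)[S4Vectors::queryHits(hits)]
      vi <- S4Vectors::subjectHits(hits)
      for (u in unique(qi)) {
        ov_idx[[u]] <- union(ov_idx[[u]], vi[qi == u])
      }
    }
  }
  has <- lengths(ov_idx) > 0L
  list(intersecting = aln[has, , drop = FALSE],
       clean = aln[!has, , drop = FALSE],
       overlaps = lapply(ov_idx[has], sort))
}

# rebuild one mate's sequence for a given allele assignment, anchored at its
# strand-aware 5' reference coordinate (precomputed), preserving read length
rebuild_mate <- function(g, chrom, anchor, strand, read_len, vtab, alleles) {
  slack <- read_len + sum(abs(nchar(vtab$alt) - nchar(vtab$ref))) + 8L
  L <- nchar(g[[chrom]])
  ws <- max(1L, anchor - slack)
  we <- min(L, anchor + slack)
  # variants outside the rebuild window (e.g. overlapping only the other
  # mate) cannot affect this mate's sequence
  vend <- vtab$pos + nchar(vtab$ref) - 1L
  inw <- vtab$pos >= ws & vend <= we
  hap <- haplotype_sequence(g, chrom, ws, we,
                            vtab[inw, c("pos", "ref", "alt"), drop = FALSE],
                            alleles[inw])
  amap <- hap$ref_to_hap[anchor - ws + 1L]
  if (is.na(amap)) {                       # anchor base deleted in this version
    later <- hap$ref_to_hap[(anchor - ws + 1L):length(hap$ref_to_hap)]
    amap <- later[!is.na(later)][1L]
    if (is.na(amap)) return(NA_character_)
  }
  s <- if (identical(strand, "-")) {
    if (amap < read_len) return(NA_character_)
    substr(hap$seq, amap - read_len + 1L, amap)
  } else {
    substr(hap$seq, amap, amap + read_len - 1L)
  }
  if (nchar(s) < read_len) NA_character_ else s
}

#' Enumerate allele-swapped versions of intersecting read pairs
#'
#' For the `h` biallelic variants a pair overlaps, builds all `2^h` allele
#' assignments (the original assignment is one of them) and rebuilds both
#' mates' sequences from the corresponding haplotype, anchored at each mate's
#' 5' reference coordinate and kept at the original read length (indel-aware:
#' flanking haplotype sequence fills or absorbs length shifts). Pairs with
#' `2^h > max_combinations` are dropped with reason `"too_many_combinations"`.
#'
#' @param intersecting Pair table of variant-overlapping pairs.
#' @param overlaps List of per-pair panel variant indices
#'   (from [find_intersecting_reads()]).
#' @param genome See [load_genome()].
#' @param panel A [phased_panel()].
#' @param max_combinations Cap on versions per pair (default 64).
#' @return List: `versions` (data.frame: `qname`, `version`, `alleles`,
#'   `seq1`, `seq2`, expected chrom/strand/anchor per mate) and `dropped`
#'   (data.frame `qname`, `reason`).
#' @export
enumerate_allele_versions <- function(intersecting, overlaps, genome, panel,
                                      max_combinations = 64L) {
  g <- load_genome(genome)
  v <- panel$variants
  out <- vector("list", nrow(intersecting))
  dropped <- character(0)
  X <- as.list(intersecting)              # column vectors: fast row access
  anch1_all <- anchor_pos(X$pos1, X$strand1, X$cigar1)
  anch2_all <- anchor_pos(X$pos2, X$strand2, X$cigar2)
  for (i in seq_len(nrow(intersecting))) {
    vidx <- overlaps[[i]]
    h <- length(vidx)
    if (2^h > max_combinations) { dropped <- c(dropped, X$qname[i]); next }
    vtab <- v[vidx, , drop = FALSE]
    combos <- as.matrix(expand.grid(rep(list(0:1), h)))
    rl1 <- nchar(X$seq1[i]); rl2 <- nchar(X$seq2[i])
    seq1 <- seq2 <- character(nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      al <- combos[ci, ]
      seq1[ci] <- rebuild_mate(g, X$chrom1[i], anch1_all[i], X$strand1[i],
                               rl1, vtab, al)
      seq2[ci] <- rebuild_mate(g, X$chrom2[i], anch2_all[i], X$strand2[i],
                               rl2, vtab, al)
    }
    out[[i]] <- data.frame(
      qname = X$qname[i], version = seq_len(nrow(combos)),
      alleles = apply(combos, 1, paste, collapse = ""),
      seq1 = seq1, seq2 = seq2,
      chrom = X$chrom1[i],
      strand1 = X$strand1[i], anchor1 = anch1_all[i],
      strand2 = X$strand2[i], anchor2 = anch2_all[i],
      stringsAsFactors = FALSE)
  }
  versions <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(versions))
    versions <- data.frame(qname = character(), version = integer(),
                           alleles = character(), seq1 = character(),
                           seq2 = character(), chrom = character(),
                           strand1 = character(), anchor1 = integer(),
                           strand2 = character(), anchor2 = integer())
  list(versions = versions,
       dropped = data.frame(qname = dropped,
                            reason = rep("too_many_combinations",
                                         length(dropped)),
                            stringsAsFactors = FALSE))
}

#' Remap allele versions and keep only stably mapping pairs
#'
#' A pair is kept iff every version of both mates maps, uniquely and with
#' mapping quality strictly greater than `mapq_min`, to the original
#' strand-aware 5' anchor on the original chromosome and strand. Otherwise
#' the pair is dropped with reason `unmapped`, `multimapped`, `low_mapq` or
#' `moved` (in that precedence).
#'
#' @param versions Version table from [enumerate_allele_versions()].
#' @param aligner An `aschip_aligner`.
#' @param mapq_min Minimum mapping quality (exclusive; default 10).
#' @return data.frame `qname`, `status` ("kept"/"dropped"), `reason`.
#' @export
remap_filter <- function(versions, aligner, mapq_min = 10L) {
  if (!nrow(versions))
    return(data.frame(qname = character(), status = character(),
                      reason = character(), stringsAsFactors = FALSE))
  # versions whose rebuild failed (anchor fell off the contig) fail the pair
  bad_build <- is.na(versions$seq1) | is.na(versions$seq2)
  vv <- versions[!bad_build, , drop = FALSE]
  # FASTQ orientation: minus-strand mates are reverse-complemented
  fq1 <- ifelse(vv$strand1 == "-", revcomp(vv$seq1), vv$seq1)
  fq2 <- ifelse(vv$strand2 == "-", revcomp(vv$seq2), vv$seq2)
  key <- paste0(vv$qname, "#v", vv$version)
  res <- aligner$align_pairs(data.frame(qname = key, seq1 = fq1, seq2 = fq2,
                                        stringsAsFactors = FALSE))
  stopifnot(nrow(res) == nrow(vv))
  classify_mate <- function(mapped, mapq, chrom, strand, obs_anchor,
                            exp_chrom, exp_strand, exp_anchor) {
    r <- rep(NA_character_, length(mapped))
    r[!mapped] <- "unmapped"
    sel <- is.na(r) & mapq == 0L
    r[sel] <- "multimapped"
    sel <- is.na(r) & mapq <= mapq_min
    r[sel] <- "low_mapq"
    sel <- is.na(r) & (chrom != exp_chrom | strand != exp_strand |
                         obs_anchor != exp_anchor)
    r[sel] <- "moved"
    r
  }
  r1 <- classify_mate(res$mapped1, res$mapq1, res$chrom1, res$strand1,
                      anchor_pos(res$pos1, res$strand1, res$cigar1),
                      vv$chrom, vv$strand1, vv$anchor1)
  r2 <- classify_mate(res$mapped2, res$mapq2, res$chrom2, res$strand2,
                      anchor_pos(res$pos2, res$strand2, res$cigar2),
                      vv$chrom, vv$strand2, vv$anchor2)
  prec <- c(unmapped = 1, multimapped = 2, low_mapq = 3, moved = 4)
  vreason <- ifelse(is.na(r1), r2, ifelse(is.na(r2), r1,
                    ifelse(prec[r1] <= prec[r2], r1, r2)))
  per_pair <- tapply(vreason, vv$qname, function(rs) {
    rs <- rs[!is.na(rs)]
    if (!length(rs)) "kept" else names(prec)[min(prec[rs])]
  })
  qn <- unique(versions$qname)
  reason <- per_pair[qn]
  reason[qn %in% versions$qname[bad_build]] <- "unmapped"
  reason[is.na(reason)] <- "unmapped"
  data.frame(qname = qn,
             status = ifelse(reason == "kept", "kept", "dropped"),
             reason = ifelse(reason == "kept", NA_character_,
                             unname(reason)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random de-duplication of read pairs
#'
#' Among pairs sharing both mates' strand-aware 5' anchors (chromosome,
#' anchor, strand for each mate) exactly one pair is retained, chosen
#' uniformly at random with the given seed — deterministic across runs —
#' so that duplicate removal cannot favour reference-allele reads.
#'
#' @param aln Pair table.
#' @param seed Integer seed.
#' @return Pair table of surviving pairs.
#' @export
dedup_random <- function(aln, seed = 1L) {
  if (!nrow(aln)) return(aln)
  key <- paste(aln$chrom1,
               anchor_pos(aln$pos1, aln$strand1, aln$cigar1), aln$strand1,
               anchor_pos(aln$pos2, aln$strand2, aln$cigar2), aln$strand2,
               sep = ":")
  keep <- with_seed(child_seed(seed, "dedup"), {
    vapply(split(seq_len(nrow(aln)), key),
           function(ix) if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
           integer(1))
  })
  out <- aln[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full indel-aware mapping-bias filter
#'
#' Convenience wrapper: identifies variant-intersecting pairs, enumerates
#' allele versions, remaps them, keeps stably mapping pairs (clean pairs pass
#' through untouched), and randomly de-duplicates.
#'
#' @param aln Pair table of original alignments.
#' @param genome See [load_genome()].
#' @param panel A [phased_panel()] (lenient set in the paper's sense).
#' @param aligner An `aschip_aligner`; defaults to [bwa_aligner()] on `genome`.
#' @param max_combinations Version cap per pair (default 64).
#' @param mapq_min Remap mapping-quality floor, exclusive (default 10).
#' @param seed Seed for random de-duplication.
#' @param dedup De-duplicate after filtering (default TRUE).
#' @return List: `aln` (filtered pair table), `summary` (named counts), and
#'   `drops` (per-pair drop reasons).
#' @export
bias_filter <- function(aln, genome, panel, aligner = NULL,
                        max_combinations = 64L, mapq_min = 10L, seed = 1L,
                        dedup = TRUE) {
  if (is.null(aligner)) aligner <- bwa_aligner(genome)
  fi <- find_intersecting_reads(aln, panel)
  en <- enumerate_allele_versions(fi$intersecting, fi$overlaps, genome, panel,
                                  max_combinations)
  rf <- remap_filter(en$versions, aligner, mapq_min)
  drops <- rbind(en$dropped,
                 rf[rf$status == "dropped", c("qname", "reason")])
  kept_q <- rf$qname[rf$status == "kept"]
  kept <- rbind(fi$clean,
                fi$intersecting[fi$intersecting$qname %in% kept_q, ,
                                drop = FALSE])
  if (dedup) kept <- dedup_random(kept, seed)
  summary <- c(n_pairs = nrow(aln),
               n_clean = nrow(fi$clean),
               n_intersecting = nrow(fi$intersecting),
               n_kept_intersecting = length(kept_q),
               n_dropped = nrow(drops),
               n_after_dedup = nrow(kept))
  list(aln = kept, summary = summary, drops = drops)
}
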