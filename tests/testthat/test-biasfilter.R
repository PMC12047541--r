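# Aligner interfaces and the indel-aware mapping-bias filter.

test_that("exact and ungapped aligners place reads and flag ambiguity", {
  g <- c(cA = paste0(rdna(300, seed = 1), rdna(120, seed = 2),
                     rdna(300, seed = 3), rdna(120, seed = 2)))  # duplicated block
  al <- exact_aligner(g)
  r1 <- substr(g[[1]], 51, 100)
  r2 <- revcomp(substr(g[[1]], 151, 200))
  res <- al$align_pairs(data.frame(qname = "p1", seq1 = r1, seq2 = r2))
  expect_equal(res$pos1, 51L)
  expect_equal(res$strand1, "+")
  expect_equal(res$pos2, 151L)
  expect_equal(res$strand2, "-")
  expect_equal(res$mapq1, 60L)
  # a read inside the duplicated 120-mer is ambiguous
  dup <- substr(g[[1]], 311, 360)
  resd <- al$align_pairs(data.frame(qname = "d", seq1 = dup, seq2 = dup))
  expect_true(resd$mapped1)
  expect_equal(resd$mapq1, 0L)

  mm <- mismatch_aligner(g, max_mismatch = 3L)
  r1m <- r1
  substr(r1m, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(r1, 10, 10))[1]
  resm <- mm$align_pairs(data.frame(qname = "m", seq1 = r1m, seq2 = r2))
  expect_equal(resm$pos1, 51L)
  # a 4 bp deletion defeats ungapped matching
  gap <- paste0(substr(g[[1]], 51, 70), substr(g[[1]], 75, 104))
  resg <- mm$align_pairs(data.frame(qname = "g", seq1 = gap, seq2 = r2))
  expect_false(resg$mapped1)
})

test_that("bwa places simulated pairs at their source coordinates", {
  g <- c(cA = rdna(5000, seed = 4))
  al <- bwa_aligner(g)
  starts <- c(101L, 1501L, 3001L)
  aln <- al$align_pairs(data.frame(
    qname = paste0("q", starts),
    seq1 = substring(g[[1]], starts, starts + 74L),
    seq2 = revcomp(substring(g[[1]], starts + 225L, starts + 299L))))
  expect_equal(aln$pos1, starts)
  expect_equal(aln$strand1, rep("+", 3))
  expect_equal(aln$pos2, starts + 225L)
  expect_equal(aln$strand2, rep("-", 3))
  expect_true(all(aln$mapq1 > 10))
})

test_that("intersecting pairs are found exactly (planted overlap counts)", {
  set.seed(8)
  g <- c(cA = rdna(100000, seed = 8))
  panel <- snp_panel(g, pos = sort(sample(seq(1000L, 99000L, by = 97L), 60)))
  # 1000 pairs; brute-force oracle decides overlap
  starts <- sort(sample.int(99500L - 400L, 1000L))
  aln <- fragments_from_hap(g[[1]], "cA", starts, frag_len = 200L,
                            read_len = 60L)
  fi <- find_intersecting_reads(aln, panel)
  vpos <- panel$variants$pos
  oracle <- vapply(starts, function(s)
    any((vpos >= s & vpos <= s + 59L) |
          (vpos >= s + 140L & vpos <= s + 199L)), logical(1))
  expect_equal(nrow(fi$intersecting), sum(oracle))
  expect_equal(nrow(fi$clean), sum(!oracle))
  expect_equal(sort(fi$intersecting$qname), sort(aln$qname[oracle]))
})

test_that("allele-version enumeration is 2^h with the 64-version cap", {
  g <- c(cA = rdna(2000, seed = 10))
  read_len <- 80L
  base <- 501L
  mk <- function(n_var) {
    panel <- snp_panel(g, pos = seq(base + 5L, by = 10L, length.out = n_var))
    aln <- pair_row("q1", "cA", base, substr(g[[1]], base, base + read_len - 1L),
                    base + 160L, substr(g[[1]], base + 160L, base + 239L))
    fi <- find_intersecting_reads(aln, panel)
    enumerate_allele_versions(fi$intersecting, fi$overlaps, g, panel)
  }
  expect_equal(nrow(mk(1L)$versions), 2L)
  en6 <- mk(6L)
  expect_equal(nrow(en6$versions), 64L)
  expect_equal(nrow(en6$dropped), 0L)
  en7 <- mk(7L)
  expect_equal(nrow(en7$versions), 0L)
  expect_equal(en7$dropped$reason, "too_many_combinations")
})

test_that("rebuilt versions preserve read length across indels", {
  g <- c(cA = rdna(2000, seed = 12))
  v <- data.frame(chrom = "cA", pos = c(540L, 580L),
                  ref = c(substr(g[[1]], 540, 545), substr(g[[1]], 580, 580)),
                  alt = c(substr(g[[1]], 540, 540),
                          paste0(substr(g[[1]], 580, 580), "ACGT")))
  panel <- phased_panel(v, "S1", matrix(0L, 2), matrix(1L, 2))
  aln <- pair_row("q1", "cA", 501L, substr(g[[1]], 501, 580),
                  601L, substr(g[[1]], 601, 680))
  fi <- find_intersecting_reads(aln, panel)
  en <- enumerate_allele_versions(fi$intersecting, fi$overlaps, g, panel)
  expect_equal(nrow(en$versions), 4L)
  expect_true(all(nchar(en$versions$seq1) == 80L))
  expect_true(all(nchar(en$versions$seq2) == 80L))
  # the all-reference version reproduces the original mate sequences
  ref_v <- en$versions[en$versions$alleles == "00", ]
  expect_equal(ref_v$seq1, aln$seq1)
  expect_equal(ref_v$seq2, aln$seq2)
})

test_that("remap decisions classify moved, low-mapq, multimapped and unmapped", {
  # scripted aligner: maps version k of pair q according to a lookup table
  make_scripted <- function(tab) {
    structure(list(align_pairs = function(df) {
      m <- tab[df$qname, , drop = FALSE]
      data.frame(qname = df$qname, chrom1 = "cA", pos1 = m$pos1,
                 strand1 = "+", mapq1 = m$mapq, cigar1 = "50M",
                 mapped1 = m$mapped, chrom2 = "cA", pos2 = m$pos2,
                 strand2 = "-", mapq2 = m$mapq, cigar2 = "50M",
                 mapped2 = m$mapped, stringsAsFactors = FALSE)
    }, name = "scripted"), class = "aschip_aligner")
  }
  versions <- data.frame(qname = rep(c("ok", "mv", "lq", "mm", "um"), each = 2),
                         version = rep(1:2, 5), alleles = rep(c("0", "1"), 5),
                         seq1 = strrep("A", 50), seq2 = strrep("C", 50),
                         chrom = "cA", strand1 = "+", anchor1 = 100L,
                         strand2 = "-", anchor2 = 249L,
                         stringsAsFactors = FALSE)
  tab <- data.frame(row.names = paste0(versions$qname, "#v", versions$version),
                    pos1 = rep(100L, 10), pos2 = rep(200L, 10),
                    mapq = rep(60L, 10), mapped = rep(TRUE, 10))
  tab["mv#v2", "pos1"] <- 600L
  tab["lq#v2", "mapq"] <- 10L            # not strictly greater than 10
  tab["mm#v2", "mapq"] <- 0L
  tab["um#v2", "mapped"] <- FALSE
  out <- remap_filter(versions, make_scripted(tab))
  st <- setNames(out$status, out$qname)
  rs <- setNames(out$reason, out$qname)
  expect_equal(unname(st["ok"]), "kept")
  expect_equal(unname(rs["mv"]), "moved")
  expect_equal(unname(rs["lq"]), "low_mapq")
  expect_equal(unname(rs["mm"]), "multimapped")
  expect_equal(unname(rs["um"]), "unmapped")
})

test_that("random de-duplication keeps one pair per coordinate group, reproducibly", {
  g <- c(cA = rdna(1000, seed = 14))
  aln <- fragments_from_hap(g[[1]], "cA", rep(101L, 3), prefix = "dup")
  out <- dedup_random(aln, seed = 5)
  expect_equal(nrow(out), 1L)
  out2 <- dedup_random(aln, seed = 5)
  expect_identical(out, out2)
  # non-duplicate pairs pass through untouched
  distinct <- fragments_from_hap(g[[1]], "cA", c(101L, 301L, 501L))
  expect_equal(nrow(dedup_random(distinct, seed = 5)), 3L)
})

test_that("de-duplication does not favour either allele", {
  # 1000 duplicate groups; in each, one ref-labelled and one alt-labelled
  # pair share coordinates; the survivor should be ref about half the time
  g <- c(cA = rdna(60000, seed = 15))
  starts <- seq(101L, by = 50L, length.out = 1000L)
  ref <- fragments_from_hap(g[[1]], "cA", starts, prefix = "ref")
  alt <- fragments_from_hap(g[[1]], "cA", starts, prefix = "alt")
  out <- dedup_random(rbind(ref, alt), seed = 33)
  expect_equal(nrow(out), 1000L)
  frac_ref <- mean(startsWith(out$qname, "ref"))
  expect_lt(abs(frac_ref - 0.5), 3 * sqrt(0.25 / 1000))
})


test_that("the filter removes the reference bias an indel induces at flanking SNPs", {
  sc <- indel_bias_scenario()
  al <- mismatch_aligner(sc$genome, max_mismatch = 3L)
  aln <- al$align_pairs(sc$reads[, c("qname", "seq1", "seq2")])
  aln$seq1 <- ifelse(!is.na(aln$strand1) & aln$strand1 == "-",
                     revcomp(sc$reads$seq1), sc$reads$seq1)
  aln$seq2 <- ifelse(!is.na(aln$strand2) & aln$strand2 == "-",
                     revcomp(sc$reads$seq2), sc$reads$seq2)
  aln$qual1 <- strrep("I", nchar(aln$seq1))
  aln$qual2 <- strrep("I", nchar(aln$seq2))
  naive <- aln[aln$mapped1 & aln$mapped2, , drop = FALSE]

  ratio_of <- function(tab) {
    ca <- count_alleles(tab, sc$panel, "S1", "cA", 1500L, 2500L,
                        genome = sc$genome)
    pv <- ca$per_variant
    pv <- pv[pv$variant_id != sc$panel$variants$id[2], ]   # flanking SNPs only
    c(ref = sum(pv$n_ref), alt = sum(pv$n_alt))
  }
  nv <- ratio_of(naive)
  naive_ratio <- nv["ref"] / sum(nv)
  # ungapped mapping loses deletion-spanning paternal reads: visible ref bias
  expect_gt(naive_ratio, 0.55)

  bf <- bias_filter(naive, sc$genome, sc$panel, aligner = al, seed = 3)
  fv <- ratio_of(bf$aln)
  n_as <- sum(fv)
  expect_gt(n_as, 30)
  # post-filter ratio is 0.5 within binomial error
  expect_lt(abs(fv["ref"] / n_as - 0.5), 3 * sqrt(0.25 / n_as))
  expect_gt(sum(bf$drops$reason == "unmapped"), 0)
})

test_that("swapping REF and ALT labels mirrors keep/drop decisions", {
  sc <- indel_bias_scenario(seed = 91, n_frag = 120L)
  # mirrored encoding: the paternal haplotype becomes the reference and every
  # variant's REF/ALT labels swap; the reads themselves are unchanged
  v <- sc$panel$variants
  hapP <- haplotype_sequence(sc$genome, "cA", 1L, 4000L,
                             v[, c("pos", "ref", "alt")], rep(1L, 3))
  g2 <- c(cA = hapP$seq)
  v2 <- data.frame(chrom = "cA",
                   pos = hapP$ref_to_hap[v$pos],
                   ref = v$alt, alt = v$ref, stringsAsFactors = FALSE)
  panel2 <- phased_panel(v2, "S1", matrix(1L, 3), matrix(0L, 3))

  run <- function(genome, panel) {
    al <- mismatch_aligner(genome, max_mismatch = 3L)
    aln <- al$align_pairs(sc$reads[, c("qname", "seq1", "seq2")])
    aln$seq1 <- ifelse(!is.na(aln$strand1) & aln$strand1 == "-",
                       revcomp(sc$reads$seq1), sc$reads$seq1)
    aln$seq2 <- ifelse(!is.na(aln$strand2) & aln$strand2 == "-",
                       revcomp(sc$reads$seq2), sc$reads$seq2)
    aln <- aln[aln$mapped1 & aln$mapped2, , drop = FALSE]
    bf <- bias_filter(aln, genome, panel, aligner = al, seed = 3,
                      dedup = FALSE)
    list(universe = aln$qname, kept = bf$aln$qname)
  }
  r1 <- run(sc$genome, sc$panel)
  r2 <- run(g2, panel2)
  # pairs mapped under both encodings must receive identical decisions;
  # reads that merely graze the indel's edge see different flank content in
  # the two encodings and are excluded from the strict comparison
  common <- intersect(r1$universe, r2$universe)
  expect_gt(length(common), 50)
  del_lo <- v$pos[2] - 6L; del_hi <- v$pos[2] + nchar(v$ref[2]) + 5L
  grazing <- vapply(common, function(q) {
    k <- match(q, sc$reads$qname)
    spans <- rbind(c(attr(sc$reads, "starts")[k],
                     attr(sc$reads, "starts")[k] + 69L),
                   c(attr(sc$reads, "starts")[k] + 90L,
                     attr(sc$reads, "starts")[k] + 159L))
    any(spans[, 1] <= del_hi & spans[, 2] >= del_lo &
          !(spans[, 1] <= del_lo & spans[, 2] >= del_hi))
  }, logical(1))
  keepers <- common[!grazing]
  expect_gt(length(keepers), 40)
  expect_equal(keepers %in% r1$kept, keepers %in% r2$kept)
})

test_that("raising the version cap never drops a previously kept pair", {
  set.seed(55)
  g <- c(cA = rdna(30000, seed = 55))
  panel <- snp_panel(g, pos = sort(sample(seq(5000L, 25000L, by = 40L), 80)))
  starts <- sample(4800:24800, 150L)
  aln <- fragments_from_hap(g[[1]], "cA", starts, frag_len = 200L,
                            read_len = 80L)
  al <- mismatch_aligner(g, max_mismatch = 3L)
  kept16 <- bias_filter(aln, g, panel, aligner = al, max_combinations = 16L,
                        dedup = FALSE)$aln$qname
  kept64 <- bias_filter(aln, g, panel, aligner = al, max_combinations = 64L,
                        dedup = FALSE)$aln$qname
  expect_true(all(kept16 %in% kept64))
})
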