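# Consensus peaks, allele-specific counting, expected-count adjustment.

test_that("consensus peaks require support from min_lines distinct lines", {
  pk <- data.frame(chrom = "cA", start = 100L, end = 500L)
  far <- data.frame(chrom = "cA", start = 5000L, end = 5400L)
  per_line <- list(A = pk, B = pk, C = pk, D = far, E = far,
                   F = data.frame(chrom = character(), start = integer(),
                                  end = integer()),
                   G = far[0, ], H = pk[0, ])
  cov <- list(cA = rep(1L, 6000L))
  cov$cA[300] <- 10L; cov$cA[5100] <- 7L
  cp <- consensus_peaks(per_line, cov, min_lines = 3L)
  expect_equal(nrow(cp), 1L)                  # far peak has only 2 lines
  expect_equal(cp$start, 100L)
  expect_equal(cp$summit, 300L)
  expect_equal(cp$n_lines, 3L)
})

test_that("overlapping peaks merge transitively and the pooled summit wins", {
  a <- data.frame(chrom = "cA", start = 100L, end = 300L)
  b <- data.frame(chrom = "cA", start = 299L, end = 500L)   # 1 bp overlap
  per_line <- list(l1 = a, l2 = a, l3 = b, l4 = b, l5 = rbind(a, b)[0, ])
  cov <- list(cA = rep(1L, 1000L)); cov$cA[430] <- 50L
  cp <- consensus_peaks(per_line, cov, min_lines = 3L)
  expect_equal(nrow(cp), 1L)
  expect_equal(c(cp$start, cp$end), c(100L, 500L))
  expect_equal(cp$summit, 430L)
  # a duplicated-line peak does not double-count support
  expect_warning(
    cp2 <- consensus_peaks(list(l1 = a, l2 = rbind(a, a)), cov, min_lines = 3L),
    "fewer peak sets")
  expect_equal(nrow(cp2), 0L)
})

test_that("empty peak input warns and returns an empty set", {
  expect_warning(cp <- consensus_peaks(list(), list()), "no input peaks")
  expect_equal(nrow(cp), 0L)
})

test_that("narrowPeak summits are converted to absolute coordinates", {
  f <- tempfile(fileext = ".narrowPeak")
  writeLines("cA\t100\t500\tpeak1\t0\t.\t5.5\t4.4\t3.3\t200", f)
  pk <- read_peaks(f)
  expect_equal(pk$start, 100L)
  expect_equal(pk$summit, 301L)
})

test_that("mate-level allele extraction handles SNPs and gapped reads", {
  # reference context: read aligned at pos 101 with a SNP at 110
  seq <- paste0(strrep("A", 9), "G", strrep("A", 20))
  expect_equal(aschip:::mate_allele_at(seq, strrep("I", 30), 101L, "30M",
                                       110L, "A", "G")$allele, 1L)
  expect_equal(aschip:::mate_allele_at(gsub("G", "A", seq), strrep("I", 30),
                                       101L, "30M", 110L, "A", "G")$allele, 0L)
  # read with a 3 bp deletion at 111-113 (variant AAAA -> A anchored at 110)
  expect_equal(aschip:::mate_allele_at(strrep("A", 27), strrep("I", 27), 101L,
                                       "10M3D17M", 110L, "AAAA", "A")$allele, 1L)
  # read with a 2 bp insertion after 110 (variant A -> ACC)
  ins <- paste0(strrep("A", 10), "CC", strrep("A", 18))
  expect_equal(aschip:::mate_allele_at(ins, strrep("I", 30), 101L,
                                       "10M2I18M", 110L, "A", "ACC")$allele, 1L)
  # base matching neither allele is neither REF nor ALT
  other <- paste0(strrep("A", 9), "T", strrep("A", 20))
  expect_true(is.na(aschip:::mate_allele_at(other, strrep("I", 30), 101L,
                                            "30M", 110L, "A", "G")$allele))
})

test_that("fragments contribute one observation and follow the phase", {
  g <- c(cA = rdna(2000, seed = 41))
  # S1 het at both SNPs: maternal carries REF at 600, ALT at 700
  v <- data.frame(chrom = "cA", pos = c(600L, 700L),
                  ref = substring(g[[1]], c(600L, 700L), c(600L, 700L)))
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  panel <- phased_panel(v, "S1", gt_m = matrix(c(0L, 1L), 2),
                        gt_p = matrix(c(1L, 0L), 2))
  hapM <- haplotype_sequence(g, "cA", 1L, 2000L, v[, c("pos", "ref", "alt")],
                             c(0L, 1L))$seq
  # one fragment spanning both het SNPs, drawn from the maternal haplotype
  aln <- fragments_from_hap(hapM, "cA", 580L, frag_len = 140L, read_len = 70L)
  ca <- count_alleles(aln, panel, "S1", "cA", 500L, 800L, genome = g)
  expect_equal(nrow(ca$fragments), 1L)        # one observation, not two
  expect_equal(ca$fragments$hap, "M")
  # 300 maternal / 100 paternal fragments -> exactly (300, 100) at a SNP
  hapP <- haplotype_sequence(g, "cA", 1L, 2000L, v[, c("pos", "ref", "alt")],
                             c(1L, 0L))$seq
  set.seed(2)
  alnM <- fragments_from_hap(hapM, "cA", sample(560:590, 300, TRUE),
                             frag_len = 100L, read_len = 50L, prefix = "m")
  alnP <- fragments_from_hap(hapP, "cA", sample(560:590, 100, TRUE),
                             frag_len = 100L, read_len = 50L, prefix = "p")
  ca2 <- count_alleles(rbind(alnM, alnP), panel, "S1", "cA", 500L, 800L,
                       genome = g)
  hapcount <- table(ca2$fragments$hap)
  expect_equal(unname(hapcount[["M"]]), 300L)
  expect_equal(unname(hapcount[["P"]]), 100L)
  # count conservation: observations never exceed region fragments
  expect_lte(nrow(ca2$fragments), ca2$n_fragments)
  # per-variant counts at SNP 600: maternal carries REF there
  pv <- ca2$per_variant[ca2$per_variant$variant_id == panel$variants$id[1], ]
  expect_equal(pv$n_ref + pv$n_alt,
               sum(ca2$fragments$variant_id == panel$variants$id[1]))
})

test_that("low base quality suppresses the allele call", {
  g <- c(cA = rdna(600, seed = 43))
  v <- data.frame(chrom = "cA", pos = 300L, ref = substr(g[[1]], 300, 300))
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  panel <- phased_panel(v, "S1", matrix(0L, 1), matrix(1L, 1))
  aln <- fragments_from_hap(g[[1]], "cA", 280L, frag_len = 100L,
                            read_len = 50L)
  q <- aln$qual1
  substr(q, 300L - 280L + 1L, 300L - 280L + 1L) <- "&"   # Phred 5
  aln$qual1 <- q
  ca <- count_alleles(aln, panel, "S1", "cA", 200L, 400L, genome = g,
                      base_qual_min = 10L)
  expect_equal(nrow(ca$fragments), 0L)
  ca2 <- count_alleles(aln, panel, "S1", "cA", 200L, 400L, genome = g,
                       base_qual_min = 5L)
  expect_equal(nrow(ca2$fragments), 1L)
})

test_that("expected counts follow library size and preserve region totals", {
  tot <- matrix(c(100, 300, 200, 400), nrow = 2,
                dimnames = list(c("r1", "r2"), c("s1", "s2")))
  # equal library sizes: E is the symmetric split
  tot_eq <- matrix(c(100, 300, 100, 300), nrow = 2,
                   dimnames = list(c("r1", "r2"), c("s1", "s2")))
  E <- adjust_expected_counts(tot_eq)
  expect_equal(unname(E[, 1]), unname(rowSums(tot_eq) / 2))
  # doubling a sample's library doubles its share
  E2 <- adjust_expected_counts(matrix(c(100, 300, 200, 600), nrow = 2,
                                      dimnames = dimnames(tot)))
  expect_equal(unname(E2[, 2] / E2[, 1]), c(2, 2))
  # per-region normalisation is exact
  expect_equal(rowSums(E2), c(r1 = 300, r2 = 900))
})

test_that("planted GC bias factors are recovered within 10%", {
  set.seed(51)
  n <- 200
  gc <- stats::runif(n, 0.3, 0.7)
  bins <- cut(gc, stats::quantile(gc, seq(0, 1, 0.25)), include.lowest = TRUE)
  fac <- c(0.5, 1, 1, 2)[as.integer(bins)]
  base <- stats::rpois(n, 4000)
  # sample s2's counts carry the GC-dependent distortion
  tot <- cbind(s1 = stats::rpois(n, base),
               s2 = stats::rpois(n, base * fac))
  rownames(tot) <- sprintf("r%03d", 1:n)
  E <- adjust_expected_counts(tot, gc = gc)
  # within each bin, the fitted expectation matches observed totals on average
  for (b in levels(bins)) {
    sel <- bins == b
    expect_equal(sum(tot[sel, "s2"]) / sum(E[sel, "s2"]), 1, tolerance = 0.1)
  }
  expect_equal(rowSums(E), rowSums(tot), tolerance = 1e-9)
})

test_that("degenerate GC input falls back to a unit factor with a warning", {
  tot <- matrix(rpois(60, 100), nrow = 30)
  rownames(tot) <- sprintf("r%d", 1:30); colnames(tot) <- c("a", "b")
  expect_warning(E <- adjust_expected_counts(tot, gc = rep(0.5, 30)),
                 "degenerate")
  expect_equal(rowSums(E), rowSums(tot))
})

test_that("region tests pass exactly the four inclusive count filters", {
  run <- null_pipeline_run()
  counts <- run$counts
  att <- attr(counts, "attrition")
  expect_equal(unname(att["pass"]),
               length(unique(paste(counts$region_id, counts$variant_id))))
  # every emitted test satisfies the documented thresholds (inclusive)
  key <- paste(counts$region_id, counts$variant_id)
  for (k in unique(key)) {
    d <- counts[key == k, ]
    expect_gte(sum(d$T), 400L)
    expect_gte(sum(d$as_ref + d$as_alt), 50L)
    expect_gte(sum(d$g == 1L), 1L)
    expect_gte(min(sum(d$g), 2L * nrow(d) - sum(d$g)), 1L)
  }
  # independent re-derivation of the pass/fail split for candidate variants:
  # every candidate either passed or failed at least one filter
  expect_equal(unname(att["candidates"]),
               unname(att["pass"] + att["fail_read_count"] +
                        att["fail_as_count"] + att["fail_het_count"] +
                        att["fail_minor_allele"]))
})
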