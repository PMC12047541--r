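# Shared fixtures, built in code at test time.

# deterministic random DNA
rdna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a crisp 6-bp motif PWM (counts): consensus ACGTAT, near-degenerate.
# match p-value 1e-3: a 6-mer has only 4096 background words, so the
# package's 1e-4 default (meant for full-length motifs) cannot call anything.
test_pwm <- function() {
  m <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "C", "G", "T", "A", "T")
  for (j in 1:6) m[cons[j], j] <- 40
  pwm(m, name = "testmotif", threshold_pval = 1e-3)
}

# write a minimal phased VCF from a record data.frame
write_test_vcf <- function(path, chrom, pos, ref, alt, gts,
                           samples = paste0("S", seq_len(ncol(gts)))) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

# a small two-sample panel over a given genome: SNPs at fixed positions
snp_panel <- function(genome, pos, alt = NULL, gt_m = NULL, gt_p = NULL,
                      samples = c("S1", "S2")) {
  g <- load_genome(genome)
  ref <- substring(g[[1]], pos, pos)
  if (is.null(alt))
    alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  v <- data.frame(chrom = names(g)[1], pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  n <- length(pos); k <- length(samples)
  if (is.null(gt_m)) gt_m <- matrix(0L, n, k)
  if (is.null(gt_p)) gt_p <- matrix(1L, n, k)
  phased_panel(v, samples, gt_m, gt_p)
}

# build a pair table row for a perfectly aligned fragment on one haplotype
# (simple 100% match CIGARs; seq must be supplied in SAM orientation)
pair_row <- function(qname, chrom, pos1, seq1, pos2, seq2,
                     strand1 = "+", strand2 = "-", mapq = 60L) {
  data.frame(qname = qname, chrom1 = chrom, pos1 = pos1, strand1 = strand1,
             mapq1 = mapq, cigar1 = paste0(nchar(seq1), "M"), seq1 = seq1,
             qual1 = strrep("I", nchar(seq1)), mapped1 = TRUE,
             chrom2 = chrom, pos2 = pos2, strand2 = strand2, mapq2 = mapq,
             cigar2 = paste0(nchar(seq2), "M"), seq2 = seq2,
             qual2 = strrep("I", nchar(seq2)), mapped2 = TRUE,
             stringsAsFactors = FALSE)
}

# fragments cut from a haplotype string: returns a pair table of read pairs
# aligned at their true reference positions (only valid for SNP-only
# haplotypes where reference and haplotype coordinates coincide)
fragments_from_hap <- function(hapseq, chrom, starts, frag_len = 120L,
                               read_len = 50L, prefix = "f") {
  rows <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    frag <- substr(hapseq, s, s + frag_len - 1L)
    pair_row(sprintf("%s%04d", prefix, i), chrom,
             pos1 = s, seq1 = substr(frag, 1L, read_len),
             pos2 = s + frag_len - read_len,
             seq2 = substr(frag, frag_len - read_len + 1L, frag_len))
  })
  do.call(rbind, rows)
}

# shared scenario for the bias-removal property: a region whose alternative
# haplotype carries a 4 bp deletion flanked by het SNPs, mapped with an
# ungapped aligner so deletion-carrying reads are lost at mapping
indel_bias_scenario <- function(seed = 77, n_frag = 300L) {
  set.seed(seed)
  g <- c(cA = rdna(4000, seed = seed))
  del_pos <- 2000L
  v <- data.frame(chrom = "cA",
                  pos = c(1940L, del_pos, 2060L),
                  ref = c(substr(g[[1]], 1940, 1940),
                          substr(g[[1]], del_pos, del_pos + 4L),
                          substr(g[[1]], 2060, 2060)),
                  alt = c(NA, substr(g[[1]], del_pos, del_pos), NA),
                  stringsAsFactors = FALSE)
  v$alt[c(1, 3)] <- vapply(v$ref[c(1, 3)], function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], "")
  panel <- phased_panel(v, "S1", matrix(0L, 3), matrix(1L, 3))
  hapM <- g[[1]]                                   # maternal = reference
  hapP <- haplotype_sequence(g, "cA", 1L, 4000L, v[, c("pos", "ref", "alt")],
                             rep(1L, 3))$seq       # paternal carries all ALTs
  frag_len <- 160L; read_len <- 70L
  starts <- sample(1700:(2300 - frag_len), n_frag, replace = TRUE)
  hap <- sample(c("M", "P"), n_frag, replace = TRUE)
  reads <- data.frame(qname = sprintf("f%04d", seq_len(n_frag)),
                      hap = hap, stringsAsFactors = FALSE)
  reads$seq1 <- reads$seq2 <- NA_character_
  for (i in seq_len(n_frag)) {
    hs <- if (hap[i] == "M") hapM else hapP
    frag <- substr(hs, starts[i], starts[i] + frag_len - 1L)
    reads$seq1[i] <- substr(frag, 1, read_len)
    reads$seq2[i] <- revcomp(substr(frag, frag_len - read_len + 1L, frag_len))
  }
  attr(reads, "starts") <- starts
  list(genome = g, panel = panel, reads = reads)
}

# ---- cached full-pipeline null run (shared by calibration tests) ----------
.t2_env <- new.env(parent = emptyenv())

null_pipeline_run <- function() {
  if (!is.null(.t2_env$run)) return(.t2_env$run)
  cfg <- sim_config(seed = 42, n_peaks = 20, depth = 1000, n_f1_lines = 8)
  .t2_env$run <- suppressWarnings(run_pipeline(cfg))
  .t2_env$run
}
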