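# AlignerInterface: an aligner is a list with class "aschip_aligner" holding
#   $align_pairs(df)  df: qname, seq1, seq2 -> data.frame per pair with
#       chrom1, pos1 (1-based leftmost), strand1, mapq1, cigar1, mapped1,
#       and the same for mate 2
#   $name, $genome_fasta
# Deterministic for a fixed reference (bwa is single-threaded here).

#' Paired-end aligner backed by the bwa binary
#'
#' Indexes the reference once (in a scratch copy unless the index already
#' exists next to the FASTA) and aligns batches of read pairs with
#' `bwa mem -t 1`. Secondary/supplementary records are ignored; a pair is
#' reported at its primary alignment with bwa's mapping qualities.
#'
#' @param genome A FASTA path or anything [load_genome()] accepts (written to
#'   a scratch FASTA if not already a file).
#' @param work_dir Scratch directory for index and batch files.
#' @return An `aschip_aligner`.
#' @export
bwa_aligner <- function(genome, work_dir = tempfile("bwa_")) {
  if (!nzchar(Sys.which("bwa")))
    stopf("the 'bwa' executable is required on PATH for bwa_aligner()")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    fa <- genome
  } else {
    fa <- file.path(work_dir, "ref.fa")
    write_fasta(load_genome(genome), fa)
  }
  if (!file.exists(paste0(fa, ".bwt"))) {
    out <- system2("bwa", c("index", shQuote(fa)), stdout = TRUE, stderr = TRUE)
    if (!file.exists(paste0(fa, ".bwt")))
      stopf("bwa index failed: %s", paste(utils::tail(out, 3), collapse = " | "))
  }
  align_pairs <- function(df) {
    stopifnot(all(c("qname", "seq1", "seq2") %in% names(df)))
    if (!nrow(df)) return(empty_pair_alignment())
    fq1 <- file.path(work_dir, "batch_R1.fq")
    fq2 <- file.path(work_dir, "batch_R2.fq")
    write_fastq(df$qname, df$seq1, fq1)
    write_fastq(df$qname, df$seq2, fq2)
    sam <- file.path(work_dir, "batch.sam")
    err <- system2("bwa", c("mem", "-t", "1", "-v", "1", shQuote(fa),
                            shQuote(fq1), shQuote(fq2)),
                   stdout = sam, stderr = FALSE)
    if (!identical(err, 0L)) stopf("bwa mem failed (exit %s)", err)
    aln <- read_sam_pairs(sam)
    # return rows in input order; pairs bwa could not place at all come back
    # as unmapped rather than silently disappearing
    m <- match(df$qname, aln$qname)
    out <- aln[ifelse(is.na(m), 1L, m), , drop = FALSE]
    if (anyNA(m)) {
      out[is.na(m), setdiff(names(out), "qname")] <- NA
      out$mapped1[is.na(m)] <- FALSE
      out$mapped2[is.na(m)] <- FALSE
    }
    out$qname <- df$qname
    rownames(out) <- NULL
    out
  }
  structure(list(align_pairs = align_pairs, name = "bwa-mem",
                 genome_fasta = fa, work_dir = work_dir),
            class = "aschip_aligner")
}

#' Exact-match paired-end aligner in pure R
#'
#' Finds exact occurrences of each mate on both strands of the reference with
#' `Biostrings` matching. A mate is uniquely mapped (mapq 60) when it has
#' exactly one exact occurrence genome-wide; multiple occurrences give mapq 0,
#' none give unmapped. Suited to desk-scale tests on synthetic genomes;
#' sequences containing alleles absent from the reference are reported
#' unmapped (use [bwa_aligner()] for indel-tolerant remapping).
#'
#' @param genome Anything [load_genome()] accepts.
#' @return An `aschip_aligner`.
#' @export
exact_aligner <- function(genome) {
  g <- load_genome(genome)
  subj <- Biostrings::DNAStringSet(g)
  align_one_set <- function(seqs) {
    res <- data.frame(chrom = NA_character_, pos = NA_integer_,
                      strand = NA_character_, mapq = 0L, cigar = NA_character_,
                      mapped = FALSE, stringsAsFactors = FALSE)[rep(1L, length(seqs)), ]
    rownames(res) <- NULL
    uq <- unique(seqs)
    for (s in uq) {
      hits <- list()
      for (ci in seq_along(subj)) {
        f <- Biostrings::matchPattern(s, subj[[ci]])
        if (length(f)) hits[[length(hits) + 1L]] <-
            data.frame(chrom = names(g)[ci], pos = Biostrings::start(f), strand = "+")
        r <- Biostrings::matchPattern(as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(s))), subj[[ci]])
        if (length(r)) hits[[length(hits) + 1L]] <-
            data.frame(chrom = names(g)[ci], pos = Biostrings::start(r), strand = "-")
      }
      hits <- if (length(hits)) do.call(rbind, hits) else NULL
      idx <- which(seqs == s)
      if (is.null(hits)) next
      if (nrow(hits) == 1L) {
        res$chrom[idx] <- hits$chrom; res$pos[idx] <- hits$pos
        res$strand[idx] <- hits$strand; res$mapq[idx] <- 60L
        res$cigar[idx] <- paste0(nchar(s), "M"); res$mapped[idx] <- TRUE
      } else {
        res$chrom[idx] <- hits$chrom[1L]; res$pos[idx] <- hits$pos[1L]
        res$strand[idx] <- hits$strand[1L]; res$mapq[idx] <- 0L
        res$cigar[idx] <- paste0(nchar(s), "M"); res$mapped[idx] <- TRUE
      }
    }
    res
  }
  align_pairs <- function(df) {
    if (!nrow(df)) return(empty_pair_alignment())
    a1 <- align_one_set(df$seq1)
    a2 <- align_one_set(df$seq2)
    data.frame(qname = df$qname,
               chrom1 = a1$chrom, pos1 = a1$pos, strand1 = a1$strand,
               mapq1 = a1$mapq, cigar1 = a1$cigar, mapped1 = a1$mapped,
               chrom2 = a2$chrom, pos2 = a2$pos, strand2 = a2$strand,
               mapq2 = a2$mapq, cigar2 = a2$cigar, mapped2 = a2$mapped,
               stringsAsFactors = FALSE)
  }
  structure(list(align_pairs = align_pairs, name = "exact-match",
                 genome_fasta = NULL),
            class = "aschip_aligner")
}

#' Ungapped mismatch-tolerant aligner in pure R
#'
#' Matches each mate against both strands of the reference allowing up to
#' `max_mismatch` substitutions but no gaps (`Biostrings` inexact matching).
#' Unique hits get mapq 60, multiple hits mapq 0, none unmapped. Because it
#' cannot place gapped reads, it reproduces at desk scale the behaviour of an
#' ungapped mapper: reads carrying alternative indel alleles go unmapped,
#' which is exactly the reference-bias failure mode the allele-swap remap
#' filter is designed to remove.
#'
#' @param genome Anything [load_genome()] accepts.
#' @param max_mismatch Maximum substitutions per mate (default 3).
#' @return An `aschip_aligner`.
#' @export
mismatch_aligner <- function(genome, max_mismatch = 3L) {
  g <- load_genome(genome)
  subj <- Biostrings::DNAStringSet(g)
  align_one_set <- function(seqs) {
    res <- data.frame(chrom = NA_character_, pos = NA_integer_,
                      strand = NA_character_, mapq = 0L, cigar = NA_character_,
                      mapped = FALSE,
                      stringsAsFactors = FALSE)[rep(1L, length(seqs)), ]
    rownames(res) <- NULL
    for (s in unique(seqs)) {
      hits <- list()
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      for (ci in seq_along(subj)) {
        for (st in c("+", "-")) {
          pat <- if (st == "+") s else rc
          h <- Biostrings::matchPattern(pat, subj[[ci]],
                                        max.mismatch = max_mismatch)
          if (length(h)) hits[[length(hits) + 1L]] <-
              data.frame(chrom = names(g)[ci], pos = Biostrings::start(h),
                         strand = st,
                         nmis = Biostrings::neditAt(pat, subj[[ci]],
                                                    at = Biostrings::start(h)))
        }
      }
      idx <- which(seqs == s)
      if (!length(hits)) next
      hits <- do.call(rbind, hits)
      hits <- hits[hits$nmis == min(hits$nmis), , drop = FALSE]
      res$chrom[idx] <- hits$chrom[1L]; res$pos[idx] <- hits$pos[1L]
      res$strand[idx] <- hits$strand[1L]
      res$mapq[idx] <- if (nrow(hits) == 1L) 60L else 0L
      res$cigar[idx] <- paste0(nchar(s), "M")
      res$mapped[idx] <- TRUE
    }
    res
  }
  align_pairs <- function(df) {
    if (!nrow(df)) return(empty_pair_alignment())
    a1 <- align_one_set(df$seq1)
    a2 <- align_one_set(df$seq2)
    data.frame(qname = df$qname,
               chrom1 = a1$chrom, pos1 = a1$pos, strand1 = a1$strand,
               mapq1 = a1$mapq, cigar1 = a1$cigar, mapped1 = a1$mapped,
               chrom2 = a2$chrom, pos2 = a2$pos, strand2 = a2$strand,
               mapq2 = a2$mapq, cigar2 = a2$cigar, mapped2 = a2$mapped,
               stringsAsFactors = FALSE)
  }
  structure(list(align_pairs = align_pairs,
                 name = sprintf("ungapped(max_mismatch=%d)", max_mismatch),
                 genome_fasta = NULL),
            class = "aschip_aligner")
}

#' @export
print.aschip_aligner <- function(x, ...) {
  cat(sprintf("aligner interface: %s\n", x$name)); invisible(x)
}

empty_pair_alignment <- function() {
  data.frame(qname = character(), chrom1 = character(), pos1 = integer(),
             strand1 = character(), mapq1 = integer(), cigar1 = character(),
             mapped1 = logical(), chrom2 = character(), pos2 = integer(),
             strand2 = character(), mapq2 = integer(), cigar2 = character(),
             mapped2 = logical(), stringsAsFactors = FALSE)
}
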