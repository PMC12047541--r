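# Sequence/alignment I/O. Internally read pairs live in a plain data.frame
# ("pair table") with one row per pair: qname, chrom1/pos1/strand1/cigar1/
# mapq1/seq1/qual1 and the mate-2 equivalents, plus mapped1/mapped2.
# Sequences follow the SAM convention (stored on the reference strand).

#' Write sequences to FASTA
#' @param genome Named character vector (or [load_genome()] input).
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  g <- load_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unclass(g)), path)
  invisible(path)
}

write_fastq <- function(qname, seq, path, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  writeLines(paste0("@", qname, "\n", seq, "\n+\n", qual), path)
  invisible(path)
}

# reference-space width of a CIGAR string (vectorised; NA-safe)
cigar_ref_width <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok))
    out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  out
}

# strand-aware 5' anchor coordinate of a mate
anchor_pos <- function(pos, strand, cigar) {
  ifelse(strand == "-", pos + cigar_ref_width(cigar) - 1L, pos)
}

#' Read paired-end alignments from SAM or BAM into a pair table
#'
#' Primary alignments only; mates are joined by read name. SAM input is
#' converted through `Rsamtools::asBam()`.
#'
#' @param path SAM or BAM file.
#' @return Pair table data.frame (one row per read pair).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile("aln_"), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(Rsamtools::BamFile(bam, yieldSize = NA),
                          param = Rsamtools::ScanBamParam(
                            what = c("qname", "flag", "rname", "strand", "pos",
                                     "mapq", "cigar", "seq", "qual")))[[1]]
  keep <- bitwAnd(b$flag, 256L + 2048L) == 0L
  d <- data.frame(qname = b$qname[keep], flag = b$flag[keep],
                  chrom = as.character(b$rname[keep]),
                  pos = b$pos[keep],
                  strand = as.character(b$strand[keep]),
                  mapq = b$mapq[keep], cigar = b$cigar[keep],
                  seq = as.character(b$seq)[keep],
                  qual = as.character(b$qual)[keep],
                  stringsAsFactors = FALSE)
  d$mapped <- bitwAnd(d$flag, 4L) == 0L
  d$strand[!d$mapped] <- NA_character_
  first <- bitwAnd(d$flag, 64L) != 0L
  d1 <- d[first, , drop = FALSE]
  d2 <- d[!first, , drop = FALSE]
  m <- match(d1$qname, d2$qname)
  pick <- function(x, col) x[[col]]
  out <- data.frame(qname = d1$qname,
                    chrom1 = d1$chrom, pos1 = d1$pos, strand1 = d1$strand,
                    mapq1 = d1$mapq, cigar1 = d1$cigar, seq1 = d1$seq,
                    qual1 = d1$qual, mapped1 = d1$mapped,
                    stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "strand", "mapq", "cigar", "seq", "qual",
                "mapped")) {
    out[[paste0(col, "2")]] <- pick(d2, col)[m]
  }
  out$mapped2[is.na(out$mapped2)] <- FALSE
  rownames(out) <- NULL
  out
}

# minimal pair view used for remap comparison (from a freshly written SAM)
read_sam_pairs <- function(path) {
  a <- read_alignments(path)
  a[, c("qname", "chrom1", "pos1", "strand1", "mapq1", "cigar1", "mapped1",
        "chrom2", "pos2", "strand2", "mapq2", "cigar2", "mapped2")]
}

#' Write a pair table to a SAM file
#'
#' @param aln Pair table (see [read_alignments()]).
#' @param path Output path (`.sam`).
#' @param contigs Named integer vector of contig lengths for the header.
#' @export
write_sam <- function(aln, path, contigs) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  qual1 <- if ("qual1" %in% names(aln)) aln$qual1 else strrep("I", nchar(aln$seq1))
  qual2 <- if ("qual2" %in% names(aln)) aln$qual2 else strrep("I", nchar(aln$seq2))
  rev1 <- !is.na(aln$strand1) & aln$strand1 == "-"
  rev2 <- !is.na(aln$strand2) & aln$strand2 == "-"
  proper <- aln$mapped1 & aln$mapped2
  flag1 <- 1L + 64L + ifelse(proper, 2L, 0L) + ifelse(rev1, 16L, 0L) +
    ifelse(rev2, 32L, 0L) + ifelse(aln$mapped1, 0L, 4L) + ifelse(aln$mapped2, 0L, 8L)
  flag2 <- 1L + 128L + ifelse(proper, 2L, 0L) + ifelse(rev2, 16L, 0L) +
    ifelse(rev1, 32L, 0L) + ifelse(aln$mapped2, 0L, 4L) + ifelse(aln$mapped1, 0L, 8L)
  line <- function(qn, flag, chrom, pos, mapq, cigar, mchrom, mpos, seq, qual) {
    paste(qn, flag,
          ifelse(is.na(chrom), "*", chrom),
          ifelse(is.na(pos), 0L, pos),
          ifelse(is.na(mapq), 0L, mapq),
          ifelse(is.na(cigar), "*", cigar),
          ifelse(is.na(mchrom), "*", "="),
          ifelse(is.na(mpos), 0L, mpos), 0L, seq, qual, sep = "\t")
  }
  l1 <- line(aln$qname, flag1, aln$chrom1, aln$pos1, aln$mapq1, aln$cigar1,
             aln$chrom2, aln$pos2, aln$seq1, qual1)
  l2 <- line(aln$qname, flag2, aln$chrom2, aln$pos2, aln$mapq2, aln$cigar2,
             aln$chrom1, aln$pos1, aln$seq2, qual2)
  writeLines(c(hdr, as.vector(rbind(l1, l2))), path)
  invisible(path)
}
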