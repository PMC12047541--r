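#' Classify a biallelic variant
#'
#' @param ref,alt Character vectors of REF/ALT allele strings.
#' @return `"snp"`, `"insertion"` or `"deletion"` per element.
#' @export
variant_kind <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "snp", ifelse(la > lr, "insertion", "deletion"))
}

variant_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

validate_variants <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  bad <- !grepl("^[ACGT]+$", v$ref) | !grepl("^[ACGT]+$", v$alt) | v$ref == v$alt |
    (nchar(v$ref) == nchar(v$alt) & nchar(v$ref) > 1L)  # MNPs not supported
  if (any(bad)) stopf("invalid REF/ALT alleles at rows: %s",
                      paste(utils::head(which(bad), 5), collapse = ", "))
  v$kind <- variant_kind(v$ref, v$alt)
  v$id <- variant_id(v$chrom, v$pos, v$ref, v$alt)
  v
}

#' Construct a phased genotype panel
#'
#' A panel holds an ordered variant table plus, for every sample, the fully
#' phased maternal and paternal allele (0 = REF, 1 = ALT) at every variant.
#' A sample is heterozygous at a variant iff the two alleles differ.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based position of
#'   the first REF base), `ref`, `alt`.
#' @param samples Character vector of sample names.
#' @param gt_m,gt_p Integer matrices (variants x samples) of maternal and
#'   paternal alleles, entries in `{0, 1}`.
#' @param dropped Named integer vector of records dropped upstream (bookkeeping).
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(variants, samples, gt_m, gt_p, dropped = integer()) {
  variants <- validate_variants(variants)
  gt_m <- as.matrix(gt_m); gt_p <- as.matrix(gt_p)
  stopifnot(nrow(gt_m) == nrow(variants), nrow(gt_p) == nrow(variants),
            ncol(gt_m) == length(samples), ncol(gt_p) == length(samples),
            all(gt_m %in% 0:1), all(gt_p %in% 0:1))
  dimnames(gt_m) <- dimnames(gt_p) <- list(variants$id, samples)
  structure(list(variants = variants, samples = samples,
                 gt_m = gt_m, gt_p = gt_p, dropped = dropped),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("Phased genotype panel: %d variants (%d SNPs, %d indels), %d samples\n",
              nrow(x$variants), sum(x$variants$kind == "snp"),
              sum(x$variants$kind != "snp"), length(x$samples)))
  if (length(x$dropped))
    cat("  dropped records:",
        paste(sprintf("%s=%d", names(x$dropped), x$dropped), collapse = ", "), "\n")
  invisible(x)
}

#' Heterozygosity matrix of a panel
#'
#' @param panel A [phased_panel()].
#' @return Logical matrix (variants x samples); TRUE where the sample is het.
#' @export
het_matrix <- function(panel) panel$gt_m != panel$gt_p

#' Genotype dosage matrix (ALT allele copies, 0/1/2)
#' @param panel A [phased_panel()].
#' @export
dosage_matrix <- function(panel) panel$gt_m + panel$gt_p

#' Load a phased variant panel from a VCF file
#'
#' Reads a VCF with phased `GT` fields (`|` separator). Multiallelic records
#' and records with missing genotypes are dropped (and counted) when
#' `require_biallelic` is set; unphased heterozygous genotypes (`0/1`) are an
#' error unless `assume_parental_phase` is set, in which case `a/b` is taken
#' as `a|b` (only safe when genotypes derive from homozygous parents).
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @param require_biallelic Drop multiallelic / missing-GT records (default TRUE).
#' @param assume_parental_phase Accept `/`-separated genotypes as phased.
#' @return A [phased_panel()]; dropped-record counts in `$dropped`.
#' @export
load_variants <- function(vcf_path, require_biallelic = TRUE,
                          assume_parental_phase = FALSE) {
  if (!file.exists(vcf_path)) stopf("VCF not found: %s", vcf_path)
  v <- try(vcfR::read.vcfR(vcf_path, verbose = FALSE), silent = TRUE)
  if (inherits(v, "try-error"))
    stopf("malformed VCF %s: %s", vcf_path, attr(v, "condition")$message)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stopf("VCF %s has no genotype columns", vcf_path)
  samples <- colnames(gt)[-1L]
  # extract the GT subfield
  gt_field <- apply(gt[, -1L, drop = FALSE], 2, function(col)
    vapply(strsplit(col, ":", fixed = TRUE), `[`, "", 1L))
  gt_field <- matrix(gt_field, ncol = length(samples))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  missing_gt <- apply(gt_field, 1, function(r) any(is.na(r) | grepl("\\.", r)))
  symbolic <- !grepl("^[ACGT]+$", fix$REF) | (!multi & !grepl("^[ACGT]+$", fix$ALT))
  drop <- if (require_biallelic) multi | missing_gt | symbolic else symbolic
  dropped <- c(multiallelic = sum(multi & require_biallelic),
               missing_gt = sum(missing_gt & !multi & require_biallelic),
               non_sequence = sum(symbolic & !multi & !missing_gt))
  keep <- !drop
  if (!any(keep)) stopf("no usable records in %s", vcf_path)

  gtk <- gt_field[keep, , drop = FALSE]
  unphased_het <- grepl("^([01])/([01])$", gtk) &
    sub("^(.)/(.)$", "\\1", gtk) != sub("^(.)/(.)$", "\\2", gtk)
  if (any(unphased_het) && !assume_parental_phase)
    stopf("unphased heterozygous genotype (e.g. '0/1') at %d records; rerun with assume_parental_phase = TRUE only if phase is implied by parental homozygosity",
          sum(rowSums(matrix(unphased_het, nrow = nrow(gtk))) > 0))
  gtk <- gsub("/", "|", gtk, fixed = TRUE)
  ok <- grepl("^[01]\\|[01]$", gtk)
  if (!all(ok)) stopf("unparseable GT value '%s'", gtk[which(!ok)[1L]])

  gm <- matrix(as.integer(substr(gtk, 1L, 1L)), ncol = length(samples))
  gp <- matrix(as.integer(substr(gtk, 3L, 3L)), ncol = length(samples))
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  phased_panel(variants, samples, gm, gp, dropped = dropped)
}

#' Phase F1 genotypes from homozygous parental genotypes
#'
#' For crosses of inbred lines every variant is phase-resolved: the F1
#' genotype at a variant is (maternal allele | paternal allele). Variants at
#' which any involved parent is heterozygous or missing are excluded and
#' counted, never guessed.
#'
#' @param variants data.frame of candidate variants (`chrom`, `pos`, `ref`, `alt`).
#' @param maternal_gts Character vector of maternal genotypes (`"0/0"`, `"1/1"`,
#'   `"0|0"`, ...), parallel to `variants`.
#' @param paternal_gts Either one such vector (a single cross) or a named list
#'   of vectors, one per paternal line; crosses share the maternal line.
#' @return A [phased_panel()] of the F1 samples; excluded-variant count in
#'   `$dropped["parent_het_or_missing"]`.
#' @export
phase_f1 <- function(variants, maternal_gts, paternal_gts) {
  if (!is.list(paternal_gts)) paternal_gts <- list(F1 = paternal_gts)
  if (is.null(names(paternal_gts)))
    names(paternal_gts) <- paste0("F1_", seq_along(paternal_gts))
  hom_allele <- function(g) {
    # "0/0"->0, "1|1"->1, anything else (het, missing) -> NA
    a <- sub("^(.)[/|](.)$", "\\1", g); b <- sub("^(.)[/|](.)$", "\\2", g)
    out <- ifelse(a == b & a %in% c("0", "1"), as.integer(a), NA_integer_)
    out[!grepl("^[01.][/|][01.]$", g)] <- NA_integer_
    out
  }
  m <- hom_allele(maternal_gts)
  p <- vapply(paternal_gts, hom_allele, integer(nrow(variants)))
  p <- matrix(p, ncol = length(paternal_gts),
              dimnames = list(NULL, names(paternal_gts)))
  keep <- !is.na(m) & !apply(p, 1, anyNA)
  n_excl <- sum(!keep)
  gm <- matrix(rep(m[keep], ncol(p)), ncol = ncol(p))
  gp <- p[keep, , drop = FALSE]
  phased_panel(variants[keep, , drop = FALSE], names(paternal_gts), gm, gp,
               dropped = c(parent_het_or_missing = n_excl))
}

#' Load a genome into a named vector of chromosome sequences
#'
#' @param genome A FASTA path, a `DNAStringSet`, or a named character vector.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
load_genome <- function(genome) {
  if (inherits(genome, "aschip_genome")) return(genome)   # already normalised
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTN]+$", genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    names(gs) <- sub("\\s.*$", "", names(gs))
    return(structure(toupper(as.character(gs)), class = "aschip_genome"))
  }
  if (inherits(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(structure(out, class = "aschip_genome"))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  structure(toupper(genome), class = "aschip_genome")
}

#' Build a haplotype sequence over a reference window
#'
#' Applies the chosen allele (0 = REF, 1 = ALT) of each variant to the
#' reference substring `[start, end]` (1-based inclusive) and returns the
#' haplotype sequence plus a bidirectional coordinate map accounting for indel
#' length shifts. Choosing all-0 returns the reference substring verbatim.
#'
#' @param genome See [load_genome()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive reference window.
#' @param variants data.frame (`pos`, `ref`, `alt`) of variants whose REF span
#'   lies inside the window; must be non-overlapping on the reference.
#' @param alleles Integer vector of 0/1 choices parallel to `variants`.
#' @return List with `seq` (character), `ref_to_hap` and `hap_to_ref`
#'   (integer vectors mapping window-local 1-based offsets; NA for bases
#'   deleted from / inserted into the haplotype).
#' @export
haplotype_sequence <- function(genome, chrom, start, end, variants = NULL,
                               alleles = NULL) {
  g <- load_genome(genome)
  if (!chrom %in% names(g)) stopf("unknown chromosome '%s'", chrom)
  refseq <- substr(g[[chrom]], start, end)
  w <- end - start + 1L
  if (is.null(variants) || nrow(variants) == 0L || is.null(alleles) ||
      !any(alleles == 1L)) {
    return(list(seq = refseq, ref_to_hap = seq_len(w), hap_to_ref = seq_len(w)))
  }
  stopifnot(nrow(variants) == length(alleles))
  v <- variants[alleles == 1L, , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  vend <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos < start) || any(vend > end))
    stopf("variant outside window [%d,%d]", start, end)
  if (nrow(v) > 1L && any(v$pos[-1L] <= vend[-nrow(v)])) {
    i <- which(v$pos[-1L] <= vend[-nrow(v)])[1L]
    stopf("overlapping variants: %s, %s",
          variant_id(chrom, v$pos[i], v$ref[i], v$alt[i]),
          variant_id(chrom, v$pos[i + 1L], v$ref[i + 1L], v$alt[i + 1L]))
  }
  # verify REF matches the genome
  obs <- substr_vec(g[[chrom]], v$pos, vend)
  if (any(obs != v$ref))
    stopf("REF allele mismatch with genome at %s:%d (VCF '%s', genome '%s')",
          chrom, v$pos[which(obs != v$ref)[1L]],
          v$ref[which(obs != v$ref)[1L]], obs[which(obs != v$ref)[1L]])

  pieces <- character(0); r2h <- rep(NA_integer_, w); h2r <- integer(0)
  cur_ref <- start          # next unconsumed reference position
  cur_hap <- 0L             # haplotype length so far
  for (i in seq_len(nrow(v))) {
    if (v$pos[i] > cur_ref) {
      seg <- substr(g[[chrom]], cur_ref, v$pos[i] - 1L)
      n <- nchar(seg)
      r2h[(cur_ref - start + 1L):(v$pos[i] - start)] <- cur_hap + seq_len(n)
      h2r <- c(h2r, (cur_ref:(v$pos[i] - 1L)) - start + 1L)
      pieces <- c(pieces, seg); cur_hap <- cur_hap + n
    }
    nr <- nchar(v$ref[i]); na <- nchar(v$alt[i])
    shared <- min(nr, na)   # VCF convention: leading base(s) shared
    # map the shared leading bases 1:1; extra REF bases are deleted (NA),
    # extra ALT bases are insertions (map to NA in hap_to_ref)
    r2h[(v$pos[i] - start + 1L):(v$pos[i] - start + shared)] <- cur_hap + seq_len(shared)
    h2r <- c(h2r, (v$pos[i] - start + 1L):(v$pos[i] - start + shared))
    if (na > shared) h2r <- c(h2r, rep(NA_integer_, na - shared))
    pieces <- c(pieces, v$alt[i]); cur_hap <- cur_hap + na
    cur_ref <- v$pos[i] + nr
  }
  if (cur_ref <= end) {
    seg <- substr(g[[chrom]], cur_ref, end)
    n <- nchar(seg)
    r2h[(cur_ref - start + 1L):(end - start + 1L)] <- cur_hap + seq_len(n)
    h2r <- c(h2r, (cur_ref:end) - start + 1L)
    pieces <- c(pieces, seg)
  }
  list(seq = paste(pieces, collapse = ""), ref_to_hap = r2h, hap_to_ref = h2r)
}

#' Write a panel to a phased VCF file
#'
#' @param panel A [phased_panel()].
#' @param path Output path (plain-text VCF).
#' @param contigs Optional named integer vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path, contigs = NULL) {
  v <- panel$variants
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$samples), collapse = "\t"))
  gt <- matrix(paste0(panel$gt_m, "|", panel$gt_p), nrow = nrow(v))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a panel as TSV
#' @param panel A [phased_panel()].
#' @param path Output path.
#' @export
write_panel_tsv <- function(panel, path) {
  gt <- matrix(paste0(panel$gt_m, "|", panel$gt_p), nrow = nrow(panel$variants),
               dimnames = list(NULL, panel$samples))
  utils::write.table(cbind(panel$variants, gt), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
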