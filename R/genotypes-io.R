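#' Read a genotype panel from PLINK or VCF files
#'
#' Reads diploid biallelic SNP genotypes into a [GenotypePanel-class].
#' Allele counts are copies of the counted allele: PLINK's A1 allele, or the
#' VCF ALT allele (so VCF genotypes 0/0, 0/1, 1/1 become 0, 1, 2).
#' Multi-allelic VCF records are skipped with a warning; missing genotypes
#' are imputed to the rounded per-SNP mean dosage. An import report (number
#' of imputed genotypes and skipped records) is stored in the panel
#' metadata under `importReport`. SNPs are sorted by chromosome and
#' position; `sampleOrder` is the file order.
#'
#' @param path for `format = "plink"`, the file prefix (without extension)
#'   of a `.bed`/`.bim`/`.fam` triplet; for `format = "vcf"`, a VCF file
#'   (plain or gzipped).
#' @param format `"plink"` or `"vcf"`.
#' @return a [GenotypePanel-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") .readPlink(path) else .readVcf(path)
}

#' Write a genotype panel to PLINK or VCF files
#'
#' Inverse of [readGenotypes()]: `writeGenotypes` followed by
#' `readGenotypes` reproduces the allele counts exactly. A TSV SNP metadata
#' table (id, chrom, pos, freq) can be written alongside.
#'
#' @param panel a [GenotypePanel-class].
#' @param path file prefix (PLINK) or file name (VCF).
#' @param format `"plink"` or `"vcf"`.
#' @param snpTable optional path for a TSV SNP-metadata table.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(panel, path, format = c("plink", "vcf"),
                           snpTable = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  format <- match.arg(format)
  if (format == "plink") .writePlink(panel, path) else .writeVcf(panel, path)
  if (!is.null(snpTable))
    utils::write.table(snpInfo(panel), snpTable, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

# ---- PLINK bed/bim/fam ------------------------------------------------------
# SNP-major .bed; 2-bit codes per sample (low bits first within each byte):
# 00 = 2 copies of A1, 10 = 1 copy, 11 = 0 copies, 01 = missing.

.readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimTab <- utils::read.table(bim, stringsAsFactors = FALSE)
  if (ncol(bimTab) < 6) stop("malformed .bim: expected 6 columns")
  famTab <- utils::read.table(fam, stringsAsFactors = FALSE)
  p <- nrow(bimTab); n <- nrow(famTab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed: bad magic number")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bps <- ceiling(n / 4)                      # bytes per SNP
  if (length(raw) - 3 != bps * p)
    stop("malformed .bed: size inconsistent with .bim/.fam (", p, " SNPs, ",
         n, " samples)")
  body <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, nrow = 4 * bps, ncol = p)
  b <- matrix(body, nrow = bps)
  for (s in 0:3) codes[seq.int(s + 1, by = 4, length.out = bps), ] <-
      (b %/% 4L^s) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]   # samples x SNPs
  counts <- matrix(NA_integer_, n, p)
  counts[codes == 0L] <- 2L
  counts[codes == 2L] <- 1L
  counts[codes == 3L] <- 0L
  counts <- t(counts)                          # SNPs x samples
  nImputed <- .imputeMissing(counts)
  counts <- attr(nImputed, "counts")
  panel <- .assemblePanel(counts, chrom = as.character(bimTab[[1]]),
                          pos = as.integer(bimTab[[4]]),
                          snpId = as.character(bimTab[[2]]),
                          sampleId = as.character(famTab[[2]]),
                          nImputed = c(nImputed), nSkipped = 0L)
  panel
}

.writePlink <- function(panel, prefix) {
  counts <- alleleCounts(panel)
  info <- snpInfo(panel)
  n <- ncol(counts); p <- nrow(counts)
  chromNum <- sub("^chr", "", info$chrom)
  utils::write.table(
    data.frame(chromNum, info$id, 0, info$pos, "A", "B"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- colnames(counts)
  utils::write.table(data.frame(ids, ids, 0, 0, 0, -9), paste0(prefix, ".fam"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  cc <- t(counts)                                   # samples x SNPs
  codeS <- matrix(c(3L, 2L, 0L)[cc + 1L], nrow = n) # 0->11, 1->10, 2->00
  pad <- 4L * ceiling(n / 4) - n
  code <- rbind(codeS, matrix(3L, pad, p))          # pad with "0 copies"
  bps <- nrow(code) / 4
  bytes <- code[seq.int(1, by = 4, length.out = bps), , drop = FALSE] +
    4L * code[seq.int(2, by = 4, length.out = bps), , drop = FALSE] +
    16L * code[seq.int(3, by = 4, length.out = bps), , drop = FALSE] +
    64L * code[seq.int(4, by = 4, length.out = bps), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

# ---- VCF --------------------------------------------------------------------

.readVcf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  nSkipped <- sum(multi)
  if (nSkipped > 0)
    warning(nSkipped, " multi-allelic record(s) skipped")
  if (all(multi)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  alleles <- gsub("\\|", "/", gt)
  counts <- matrix(NA_integer_, nrow(alleles), ncol(alleles))
  counts[alleles %in% c("0/0")] <- 0L
  counts[alleles %in% c("0/1", "1/0")] <- 1L
  counts[alleles %in% c("1/1")] <- 2L
  bad <- !is.na(alleles) & !(alleles %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad)) {
    rec <- arrayInd(which(bad)[1], dim(alleles))[1]
    stop("malformed genotype '", alleles[which(bad)[1]], "' at record ",
         fix[rec, "CHROM"], ":", fix[rec, "POS"])
  }
  nImputed <- .imputeMissing(counts)
  counts <- attr(nImputed, "counts")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  .assemblePanel(counts, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                 snpId = ids, sampleId = colnames(gt),
                 nImputed = c(nImputed), nSkipped = nSkipped)
}

.writeVcf <- function(panel, path) {
  counts <- alleleCounts(panel)
  info <- snpInfo(panel)
  gtStrings <- matrix(c("0/0", "0/1", "1/1")[counts + 1L], nrow = nrow(counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(counts)), collapse = "\t")),
             con)
  body <- cbind(info$chrom, info$pos, info$id, "A", "B", ".", "PASS", ".",
                "GT", gtStrings)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# ---- shared helpers ---------------------------------------------------------

# rounded per-SNP mean-dosage imputation; returns count, counts via attr
.imputeMissing <- function(counts) {
  nImputed <- 0L
  miss <- which(is.na(counts), arr.ind = TRUE)
  if (nrow(miss)) {
    means <- rowMeans(counts, na.rm = TRUE)
    means[is.nan(means)] <- 0
    counts[miss] <- as.integer(pmin(2L, pmax(0L, round(means[miss[, 1]]))))
    nImputed <- nrow(miss)
  }
  structure(nImputed, counts = counts)
}

.assemblePanel <- function(counts, chrom, pos, snpId, sampleId, nImputed,
                           nSkipped) {
  colnames(counts) <- sampleId
  ord <- order(factor(chrom, levels = unique(chrom)), pos)
  panel <- GenotypePanel(counts[ord, , drop = FALSE], chrom = chrom[ord],
                         pos = pos[ord], snpId = snpId[ord],
                         sampleOrder = seq_len(ncol(counts)))
  metadata(panel)$importReport <- list(nImputed = nImputed,
                                       nMultiallelicSkipped = nSkipped)
  panel
}
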