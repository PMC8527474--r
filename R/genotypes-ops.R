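#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose minor allele frequency min(f, 1 - f) is greater than
#' or equal to `threshold` (the boundary is kept). Idempotent; SNP order is
#' preserved.
#'
#' @param panel a [GenotypePanel-class].
#' @param threshold MAF threshold in \[0, 0.5\]; the standard array-cleaning
#'   default is 0.01.
#' @return the filtered [GenotypePanel-class].
#' @export
filterByMAF <- function(panel, threshold = 0.01) {
  stopifnot(is(panel, "GenotypePanel"))
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  f <- snpFrequencies(panel)
  keep <- which(pmin(f, 1 - f) >= threshold)
  if (length(keep) == 0) stop("empty panel: all SNPs removed by MAF filter")
  if (length(keep) == nrow(panel)) return(panel)
  subsetSnps(panel, keep)
}

#' Center and scale genotypes
#'
#' Builds the regression design matrix x_ij = (w_ij - 2 f_j) /
#' sqrt(2 f_j (1 - f_j)), with frequencies f_j computed on the
#' `frequencySource` samples (by default all samples: in a
#' genomic-selection validation design all genotypes are observed; pass the
#' learning indices to standardize on the learning set only). Columns have
#' exactly mean zero over the frequency-source samples, and variance close
#' to 1 under Hardy-Weinberg-like sampling.
#'
#' @param panel a [GenotypePanel-class].
#' @param frequencySource integer sample indices frequencies are computed on.
#' @return a [StandardizedGenotypes-class] (samples x SNPs design matrix).
#' @export
standardizeGenotypes <- function(panel, frequencySource = seq_len(ncol(panel))) {
  stopifnot(is(panel, "GenotypePanel"))
  w <- alleleCounts(panel)
  f <- rowMeans(w[, frequencySource, drop = FALSE]) / 2
  if (any(f <= 0 | f >= 1))
    stop("monomorphic SNP within the frequency source; apply filterByMAF() first")
  centers <- 2 * f
  scales <- sqrt(2 * f * (1 - f))
  x <- t((w - centers) / scales)
  dimnames(x) <- list(colnames(w), rownames(w))
  new("StandardizedGenotypes", values = x, centers = centers, scales = scales,
      freqSource = as.integer(frequencySource))
}

#' Split samples into learning and validation sets by age rank
#'
#' Mirrors the holdout design of routine genomic selection: the oldest
#' `floor(learningFraction * n)` individuals (lowest `sampleOrder` ranks)
#' form the learning set and the youngest remainder the validation set.
#'
#' @param panel a [GenotypePanel-class].
#' @param learningFraction target learning fraction in (0, 1); default 0.8.
#' @return a [SplitSpec-class].
#' @export
splitByAge <- function(panel, learningFraction = 0.8) {
  stopifnot(is(panel, "GenotypePanel"))
  if (learningFraction <= 0 || learningFraction >= 1)
    stop("learningFraction must be in (0, 1)")
  n <- ncol(panel)
  if (n < 2) stop("need at least 2 samples to split")
  nl <- floor(learningFraction * n)
  ord <- order(sampleOrder(panel))
  new("SplitSpec", learning = sort(ord[seq_len(nl)]),
      validation = sort(ord[seq.int(nl + 1, n)]),
      learningFraction = learningFraction)
}
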