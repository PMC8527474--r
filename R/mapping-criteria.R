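#' Per-SNP maximum a posteriori class
#'
#' Assigns each SNP to its most probable effect-size class (1 = null,
#' 2 = small, 3 = medium, 4 = large); ties are broken toward the lowest
#' class index.
#'
#' @param pip a posterior inclusion probability matrix (rows sum to 1) or a
#'   single row.
#' @return integer class label(s).
#' @export
mapRule <- function(pip) {
  m <- .asPipMatrix(pip)
  max.col(m, ties.method = "first")
}

#' Per-SNP nonnull maximum a posteriori indicator
#'
#' A SNP is called nonnull when the merged nonnull mass exceeds one half:
#' 1 - PIP_i(1) > 0.5 (strict, so PIP_i(1) = 0.5 is called null).
#'
#' @inheritParams mapRule
#' @return integer 0/1 vector.
#' @export
nonnullMapRule <- function(pip) {
  m <- .asPipMatrix(pip)
  as.integer(1 - m[, 1] > 0.5)
}

.asPipMatrix <- function(pip) {
  m <- if (is.matrix(pip)) pip else matrix(pip, nrow = 1)
  if (any(m < 0)) stop("negative inclusion probabilities")
  if (any(abs(rowSums(m) - 1) > 1e-6)) stop("pip rows must sum to 1")
  m
}

#' Per-SNP posterior variance estimates
#'
#' The posterior variance of SNP i on the standardized scale is estimated
#' as V_i = posterior mean of beta_i^2, i.e. the sum of the posterior
#' variance and the squared posterior mean of the effect. The proportion of
#' genetic variance is V_i / sum_j V_j.
#'
#' @param summary a [PosteriorSummary-class].
#' @return list with `vHat` and `vProp`; `vProp` is NA (with a warning)
#'   when all V_i are zero.
#' @export
snpVarianceEstimates <- function(summary) {
  stopifnot(is(summary, "PosteriorSummary"))
  vHat <- betaSqMean(summary)
  tot <- sum(vHat)
  if (tot == 0) {
    warning("all posterior variances are zero: vProp undefined")
    vProp <- rep(NA_real_, length(vHat))
  } else vProp <- vHat / tot
  list(vHat = vHat, vProp = vProp)
}

#' Sliding-window neighborhood criteria
#'
#' For each SNP i, the neighborhood is the up-to-15 SNPs within +/-
#' `halfWidth` index positions on the same chromosome (truncated at
#' chromosome ends). The neighborhood representative i' is the window
#' member maximizing the per-SNP inclusion 1 - PIP(1) (ties broken toward
#' the window center, then the lower index). The neighborhood PIP vector is
#' i''s row; IP_i = 1 - PIP_i'(1); the neighborhood MAP rules apply
#' [mapRule()] / [nonnullMapRule()] to that row; the neighborhood variance
#' is the maximum V over the window.
#'
#' @param pip p x 4 posterior inclusion probability matrix.
#' @param vHat per-SNP posterior variances.
#' @param chrom chromosome label per SNP; SNPs must be ordered by
#'   chromosome then position.
#' @param halfWidth SNPs on each side (default 7).
#' @return data.frame with `nbIp`, `nbMap`, `nbMapNonnull`, `nbV`, the
#'   representative index `nbIndex`, and the neighborhood PIP columns
#'   `nbPip1..4`.
#' @export
neighborhoodSummary <- function(pip, vHat, chrom, halfWidth = 7L) {
  m <- .asPipMatrix(pip)
  p <- nrow(m)
  if (length(chrom) != p || length(vHat) != p)
    stop("pip, vHat and chrom must agree in length")
  if (is.unsorted(match(chrom, unique(chrom))))
    stop("SNPs must be grouped by chromosome in positional order")
  ip <- 1 - m[, 1]
  nbIndex <- integer(p); nbV <- numeric(p)
  for (i in seq_len(p)) {
    w <- .indexWindow(i, chrom, halfWidth)
    best <- w[ip[w] == max(ip[w])]
    if (length(best) > 1) {
      d <- abs(best - i)
      best <- best[d == min(d)]
      best <- min(best)
    }
    nbIndex[i] <- best
    nbV[i] <- max(vHat[w])
  }
  nbPip <- m[nbIndex, , drop = FALSE]
  out <- data.frame(nbIndex = nbIndex, nbIp = 1 - nbPip[, 1],
                    nbMap = mapRule(nbPip), nbMapNonnull = nonnullMapRule(nbPip),
                    nbV = nbV)
  colnames(nbPip) <- paste0("nbPip", seq_len(ncol(nbPip)))
  cbind(out, as.data.frame(nbPip, row.names = FALSE))
}

#' Weighted cumulative inclusion probability (CIP)
#'
#' Sliding-window statistic flagging regions whose nonnull assignments are
#' diluted over several SNPs in LD: for each SNP i,
#' CIP_i = sum over the window of (0 PIP(1) + 1e-4 PIP(2) + 1e-3 PIP(3) +
#' 1e-2 PIP(4)), i.e. each window member contributes its class PIPs
#' weighted by the class prior variance fractions. Windows truncate at
#' chromosome ends.
#'
#' @inheritParams neighborhoodSummary
#' @param weights per-class weights (default the prior variance fractions
#'   `c(0, 1e-4, 1e-3, 1e-2)`).
#' @return numeric CIP vector.
#' @export
cipStatistic <- function(pip, chrom, halfWidth = 7L,
                         weights = c(0, 1e-4, 1e-3, 1e-2)) {
  m <- .asPipMatrix(pip)
  if (length(weights) != ncol(m))
    stop("weights length must match the class count (", ncol(m), ")")
  if (length(chrom) != nrow(m)) stop("pip and chrom must agree in length")
  s <- drop(m %*% weights)
  unlist(lapply(split(seq_along(s), factor(chrom, levels = unique(chrom))),
                function(ix) {
                  x <- s[ix]; nc <- length(x)
                  cs <- cumsum(c(0, x))
                  lo <- pmax(1, seq_len(nc) - halfWidth)
                  hi <- pmin(nc, seq_len(nc) + halfWidth)
                  cs[hi + 1] - cs[lo]
                }), use.names = FALSE)
}

#' Lewontin D' between two biallelic loci
#'
#' D = p_AB - p_A p_B; D' = D / D_max with D_max =
#' max(-p_A p_B, -(1 - p_A)(1 - p_B)) when D < 0 and
#' min(p_A (1 - p_B), (1 - p_A) p_B) otherwise. D = 0 (including fixed
#' loci, where D_max = 0) returns D' = 0 by convention. Vectorized.
#'
#' @param pA,pB allele frequencies at the two loci.
#' @param pAB frequency of the haplotype carrying both alleles; must
#'   satisfy the Frechet bounds max(0, pA + pB - 1) <= pAB <= min(pA, pB).
#' @return D' value(s) in \[0, 1\].
#' @export
lewontinDprime <- function(pA, pB, pAB) {
  if (any(pA < 0 | pA > 1 | pB < 0 | pB > 1 | pAB < 0))
    stop("frequencies must be in [0, 1]")
  if (any(pAB > pmin(pA, pB) + 1e-9 | pAB < pmax(0, pA + pB - 1) - 1e-9))
    stop("inconsistent frequencies: pAB violates the Frechet bounds")
  d <- pAB - pA * pB
  dmax <- ifelse(d < 0, pmax(-pA * pB, -(1 - pA) * (1 - pB)),
                 pmin(pA * (1 - pB), (1 - pA) * pB))
  # exact arithmetic keeps D/Dmax in [0, 1]; clamp floating-point overshoot
  pmin(ifelse(d == 0 | dmax == 0, 0, d / dmax), 1)
}

#' Maximum D' of a QTL with its window neighbors
#'
#' Reference LD of a region: the maximum Lewontin D' between the QTL and
#' every other member of its 15-SNP window. Haplotype frequencies come from
#' the true phased haplotypes when the panel carries them (synthetic
#' panels), otherwise from a two-locus expectation-maximization fit on the
#' unphased genotype pairs.
#'
#' @param panel a [GenotypePanel-class].
#' @param qtlIndex SNP index of the QTL within the panel.
#' @param halfWidth half window width (default 7).
#' @param method `"auto"` (haplotypes when available), `"haplotype"`, or
#'   `"em"`.
#' @return maximum D' over the window neighbors.
#' @export
qtlLdContext <- function(panel, qtlIndex, halfWidth = 7L,
                         method = c("auto", "haplotype", "em")) {
  method <- match.arg(method)
  stopifnot(is(panel, "GenotypePanel"))
  chrom <- snpInfo(panel)$chrom
  w <- setdiff(.indexWindow(qtlIndex, chrom, halfWidth), qtlIndex)
  if (length(w) < 1) stop("window around the QTL has fewer than 2 SNPs")
  hap <- haplotypes(panel)
  useHap <- (method == "haplotype") ||
    (method == "auto" && !is.null(hap))
  if (useHap && is.null(hap)) stop("panel carries no phased haplotypes")
  if (useHap) {
    hq <- c(hap[qtlIndex, , ])
    dp <- vapply(w, function(j) {
      hj <- c(hap[j, , ])
      lewontinDprime(mean(hq), mean(hj), mean(hq & hj))
    }, numeric(1))
  } else {
    g <- alleleCounts(panel)
    dp <- vapply(w, function(j) {
      fr <- emHaplotypeFrequency(g[qtlIndex, ], g[j, ])
      lewontinDprime(fr["pA"], fr["pB"], fr["pAB"])
    }, numeric(1))
  }
  max(dp)
}

#' Two-locus haplotype frequency by expectation-maximization
#'
#' Estimates the AB haplotype frequency from unphased genotype dosage pairs
#' (only the double heterozygote is phase-ambiguous). Used for D'
#' computation on panels without phased haplotypes.
#'
#' @param g1,g2 allele-count vectors (0/1/2) at the two loci.
#' @param maxIter,tol EM controls.
#' @return named vector `c(pA, pB, pAB)`.
#' @export
emHaplotypeFrequency <- function(g1, g2, maxIter = 100L, tol = 1e-10) {
  stopifnot(length(g1) == length(g2))
  n <- length(g1)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  # known haplotype counts; the 2n haplotypes of the double het split
  # between AB/ab and Ab/aB phases with weight re-estimated each step
  nDH <- sum(g1 == 1 & g2 == 1)
  # unambiguous AB haplotype count over the 9 genotype cells
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  cAB <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"]
  pAB <- pA * pB
  for (it in seq_len(maxIter)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    num <- pAB * pab
    den <- num + pAb * paB
    w <- if (den > 0) num / den else 0.5   # P(double het is AB/ab phase)
    newPAB <- (cAB + w * nDH) / (2 * n)
    if (abs(newPAB - pAB) < tol) { pAB <- newPAB; break }
    pAB <- newPAB
  }
  c(pA = pA, pB = pB, pAB = max(min(pAB, min(pA, pB)), max(0, pA + pB - 1)))
}

#' Rank SNPs by a mapping statistic
#'
#' Indices of the `topN` largest values in descending order; ties broken by
#' ascending SNP index; if fewer than `topN` SNPs exist, all are returned.
#' The standard prioritization uses the top 10 by posterior variance V and
#' the top 150 by CIP (CIP values are shared across a window, so a larger
#' cut absorbs that redundancy).
#'
#' @param values per-SNP statistic.
#' @param topN number of SNPs to return.
#' @return integer index vector.
#' @export
rankCandidates <- function(values, topN) {
  if (length(values) == 0) stop("empty input")
  if (topN < 1) stop("topN must be >= 1")
  ord <- order(-values, seq_along(values))
  ord[seq_len(min(topN, length(values)))]
}

#' Assemble the full per-SNP criterion table
#'
#' Computes every mapping statistic from a posterior summary: per-SNP MAP
#' and nonnull-MAP calls, posterior variances V and their proportions,
#' the 15-SNP neighborhood criteria, and the CIP sliding-window statistic.
#' Optionally adds each SNP's maximum D' with its window neighbors (from
#' true haplotypes; quadratic in window width, so off by default).
#'
#' @param summary a [PosteriorSummary-class].
#' @param panel the [GenotypePanel-class] the model was fitted on (provides
#'   SNP order, chromosome and position).
#' @param halfWidth half window width (default 7).
#' @param weights CIP class weights.
#' @param dprime logical; add a `dprimeMax` column (needs haplotypes).
#' @return data.frame, one row per SNP.
#' @export
criterionTable <- function(summary, panel, halfWidth = 7L,
                           weights = c(0, 1e-4, 1e-3, 1e-2), dprime = FALSE) {
  stopifnot(is(summary, "PosteriorSummary"), is(panel, "GenotypePanel"))
  info <- snpInfo(panel)
  m <- pipMatrix(summary)
  if (nrow(m) != nrow(info))
    stop("summary and panel disagree on the number of SNPs")
  v <- snpVarianceEstimates(summary)
  nb <- neighborhoodSummary(m, v$vHat, info$chrom, halfWidth)
  out <- data.frame(snp = info$id, chrom = info$chrom, pos = info$pos,
                    mapClass = mapRule(m), mapNonnull = nonnullMapRule(m),
                    vHat = unname(v$vHat), vProp = unname(v$vProp),
                    row.names = NULL)
  out <- cbind(out, nb)
  out$cip <- cipStatistic(m, info$chrom, halfWidth, weights)
  if (dprime) {
    hap <- haplotypes(panel)
    if (is.null(hap)) stop("dprime = TRUE needs phased haplotypes")
    out$dprimeMax <- vapply(seq_len(nrow(info)), function(i) {
      w <- setdiff(.indexWindow(i, info$chrom, halfWidth), i)
      if (!length(w)) return(0)
      hi <- c(hap[i, , ])
      max(vapply(w, function(j) {
        hj <- c(hap[j, , ])
        lewontinDprime(mean(hi), mean(hj), mean(hi & hj))
      }, numeric(1)))
    }, numeric(1))
  }
  out
}
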