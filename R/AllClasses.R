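#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom stats rnorm runif rbinom var sd cor setNames
#' @importFrom utils head tail
NULL

#' GenotypePanel: allele-count matrix with SNP metadata and sample ordering
#'
#' A `GenotypePanel` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with a single `"counts"` assay holding per-SNP (rows) per-sample (columns)
#' copies of the counted allele, each entry in \{0, 1, 2\}. `rowRanges()`
#' carries the SNP identifier, chromosome and base-pair position, plus the
#' counted-allele frequency in `mcols()$freq`. `colData()$sampleOrder` is a
#' permutation of `1:n` standing in for age rank (lower = older), used by
#' [splitByAge()]. For panels built by [generateGenotypes()] the phased
#' founder-mosaic haplotypes are kept in `metadata()$haplotypes` so that
#' linkage disequilibrium can be measured on true haplotypes.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

.validGenotypePanel <- function(object) {
  msg <- character()
  a <- assay(object, "counts")
  if (!all(a %in% c(0L, 1L, 2L)))
    msg <- c(msg, "allele counts must all be in {0, 1, 2}")
  rr <- rowRanges(object)
  if (is.null(mcols(rr)$freq))
    msg <- c(msg, "rowRanges must carry mcols()$freq")
  else {
    f <- rowMeans(a) / 2
    if (max(abs(f - mcols(rr)$freq)) > 1e-8)
      msg <- c(msg, "stored freq does not match frequencies recomputed from counts")
  }
  pos <- split(start(rr), as.character(seqnames(rr)))
  if (!all(vapply(pos, function(x) all(diff(x) > 0), logical(1))))
    msg <- c(msg, "positions must strictly increase within each chromosome")
  so <- colData(object)$sampleOrder
  if (is.null(so) || !setequal(so, seq_len(ncol(object))))
    msg <- c(msg, "colData()$sampleOrder must be a permutation of 1..n")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param counts integer matrix of allele counts, SNPs in rows, samples in
#'   columns, entries in \{0,1,2\}.
#' @param chrom chromosome label per SNP.
#' @param pos 1-based base-pair position per SNP (strictly increasing within
#'   each chromosome).
#' @param snpId SNP identifiers; defaults to `snp1..snpP`.
#' @param sampleOrder permutation of `1:n`, age rank (1 = oldest); defaults to
#'   column order.
#' @param haplotypes optional phased haplotype array (`p x n x 2`, entries
#'   0/1) stored in `metadata()`.
#' @return a [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(counts, chrom, pos, snpId = NULL, sampleOrder = NULL,
                          haplotypes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  p <- nrow(counts); n <- ncol(counts)
  if (is.null(snpId)) snpId <- paste0("snp", seq_len(p))
  if (is.null(sampleOrder)) sampleOrder <- seq_len(n)
  rr <- GRanges(as.character(chrom), IRanges(start = pos, width = 1L))
  names(rr) <- snpId
  mcols(rr)$freq <- rowMeans(counts) / 2
  cd <- DataFrame(sampleOrder = as.integer(sampleOrder),
                  row.names = if (is.null(colnames(counts)))
                    paste0("sample", seq_len(n)) else colnames(counts))
  dimnames(counts) <- list(snpId, rownames(cd))
  se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = rr,
                             colData = cd)
  md <- list()
  if (!is.null(haplotypes)) md$haplotypes <- haplotypes
  metadata(se) <- md
  new("GenotypePanel", se)
}

#' StandardizedGenotypes: centered and scaled design matrix
#'
#' Holds the regression design matrix with samples in rows and SNPs in
#' columns, where column j is (w_ij - 2 f_j) / sqrt(2 f_j (1 - f_j)) with
#' f_j the counted-allele frequency computed on `freqSource` samples.
#'
#' @slot values numeric matrix, n x p (samples x SNPs).
#' @slot centers numeric, per-SNP 2 f_j.
#' @slot scales numeric, per-SNP sqrt(2 f_j (1 - f_j)), all > 0.
#' @slot freqSource integer indices of the samples frequencies came from.
#' @export
setClass("StandardizedGenotypes",
         representation(values = "matrix", centers = "numeric",
                        scales = "numeric", freqSource = "integer"),
         validity = function(object) {
           msg <- character()
           if (any(object@scales <= 0)) msg <- c(msg, "scales must be strictly positive")
           cm <- colMeans(object@values[object@freqSource, , drop = FALSE])
           if (length(cm) && max(abs(cm)) > 1e-8)
             msg <- c(msg, "columns must be centered over freqSource samples")
           if (length(msg)) msg else TRUE
         })

#' SplitSpec: age-ordered learning/validation partition
#'
#' @slot learning integer indices of the learning (oldest) samples.
#' @slot validation integer indices of the validation (youngest) samples.
#' @slot learningFraction target learning fraction.
#' @export
setClass("SplitSpec",
         representation(learning = "integer", validation = "integer",
                        learningFraction = "numeric"),
         validity = function(object) {
           n <- length(object@learning) + length(object@validation)
           if (!setequal(c(object@learning, object@validation), seq_len(n)))
             return("learning and validation must partition 1..n")
           TRUE
         })

#' LDModel: founder-mosaic model for synthetic LD-structured genotypes
#'
#' Individuals are built as two mosaic copies of a pool of founder
#' haplotypes; a copied haplotype switches template with probability
#' `switchRate` at each SNP, so smaller rates give longer shared segments
#' and stronger local LD.
#'
#' @slot nFounders number of founder haplotypes.
#' @slot switchRate per-SNP template switch probability, in (0, 1).
#' @slot founderCorrelation per-adjacent-SNP probability that a founder
#'   haplotype repeats its previous allele state, in \[0, 1); controls the
#'   LD carried by the founder pool itself (0 = independent loci).
#' @slot mafRange interval for founder allele frequencies, inside (0, 0.5].
#' @slot snpSpacingBp mean inter-SNP spacing in base pairs.
#' @slot nChromosomes number of chromosomes SNPs are spread over.
#' @export
setClass("LDModel",
         representation(nFounders = "integer", switchRate = "numeric",
                        founderCorrelation = "numeric", mafRange = "numeric",
                        snpSpacingBp = "numeric", nChromosomes = "integer"),
         validity = function(object) {
           msg <- character()
           if (object@switchRate <= 0 || object@switchRate >= 1)
             msg <- c(msg, "switchRate must be in (0, 1)")
           if (object@founderCorrelation < 0 || object@founderCorrelation >= 1)
             msg <- c(msg, "founderCorrelation must be in [0, 1)")
           mr <- object@mafRange
           if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2] ||
               (mr[1] == mr[2] && mr[1] == 0))
             msg <- c(msg, "mafRange must be a non-degenerate interval inside (0, 0.5]")
           if (object@snpSpacingBp <= 0) msg <- c(msg, "snpSpacingBp must be > 0")
           if (object@nFounders < 2) msg <- c(msg, "need at least 2 founder haplotypes")
           if (length(msg)) msg else TRUE
         })

#' Construct an LDModel
#'
#' Defaults give block-wise LD at the scale of a 15-SNP / ~1 Mb window on a
#' cattle-like 29-autosome panel: 40 founders with adjacent-locus allele
#' correlation 0.85 (LD blocks decaying over roughly 7-15 SNPs, the scale
#' the 15-SNP window criteria are designed around), switch rate 0.05,
#' founder MAF in [0.05, 0.5], 65 kb mean spacing.
#'
#' @param nFounders,switchRate,founderCorrelation,mafRange,snpSpacingBp,nChromosomes
#'   see slots.
#' @return an [LDModel-class].
#' @export
LDModel <- function(nFounders = 40L, switchRate = 0.05,
                    founderCorrelation = 0.85, mafRange = c(0.05, 0.5),
                    snpSpacingBp = 65000, nChromosomes = 29L) {
  new("LDModel", nFounders = as.integer(nFounders), switchRate = switchRate,
      founderCorrelation = founderCorrelation, mafRange = as.numeric(mafRange),
      snpSpacingBp = snpSpacingBp, nChromosomes = as.integer(nChromosomes))
}

#' Scenario: one cell of the simulation grid
#'
#' @slot k per-QTL fraction of the additive genetic variance sigma_g2.
#' @slot h2 heritability sigma_g2 / sigma_y2, in (0, 1).
#' @slot nQtl number of large QTLs.
#' @slot polyFraction per-polygenic-SNP fraction of sigma_g2.
#' @slot nPoly number of polygenic SNPs (derived via [polygenicCount()]).
#' @slot panelVariant `"fifty_k"` (QTL columns excluded, classic array) or
#'   `"fifty_k_custom"` (QTLs genotyped, custom array).
#' @slot repetition repetition id; scenarios sharing it share the QTL set.
#' @slot nIntermediate number of intermediate QTLs (0 disables).
#' @slot intermediateRelSize intermediate-QTL variance relative to k.
#' @slot sigmaY2 phenotypic variance.
#' @slot mu intercept.
#' @export
setClass("Scenario",
         representation(k = "numeric", h2 = "numeric", nQtl = "integer",
                        polyFraction = "numeric", nPoly = "integer",
                        panelVariant = "character", repetition = "integer",
                        nIntermediate = "integer", intermediateRelSize = "numeric",
                        sigmaY2 = "numeric", mu = "numeric"),
         validity = function(object) {
           msg <- character()
           if (object@h2 <= 0 || object@h2 >= 1) msg <- c(msg, "h2 must be in (0, 1)")
           if (object@k <= 0) msg <- c(msg, "k must be > 0")
           budget <- object@nQtl * object@k + object@nPoly * object@polyFraction +
             object@nIntermediate * object@intermediateRelSize * object@k
           if (budget > 1 + 1e-8)
             msg <- c(msg, "variance budget exceeds sigma_g2")
           if (!object@panelVariant %in% c("fifty_k", "fifty_k_custom"))
             msg <- c(msg, "panelVariant must be 'fifty_k' or 'fifty_k_custom'")
           if (length(msg)) msg else TRUE
         })

#' Construct a Scenario
#'
#' @param k per-QTL fraction of sigma_g2 (e.g. 0.02 for 2%).
#' @param h2 heritability.
#' @param nQtl number of large QTLs (default 5).
#' @param polyFraction per-polygenic-SNP fraction of sigma_g2 (default 1e-4).
#' @param nPoly polygenic SNP count; defaults to [polygenicCount()] so the
#'   variance budget sums to ~100%.
#' @param panelVariant `"fifty_k"` or `"fifty_k_custom"`.
#' @param repetition repetition id.
#' @param nIntermediate,intermediateRelSize optional intermediate QTLs whose
#'   per-QTL variance is `intermediateRelSize * k * sigma_g2` (default 0 and
#'   0.1); their budget is deducted from the polygenic pool.
#' @param sigmaY2 phenotypic variance (default 100).
#' @param mu intercept (default 0).
#' @return a [Scenario-class].
#' @export
Scenario <- function(k, h2, nQtl = 5L, polyFraction = 1e-4, nPoly = NULL,
                     panelVariant = "fifty_k", repetition = 1L,
                     nIntermediate = 0L, intermediateRelSize = 0.1,
                     sigmaY2 = 100, mu = 0) {
  if (is.null(nPoly))
    nPoly <- polygenicCount(k, nQtl, polyFraction,
                            nIntermediate = nIntermediate,
                            intermediateRelSize = intermediateRelSize)
  new("Scenario", k = k, h2 = h2, nQtl = as.integer(nQtl),
      polyFraction = polyFraction, nPoly = as.integer(nPoly),
      panelVariant = panelVariant, repetition = as.integer(repetition),
      nIntermediate = as.integer(nIntermediate),
      intermediateRelSize = intermediateRelSize, sigmaY2 = sigmaY2, mu = mu)
}

#' TraitArchitecture: realized causal SNPs, signs and effects
#'
#' Effects are on the standardized-genotype scale, so a causal SNP i with
#' effect beta_i contributes Var(x_i beta_i) = beta_i^2 to the additive
#' genetic variance: beta_i^2 = k sigma_g2 for large QTLs,
#' relSize * k * sigma_g2 for intermediate QTLs and
#' polyFraction * sigma_g2 for polygenic SNPs.
#'
#' @slot qtlIndices,intermediateIndices,polygenicIndices disjoint SNP indices.
#' @slot signs per-causal-SNP sign in \{-1, +1\} (named by SNP index).
#' @slot beta full length-p effect vector, zero outside causal SNPs.
#' @slot sigmaG2 additive genetic variance h2 * sigmaY2.
#' @slot sigmaE2 residual variance sigmaY2 - sigmaG2.
#' @export
setClass("TraitArchitecture",
         representation(qtlIndices = "integer", intermediateIndices = "integer",
                        polygenicIndices = "integer", signs = "numeric",
                        beta = "numeric", sigmaG2 = "numeric", sigmaE2 = "numeric"),
         validity = function(object) {
           msg <- character()
           causal <- c(object@qtlIndices, object@intermediateIndices,
                       object@polygenicIndices)
           causal <- causal[!is.na(causal)]   # NA marks a removed QTL column
           if (anyDuplicated(causal)) msg <- c(msg, "causal index sets must be disjoint")
           nz <- which(object@beta != 0)
           if (!all(nz %in% causal)) msg <- c(msg, "beta must be 0 outside causal SNPs")
           if (object@sigmaE2 < 0) msg <- c(msg, "sigmaE2 must be >= 0")
           if (length(msg)) msg else TRUE
         })

#' SimulatedDataset: one simulated phenotype dataset ready to fit
#'
#' @slot panel the [GenotypePanel-class] restricted to the variant's SNPs.
#' @slot y simulated phenotypes.
#' @slot architecture [TraitArchitecture-class] with indices mapped to the
#'   variant's SNP order (QTL indices are 0 when the QTL column was removed).
#' @slot split [SplitSpec-class].
#' @slot truthWindows list of per-QTL 15-SNP index windows into `panel`.
#' @slot scenario the generating [Scenario-class].
#' @export
setClass("SimulatedDataset",
         representation(panel = "GenotypePanel", y = "numeric",
                        architecture = "TraitArchitecture", split = "SplitSpec",
                        truthWindows = "list", scenario = "Scenario"))

#' MixturePrior: per-class variance fractions and Dirichlet pseudocounts
#'
#' Default is the BayesR four-class prior: effect variances
#' (0, 1e-4, 1e-3, 1e-2) x sigma_g2 and a flat Dirichlet(1,1,1,1) on the
#' mixing proportions.
#'
#' @slot varianceFractions per-class fraction of sigma_g2; first entry 0.
#' @slot dirichletAlpha Dirichlet pseudocounts, all > 0.
#' @export
setClass("MixturePrior",
         representation(varianceFractions = "numeric", dirichletAlpha = "numeric"),
         validity = function(object) {
           msg <- character()
           vf <- object@varianceFractions
           if (length(vf) < 2) msg <- c(msg, "need at least 2 classes")
           if (vf[1] != 0) msg <- c(msg, "first variance fraction must be exactly 0")
           if (any(diff(vf) <= 0)) msg <- c(msg, "variance fractions must strictly increase")
           if (length(object@dirichletAlpha) != length(vf))
             msg <- c(msg, "dirichletAlpha must match varianceFractions in length")
           if (any(object@dirichletAlpha <= 0)) msg <- c(msg, "alphas must be > 0")
           if (length(msg)) msg else TRUE
         })

#' @param varianceFractions,dirichletAlpha see slots.
#' @rdname MixturePrior-class
#' @export
MixturePrior <- function(varianceFractions = c(0, 1e-4, 1e-3, 1e-2),
                         dirichletAlpha = rep(1, length(varianceFractions))) {
  new("MixturePrior", varianceFractions = varianceFractions,
      dirichletAlpha = dirichletAlpha)
}

#' HyperPriors: scaled inverse-chi-square priors on variance components
#'
#' Defaults (nu0 = -2, S0 = 0) give improper flat priors on sigma_g2 and
#' sigma_e2.
#'
#' @slot sigmaG2Prior length-2 numeric (nu0, S0^2).
#' @slot sigmaE2Prior length-2 numeric (nu, S^2).
#' @export
setClass("HyperPriors",
         representation(sigmaG2Prior = "numeric", sigmaE2Prior = "numeric"))

#' @param sigmaG2Prior,sigmaE2Prior see slots.
#' @rdname HyperPriors-class
#' @export
HyperPriors <- function(sigmaG2Prior = c(-2, 0), sigmaE2Prior = c(-2, 0)) {
  new("HyperPriors", sigmaG2Prior = sigmaG2Prior, sigmaE2Prior = sigmaE2Prior)
}

#' GibbsConfig: MCMC run settings
#'
#' Defaults follow the full-scale protocol (50,000 iterations, 20,000
#' burn-in, thinning 10); desk-scale runs typically use 10,000 / 4,000 / 10.
#'
#' @slot nIter total Gibbs iterations.
#' @slot burnIn discarded initial iterations.
#' @slot thin thinning interval on retained iterations.
#' @slot seed RNG seed for the sampler.
#' @export
setClass("GibbsConfig",
         representation(nIter = "integer", burnIn = "integer", thin = "integer",
                        seed = "numeric"),
         validity = function(object) {
           msg <- character()
           if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
           if (object@thin < 1) msg <- c(msg, "thin must be >= 1")
           if (length(msg)) msg else TRUE
         })

#' @param nIter,burnIn,thin,seed see slots.
#' @rdname GibbsConfig-class
#' @export
GibbsConfig <- function(nIter = 50000L, burnIn = 20000L, thin = 10L, seed = 1) {
  new("GibbsConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.numeric(seed))
}

#' PosteriorSummary: posterior summaries from one MCMC run
#'
#' @slot pip p x K matrix of posterior class-inclusion probabilities; rows
#'   sum to 1. BayesCpi results are padded to 4 columns (zeros in the two
#'   middle columns) for compatibility with the mapping criteria.
#' @slot betaMean posterior mean effect per SNP.
#' @slot betaSqMean posterior mean of beta_i^2 (posterior variance plus
#'   squared posterior mean of the effect).
#' @slot classCountsMean posterior mean class cardinalities; sums to p.
#' @slot piMean posterior mean mixing proportions.
#' @slot sigmaG2Mean,sigmaE2Mean,muMean posterior means of the variance
#'   components and intercept.
#' @slot retainedDraws number of retained (post burn-in, thinned) draws.
#' @slot model `"bayesr"` or `"bayescpi"`.
#' @slot trace retained-draw traces (sigma_g2, sigma_e2, mu, nonnull count).
#' @export
setClass("PosteriorSummary",
         representation(pip = "matrix", betaMean = "numeric",
                        betaSqMean = "numeric", classCountsMean = "numeric",
                        piMean = "numeric", sigmaG2Mean = "numeric",
                        sigmaE2Mean = "numeric", muMean = "numeric",
                        retainedDraws = "integer", model = "character",
                        trace = "matrix"),
         validity = function(object) {
           msg <- character()
           rs <- rowSums(object@pip)
           if (length(rs) && max(abs(rs - 1)) > 1e-8)
             msg <- c(msg, "pip rows must sum to 1")
           if (abs(sum(object@classCountsMean) - nrow(object@pip)) > 1e-6)
             msg <- c(msg, "classCountsMean must sum to p")
           if (any(object@betaSqMean < object@betaMean^2 - 1e-10))
             msg <- c(msg, "betaSqMean must dominate betaMean^2")
           if (object@sigmaG2Mean < 0) msg <- c(msg, "sigmaG2Mean must be >= 0")
           if (length(msg)) msg else TRUE
         })

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object), "SNPs x", ncol(object), "samples\n")
  f <- mcols(rowRanges(object))$freq
  cat("  chromosomes:", length(unique(as.character(seqnames(rowRanges(object))))),
      " MAF range:", sprintf("[%.3f, %.3f]", min(pmin(f, 1 - f)), max(pmin(f, 1 - f))),
      "\n")
  if (!is.null(metadata(object)$haplotypes)) cat("  phased haplotypes available\n")
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary (%s): %d SNPs, %d retained draws\n",
              object@model, nrow(object@pip), object@retainedDraws))
  cat(sprintf("  sigma_g2 = %.3f  sigma_e2 = %.3f  mu = %.3f\n",
              object@sigmaG2Mean, object@sigmaE2Mean, object@muMean))
  cat("  mean class counts:", paste(sprintf("%.1f", object@classCountsMean),
                                    collapse = " / "), "\n")
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: k = %g, h2 = %g, %d QTLs + %d polygenic (%s), rep %d\n",
              object@k, object@h2, object@nQtl, object@nPoly,
              object@panelVariant, object@repetition))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d samples x %d SNPs, %d truth windows\n",
              length(object@y), nrow(object@panel), length(object@truthWindows)))
})
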