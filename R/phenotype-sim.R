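#' Number of polygenic SNPs for a given QTL architecture
#'
#' The simulation grid allocates the additive genetic variance sigma_g2
#' completely: `nQtl` large QTLs take a fraction `k` each (plus optional
#' intermediate QTLs at `intermediateRelSize * k` each) and the remainder is
#' split over polygenic SNPs carrying `polyFraction` each, so the count is
#' `floor((1 - nQtl*k - nIntermediate*intermediateRelSize*k) / polyFraction)`.
#' With the grid defaults (5 QTLs, 1e-4 per polygenic SNP) this gives 9637,
#' 9000 and 7500 polygenic SNPs at k = 0.725%, 2% and 5%.
#'
#' @param k per-QTL fraction of sigma_g2.
#' @param nQtl number of large QTLs (default 5).
#' @param polyFraction per-polygenic-SNP fraction of sigma_g2 (default 1e-4).
#' @param nIntermediate,intermediateRelSize optional intermediate QTLs.
#' @return integer polygenic SNP count.
#' @export
polygenicCount <- function(k, nQtl = 5L, polyFraction = 1e-4,
                           nIntermediate = 0L, intermediateRelSize = 0.1) {
  remainder <- 1 - nQtl * k - nIntermediate * intermediateRelSize * k
  if (remainder <= 0)
    stop("QTLs exhaust the variance budget: nQtl * k must be < 1")
  as.integer(floor(remainder / polyFraction))
}

#' Build a grid of simulation scenarios
#'
#' Cartesian product of QTL effect sizes, heritabilities, repetitions and
#' panel variants. Scenarios sharing a repetition id share the QTL set (and
#' their signs) once architectures are drawn with [sampleArchitecture()], so
#' comparisons across k, h2 and panel variant are paired. The full-scale
#' grid (13 k values, 4 heritabilities, 10 repetitions, 2 variants) has
#' 1040 cells.
#'
#' @param kValues distinct per-QTL variance fractions.
#' @param h2Values heritabilities.
#' @param nRepetitions repetitions per cell.
#' @param panelVariants subset of `c("fifty_k", "fifty_k_custom")`.
#' @param ... further arguments passed to [Scenario()] (e.g. `polyFraction`,
#'   `nQtl`, `nIntermediate`).
#' @return list of [Scenario-class] objects.
#' @examples
#' grid <- buildScenarioGrid(c(0.02, 0.05), c(0.3, 0.5), 2)
#' length(grid)  # 2 k x 2 h2 x 2 reps x 2 variants = 16
#' @export
buildScenarioGrid <- function(kValues = defaultKGrid(),
                              h2Values = c(0.1, 0.3, 0.5, 0.8),
                              nRepetitions = 10,
                              panelVariants = c("fifty_k", "fifty_k_custom"),
                              ...) {
  if (length(kValues) == 0 || length(h2Values) == 0 || nRepetitions < 1 ||
      length(panelVariants) == 0) stop("all grid dimensions must be non-empty")
  if (anyDuplicated(kValues)) stop("duplicate k values")
  cells <- expand.grid(variant = panelVariants, rep = seq_len(nRepetitions),
                       h2 = h2Values, k = kValues, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    Scenario(k = cells$k[i], h2 = cells$h2[i],
             panelVariant = cells$variant[i], repetition = cells$rep[i], ...))
}

#' The 13 per-QTL variance fractions of the standard grid
#'
#' Fractions of sigma_g2 per large QTL, denser between 0.725% and 2% where
#' QTL sizes are most plausible.
#'
#' @return numeric vector of length 13.
#' @export
defaultKGrid <- function() {
  c(0.00725, 0.009, 0.010, 0.011, 0.013, 0.015, 0.018,
    0.02, 0.025, 0.03, 0.035, 0.04, 0.05)
}

#' Draw a trait architecture for a scenario
#'
#' Causal SNPs are drawn uniformly without replacement from SNPs with
#' MAF >= 0.15 (frequent QTLs are targeted to limit the impact of extreme
#' MAFs on prediction and detection). The QTL set and its signs use a
#' repetition-level seed, so they are identical across scenarios sharing a
#' repetition id; the polygenic set and its signs use a scenario-level seed
#' and are re-drawn per scenario. Effects on the standardized scale are
#' beta_i = u_i * sqrt(v_i), with u_i uniform on \{-1, +1\} and v_i =
#' k * sigma_g2 for large QTLs, `intermediateRelSize * k * sigma_g2` for
#' intermediate QTLs and `polyFraction * sigma_g2` for polygenic SNPs, so
#' each causal SNP contributes exactly v_i to the genetic variance.
#'
#' @param panel a [GenotypePanel-class].
#' @param scenario a [Scenario-class].
#' @param seed master integer seed (repetition/scenario streams are derived
#'   from it deterministically).
#' @param mafMin causal-SNP MAF floor (default 0.15).
#' @return a [TraitArchitecture-class].
#' @export
sampleArchitecture <- function(panel, scenario, seed, mafMin = 0.15) {
  stopifnot(is(panel, "GenotypePanel"), is(scenario, "Scenario"))
  f <- snpFrequencies(panel)
  eligible <- which(pmin(f, 1 - f) >= mafMin)
  need <- scenario@nQtl + scenario@nIntermediate + scenario@nPoly
  if (length(eligible) < need)
    stop("insufficient SNPs with MAF >= ", mafMin, ": need ", need,
         ", have ", length(eligible), " (short by ", need - length(eligible), ")")
  sigmaG2 <- scenario@h2 * scenario@sigmaY2
  sigmaE2 <- scenario@sigmaY2 - sigmaG2

  repSeed <- deriveSeed(seed, scenario@repetition)
  repDraw <- withSeed(repSeed, {
    qtl <- sort(sample(eligible, scenario@nQtl))
    uQtl <- sample(c(-1, 1), scenario@nQtl, replace = TRUE)
    rest <- setdiff(eligible, qtl)
    inter <- integer(0); uInter <- numeric(0)
    if (scenario@nIntermediate > 0) {
      inter <- sort(sample(rest, scenario@nIntermediate))
      uInter <- sample(c(-1, 1), scenario@nIntermediate, replace = TRUE)
    }
    list(qtl = qtl, uQtl = uQtl, inter = inter, uInter = uInter)
  })

  scenSeed <- deriveSeed(seed, scenario@repetition, round(scenario@k * 1e8),
                         round(scenario@h2 * 1e4), scenario@nPoly)
  polyDraw <- withSeed(scenSeed, {
    rest <- setdiff(eligible, c(repDraw$qtl, repDraw$inter))
    poly <- sort(sample(rest, scenario@nPoly))
    uPoly <- sample(c(-1, 1), scenario@nPoly, replace = TRUE)
    list(poly = poly, uPoly = uPoly)
  })

  p <- nrow(panel)
  beta <- numeric(p)
  beta[repDraw$qtl] <- repDraw$uQtl * sqrt(scenario@k * sigmaG2)
  if (scenario@nIntermediate > 0)
    beta[repDraw$inter] <- repDraw$uInter *
      sqrt(scenario@intermediateRelSize * scenario@k * sigmaG2)
  beta[polyDraw$poly] <- polyDraw$uPoly *
    sqrt(scenario@polyFraction * sigmaG2)
  signs <- setNames(c(repDraw$uQtl, repDraw$uInter, polyDraw$uPoly),
                    c(repDraw$qtl, repDraw$inter, polyDraw$poly))
  new("TraitArchitecture", qtlIndices = as.integer(repDraw$qtl),
      intermediateIndices = as.integer(repDraw$inter),
      polygenicIndices = as.integer(polyDraw$poly), signs = signs,
      beta = beta, sigmaG2 = sigmaG2, sigmaE2 = sigmaE2)
}

#' Simulate phenotypes from a trait architecture
#'
#' y = mu * 1 + X beta + e with e ~ N(0, sigma_e2 I) on the standardized
#' design matrix; deterministic given the seed.
#'
#' @param X a [StandardizedGenotypes-class] or numeric design matrix
#'   (samples x SNPs).
#' @param arch a [TraitArchitecture-class].
#' @param mu intercept (default 0).
#' @param seed integer seed for the residual draw.
#' @return numeric phenotype vector.
#' @export
simulatePhenotypes <- function(X, arch, mu = 0, seed) {
  stopifnot(is(arch, "TraitArchitecture"))
  xm <- if (is(X, "StandardizedGenotypes")) designMatrix(X) else X
  if (ncol(xm) != length(arch@beta))
    stop("design matrix has ", ncol(xm), " columns but beta has length ",
         length(arch@beta))
  if (arch@sigmaE2 < 0) stop("sigmaE2 must be >= 0")
  g <- unname(drop(xm %*% arch@beta))
  withSeed(seed, mu + g + rnorm(nrow(xm), 0, sqrt(arch@sigmaE2)))
}

#' Apply a panel variant: classic 50k vs custom 50k
#'
#' The `fifty_k` variant removes the QTL columns from the panel (a classic
#' array that does not carry the causal variants) and records each QTL's
#' truth window as the 15 surviving SNPs nearest its position; the
#' `fifty_k_custom` variant keeps all columns (custom array carrying the
#' causal variants) and centers each truth window on the QTL itself.
#' Windows never cross chromosome boundaries and truncate at chromosome
#' ends. Architecture indices are remapped to the reduced panel; removed
#' QTLs get index `NA`.
#'
#' @param panel a [GenotypePanel-class].
#' @param arch a [TraitArchitecture-class] drawn on `panel`.
#' @param variant `"fifty_k"` or `"fifty_k_custom"`.
#' @param halfWidth half window width in SNPs (default 7, 15-SNP windows).
#' @return list with elements `panel`, `architecture`, `truthWindows`.
#' @export
makePanelVariant <- function(panel, arch, variant = c("fifty_k", "fifty_k_custom"),
                             halfWidth = 7L) {
  variant <- match.arg(variant)
  stopifnot(is(panel, "GenotypePanel"), is(arch, "TraitArchitecture"))
  chrom <- snpInfo(panel)$chrom
  p <- nrow(panel)
  qtl <- arch@qtlIndices

  if (variant == "fifty_k_custom") {
    tw <- lapply(qtl, function(q) .indexWindow(q, chrom, halfWidth))
    return(list(panel = panel, architecture = arch, truthWindows = tw))
  }

  keep <- setdiff(seq_len(p), qtl)
  newIdx <- rep(NA_integer_, p)
  newIdx[keep] <- seq_along(keep)
  newPanel <- subsetSnps(panel, keep)
  newChrom <- chrom[keep]
  # nearest 15 surviving SNPs around each removed QTL: with j survivors
  # before the QTL on its chromosome, the window is {j-6, ..., j+8}
  tw <- lapply(qtl, function(q) {
    onChrom <- which(newChrom == chrom[q])
    j <- sum(keep < q & chrom[keep] == chrom[q])        # survivors before QTL
    lo <- j - (halfWidth - 1L); hi <- j + (halfWidth + 1L)
    win <- intersect(seq.int(lo, hi), seq_along(onChrom))
    onChrom[win]
  })
  beta <- arch@beta[keep]
  remap <- function(ix) as.integer(newIdx[ix])
  newArch <- new("TraitArchitecture",
                 qtlIndices = rep(NA_integer_, length(qtl)),
                 intermediateIndices = remap(arch@intermediateIndices),
                 polygenicIndices = remap(arch@polygenicIndices),
                 signs = arch@signs, beta = beta,
                 sigmaG2 = arch@sigmaG2, sigmaE2 = arch@sigmaE2)
  list(panel = newPanel, architecture = newArch, truthWindows = tw)
}

# window of indices around center i, same chromosome, truncated at ends
.indexWindow <- function(i, chrom, halfWidth) {
  w <- seq.int(i - halfWidth, i + halfWidth)
  w <- w[w >= 1 & w <= length(chrom)]
  w[chrom[w] == chrom[i]]
}

#' Simulate one complete dataset for a scenario
#'
#' Orchestrates architecture drawing, phenotype simulation (always on the
#' full panel, so the two panel variants of a scenario share identical
#' phenotypes), variant application and the 80/20 age split.
#'
#' @param panel the full [GenotypePanel-class] (QTLs included).
#' @param scenario a [Scenario-class].
#' @param seed master integer seed.
#' @param learningFraction learning fraction for [splitByAge()].
#' @param mafMin causal-SNP MAF floor.
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(panel, scenario, seed, learningFraction = 0.8,
                            mafMin = 0.15) {
  arch <- sampleArchitecture(panel, scenario, seed, mafMin = mafMin)
  X <- standardizeGenotypes(panel)
  phenoSeed <- deriveSeed(seed, scenario@repetition,
                          round(scenario@k * 1e8),
                          round(scenario@h2 * 1e4), 7L)
  y <- simulatePhenotypes(X, arch, mu = scenario@mu, seed = phenoSeed)
  variant <- makePanelVariant(panel, arch, scenario@panelVariant)
  split <- splitByAge(variant$panel, learningFraction)
  new("SimulatedDataset", panel = variant$panel, y = y,
      architecture = variant$architecture, split = split,
      truthWindows = variant$truthWindows, scenario = scenario)
}
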