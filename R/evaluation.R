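#' Validation correlation between true and predicted phenotypes
#'
#' Pearson correlation on the validation set; the standard accuracy measure
#' in genomic-selection benchmarks. Constant predictions make the
#' correlation undefined: that case is signalled with a dedicated warning
#' (class `"bayesrmap_constant_prediction"`) and returns `NA`, so it can be
#' distinguished from numeric failure and excluded from aggregation.
#'
#' @param yTrue,yHat numeric vectors of equal length >= 3.
#' @return Pearson correlation, or NA for constant predictions.
#' @export
validationCorrelation <- function(yTrue, yHat) {
  if (length(yTrue) != length(yHat) || length(yTrue) < 3)
    stop("need equal lengths >= 3")
  if (var(yTrue) == 0) stop("yTrue is constant")
  if (var(yHat) == 0) {
    warning(warningCondition("constant predictions: correlation undefined",
                             class = "bayesrmap_constant_prediction"))
    return(NA_real_)
  }
  cor(yTrue, yHat)
}

#' QTL-window detection for one mapping criterion
#'
#' A QTL counts as detected when at least one SNP of its 15-SNP truth
#' window is flagged by the criterion. Modes: `"map"` flags SNPs whose
#' neighborhood MAP class is medium or large; `"nonnull_map"` flags
#' neighborhood nonnull-MAP calls; `"top_v"` / `"top_cip"` flag membership
#' in the top-10 posterior-variance / top-150 CIP ranking.
#'
#' @param criteria a [criterionTable()] data.frame.
#' @param truthWindows list of per-QTL index windows (see
#'   [SimulatedDataset-class]).
#' @param mode one of `"map"`, `"nonnull_map"`, `"top_v"`, `"top_cip"`.
#' @param topV,topCip ranking cutoffs for the two ranked modes.
#' @return list with `count` (detected QTLs) and `detail` (per-QTL
#'   data.frame with the triggering SNP and, for `"map"`, the detected
#'   class labels present in the window).
#' @export
qtlWindowDetection <- function(criteria, truthWindows,
                               mode = c("map", "nonnull_map", "top_v", "top_cip"),
                               topV = 10L, topCip = 150L) {
  mode <- match.arg(mode)
  p <- nrow(criteria)
  flags <- switch(mode,
    map = criteria$nbMap %in% c(3L, 4L),
    nonnull_map = criteria$nbMapNonnull == 1L,
    top_v = seq_len(p) %in% rankCandidates(criteria$vHat, topV),
    top_cip = seq_len(p) %in% rankCandidates(criteria$cip, topCip))
  if (length(truthWindows) > 1) {
    allIdx <- unlist(truthWindows)
    if (anyDuplicated(allIdx))
      warning("overlapping truth windows: each QTL counted once")
  }
  detail <- do.call(rbind, lapply(seq_along(truthWindows), function(q) {
    w <- truthWindows[[q]]
    hit <- w[flags[w]]
    lab <- if (mode == "map" && length(hit))
      paste(sort(unique(criteria$nbMap[hit])), collapse = "/") else NA_character_
    data.frame(qtl = q, detected = length(hit) > 0,
               triggeringSnp = if (length(hit)) hit[1] else NA_integer_,
               classLabels = lab)
  }))
  list(count = sum(detail$detected), detail = detail)
}

#' AUROC over the top-ranked SNP subset
#'
#' Genome-wide AUROC is dominated by the massive negative class, so scoring
#' is restricted to the `topN` highest-ranked SNPs: each is labelled
#' positive iff it falls in a QTL truth window, and the AUROC is the
#' normalized Mann-Whitney U of the scores of positives vs negatives within
#' that subset (midranks for ties). A subset with no positives scores 0 by
#' convention; all positives scores 1.
#'
#' @param scores per-SNP criterion values (higher = stronger candidate).
#' @param positiveSet integer indices of positive SNPs (union of truth
#'   windows).
#' @param topN subset size (10 for V, 150 for CIP).
#' @return AUROC in \[0, 1\].
#' @export
aurocTopRanked <- function(scores, positiveSet, topN) {
  if (length(scores) == 0) stop("empty ranked list")
  top <- rankCandidates(scores, topN)
  lab <- top %in% positiveSet
  nPos <- sum(lab); nNeg <- sum(!lab)
  if (nPos == 0) return(0)
  if (nNeg == 0) return(1)
  r <- rank(scores[top], ties.method = "average")
  u <- sum(r[lab]) - nPos * (nPos + 1) / 2
  u / (nPos * nNeg)
}

#' Monte Carlo standard error over repetitions
#'
#' Sample standard deviation divided by the square root of the number of
#' repetitions.
#'
#' @param values per-repetition statistics (length >= 2).
#' @return the Monte Carlo SE.
#' @export
monteCarloSE <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  sd(values) / sqrt(length(values))
}

#' Pairwise correlation of SNP effects across prior settings
#'
#' Sensitivity diagnostic: Pearson correlations between the posterior mean
#' effect vectors obtained on the same data under different mixture priors.
#'
#' @param summaries list of [PosteriorSummary-class] objects fitted on
#'   identical SNP sets.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
priorSensitivityCorrelation <- function(summaries) {
  if (length(summaries) < 2) stop("need at least 2 summaries")
  ps <- vapply(summaries, function(s) length(betaMean(s)), integer(1))
  if (length(unique(ps)) != 1) stop("mismatched SNP sets")
  b <- vapply(summaries, betaMean, numeric(ps[1]))
  cor(b)
}

#' Run the simulation benchmark over a scenario grid
#'
#' For every scenario: simulate a dataset, fit BayesR (or BayesCpi) on the
#' learning set, predict the validation set, compute all mapping criteria
#' and score detection and AUROC against the truth windows. Fully seeded:
#' rerunning with the same master seed reproduces the report bitwise. When
#' `outDir` is given, one TSV row is written per scenario and existing rows
#' are not recomputed, so an interrupted run resumes where it stopped.
#'
#' @param scenarios list of [Scenario-class] (see [buildScenarioGrid()]).
#' @param panel full [GenotypePanel-class] (QTLs included).
#' @param seed master integer seed.
#' @param config a [GibbsConfig()] for the sampler.
#' @param prior a [MixturePrior()].
#' @param model `"bayesr"` or `"bayescpi"`.
#' @param learningFraction,mafMin simulation settings.
#' @param topV,topCip ranking cutoffs.
#' @param outDir optional directory for per-scenario TSV rows (resumable).
#' @return data.frame, one row per scenario, with validation correlation,
#'   posterior variance components, per-criterion detection counts,
#'   AUROC values, and the count of nesting violations (QTLs detected by
#'   nonnull neighborhood MAP but missed by top-10 V, or detected by top-10
#'   V but missed by top-150 CIP — expected to be 0).
#' @export
runBenchmark <- function(scenarios, panel, seed, config = GibbsConfig(10000, 4000, 10),
                         prior = MixturePrior(), model = c("bayesr", "bayescpi"),
                         learningFraction = 0.8, mafMin = 0.15,
                         topV = 10L, topCip = 150L, outDir = NULL) {
  model <- match.arg(model)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    tag <- sprintf("scenario_%03d_k%g_h%g_%s_rep%d", i, sc@k, sc@h2,
                   sc@panelVariant, sc@repetition)
    cache <- if (!is.null(outDir)) file.path(outDir, paste0(tag, ".tsv"))
    if (!is.null(cache) && file.exists(cache))
      return(utils::read.table(cache, header = TRUE, sep = "\t"))
    row <- .runOneScenario(sc, panel, seed, config, prior, model,
                           learningFraction, mafMin, topV, topCip)
    row <- cbind(scenarioId = i, row)
    if (!is.null(cache))
      utils::write.table(row, cache, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    row
  })
  do.call(rbind, rows)
}

.runOneScenario <- function(sc, panel, seed, config, prior, model,
                            learningFraction, mafMin, topV, topCip) {
  ds <- simulateDataset(panel, sc, seed, learningFraction, mafMin)
  X <- standardizeGenotypes(ds@panel)
  xm <- designMatrix(X)
  learn <- learningSet(ds); valid <- validationSet(ds)
  fitSeed <- deriveSeed(seed, sc@repetition, round(sc@k * 1e8),
                        round(sc@h2 * 1e4),
                        if (sc@panelVariant == "fifty_k") 1L else 2L, 13L)
  cfg <- GibbsConfig(config@nIter, config@burnIn, config@thin, seed = fitSeed)
  fit <- if (model == "bayesr")
    fitBayesR(xm[learn, , drop = FALSE], ds@y[learn], prior = prior, config = cfg)
  else
    fitBayesCpi(xm[learn, , drop = FALSE], ds@y[learn], config = cfg)
  yhat <- predictPhenotypes(fit, xm[valid, , drop = FALSE])
  vc <- withCallingHandlers(
    validationCorrelation(ds@y[valid], yhat),
    bayesrmap_constant_prediction = function(w) invokeRestart("muffleWarning"))
  crit <- criterionTable(fit, ds@panel)
  tw <- truthWindows(ds)
  detMap <- qtlWindowDetection(crit, tw, "map")
  detNn <- qtlWindowDetection(crit, tw, "nonnull_map")
  detV <- qtlWindowDetection(crit, tw, "top_v", topV = topV)
  detCip <- qtlWindowDetection(crit, tw, "top_cip", topCip = topCip)
  nesting <- sum(detNn$detail$detected & !detV$detail$detected) +
    sum(detV$detail$detected & !detCip$detail$detected)
  pos <- unique(unlist(tw))
  data.frame(k = sc@k, h2 = sc@h2, variant = sc@panelVariant,
             repetition = sc@repetition, model = model,
             nSnp = ncol(xm), nLearning = length(learn),
             validationCorrelation = vc,
             validationUndefined = is.na(vc),
             sigmaG2Mean = sigmaG2Mean(fit), sigmaE2Mean = sigmaE2Mean(fit),
             detectedMap = detMap$count, detectedNonnullMap = detNn$count,
             detectedTopV = detV$count, detectedTopCip = detCip$count,
             nQtl = length(tw),
             aurocV = aurocTopRanked(crit$vHat, pos, topV),
             aurocCip = aurocTopRanked(crit$cip, pos, topCip),
             nestingViolations = nesting)
}

#' Aggregate a benchmark report over repetitions
#'
#' Means and Monte Carlo standard errors per (k, h2, panel variant) cell;
#' undefined validation correlations are excluded from the mean and counted
#' in `nUndefined`.
#'
#' @param report output of [runBenchmark()].
#' @return aggregated data.frame keyed by (k, h2, variant).
#' @export
aggregateBenchmark <- function(report) {
  key <- interaction(report$k, report$h2, report$variant, drop = TRUE)
  rows <- lapply(split(report, key), function(d) {
    vc <- d$validationCorrelation[!is.na(d$validationCorrelation)]
    data.frame(k = d$k[1], h2 = d$h2[1], variant = d$variant[1],
               nRepetitions = nrow(d),
               meanValidationCorrelation = mean(vc),
               seValidationCorrelation = if (length(vc) >= 2)
                 monteCarloSE(vc) else NA_real_,
               nUndefined = sum(is.na(d$validationCorrelation)),
               meanSigmaG2 = mean(d$sigmaG2Mean),
               seSigmaG2 = if (nrow(d) >= 2) monteCarloSE(d$sigmaG2Mean)
                 else NA_real_,
               detectedMap = sum(d$detectedMap),
               detectedNonnullMap = sum(d$detectedNonnullMap),
               detectedTopV = sum(d$detectedTopV),
               detectedTopCip = sum(d$detectedTopCip),
               totalQtl = sum(d$nQtl),
               meanAurocV = mean(d$aurocV), meanAurocCip = mean(d$aurocCip),
               nestingViolations = sum(d$nestingViolations))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$k, out$h2, out$variant), ]
}
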