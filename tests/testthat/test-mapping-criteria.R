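test_that("MAP rules follow the argmax with low-class tie-break and strict threshold", {
  expect_equal(mapRule(c(0.7, 0.1, 0.1, 0.1)), 1L)
  expect_equal(mapRule(c(0.1, 0.2, 0.3, 0.4)), 4L)
  expect_equal(mapRule(c(0.4, 0.4, 0.1, 0.1)), 1L)   # tie toward lower class
  expect_equal(mapRule(rbind(c(1, 0, 0, 0), c(0, 0, 0.5, 0.5))), c(1L, 3L))
  expect_error(mapRule(c(-0.1, 0.6, 0.3, 0.2)), "negative")
  expect_error(mapRule(c(0.5, 0.1, 0.1, 0.1)), "sum")

  expect_equal(nonnullMapRule(c(0.45, 0.25, 0.2, 0.1)), 1L)  # 0.55 > 0.5
  expect_equal(nonnullMapRule(c(0.5, 0.3, 0.1, 0.1)), 0L)    # strict at 0.5
  expect_equal(nonnullMapRule(c(1, 0, 0, 0)), 0L)
})

test_that("posterior variance estimates normalize to proportions", {
  mk <- function(bsq) new("PosteriorSummary", pip = randomPip(length(bsq), 1),
                          betaMean = sqrt(bsq) * 0, betaSqMean = bsq,
                          classCountsMean = c(length(bsq), 0, 0, 0),
                          piMean = rep(0.25, 4), sigmaG2Mean = 1,
                          sigmaE2Mean = 1, muMean = 0, retainedDraws = 5L,
                          model = "bayesr", trace = matrix(0, 1, 4))
  # chain constantly at beta = 2 -> vHat = 4; alternating -1/+1 -> vHat = 1
  v <- snpVarianceEstimates(mk(c(4, 1, 3)))
  expect_equal(unname(v$vHat), c(4, 1, 3))
  expect_equal(sum(v$vProp), 1)
  expect_warning(v0 <- snpVarianceEstimates(mk(c(0, 0))), "zero")
  expect_true(all(is.na(v0$vProp)))
})

test_that("neighborhood criteria pick the strongest window member", {
  p <- 20
  pip <- matrix(rep(c(1, 0, 0, 0), each = p), p)
  pip[8, ] <- c(0.2, 0.3, 0.1, 0.4)
  vhat <- rep(0.01, p); vhat[8] <- 0.5; vhat[3] <- 0.2
  nb <- neighborhoodSummary(pip, vhat, rep("chr1", p))
  # all-null window far from SNP 8
  expect_equal(nb$nbIp[20], 0)
  expect_equal(nb$nbMap[20], 1L)
  # windows containing SNP 8 take its PIP row
  expect_equal(nb$nbIp[5], 0.8)
  expect_equal(nb$nbMap[5], 4L)
  expect_equal(nb$nbMapNonnull[5], 1L)
  expect_equal(unlist(nb[5, paste0("nbPip", 1:4)], use.names = FALSE),
               c(0.2, 0.3, 0.1, 0.4))
  # neighborhood variance is the window maximum
  expect_equal(nb$nbV[1], 0.5)    # window 1..8 contains SNP 8
  expect_equal(nb$nbV[16], 0.01)  # window 9..20 all small
  # windows never cross chromosomes
  nb2 <- neighborhoodSummary(pip, vhat, rep(c("chr1", "chr2"), each = 10))
  expect_equal(nb2$nbIp[11], 0)   # SNP 8 not visible from chr2
  expect_error(neighborhoodSummary(pip, vhat, rep(c("chr2", "chr1", "chr2"),
                                                  c(5, 5, 10))), "grouped")
})

test_that("neighborhood ties break toward the center then the lower index", {
  p <- 15
  pip <- matrix(rep(c(1, 0, 0, 0), each = p), p)
  pip[c(4, 9), ] <- rep(c(0.4, 0.6, 0, 0), each = 2)  # equal inclusion
  nb <- neighborhoodSummary(pip, rep(0, p), rep("chr1", p))
  expect_equal(nb$nbIndex[6], 4L)   # distance 2 beats distance 3
  expect_equal(nb$nbIndex[7], 9L)   # distance 2 beats distance 3
  # SNP 10: |10-9| = 1 beats |10-4|; SNP 1: only 4 in window
  expect_equal(nb$nbIndex[10], 9L)
  expect_equal(nb$nbIndex[1], 4L)
  # exact midpoint: lower index wins
  pip2 <- matrix(rep(c(1, 0, 0, 0), each = p), p)
  pip2[c(5, 9), ] <- rep(c(0.4, 0.6, 0, 0), each = 2)
  nb2 <- neighborhoodSummary(pip2, rep(0, p), rep("chr1", p))
  expect_equal(nb2$nbIndex[7], 5L)
})

test_that("CIP is the weighted windowed sum with chromosome truncation", {
  p <- 30
  pip <- matrix(rep(c(1, 0, 0, 0), each = p), p)
  cip0 <- cipStatistic(pip, rep("chr1", p))
  expect_equal(cip0, rep(0, p))
  pip[15, ] <- c(0, 0, 0, 1)
  cip1 <- cipStatistic(pip, rep("chr1", p))
  expect_equal(cip1[10], 0.01)   # lone large-class SNP inside the window
  expect_equal(cip1[7], 0)       # outside +/- 7
  pipAll2 <- matrix(rep(c(0, 1, 0, 0), each = 15), 15)
  expect_equal(cipStatistic(pipAll2, rep("chr1", 15))[8], 15e-4)
  expect_error(cipStatistic(pip, rep("chr1", p), weights = c(0, 1)), "weights")

  # shifting mass from medium to large never decreases CIP
  set.seed(7)
  m <- randomPip(40, 3)
  shifted <- m
  shifted[, 4] <- shifted[, 4] + shifted[, 3]
  shifted[, 3] <- 0
  expect_true(all(cipStatistic(shifted, rep("chr1", 40)) -
                    cipStatistic(m, rep("chr1", 40)) > -1e-12))
})

test_that("Lewontin D' matches its definition and worked values", {
  expect_equal(lewontinDprime(0.4, 0.7, 0.28), 0)          # independence
  expect_equal(lewontinDprime(0.5, 0.5, 0.5), 1)           # perfect LD
  expect_equal(lewontinDprime(0.6, 0.5, 0.35), 0.25)       # D = 0.05, Dmax = 0.2
  # negative D: pA = pB = 0.5, pAB = 0.15 -> D = -0.1, Dmax = -0.25
  expect_equal(lewontinDprime(0.5, 0.5, 0.15), 0.4)
  # allele relabeling at both loci leaves D' unchanged
  set.seed(11)
  for (i in 1:25) {
    pA <- runif(1, 0.1, 0.9); pB <- runif(1, 0.1, 0.9)
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    pAB <- runif(1, lo, hi)
    d1 <- lewontinDprime(pA, pB, pAB)
    d2 <- lewontinDprime(1 - pA, 1 - pB, 1 - pA - pB + pAB)
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_lte(abs(d1), 1)
    expect_gte(d1, 0)
  }
  expect_error(lewontinDprime(0.2, 0.2, 0.5), "Frechet")
  expect_error(lewontinDprime(1.2, 0.2, 0.1), "frequencies")
})

test_that("QTL LD context: duplicated neighbor gives D' = 1, EM matches phased truth", {
  panel <- smallPanel(p = 80, n = 120, seed = 13)
  chrom <- snpInfo(panel)$chrom
  mid <- which(chrom == chrom[10])[10]
  dmax <- qtlLdContext(panel, mid)
  expect_gte(dmax, 0); expect_lte(dmax, 1)
  # EM on unphased genotypes agrees with the phased-truth path
  dEm <- qtlLdContext(panel, mid, method = "em")
  expect_lt(abs(dEm - dmax), 0.1)
  # mean absolute agreement over several windows
  idx <- seq(10, 60, by = 10)
  diffs <- vapply(idx, function(i)
    abs(qtlLdContext(panel, i) - qtlLdContext(panel, i, method = "em")),
    numeric(1))
  expect_lt(mean(diffs), 0.05)
  expect_error(qtlLdContext(smallPanel(p = 16, n = 20, seed = 2), 1,
                            halfWidth = 0L), "fewer")
})

test_that("two-locus EM recovers haplotype frequencies", {
  set.seed(23)
  # simulate phased haplotypes with known pAB
  n <- 4000; pA <- 0.6; pB <- 0.4; pAB <- 0.35
  hfreq <- c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
  draw <- function() sample(names(hfreq), 2 * n, TRUE, prob = hfreq)
  h1 <- draw()[1:n]; h2 <- draw()[1:n]
  g1 <- (h1 %in% c("AB", "Ab")) + (h2 %in% c("AB", "Ab"))
  g2 <- (h1 %in% c("AB", "aB")) + (h2 %in% c("AB", "aB"))
  est <- emHaplotypeFrequency(g1, g2)
  expect_lt(abs(est["pAB"] - mean(c(h1 == "AB", h2 == "AB"))), 0.01)
})

test_that("ranking is descending with index tie-break and saturates", {
  v <- c(0.3, 0.9, 0.9, 0.1, 0.5)
  expect_equal(rankCandidates(v, 3), c(2L, 3L, 5L))  # tie: lower index first
  expect_equal(rankCandidates(v, 150), c(2L, 3L, 5L, 1L, 4L))
  expect_length(rankCandidates(rep(1, 100), 150), 100)
  expect_error(rankCandidates(numeric(0), 10), "empty")
})

test_that("the criterion table satisfies its cross-column invariants", {
  panel <- smallPanel(p = 120, n = 60, seed = 17)
  p <- nrow(panel)
  set.seed(3)
  pipM <- randomPip(p, 5)
  bm <- rnorm(p, 0, 0.1)
  fitLike <- new("PosteriorSummary", pip = pipM,
                 betaMean = bm,
                 betaSqMean = bm^2 + abs(rnorm(p, 0, 0.05)),
                 classCountsMean = unname(colSums(pipM)),
                 piMean = rep(0.25, 4), sigmaG2Mean = 1, sigmaE2Mean = 1,
                 muMean = 0, retainedDraws = 10L, model = "bayesr",
                 trace = matrix(0, 1, 4))
  crit <- criterionTable(fitLike, panel, dprime = TRUE)
  expect_equal(nrow(crit), p)
  expect_true(all(crit$nbIp >= 1 - pipMatrix(fitLike)[, 1] - 1e-12))
  expect_true(all(crit$nbV >= crit$vHat - 1e-12))
  expect_true(all(crit$cip >= 0 & crit$cip <= 15 * 0.01 + 1e-12))
  expect_true(all(crit$dprimeMax >= 0 & crit$dprimeMax <= 1))
  expect_equal(sum(crit$vProp), 1)
  # a nonnull MAP call implies a nonnull neighborhood MAP call
  expect_true(all(crit$nbMapNonnull[crit$mapNonnull == 1] == 1))
})
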