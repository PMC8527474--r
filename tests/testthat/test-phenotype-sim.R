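test_that("polygenic counts reproduce the full design table", {
  counts <- vapply(defaultKGrid(), polygenicCount, integer(1))
  expect_identical(counts, c(9637L, 9550L, 9500L, 9450L, 9350L, 9250L, 9100L,
                             9000L, 8750L, 8500L, 8250L, 8000L, 7500L))
  # floor rule: k = 0.725% gives floor(9637.5)
  expect_identical(polygenicCount(0.00725), 9637L)
  expect_error(polygenicCount(0.2, nQtl = 5), "budget")
})

test_that("variance budget conservation holds across the k grid", {
  for (k in defaultKGrid()) {
    budget <- 5 * k + polygenicCount(k) * 1e-4
    expect_lte(budget, 1)
    expect_gt(budget, 1 - 1e-4)
  }
})

test_that("the scenario grid enumerates the full factorial design", {
  grid <- buildScenarioGrid()
  expect_length(grid, 13 * 4 * 10 * 2)   # 1040 datasets
  small <- buildScenarioGrid(0.02, 0.5, 1)
  expect_length(small, 2)                # two panel variants
  expect_error(buildScenarioGrid(c(0.02, 0.02), 0.5, 1), "duplicate")
  expect_error(buildScenarioGrid(numeric(0), 0.5, 1), "non-empty")
})

test_that("QTL sets and signs are invariant across k, h2 and variant within a repetition", {
  panel <- smallPanel(p = 400, n = 60, seed = 21, nChrom = 3L)
  arches <- lapply(list(
    Scenario(0.02, 0.5, polyFraction = 5e-3, repetition = 3L),
    Scenario(0.05, 0.5, polyFraction = 5e-3, repetition = 3L),
    Scenario(0.02, 0.8, polyFraction = 5e-3, repetition = 3L,
             panelVariant = "fifty_k_custom")),
    function(sc) sampleArchitecture(panel, sc, seed = 77))
  qtls <- lapply(arches, function(a) a@qtlIndices)
  expect_identical(qtls[[1]], qtls[[2]])
  expect_identical(qtls[[1]], qtls[[3]])
  sgn <- function(a) a@signs[as.character(a@qtlIndices)]
  expect_identical(sgn(arches[[1]]), sgn(arches[[2]]))
  # different repetition draws a different QTL set
  other <- sampleArchitecture(panel,
    Scenario(0.02, 0.5, polyFraction = 5e-3, repetition = 4L), seed = 77)
  expect_false(identical(qtls[[1]], other@qtlIndices))
})

test_that("causal SNPs respect the MAF floor and the stated effect sizes", {
  panel <- smallPanel(p = 400, n = 60, seed = 21, nChrom = 3L)
  sc <- Scenario(0.02, 0.5, polyFraction = 5e-3, repetition = 1L)
  arch <- sampleArchitecture(panel, sc, seed = 5)
  f <- snpFrequencies(panel)
  causal <- c(arch@qtlIndices, arch@polygenicIndices)
  expect_true(all(pmin(f, 1 - f)[causal] >= 0.15))
  # k = 0.02, h2 = 0.5, sigma_y2 = 100: QTL beta^2 = 0.02 * 50 = 1
  expect_equal(unname(arch@beta[arch@qtlIndices]^2), rep(1, 5))
  expect_equal(unname(arch@beta[arch@polygenicIndices]^2),
               rep(5e-3 * 50, length(arch@polygenicIndices)))
  expect_identical(sampleArchitecture(panel, sc, seed = 5)@beta, arch@beta)

  lowMaf <- makeFreqPanel(rep(0.05, 60), n = 50)
  expect_error(sampleArchitecture(lowMaf, sc, seed = 1), "insufficient")
})

test_that("phenotypes follow y = mu + X beta + e", {
  panel <- smallPanel(p = 200, n = 50, seed = 31, nChrom = 2L)
  X <- standardizeGenotypes(panel)
  sc <- Scenario(0.02, 0.5, polyFraction = 1e-2, repetition = 1L)
  arch <- sampleArchitecture(panel, sc, seed = 4)
  noiseless <- arch
  noiseless@sigmaE2 <- 0
  noiseless@beta[] <- 0
  y0 <- simulatePhenotypes(X, noiseless, mu = 3.5, seed = 1)
  expect_equal(y0, rep(3.5, 50))
  y1 <- simulatePhenotypes(X, arch, mu = 0, seed = 9)
  expect_identical(y1, simulatePhenotypes(X, arch, mu = 0, seed = 9))
  expect_false(identical(y1, simulatePhenotypes(X, arch, mu = 0, seed = 10)))
  expect_error(simulatePhenotypes(designMatrix(X)[, 1:10], arch, 0, 1),
               "columns")
})

test_that("simulated variance components match their targets at scale", {
  panel <- filterByMAF(generateGenotypes(LDModel(nChromosomes = 5L),
                                         n = 2000, p = 700, seed = 61), 0.05)
  X <- standardizeGenotypes(panel)
  vy <- vg <- numeric(10)
  for (s in 1:10) {
    sc <- Scenario(0.02, 0.5, polyFraction = 5e-3, repetition = s)
    arch <- sampleArchitecture(panel, sc, seed = 100 + s)
    g <- drop(designMatrix(X) %*% arch@beta)
    vg[s] <- var(g)
    vy[s] <- var(simulatePhenotypes(X, arch, mu = 0, seed = 200 + s))
  }
  # var(g) targets sigma_g2 = 50, var(y) targets 100; 3 SE over seeds
  expect_lt(abs(mean(vg) - 50), 3 * sd(vg) / sqrt(10) + 1e-9)
  expect_lt(abs(mean(vy) - 100), 3 * sd(vy) / sqrt(10) + 1e-9)
  h2hat <- vg / vy
  expect_lt(abs(mean(h2hat) - 0.5), 3 * sd(h2hat) / sqrt(10) + 1e-9)
})

test_that("panel variants drop or keep QTL columns and build truth windows", {
  counts <- alleleCounts(smallPanel(p = 40, n = 20, seed = 8))
  panel <- GenotypePanel(counts, chrom = rep("chr1", 40), pos = 1:40 * 1000)
  arch <- new("TraitArchitecture", qtlIndices = c(5L, 20L),
              intermediateIndices = integer(0),
              polygenicIndices = c(10L, 30L),
              signs = setNames(c(1, -1, 1, 1), c(5, 20, 10, 30)),
              beta = replace(numeric(40), c(5, 20, 10, 30), c(1, -1, .2, .2)),
              sigmaG2 = 50, sigmaE2 = 50)

  custom <- makePanelVariant(panel, arch, "fifty_k_custom")
  expect_equal(nrow(custom$panel), 40)
  expect_equal(custom$truthWindows[[2]], 13:27)   # centered on the QTL

  fifty <- makePanelVariant(panel, arch, "fifty_k")
  expect_equal(nrow(fifty$panel), 38)             # p_out = p_in - nQtl
  # QTL 20 leaves j = 18 survivors before it: window {12, ..., 26}
  expect_equal(fifty$truthWindows[[2]], 12:26)
  # QTL 5 near the start: j = 4, window truncated at the chromosome edge
  expect_equal(fifty$truthWindows[[1]], 1:12)
  expect_true(all(is.na(fifty$architecture@qtlIndices)))
  # polygenic indices remapped past the removed columns
  expect_identical(fifty$architecture@polygenicIndices, c(9L, 28L))
  expect_error(makePanelVariant(panel, arch, "whatever"))
})

test_that("datasets share phenotypes across panel variants", {
  panel <- smallPanel(p = 300, n = 50, seed = 41, nChrom = 2L)
  sc1 <- Scenario(0.05, 0.5, polyFraction = 5e-3, repetition = 2L)
  sc2 <- Scenario(0.05, 0.5, polyFraction = 5e-3, repetition = 2L,
                  panelVariant = "fifty_k_custom")
  d1 <- simulateDataset(panel, sc1, seed = 99)
  d2 <- simulateDataset(panel, sc2, seed = 99)
  expect_identical(phenotypes(d1), phenotypes(d2))
  expect_equal(nrow(d1@panel), nrow(panel) - 5)
  expect_equal(nrow(d2@panel), nrow(panel))
  expect_length(truthWindows(d1), 5)
})

test_that("intermediate QTLs take a tenth of the large-QTL variance", {
  panel <- smallPanel(p = 400, n = 60, seed = 21, nChrom = 3L)
  sc <- Scenario(0.05, 0.5, polyFraction = 1e-2, nIntermediate = 5L,
                 repetition = 2L)
  # budget: 5 * 0.05 + 5 * 0.1 * 0.05 + nPoly * 0.01 <= 1
  expect_equal(sc@nPoly, polygenicCount(0.05, polyFraction = 1e-2,
                                        nIntermediate = 5L))
  arch <- sampleArchitecture(panel, sc, seed = 9)
  expect_length(arch@intermediateIndices, 5)
  expect_equal(unname(arch@beta[arch@intermediateIndices]^2),
               rep(0.1 * 0.05 * 50, 5))
  # intermediate set shared across k within a repetition
  sc2 <- Scenario(0.02, 0.5, polyFraction = 1e-2, nIntermediate = 5L,
                  repetition = 2L)
  arch2 <- sampleArchitecture(panel, sc2, seed = 9)
  expect_identical(arch@intermediateIndices, arch2@intermediateIndices)
})
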