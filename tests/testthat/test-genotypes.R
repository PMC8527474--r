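test_that("VCF genotypes are read as ALT-allele dosages", {
  vcf <- file.path(tempdir(), "tiny.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "0/1", "0/0", sep = "\t")), vcf)
  panel <- readGenotypes(vcf, "vcf")
  expect_identical(unname(alleleCounts(panel)["rs1", ]), c(0L, 1L, 2L))
  expect_identical(unname(alleleCounts(panel)["rs2", ]), c(1L, 1L, 0L))
  expect_equal(snpInfo(panel)$pos, c(100L, 200L))
})

test_that("multi-allelic VCF records are skipped with a warning count", {
  vcf <- file.path(tempdir(), "multi.vcf")
  recs <- vapply(1:10, function(i)
    paste("1", i * 100, paste0("rs", i), "A",
          if (i == 4) "G,T" else "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t"), character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    recs), vcf)
  expect_warning(panel <- readGenotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(nrow(panel), 9L)
  expect_equal(importReport(panel)$nMultiallelicSkipped, 1L)
})

test_that("PLINK and VCF round trips reproduce allele counts exactly", {
  panel <- smallPanel(p = 60, n = 21, seed = 3)
  pfx <- file.path(tempdir(), "rt")
  writeGenotypes(panel, pfx, "plink")
  back <- readGenotypes(pfx, "plink")
  expect_identical(alleleCounts(back), alleleCounts(panel))
  expect_equal(snpInfo(back)$pos, snpInfo(panel)$pos)

  vcf <- file.path(tempdir(), "rt.vcf")
  writeGenotypes(panel, vcf, "vcf", snpTable = file.path(tempdir(), "rt.tsv"))
  back2 <- readGenotypes(vcf, "vcf")
  expect_identical(alleleCounts(back2), alleleCounts(panel))
  tab <- read.table(file.path(tempdir(), "rt.tsv"), header = TRUE)
  expect_equal(tab$freq, unname(snpFrequencies(panel)))
})

test_that("missing genotypes are imputed to rounded mean dosage and reported", {
  vcf <- file.path(tempdir(), "miss.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "1/1", "1/1", "./.", "1/1", sep = "\t")), vcf)
  panel <- readGenotypes(vcf, "vcf")
  expect_identical(unname(alleleCounts(panel)[1, 3]), 2L)  # mean dosage 2
  expect_equal(importReport(panel)$nImputed, 1L)
})

test_that("MAF filter keeps the boundary, is idempotent and errors when empty", {
  panel <- makeFreqPanel(c(0.005, 0.01, 0.3, 0.6, 0.995), n = 100)
  kept <- filterByMAF(panel, 0.01)
  expect_equal(snpInfo(kept)$id, paste0("snp", 2:4))   # 0.005 and 0.995 out
  expect_identical(alleleCounts(filterByMAF(kept, 0.01)), alleleCounts(kept))
  expect_identical(alleleCounts(filterByMAF(panel, 0)), alleleCounts(panel))
  expect_error(filterByMAF(panel, 0.45), "empty panel")
  expect_error(filterByMAF(panel, 0.7), "threshold")
})

test_that("standardization matches the closed form and centers exactly", {
  counts <- rbind(c(2L, 1L, 1L, 0L),        # f = 0.5, has hets and homs
                  c(1L, 1L, 0L, 0L))        # f = 0.25
  panel <- GenotypePanel(counts, chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  X <- standardizeGenotypes(panel)
  xm <- designMatrix(X)
  # f = 0.5: w = 1 -> 0, w = 2 -> sqrt(2)
  expect_equal(unname(xm[2, 1]), 0)
  expect_equal(unname(xm[1, 1]), sqrt(2))
  expect_lt(max(abs(colMeans(xm))), 1e-10)

  mono <- makeFreqPanel(c(0.3, 1e-9), n = 10)  # second column all zero
  expect_error(standardizeGenotypes(mono), "monomorphic")
})

test_that("standardization can use learning-only frequencies", {
  panel <- smallPanel(p = 40, n = 30, seed = 9)
  idx <- 1:20
  X <- standardizeGenotypes(panel, frequencySource = idx)
  expect_lt(max(abs(colMeans(designMatrix(X)[idx, ]))), 1e-10)
})

test_that("age split takes the floor of the oldest fraction", {
  panel <- smallPanel(p = 30, n = 10, seed = 2)
  sp <- splitByAge(panel, 0.8)
  expect_length(learningSet(sp), 8)
  expect_length(validationSet(sp), 2)

  counts <- alleleCounts(smallPanel(p = 20, n = 4, seed = 5))
  p4 <- GenotypePanel(counts, chrom = rep("chr1", 20), pos = 1:20 * 100,
                      sampleOrder = c(3L, 1L, 4L, 2L))
  sp2 <- splitByAge(p4, 0.5)
  expect_identical(learningSet(sp2), c(2L, 4L))   # orders 1 and 2

  # full-scale arithmetic: floor(0.8 * 2605) learning
  expect_identical(floor(0.8 * 2605), 2084)
})

test_that("synthetic panels are deterministic and validity-checked", {
  a <- generateGenotypes(LDModel(nChromosomes = 3L), n = 25, p = 60, seed = 42)
  b <- generateGenotypes(LDModel(nChromosomes = 3L), n = 25, p = 60, seed = 42)
  expect_identical(alleleCounts(a), alleleCounts(b))
  expect_identical(haplotypes(a), haplotypes(b))
  expect_true(validObject(a))
  expect_error(generateGenotypes(LDModel(), n = 1, p = 60, seed = 1), "n >= 2")
  expect_error(LDModel(mafRange = c(0, 0)), "mafRange")
  expect_error(LDModel(switchRate = 0), "switchRate")
})

test_that("near-zero switch rate copies whole founder chromosomes", {
  m <- LDModel(nFounders = 6L, switchRate = 1e-9, founderCorrelation = 0,
               nChromosomes = 2L)
  panel <- generateGenotypes(m, n = 10, p = 40, seed = 7)
  hap <- haplotypes(panel)
  chrom <- snpInfo(panel)$chrom
  # every haplotype copy must match one founder exactly per chromosome;
  # founders are recovered as the unique haplotype patterns
  for (ci in split(seq_len(40), chrom)) {
    H <- cbind(hap[ci, , 1], hap[ci, , 2])
    expect_lte(nrow(unique(t(H))), 6)
  }
})

test_that("adjacent-SNP D' decreases with the switch rate", {
  meanAdjDprime <- function(panel) {
    hap <- haplotypes(panel)
    H <- cbind(hap[, , 1], hap[, , 2])
    chrom <- snpInfo(panel)$chrom
    f <- rowMeans(H)
    ok <- which(chrom[-1] == chrom[-nrow(H)] &
                  f[-1] > 0 & f[-1] < 1 & f[-nrow(H)] > 0 & f[-nrow(H)] < 1)
    mean(vapply(ok, function(j)
      lewontinDprime(f[j], f[j + 1], mean(H[j, ] & H[j + 1, ])), numeric(1)))
  }
  rates <- c(0.02, 0.2, 0.8)
  dp <- vapply(rates, function(r) {
    vals <- vapply(1:3, function(s)
      meanAdjDprime(generateGenotypes(
        LDModel(switchRate = r, nChromosomes = 2L), n = 60, p = 150,
        seed = 100 + s)), numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(dp) < 0))
})

test_that("at switch rate near 1 adjacent D' matches the independence null", {
  panel <- generateGenotypes(LDModel(switchRate = 0.99, founderCorrelation = 0,
                                     nChromosomes = 1L),
                             n = 150, p = 200, seed = 11)
  hap <- haplotypes(panel)
  H <- cbind(hap[, , 1], hap[, , 2])
  f <- rowMeans(H)
  ok <- which(f[-1] > 0 & f[-1] < 1 & f[-200] > 0 & f[-200] < 1)
  obs <- mean(vapply(ok, function(j)
    lewontinDprime(f[j], f[j + 1], mean(H[j, ] & H[j + 1, ])), numeric(1)))
  # independence oracle: permute each column's haplotypes independently
  set.seed(99)
  perm <- vapply(ok, function(j) {
    hj <- H[j, sample(ncol(H))]
    lewontinDprime(mean(hj), f[j + 1], mean(hj & H[j + 1, ]))
  }, numeric(1))
  expect_lt(abs(obs - mean(perm)), 3 * sd(perm) / sqrt(length(perm)) + 0.05)
})
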