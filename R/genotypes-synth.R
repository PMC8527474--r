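#' Generate a synthetic LD-structured genotype panel
#'
#' Emulates a medium-density SNP array with block-wise linkage
#' disequilibrium. A pool of founder haplotypes is drawn with per-SNP allele
#' frequencies uniform on the model's `mafRange`; each individual is then
#' built as two mosaic copies of the founders, where the copied template
#' switches to a uniformly chosen founder with probability `switchRate` at
#' each SNP. Small switch rates give long shared founder segments and hence
#' strong local LD; rates near 1 give essentially independent SNPs. SNPs are
#' spread over `nChromosomes` chromosomes with mean spacing `snpSpacingBp`
#' (default 65 kb, so a 15-SNP window spans roughly 1 Mb). The phased
#' haplotypes are retained in the panel metadata for downstream LD
#' computations, and `sampleOrder` is the generation order (used as an age
#' stand-in by [splitByAge()]).
#'
#' @param model an [LDModel-class]; see [LDModel()] for defaults.
#' @param n number of diploid individuals (>= 2).
#' @param p number of SNPs (>= 15).
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return a [GenotypePanel-class] with phased haplotypes in its metadata.
#' @examples
#' panel <- generateGenotypes(LDModel(nChromosomes = 2L), n = 50, p = 100, seed = 1)
#' panel
#' @export
generateGenotypes <- function(model = LDModel(), n, p, seed) {
  stopifnot(is(model, "LDModel"))
  validObject(model)
  if (n < 2) stop("need n >= 2 individuals")
  if (p < 15) stop("need p >= 15 SNPs")
  H <- model@nFounders
  rate <- model@switchRate

  withSeed(seed, {
    # chromosome assignment: near-equal SNP counts, positions with jittered
    # spacing whose expectation is snpSpacingBp
    base <- p %/% model@nChromosomes
    counts <- rep(base, model@nChromosomes)
    extra <- p - sum(counts)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    counts <- counts[counts > 0]
    chrom <- rep(paste0("chr", seq_along(counts)), counts)
    gaps <- pmax(1, round(runif(p, 0.5, 1.5) * model@snpSpacingBp))
    pos <- unlist(lapply(split(gaps, chrom)[unique(chrom)], cumsum),
                  use.names = FALSE)

    # founder pool: fresh Bernoulli(f0) draws, but each founder repeats its
    # previous allele state with probability founderCorrelation so the pool
    # itself carries decaying LD along each chromosome
    f0 <- runif(p, model@mafRange[1], model@mafRange[2])
    founders <- matrix(0L, nrow = H, ncol = p)
    fc <- model@founderCorrelation
    chromOf <- rep(seq_along(counts), counts)
    for (j in seq_len(p)) {
      fresh <- rbinom(H, 1L, f0[j])
      if (j > 1 && fc > 0 && chromOf[j] == chromOf[j - 1]) {
        keep <- runif(H) < fc
        founders[, j] <- ifelse(keep, founders[, j - 1], fresh)
      } else founders[, j] <- fresh
    }

    chromIdx <- split(seq_len(p), chrom)[unique(chrom)]
    hap <- array(0L, dim = c(p, n, 2L))
    for (i in seq_len(n)) {
      for (copy in 1:2) {
        for (ci in chromIdx) {
          m <- length(ci)
          sw <- c(TRUE, runif(m - 1) < rate)
          seg <- cumsum(sw)
          templates <- sample.int(H, max(seg), replace = TRUE)
          hap[ci, i, copy] <- founders[cbind(templates[seg], ci)]
        }
      }
    }
    counts2 <- hap[, , 1] + hap[, , 2]
    GenotypePanel(counts2, chrom = chrom, pos = pos,
                  sampleOrder = seq_len(n), haplotypes = hap)
  })
}
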