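# internal helpers

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  env <- parent.frame()
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval(substitute(expr), env)
}

# deterministic 32-bit-safe seed derivation (master -> stream)
deriveSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (x in parts) h <- (h * 69069 + round(abs(x) * 1021) + 1) %% 2147483629
  as.integer(h + 1)
}

# rebuild a panel keeping a subset of SNP rows (also subsets haplotypes)
subsetSnps <- function(panel, idx) {
  info <- snpInfo(panel)
  hap <- haplotypes(panel)
  GenotypePanel(alleleCounts(panel)[idx, , drop = FALSE],
                chrom = info$chrom[idx], pos = info$pos[idx],
                snpId = info$id[idx], sampleOrder = sampleOrder(panel),
                haplotypes = if (!is.null(hap)) hap[idx, , , drop = FALSE])
}
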