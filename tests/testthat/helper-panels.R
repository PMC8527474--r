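# shared fixture builders (all data generated in code)

# panel with exact per-SNP allele frequencies (single chromosome)
makeFreqPanel <- function(freqs, n = 100) {
  counts <- vapply(freqs, function(f) {
    nAlt <- round(2 * n * f)
    g <- integer(n)
    g[seq_len(nAlt %/% 2)] <- 2L
    if (nAlt %% 2 == 1) g[nAlt %/% 2 + 1] <- 1L
    g
  }, integer(n))
  GenotypePanel(t(counts), chrom = rep("chr1", length(freqs)),
                pos = seq_along(freqs) * 1000L)
}

# small LD panel for fit-based tests
smallPanel <- function(p = 120, n = 80, seed = 1, nChrom = 2L) {
  filterByMAF(generateGenotypes(LDModel(nChromosomes = nChrom), n = n, p = p,
                                seed = seed), 0.01)
}

# uniform random pip matrix with rows summing to 1
randomPip <- function(p, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(p * 4), ncol = 4)
  m / rowSums(m)
}

# exhaustive-enumeration posterior over class assignments for a K-class
# normal mixture with all hyperparameters clamped; returns p x K PIP matrix
enumeratePip <- function(X, y, classVars, piVec, sigmaE2, mu = 0) {
  p <- ncol(X); n <- nrow(X); K <- length(classVars)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), p)))
  logw <- apply(grid, 1, function(assign) {
    V <- classVars[assign]
    Sigma <- diag(sigmaE2, n)
    for (j in seq_len(p))
      if (V[j] > 0) Sigma <- Sigma + V[j] * tcrossprod(X[, j])
    ch <- chol(Sigma)
    z <- backsolve(ch, y - mu, transpose = TRUE)
    sum(log(piVec[assign])) - sum(log(diag(ch))) - 0.5 * sum(z^2)
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  pip <- matrix(0, p, K)
  for (j in seq_len(p))
    for (k in seq_len(K)) pip[j, k] <- sum(w[grid[, j] == k])
  pip
}

# brute-force AUROC: fraction of positive-negative pairs correctly ordered,
# ties counted 1/2
bruteAuroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0) return(0)
  if (length(neg) == 0) return(1)
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
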