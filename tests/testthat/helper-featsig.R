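## Shared fixtures and independent brute-force oracles for the test suite.
## The oracles deliberately use plain loops and never call the vectorized
## package internals they are checking.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

## -- brute-force expansion: nested loop over the joint pattern space ------
bruteExpand <- function(sig) {
  space <- featureSpace(sig)
  f <- featureProbs(sig)
  P <- nPatterns(space)
  out <- numeric(P)
  for (idx in seq_len(P)) {
    m <- decodePattern(space, idx)
    p <- 1
    for (l in seq_along(f)) p <- p * f[[l]][[m[l]]]
    out[idx] <- p
  }
  out
}

## -- brute-force log-likelihood: loop over samples and patterns -----------
bruteLogLik <- function(counts, sigs, Q, bg = NULL) {
  space <- featureSpace(sigs[[1L]])
  ll <- 0
  off <- as.integer(!is.null(bg))
  for (i in seq_len(nrow(counts))) {
    for (m in seq_len(ncol(counts))) {
      if (counts[i, m] == 0) next
      p <- 0
      if (!is.null(bg)) p <- p + Q[i, 1L] * patternProbs(bg)[[m]]
      for (k in seq_along(sigs))
        p <- p + Q[i, off + k] * patternProb(sigs[[k]], m)
      ll <- ll + counts[i, m] * log(p)
    }
  }
  ll
}

## -- brute-force E-step and M-step (the responsibility/update equations) --
bruteEStep <- function(counts, sigs, Q, bg = NULL) {
  off <- as.integer(!is.null(bg))
  Kstar <- length(sigs) + off
  obs <- which(colSums(counts) > 0)
  theta <- array(0, c(nrow(counts), Kstar, length(obs)))
  for (i in seq_len(nrow(counts))) {
    for (mi in seq_along(obs)) {
      m <- obs[mi]
      num <- numeric(Kstar)
      if (!is.null(bg)) num[1L] <- Q[i, 1L] * patternProbs(bg)[[m]]
      for (k in seq_along(sigs))
        num[off + k] <- Q[i, off + k] * patternProb(sigs[[k]], m)
      theta[i, , mi] <- num / sum(num)
    }
  }
  list(theta = theta, obs = obs)
}

bruteMStep <- function(counts, sigs, Q, bg = NULL) {
  space <- featureSpace(sigs[[1L]])
  M <- unname(cardinalities(space))
  es <- bruteEStep(counts, sigs, Q, bg)
  off <- as.integer(!is.null(bg))
  Kstar <- length(sigs) + off
  newF <- vector("list", length(sigs))
  for (k in seq_along(sigs)) {
    fk <- vector("list", length(M))
    for (l in seq_along(M)) {
      num <- numeric(M[l])
      for (i in seq_len(nrow(counts))) {
        for (mi in seq_along(es$obs)) {
          m <- es$obs[mi]
          ml <- decodePattern(space, m)[l]
          num[ml] <- num[ml] + counts[i, m] * es$theta[i, off + k, mi]
        }
      }
      fk[[l]] <- num / sum(num)
    }
    newF[[k]] <- fk
  }
  newQ <- matrix(0, nrow(counts), Kstar)
  for (i in seq_len(nrow(counts))) {
    for (k in seq_len(Kstar)) {
      s <- 0
      for (mi in seq_along(es$obs))
        s <- s + counts[i, es$obs[mi]] * es$theta[i, k, mi]
      newQ[i, k] <- s
    }
    newQ[i, ] <- newQ[i, ] / sum(newQ[i, ])
  }
  list(F = newF, Q = newQ)
}

## -- small random instances ----------------------------------------------
randomCatalog <- function(space, I = 4L, J = 100L, K = 2L, seed = 1L) {
  simulateCatalog(space, K = K, I = I, J = J, seed = seed, gamma = 0.5)
}

randomMemberships <- function(I, Kstar, seed = 1L) {
  set.seed(seed)
  Q <- matrix(rgamma(I * Kstar, 1), I, Kstar)
  Q / rowSums(Q)
}

## A SignatureFit built directly from known parts (for diagnostics tests).
makeFit <- function(space, sigs, Q, totals = rep(1, nrow(Q)), model = "independent") {
  names(sigs) <- sprintf("S%d", seq_along(sigs))
  colnames(Q) <- names(sigs)
  if (is.null(rownames(Q))) rownames(Q) <- sprintf("sample%d", seq_len(nrow(Q)))
  new("SignatureFit", space = space, model = model, signatures = sigs,
      background = NULL, memberships = Q,
      sampleTotals = stats::setNames(totals, rownames(Q)),
      logLik = NA_real_, logLikTrace = numeric(0), nRestarts = 1L,
      bestRestart = 1L, nIter = 0L, converged = TRUE, seed = NA_integer_)
}

## A point-mass independent signature concentrated on one feature vector.
pointMassSignature <- function(space, m) {
  M <- unname(cardinalities(space))
  f <- lapply(seq_along(M), function(l) {
    v <- rep(0, M[l]); v[m[l]] <- 1; v
  })
  IndependentSignature(space, f)
}

uniformSignature <- function(space) {
  M <- unname(cardinalities(space))
  IndependentSignature(space, lapply(M, function(m) rep(1 / m, m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTempTSV <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
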