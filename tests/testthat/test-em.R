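test_that("patternProb multiplies feature probabilities", {
  sp <- buildFeatureSpace(1)
  expect_equal(patternProb(uniformSignature(sp), c(1L, 1L, 1L)), 1 / 96)
  pm <- pointMassSignature(sp, c(2L, 3L, 1L))
  expect_equal(patternProb(pm, c(2L, 3L, 1L)), 1)
  expect_equal(patternProb(pm, c(2L, 3L, 2L)), 0)
  set.seed(41)
  sig <- randomSignature(sp, 1)
  full <- patternProbs(expandToFull(sig))
  for (idx in sample(96, 10))
    expect_equal(patternProb(sig, idx), unname(full[idx]), tolerance = 1e-12)
})

test_that("log-likelihood has its closed form and symmetries", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 3, J = 50, K = 2, seed = 42)
  catal <- sim$catalog
  N <- sum(totalMutations(catal))
  llUnif <- logLikelihood(catal, list(uniformSignature(sp)),
                          matrix(1, 3, 1))
  expect_equal(llUnif, N * log(1 / 96), tolerance = 1e-10)

  set.seed(43)
  sigs <- list(randomSignature(sp, 1), randomSignature(sp, 1))
  Q <- randomMemberships(3, 2, seed = 44)
  ll <- logLikelihood(catal, sigs, Q)
  ## label symmetry
  expect_equal(logLikelihood(catal, sigs[c(2, 1)], Q[, c(2, 1)]), ll,
               tolerance = 1e-12)
  ## brute-force per-pattern loop
  expect_equal(ll, bruteLogLik(as.matrix(mutationCounts(catal)), sigs, Q),
               tolerance = 1e-10)
})

test_that("E-step responsibilities match direct arithmetic", {
  sp0 <- buildFeatureSpace(0)
  ## one sample, one mutation of substitution type 1
  catal <- catalogFromTriplets(sp0, "s1", 1L)
  f1 <- c(0.8, 0.04, 0.04, 0.04, 0.04, 0.04)
  f2 <- c(0.2, 0.16, 0.16, 0.16, 0.16, 0.16)
  sigs <- list(IndependentSignature(sp0, list(f1)),
               IndependentSignature(sp0, list(f2)))
  es <- eStep(catal, sigs, matrix(c(0.5, 0.5), 1))
  expect_equal(as.vector(es$theta[1, , 1]), c(0.8, 0.2), tolerance = 1e-12)

  ## K = 1 gives unit responsibilities
  es1 <- eStep(catal, sigs[1], matrix(1, 1, 1))
  expect_equal(as.vector(es1$theta), 1)

  ## deterministic disjoint signatures split patterns 0/1
  sp <- buildFeatureSpace(1)
  cat2 <- catalogFromTriplets(sp, c("s1", "s1"), c(1L, 96L))
  own <- list(pointMassSignature(sp, c(1L, 1L, 1L)),
              pointMassSignature(sp, c(6L, 4L, 4L)))
  es2 <- eStep(cat2, own, matrix(c(0.5, 0.5), 1))
  expect_equal(as.vector(es2$theta[1, , ]), c(1, 0, 0, 1))
})

test_that("one EM step matches the brute-force update equations", {
  sp <- buildFeatureSpace(1)
  for (seed in c(51, 52)) {
    sim <- randomCatalog(sp, I = 4, J = 50, K = 2, seed = seed)
    counts <- as.matrix(mutationCounts(sim$catalog))
    set.seed(seed + 100)
    sigs <- list(randomSignature(sp, 1), randomSignature(sp, 1))
    Q <- randomMemberships(4, 2, seed = seed + 200)
    es <- eStep(sim$catalog, sigs, Q)
    oracle <- bruteEStep(counts, sigs, Q)
    expect_equal(unname(es$theta), oracle$theta, tolerance = 1e-10)
    ms <- mStep(sim$catalog, es)
    oracleM <- bruteMStep(counts, sigs, Q)
    for (k in 1:2) for (l in 1:3)
      expect_equal(unname(featureProbs(ms$signatures[[k]])[[l]]),
                   oracleM$F[[k]][[l]], tolerance = 1e-10)
    expect_equal(unname(ms$memberships), oracleM$Q, tolerance = 1e-10)
    ## the fitting loop applies exactly this update
    fit1 <- fitSignatures(sim$catalog, 2, nRestarts = 1, maxIter = 1,
                          init = list(F = lapply(sigs, function(s)
                            lapply(featureProbs(s), unname)), Q = Q))
    for (k in 1:2) for (l in 1:3)
      expect_equal(unname(featureProbs(signatures(fit1)[[k]])[[l]]),
                   oracleM$F[[k]][[l]], tolerance = 1e-10)
  }
})

test_that("M-step reduces to empirical frequencies in degenerate cases", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 3, J = 60, K = 1, seed = 61)
  catal <- sim$catalog
  es <- eStep(catal, list(uniformSignature(sp)), matrix(1, 3, 1))
  ms <- mStep(catal, es)
  counts <- Matrix::colSums(mutationCounts(catal))
  pm <- decodePattern(sp, seq_len(96))
  for (l in 1:3) {
    emp <- vapply(seq_len(unname(cardinalities(sp))[l]), function(v)
      sum(counts[pm[, l] == v]), numeric(1))
    expect_equal(unname(featureProbs(ms$signatures[[1]])[[l]]),
                 emp / sum(emp), tolerance = 1e-12)
  }
  expect_equal(as.vector(ms$memberships), c(1, 1, 1))
})

test_that("plain EM log-likelihood never decreases", {
  sp <- buildFeatureSpace(1)
  for (seed in 71:75) {
    sim <- randomCatalog(sp, I = 4, J = 80, K = 2, seed = seed)
    fit <- fitSignatures(sim$catalog, 2, nRestarts = 1, seed = seed,
                         maxIter = 60, tol = 0)
    expect_true(all(diff(logLikTrace(fit)) >= -1e-8))
  }
})

test_that("a single planted signature is recovered at large J", {
  sp <- buildFeatureSpace(1)
  set.seed(81)
  truth <- randomSignature(sp, 0.5)
  sim <- simulateCatalog(sp, signatures = list(truth), I = 1, J = 1e4, seed = 81)
  fit <- fitSignatures(sim$catalog, 1, nRestarts = 2, seed = 82, tol = 1e-9,
                       maxIter = 500)
  tv <- 0.5 * sum(abs(patternProbs(expandToFull(signatures(fit)[[1]])) -
                      patternProbs(expandToFull(truth))))
  expect_lt(tv, 0.02)
})

test_that("two well-separated signatures are recovered", {
  sp <- buildFeatureSpace(1)
  set.seed(91)
  repeat {
    sigs <- list(randomSignature(sp, 0.3), randomSignature(sp, 0.3))
    if (cosineSimilarity(sigs[[1]], sigs[[2]]) < 0.5) break
  }
  sim <- simulateCatalog(sp, signatures = sigs, I = 10, J = 1000, seed = 92)
  fit <- fitSignatures(sim$catalog, 2, nRestarts = 5, seed = 93, tol = 1e-8,
                       maxIter = 1000)
  perm <- matchSignatures(signatures(fit), sigs)
  expect_true(all(attr(perm, "similarity") >= 0.99))
})

test_that("relabeling samples permutes the fit equivariantly", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 5, J = 100, K = 2, seed = 95)
  counts <- as.matrix(mutationCounts(sim$catalog))
  perm <- c(3, 1, 5, 2, 4)
  catP <- MutationCatalog(sp, counts[perm, ])
  f1 <- fitSignatures(sim$catalog, 2, nRestarts = 2, seed = 7,
                      maxIter = 3000, tol = 1e-12)
  f2 <- fitSignatures(catP, 2, nRestarts = 2, seed = 7,
                      maxIter = 3000, tol = 1e-12)
  expect_equal(logLik(f2), logLik(f1), tolerance = 1e-8)
  sigPerm <- matchSignatures(signatures(f2), signatures(f1))
  expect_equal(unname(memberships(f2)[, sigPerm]),
               unname(memberships(f1)[perm, ]), tolerance = 1e-4)
})

test_that("the full model on product expansions reproduces the independent likelihood", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 4, J = 100, K = 2, seed = 101)
  set.seed(102)
  sigs <- list(randomSignature(sp, 1), randomSignature(sp, 1))
  Q <- randomMemberships(4, 2, seed = 103)
  fullSigs <- lapply(sigs, expandToFull)
  expect_equal(logLikelihood(sim$catalog, fullSigs, Q),
               logLikelihood(sim$catalog, sigs, Q), tolerance = 1e-10)
})

test_that("accelerated and plain EM reach the same optimum", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 5, J = 300, K = 2, seed = 111)
  plain <- fitSignatures(sim$catalog, 2, nRestarts = 3, seed = 5,
                         tol = 1e-12, maxIter = 5000)
  accel <- fitSignatures(sim$catalog, 2, nRestarts = 3, seed = 5,
                         tol = 1e-12, maxIter = 5000, accelerate = TRUE)
  expect_equal(logLik(accel), logLik(plain), tolerance = 1e-6)
  expect_true(all(diff(logLikTrace(accel)) >= -1e-6))
})

test_that("background-only data pushes the background membership to one", {
  sp <- buildFeatureSpace(1)
  bg <- uniformBackground(sp)
  set.seed(121)
  counts <- t(stats::rmultinom(1, 20000, patternProbs(bg)))
  rownames(counts) <- "s1"
  catal <- MutationCatalog(sp, counts)
  fit <- fitSignatures(catal, 1, background = bg, nRestarts = 3, seed = 122,
                       maxIter = 2000, tol = 1e-10)
  expect_gt(memberships(fit)[1, "background"], 0.8)
})

test_that("fit warns when K exceeds the observed pattern diversity", {
  sp <- buildFeatureSpace(0)
  catal <- catalogFromTriplets(sp, c("s1", "s1"), c(1L, 2L), c(5, 5))
  expect_warning(fitSignatures(catal, 3, nRestarts = 1, seed = 1, maxIter = 20),
                 "exceeds")
})
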