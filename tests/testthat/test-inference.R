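test_that("cosine similarity behaves on the expanded pattern space", {
  sp <- buildFeatureSpace(1)
  set.seed(131)
  sig <- randomSignature(sp, 1)
  expect_equal(cosineSimilarity(sig, sig), 1, tolerance = 1e-12)
  expect_equal(cosineSimilarity(sig, expandToFull(sig)), 1, tolerance = 1e-12)
  a <- pointMassSignature(sp, c(1L, 1L, 1L))
  b <- pointMassSignature(sp, c(2L, 2L, 2L))
  expect_equal(cosineSimilarity(a, b), 0)
  expect_error(cosineSimilarity(sig, randomSignature(buildFeatureSpace(2), 1)),
               "different feature spaces")
})

test_that("Frobenius distance is the l2 distance of parameter matrices", {
  sp <- buildFeatureSpace(1)
  set.seed(132)
  sig <- randomSignature(sp, 1)
  expect_equal(frobeniusDistance(sig, sig), 0)
  a <- pointMassSignature(sp, c(1L, 1L, 1L))
  b <- pointMassSignature(sp, c(2L, 1L, 1L))   # differs in one feature value
  expect_equal(frobeniusDistance(a, b), sqrt(2), tolerance = 1e-12)
  sig2 <- randomSignature(sp, 1)
  expect_equal(frobeniusDistance(sig, sig2), frobeniusDistance(sig2, sig))
  ## direct sum-of-squares oracle
  d2 <- sum((unlist(featureProbs(sig)) - unlist(featureProbs(sig2)))^2)
  expect_equal(frobeniusDistance(sig, sig2), sqrt(d2), tolerance = 1e-12)
  expect_error(frobeniusDistance(expandToFull(sig), expandToFull(sig2)),
               "independent")
})

test_that("signature matching resolves label switching", {
  sp <- buildFeatureSpace(1)
  set.seed(133)
  ref <- list(randomSignature(sp, 0.3), randomSignature(sp, 0.3),
              randomSignature(sp, 0.3))
  shuffled <- ref[c(3, 1, 2)]
  for (method in c("greedy", "exact")) {
    perm <- matchSignatures(shuffled, ref, method = method)
    expect_equal(as.integer(perm), c(2L, 3L, 1L))
    expect_equal(attr(perm, "similarity"), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("membership correlation diagnoses duplicated signatures", {
  sp <- buildFeatureSpace(1)
  set.seed(134)
  sigs <- list(randomSignature(sp, 1), randomSignature(sp, 1),
               randomSignature(sp, 1))
  q1 <- runif(6)
  Q <- cbind(q1, q1, 2 - 2 * q1)
  Q <- Q / rowSums(Q)
  fit <- makeFit(sp, sigs, Q)
  C <- membershipCorrelation(fit)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_lt(C[1, 3], 0)

  ## orthogonal loadings: each sample on one signature -> negative off-diag
  Q2 <- diag(3)[rep(1:3, 2), ]
  fit2 <- makeFit(sp, sigs, Q2)
  C2 <- membershipCorrelation(fit2)
  expect_true(all(C2[upper.tri(C2)] < 0))

  ## constant column -> 0 with warning
  u <- runif(4, 0.1, 0.4)
  Qc <- cbind(0.5, u, 0.5 - u)
  fitc <- makeFit(sp, sigs, Qc)
  expect_warning(Cc <- membershipCorrelation(fitc), "constant")
  expect_equal(Cc[1, 2], 0)
})

test_that("bootstrap SEs are zero for a deterministic catalog", {
  sp <- buildFeatureSpace(1)
  catal <- catalogFromTriplets(sp, c("s1", "s2", "s3"), rep(5L, 3))
  fit <- fitSignatures(catal, 1, nRestarts = 1, seed = 1, maxIter = 50)
  boot <- bootstrapSE(catal, fit, B = 5, seed = 2)
  expect_equal(meanSignatureSE(boot), 0)
  expect_true(all(boot@membershipSE == 0))
  expect_error(bootstrapSE(catal, fit, B = 1), "B must be")
  expect_equal(eval(formals(bootstrapSE)$B), 100L)
})

test_that("bootstrap SEs have sane shape and magnitude on simulated data", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 6, J = 200, K = 2, seed = 141)
  fit <- fitSignatures(sim$catalog, 2, nRestarts = 3, seed = 142, maxIter = 500,
                       tol = 1e-8)
  boot <- bootstrapSE(sim$catalog, fit, B = 15, seed = 143)
  expect_equal(length(boot@signatureSE), 2L)
  expect_equal(dim(boot@membershipSE), dim(memberships(fit)))
  expect_true(all(unlist(boot@signatureSE) >= 0))
  expect_gt(meanSignatureSE(boot), 0)
})

test_that("merging clusters by single linkage under the distance threshold", {
  sp <- buildFeatureSpace(1)
  set.seed(151)
  base <- randomSignature(sp, 0.3)
  ## two copies of one signature merge into a single cluster
  fitA <- makeFit(sp, list(base), matrix(1, 2, 1), totals = c(10, 20))
  fitB <- makeFit(sp, list(base), matrix(1, 2, 1), totals = c(5, 5))
  m <- mergeSignatures(list(a = fitA, b = fitB), threshold = 0.6)
  expect_equal(length(m), 1L)
  expect_equal(nrow(m[[1]]$members), 2L)
  expect_equal(unlist(featureProbs(m[[1]]$consensus)),
               unlist(featureProbs(base)), ignore_attr = TRUE,
               tolerance = 1e-12)

  ## distant signatures stay singletons
  far1 <- pointMassSignature(sp, c(1L, 1L, 1L))
  far2 <- pointMassSignature(sp, c(2L, 2L, 2L))
  mf <- mergeSignatures(list(a = makeFit(sp, list(far1), matrix(1, 1, 1)),
                             b = makeFit(sp, list(far2), matrix(1, 1, 1))),
                        threshold = 0.6)
  expect_equal(length(mf), 2L)

  ## chain A-B close, B-C close, A-C far -> one cluster (single linkage)
  mk <- function(eps) {
    f <- lapply(unname(cardinalities(sp)), function(m) {
      v <- rep((1 - eps) / m, m); v[1] <- v[1] + eps; v
    })
    IndependentSignature(sp, f)
  }
  A <- mk(0); B <- mk(0.3); C <- mk(0.6)
  expect_lt(frobeniusDistance(A, B), 0.6)
  expect_lt(frobeniusDistance(B, C), 0.6)
  expect_gt(frobeniusDistance(A, C), 0.6)
  mc <- mergeSignatures(list(x = makeFit(sp, list(A), matrix(1, 1, 1)),
                             y = makeFit(sp, list(B), matrix(1, 1, 1)),
                             z = makeFit(sp, list(C), matrix(1, 1, 1))),
                        threshold = 0.6)
  expect_equal(length(mc), 1L)

  ## input order does not change the clustering
  mc2 <- mergeSignatures(list(z = makeFit(sp, list(C), matrix(1, 1, 1)),
                              x = makeFit(sp, list(A), matrix(1, 1, 1)),
                              y = makeFit(sp, list(B), matrix(1, 1, 1))),
                         threshold = 0.6)
  expect_equal(lapply(mc2, `[[`, "members"), lapply(mc, `[[`, "members"))
  expect_error(mergeSignatures(list()), "no fits")
})

test_that("the K-selection report covers the range with sane diagnostics", {
  sp <- buildFeatureSpace(1)
  sim <- randomCatalog(sp, I = 8, J = 300, K = 2, seed = 161)
  rep_ <- kSelectionReport(sim$catalog, Ks = 1:3, B = 4, seed = 162,
                           nRestarts = 3, maxIter = 300, tol = 1e-7)
  expect_equal(rep_$K, 1:3)
  ## nested models: best-of-restarts likelihood non-decreasing in K
  expect_true(all(diff(rep_$logLik) >= -1e-4 * abs(rep_$logLik[-1])))
  expect_true(all(rep_$meanSigSE >= 0))
  expect_true(is.na(rep_$maxMembershipCor[1]))
  expect_error(kSelectionReport(sim$catalog, integer(0)), "empty")
})
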