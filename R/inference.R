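#' Cosine similarity between two signatures
#'
#' Both signatures are expanded to the full joint pattern space before the
#' cosine is taken, which allows comparison between independent-model and
#' full-model signatures over the same space.
#'
#' @param sigA,sigB signatures ([IndependentSignature-class] or
#'   [FullSignature-class]) over the same feature space.
#' @return numeric in \[0, 1\].
#' @export
cosineSimilarity <- function(sigA, sigB) {
  if (!identical(sigA@space@M, sigB@space@M))
    stop("signatures live in different feature spaces")
  a <- expandToFull(sigA)@probs
  b <- expandToFull(sigB)@probs
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Frobenius distance between two independent-model signatures
#'
#' The entrywise l2 distance of the signature parameter matrices (the
#' per-feature probability vectors arranged as rows), i.e.
#' sqrt(Tr((F1 - F2)(F1 - F2)^t)).  Signatures closer than a threshold
#' (0.6 in typical use) are considered the same mutational process.
#'
#' @param sigA,sigB [IndependentSignature-class] objects on the same space.
#' @return non-negative numeric.
#' @export
frobeniusDistance <- function(sigA, sigB) {
  if (!is(sigA, "IndependentSignature") || !is(sigB, "IndependentSignature"))
    stop("Frobenius distance is defined for independent-model signatures")
  if (!identical(sigA@space@M, sigB@space@M))
    stop("signatures live in different feature spaces")
  d2 <- 0
  for (l in seq_along(sigA@f))
    d2 <- d2 + sum((sigA@f[[l]] - sigB@f[[l]])^2)
  sqrt(d2)
}

#' Match one set of signatures to a reference set
#'
#' Resolves label switching: components are matched to the reference by
#' cosine similarity on the expanded pattern space, either greedily
#' (repeatedly taking the best remaining pair) or by exact assignment
#' (enumerating permutations, `method = "exact"`, K <= 8).
#'
#' @param sigs list of signatures to relabel.
#' @param ref list of reference signatures (same length and space).
#' @param method `"greedy"` (default) or `"exact"`.
#' @return integer vector `perm` such that `sigs[[perm[k]]]` corresponds to
#'   `ref[[k]]`, with the matched cosine similarities as attribute
#'   `"similarity"`.
#' @export
matchSignatures <- function(sigs, ref, method = c("greedy", "exact")) {
  method <- match.arg(method)
  K <- length(ref)
  if (length(sigs) != K) stop("signature sets differ in size")
  S <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    S[i, j] <- cosineSimilarity(ref[[i]], sigs[[j]])
  perm <- integer(K)
  if (method == "greedy") {
    Swork <- S
    for (step in seq_len(K)) {
      ij <- arrayInd(which.max(Swork), dim(Swork))
      perm[ij[1L]] <- ij[2L]
      Swork[ij[1L], ] <- -Inf
      Swork[, ij[2L]] <- -Inf
    }
  } else {
    if (K > 8L) stop("exact matching supported for K <= 8")
    perms <- .permutations(K)
    tot <- apply(perms, 1L, function(p) sum(S[cbind(seq_len(K), p)]))
    perm <- perms[which.max(tot), ]
  }
  attr(perm, "similarity") <- S[cbind(seq_len(K), perm)]
  perm
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Non-parametric bootstrap standard errors for a fitted model
#'
#' Mutations are resampled with replacement within each sample (preserving
#' each sample's total), the model is refitted warm-started at the original
#' estimates, components are matched back to the original fit by cosine
#' similarity, and standard errors are the sample standard deviations of
#' the matched parameter estimates across replicates.
#'
#' @param catalog the [MutationCatalog-class] the fit was produced from.
#' @param fit the original [SignatureFit-class].
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @param keepReplicates logical; retain per-replicate estimates.
#' @param tol,maxIter EM settings for the warm-started refits.
#' @return A [BootstrapResult-class].
#' @export
bootstrapSE <- function(catalog, fit, B = 100L, seed = NULL,
                        keepReplicates = FALSE, tol = 1e-8, maxIter = 2000L) {
  if (B < 2L) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  counts <- as.matrix(catalog@counts)
  I <- nrow(counts)
  K <- length(fit@signatures)
  hasBg <- !is.null(fit@background)
  sigDraws <- vector("list", B)
  memDraws <- vector("list", B)
  for (b in seq_len(B)) {
    bc <- counts
    for (i in seq_len(I)) {
      J <- sum(counts[i, ])
      if (J > 0)
        bc[i, ] <- as.numeric(stats::rmultinom(1L, J, counts[i, ] / J))
    }
    bcat <- MutationCatalog(catalog@space, bc)
    refit <- fitSignatures(bcat, K, model = fit@model,
                           background = fit@background, nRestarts = 1L,
                           tol = tol, maxIter = maxIter, init = fit)
    perm <- matchSignatures(refit@signatures, fit@signatures)
    sigDraws[[b]] <- refit@signatures[perm]
    Q <- refit@memberships
    ord <- c(if (hasBg) 1L, as.integer(perm) + as.integer(hasBg))
    memDraws[[b]] <- Q[, ord, drop = FALSE]
  }
  sigSE <- vector("list", K)
  for (k in seq_len(K)) {
    if (fit@model == "independent") {
      sigSE[[k]] <- lapply(seq_along(fit@space@M), function(l) {
        draws <- vapply(sigDraws, function(s) s[[k]]@f[[l]],
                        numeric(fit@space@M[l]))
        if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1L)
        stats::setNames(apply(draws, 1L, stats::sd), fit@space@labels[[l]])
      })
      names(sigSE[[k]]) <- names(fit@space@labels)
    } else {
      draws <- vapply(sigDraws, function(s) s[[k]]@probs,
                      numeric(nPatterns(fit@space)))
      sigSE[[k]] <- apply(draws, 1L, stats::sd)
    }
  }
  names(sigSE) <- names(fit@signatures)
  memArr <- simplify2array(memDraws)
  memSE <- apply(memArr, c(1L, 2L), stats::sd)
  dimnames(memSE) <- dimnames(fit@memberships)
  new("BootstrapResult", B = as.integer(B), signatureSE = sigSE,
      membershipSE = memSE,
      replicates = if (keepReplicates)
        list(signatures = sigDraws, memberships = memDraws) else list())
}

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d replicates, %d signature(s)\n",
    object@B, length(object@signatureSE)))
  cat(sprintf("  mean signature SE = %.4g; mean membership SE = %.4g\n",
    meanSignatureSE(object), mean(object@membershipSE)))
})

#' Mean signature standard error of a bootstrap result
#' @param boot a [BootstrapResult-class].
#' @return numeric scalar.
#' @export
meanSignatureSE <- function(boot) {
  mean(unlist(boot@signatureSE, use.names = FALSE))
}

#' Correlation matrix of membership columns
#'
#' Pearson correlations between the per-sample membership proportions of
#' each pair of signatures (the fixed background component is excluded).
#' Strongly correlated columns whose signatures also look alike suggest one
#' signature was split in two, i.e. K is too large.
#'
#' @param fit a [SignatureFit-class] with at least 3 samples.
#' @return K x K symmetric correlation matrix with unit diagonal; constant
#'   columns yield 0 with a warning.
#' @export
membershipCorrelation <- function(fit) {
  Q <- fit@memberships
  if (!is.null(fit@background)) Q <- Q[, -1L, drop = FALSE]
  if (nrow(Q) < 3L) stop("membership correlation requires >= 3 samples")
  K <- ncol(Q)
  sds <- apply(Q, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant membership column(s); correlations reported as 0")
  C <- matrix(0, K, K, dimnames = list(colnames(Q), colnames(Q)))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    C[i, j] <- if (i == j) 1 else if (sds[i] == 0 || sds[j] == 0) 0 else
      stats::cor(Q[, i], Q[, j])
  }
  C
}

#' Merge similar signatures across fits
#'
#' Pools the signatures of several fits (e.g. one per cancer type) and
#' clusters them by single linkage on the Frobenius distance: clusters are
#' formed exactly by the chains of signatures whose linkage distance is
#' strictly below `threshold`.  Each cluster reports a consensus signature:
#' the mutation-count-weighted average of the members' per-feature
#' probability vectors, renormalized per feature.
#'
#' @param fits named list of [SignatureFit-class] objects (independent
#'   model) sharing one feature space; names are the group labels.
#' @param threshold merge distance threshold (default 0.6).
#' @return list of clusters, each a list with `members` (data.frame of
#'   group, signature, weight) and `consensus` (an
#'   [IndependentSignature-class]); clusters are ordered by their
#'   lexicographically first member.
#' @export
mergeSignatures <- function(fits, threshold = 0.6) {
  if (length(fits) == 0L) stop("no fits supplied")
  if (is.null(names(fits))) names(fits) <- sprintf("group%d", seq_along(fits))
  space <- fits[[1L]]@space
  sigs <- list(); groups <- character(0); signames <- character(0); weights <- numeric(0)
  for (g in names(fits)) {
    fit <- fits[[g]]
    if (!identical(fit@space@M, space@M)) stop("fits use different feature spaces")
    Jtot <- fit@sampleTotals
    Q <- fit@memberships
    if (!is.null(fit@background)) Q <- Q[, -1L, drop = FALSE]
    for (k in seq_along(fit@signatures)) {
      sigs[[length(sigs) + 1L]] <- fit@signatures[[k]]
      groups <- c(groups, g)
      signames <- c(signames, names(fit@signatures)[k])
      w <- if (length(Jtot) == nrow(Q)) sum(Q[, k] * Jtot) else sum(Q[, k])
      weights <- c(weights, w)
    }
  }
  ## deterministic pooling order regardless of input order
  ord <- order(groups, signames)
  sigs <- sigs[ord]; groups <- groups[ord]
  signames <- signames[ord]; weights <- weights[ord]
  n <- length(sigs)
  cl <- rep(1L, n)
  if (n > 1L) {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- frobeniusDistance(sigs[[i]], sigs[[j]])
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    nClusters <- sum(hc$height >= threshold) + 1L  # merge strictly below
    cl <- stats::cutree(hc, k = nClusters)
  }
  out <- list()
  for (c_ in sort(unique(cl))) {
    idx <- which(cl == c_)
    w <- weights[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    fcons <- lapply(seq_along(space@M), function(l) {
      v <- rep(0, space@M[l])
      for (ii in seq_along(idx)) v <- v + w[ii] * sigs[[idx[ii]]]@f[[l]]
      v / sum(v)
    })
    out[[length(out) + 1L]] <- list(
      members = data.frame(group = groups[idx], signature = signames[idx],
                           weight = weights[idx], stringsAsFactors = FALSE),
      consensus = IndependentSignature(space, fcons))
  }
  firsts <- vapply(out, function(cluster)
    paste(cluster$members$group[1L], cluster$members$signature[1L]), character(1L))
  out[order(firsts)]
}

#' Model-selection diagnostics over a range of K
#'
#' Fits the model for each K, runs a reduced bootstrap, and reports the
#' log-likelihood, the mean bootstrap standard error of the signature
#' parameters, and the largest off-diagonal membership correlation.  The
#' table supports the manual selection strategy — pick K where the
#' likelihood is high, standard errors are low, and no pair of signatures
#' shows strongly correlated memberships — and never chooses K itself.
#'
#' @param catalog a [MutationCatalog-class].
#' @param Ks integer vector of candidate signature numbers.
#' @param B bootstrap replicates per K (default 20, reduced for speed).
#' @param seed optional integer seed.
#' @param ... passed to [fitSignatures()].
#' @return data.frame with columns K, logLik, meanSigSE, maxMembershipCor.
#' @export
kSelectionReport <- function(catalog, Ks, B = 20L, seed = NULL, ...) {
  if (length(Ks) == 0L) stop("empty K range")
  rows <- lapply(seq_along(Ks), function(ki) {
    K <- Ks[ki]
    fit <- fitSignatures(catalog, K,
                         seed = if (!is.null(seed)) seed + ki else NULL, ...)
    boot <- bootstrapSE(catalog, fit, B = B,
                        seed = if (!is.null(seed)) seed + 1000L + ki else NULL)
    corMax <- if (K >= 2L && nrow(fit@memberships) >= 3L) {
      C <- suppressWarnings(membershipCorrelation(fit))
      max(C[upper.tri(C)])
    } else NA_real_
    data.frame(K = K, logLik = fit@logLik,
               meanSigSE = meanSignatureSE(boot),
               maxMembershipCor = corMax)
  })
  do.call(rbind, rows)
}
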