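## EM engine for the mixed-membership signature model.
##
## Internally the model is fitted in the reduced space of *observed*
## patterns: G (samples x observed patterns) holds the counts, `feat` the
## feature values of each observed pattern.  A state is
##   list(F = list of K signature parameter sets, Q = memberships)
## where each F[[k]] is a list of per-feature probability vectors
## (independent model) or a probability vector over observed patterns
## (full model).  When a background is present its fixed probabilities over
## observed patterns (`bgobs`) occupy mixture column 1 and only its
## membership weight is updated.

.componentProbs <- function(Fk, feat, model, bgobs = NULL) {
  K <- length(Fk)
  P <- matrix(0, nrow(feat), K + as.integer(!is.null(bgobs)))
  off <- 0L
  if (!is.null(bgobs)) {
    P[, 1L] <- bgobs
    off <- 1L
  }
  for (k in seq_len(K)) {
    if (model == "independent") {
      p <- rep(1, nrow(feat))
      for (l in seq_along(Fk[[k]])) p <- p * Fk[[k]][[l]][feat[, l]]
      P[, off + k] <- p
    } else {
      P[, off + k] <- Fk[[k]]
    }
  }
  P
}

.emLogLik <- function(state, G, feat, model, bgobs) {
  P <- .componentProbs(state$F, feat, model, bgobs)
  D <- state$Q %*% t(P)
  pos <- G > 0
  if (any(D[pos] <= 0)) return(-Inf)
  sum(G[pos] * log(D[pos]))
}

## One EM update (E-step Eq for responsibilities, M-step with the sum over
## samples in both numerator and denominator of the f update).
.emUpdate <- function(state, G, feat, M, model, bgobs, pseudocount = 0) {
  Q <- state$Q
  K <- length(state$F)
  hasBg <- !is.null(bgobs)
  off <- as.integer(hasBg)
  P <- .componentProbs(state$F, feat, model, bgobs)
  D <- Q %*% t(P)                      # I x Pobs mixture probabilities
  W <- G / D
  W[G == 0] <- 0                       # avoid 0/0 for unobserved cells
  A <- (t(W) %*% Q) * P                # Pobs x K*: sum_i g_im * theta_ikm
  N <- (W %*% P) * Q                   # I x K*:  sum_m g_im * theta_ikm
  newF <- state$F
  for (k in seq_len(K)) {
    w <- A[, off + k]
    if (sum(w) <= .Machine$double.eps * sum(G)) {
      warning("signature ", k, " received ~zero responsibility; re-initializing")
      newF[[k]] <- .randomSignatureParams(M, model, nrow(feat))
      next
    }
    if (model == "independent") {
      fk <- vector("list", length(M))
      for (l in seq_along(M)) {
        num <- rep(0, M[l])
        s <- rowsum(w, feat[, l])
        num[as.integer(rownames(s))] <- s[, 1L]
        num <- num + pseudocount
        fk[[l]] <- num / sum(num)
      }
      newF[[k]] <- fk
    } else {
      num <- w + pseudocount
      newF[[k]] <- num / sum(num)
    }
  }
  rs <- rowSums(N)
  empty <- rs <= 0
  rs[empty] <- 1
  newQ <- N / rs
  ## samples with no mutations carry no information: uniform memberships
  if (any(empty)) newQ[empty, ] <- 1 / ncol(newQ)
  list(F = newF, Q = newQ)
}

.randomSignatureParams <- function(M, model, nObs) {
  if (model == "independent") {
    lapply(M, function(m) .rdirichlet1(rep(1, m)))
  } else {
    .rdirichlet1(rep(1, nObs))
  }
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

## --- state packing for SQUAREM-style extrapolation ---------------------

.packState <- function(state) {
  c(unlist(state$F, use.names = FALSE), as.vector(state$Q))
}

.unpackState <- function(par, template) {
  state <- template
  pos <- 1L
  for (k in seq_along(template$F)) {
    if (is.list(template$F[[k]])) {
      for (l in seq_along(template$F[[k]])) {
        n <- length(template$F[[k]][[l]])
        v <- pmax(par[pos:(pos + n - 1L)], 1e-10)
        state$F[[k]][[l]] <- v / sum(v)
        pos <- pos + n
      }
    } else {
      n <- length(template$F[[k]])
      v <- pmax(par[pos:(pos + n - 1L)], 1e-10)
      state$F[[k]] <- v / sum(v)
      pos <- pos + n
    }
  }
  nq <- length(template$Q)
  Qv <- pmax(par[pos:(pos + nq - 1L)], 1e-10)
  Q <- matrix(Qv, nrow(template$Q), ncol(template$Q))
  state$Q <- Q / rowSums(Q)
  dimnames(state$Q) <- dimnames(template$Q)
  state
}

## --- single restart ----------------------------------------------------

.fitOneRestart <- function(state, G, feat, M, model, bgobs,
                           tol, maxIter, accelerate, pseudocount) {
  upd <- function(s) .emUpdate(s, G, feat, M, model, bgobs, pseudocount)
  ll <- .emLogLik(state, G, feat, model, bgobs)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    if (!accelerate) {
      state <- upd(state)
      iter <- iter + 1L
    } else {
      ## SQUAREM (SqS3) squared extrapolation with monotonicity safeguard
      s1 <- upd(state)
      s2 <- upd(s1)
      iter <- iter + 2L
      x0 <- .packState(state); x1 <- .packState(s1); x2 <- .packState(s2)
      r <- x1 - x0
      v <- (x2 - x1) - r
      vnorm <- sqrt(sum(v^2))
      if (vnorm > 0) {
        alpha <- -sqrt(sum(r^2)) / vnorm
        cand <- .unpackState(x0 - 2 * alpha * r + alpha^2 * v, state)
        cand <- upd(cand)           # stabilizing EM step
        iter <- iter + 1L
        llCand <- .emLogLik(cand, G, feat, model, bgobs)
        ll2 <- .emLogLik(s2, G, feat, model, bgobs)
        state <- if (is.finite(llCand) && llCand >= ll2) cand else s2
      } else {
        state <- s2
      }
    }
    llNew <- .emLogLik(state, G, feat, model, bgobs)
    trace <- c(trace, llNew)
    if (is.finite(ll) && abs(llNew - ll) <= tol * (abs(ll) + tol)) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  list(state = state, logLik = ll, trace = trace,
       converged = converged, nIter = iter)
}

## --- public fitting interface ------------------------------------------

#' Fit the mixed-membership mutation signature model by EM
#'
#' Maximum-likelihood estimation of K mutation signatures and per-sample
#' membership proportions from a mutation catalog.  Signatures are either
#' products of independent per-feature multinomials (`model = "independent"`)
#' or unconstrained distributions over the joint pattern space
#' (`model = "full"`, the single meta-feature special case equivalent to
#' earlier approaches).  An optional fixed background signature is included
#' as an extra mixture component whose pattern distribution is never
#' updated, only its membership weight.
#'
#' The EM algorithm is restarted `nRestarts` times from random
#' Dirichlet(1) initializations and the restart with the highest
#' log-likelihood is returned.  With `accelerate = TRUE` a SQUAREM-style
#' squared extrapolation is applied with a monotonicity safeguard (the
#' plain EM step is taken whenever extrapolation would decrease the
#' likelihood).
#'
#' @param catalog a [MutationCatalog-class].
#' @param K number of signatures to estimate (excluding the background).
#' @param model `"independent"` (default) or `"full"`.
#' @param background optional [BackgroundSignature-class] (or any
#'   [FullSignature-class]) over the same space, held fixed during fitting.
#' @param nRestarts number of random EM restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations per restart (default 10000).
#' @param accelerate logical, use SQUAREM-style acceleration.
#' @param seed optional integer seed controlling the whole restart sequence.
#' @param init optional warm start: a [SignatureFit-class] or a
#'   `list(F=, Q=)` state used for the first restart.
#' @param pseudocount added to M-step numerators (default 0).
#' @return A [SignatureFit-class].
#' @examples
#' sp <- buildFeatureSpace(1)
#' sim <- simulateCatalog(sp, K = 2, I = 6, J = 300, seed = 1)
#' fit <- fitSignatures(sim$catalog, K = 2, nRestarts = 3, seed = 1,
#'                      tol = 1e-6, maxIter = 500)
#' logLik(fit)
#' @export
fitSignatures <- function(catalog, K, model = c("independent", "full"),
                          background = NULL, nRestarts = 10L, tol = 1e-8,
                          maxIter = 10000L, accelerate = FALSE, seed = NULL,
                          init = NULL, pseudocount = 0) {
  model <- match.arg(model)
  stopifnot(is(catalog, "MutationCatalog"), K >= 1)
  dd <- .catalogDense(catalog)
  if (length(dd$obs) == 0L) stop("catalog contains no mutations")
  if (K > length(dd$obs))
    warning("K exceeds the number of distinct observed patterns")
  M <- catalog@space@M
  bgobs <- NULL
  if (!is.null(background)) {
    if (!identical(background@space@M, catalog@space@M))
      stop("background signature space does not match the catalog")
    bgobs <- background@probs[dd$obs]
  }
  Kstar <- K + as.integer(!is.null(bgobs))
  I <- nrow(dd$G)
  if (!is.null(seed)) set.seed(seed)
  seedUsed <- if (is.null(seed)) NA_integer_ else as.integer(seed)

  initState <- NULL
  if (!is.null(init)) {
    initState <- if (is(init, "SignatureFit")) .fitToState(init, dd, model) else init
  }

  best <- NULL
  bestRestart <- NA_integer_
  for (r in seq_len(nRestarts)) {
    state <- if (r == 1L && !is.null(initState)) initState else
      list(
        F = lapply(seq_len(K), function(k)
          .randomSignatureParams(M, model, length(dd$obs))),
        Q = {
          Q <- matrix(stats::rgamma(I * Kstar, 1), I, Kstar)
          Q / rowSums(Q)
        })
    res <- .fitOneRestart(state, dd$G, dd$feat, M, model, bgobs,
                          tol, maxIter, accelerate, pseudocount)
    if (is.null(best) || res$logLik > best$logLik) {
      best <- res
      bestRestart <- r
    }
  }

  .stateToFit(best, catalog, K, model, background, dd,
              nRestarts = as.integer(nRestarts),
              bestRestart = bestRestart, seed = seedUsed)
}

.fitToState <- function(fit, dd, model) {
  Fk <- lapply(fit@signatures, function(s) {
    if (model == "independent") {
      if (!is(s, "IndependentSignature"))
        stop("warm start model does not match 'model'")
      lapply(s@f, unname)
    } else {
      expandToFull(s)@probs[dd$obs] / sum(expandToFull(s)@probs[dd$obs])
    }
  })
  list(F = Fk, Q = unname(fit@memberships))
}

.stateToFit <- function(res, catalog, K, model, background, dd,
                        nRestarts, bestRestart, seed) {
  space <- catalog@space
  sigs <- vector("list", K)
  for (k in seq_len(K)) {
    if (model == "independent") {
      sigs[[k]] <- IndependentSignature(space, res$state$F[[k]])
    } else {
      full <- rep(0, nPatterns(space))
      full[dd$obs] <- res$state$F[[k]]
      sigs[[k]] <- FullSignature(space, full)
    }
  }
  names(sigs) <- sprintf("S%d", seq_len(K))
  Q <- res$state$Q
  rownames(Q) <- rownames(dd$G)
  colnames(Q) <- c(if (!is.null(background)) "background", sprintf("S%d", seq_len(K)))
  new("SignatureFit",
    space = space, model = model, signatures = sigs,
    background = background, memberships = Q,
    sampleTotals = stats::setNames(rowSums(dd$G), rownames(dd$G)),
    logLik = res$logLik, logLikTrace = res$trace,
    nRestarts = nRestarts, bestRestart = as.integer(bestRestart),
    nIter = as.integer(res$nIter), converged = res$converged,
    seed = seed)
}

#' Probability of one mutation pattern under a signature
#'
#' For an independent signature this is the product of the per-feature
#' probabilities of the pattern's feature values; for a full signature, the
#' stored entry.
#'
#' @param sig an [IndependentSignature-class] or [FullSignature-class].
#' @param m integer feature vector (1-based values) or pattern index.
#' @return numeric probability.
#' @export
patternProb <- function(sig, m) {
  space <- sig@space
  if (length(m) == 1L && nFeatures(space) > 1L) {
    m <- decodePattern(space, m)
  }
  if (is(sig, "FullSignature")) {
    return(unname(sig@probs[encodePattern(space, m)]))
  }
  p <- 1
  for (l in seq_along(sig@f)) p <- p * sig@f[[l]][[m[l]]]
  unname(p)
}

#' Log-likelihood of a catalog under given signatures and memberships
#'
#' Computes sum over samples and observed patterns of
#' g[i, m] * log(sum_k q[i, k] * Pr(m | k)), with the background (if
#' supplied) as the first mixture component.
#'
#' @param catalog a [MutationCatalog-class].
#' @param signatures list of signatures (all independent or all full).
#' @param memberships samples x components matrix, rows on the simplex; when
#'   `background` is given, its column comes first.
#' @param background optional fixed [FullSignature-class] component.
#' @return numeric scalar (possibly `-Inf`).
#' @export
logLikelihood <- function(catalog, signatures, memberships, background = NULL) {
  dd <- .catalogDense(catalog)
  model <- if (is(signatures[[1L]], "IndependentSignature")) "independent" else "full"
  Fk <- lapply(signatures, function(s)
    if (model == "independent") lapply(s@f, unname) else s@probs[dd$obs])
  bgobs <- if (!is.null(background)) background@probs[dd$obs] else NULL
  memberships <- as.matrix(memberships)
  if (ncol(memberships) != length(Fk) + as.integer(!is.null(bgobs)))
    stop("memberships have the wrong number of components")
  if (nrow(memberships) != nrow(dd$G)) stop("memberships/catalog sample mismatch")
  .emLogLik(list(F = Fk, Q = memberships), dd$G, dd$feat, model, bgobs)
}

#' E-step: posterior responsibilities of components for observed patterns
#'
#' Computes theta[i, k, m] = q[i, k] Pr(m|k) / sum_k' q[i, k'] Pr(m|k') for
#' every sample i and observed pattern m.
#'
#' @inheritParams logLikelihood
#' @return list with `theta` (array samples x components x observed
#'   patterns), `patterns` (pattern indices), and `components` (names;
#'   `"background"` first when present).
#' @export
eStep <- function(catalog, signatures, memberships, background = NULL) {
  dd <- .catalogDense(catalog)
  model <- if (is(signatures[[1L]], "IndependentSignature")) "independent" else "full"
  Fk <- lapply(signatures, function(s)
    if (model == "independent") lapply(s@f, unname) else s@probs[dd$obs])
  bgobs <- if (!is.null(background)) background@probs[dd$obs] else NULL
  memberships <- as.matrix(memberships)
  P <- .componentProbs(Fk, dd$feat, model, bgobs)
  D <- memberships %*% t(P)
  if (any(D <= 0))
    stop("zero mixture probability for observed pattern(s): ",
         paste(utils::head(colnames(dd$G)[colSums(D <= 0) > 0], 3L), collapse = ", "))
  Kstar <- ncol(P)
  theta <- array(0, c(nrow(dd$G), Kstar, length(dd$obs)))
  for (k in seq_len(Kstar))
    theta[, k, ] <- (memberships[, k] %o% P[, k]) / D
  comp <- c(if (!is.null(bgobs)) "background",
            sprintf("S%d", seq_along(signatures)))
  dimnames(theta) <- list(rownames(dd$G), comp, colnames(dd$G))
  list(theta = theta, patterns = dd$obs, components = comp)
}

#' M-step: update signatures and memberships from responsibilities
#'
#' Aggregates responsibility-weighted counts over samples and patterns:
#' the per-feature probabilities of each signature become the normalized
#' weighted marginal frequencies, and each sample's memberships the
#' normalized weighted totals.  A fixed background component (first slot of
#' `theta`) keeps its pattern distribution; only its weight is updated.
#'
#' @param catalog a [MutationCatalog-class].
#' @param resp an [eStep()] result for this catalog.
#' @param model `"independent"` or `"full"`.
#' @param fixedBackground logical; is component 1 a fixed background?
#' @return list with `signatures` (list of signature objects) and
#'   `memberships` (samples x components matrix).
#' @export
mStep <- function(catalog, resp, model = c("independent", "full"),
                  fixedBackground = FALSE) {
  model <- match.arg(model)
  dd <- .catalogDense(catalog)
  stopifnot(identical(resp$patterns, dd$obs))
  theta <- resp$theta
  Kstar <- dim(theta)[2L]
  off <- as.integer(fixedBackground)
  K <- Kstar - off
  M <- catalog@space@M
  space <- catalog@space
  ## weighted counts per (component, pattern) and (sample, component)
  A <- matrix(0, length(dd$obs), Kstar)
  N <- matrix(0, nrow(dd$G), Kstar)
  for (k in seq_len(Kstar)) {
    wk <- dd$G * theta[, k, , drop = TRUE]
    if (is.null(dim(wk))) wk <- matrix(wk, nrow = nrow(dd$G))
    A[, k] <- colSums(wk)
    N[, k] <- rowSums(wk)
  }
  sigs <- vector("list", K)
  for (k in seq_len(K)) {
    w <- A[, off + k]
    if (sum(w) == 0) {
      warning("signature ", k, " received zero responsibility; re-initializing")
      w <- .rdirichlet1(rep(1, length(w)))
    }
    if (model == "independent") {
      fk <- vector("list", length(M))
      for (l in seq_along(M)) {
        num <- rep(0, M[l])
        s <- rowsum(w, dd$feat[, l])
        num[as.integer(rownames(s))] <- s[, 1L]
        fk[[l]] <- num / sum(num)
      }
      sigs[[k]] <- IndependentSignature(space, fk)
    } else {
      full <- rep(0, nPatterns(space))
      full[dd$obs] <- w / sum(w)
      sigs[[k]] <- FullSignature(space, full)
    }
  }
  Q <- N / rowSums(N)
  rownames(Q) <- rownames(dd$G)
  colnames(Q) <- resp$components
  list(signatures = sigs, memberships = Q)
}

## --- SignatureFit accessors --------------------------------------------

#' Fitted signatures
#' @param x a [SignatureFit-class].
#' @rdname signatures
#' @export
setMethod("signatures", "SignatureFit", function(x) x@signatures)

#' Fitted membership proportions
#' @param x a [SignatureFit-class].
#' @rdname memberships
#' @export
setMethod("memberships", "SignatureFit", function(x) x@memberships)

#' Per-iteration log-likelihood trace of the best restart
#' @param x a [SignatureFit-class].
#' @rdname logLikTrace
#' @export
setMethod("logLikTrace", "SignatureFit", function(x) x@logLikTrace)

#' Fixed background component of a fit (or NULL)
#' @param x a [SignatureFit-class].
#' @rdname backgroundSignatureOf
#' @export
setMethod("backgroundSignatureOf", "SignatureFit", function(x) x@background)

#' @export
logLik.SignatureFit <- function(object, ...) object@logLik

setMethod("show", "SignatureFit", function(object) {
  cat(sprintf("SignatureFit: %d %s-model signature(s)%s, %d samples\n",
    length(object@signatures), object@model,
    if (!is.null(object@background)) " + fixed background" else "",
    nrow(object@memberships)))
  cat(sprintf("  logLik = %.4f; restart %d/%d; %d iterations; converged: %s\n",
    object@logLik, object@bestRestart, object@nRestarts,
    object@nIter, object@converged))
})
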