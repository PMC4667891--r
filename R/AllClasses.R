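#' @import methods
#' @importFrom Matrix sparseMatrix Matrix rowSums colSums
NULL

.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.STRANDS <- c("+", "-")
.SIMPLEX_TOL <- 1e-6

#' FeatureSpace: the set of mutation features and their cardinalities
#'
#' A mutation pattern is decomposed into L discrete features in the fixed
#' order (substitution, 5' flanking bases from -nFlank to -1, 3' flanking
#' bases from +1 to +nFlank, optionally transcription strand).  Feature l
#' takes one of `M[l]` values; the substitution feature has 6 values
#' (pyrimidine-normalized C>A, C>G, C>T, T>A, T>C, T>G), each flanking base
#' 4 (A, C, G, T), the strand 2 (+, -).
#'
#' @slot nFlank integer, number of flanking bases considered on each side.
#' @slot includeStrand logical, whether the transcription strand is a feature.
#' @slot M integer vector of feature cardinalities.
#' @slot labels named list of character vectors, the value labels per feature.
#' @export
setClass("FeatureSpace",
  representation(
    nFlank = "integer",
    includeStrand = "logical",
    M = "integer",
    labels = "list"
  )
)

setValidity("FeatureSpace", function(object) {
  L <- 1L + 2L * object@nFlank + as.integer(object@includeStrand)
  if (object@nFlank < 0L) return("nFlank must be >= 0")
  if (length(object@M) != L) return("length(M) must equal 1 + 2*nFlank + strand")
  if (object@M[1L] != 6L) return("substitution feature must have 6 values")
  if (object@nFlank > 0L && !all(object@M[2L:(1L + 2L * object@nFlank)] == 4L))
    return("flanking-base features must have 4 values")
  if (object@includeStrand && object@M[L] != 2L)
    return("strand feature must have 2 values")
  if (length(object@labels) != L) return("labels must have one entry per feature")
  if (!all(lengths(object@labels) == object@M))
    return("label vectors must match feature cardinalities")
  TRUE
})

#' MutationCatalog: per-sample counts of mutation-feature patterns
#'
#' Stores the counts g[i, m] of mutations in sample i carrying joint
#' mutation-feature pattern m, as a sparse samples x patterns matrix whose
#' columns follow the mixed-radix pattern encoding of the feature space.
#'
#' @slot space the [FeatureSpace-class] the patterns live in.
#' @slot counts a sparse `Matrix` (samples x patterns) of non-negative counts.
#' @export
setClass("MutationCatalog",
  representation(space = "FeatureSpace", counts = "Matrix")
)

setValidity("MutationCatalog", function(object) {
  P <- prod(object@space@M)
  if (ncol(object@counts) != P)
    return(sprintf("counts must have %d pattern columns", P))
  if (any(object@counts@x < 0)) return("counts must be non-negative")
  if (is.null(rownames(object@counts))) return("counts must carry sample ids as rownames")
  TRUE
})

#' IndependentSignature: a product-of-multinomials mutation signature
#'
#' One probability vector per mutation feature; the joint probability of a
#' pattern is the product of its per-feature probabilities (the independence
#' assumption that reduces the parameter count from prod(M) - 1 to
#' sum(M - 1) per signature).
#'
#' @slot space the [FeatureSpace-class].
#' @slot f named list of numeric probability vectors, one per feature.
#' @export
setClass("IndependentSignature",
  representation(space = "FeatureSpace", f = "list")
)

setValidity("IndependentSignature", function(object) {
  M <- object@space@M
  if (length(object@f) != length(M)) return("f must have one vector per feature")
  if (!all(lengths(object@f) == M)) return("feature vector lengths must match M")
  for (v in object@f) {
    if (any(v < -.SIMPLEX_TOL)) return("feature probabilities must be non-negative")
    if (abs(sum(v) - 1) > .SIMPLEX_TOL)
      return("each feature vector must sum to 1 (tolerance 1e-6)")
  }
  TRUE
})

#' FullSignature: an unconstrained distribution over the joint pattern space
#'
#' The representation used by earlier signature models: a single probability
#' vector over all prod(M) joint patterns (one "meta-feature").
#'
#' @slot space the [FeatureSpace-class].
#' @slot probs numeric vector of length `nPatterns(space)` summing to 1.
#' @export
setClass("FullSignature",
  representation(space = "FeatureSpace", probs = "numeric")
)

setValidity("FullSignature", function(object) {
  if (length(object@probs) != prod(object@space@M))
    return("probs must cover the full pattern space")
  if (any(object@probs < -.SIMPLEX_TOL)) return("probabilities must be non-negative")
  if (abs(sum(object@probs) - 1) > .SIMPLEX_TOL) return("probs must sum to 1")
  TRUE
})

#' BackgroundSignature: a fixed compositional mixture component
#'
#' A [FullSignature-class] computed from the k-mer composition of reference
#' sequence, held fixed during fitting to absorb intrinsic sequence
#' composition bias (e.g. CpG depletion).
#'
#' @export
setClass("BackgroundSignature", contains = "FullSignature")

#' SignatureFit: result of fitting the mixed-membership signature model
#'
#' @slot space the [FeatureSpace-class].
#' @slot model `"independent"` or `"full"`.
#' @slot signatures list of K fitted signatures
#'   ([IndependentSignature-class] or [FullSignature-class]).
#' @slot background the fixed [BackgroundSignature-class], or NULL.
#' @slot memberships samples x components matrix of membership proportions;
#'   when a background is used its column is first and named `"background"`.
#' @slot sampleTotals per-sample mutation totals J_i of the fitted catalog.
#' @slot logLik best log-likelihood reached.
#' @slot logLikTrace per-iteration log-likelihood of the best restart.
#' @slot nRestarts,bestRestart,nIter,converged,seed fitting metadata.
#' @export
setClass("SignatureFit",
  representation(
    space = "FeatureSpace",
    model = "character",
    signatures = "list",
    background = "ANY",
    memberships = "matrix",
    sampleTotals = "numeric",
    logLik = "numeric",
    logLikTrace = "numeric",
    nRestarts = "integer",
    bestRestart = "integer",
    nIter = "integer",
    converged = "logical",
    seed = "integer"
  )
)

setValidity("SignatureFit", function(object) {
  K <- length(object@signatures)
  Kstar <- K + as.integer(!is.null(object@background))
  if (ncol(object@memberships) != Kstar)
    return("memberships must have one column per component")
  rs <- rowSums(object@memberships)
  if (any(abs(rs - 1) > 1e-6)) return("membership rows must sum to 1")
  if (any(object@memberships < -1e-9)) return("memberships must be non-negative")
  TRUE
})

#' BootstrapResult: non-parametric bootstrap standard errors for a fit
#'
#' @slot B number of bootstrap replicates.
#' @slot signatureSE list over signatures; for the independent model each
#'   element is a list of per-feature SE vectors, for the full model a single
#'   SE vector over patterns.
#' @slot membershipSE samples x components matrix of membership SEs.
#' @slot replicates optional list of per-replicate matched estimates.
#' @export
setClass("BootstrapResult",
  representation(
    B = "integer",
    signatureSE = "list",
    membershipSE = "matrix",
    replicates = "list"
  )
)
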