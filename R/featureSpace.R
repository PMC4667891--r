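#' Build a mutation feature space
#'
#' Constructs the feature space for mutation patterns consisting of the
#' substitution type (6 pyrimidine-normalized values), `nFlank` flanking
#' bases on each side (4 values each) and optionally the transcription
#' strand (2 values).  Feature order is fixed: substitution, flanks
#' -nFlank..-1, flanks +1..+nFlank, strand.
#'
#' @param nFlank integer in 0..5, number of flanking bases on each side.
#' @param includeStrand logical, include the transcription-strand feature.
#' @return A [FeatureSpace-class] object.
#' @examples
#' sp <- buildFeatureSpace(2, FALSE)
#' cardinalities(sp)   # 6 4 4 4 4
#' independentParamCount(sp)  # 17
#' @export
buildFeatureSpace <- function(nFlank, includeStrand = FALSE) {
  if (!is.numeric(nFlank) || length(nFlank) != 1L || is.na(nFlank) ||
      nFlank < 0 || nFlank > 5 || nFlank != as.integer(nFlank))
    stop("'nFlank' must be a single integer in 0..5")
  nFlank <- as.integer(nFlank)
  includeStrand <- isTRUE(includeStrand)
  labels <- list(substitution = .SUBSTITUTIONS)
  if (nFlank > 0L) {
    for (o in seq.int(-nFlank, -1L)) labels[[sprintf("flank%+d", o)]] <- .BASES
    for (o in seq_len(nFlank)) labels[[sprintf("flank%+d", o)]] <- .BASES
  }
  if (includeStrand) labels[["strand"]] <- .STRANDS
  new("FeatureSpace",
    nFlank = nFlank, includeStrand = includeStrand,
    M = as.integer(lengths(labels)), labels = labels)
}

#' @describeIn buildFeatureSpace number of joint mutation patterns, prod(M).
#' @param space a [FeatureSpace-class].
#' @export
setMethod("nPatterns", "FeatureSpace", function(space) as.integer(prod(space@M)))

#' Number of features L
#' @param space a [FeatureSpace-class].
#' @rdname nFeatures
#' @export
setMethod("nFeatures", "FeatureSpace", function(space) length(space@M))

#' Feature cardinalities M
#' @param space a [FeatureSpace-class].
#' @rdname cardinalities
#' @export
setMethod("cardinalities", "FeatureSpace", function(space) {
  stats::setNames(space@M, names(space@labels))
})

#' Free parameters per signature under the independent model
#'
#' Each feature contributes its cardinality minus one: sum(M - 1), e.g.
#' 5 + 6 n for substitution plus n flanking bases on each side.
#' @param space a [FeatureSpace-class].
#' @rdname independentParamCount
#' @export
setMethod("independentParamCount", "FeatureSpace", function(space) {
  as.integer(sum(space@M - 1L))
})

#' Free parameters per signature under the full (unconstrained) model
#'
#' One probability per joint pattern, minus the sum-to-one constraint:
#' prod(M) - 1.
#' @param space a [FeatureSpace-class].
#' @rdname fullParamCount
#' @export
setMethod("fullParamCount", "FeatureSpace", function(space) {
  as.integer(prod(space@M) - 1L)
})

#' Per-feature value labels
#' @param space a [FeatureSpace-class].
#' @return named list of character vectors.
#' @rdname featureLabels
#' @export
featureLabels <- function(space) space@labels

## Mixed-radix pattern encoding: the substitution varies slowest, then the
## flanks from -n to +n, then the strand.  1-based throughout.

#' Encode a feature vector as a pattern index
#'
#' Bijectively maps a length-L vector of 1-based feature values to an index
#' in 1..prod(M) (mixed radix, first feature most significant).
#'
#' @param space a [FeatureSpace-class].
#' @param m integer vector (or matrix, one row per pattern) of feature values.
#' @return integer pattern index (vector if `m` is a matrix).
#' @export
encodePattern <- function(space, m) {
  M <- space@M
  if (is.matrix(m)) {
    if (ncol(m) != length(M)) stop("pattern matrix must have L columns")
    bad <- m < 1L | m > matrix(M, nrow(m), length(M), byrow = TRUE)
    if (any(bad)) stop("feature value out of range")
    idx <- rep.int(0L, nrow(m))
    for (l in seq_along(M)) idx <- idx * M[l] + (m[, l] - 1L)
    return(as.integer(idx + 1L))
  }
  if (length(m) != length(M)) stop("pattern must have L components")
  if (any(m < 1L | m > M)) stop("feature value out of range")
  idx <- 0L
  for (l in seq_along(M)) idx <- idx * M[l] + (m[l] - 1L)
  as.integer(idx + 1L)
}

#' Decode a pattern index into a feature vector
#'
#' @param space a [FeatureSpace-class].
#' @param index integer pattern index (may be a vector).
#' @return integer vector of feature values, or a matrix (one row per index).
#' @export
decodePattern <- function(space, index) {
  M <- space@M
  P <- prod(M)
  if (any(index < 1L | index > P)) stop("pattern index out of range")
  idx <- as.integer(index) - 1L
  out <- matrix(0L, length(idx), length(M))
  for (l in rev(seq_along(M))) {
    out[, l] <- idx %% M[l] + 1L
    idx <- idx %/% M[l]
  }
  colnames(out) <- names(space@labels)
  if (length(index) == 1L) out[1L, ] else out
}

## Feature-value matrix for all prod(M) patterns, in encoding order.
.patternMatrix <- function(space) {
  decodePattern(space, seq_len(nPatterns(space)))
}

#' Human-readable labels for all joint patterns
#'
#' Labels take the form `"AA[C>A]TG,+"`: all 5' flanking bases, the bracketed
#' substitution, all 3' flanking bases, and (when the strand feature is
#' present) a strand suffix.  With no flanking bases the label is just the
#' substitution, e.g. `"C>A"`.
#'
#' @param space a [FeatureSpace-class].
#' @return character vector of length `nPatterns(space)` in encoding order.
#' @rdname patternLabels
#' @export
setMethod("patternLabels", "FeatureSpace", function(space) {
  pm <- .patternMatrix(space)
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1L)
  .patternLabelFromMatrix(space, pm)
})

.patternLabelFromMatrix <- function(space, pm) {
  n <- space@nFlank
  sub <- .SUBSTITUTIONS[pm[, 1L]]
  left <- right <- rep("", nrow(pm))
  if (n > 0L) {
    for (l in seq_len(n)) left <- paste0(left, .BASES[pm[, 1L + l]])
    for (l in seq_len(n)) right <- paste0(right, .BASES[pm[, 1L + n + l]])
  }
  lab <- if (n > 0L) paste0(left, "[", sub, "]", right) else sub
  if (space@includeStrand)
    lab <- paste0(lab, ",", .STRANDS[pm[, ncol(pm)]])
  lab
}

#' Parse pattern labels back into feature vectors
#'
#' Inverse of [patternLabels()]; errors on labels that do not match the space.
#' @param space a [FeatureSpace-class].
#' @param labels character vector of pattern labels.
#' @return integer matrix of feature values (one row per label).
#' @export
parsePatternLabels <- function(space, labels) {
  n <- space@nFlank
  L <- nFeatures(space)
  out <- matrix(0L, length(labels), L)
  body <- labels
  if (space@includeStrand) {
    parts <- regmatches(labels, regexpr(",[+-]$", labels))
    if (any(lengths(regmatches(labels, gregexpr(",[+-]$", labels))) == 0L))
      stop("pattern label missing strand suffix for a stranded space")
    out[, L] <- match(substring(parts, 2L), .STRANDS)
    body <- sub(",[+-]$", "", labels)
  }
  if (n > 0L) {
    pat <- sprintf("^([ACGT]{%d})\\[([CT]>[ACGT])\\]([ACGT]{%d})$", n, n)
    ok <- grepl(pat, body)
    if (!all(ok))
      stop("malformed pattern label(s): ", paste(utils::head(body[!ok], 3L), collapse = ", "))
    left <- sub(pat, "\\1", body)
    sub_ <- sub(pat, "\\2", body)
    right <- sub(pat, "\\3", body)
    out[, 1L] <- match(sub_, .SUBSTITUTIONS)
    for (l in seq_len(n))
      out[, 1L + l] <- match(substring(left, l, l), .BASES)
    for (l in seq_len(n))
      out[, 1L + n + l] <- match(substring(right, l, l), .BASES)
  } else {
    out[, 1L] <- match(body, .SUBSTITUTIONS)
  }
  if (anyNA(out)) stop("pattern label does not match the feature space")
  colnames(out) <- names(space@labels)
  out
}

#' Construct an independent signature
#'
#' @param space a [FeatureSpace-class].
#' @param f list of per-feature probability vectors (recycled names from the
#'   space); each must sum to 1 within 1e-6.
#' @return An [IndependentSignature-class].
#' @export
IndependentSignature <- function(space, f) {
  f <- lapply(f, as.numeric)
  names(f) <- names(space@labels)
  for (l in seq_along(f)) names(f[[l]]) <- space@labels[[l]]
  new("IndependentSignature", space = space, f = f)
}

#' Construct a full signature
#'
#' @param space a [FeatureSpace-class].
#' @param probs probability vector over all `nPatterns(space)` patterns.
#' @return A [FullSignature-class].
#' @export
FullSignature <- function(space, probs) {
  probs <- as.numeric(probs)
  if (length(probs) != nPatterns(space))
    stop("probs must cover the full pattern space (", nPatterns(space),
         " entries)")
  names(probs) <- patternLabels(space)
  new("FullSignature", space = space, probs = probs)
}

#' Per-feature probability vectors of a signature
#' @param sig an [IndependentSignature-class].
#' @return named list of numeric vectors.
#' @export
featureProbs <- function(sig) sig@f

#' Joint pattern probabilities of a signature
#' @param sig a [FullSignature-class] (or [BackgroundSignature-class]).
#' @return named numeric vector over patterns.
#' @export
patternProbs <- function(sig) sig@probs

#' Expand an independent signature to the full pattern space
#'
#' Under the independence assumption the probability of joint pattern m is
#' the product over features of the per-feature probabilities; this returns
#' the full-length vector of those products (a [FullSignature-class]).
#'
#' @param sig an [IndependentSignature-class] (a full signature is returned
#'   unchanged).
#' @rdname expandToFull
#' @export
setMethod("expandToFull", "IndependentSignature", function(sig) {
  pm <- .patternMatrix(sig@space)
  p <- rep(1, nrow(pm))
  for (l in seq_along(sig@f)) p <- p * sig@f[[l]][pm[, l]]
  FullSignature(sig@space, unname(p))
})

#' @rdname expandToFull
#' @export
setMethod("expandToFull", "FullSignature", function(sig) sig)

#' @rdname featureSpace
#' @param x an object carrying a feature space.
#' @export
setMethod("featureSpace", "IndependentSignature", function(x) x@space)
#' @rdname featureSpace
#' @export
setMethod("featureSpace", "FullSignature", function(x) x@space)
#' @rdname featureSpace
#' @export
setMethod("featureSpace", "MutationCatalog", function(x) x@space)
#' @rdname featureSpace
#' @export
setMethod("featureSpace", "SignatureFit", function(x) x@space)

setMethod("show", "FeatureSpace", function(object) {
  cat(sprintf("FeatureSpace: L = %d, M = (%s)%s\n",
    nFeatures(object), paste(object@M, collapse = ", "),
    if (object@includeStrand) " [stranded]" else ""))
  cat(sprintf("  %d patterns; %d independent / %d full parameters per signature\n",
    nPatterns(object), independentParamCount(object), fullParamCount(object)))
})

setMethod("show", "IndependentSignature", function(object) {
  cat(sprintf("IndependentSignature over %d features:\n", nFeatures(object@space)))
  for (nm in names(object@f))
    cat(sprintf("  %-12s %s\n", nm,
      paste(sprintf("%s=%.3f", names(object@f[[nm]]), object@f[[nm]]), collapse = " ")))
})

setMethod("show", "FullSignature", function(object) {
  cat(sprintf("%s over %d patterns (top 5):\n", class(object), length(object@probs)))
  top <- utils::head(sort(object@probs, decreasing = TRUE), 5L)
  for (i in seq_along(top)) cat(sprintf("  %-14s %.4f\n", names(top)[i], top[i]))
})
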