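#' Construct a mutation catalog from counts
#'
#' @param space a [FeatureSpace-class].
#' @param counts matrix-like (samples x patterns) of non-negative counts,
#'   with sample ids as rownames; coerced to a sparse `Matrix`.  Columns must
#'   be in pattern-encoding order (or named by pattern labels, in which case
#'   they are matched).
#' @return A [MutationCatalog-class].
#' @export
MutationCatalog <- function(space, counts) {
  P <- nPatterns(space)
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (!is.null(colnames(counts)) && ncol(counts) == P) {
    perm <- match(patternLabels(space), colnames(counts))
    if (!anyNA(perm)) counts <- counts[, perm, drop = FALSE]
  }
  colnames(counts) <- patternLabels(space)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sample%d", seq_len(nrow(counts)))
  new("MutationCatalog", space = space, counts = counts)
}

#' Build a catalog from (sample, pattern index, count) triplets
#' @param space a [FeatureSpace-class].
#' @param sample character vector of sample ids.
#' @param pattern integer vector of pattern indices.
#' @param count numeric vector of counts (default 1 per row).
#' @param sampleIDs optional full ordered sample id set (samples with no
#'   mutations are kept as all-zero rows).
#' @return A [MutationCatalog-class].
#' @export
catalogFromTriplets <- function(space, sample, pattern, count = rep(1, length(sample)),
                                sampleIDs = NULL) {
  if (is.null(sampleIDs)) sampleIDs <- unique(sample)
  i <- match(sample, sampleIDs)
  if (anyNA(i)) stop("sample id not in 'sampleIDs'")
  m <- Matrix::sparseMatrix(
    i = i, j = as.integer(pattern), x = as.numeric(count),
    dims = c(length(sampleIDs), nPatterns(space)),
    dimnames = list(sampleIDs, patternLabels(space)))
  new("MutationCatalog", space = space, counts = m)
}

#' @rdname sampleIDs
#' @param x a [MutationCatalog-class] or [SignatureFit-class].
#' @export
setMethod("sampleIDs", "MutationCatalog", function(x) rownames(x@counts))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "SignatureFit", function(x) rownames(x@memberships))

#' Sparse per-sample pattern counts
#' @param x a [MutationCatalog-class].
#' @rdname mutationCounts
#' @export
setMethod("mutationCounts", "MutationCatalog", function(x) x@counts)

#' Total mutation count per sample (J_i)
#' @param x a [MutationCatalog-class].
#' @rdname totalMutations
#' @export
setMethod("totalMutations", "MutationCatalog", function(x) {
  stats::setNames(Matrix::rowSums(x@counts), rownames(x@counts))
})

setMethod("show", "MutationCatalog", function(object) {
  cat(sprintf("MutationCatalog: %d samples, %d mutations, %d/%d patterns observed\n",
    nrow(object@counts), sum(object@counts),
    sum(Matrix::colSums(object@counts) > 0), ncol(object@counts)))
  show(object@space)
})

## Internal dense view restricted to observed patterns, plus the per-pattern
## feature values; the EM engine works in this reduced space.
.catalogDense <- function(catalog) {
  cs <- Matrix::colSums(catalog@counts)
  obs <- which(cs > 0)
  G <- as.matrix(catalog@counts[, obs, drop = FALSE])
  feat <- decodePattern(catalog@space, obs)
  if (is.null(dim(feat))) feat <- matrix(feat, nrow = 1L,
    dimnames = list(NULL, names(catalog@space@labels)))
  list(G = G, obs = obs, feat = feat)
}
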