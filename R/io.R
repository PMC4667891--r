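## TSV readers/writers for catalogs, signatures and memberships.  All files
## are label-keyed (pattern labels, feature value labels), never bare
## integer codes, so they survive any reordering of the internal encoding.

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTSV <- function(path, expected) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(expected, colnames(df))
  if (length(missing) > 0L)
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read a mutation catalog as TSV
#'
#' Long format with columns `sample`, `pattern` (label) and `count`;
#' zero-count cells are omitted.  Reading validates every pattern label
#' against the supplied space and errors on a mismatch (e.g. a ±1-flank
#' file read into a ±2 space).
#'
#' @param catalog a [MutationCatalog-class].
#' @param path file path.
#' @rdname catalogIO
#' @export
writeCatalog <- function(catalog, path) {
  counts <- catalog@counts
  idx <- which(as.matrix(counts) > 0, arr.ind = TRUE)
  df <- data.frame(
    sample = rownames(counts)[idx[, 1L]],
    pattern = colnames(counts)[idx[, 2L]],
    count = as.matrix(counts)[idx])
  df <- df[order(df$sample, df$pattern), , drop = FALSE]
  .writeTSV(df, path)
  invisible(path)
}

#' @param space the [FeatureSpace-class] the file is expected to match.
#' @param sampleIDs optional ordered sample id vector (zero-mutation
#'   samples included).
#' @rdname catalogIO
#' @export
readCatalog <- function(path, space, sampleIDs = NULL) {
  df <- .readTSV(path, c("sample", "pattern", "count"))
  feat <- tryCatch(parsePatternLabels(space, df$pattern),
    error = function(e) stop("pattern labels do not match the feature space (",
                             conditionMessage(e), ")"))
  catalogFromTriplets(space, df$sample, encodePattern(space, feat),
                      df$count, sampleIDs = sampleIDs)
}

#' Write / read independent signatures as TSV
#'
#' Long format with columns `signature`, `feature`, `value`, `probability`,
#' one row per parameter.  Reading reconstructs the signatures and
#' validates the feature set against the space.
#'
#' @param sigs named list of [IndependentSignature-class] objects.
#' @param path file path.
#' @rdname signatureIO
#' @export
writeSignatures <- function(sigs, path) {
  if (is.null(names(sigs))) names(sigs) <- sprintf("S%d", seq_along(sigs))
  rows <- list()
  for (nm in names(sigs)) {
    sig <- sigs[[nm]]
    for (ft in names(sig@f)) {
      rows[[length(rows) + 1L]] <- data.frame(
        signature = nm, feature = ft,
        value = names(sig@f[[ft]]),
        probability = sprintf("%.15g", unname(sig@f[[ft]])))
    }
  }
  .writeTSV(do.call(rbind, rows), path)
  invisible(path)
}

#' @param space the expected [FeatureSpace-class].
#' @rdname signatureIO
#' @export
readSignatures <- function(path, space) {
  df <- .readTSV(path, c("signature", "feature", "value", "probability"))
  featNames <- names(space@labels)
  fileFeats <- unique(df$feature)
  if (!setequal(fileFeats, featNames))
    stop("signature file features (", paste(fileFeats, collapse = ","),
         ") do not match the feature space (", paste(featNames, collapse = ","), ")")
  out <- list()
  for (nm in unique(df$signature)) {
    sub <- df[df$signature == nm, ]
    f <- lapply(featNames, function(ft) {
      rows <- sub[sub$feature == ft, ]
      v <- match(space@labels[[ft]], rows$value)
      if (anyNA(v))
        stop("feature '", ft, "' of signature '", nm, "' has missing values")
      as.numeric(rows$probability)[v]
    })
    out[[nm]] <- IndependentSignature(space, f)
  }
  out
}

#' Write / read full signatures (pattern, probability) as TSV
#'
#' @param sigs named list of [FullSignature-class] objects (a single
#'   signature may be passed directly).
#' @param path file path.
#' @rdname fullSignatureIO
#' @export
writeFullSignatures <- function(sigs, path) {
  if (is(sigs, "FullSignature")) sigs <- list(S1 = sigs)
  if (is.null(names(sigs))) names(sigs) <- sprintf("S%d", seq_along(sigs))
  rows <- lapply(names(sigs), function(nm) data.frame(
    signature = nm, pattern = names(sigs[[nm]]@probs),
    probability = sprintf("%.15g", unname(sigs[[nm]]@probs))))
  .writeTSV(do.call(rbind, rows), path)
  invisible(path)
}

#' @param space the expected [FeatureSpace-class].
#' @rdname fullSignatureIO
#' @export
readFullSignatures <- function(path, space) {
  df <- .readTSV(path, c("signature", "pattern", "probability"))
  labs <- patternLabels(space)
  out <- list()
  for (nm in unique(df$signature)) {
    sub <- df[df$signature == nm, ]
    v <- match(labs, sub$pattern)
    if (anyNA(v))
      stop("pattern labels do not cover the feature space")
    out[[nm]] <- FullSignature(space, as.numeric(sub$probability)[v])
  }
  out
}

#' Write / read membership proportions as TSV
#'
#' Long format with columns `sample`, `signature`, `probability`.
#'
#' @param Q memberships matrix (samples x components, dimnames set) or a
#'   [SignatureFit-class].
#' @param path file path.
#' @rdname membershipIO
#' @export
writeMemberships <- function(Q, path) {
  if (is(Q, "SignatureFit")) Q <- memberships(Q)
  df <- data.frame(
    sample = rep(rownames(Q), ncol(Q)),
    signature = rep(colnames(Q), each = nrow(Q)),
    probability = sprintf("%.15g", as.vector(Q)))
  df <- df[order(match(df$sample, rownames(Q))), ]
  .writeTSV(df, path)
  invisible(path)
}

#' @rdname membershipIO
#' @export
readMemberships <- function(path) {
  df <- .readTSV(path, c("sample", "signature", "probability"))
  samples <- unique(df$sample)
  sigs <- unique(df$signature)
  Q <- matrix(NA_real_, length(samples), length(sigs),
              dimnames = list(samples, sigs))
  Q[cbind(match(df$sample, samples), match(df$signature, sigs))] <-
    as.numeric(df$probability)
  if (anyNA(Q)) stop("incomplete membership table")
  Q
}
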