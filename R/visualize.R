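#' @import ggplot2
#' @importFrom rlang .data
NULL

.BASE_COLORS <- c(A = "#33A02C", C = "#1F78B4", G = "#FF7F00", T = "#E31A1C")
.SUB_COLORS <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
                 "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC5C4")

#' Entropy-based height scaling for logo boxes
#'
#' Returns `1 + 0.5 * log2(sum(f^2))`, i.e. one minus half the order-2
#' Rényi entropy in bits: 0 for a uniform distribution over 4 bases, 1 for
#' a point mass.  Used to shrink uninformative flanking-site boxes in the
#' signature logo, analogous to information-content scaling in sequence
#' logos.
#'
#' @param f a probability vector.
#' @param base logarithm base (default 2, the entropy-in-bits reading).
#' @return numeric scalar.
#' @export
logoHeightScale <- function(f, base = 2) {
  if (any(f < -.SIMPLEX_TOL) || abs(sum(f) - 1) > .SIMPLEX_TOL)
    stop("'f' must be a probability vector")
  1 + 0.5 * log(sum(f^2), base = base)
}

#' Conditional layout of the substitution panel
#'
#' Groups the six substitution probabilities by their original (pyrimidine)
#' base: box widths are the original-base marginals P(C), P(T) and box
#' heights the conditional probabilities of each alternate base given the
#' original base, so widths x heights reconstruct the substitution vector.
#'
#' @param sig an [IndependentSignature-class].
#' @return list with `widths` (named length-2) and `heights` (3 x 2 matrix
#'   of conditionals, columns C and T, rows the alternate bases in
#'   substitution order).
#' @export
substitutionPanel <- function(sig) {
  f <- sig@f[[1L]]
  wC <- sum(f[1:3]); wT <- sum(f[4:6])
  heights <- cbind(
    C = if (wC > 0) unname(f[1:3]) / wC else rep(0, 3),
    T = if (wT > 0) unname(f[4:6]) / wT else rep(0, 3))
  rownames(heights) <- c("alt1", "alt2", "alt3")  # A,G,T for C; A,C,G for T
  list(widths = c(C = wC, T = wT), heights = heights)
}

#' Numeric layout of a signature logo
#'
#' Pure function computing everything the logo drawing needs: per-flank box
#' widths (base frequencies) and entropy-scaled row heights, the
#' substitution panel conditionals, and (when present) the strand panel
#' heights.
#'
#' @param sig an [IndependentSignature-class].
#' @param base logarithm base for the height scaling.
#' @return list with elements `flanks` (data.frame offset, base, width,
#'   rowHeight), `substitution` (see [substitutionPanel()]), and `strand`
#'   (named heights or NULL).
#' @export
signatureLogoLayout <- function(sig, base = 2) {
  space <- sig@space
  n <- space@nFlank
  flanks <- NULL
  if (n > 0L) {
    offsets <- c(seq.int(-n, -1L), seq_len(n))
    rows <- lapply(seq_along(offsets), function(j) {
      f <- sig@f[[1L + j]]
      data.frame(offset = offsets[j], base = .BASES, width = unname(f),
                 rowHeight = max(0, logoHeightScale(unname(f), base)))
    })
    flanks <- do.call(rbind, rows)
  }
  strand <- NULL
  if (space@includeStrand)
    strand <- sig@f[[nFeatures(space)]]
  list(flanks = flanks, substitution = substitutionPanel(sig),
       strand = strand)
}

.openDevice <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdf = grDevices::pdf(path, width = width, height = height),
    png = grDevices::png(path, width = width * 100, height = height * 100),
    svg = grDevices::svg(path, width = width, height = height),
    grDevices::pdf(path, width = width, height = height))
}

#' Render an independent-signature logo
#'
#' Draws the sequence-logo style representation: one row of boxes per
#' flanking position (widths = base frequencies, row height scaled by
#' `1 + 0.5 log2 sum f^2`), a substitution panel of conditional alternate
#' frequencies over the original-base marginals, and a strand panel when
#' the strand feature is present.
#'
#' @param sig an [IndependentSignature-class].
#' @param path optional output file (pdf/png/svg by extension); when NULL
#'   the plot object is returned without writing.
#' @param base logarithm base for height scaling.
#' @return the ggplot object, invisibly when written to a file.
#' @export
plotSignatureLogo <- function(sig, path = NULL, base = 2) {
  lay <- signatureLogoLayout(sig, base)
  space <- sig@space
  n <- space@nFlank
  rects <- list()
  ## substitution panel occupies y in [1.3, 2.3] at x in [0, 2]
  sp_ <- lay$substitution
  altBases <- list(C = c("A", "G", "T"), T = c("A", "C", "G"))
  x0 <- 0
  for (ob in c("C", "T")) {
    w <- sp_$widths[[ob]]
    y0 <- 1.3
    for (a in seq_len(3L)) {
      h <- sp_$heights[a, ob]
      rects[[length(rects) + 1L]] <- data.frame(
        xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
        fill = .SUB_COLORS[[paste0(ob, ">", altBases[[ob]][a])]],
        label = paste0(ob, ">", altBases[[ob]][a]))
      y0 <- y0 + h
    }
    x0 <- x0 + w
  }
  ## flank rows: one per offset, y in [0, 1.2), each row height scaled
  if (n > 0L) {
    offsets <- c(seq.int(-n, -1L), seq_len(n))
    for (j in seq_along(offsets)) {
      sel <- lay$flanks[lay$flanks$offset == offsets[j], ]
      ## flank positions run left-to-right in genomic order, gap at centre
      xpos <- if (offsets[j] < 0) offsets[j] + n else offsets[j] + n + 1
      x0 <- xpos * (2 / (2 * n + 1))
      y0 <- 0
      for (b in seq_len(4L)) {
        w <- sel$width[b] * (2 / (2 * n + 1)) * 0.92
        h <- sel$rowHeight[1L]
        rects[[length(rects) + 1L]] <- data.frame(
          xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
          fill = .BASE_COLORS[[sel$base[b]]], label = sel$base[b])
        x0 <- x0 + w
      }
    }
  }
  ## strand panel top-right
  if (!is.null(lay$strand)) {
    rects[[length(rects) + 1L]] <- data.frame(
      xmin = 2.1, xmax = 2.3, ymin = 1.3, ymax = 1.3 + lay$strand[[1L]],
      fill = "#777777", label = "+")
    rects[[length(rects) + 1L]] <- data.frame(
      xmin = 2.35, xmax = 2.55, ymin = 1.3, ymax = 1.3 + lay$strand[[2L]],
      fill = "#BBBBBB", label = "-")
  }
  df <- do.call(rbind, rects)
  p <- ggplot(df) +
    geom_rect(aes(xmin = .data$xmin, xmax = .data$xmax,
                  ymin = .data$ymin, ymax = .data$ymax),
              fill = df$fill, colour = "grey30", linewidth = 0.2) +
    theme_void() +
    ggtitle("mutation signature")
  if (!is.null(path)) {
    .openDevice(path, 6, 4)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}

#' Render a full-model signature barplot
#'
#' One bar per joint pattern, faceted into panels by substitution type (and
#' strand when present); each panel therefore holds
#' `nPatterns / 6 / strands` bars (256 for a ±2-flank space).
#'
#' @param sig a [FullSignature-class].
#' @param path optional output file.
#' @return the ggplot object, invisibly when written to a file.
#' @export
plotFullBarplot <- function(sig, path = NULL) {
  space <- sig@space
  pm <- .patternMatrix(space)
  df <- data.frame(
    prob = unname(sig@probs),
    substitution = .SUBSTITUTIONS[pm[, 1L]],
    panel = if (space@includeStrand)
      paste0(.SUBSTITUTIONS[pm[, 1L]], " (", .STRANDS[pm[, ncol(pm)]], ")")
      else .SUBSTITUTIONS[pm[, 1L]])
  df$x <- stats::ave(df$prob, df$panel, FUN = seq_along)
  p <- ggplot(df, aes(x = .data$x, y = .data$prob,
                      fill = .data$substitution)) +
    geom_col(width = 1) +
    scale_fill_manual(values = .SUB_COLORS) +
    facet_wrap(~panel, scales = "free_x") +
    theme_minimal() +
    theme(axis.text.x = element_blank()) +
    labs(x = "joint flanking-base pattern", y = "probability")
  if (!is.null(path)) {
    .openDevice(path, 8, 5)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}

#' Render a stacked membership barplot
#'
#' @param fit a [SignatureFit-class], or a memberships matrix with dimnames.
#' @param path optional output file.
#' @return the ggplot object, invisibly when written to a file.
#' @export
plotMembership <- function(fit, path = NULL) {
  Q <- if (is(fit, "SignatureFit")) fit@memberships else as.matrix(fit)
  df <- data.frame(
    sample = rep(rownames(Q), ncol(Q)),
    signature = rep(colnames(Q), each = nrow(Q)),
    proportion = as.vector(Q))
  df$sample <- factor(df$sample, levels = rownames(Q))
  p <- ggplot(df, aes(x = .data$sample, y = .data$proportion,
                      fill = .data$signature)) +
    geom_col() +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1)) +
    labs(x = NULL, y = "membership proportion")
  if (!is.null(path)) {
    .openDevice(path, max(6, nrow(Q) * 0.25), 4)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}
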