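.revcompVec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count context k-mers with a central pyrimidine
#'
#' Slides a window of odd width `k` over each supplied sequence and tallies
#' k-mers after normalizing the central base to a pyrimidine: windows whose
#' centre is A or G are reverse-complemented (and their strand label
#' flipped, when strand labels are tracked).  Windows containing non-ACGT
#' characters are skipped.
#'
#' @param sequences character vector or `DNAStringSet` of sequences (e.g.
#'   exonic regions).
#' @param k odd window width, `2 * nFlank + 1`.
#' @param strandLabels optional character vector (`"+"`/`"-"`, one per
#'   sequence) giving the transcription strand of each region relative to
#'   the supplied (plus-strand) sequence.
#' @return named numeric vector of counts; names are k-mers, or
#'   `"kmer,strand"` when strand labels are given.  Carries attributes `k`
#'   and `stranded`.
#' @export
countContextKmers <- function(sequences, k, strandLabels = NULL) {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (length(sequences) == 0L || sum(nchar(sequences)) == 0L)
    stop("no input sequence")
  if (k %% 2L != 1L || k < 1L) stop("k must be odd and positive")
  stranded <- !is.null(strandLabels)
  if (stranded && length(strandLabels) != length(sequences))
    stop("one strand label per sequence required")
  half <- (k - 1L) %/% 2L
  tallies <- list()
  for (s in seq_along(sequences)) {
    sq <- toupper(sequences[[s]])
    L <- nchar(sq)
    if (L < k) next
    win <- substring(sq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    win <- win[grepl("^[ACGT]+$", win)]
    if (length(win) == 0L) next
    centre <- substring(win, half + 1L, half + 1L)
    flip <- centre %in% c("A", "G")
    win[flip] <- .revcompVec(win[flip])
    key <- win
    if (stranded) {
      st <- rep(strandLabels[[s]], length(win))
      st[flip] <- ifelse(st[flip] == "+", "-", "+")
      key <- paste0(win, ",", st)
    }
    tallies[[length(tallies) + 1L]] <- table(key)
  }
  if (length(tallies) == 0L) stop("no valid k-mer window in input")
  all <- unlist(lapply(tallies, function(t) as.numeric(t)))
  names(all) <- unlist(lapply(tallies, names))
  out <- tapply(all, names(all), sum)
  out <- stats::setNames(as.numeric(out), names(out))
  attr(out, "k") <- k
  attr(out, "stranded") <- stranded
  out
}

#' Derive the background signature from context k-mer frequencies
#'
#' The background mutation-pattern distribution is obtained from the
#' pyrimidine-centred k-mer composition by assuming the three possible
#' alternate bases are equally likely for each central base: the frequency
#' of pattern (substitution, flanks, strand) is the matching k-mer (and
#' strand) frequency times 1/3, normalized to sum to one.
#'
#' @param kmerFreqs output of [countContextKmers()] with
#'   `k = 2 * nFlank(space) + 1` and strand tracking matching the space.
#' @param space a [FeatureSpace-class].
#' @return A [BackgroundSignature-class].
#' @export
backgroundSignature <- function(kmerFreqs, space) {
  k <- attr(kmerFreqs, "k")
  stranded <- isTRUE(attr(kmerFreqs, "stranded"))
  if (is.null(k) || k != 2L * space@nFlank + 1L)
    stop("k-mer width does not match the feature space")
  if (space@includeStrand && !stranded)
    stop("the stranded space requires strand-tracked k-mer counts")
  if (sum(kmerFreqs) <= 0) stop("zero total k-mer counts")
  n <- space@nFlank
  pm <- .patternMatrix(space)
  centre <- ifelse(pm[, 1L] <= 3L, "C", "T")
  left <- right <- rep("", nrow(pm))
  if (n > 0L) {
    for (l in seq_len(n)) left <- paste0(left, .BASES[pm[, 1L + l]])
    for (l in seq_len(n)) right <- paste0(right, .BASES[pm[, 1L + n + l]])
  }
  key <- paste0(left, centre, right)
  if (space@includeStrand)
    key <- paste0(key, ",", .STRANDS[pm[, ncol(pm)]])
  freq <- kmerFreqs[key]
  freq[is.na(freq)] <- 0
  probs <- as.numeric(freq) / 3
  tot <- sum(probs)
  if (tot <= 0) stop("no k-mer mass maps onto the feature space")
  new("BackgroundSignature", space = space,
      probs = stats::setNames(probs / tot, patternLabels(space)))
}

#' Background signature directly from sequences
#'
#' Convenience wrapper: counts context k-mers over the supplied sequences
#' (optionally restricted to strand-annotated regions) and derives the
#' background signature.
#'
#' @param reference a `DNAStringSet`, character vector of sequences, or a
#'   FASTA path.
#' @param space a [FeatureSpace-class].
#' @param annotation optional strand-annotated `GRanges`; when given,
#'   k-mers are counted within these regions with their gene strand (a
#'   requirement when the space includes the strand feature).
#' @return A [BackgroundSignature-class].
#' @export
backgroundFromSequences <- function(reference, space, annotation = NULL) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (is(reference, "DNAStringSet")) {
    names(reference) <- sub("\\s.*$", "", names(reference))
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  k <- 2L * space@nFlank + 1L
  if (is.null(annotation)) {
    if (space@includeStrand)
      stop("the stranded space requires a strand-annotated region set")
    km <- countContextKmers(reference, k)
  } else {
    chrom <- as.character(GenomicRanges::seqnames(annotation))
    segs <- substring(reference[chrom],
                      GenomicRanges::start(annotation),
                      GenomicRanges::end(annotation))
    km <- countContextKmers(segs, k,
      strandLabels = as.character(GenomicRanges::strand(annotation)))
  }
  backgroundSignature(km, space)
}

#' Uniform background signature
#'
#' All joint patterns equally likely; a neutral built-in useful for tests
#' and as a no-information default.
#'
#' @param space a [FeatureSpace-class].
#' @return A [BackgroundSignature-class].
#' @export
uniformBackground <- function(space) {
  P <- nPatterns(space)
  new("BackgroundSignature", space = space,
      probs = stats::setNames(rep(1 / P, P), patternLabels(space)))
}
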