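#' Draw a random independent signature
#'
#' Each per-feature probability vector is drawn from a symmetric Dirichlet
#' whose concentration is `gamma / M_l`; small `gamma` gives sharp,
#' well-separated signatures, large `gamma` nearly uniform ones.
#'
#' @param space a [FeatureSpace-class].
#' @param gamma Dirichlet sharpness (default 1).
#' @return An [IndependentSignature-class].
#' @export
randomSignature <- function(space, gamma = 1) {
  IndependentSignature(space,
    lapply(space@M, function(m) .rdirichlet1(rep(gamma / m, m))))
}

#' Simulate a mutation catalog from the generative model
#'
#' For each sample, membership proportions are drawn from a Dirichlet
#' (optionally with a fixed background weight); for each mutation a
#' signature is chosen from the memberships and the mutation features are
#' drawn independently from that signature's per-feature multinomials (or
#' jointly from the background distribution).
#'
#' @param space a [FeatureSpace-class].
#' @param K number of signatures (ignored when `signatures` is given).
#' @param signatures optional list of true [IndependentSignature-class]
#'   objects; when NULL, K signatures are drawn with [randomSignature()].
#' @param gamma sharpness for randomly drawn true signatures (default 0.5,
#'   yielding concentrated, distinguishable signatures).
#' @param alpha membership Dirichlet concentration (scalar or length-K
#'   vector; default 1).
#' @param I number of samples.
#' @param J mutations per sample: scalar, length-I vector, or with
#'   `poissonJ = TRUE` the Poisson mean.
#' @param poissonJ logical; draw J_i ~ Poisson(J).
#' @param backgroundWeight fixed membership weight of the background
#'   component (default 0 = no background).
#' @param background [BackgroundSignature-class] used when
#'   `backgroundWeight > 0` (default uniform).
#' @param seed optional integer seed; identical seeds give identical output.
#' @return list with `catalog` (a [MutationCatalog-class]) and `truth`
#'   (list of signatures, memberships including any background column, and
#'   per-sample z counts).
#' @export
simulateCatalog <- function(space, K = NULL, signatures = NULL, gamma = 0.5,
                            alpha = 1, I = 10L, J = 1000L, poissonJ = FALSE,
                            backgroundWeight = 0, background = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(signatures)) {
    if (is.null(K)) stop("either K or signatures must be given")
    signatures <- lapply(seq_len(K), function(k) randomSignature(space, gamma))
  }
  K <- length(signatures)
  names(signatures) <- sprintf("S%d", seq_len(K))
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  hasBg <- backgroundWeight > 0
  if (hasBg && is.null(background)) background <- uniformBackground(space)
  if (hasBg && !identical(background@space@M, space@M))
    stop("background space mismatch")
  Js <- if (poissonJ) stats::rpois(I, J) else rep_len(J, I)
  if (any(Js < 0)) stop("negative mutation counts")
  P <- nPatterns(space)
  expanded <- vapply(signatures, function(s) expandToFull(s)@probs, numeric(P))
  counts <- matrix(0, I, P)
  Q <- matrix(0, I, K + as.integer(hasBg))
  zCounts <- matrix(0L, I, K + as.integer(hasBg))
  for (i in seq_len(I)) {
    qi <- .rdirichlet1(alpha)
    if (hasBg) qi <- c(backgroundWeight, (1 - backgroundWeight) * qi)
    Q[i, ] <- qi
    if (Js[i] == 0L) next
    z <- as.integer(stats::rmultinom(1L, Js[i], qi))
    zCounts[i, ] <- z
    for (k in seq_along(qi)) {
      if (z[k] == 0L) next
      probs <- if (hasBg && k == 1L) background@probs else
        expanded[, k - as.integer(hasBg)]
      counts[i, ] <- counts[i, ] + as.numeric(stats::rmultinom(1L, z[k], probs))
    }
  }
  rownames(counts) <- sprintf("sample%d", seq_len(I))
  colnames(Q) <- colnames(zCounts) <-
    c(if (hasBg) "background", names(signatures))
  rownames(Q) <- rownames(zCounts) <- rownames(counts)
  list(catalog = MutationCatalog(space, counts),
       truth = list(signatures = signatures, memberships = Q,
                    zCounts = zCounts,
                    background = if (hasBg) background else NULL))
}

#' Down-sample a mutation catalog
#'
#' Retains `round(r * total)` mutations drawn uniformly without replacement
#' from the pooled catalog (a multivariate hypergeometric draw over the
#' (sample, pattern) cells).
#'
#' @param catalog a [MutationCatalog-class].
#' @param r retained fraction in (0, 1].
#' @param seed optional integer seed.
#' @return A [MutationCatalog-class] with the same samples.
#' @export
downsampleCatalog <- function(catalog, r, seed = NULL) {
  if (r <= 0 || r > 1) stop("'r' must be in (0, 1]")
  if (r == 1) return(catalog)
  if (!is.null(seed)) set.seed(seed)
  counts <- as.matrix(catalog@counts)
  cells <- which(counts > 0)
  pool <- rep.int(cells, counts[cells])
  nKeep <- round(r * length(pool))
  kept <- sample(pool, nKeep, replace = FALSE)
  newCounts <- matrix(0, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
  tab <- table(kept)
  newCounts[as.integer(names(tab))] <- as.numeric(tab)
  MutationCatalog(catalog@space, newCounts)
}

#' Down-sampling robustness experiment
#'
#' Measures the stability of inferred signatures as data shrink: for each
#' retained fraction and repetition the catalog is down-sampled, the model
#' refitted with the same K, components matched to the gold-standard fit by
#' cosine similarity on the full pattern space, and the similarities
#' recorded.
#'
#' @param catalog the full [MutationCatalog-class].
#' @param gold the [SignatureFit-class] obtained on the full catalog.
#' @param ratios retained fractions (default the classic
#'   1%, 2.5%, 5%, 10%, 25%, 50% ladder).
#' @param reps repetitions per ratio (default 100).
#' @param seed integer seed; replicate seeds are derived deterministically.
#' @param nRestarts,tol,maxIter EM settings for the refits.
#' @return data.frame(ratio, rep, signature, cosine); the per-(ratio,
#'   signature) means are available via `aggregate`.
#' @export
downsamplingExperiment <- function(catalog, gold,
                                   ratios = c(0.01, 0.025, 0.05, 0.10, 0.25, 0.50),
                                   reps = 100L, seed = 1L, nRestarts = 3L,
                                   tol = 1e-6, maxIter = 500L) {
  if (any(ratios > 1)) stop("ratios must be <= 1")
  K <- length(gold@signatures)
  rows <- vector("list", length(ratios) * reps)
  n <- 0L
  for (ri in seq_along(ratios)) {
    for (b in seq_len(reps)) {
      subSeed <- (seed * 10000L + ri * 1000L + b) %% .Machine$integer.max
      ds <- downsampleCatalog(catalog, ratios[ri], seed = subSeed)
      refit <- fitSignatures(ds, K, model = gold@model,
                             background = gold@background,
                             nRestarts = nRestarts, tol = tol,
                             maxIter = maxIter, seed = subSeed + 1L)
      perm <- matchSignatures(refit@signatures, gold@signatures)
      n <- n + 1L
      rows[[n]] <- data.frame(
        ratio = ratios[ri], rep = b,
        signature = names(gold@signatures),
        cosine = attr(perm, "similarity"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- synthetic reference data ------------------------------------------

#' Simulate a random reference genome
#'
#' @param nChrom number of chromosomes.
#' @param chromLength length of each chromosome (recycled).
#' @param gc GC content (default 0.5).
#' @param seed optional integer seed.
#' @return a named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
simulateGenome <- function(nChrom = 1L, chromLength = 10000L, gc = 0.5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chromLength <- rep_len(chromLength, nChrom)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(nChrom), function(i)
    paste(sample(names(p), chromLength[i], replace = TRUE, prob = p),
          collapse = ""), character(1L))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("chr%d", seq_len(nChrom))
  out
}

#' Simulate a strand-annotated gene interval set
#'
#' Places non-overlapping "gene" intervals with random strands on a genome;
#' suitable as the annotation input for the transcription-strand feature.
#'
#' @param genome a named `DNAStringSet`.
#' @param nGenes number of genes per chromosome.
#' @param geneLength gene length.
#' @param seed optional integer seed.
#' @return a strand-annotated `GRanges`.
#' @export
simulateAnnotation <- function(genome, nGenes = 10L, geneLength = 500L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- character(0); starts <- integer(0); strands <- character(0)
  for (ch in names(genome)) {
    L <- nchar(as.character(genome[[ch]]))
    slot <- L %/% nGenes
    if (slot <= geneLength + 2L)
      stop("chromosome too short for the requested genes")
    chroms <- c(chroms, rep(ch, nGenes))
    starts <- c(starts, (seq_len(nGenes) - 1L) * slot +
      sample(slot - geneLength, nGenes, replace = TRUE))
    strands <- c(strands, sample(c("+", "-"), nGenes, replace = TRUE))
  }
  GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, width = geneLength),
                         strand = strands)
}

#' Simulate mutation position records from known signatures
#'
#' Generates per-sample mutation records (sample, chrom, pos, ref, alt)
#' whose extracted feature patterns follow the generative model: sample
#' memberships are drawn from a Dirichlet, patterns from the chosen
#' signature, and each pattern is placed at a uniformly chosen genome
#' position whose context (after pyrimidine normalization and, when the
#' space is stranded, gene-strand assignment) realizes that pattern.
#' Patterns with no compatible genome position are re-drawn.
#'
#' @param genome a named `DNAStringSet`.
#' @param space a [FeatureSpace-class].
#' @param signatures list of true [IndependentSignature-class] objects.
#' @param annotation strand-annotated `GRanges`, required for stranded
#'   spaces; when given, mutations are placed only inside genes.
#' @param I number of samples.
#' @param J mutations per sample (scalar or length-I vector).
#' @param alpha membership Dirichlet concentration.
#' @param seed optional integer seed.
#' @return list with `records` (data.frame), `truth` (memberships and
#'   signatures).
#' @export
simulateMutationPositions <- function(genome, space, signatures,
                                      annotation = NULL, I = 5L, J = 200L,
                                      alpha = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (space@includeStrand && is.null(annotation))
    stop("stranded space requires an annotation")
  n <- space@nFlank
  seqs <- as.character(genome)
  ## index all placeable positions by their realized pattern context key
  sites <- list()   # key -> data.frame(chrom, pos, flipped)
  for (ch in names(seqs)) {
    sq <- seqs[[ch]]
    L <- nchar(sq)
    pos <- seq.int(n + 1L, L - n)
    if (!is.null(annotation)) {
      ann <- annotation[as.character(GenomicRanges::seqnames(annotation)) == ch]
      if (length(ann) == 0L) next
      inGene <- rep(FALSE, length(pos))
      strandOf <- rep(NA_character_, length(pos))
      for (gi in seq_along(ann)) {
        sel <- pos >= GenomicRanges::start(ann)[gi] &
               pos <= GenomicRanges::end(ann)[gi]
        amb <- sel & inGene &
          strandOf != as.character(GenomicRanges::strand(ann))[gi]
        strandOf[sel] <- as.character(GenomicRanges::strand(ann))[gi]
        inGene <- inGene | sel
        strandOf[amb] <- NA_character_
      }
      keep <- inGene & !is.na(strandOf)
      pos <- pos[keep]
      strandOf <- strandOf[keep]
    }
    if (length(pos) == 0L) next
    ctx <- substring(sq, pos - n, pos + n)
    ok <- grepl("^[ACGT]+$", ctx)
    pos <- pos[ok]; ctx <- ctx[ok]
    if (!is.null(annotation)) strandOf <- strandOf[ok]
    centre <- substring(ctx, n + 1L, n + 1L)
    flip <- centre %in% c("A", "G")
    ctxN <- ctx
    ctxN[flip] <- .revcompVec(ctx[flip])
    key <- ctxN
    if (space@includeStrand) {
      featStrand <- ifelse(xor(strandOf == "-", flip), "-", "+")
      key <- paste0(ctxN, ",", featStrand)
    }
    df <- data.frame(chrom = ch, pos = pos, flipped = flip,
                     stringsAsFactors = FALSE)
    sp_ <- split(seq_len(nrow(df)), key)
    for (kk in names(sp_)) {
      sites[[kk]] <- rbind(sites[[kk]], df[sp_[[kk]], , drop = FALSE])
    }
  }
  if (length(sites) == 0L) stop("no placeable positions in the genome")
  K <- length(signatures)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  Js <- rep_len(J, I)
  Q <- matrix(0, I, K, dimnames = list(sprintf("sample%d", seq_len(I)),
                                       sprintf("S%d", seq_len(K))))
  pm <- .patternMatrix(space)
  expanded <- vapply(signatures, function(s) expandToFull(s)@probs,
                     numeric(nPatterns(space)))
  ## context key of every pattern (flanks + central pyrimidine, + strand)
  centreAll <- ifelse(pm[, 1L] <= 3L, "C", "T")
  leftAll <- rightAll <- rep("", nrow(pm))
  if (n > 0L) {
    for (l in seq_len(n)) leftAll <- paste0(leftAll, .BASES[pm[, 1L + l]])
    for (l in seq_len(n)) rightAll <- paste0(rightAll, .BASES[pm[, 1L + n + l]])
  }
  keyAll <- paste0(leftAll, centreAll, rightAll)
  if (space@includeStrand)
    keyAll <- paste0(keyAll, ",", .STRANDS[pm[, ncol(pm)]])
  placeable <- keyAll %in% names(sites)
  if (!any(placeable)) stop("no pattern is placeable on this genome")
  recs <- list()
  for (i in seq_len(I)) {
    qi <- .rdirichlet1(alpha)
    Q[i, ] <- qi
    mix <- as.numeric(expanded %*% qi)
    mix[!placeable] <- 0
    mix <- mix / sum(mix)
    drawn <- sample.int(nrow(pm), Js[i], replace = TRUE, prob = mix)
    for (d in drawn) {
      cand <- sites[[keyAll[d]]]
      row <- cand[sample.int(nrow(cand), 1L), ]
      sub <- .SUBSTITUTIONS[pm[d, 1L]]
      refPyr <- substr(sub, 1L, 1L)
      altPyr <- substr(sub, 3L, 3L)
      ref <- if (row$flipped) .COMPLEMENT[[refPyr]] else refPyr
      alt <- if (row$flipped) .COMPLEMENT[[altPyr]] else altPyr
      recs[[length(recs) + 1L]] <- data.frame(
        sample = rownames(Q)[i], chrom = row$chrom, pos = row$pos,
        ref = ref, alt = alt, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records,
       truth = list(signatures = signatures, memberships = Q))
}
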