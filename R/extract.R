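#' @importFrom Biostrings readDNAStringSet DNAStringSet
#' @importFrom GenomicRanges GRanges findOverlaps strand seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(.COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Read a mutation position file
#'
#' Reads a tab-separated file of somatic single-nucleotide variants with
#' columns (sample id, chromosome, 1-based position, reference base,
#' alternate base); a header line is detected automatically.  Rows whose
#' ref or alt is a multi-base ACGT string (non-SNV) are skipped and tallied;
#' rows with a non-numeric position or a base outside A/C/G/T raise an
#' error naming the line.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sample, chrom, pos, ref, alt and an
#'   attribute `"skipped"` giving the number of non-SNV rows dropped.
#' @export
readMutationPositions <- function(path) {
  if (!file.exists(path)) stop("mutation position file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  firstLine <- 1L
  f1 <- fields[[1L]]
  ## a header has a non-numeric position AND non-base ref/alt columns
  if (length(f1) >= 5L && is.na(suppressWarnings(as.numeric(f1[3L]))) &&
      !grepl("^[ACGTacgt]+$", f1[4L]) && !grepl("^[ACGTacgt]+$", f1[5L]))
    firstLine <- 2L
  rows <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq.int(firstLine, length.out = length(lines) - firstLine + 1L)) {
    f <- fields[[i]]
    if (length(f) < 5L)
      stop(sprintf("line %d: expected >= 5 tab-separated fields", i))
    pos <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(pos) || pos != as.integer(pos) || pos < 1)
      stop(sprintf("line %d: malformed position '%s'", i, f[3L]))
    ref <- toupper(f[4L]); alt <- toupper(f[5L])
    if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
      stop(sprintf("line %d: malformed base ('%s' > '%s')", i, f[4L], f[5L]))
    if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.frame(sample = f[1L], chrom = f[2L],
                            pos = as.integer(pos), ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  if (skipped > 0L)
    message(skipped, " non-SNV row(s) skipped")
  attr(out, "skipped") <- skipped
  out
}

#' Normalize a substitution to a pyrimidine reference base
#'
#' Substitutions are represented with the original base fixed to C or T to
#' remove the redundancy of complementary strands.  When the reference base
#' is a purine (A or G), ref and alt are complemented and the context is
#' reverse-complemented (`flipped = TRUE`).
#'
#' @param ref,alt single reference/alternate bases.
#' @param context the (2n+1)-mer centred on the mutated base; its centre
#'   must equal `ref`.
#' @return list with `substitution` (one of the 6 canonical labels),
#'   `flanks` (character vector of 2n bases in offset order -n..-1, +1..+n),
#'   `flipped` (logical), and `valid` (FALSE when the context contains a
#'   non-ACGT character, in which case the record should be dropped).
#' @export
normalizePyrimidine <- function(ref, alt, context) {
  n <- (nchar(context) - 1L) %/% 2L
  if (nchar(context) != 2L * n + 1L)
    stop("context length must be odd")
  if (!grepl("^[ACGT]+$", context))
    return(list(substitution = NA_character_, flanks = NA_character_,
                flipped = NA, valid = FALSE))
  if (substr(context, n + 1L, n + 1L) != ref)
    stop("context centre does not match ref")
  flipped <- ref %in% c("A", "G")
  if (flipped) {
    ref <- .COMPLEMENT[[ref]]
    alt <- .COMPLEMENT[[alt]]
    context <- .revcomp(context)
  }
  sub <- paste0(ref, ">", alt)
  if (!sub %in% .SUBSTITUTIONS) stop("invalid substitution ", sub)
  flanks <- character(0L)
  if (n > 0L) {
    ch <- strsplit(context, "", fixed = TRUE)[[1L]]
    flanks <- c(ch[seq_len(n)], ch[(n + 2L):(2L * n + 1L)])
  }
  list(substitution = sub, flanks = flanks, flipped = flipped, valid = TRUE)
}

#' Read a BED6 gene annotation with strand
#'
#' @param path path to a BED file whose 6th column holds the gene strand.
#' @return a `GRanges` with strand set.
#' @export
readAnnotationBED <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("annotation intervals must carry a gene strand (+/-)")
  gr
}

#' Assign the transcription-strand feature to mutations
#'
#' A pyrimidine-normalized mutation gets strand `"+"` when it lies on the
#' coding (untranscribed) strand of the overlapping gene and `"-"` when on
#' the template strand, i.e. the gene strand XOR'ed with the pyrimidine
#' flip.  Mutations outside all annotated intervals, or inside genes on
#' both strands, are dropped (`NA`).
#'
#' @param chrom,pos vectors of mutation coordinates (1-based).
#' @param flipped logical vector from [normalizePyrimidine()].
#' @param annotation a strand-annotated `GRanges` (see [readAnnotationBED()]).
#' @return character vector of `"+"`, `"-"` or `NA` (drop).
#' @export
assignTranscriptionStrand <- function(chrom, pos, flipped, annotation) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(gr, annotation)
  geneStrand <- rep(NA_character_, length(gr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  st <- as.character(GenomicRanges::strand(annotation))[sh]
  for (i in unique(qh)) {
    ss <- unique(st[qh == i])
    geneStrand[i] <- if (length(ss) == 1L) ss else NA_character_  # ambiguous
  }
  ## gene "+" and not flipped -> mutation sits on the coding strand -> "+"
  ifelse(is.na(geneStrand), NA_character_,
         ifelse(xor(geneStrand == "-", flipped), "-", "+"))
}

#' Extract a mutation catalog from records and a reference sequence
#'
#' Looks up the (2 nFlank + 1)-mer context of every mutation in the
#' reference, normalizes to a pyrimidine original base, optionally assigns
#' the transcription strand from a gene annotation, and tallies per-sample
#' pattern counts.  Records are dropped (and tallied in the report) when
#' their context contains N/non-ACGT bases, their stated ref mismatches the
#' reference sequence (hard error with `strict = TRUE`), or — when the
#' strand feature is enabled — they are intergenic or overlap genes on both
#' strands.
#'
#' @param records data.frame as from [readMutationPositions()].
#' @param reference a named `DNAStringSet`, or path to a FASTA file.
#' @param space a [FeatureSpace-class].
#' @param annotation strand-annotated `GRanges` (required when
#'   `space` includes the strand feature).
#' @param strict logical; promote reference-base mismatches to an error.
#' @return A [MutationCatalog-class] with an attribute-like report available
#'   via [extractionReport()].
#' @export
extractCatalog <- function(records, reference, space, annotation = NULL,
                           strict = FALSE) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  seqs <- as.character(reference)
  if (space@includeStrand && is.null(annotation))
    stop("the strand feature requires a gene annotation")
  n <- space@nFlank
  sampleIDs <- unique(records$sample)
  report <- c(retained = 0L, refMismatch = 0L, invalidContext = 0L,
              intergenic = 0L, outOfBounds = 0L)
  nr <- nrow(records)
  if (nr == 0L) {
    cat0 <- catalogFromTriplets(space, character(0), integer(0),
                                numeric(0), sampleIDs = sampleIDs %||% "empty")
    attr(cat0, "report") <- report
    return(cat0)
  }
  keep <- rep(TRUE, nr)
  feat <- matrix(NA_integer_, nr, nFeatures(space))
  flipped <- rep(NA, nr)
  for (i in seq_len(nr)) {
    chrom <- records$chrom[i]; pos <- records$pos[i]
    if (!chrom %in% names(seqs) || pos - n < 1L || pos + n > nchar(seqs[[chrom]])) {
      report["outOfBounds"] <- report["outOfBounds"] + 1L
      keep[i] <- FALSE
      next
    }
    refBase <- substr(seqs[[chrom]], pos, pos)
    if (refBase != records$ref[i]) {
      if (strict)
        stop(sprintf("record %d: ref '%s' does not match reference base '%s'",
                     i, records$ref[i], refBase))
      report["refMismatch"] <- report["refMismatch"] + 1L
      keep[i] <- FALSE
      next
    }
    ctx <- substr(seqs[[chrom]], pos - n, pos + n)
    nm <- normalizePyrimidine(records$ref[i], records$alt[i], ctx)
    if (!nm$valid) {
      report["invalidContext"] <- report["invalidContext"] + 1L
      keep[i] <- FALSE
      next
    }
    feat[i, 1L] <- match(nm$substitution, .SUBSTITUTIONS)
    if (n > 0L)
      feat[i, 1L + seq_len(2L * n)] <- match(nm$flanks, .BASES)
    flipped[i] <- nm$flipped
  }
  if (space@includeStrand) {
    idx <- which(keep)
    if (length(idx) > 0L) {
      st <- assignTranscriptionStrand(records$chrom[idx], records$pos[idx],
                                      flipped[idx], annotation)
      drop <- is.na(st)
      report["intergenic"] <- report["intergenic"] + sum(drop)
      keep[idx[drop]] <- FALSE
      feat[idx[!drop], nFeatures(space)] <- match(st[!drop], .STRANDS)
    }
  }
  report["retained"] <- sum(keep)
  pat <- if (any(keep)) encodePattern(space, feat[keep, , drop = FALSE]) else integer(0)
  out <- catalogFromTriplets(space, records$sample[keep], pat,
                             sampleIDs = sampleIDs)
  attr(out, "report") <- report
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Extraction report of a catalog
#'
#' @param catalog a [MutationCatalog-class] produced by [extractCatalog()].
#' @return named integer vector of retained/dropped record tallies.
#' @export
extractionReport <- function(catalog) {
  rep <- attr(catalog, "report")
  if (is.null(rep)) stop("catalog carries no extraction report")
  rep
}
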