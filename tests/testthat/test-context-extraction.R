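test_that("mutation position files are read and filtered", {
  f <- writeTempTSV(c(
    "sample\tchrom\tpos\tref\talt",
    "s1\tchr1\t10\tC\tA",
    "s1\tchr1\t20\tG\tT",
    "s2\tchr1\t30\tT\tG"))
  recs <- readMutationPositions(f)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$pos, c(10L, 20L, 30L))

  f2 <- writeTempTSV(c("s1\tchr1\t10\tAT\tA", "s1\tchr1\t12\tC\tT"))
  expect_message(recs2 <- readMutationPositions(f2), "non-SNV")
  expect_equal(nrow(recs2), 1L)
  expect_equal(attr(recs2, "skipped"), 1L)

  f3 <- writeTempTSV(character(0))
  expect_equal(nrow(readMutationPositions(f3)), 0L)

  f4 <- writeTempTSV("s1\tchr1\tabc\tC\tA")
  expect_error(readMutationPositions(f4), "line 1")
  expect_error(readMutationPositions(tempfile()), "not found")
})

test_that("pyrimidine normalization flips purine contexts", {
  r <- normalizePyrimidine("C", "A", "AACGT")
  expect_equal(r$substitution, "C>A")
  expect_equal(r$flanks, c("A", "A", "G", "T"))
  expect_false(r$flipped)

  r2 <- normalizePyrimidine("G", "T", "AAGCT")
  expect_equal(r2$substitution, "C>A")
  expect_equal(r2$flanks, c("A", "G", "T", "T"))
  expect_true(r2$flipped)

  expect_false(normalizePyrimidine("C", "A", "ANCGT")$valid)
  expect_error(normalizePyrimidine("C", "A", "AATGT"), "centre")
})

test_that("normalization is idempotent over all +/-1 contexts", {
  ## every (substitution, -1 base, +1 base) combination, on both strands
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in c("C", "T")) for (alt in setdiff(bases, ref))
    for (b5 in bases) for (b3 in bases) {
      ctx <- paste0(b5, ref, b3)
      r <- normalizePyrimidine(ref, alt, ctx)
      expect_false(r$flipped)
      expect_equal(r$substitution, paste0(ref, ">", alt))
      ## the same mutation seen from the other strand normalizes identically
      rcCtx <- paste0(comp[b3], comp[ref], comp[b5])
      r2 <- normalizePyrimidine(comp[[ref]], comp[[alt]], rcCtx)
      expect_true(r2$flipped)
      expect_equal(r2$substitution, r$substitution)
      expect_equal(r2$flanks, r$flanks)
    }
})

test_that("transcription strand is gene strand XOR pyrimidine flip", {
  ann <- GRanges("chr1", IRanges(c(100, 300), width = 50), strand = c("+", "-"))
  st <- assignTranscriptionStrand(
    chrom = rep("chr1", 5), pos = c(110, 120, 310, 320, 500),
    flipped = c(FALSE, TRUE, FALSE, TRUE, FALSE), annotation = ann)
  expect_equal(st, c("+", "-", "-", "+", NA))
  ## ambiguous overlap of genes on both strands drops the mutation
  ann2 <- GRanges("chr1", IRanges(c(100, 120), width = 50), strand = c("+", "-"))
  expect_true(is.na(assignTranscriptionStrand("chr1", 130, FALSE, ann2)))
})

test_that("extractCatalog produces the expected single-pattern count", {
  genome <- DNAStringSet(c(chr1 = "AAACGTTT"))
  sp <- buildFeatureSpace(1)
  recs <- data.frame(sample = "s1", chrom = "chr1", pos = 4L,
                     ref = "C", alt = "T", stringsAsFactors = FALSE)
  cat_ <- extractCatalog(recs, genome, sp)
  m <- c(match("C>T", featureLabels(sp)$substitution),
         match("A", featureLabels(sp)$`flank-1`),
         match("G", featureLabels(sp)$`flank+1`))
  counts <- as.matrix(mutationCounts(cat_))
  expect_equal(sum(counts), 1)
  expect_equal(unname(counts[1L, encodePattern(sp, m)]), 1)
  expect_equal(unname(extractionReport(cat_)["retained"]), 1L)
})

test_that("reference mismatches are dropped, or fatal in strict mode", {
  genome <- DNAStringSet(c(chr1 = "AAACGTTT"))
  sp <- buildFeatureSpace(1)
  recs <- data.frame(sample = c("s1", "s1"), chrom = "chr1",
                     pos = c(4L, 5L), ref = c("C", "C"), alt = "T",
                     stringsAsFactors = FALSE)  # pos 5 is G, not C
  cat_ <- extractCatalog(recs, genome, sp)
  expect_equal(unname(extractionReport(cat_)[c("retained", "refMismatch")]),
               c(1L, 1L))
  expect_error(extractCatalog(recs, genome, sp, strict = TRUE), "does not match")
})

test_that("strand feature only removes mutations, never adds", {
  set.seed(11)
  genome <- simulateGenome(1, 20000, seed = 11)
  ann <- simulateAnnotation(genome, nGenes = 8, geneLength = 600, seed = 12)
  spS <- buildFeatureSpace(1, TRUE)
  spN <- buildFeatureSpace(1, FALSE)
  sigs <- list(randomSignature(spS, 0.5))
  sim <- simulateMutationPositions(genome, spS, sigs, annotation = ann,
                                   I = 2, J = 100, seed = 13)
  withS <- extractCatalog(sim$records, genome, spS, annotation = ann)
  without <- extractCatalog(sim$records, genome, spN)
  expect_gte(sum(totalMutations(without)), sum(totalMutations(withS)))
  ## intergenic-only records are all dropped under the stranded space
  farRec <- sim$records[1, ]; farRec$pos <- 3L
  farRec$ref <- substr(as.character(genome[["chr1"]]), 3, 3)
  farRec$alt <- setdiff(c("A", "C", "G", "T"), farRec$ref)[1]
  catFar <- extractCatalog(farRec, genome, spS, annotation = ann)
  expect_equal(sum(totalMutations(catFar)), 0)
})

test_that("extraction is invariant to record order and matches a site oracle", {
  genome <- simulateGenome(1, 5000, seed = 21)
  sp <- buildFeatureSpace(1)
  sigs <- list(randomSignature(sp, 0.5))
  sim <- simulateMutationPositions(genome, sp, sigs, I = 3, J = 80, seed = 22)
  cat1 <- extractCatalog(sim$records, genome, sp)
  perm <- sample(nrow(sim$records))
  cat2 <- extractCatalog(sim$records[perm, ], genome, sp)
  expect_equal(as.matrix(mutationCounts(cat1))[sampleIDs(cat1), ],
               as.matrix(mutationCounts(cat2))[sampleIDs(cat1), ])

  ## oracle: recompute each record's pattern independently with Biostrings
  seqstr <- as.character(genome[["chr1"]])
  expected <- table(vapply(seq_len(nrow(sim$records)), function(i) {
    p <- sim$records$pos[i]
    ctx <- substr(seqstr, p - 1, p + 1)
    ref <- sim$records$ref[i]; alt <- sim$records$alt[i]
    if (ref %in% c("A", "G")) {
      rc <- as.character(reverseComplement(DNAStringSet(ctx)))
      ref <- chartr("AG", "TC", ref); alt <- chartr("ACGT", "TGCA", alt)
      ctx <- rc
    }
    paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  }, character(1)))
  got <- Matrix::colSums(mutationCounts(cat1))
  got <- got[got > 0]
  expect_equal(sort(names(got)), sort(names(expected)))
  expect_equal(as.numeric(got[names(expected)]), as.numeric(expected))
})
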