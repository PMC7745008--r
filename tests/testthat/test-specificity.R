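params <- designParameters()

test_that("index construction records every k-mer occurrence", {
  idx <- buildSpecificityIndex(c(s = "ACGTACGTACGT"), k = 8)
  expect_identical(seedLength(idx), 8L)
  total <- sum(vapply(ls(idx@seeds), function(km) nrow(idx@seeds[[km]]),
                      integer(1)))
  expect_identical(total, 5L)  # 12 - 8 + 1
  # duplicated k-mer lists both loci
  idx2 <- buildSpecificityIndex(c(s = paste0("ACGTACGTAAAA", "ACGTACGT")),
                                k = 8)
  expect_identical(nrow(idx2@seeds[["ACGTACGT"]]), 2L)
  expect_warning(buildSpecificityIndex(c(tiny = "ACGT"), k = 8),
                 "shorter than k")
  expect_error(buildSpecificityIndex(c(s = "ACGT"), k = 4), ">= 8")
})

test_that("planted oligos are found with the correct orientation and
           position", {
  set.seed(301)
  ctg <- randomSeq(3000)
  oligo <- substr(ctg, 501, 530)
  idx <- buildSpecificityIndex(c(c1 = ctg), k = 12)
  h <- findHits(oligo, idx)
  expect_identical(nrow(h), 1L)
  expect_identical(h$orientation, "plus/plus")
  expect_identical(h$start, 500L)       # 0-based
  expect_identical(h$end, 529L)
  expect_identical(h$matched, 30L)
  hrc <- findHits(reverseComplementStr(oligo), idx)
  expect_identical(nrow(hrc), 1L)
  expect_identical(hrc$orientation, "plus/minus")
  expect_identical(hrc$start, 500L)     # reported on the plus strand
})

test_that("hits tolerate up to two internal mismatches", {
  set.seed(302)
  ctg <- randomSeq(2000)
  oligo <- substr(ctg, 1001, 1030)
  mutate <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  idx <- buildSpecificityIndex(c(c1 = ctg), k = 12)
  # two mismatches leave >= 18 matched bases: still one hit
  h2 <- findHits(mutate(oligo, c(16, 22)), idx)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$matched, 28L)
})

test_that("findHits agrees with the exhaustive position-scan oracle", {
  set.seed(303)
  db <- list(cA = randomSeq(6000), cB = randomSeq(3000))
  # plant a duplication so some oligos have two true loci
  substr(db$cB, 1001, 1300) <- substr(db$cA, 2001, 2300)
  db <- vapply(db, identity, character(1))
  idx <- buildSpecificityIndex(db, k = 12)
  keyOf <- function(h) {
    if (!nrow(h)) return(character())
    sort(sprintf("%s|%s|%d", h$sequence_id, h$orientation, h$matched))
  }
  nOligos <- 120
  for (i in seq_len(nOligos)) {
    oligo <- if (i %% 3 == 0) randomSeq(30)
    else {
      src <- sample(names(db), 1)
      p <- sample(nchar(db[[src]]) - 29, 1)
      s <- substr(db[[src]], p, p + 29)
      if (i %% 2 == 0) reverseComplementStr(s) else s
    }
    got <- findHits(oligo, idx, merge = FALSE)
    want <- oracleHits(oligo, as.list(db))
    expect_identical(keyOf(got), keyOf(want), info = oligo)
  }
})

test_that("overlapping alignments at one locus merge to the best", {
  h <- data.frame(
    sequence_id = c("s", "s", "s"),
    orientation = c("plus/plus", "plus/minus", "plus/plus"),
    start = c(100L, 110L, 400L), end = c(129L, 139L, 429L),
    matched = c(24L, 30L, 20L), stringsAsFactors = FALSE)
  m <- ProbeTiler:::.mergeHits(h)
  expect_identical(nrow(m), 2L)
  expect_identical(m$matched[m$start == 110L], 30L)
})

test_that("genome uniqueness keeps single-copy oligos and drops
           duplicated ones", {
  fx <- sharedDupFixture()
  idx <- buildSpecificityIndex(fx$genome, k = 12, name = "genome")
  dupTruth <- fx$truth$duplications
  uniqueOligo <- substr(fx$genome[["chrA"]], 5001, 5030)
  dupOligo <- substr(fx$genome[["chrA"]], 2101, 2130)   # inside duplication
  cands <- data.frame(
    target_label = "t", offset = c(5000L, 2100L),
    sequence = c(uniqueOligo, dupOligo), stringsAsFactors = FALSE)
  kept <- genomeUniquenessFilter(cands, idx, params)
  expect_identical(kept$sequence, uniqueOligo)
  expect_identical(kept$genome_hits, 1L)
  # an oligo whose reverse complement is also planted elsewhere is dropped
  rcDup <- reverseComplementStr(dupOligo)
  h <- findHits(rcDup, idx)
  expect_identical(nrow(h), 2L)
  # absent oligo: self-locus missing is an error
  expect_error(
    genomeUniquenessFilter(
      data.frame(target_label = "t", offset = 0L,
                 sequence = substr(strrep("ACGT", 8), 1, 30),
                 stringsAsFactors = FALSE),
      idx, params),
    "no genome alignment")
})

test_that("the four antisense orientation cases resolve as specified", {
  set.seed(305)
  txPlus <- randomSeq(900)
  txMinus <- randomSeq(900)
  caseA <- randomSeq(30)                        # no transcript overlap
  caseB <- substr(txPlus, 301, 330)             # sense of a + gene
  caseC <- reverseComplementStr(substr(txMinus, 301, 330))
  caseD <- substr(txPlus, 601, 630)             # in two genes, both strands
  txBoth <- paste0(randomSeq(200), reverseComplementStr(caseD),
                   randomSeq(200))
  idx <- buildSpecificityIndex(
    c(txP = txPlus, txM = txMinus, txB = txBoth), k = 12,
    name = "unspliced")
  cands <- data.frame(
    target_label = "t", offset = c(0L, 40L, 80L, 120L),
    sequence = c(caseA, caseB, caseC, caseD), stringsAsFactors = FALSE)
  out <- antisenseFilter(cands, idx, params)
  # case A: untouched
  expect_true(caseA %in% out$sequence)
  expect_false(out$revcomped[out$sequence == caseA])
  # case B: replaced by its reverse complement
  expect_false(caseB %in% out$sequence)
  expect_true(reverseComplementStr(caseB) %in% out$sequence)
  expect_true(out$revcomped[out$sequence == reverseComplementStr(caseB)])
  # case C: plus/minus only, retained unchanged
  expect_true(caseC %in% out$sequence)
  expect_false(out$revcomped[out$sequence == caseC])
  # case D: hits in both orientations, rejected
  expect_false(caseD %in% out$sequence)
  expect_false(reverseComplementStr(caseD) %in% out$sequence)
  expect_identical(nrow(out), 3L)
})

test_that("antisense-filter output probes cannot bind unspliced
           transcripts (re-query check)", {
  fx <- sharedGeneFixture()
  gTruth <- fx$truth$genes
  regions <- extractRegions(
    fx$genome, data.frame(contig = "chrA",
                          start = c(1001, 3001, 4501),
                          end = c(1800, 3800, 5300),
                          label = c("inPlus", "inMinus", "intergenic")))
  cands <- scanTargets(regions, params)
  gIdx <- buildSpecificityIndex(fx$genome, k = 12)
  cands <- genomeUniquenessFilter(cands, gIdx, params)
  uIdx <- buildSpecificityIndex(fx$unspliced, k = 12)
  out <- antisenseFilter(cands, uIdx, params)
  expect_gt(nrow(out), 0)
  # probes are reverse complements of the retained oligos; none may align
  # to an unspliced transcript in the orientation that binds RNA
  for (s in out$sequence) {
    h <- findHits(s, uIdx, params@minMatched, params@maxMismatch)
    expect_false("plus/plus" %in% h$orientation, info = s)
  }
  # sense-strand oligos from the + gene were flipped, not dropped
  expect_true(any(out$revcomped[out$target_label == "inPlus"]))
})

test_that("exon avoidance rejects oligos touching spliced transcripts", {
  fx <- sharedGeneFixture()
  sIdx <- buildSpecificityIndex(fx$spliced, k = 12)
  exonic <- substr(fx$genome[["chrA"]], 1101, 1130)    # inside exon 1
  intronic <- substr(fx$genome[["chrA"]], 1351, 1380)  # inside the intron
  away <- substr(fx$genome[["chrA"]], 5001, 5030)
  cands <- data.frame(target_label = "t", offset = c(0L, 40L, 80L),
                      sequence = c(exonic, intronic, away),
                      stringsAsFactors = FALSE)
  out <- exonAvoidanceFilter(cands, sIdx, params)
  expect_identical(sort(out$sequence), sort(c(intronic, away)))
  # an oligo straddling the exon-intron boundary with >= minMatched
  # exonic bases is also rejected
  straddle <- substr(fx$genome[["chrA"]], 1281, 1310)  # 20 exonic + 10 in
  h <- findHits(straddle, sIdx, params@minMatched, params@maxMismatch)
  out2 <- exonAvoidanceFilter(
    data.frame(target_label = "t", offset = 0L, sequence = straddle,
               stringsAsFactors = FALSE), sIdx, params)
  expect_identical(nrow(out2), 0L)
  expect_gt(nrow(h), 0)
})

test_that("isoform specificity keeps within-gene oligos and drops
           cross-gene ones", {
  iso <- sharedIsoformDb()
  idx <- buildSpecificityIndex(iso$seqs, k = 12, geneMap = iso$geneMap)
  inBoth <- substr(iso$common, 201, 230)     # both isoforms of geneA only
  inA1 <- substr(iso$uniqueA, 101, 130)      # single isoform
  crossGene <- substr(iso$common, 111, 140)  # copied into geneB
  cands <- data.frame(target_label = "tx_a1", offset = c(0L, 40L, 80L),
                      sequence = c(inBoth, inA1, crossGene),
                      stringsAsFactors = FALSE)
  out <- isoformSpecificityFilter(cands, idx, "geneA", params)
  expect_identical(sort(out$sequence), sort(c(inBoth, inA1)))
  # plus/minus-only overlap with another gene does not disqualify
  set.seed(306)
  pmSeg <- randomSeq(30)
  seqs2 <- c(txX = paste0(randomSeq(100), pmSeg, randomSeq(100)),
             txY = paste0(randomSeq(100), reverseComplementStr(pmSeg),
                          randomSeq(100)))
  idx2 <- buildSpecificityIndex(seqs2, k = 12,
                                geneMap = c(txX = "gX", txY = "gY"))
  out2 <- isoformSpecificityFilter(
    data.frame(target_label = "txX", offset = 0L, sequence = pmSeg,
               stringsAsFactors = FALSE), idx2, "gX", params)
  expect_identical(nrow(out2), 1L)
  # zero plus/plus hits cannot happen for a real candidate
  expect_error(
    isoformSpecificityFilter(
      data.frame(target_label = "t", offset = 0L,
                 sequence = randomSeq(30),
                 stringsAsFactors = FALSE), idx2, "gY", params),
    "own transcript")
})

test_that("retained oligos re-query to exactly one genome alignment", {
  fx <- sharedDupFixture()
  idx <- buildSpecificityIndex(fx$genome, k = 12)
  regions <- extractRegions(
    fx$genome, data.frame(contig = "chrA", start = 1901, end = 2500,
                          label = "overDup"))
  cands <- scanTargets(regions, params)
  kept <- genomeUniquenessFilter(cands, idx, params)
  expect_true(nrow(kept) < nrow(cands))  # duplicated stretch was dropped
  for (s in kept$sequence)
    expect_identical(nrow(findHits(s, idx, params@minMatched,
                                   params@maxMismatch)), 1L)
})
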