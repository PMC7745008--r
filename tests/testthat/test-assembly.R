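params <- designParameters()

mkOligos <- function(n, label = "t") {
  data.frame(target_label = label, offset = seq(0L, by = 40L,
                                                length.out = n),
             sequence = vapply(seq_len(n), function(i) randomSeq(30),
                               character(1)),
             tm = 70, gc = 50, stringsAsFactors = FALSE)
}

test_that("even-spaced probe selection follows the spacing formula", {
  set.seed(501)
  ol <- mkOligos(10)
  expect_identical(selectProbes(ol, NA)$offset, ol$offset)
  expect_identical(selectProbes(ol, "all")$offset, ol$offset)
  # n = 2 keeps the first and last by offset
  expect_identical(selectProbes(ol, 2)$offset,
                   ol$offset[c(1, 10)])
  # n = 1 keeps the middle probe
  expect_identical(nrow(selectProbes(ol, 1)), 1L)
  expect_identical(selectProbes(ol, 1)$offset,
                   ol$offset[round((10 - 1) / 2) + 1])
  # general case: indices round(i (m-1)/(n-1)) + 1
  got <- selectProbes(ol, 4)$offset
  expect_identical(got, ol$offset[round((0:3) * 9 / 3) + 1])
  expect_warning(out <- selectProbes(mkOligos(3), 5), "only 3")
  expect_identical(nrow(out), 3L)
  expect_error(selectProbes(ol, 0), ">= 1")
})

test_that("single-readout assembly builds the documented construct", {
  set.seed(502)
  ol <- mkOligos(2)
  readout <- list(readout_id = "DR07", sequence = randomSeq(20))
  primers <- data.frame(forward = randomSeq(20), reverse = randomSeq(20))
  rec <- assembleSingleReadout(ol, readout, primers, "chromatin")
  expect_identical(nrow(rec), 2L)
  # template = fwd + readout + targeting + readout + revcomp(reverse)
  expect_identical(nchar(rec$template_sequence),
                   rep(30L + 2L * 20L + 2L * 20L, 2))
  expect_identical(
    rec$template_sequence[1],
    paste0(primers$forward, readout$sequence, ol$sequence[1],
           readout$sequence, reverseComplementStr(primers$reverse)))
  # primary = revcomp(core without primers)
  expect_identical(
    rec$primary_sequence[1],
    reverseComplementStr(paste0(readout$sequence, ol$sequence[1],
                                readout$sequence)))
  # both probes of the target share the readout id
  expect_identical(unique(rec$readout_ids), "DR07")
  # without primers the template is the bare core
  rec0 <- assembleSingleReadout(ol, readout, NULL, "smfish")
  expect_identical(nchar(rec0$template_sequence[1]), 70L)
  expect_identical(rec0$primary_sequence,
                   reverseComplementStr(rec0$template_sequence))
  expect_error(assembleSingleReadout(rbind(ol, mkOligos(1, "other")),
                                     readout, NULL, "chromatin"),
               "one target label")
})

test_that("MERFISH assembly places one readout upstream and two
           downstream, cycling the triplets", {
  set.seed(503)
  ol <- mkOligos(6, "tx1")
  ol$gene_id <- "gene1"
  readouts <- data.frame(readout_id = sprintf("R%02d", 1:16),
                         sequence = vapply(1:16, function(i)
                           randomSeq(20), character(1)))
  cb <- assignCodewords("gene1", c(gene1 = 4))
  primers <- data.frame(forward = randomSeq(20), reverse = randomSeq(20))
  rec <- assembleMerfish(ol, cb, readouts, primers)
  expect_identical(nrow(rec), 6L)
  expect_identical(nchar(rec$template_sequence),
                   rep(30L + 3L * 20L + 2L * 20L, 6))
  onBits <- which(codewords(cb)[geneAssignment(cb)[["gene1"]], ] == 1L)
  for (i in seq_len(nrow(rec))) {
    ids <- strsplit(rec$readout_ids[i], ";")[[1]]
    expect_length(ids, 3L)
    bits <- match(ids, readouts$readout_id)
    expect_true(all(bits %in% onBits))
    expect_identical(bits, probeReadoutTriplet(onBits, i - 1L))
    # structure: fwd | up readout | targeting | down1 | down2 | rc(rev)
    expect_identical(
      rec$template_sequence[i],
      paste0(primers$forward, readouts$sequence[bits[1]],
             ol$sequence[i], readouts$sequence[bits[2]],
             readouts$sequence[bits[3]],
             reverseComplementStr(primers$reverse)))
  }
  # across 4 consecutive probes, all four on-bit readouts appear
  seen <- unique(unlist(strsplit(rec$readout_ids[1:4], ";")))
  expect_setequal(match(seen, readouts$readout_id), onBits)
  expect_error(assembleMerfish(transform(ol, gene_id = "nope"), cb,
                               readouts, NULL), "no codeword")
})

test_that("probe outputs round-trip and honor the output mode", {
  set.seed(504)
  ol <- mkOligos(4)
  readout <- list(readout_id = "DR01", sequence = randomSeq(20))
  primers <- data.frame(forward = randomSeq(20), reverse = randomSeq(20))
  rec <- assembleSingleReadout(ol, readout, primers, "chromatin")
  outT <- withr::local_tempdir()
  paths <- writeProbeOutputs(rec, outT, "template")
  fasta <- readFastaSeqs(paths[["fasta"]])
  expect_identical(length(fasta), nrow(rec))
  expect_identical(unname(fasta), rec$template_sequence)
  tab <- read.csv(paths[["table"]], stringsAsFactors = FALSE)
  expect_identical(nrow(tab), nrow(rec))
  expect_identical(tab$template_sequence, rec$template_sequence)
  # primary mode: no primer subsequence appears in any output sequence
  recP <- assembleSingleReadout(ol, readout, NULL, "chromatin")
  outP <- withr::local_tempdir()
  pathsP <- writeProbeOutputs(recP, outP, "primary")
  fastaP <- readFastaSeqs(pathsP[["fasta"]])
  expect_false(any(grepl(primers$forward, fastaP, fixed = TRUE)))
  expect_false(any(grepl(primers$reverse, fastaP, fixed = TRUE)))
  expect_identical(unname(fastaP), recP$primary_sequence)
  expect_error(writeProbeOutputs(rec[0, ], outT, "template"), "no probe")
})

test_that("template and primary sequences are mutual reverse complements
           modulo primers", {
  set.seed(505)
  ol <- mkOligos(3)
  readout <- list(readout_id = "DR02", sequence = randomSeq(20))
  primers <- data.frame(forward = randomSeq(20), reverse = randomSeq(20))
  rec <- assembleSingleReadout(ol, readout, primers, "chromatin")
  core <- substr(rec$template_sequence, 21, nchar(rec$template_sequence) - 20)
  expect_identical(reverseComplementStr(core), rec$primary_sequence)
  # the targeting region sits verbatim inside every template
  for (i in 1:3)
    expect_true(grepl(ol$sequence[i], rec$template_sequence[i],
                      fixed = TRUE))
})

test_that("default readout libraries and primers have the documented
           shape", {
  chrom <- defaultReadouts("chromatin")
  rna <- defaultReadouts("rna")
  expect_identical(nrow(chrom), 50L)
  expect_identical(nrow(rna), 16L)
  expect_identical(anyDuplicated(c(chrom$sequence, rna$sequence)), 0L)
  expect_true(all(nchar(chrom$sequence) == 20L))
  prim <- defaultPrimers()
  expect_identical(sort(prim$probe_type),
                   c("chromatin", "merfish", "smfish"))
  # orthogonality of the synthetic sets: no shared 12-mer in any
  # orientation between any two oligos
  all20 <- c(chrom$sequence, rna$sequence, prim$forward, prim$reverse)
  kmers <- lapply(all20, function(s)
    c(substring(s, 1:9, 12:20),
      substring(reverseComplementStr(s), 1:9, 12:20)))
  for (i in seq_along(kmers)[-1]) {
    prior <- unlist(kmers[seq_len(i - 1)])
    expect_false(any(kmers[[i]] %in% prior), info = all20[i])
  }
  gc <- vapply(all20, gcContent, numeric(1))
  expect_true(all(gc >= 40 & gc <= 60))
})

test_that("orthogonal set generation is deterministic and seed-sensitive", {
  s1 <- generateOrthogonalSet(5, seed = 9)
  s2 <- generateOrthogonalSet(5, seed = 9)
  s3 <- generateOrthogonalSet(5, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})
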