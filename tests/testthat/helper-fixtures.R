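# Shared synthetic fixtures, built once per test run.

# Small genome with a planted duplication: chrA 8 kb, chrB 3 kb;
# chrA:2001-2300 copied to chrB:1001-1300.
sharedDupFixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx))
      fx <<- generateFixture(
        seed = 2024, contigLengths = c(chrA = 8000L, chrB = 3000L),
        duplications = data.frame(contig = "chrA", start = 2001L,
                                  end = 2300L, destContig = "chrB",
                                  destStart = 1001L))
    fx
  }
})

# Transcriptome fixture with planted genes on both strands:
# gPlus (+) and gMinus (-) on chrA, plus an intergenic gap.
sharedGeneFixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx))
      fx <<- generateFixture(
        seed = 31, contigLengths = c(chrA = 6000L),
        genes = data.frame(
          gene_id = c("gPlus", "gMinus"),
          transcript_id = c("txPlus", "txMinus"),
          contig = "chrA", start = c(1001L, 3001L), end = c(1800L, 3800L),
          strand = c("+", "-"),
          exons = c("1001-1300;1501-1800", "3001-3300;3501-3800")))
    fx
  }
})

# Hand-built spliced transcriptome with two isoforms of one gene and a
# second gene carrying a verbatim copy of part of the first gene's exon
# (a cross-gene repeat), for the isoform specificity rules.
sharedIsoformDb <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      set.seed(77)
      common <- randomSeq(400)   # exon shared by both isoforms
      uniqueA <- randomSeq(300)  # isoform-a-only exon
      uniqueB <- randomSeq(300)
      offtarget <- randomSeq(500)
      crossSeg <- substr(common, 101, 160)  # 60 nt copied into gene 2
      db <<- list(
        seqs = c(tx_a1 = paste0(common, uniqueA),
                 tx_a2 = paste0(common, uniqueB),
                 tx_b = paste0(offtarget, crossSeg)),
        geneMap = c(tx_a1 = "geneA", tx_a2 = "geneA", tx_b = "geneB"),
        common = common, uniqueA = uniqueA, crossSeg = crossSeg)
    }
    db
  }
})

# Write a target CSV and return its path.
writeTargetCsv <- function(df, dir = tempfile("targets")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "targets.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
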