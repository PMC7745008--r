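# End-to-end pipeline orchestration: load -> scan -> specificity ->
# (codebook) -> subsample -> assemble -> write, with a per-stage run
# report.

.logMsg <- function(...) message("[probe-design] ", ...)

.buildBackendIndex <- function(db, backend, k, geneMap = character(),
                               name = "db") {
  if (backend == "blast")
    buildBlastDatabase(db, geneMap = geneMap, name = name)
  else
    buildSpecificityIndex(db, k = k, geneMap = geneMap, name = name)
}

#' Run an end-to-end probe design
#'
#' Executes the full pipeline described by a [RunConfig-class]: reads the
#' inputs, scans every target with the sliding-window filter stack,
#' applies the specificity rule set of the chosen probe type (genome
#' uniqueness and optional antisense/exon rules for chromatin tracing;
#' the isoform rule for MERFISH and sequential smFISH), assigns MHD4
#' codewords for MERFISH, subsamples probes, assembles template or
#' primary sequences, and writes all outputs plus a run report of
#' per-target counts at each stage. The pipeline is deterministic:
#' rerunning an identical configuration reproduces the outputs
#' byte-identically.
#'
#' @param config a [RunConfig-class] object.
#' @return Invisibly, a list with \code{records} (probe table),
#'   \code{report} (per-target stage counts), \code{codebook} (assigned
#'   codebook or NULL) and \code{paths} (written files).
#' @export
runDesign <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  stage <- "configuration"
  fail <- function(e) stop("stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    params <- if (nzchar(config@params)) readParameterTable(config@params)
              else designParameters()
    targetsTab <- readTargetTable(config@targets)
    kind <- attr(targetsTab, "targetKind")

    stage <- "load"
    rnaMode <- config@probeType %in% c("merfish", "smfish")
    if (rnaMode) {
      if (kind != "transcripts")
        stop("RNA probe types need a transcript_id target table")
      spliced <- readFastaSeqs(config@spliced)
      gmap <- readGeneMap(config@geneMapFile)
      targets <- loadTranscriptTargets(targetsTab, spliced, gmap)
      if (config@probeType == "merfish" && anyNA(targets$expression))
        stop("MERFISH requires expression values for every target")
      nGenes <- length(unique(targets$gene_id))
      capacity <- 140L
      if (config@probeType == "merfish" && nGenes > capacity)
        stop("MERFISH encoding accepts up to ", capacity,
             " input genes; got ", nGenes)
      seqs <- stats::setNames(targets$sequence, targets$label)
    } else {
      if (kind != "coordinates")
        stop("chromatin tracing needs a (contig,start,end) target table")
      genome <- readFastaSeqs(config@genome)
      seqs <- extractRegions(genome, targetsTab)
      targets <- data.frame(label = names(seqs), stringsAsFactors = FALSE)
    }
    readouts <-
      if (nzchar(config@readouts)) readReadoutTable(config@readouts)
      else defaultReadouts(if (rnaMode) "rna" else "chromatin")
    if (!rnaMode || config@probeType == "smfish") {
      if (length(seqs) > nrow(readouts))
        stop(length(seqs), " targets exceed the ", nrow(readouts),
             "-entry readout library; provide additional readout ",
             "sequences")
    }
    primers <- NULL
    if (config@outputMode == "template") {
      primerTab <- if (nzchar(config@primers))
        readPrimerTable(config@primers) else defaultPrimers()
      primers <- primerTab[primerTab$probe_type == config@probeType, ,
                           drop = FALSE]
      if (nrow(primers) != 1L)
        stop("no primer pair for probe type '", config@probeType, "'")
    }

    stage <- "scan"
    .logMsg("scanning ", length(seqs), " target(s)")
    cand <- scanTargets(seqs, params)
    report <- data.frame(target = names(seqs),
                         scanned = as.integer(table(
                           factor(cand$target_label, levels = names(seqs)))),
                         stringsAsFactors = FALSE)

    stage <- "specificity"
    if (rnaMode) {
      gmapFull <- readGeneMap(config@geneMapFile)
      splicedIdx <- .buildBackendIndex(readFastaSeqs(config@spliced),
                                       config@backend, params@seedK,
                                       geneMap = gmapFull, name = "spliced")
      kept <- list()
      for (i in seq_len(nrow(targets))) {
        ci <- cand[cand$target_label == targets$label[i], , drop = FALSE]
        if (!nrow(ci)) { kept[[i]] <- ci; next }
        kept[[i]] <- isoformSpecificityFilter(ci, splicedIdx,
                                              targets$gene_id[i], params)
      }
      cand <- do.call(rbind, kept)
    } else {
      genomeIdx <- .buildBackendIndex(genome, config@backend,
                                      params@seedK, name = "genome")
      cand <- genomeUniquenessFilter(cand, genomeIdx, params)
      if (config@antisenseOnly) {
        unsplIdx <- .buildBackendIndex(readFastaSeqs(config@unspliced),
                                       config@backend, params@seedK,
                                       name = "unspliced")
        cand <- antisenseFilter(cand, unsplIdx, params)
      }
      if (config@avoidExons) {
        splIdx <- .buildBackendIndex(readFastaSeqs(config@spliced),
                                     config@backend, params@seedK,
                                     name = "spliced")
        cand <- exonAvoidanceFilter(cand, splIdx, params)
      }
    }
    report$specific <- as.integer(table(
      factor(cand$target_label, levels = report$target)))

    stage <- "codebook"
    codebook <- NULL
    if (config@probeType == "merfish") {
      expr <- tapply(targets$expression, targets$gene_id, max)
      codebook <- assignCodewords(names(expr),
                                  stats::setNames(as.numeric(expr),
                                                  names(expr)))
    }

    stage <- "select"
    if (!"revcomped" %in% names(cand)) cand$revcomped <- FALSE
    selected <- list()
    for (i in seq_len(nrow(report))) {
      ci <- cand[cand$target_label == report$target[i], , drop = FALSE]
      selected[[i]] <- selectProbes(ci, config@probesPerTarget)
    }
    cand <- do.call(rbind, selected)
    report$selected <- as.integer(table(
      factor(cand$target_label, levels = report$target)))
    zero <- report$target[report$selected == 0L]
    if (length(zero))
      warning("no probes retained for target(s): ",
              paste(zero, collapse = ", "))

    stage <- "assemble"
    if (config@probeType == "merfish") {
      cand$gene_id <- targets$gene_id[match(cand$target_label,
                                            targets$label)]
      records <- assembleMerfish(cand, codebook, readouts, primers)
    } else {
      rows <- list()
      for (i in seq_len(nrow(report))) {
        ci <- cand[cand$target_label == report$target[i], , drop = FALSE]
        if (!nrow(ci)) next
        rows[[length(rows) + 1L]] <- assembleSingleReadout(
          ci, readouts[i, ], primers,
          if (config@probeType == "chromatin") "chromatin" else "smfish")
      }
      records <- do.call(rbind, rows)
    }

    stage <- "write"
    if (is.null(records) || !nrow(records))
      stop("no probes retained for any target")
    paths <- writeProbeOutputs(records, config@outDir, config@outputMode,
                               codebook = codebook)
    report$assembled <- as.integer(table(
      factor(records$target_label, levels = report$target)))
    reportPath <- file.path(config@outDir, "run_report.txt")
    writeLines(c(
      sprintf("probe_type=%s output_mode=%s backend=%s seed=%d",
              config@probeType, config@outputMode, config@backend,
              config@seed),
      sprintf("total_probes=%d", nrow(records)),
      utils::capture.output(print(report, row.names = FALSE))),
      reportPath)
    paths["report"] <- reportPath
    .logMsg("wrote ", nrow(records), " probes to ", config@outDir)
    invisible(list(records = records, report = report,
                   codebook = codebook, paths = paths))
  }, error = fail)
}
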