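# Probe assembly and export: even-spaced subsampling, readout and primer
# appending, template/primary sequence construction, output writers.

#' Subsample probes evenly along a target
#'
#' Keeps \code{n} probes spread evenly over the offset-sorted candidates:
#' indices \code{round(i * (m - 1) / (n - 1))} for \code{i = 0..n-1} over
#' the \code{m} candidates (so \code{n = 2} keeps the first and last;
#' \code{n = 1} keeps the middle probe). Requesting at least as many
#' probes as exist returns all of them with a warning.
#'
#' @param oligos candidate data.frame with an \code{offset} column.
#' @param n number of probes to keep, or \code{NA}/\code{"all"} for all.
#' @return The selected rows, offset-sorted.
#' @export
selectProbes <- function(oligos, n = NA) {
  stopifnot(is.data.frame(oligos), "offset" %in% names(oligos))
  oligos <- oligos[order(oligos$offset), , drop = FALSE]
  rownames(oligos) <- NULL
  if (identical(n, "all") || is.null(n) || is.na(n)) return(oligos)
  n <- as.integer(n)
  if (n <= 0L) stop("n must be >= 1", call. = FALSE)
  m <- nrow(oligos)
  if (m == 0L) return(oligos)
  if (n >= m) {
    if (n > m)
      warning("requested ", n, " probes but only ", m, " available; ",
              "returning all")
    return(oligos)
  }
  idx <- if (n == 1L) round((m - 1) / 2) + 1L
         else unique(round((0:(n - 1L)) * (m - 1) / (n - 1L)) + 1L)
  oligos[idx, , drop = FALSE]
}

# Construct template and primary sequences for one probe.
# template = forward + upstream readouts + targeting + downstream
#            readouts + revcomp(reverse primer); without primers the
#            template is just the readout-flanked core. The primary probe
#            is the reverse complement of the primer-less core.
.buildRecord <- function(targetLabel, oligoRow, upSeqs, downSeqs,
                         readoutIdStr, primers, probeType, geneId = NA) {
  core <- paste0(paste0(upSeqs, collapse = ""), oligoRow$sequence,
                 paste0(downSeqs, collapse = ""))
  hasPrimers <- !is.null(primers)
  template <- if (hasPrimers)
    paste0(primers$forward, core, reverseComplementStr(primers$reverse))
  else core
  data.frame(
    target_label = targetLabel,
    gene_id = geneId,
    offset = oligoRow$offset,
    targeting_sequence = oligoRow$sequence,
    revcomped = isTRUE(oligoRow$revcomped),
    readout_ids = readoutIdStr,
    probe_type = probeType,
    forward_primer = if (hasPrimers) primers$forward else NA_character_,
    reverse_primer = if (hasPrimers) primers$reverse else NA_character_,
    template_sequence = template,
    primary_sequence = reverseComplementStr(core),
    stringsAsFactors = FALSE)
}

#' Assemble probes carrying a single readout (chromatin tracing / smFISH)
#'
#' Every probe of one target carries the same readout sequence once
#' upstream and once downstream of its targeting region, so all probes of
#' a target light up in the same imaging round.
#'
#' @param oligos candidate data.frame for one target (shared
#'   \code{target_label}).
#' @param readout list or one-row data.frame with \code{readout_id} and
#'   \code{sequence}.
#' @param primers optional one-row data.frame with \code{forward} and
#'   \code{reverse} (omit for primary-probe output).
#' @param probeType \code{"chromatin"} or \code{"smfish"}.
#' @return data.frame of probe records (one per oligo) with template and
#'   primary sequences.
#' @export
assembleSingleReadout <- function(oligos, readout, primers = NULL,
                                  probeType = c("chromatin", "smfish")) {
  probeType <- match.arg(probeType)
  stopifnot(is.data.frame(oligos))
  if (!nrow(oligos)) return(NULL)
  if (length(unique(oligos$target_label)) != 1L)
    stop("all oligos must share one target label", call. = FALSE)
  rows <- lapply(seq_len(nrow(oligos)), function(i)
    .buildRecord(oligos$target_label[1L], oligos[i, ],
                 readout$sequence, readout$sequence,
                 as.character(readout$readout_id), primers, probeType))
  do.call(rbind, rows)
}

#' Assemble MERFISH probes with barcode readout triplets
#'
#' Probe \code{i} (0-based, offset order) of a gene carries the readout
#' triplet [probeReadoutTriplet()] draws from the gene's codeword: the
#' triplet's first readout upstream of the targeting region and the
#' remaining two downstream, so each readout appears on three of every
#' four consecutive probes.
#'
#' @param oligosByGene candidate data.frame with \code{gene_id} (and
#'   \code{target_label}, \code{offset}, \code{sequence}) columns.
#' @param codebook an assigned [Codebook-class] covering every gene.
#' @param readouts data.frame of the 16 bit-position readout sequences
#'   (columns \code{readout_id}, \code{sequence}), in bit order.
#' @param primers optional one-row data.frame with \code{forward} and
#'   \code{reverse}.
#' @return data.frame of probe records.
#' @export
assembleMerfish <- function(oligosByGene, codebook, readouts,
                            primers = NULL) {
  stopifnot(is.data.frame(oligosByGene),
            all(c("gene_id", "offset") %in% names(oligosByGene)),
            is(codebook, "Codebook"))
  if (nrow(readouts) < ncol(codebook@bits))
    stop("readout library must cover all ", ncol(codebook@bits), " bits",
         call. = FALSE)
  a <- codebook@assignment
  out <- list()
  for (g in unique(oligosByGene$gene_id)) {
    if (!g %in% names(a))
      stop("gene '", g, "' has no codeword assignment", call. = FALSE)
    og <- oligosByGene[oligosByGene$gene_id == g, , drop = FALSE]
    og <- og[order(og$target_label, og$offset), , drop = FALSE]
    cw <- codebook@bits[a[[g]], ]
    for (i in seq_len(nrow(og))) {
      bits <- probeReadoutTriplet(cw, i - 1L)
      rs <- readouts$sequence[bits]
      ids <- readouts$readout_id[bits]
      out[[length(out) + 1L]] <-
        .buildRecord(og$target_label[i], og[i, ], rs[1L], rs[2:3],
                     paste(ids, collapse = ";"), primers, "merfish",
                     geneId = g)
    }
  }
  do.call(rbind, out)
}

#' Write probe design outputs
#'
#' Emits (a) a FASTA of the designed probes with headers
#' \code{label|offset|probe_type|readout_ids}, (b) a CSV table with one
#' row per probe carrying full provenance (targeting region, readouts,
#' primers, template and primary sequences), and (c) for MERFISH designs
#' a codebook CSV via [writeCodebook()]. \code{mode} selects whether the
#' FASTA body holds template oligos (for pooled synthesis) or primary
#' probe sequences (reverse complements, for direct ordering).
#'
#' @param records probe record data.frame from the assembly functions.
#' @param outDir output directory (created if needed).
#' @param mode \code{"template"} or \code{"primary"}.
#' @param codebook optional assigned [Codebook-class] (MERFISH).
#' @return Named character vector of the written file paths, invisibly.
#' @export
writeProbeOutputs <- function(records, outDir,
                              mode = c("template", "primary"),
                              codebook = NULL) {
  mode <- match.arg(mode)
  if (is.null(records) || !nrow(records))
    stop("no probe records to write", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir))
    stop("cannot create output directory: ", outDir, call. = FALSE)
  body <- if (mode == "template") records$template_sequence
          else records$primary_sequence
  headers <- sprintf("%s|%d|%s|%s", records$target_label, records$offset,
                     records$probe_type, records$readout_ids)
  fasta <- file.path(outDir, sprintf("probes_%s.fasta", mode))
  writeFastaSeqs(stats::setNames(body, headers), fasta)
  csv <- file.path(outDir, "probes.csv")
  utils::write.csv(records, csv, row.names = FALSE)
  paths <- c(fasta = fasta, table = csv)
  if (!is.null(codebook)) {
    cbPath <- file.path(outDir, "codebook.csv")
    writeCodebook(codebook, cbPath)
    paths["codebook"] <- cbPath
  }
  invisible(paths)
}
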