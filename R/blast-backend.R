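# Optional BLAST+ backend for specificity screening, for parity with
# workflows built on makeblastdb/blastn. Requires the BLAST+ binaries on
# the PATH; the built-in k-mer engine needs no external software.

#' BLAST+ specificity database
#'
#' Wraps a formatted nucleotide BLAST database plus the metadata the
#' retention filters need (gene map). Hits are parsed back into the same
#' structure [findHits()] produces, with the same minimum-matched-bases
#' threshold applied, so the retention filters are backend-agnostic.
#'
#' @slot databaseName character label.
#' @slot dbPrefix path prefix of the formatted BLAST database.
#' @slot fastaPath path of the database FASTA.
#' @slot geneMap named character vector (sequence id to gene id) or empty.
#' @export
setClass("BlastDatabase",
  representation(databaseName = "character", dbPrefix = "character",
                 fastaPath = "character", geneMap = "character"))

#' @rdname BlastDatabase-class
#' @param x a \code{BlastDatabase}.
#' @export
setMethod("geneMap", "BlastDatabase", function(x) x@geneMap)

setMethod("show", "BlastDatabase", function(object) {
  cat(sprintf("BlastDatabase '%s' at %s\n", object@databaseName,
              object@dbPrefix))
  invisible(NULL)
})

#' @return \code{hasBlast}: TRUE when makeblastdb and blastn are on the
#'   PATH.
#' @rdname buildBlastDatabase
#' @export
hasBlast <- function() {
  nzchar(Sys.which("makeblastdb")) && nzchar(Sys.which("blastn"))
}

#' Build a BLAST+ database from sequences
#'
#' @param db named character vector of database sequences.
#' @param geneMap optional named character vector (sequence id to gene
#'   id).
#' @param name database label.
#' @param dir directory for the formatted database (default a tempdir).
#' @return A [BlastDatabase-class] object.
#' @export
buildBlastDatabase <- function(db, geneMap = character(), name = "db",
                               dir = tempfile("blastdb")) {
  if (!hasBlast())
    stop("BLAST+ (makeblastdb/blastn) not found on PATH; ",
         "use the builtin backend", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(name, ".fa"))
  writeFastaSeqs(db, fa)
  prefix <- file.path(dir, name)
  status <- system2("makeblastdb",
                    c("-in", shQuote(fa), "-dbtype", "nucl",
                      "-out", shQuote(prefix)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed", call. = FALSE)
  new("BlastDatabase", databaseName = name, dbPrefix = prefix,
      fastaPath = fa,
      geneMap = if (length(geneMap)) geneMap[names(db)] else character())
}

#' Query oligos against a BLAST+ database
#'
#' Runs \code{blastn -task blastn-short} (e-value 10, dust off) on a batch
#' of oligos and parses the tabular output into the hit structure of
#' [findHits()]: plus-strand 0-based coordinates, orientation
#' \code{plus/plus} or \code{plus/minus}, matched base count
#' (alignment length minus mismatches and gaps). HSPs below
#' \code{minMatched} matched bases are dropped and overlapping hits at one
#' locus are merged to the best, mirroring the built-in engine.
#'
#' @param oligos character vector of query oligos.
#' @param db a [BlastDatabase-class].
#' @param minMatched minimum matched bases (default 18).
#' @return A list of hit data.frames, one per query oligo.
#' @export
blastHits <- function(oligos, db, minMatched = 18L) {
  stopifnot(is(db, "BlastDatabase"))
  qfa <- tempfile(fileext = ".fa")
  on.exit(unlink(qfa))
  qnames <- sprintf("q%06d", seq_along(oligos))
  writeFastaSeqs(stats::setNames(toupper(oligos), qnames), qfa)
  out <- system2("blastn",
                 c("-task", "blastn-short", "-evalue", "10", "-dust", "no",
                   "-query", shQuote(qfa), "-db", shQuote(db@dbPrefix),
                   "-outfmt",
                   shQuote("6 qseqid sseqid length mismatch gapopen qstart qend sstart send")),
                 stdout = TRUE, stderr = FALSE)
  empty <- data.frame(sequence_id = character(), orientation = character(),
                      start = integer(), end = integer(), matched = integer(),
                      stringsAsFactors = FALSE)
  res <- rep(list(empty), length(oligos))
  names(res) <- qnames
  if (length(out)) {
    tab <- utils::read.delim(text = out, header = FALSE,
                             stringsAsFactors = FALSE)
    names(tab) <- c("qseqid", "sseqid", "length", "mismatch", "gapopen",
                    "qstart", "qend", "sstart", "send")
    tab$matched <- tab$length - tab$mismatch - tab$gapopen
    tab <- tab[tab$matched >= minMatched, , drop = FALSE]
    if (nrow(tab)) {
      minus <- tab$sstart > tab$send
      hits <- data.frame(
        qseqid = tab$qseqid,
        sequence_id = tab$sseqid,
        orientation = ifelse(minus, "plus/minus", "plus/plus"),
        start = ifelse(minus, tab$send, tab$sstart) - 1L,
        end = ifelse(minus, tab$sstart, tab$send) - 1L,
        matched = as.integer(tab$matched),
        stringsAsFactors = FALSE)
      for (qn in unique(hits$qseqid))
        res[[qn]] <- .mergeHits(hits[hits$qseqid == qn,
                                     names(hits) != "qseqid", drop = FALSE])
    }
  }
  unname(res)
}
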