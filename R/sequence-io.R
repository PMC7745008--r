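# Reading genomes, transcriptomes and target specifications; coordinate
# extraction and strand utilities.

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases
#' sequences, trims headers to the first whitespace, preserves record
#' order, and enforces the package's sequence invariants: names unique,
#' sequences non-empty, alphabet restricted to A/C/G/T/N.
#'
#' @param path path to a FASTA file.
#' @param allowN logical; when \code{FALSE}, reject sequences containing N
#'   (ambiguity codes other than N are always rejected).
#' @return Named character vector of uppercase sequences, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", ">b desc", "GGCC"), fa)
#' readFastaSeqs(fa)
#' @export
readFastaSeqs <- function(path, allowN = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0L))
    stop("FASTA record(s) with empty sequence: ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  pat <- if (allowN) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named", call. = FALSE)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick reverse complement over the alphabet A/C/G/T/N (N maps to
#' N). Vectorised over its input.
#'
#' @param seq character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplementStr("AAGN")  # "NCTT"
#' @export
reverseComplementStr <- function(seq) {
  if (!is.character(seq)) stop("seq must be character", call. = FALSE)
  s <- toupper(seq)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    stop("non-nucleotide character in sequence(s): ",
         paste(utils::head(seq[bad], 3L), collapse = ", "), call. = FALSE)
  vapply(s, function(x)
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x)))),
    character(1), USE.NAMES = FALSE)
}

#' Extract plus-strand genomic regions
#'
#' Pulls target segments out of a genome assembly from 1-based inclusive
#' coordinates (UCSC spreadsheet style). The returned sequence has length
#' \code{end - start + 1} and lies on the plus strand.
#'
#' @param assembly named character vector of contig sequences (e.g. from
#'   [readFastaSeqs()]).
#' @param regions data.frame with columns \code{contig}, \code{start},
#'   \code{end} and optionally \code{label} (defaults to
#'   \code{contig:start-end}).
#' @return Named character vector of region sequences (names = labels).
#' @examples
#' extractRegions(c(chr1 = "AACCGGTT"),
#'                data.frame(contig = "chr1", start = 1, end = 4))
#' @export
extractRegions <- function(assembly, regions) {
  stopifnot(is.data.frame(regions),
            all(c("contig", "start", "end") %in% names(regions)))
  labels <- if ("label" %in% names(regions) && !all(is.na(regions$label)))
    as.character(regions$label)
  else sprintf("%s:%d-%d", regions$contig, as.integer(regions$start),
               as.integer(regions$end))
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ctg <- as.character(regions$contig[i])
    s <- as.integer(regions$start[i]); e <- as.integer(regions$end[i])
    if (!ctg %in% names(assembly))
      stop("region ", i, " (", labels[i], "): unknown contig '", ctg, "'",
           call. = FALSE)
    n <- nchar(assembly[[ctg]])
    if (is.na(s) || is.na(e) || s < 1L || e < s || e > n)
      stop("region ", i, " (", labels[i], "): coordinates (", s, ",", e,
           ") out of bounds for contig '", ctg, "' of length ", n,
           call. = FALSE)
    out[i] <- substr(assembly[[ctg]], s, e)
  }
  names(out) <- labels
  out
}

#' Strip transcript version suffixes
#'
#' Removes a trailing \code{.N} version tail from Ensembl-style transcript
#' ids (\code{ENST0001.5} becomes \code{ENST0001}).
#'
#' @param ids character vector of transcript ids.
#' @return Character vector without version suffixes.
#' @export
stripVersion <- function(ids) sub("\\.\\d+$", "", as.character(ids))

#' Resolve transcript targets against a transcriptome
#'
#' Matches requested transcript ids (version suffixes stripped on both
#' sides) to their spliced sequences and owning genes.
#'
#' @param targets data.frame with column \code{transcript_id} and optional
#'   columns \code{expression} (non-negative; required for MERFISH designs)
#'   and \code{label}.
#' @param transcriptome named character vector of spliced transcript
#'   sequences (names = transcript ids).
#' @param geneMap named character vector mapping transcript id to gene id.
#' @return data.frame with columns \code{label}, \code{transcript_id},
#'   \code{gene_id}, \code{expression} (NA when absent) and
#'   \code{sequence}.
#' @export
loadTranscriptTargets <- function(targets, transcriptome, geneMap) {
  stopifnot(is.data.frame(targets), "transcript_id" %in% names(targets))
  txNames <- stripVersion(names(transcriptome))
  mapNames <- stripVersion(names(geneMap))
  ids <- stripVersion(targets$transcript_id)
  if (length(ids) == 0L)
    return(data.frame(label = character(), transcript_id = character(),
                      gene_id = character(), expression = numeric(),
                      sequence = character(), stringsAsFactors = FALSE))
  hit <- match(ids, txNames)
  if (anyNA(hit))
    stop("transcript id(s) not found in transcriptome: ",
         paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
  gidx <- match(ids, mapNames)
  if (anyNA(gidx))
    stop("transcript id(s) missing from gene map: ",
         paste(ids[is.na(gidx)], collapse = ", "), call. = FALSE)
  expr <- if ("expression" %in% names(targets))
    as.numeric(targets$expression) else rep(NA_real_, length(ids))
  if (any(!is.na(expr) & (expr < 0 | !is.finite(expr))))
    stop("expression values must be finite and >= 0", call. = FALSE)
  lab <- if ("label" %in% names(targets) && !all(is.na(targets$label)))
    as.character(targets$label) else ids
  data.frame(label = lab, transcript_id = ids,
             gene_id = unname(geneMap[gidx]), expression = expr,
             sequence = unname(transcriptome[hit]),
             stringsAsFactors = FALSE)
}

# Read a delimited or Excel table by extension (.csv, .tsv/.txt, .xlsx).
.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext %in% c("tsv", "txt", "bed")) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package; ",
           "use CSV/TSV instead", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else stop("unsupported table format: .", ext, call. = FALSE)
}

#' Read a target specification table
#'
#' Accepts CSV/TSV (or XLSX via readxl) with either chromatin-tracing
#' columns (\code{contig}, \code{start}, \code{end}, optional
#' \code{label}) or RNA FISH columns (\code{transcript_id}, optional
#' \code{expression} and \code{label}).
#'
#' @param path table file path.
#' @return The table as a data.frame with a \code{"targetKind"} attribute
#'   of \code{"coordinates"} or \code{"transcripts"}.
#' @export
readTargetTable <- function(path) {
  tab <- .readTable(path)
  names(tab) <- tolower(names(tab))
  if (all(c("contig", "start", "end") %in% names(tab))) {
    attr(tab, "targetKind") <- "coordinates"
  } else if ("transcript_id" %in% names(tab)) {
    attr(tab, "targetKind") <- "transcripts"
  } else {
    stop("target table must have columns (contig,start,end[,label]) or ",
         "(transcript_id[,expression,label])", call. = FALSE)
  }
  tab
}

#' Read a transcript-to-gene map
#'
#' Two-column table (\code{transcript_id}, \code{gene_id}); version
#' suffixes are stripped. Every transcript must map to exactly one gene.
#'
#' @param path CSV/TSV file path.
#' @return Named character vector: transcript id -> gene id.
#' @export
readGeneMap <- function(path) {
  tab <- .readTable(path)
  names(tab) <- tolower(names(tab))
  if (!all(c("transcript_id", "gene_id") %in% names(tab)))
    stop("gene map needs columns transcript_id and gene_id", call. = FALSE)
  tx <- stripVersion(tab$transcript_id)
  if (anyDuplicated(tx)) {
    dup <- unique(tx[duplicated(tx)])
    stop("transcript id(s) mapped to more than one gene: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(tab$gene_id), tx)
}
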