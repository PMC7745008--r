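# Readout (secondary) sequence libraries and primer pairs. The shipped
# default sets are synthetic: deterministic, mutually orthogonal
# placeholder sequences with the documented counts (50 chromatin readouts,
# 16 RNA readouts, 3 primer pairs). Experimentalists should substitute
# their validated readout and primer sets via the editable CSV tables.

#' Generate an orthogonal oligo set
#'
#' Deterministic rejection sampler for synthetic readout/primer sequences:
#' candidate oligos are drawn base-wise and accepted when their GC content
#' lies in [40, 60] percent, no homopolymer run exceeds 4 nt, and they
#' share no 12-mer (in either orientation) with any previously accepted
#' sequence in the batch. The caller's RNG stream is left untouched.
#'
#' @param n number of sequences.
#' @param length sequence length in nt (default 20).
#' @param seed integer seed making the set reproducible.
#' @param exclude character vector of sequences whose 12-mers must also be
#'   avoided (to make several sets mutually orthogonal).
#' @return Character vector of \code{n} sequences.
#' @export
generateOrthogonalSet <- function(n, length = 20L, seed = 1L,
                                  exclude = character()) {
  stopifnot(length >= 12L)
  kmerPool <- function(seqs) {
    unlist(lapply(c(seqs, reverseComplementStr(seqs)), function(s) {
      st <- 1:(nchar(s) - 12L + 1L)
      substring(s, st, st + 11L)
    }), use.names = FALSE)
  }
  pool <- if (length(exclude)) kmerPool(exclude) else character()
  .withLocalSeed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 100000L)
        stop("could not build an orthogonal set of size ", n, call. = FALSE)
      s <- paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
      gc <- gcContent(s)
      if (gc < 40 || gc > 60 || .maxRunLength(s) > 4L) next
      st <- 1:(length - 12L + 1L)
      kms <- substring(s, st, st + 11L)
      if (any(c(kms, reverseComplementStr(kms)) %in% pool)) next
      out <- c(out, s)
      pool <- c(pool, kmerPool(s))
    }
    out
  })
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ProbeTiler")
  if (!nzchar(path)) stop("missing package data file: ", file, call. = FALSE)
  path
}

#' Default readout (secondary) sequence library
#'
#' The chromatin tracing library holds 50 readout sequences and the RNA
#' library (MERFISH / sequential smFISH) holds 16, matching the default
#' library sizes of sequential FISH workflows. The shipped sequences are
#' synthetic placeholders (see \code{inst/extdata/readouts_*.csv});
#' replace them with validated readout sets for real experiments via the
#' \code{path} argument of [runDesign()] or [readReadoutTable()].
#'
#' @param type \code{"chromatin"} or \code{"rna"}.
#' @return data.frame with columns \code{readout_id}, \code{sequence}.
#' @export
defaultReadouts <- function(type = c("chromatin", "rna")) {
  type <- match.arg(type)
  readReadoutTable(.extdata(sprintf("readouts_%s_synthetic.csv", type)))
}

#' Default primer pairs
#'
#' One distinct primer pair per probe type (chromatin tracing, MERFISH,
#' sequential smFISH) so separately designed template libraries can be
#' pooled in one oligo order and amplified selectively. Shipped sequences
#' are synthetic placeholders.
#'
#' @return data.frame with columns \code{probe_type}, \code{forward},
#'   \code{reverse} (both 5'->3').
#' @export
defaultPrimers <- function() {
  readPrimerTable(.extdata("primers_synthetic.csv"))
}

#' Read a readout sequence table
#'
#' @param path CSV/TSV (or XLSX) with columns \code{readout_id},
#'   \code{sequence}.
#' @return data.frame of validated, unique readout sequences.
#' @export
readReadoutTable <- function(path) {
  tab <- .readTable(path)
  names(tab) <- tolower(names(tab))
  if (!all(c("readout_id", "sequence") %in% names(tab)))
    stop("readout table needs columns readout_id and sequence",
         call. = FALSE)
  tab$sequence <- vapply(tab$sequence, .normalizeSeq, character(1),
                         allowN = FALSE)
  if (anyDuplicated(tab$sequence))
    stop("readout sequences must be unique", call. = FALSE)
  if (anyDuplicated(tab$readout_id))
    stop("readout ids must be unique", call. = FALSE)
  tab[, c("readout_id", "sequence")]
}

#' Read a primer pair table
#'
#' @param path CSV/TSV (or XLSX) with columns \code{probe_type},
#'   \code{forward}, \code{reverse}.
#' @return data.frame of validated primer pairs.
#' @export
readPrimerTable <- function(path) {
  tab <- .readTable(path)
  names(tab) <- tolower(names(tab))
  if (!all(c("probe_type", "forward", "reverse") %in% names(tab)))
    stop("primer table needs columns probe_type, forward, reverse",
         call. = FALSE)
  tab$forward <- vapply(tab$forward, .normalizeSeq, character(1),
                        allowN = FALSE)
  tab$reverse <- vapply(tab$reverse, .normalizeSeq, character(1),
                        allowN = FALSE)
  if (anyDuplicated(tab$probe_type))
    stop("one primer pair per probe type", call. = FALSE)
  tab[, c("probe_type", "forward", "reverse")]
}
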