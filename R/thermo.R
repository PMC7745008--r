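# Physical-property computations and filters for candidate oligos:
# nearest-neighbor duplex Tm, GC content, homopolymer runs, hairpin stems,
# and cross-hybridization against the accepted probe pool.

# Unified nearest-neighbor parameters (SantaLucia 1998 / Allawi &
# SantaLucia 1997): dH in kcal/mol, dS in cal/(mol K), keyed by the
# 5'->3' top-strand dinucleotide. A dimer and its reverse complement
# describe the same stack.
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation per terminal base pair
.NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_CONSTANT <- 1.987  # cal/(mol K)

.isSelfComplementary <- function(seq) {
  nchar(seq) %% 2L == 0L && identical(seq, reverseComplementStr(seq))
}

#' GC content of a sequence
#'
#' @param seq nucleotide string over A/C/G/T.
#' @return Percent GC: \code{100 * (G + C) / length}.
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(seq) {
  s <- .normalizeSeq(seq, allowN = FALSE)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  v <- .seqInts(s)
  100 * sum(v == 2L | v == 3L) / length(v)
}

#' Longest homopolymer run
#'
#' Length of the longest run of one identical base. Under the default
#' parameters a run longer than 5 nt (e.g. \code{GGGGGG}) disqualifies an
#' oligo.
#'
#' @param seq nucleotide string.
#' @return Integer run length.
#' @examples
#' longestHomopolymer("AAATTTT")  # 4
#' @export
longestHomopolymer <- function(seq) {
  s <- .normalizeSeq(seq, allowN = TRUE)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  .maxRunLength(s)
}

#' Nearest-neighbor melting temperature of a perfect duplex
#'
#' Tm of \code{seq} paired with its perfect complement, from the unified
#' nearest-neighbor model:
#' \deqn{T_m = \Delta H / (\Delta S + R \ln(C_T/x)) - 273.15}
#' with \eqn{\Delta H} and \eqn{\Delta S} summed over dinucleotide stacks
#' plus the two terminal initiation terms, \eqn{R = 1.987}
#' cal/(mol K), \eqn{C_T} the total strand concentration, and \eqn{x = 4}
#' for non-self-complementary duplexes (\eqn{x = 1}, with the symmetry
#' entropy correction, for self-complementary ones). At the default 1 M
#' Na+ reference state no salt correction applies.
#'
#' @param seq nucleotide string over A/C/G/T, length >= 2.
#' @param params a [DesignParameters-class] object (supplies \code{probeConc}).
#' @return Tm in degrees Celsius.
#' @examples
#' duplexTm("GCGCGCGCGCGCGCGCGCGC") > duplexTm("ATATATATATATATATATAT")
#' @export
duplexTm <- function(seq, params = designParameters()) {
  s <- .normalizeSeq(seq, allowN = FALSE)
  n <- nchar(s)
  if (n < 2L) stop("duplex Tm requires length >= 2", call. = FALSE)
  dimers <- substring(s, 1:(n - 1L), 2:n)
  dH <- sum(.NN_DH[dimers]) +
    .NN_INIT_DH[[substr(s, 1L, 1L)]] + .NN_INIT_DH[[substr(s, n, n)]]
  dS <- sum(.NN_DS[dimers]) +
    .NN_INIT_DS[[substr(s, 1L, 1L)]] + .NN_INIT_DS[[substr(s, n, n)]]
  x <- 4
  if (.isSelfComplementary(s)) {
    dS <- dS - 1.4
    x <- 1
  }
  dH * 1000 / (dS + .GAS_CONSTANT * log(params@probeConc / x)) - 273.15
}

# All perfect stems of a sequence: substring pairs (i, j), each of length
# m >= minStem, with the downstream substring equal to the reverse
# complement of the upstream one and >= minLoop unpaired nt between them.
# Returns a character vector of stem sequences (upstream arm, 5'->3').
.enumerateStems <- function(seq, minStem = 4L, minLoop = 3L) {
  n <- nchar(seq)
  maxStem <- (n - minLoop) %/% 2L
  if (maxStem < minStem) return(character())
  rcseq <- reverseComplementStr(seq)
  stems <- character()
  for (m in minStem:maxStem) {
    starts <- 1:(n - m + 1L)
    subs <- substring(seq, starts, starts + m - 1L)
    # rc of substring(seq, i, i+m-1) == substring(rc(seq), n-i-m+2, n-i+1)
    rcs <- substring(rcseq, n - starts - m + 2L, n - starts + 1L)
    pos <- split(starts, subs)
    for (idx in seq_along(starts)) {
      i <- starts[idx]
      js <- pos[[rcs[idx]]]
      if (!is.null(js) && any(js >= i + m + minLoop))
        stems <- c(stems, subs[idx])
    }
  }
  unique(stems)
}

#' Maximum hairpin stem melting temperature
#'
#' Enumerates every perfect stem a sequence can fold into (two substrings
#' that are exact reverse complements, stem length >= 4 nt, separated by a
#' loop of >= 3 nt) and returns the highest duplex Tm over the stem
#' sequences. A sequence with no such stem returns \code{-Inf} and always
#' passes the secondary-structure filter. This is a deterministic
#' perfect-stem approximation of a free-energy folding routine; the
#' threshold semantics (Tm of the concatenated stem) are unchanged.
#'
#' @param seq nucleotide string.
#' @param params a [DesignParameters-class] object.
#' @return Maximum stem Tm in degrees C, or \code{-Inf}.
#' @export
hairpinStemTm <- function(seq, params = designParameters()) {
  s <- .normalizeSeq(seq, allowN = FALSE)
  stems <- .enumerateStems(s)
  if (!length(stems)) return(-Inf)
  max(vapply(stems, duplexTm, numeric(1), params = params))
}

# Concatenated exactly-matching columns of the best local alignments of
# `candidate` against each sequence in `pool` (and, optionally, a single
# one). Returns a character vector, one matched-region string per pool
# entry ("" when nothing aligns).
.substMatrixCache <- new.env(parent = emptyenv())

.substMatrix <- function(params) {
  key <- paste(params@alnMatch, params@alnMismatch)
  m <- .substMatrixCache[[key]]
  if (is.null(m)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(
      match = params@alnMatch, mismatch = params@alnMismatch,
      baseOnly = TRUE)
    .substMatrixCache[[key]] <- m
  }
  m
}

.matchedRegions <- function(candidate, pool, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(pool),
    subject = Biostrings::DNAString(candidate),
    type = "local", substitutionMatrix = .substMatrix(params),
    gapOpening = params@alnGapOpen, gapExtension = params@alnGapExtend)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")
  s <- strsplit(as.character(Biostrings::subject(aln)), "")
  vapply(seq_along(p), function(i) {
    keep <- p[[i]] == s[[i]] & p[[i]] != "-"
    paste0(p[[i]][keep], collapse = "")
  }, character(1))
}

.kmerSet <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# Incremental cross-hybridization pool: caches each accepted oligo, its
# reverse complement, and the k-mer sets of both so the per-window
# prescreen does no recomputation. Used by the scanner; the exported
# crossHybridizationTm() also accepts one in place of a character vector.
.newCrossPool <- function(prescreenK = 8L) {
  e <- new.env(parent = emptyenv())
  e$seqs <- character()
  e$rcs <- character()
  e$ksetF <- list()
  e$ksetR <- list()
  e$k <- as.integer(prescreenK)
  class(e) <- "CrossHybPool"
  e
}

.addToPool <- function(pool, seq) {
  rc <- reverseComplementStr(seq)
  i <- length(pool$seqs) + 1L
  pool$seqs[i] <- seq
  pool$rcs[i] <- rc
  pool$ksetF[[i]] <- .kmerSet(seq, pool$k)
  pool$ksetR[[i]] <- .kmerSet(rc, pool$k)
  invisible(pool)
}

#' Cross-hybridization melting temperature against a probe pool
#'
#' For each accepted oligo, finds the best local alignment of the
#' candidate against the oligo and against its reverse complement (match
#' +5, mismatch -4, gap opening 8, gap extension 6, as positive costs),
#' concatenates the exactly-matching aligned columns into one sequence,
#' and returns the maximum duplex Tm of that matched region over the whole
#' pool. An empty pool (or matched regions shorter than 2 nt) returns
#' \code{-Inf}, so the first candidate always passes.
#'
#' For speed, pool entries sharing no exact \code{prescreenK}-mer with the
#' candidate in the tested orientation are skipped: their matched regions
#' consist only of sub-\code{prescreenK} exact runs, whose duplex Tm lies
#' far below any practical rejection threshold. Set
#' \code{prescreenK = NA} to force the full alignment against every pool
#' entry.
#'
#' @param candidate nucleotide string.
#' @param accepted character vector of previously accepted oligos.
#' @param params a [DesignParameters-class] object.
#' @param prescreenK integer seed length of the shared-k-mer prescreen
#'   (default 8), or \code{NA} to disable.
#' @return Maximum matched-region Tm in degrees C, or \code{-Inf}.
#' @export
crossHybridizationTm <- function(candidate, accepted,
                                 params = designParameters(),
                                 prescreenK = 8L) {
  cand <- .normalizeSeq(candidate, allowN = FALSE)
  if (inherits(accepted, "CrossHybPool")) {
    if (!length(accepted$seqs)) return(-Inf)
    ck <- .kmerSet(cand, accepted$k)
    keepF <- vapply(accepted$ksetF, function(ks) any(ks %in% ck), logical(1))
    keepR <- vapply(accepted$ksetR, function(ks) any(ks %in% ck), logical(1))
    pool <- c(accepted$seqs[keepF], accepted$rcs[keepR])
  } else if (!length(accepted)) {
    return(-Inf)
  } else if (!is.na(prescreenK)) {
    accepted <- as.character(accepted)
    ck <- .kmerSet(cand, prescreenK)
    keepF <- vapply(accepted, function(a)
      any(.kmerSet(a, prescreenK) %in% ck), logical(1), USE.NAMES = FALSE)
    rcs <- reverseComplementStr(accepted)
    keepR <- vapply(rcs, function(a)
      any(.kmerSet(a, prescreenK) %in% ck), logical(1), USE.NAMES = FALSE)
    pool <- c(accepted[keepF], rcs[keepR])
  } else {
    pool <- c(as.character(accepted), reverseComplementStr(accepted))
  }
  if (!length(pool)) return(-Inf)
  regions <- .matchedRegions(cand, pool, params)
  regions <- regions[nchar(regions) >= 2L]
  if (!length(regions)) return(-Inf)
  max(vapply(unique(regions), duplexTm, numeric(1), params = params))
}

#' Apply all physical filters to a candidate window
#'
#' Applies, in order: alphabet (no N), GC bounds (inclusive), homopolymer
#' run (reject runs longer than \code{maxRun}), minimum Tm (a window with
#' Tm exactly at \code{tmMin} passes), hairpin stem Tm (reject above
#' \code{stemTmMax}), and cross-hybridization Tm against the accepted pool
#' (reject above \code{crossHybTmMax}). Evaluation short-circuits at the
#' first failing rule.
#'
#' @param seq candidate window sequence.
#' @param params a [DesignParameters-class] object.
#' @param accepted character vector of already accepted oligos
#'   (cross-hybridization pool).
#' @return A list of class \code{"FilterVerdict"} with elements
#'   \code{passed} (logical), \code{failedRule} (one of \code{"alphabet"},
#'   \code{"gc"}, \code{"repeat"}, \code{"tm"}, \code{"hairpin"},
#'   \code{"crosshyb"}, or \code{NA} when passed) and \code{measured}
#'   (named numeric of the quantities computed before the verdict).
#' @export
passesPhysicalFilters <- function(seq, params = designParameters(),
                                  accepted = character()) {
  measured <- c()
  verdict <- function(rule) {
    structure(list(passed = is.na(rule), failedRule = rule,
                   measured = measured), class = "FilterVerdict")
  }
  s <- toupper(seq)
  if (grepl("[^ACGT]", s)) return(verdict("alphabet"))
  gc <- gcContent(s)
  measured["gc"] <- gc
  if (gc < params@gcMin || gc > params@gcMax) return(verdict("gc"))
  run <- longestHomopolymer(s)
  measured["run"] <- run
  if (run > params@maxRun) return(verdict("repeat"))
  tm <- duplexTm(s, params)
  measured["tm"] <- tm
  if (tm < params@tmMin) return(verdict("tm"))
  stemTm <- hairpinStemTm(s, params)
  measured["stem_tm"] <- stemTm
  if (stemTm > params@stemTmMax) return(verdict("hairpin"))
  xTm <- crossHybridizationTm(s, accepted, params)
  measured["crosshyb_tm"] <- xTm
  if (xTm > params@crossHybTmMax) return(verdict("crosshyb"))
  verdict(NA_character_)
}

#' @export
print.FilterVerdict <- function(x, ...) {
  cat(if (x$passed) "FilterVerdict: passed\n"
      else sprintf("FilterVerdict: failed rule '%s'\n", x$failedRule))
  if (length(x$measured))
    cat("  measured:", paste(sprintf("%s=%.3g", names(x$measured),
                                     x$measured), collapse = ", "), "\n")
  invisible(x)
}

#' Read a design parameter sheet
#'
#' Parameter tables mirror the editable oligo-parameter spreadsheet: one
#' row per parameter with \code{name} and \code{value} columns (CSV/TSV,
#' or XLSX via readxl). Unknown names are rejected; unlisted parameters
#' keep their defaults.
#'
#' @param path table file path.
#' @return A validated [DesignParameters-class] object.
#' @export
readParameterTable <- function(path) {
  tab <- .readTable(path)
  names(tab) <- tolower(names(tab))
  if (!all(c("name", "value") %in% names(tab)))
    stop("parameter table needs columns name and value", call. = FALSE)
  known <- slotNames("DesignParameters")
  nm <- as.character(tab$name)
  bad <- setdiff(nm, known)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  vals <- lapply(seq_along(nm), function(i) {
    v <- tab$value[i]
    if (nm[i] == "nnTable") as.character(v) else as.numeric(v)
  })
  do.call(designParameters, stats::setNames(vals, nm))
}
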