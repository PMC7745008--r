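# Strand-aware specificity screening: k-mer seed-and-extend search over
# genome/transcriptome databases and the derived retention filters.

#' Build a k-mer specificity index
#'
#' Records every k-mer occurrence of every database sequence for
#' seed-and-extend querying with [findHits()]. Replaces an external BLAST
#' database build for desk-scale screening of short probes.
#'
#' @param db named character vector of database sequences (e.g. a genome
#'   from [readFastaSeqs()], or a spliced/unspliced transcriptome).
#' @param k seed length in nt (>= 8; default 12).
#' @param geneMap optional named character vector mapping sequence id to
#'   gene id (transcriptome indexes).
#' @param name database label used in messages.
#' @return A [SpecificityIndex-class] object.
#' @export
buildSpecificityIndex <- function(db, k = 12L, geneMap = character(),
                                  name = "db") {
  k <- as.integer(k)
  if (k < 8L) stop("seed length k must be >= 8", call. = FALSE)
  if (length(db) && is.null(names(db)))
    stop("database sequences must be named", call. = FALSE)
  db <- vapply(db, .normalizeSeq, character(1), allowN = TRUE)
  seeds <- new.env(hash = TRUE, parent = emptyenv())
  seqInts <- vector("list", length(db))
  for (i in seq_along(db)) {
    s <- db[[i]]
    n <- nchar(s)
    seqInts[[i]] <- .seqInts(s)
    if (n < k) {
      warning("sequence '", names(db)[i], "' shorter than k; no seeds indexed")
      next
    }
    starts <- 1:(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    occ <- split(starts[keep], kmers[keep])
    for (km in names(occ)) {
      prev <- seeds[[km]]
      add <- cbind(i, occ[[km]])
      seeds[[km]] <- if (is.null(prev)) add else rbind(prev, add)
    }
  }
  if (length(geneMap)) {
    miss <- setdiff(names(db), names(geneMap))
    if (length(miss))
      stop("gene map missing sequence id(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  new("SpecificityIndex", databaseName = name, k = k, seeds = seeds,
      sequences = db, seqInts = seqInts,
      geneMap = if (length(geneMap)) geneMap[names(db)] else character())
}

# Best window with at most `maxMM` mismatches in a 0/1 match vector:
# returns c(nMatches, startIdx, endIdx) maximizing matches.
.bestMismatchWindow <- function(m, maxMM) {
  n <- length(m)
  best <- c(0L, 1L, 0L)
  lo <- 1L
  mm <- 0L
  ones <- 0L
  for (hi in seq_len(n)) {
    if (m[hi]) ones <- ones + 1L else mm <- mm + 1L
    while (mm > maxMM) {
      if (m[lo]) ones <- ones - 1L else mm <- mm - 1L
      lo <- lo + 1L
    }
    if (ones > best[1L]) best <- c(ones, lo, hi)
  }
  best
}

# Evaluate one diagonal: query ints `qv` against subject ints `sv` with
# subject position = d + query position. A diagonal is a hit when it
# carries an exact run >= k (seedable) and its best window with <= maxMM
# mismatches matches >= minMatched bases. Returns NULL or
# list(start, end, matched) with 1-based subject coordinates of the
# winning window.
.evalDiagonal <- function(qv, sv, d, k, minMatched, maxMM) {
  Lq <- length(qv)
  N <- length(sv)
  i1 <- max(1L, 1L - d)
  i2 <- min(Lq, N - d)
  if (i2 - i1 + 1L < k) return(NULL)
  idx <- i1:i2
  m <- qv[idx] == sv[d + idx] & qv[idx] != 0L & sv[d + idx] != 0L
  if (sum(m) < minMatched) return(NULL)
  r <- rle(m)
  if (max(r$lengths[r$values]) < k) return(NULL)
  w <- .bestMismatchWindow(m, maxMM)
  if (w[1L] < minMatched) return(NULL)
  list(start = d + idx[w[2L]], end = d + idx[w[3L]], matched = w[1L])
}

# Merge hits per sequence: overlapping subject intervals are one
# alignment; the best-matched hit represents the locus (ties prefer
# plus/plus, then the leftmost start).
.mergeHits <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (sid in unique(hits$sequence_id)) {
    h <- hits[hits$sequence_id == sid, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- integer(nrow(h))
    g <- 1L
    hiEnd <- h$end[1L]
    grp[1L] <- g
    for (i in seq_len(nrow(h))[-1L]) {
      if (h$start[i] <= hiEnd) {
        grp[i] <- g
        hiEnd <- max(hiEnd, h$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        hiEnd <- h$end[i]
      }
    }
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      ord <- order(-hg$matched, hg$orientation != "plus/plus", hg$start)
      out[[length(out) + 1L]] <- hg[ord[1L], , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find specificity hits for an oligo
#'
#' Strand-aware ungapped seed-and-extend search: k-mer seeds of the oligo
#' and of its reverse complement are looked up in the index, each
#' candidate diagonal is extended in both directions tolerating up to
#' \code{maxMismatch} internal mismatches, and alignments matching at
#' least \code{minMatched} bases are reported. Orientation is
#' \code{plus/plus} when the forward oligo aligns to the database plus
#' strand and \code{plus/minus} when its reverse complement does; both are
#' reported in database plus-strand coordinates. Overlapping alignments at
#' one locus are merged to the best.
#'
#' @param oligo nucleotide string (length >= the index seed length).
#' @param index a [SpecificityIndex-class].
#' @param minMatched minimum matched bases for a hit (default 18).
#' @param maxMismatch mismatches tolerated inside an extension (default 2).
#' @param merge logical; merge overlapping hits at one locus (default
#'   TRUE).
#' @return data.frame with columns \code{sequence_id}, \code{orientation},
#'   \code{start} (0-based), \code{end} (0-based inclusive),
#'   \code{matched}.
#' @export
findHits <- function(oligo, index, minMatched = 18L, maxMismatch = 2L,
                     merge = TRUE) {
  stopifnot(is(index, "SpecificityIndex"))
  oligo <- .normalizeSeq(oligo, allowN = TRUE)
  k <- index@k
  if (nchar(oligo) < k)
    stop("oligo shorter than index seed length", call. = FALSE)
  queries <- c("plus/plus" = oligo,
               "plus/minus" = reverseComplementStr(oligo))
  rows <- list()
  for (ori in names(queries)) {
    q <- queries[[ori]]
    Lq <- nchar(q)
    qv <- .seqInts(q)
    starts <- 1:(Lq - k + 1L)
    kmers <- substring(q, starts, starts + k - 1L)
    diags <- list()
    for (j in seq_along(kmers)) {
      occ <- index@seeds[[kmers[j]]]
      if (is.null(occ)) next
      diags[[length(diags) + 1L]] <- cbind(occ[, 1L], occ[, 2L] - starts[j])
    }
    if (!length(diags)) next
    dd <- unique(do.call(rbind, diags))
    for (r in seq_len(nrow(dd))) {
      si <- dd[r, 1L]
      hit <- .evalDiagonal(qv, index@seqInts[[si]], dd[r, 2L], k,
                           minMatched, maxMismatch)
      if (is.null(hit)) next
      rows[[length(rows) + 1L]] <-
        data.frame(sequence_id = names(index@sequences)[si],
                   orientation = ori, start = hit$start - 1L,
                   end = hit$end - 1L, matched = hit$matched,
                   stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(sequence_id = character(), orientation = character(),
                      start = integer(), end = integer(), matched = integer(),
                      stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  if (merge) .mergeHits(hits) else hits
}

# Hits for a vector of oligos against either backend (SpecificityIndex or
# BlastDatabase); returns a list of hit data.frames.
.hitsFor <- function(seqs, db, params) {
  if (is(db, "SpecificityIndex")) {
    lapply(seqs, findHits, index = db, minMatched = params@minMatched,
           maxMismatch = params@maxMismatch)
  } else if (is(db, "BlastDatabase")) {
    blastHits(seqs, db, minMatched = params@minMatched)
  } else stop("unsupported specificity backend: ", class(db)[1L],
              call. = FALSE)
}

.checkCandidates <- function(oligos) {
  stopifnot(is.data.frame(oligos), "sequence" %in% names(oligos))
  oligos
}

#' Genome uniqueness filter (chromatin tracing)
#'
#' Retains oligos with exactly one alignment in the genome over both
#' orientations combined -- the oligo's own locus. An oligo with zero hits
#' indicates a database/target mismatch and raises an error.
#'
#' @param oligos candidate data.frame from [scanTarget()] (must have a
#'   \code{sequence} column).
#' @param genomeIndex a [SpecificityIndex-class] (or BLAST database) over
#'   the genome.
#' @param params a [DesignParameters-class] object.
#' @return The retained subset of \code{oligos}, with a \code{genome_hits}
#'   column appended.
#' @export
genomeUniquenessFilter <- function(oligos, genomeIndex,
                                   params = designParameters()) {
  oligos <- .checkCandidates(oligos)
  if (!nrow(oligos)) return(cbind(oligos, genome_hits = integer()))
  hits <- .hitsFor(oligos$sequence, genomeIndex, params)
  n <- vapply(hits, nrow, integer(1))
  if (any(n == 0L))
    stop("oligo(s) with no genome alignment (self-locus missing; does the ",
         "index cover the target region?): ",
         paste(utils::head(oligos$sequence[n == 0L], 3L), collapse = ", "),
         call. = FALSE)
  out <- oligos[n == 1L, , drop = FALSE]
  out$genome_hits <- n[n == 1L]
  rownames(out) <- NULL
  out
}

#' Antisense-strand filter (chromatin tracing with RNA retention)
#'
#' Screens genome-unique oligos against the unspliced transcriptome so
#' the final probes cannot hybridize to (nascent) transcripts. Per oligo:
#' no hits -- retained unchanged; hits only in plus/plus orientation --
#' replaced by its reverse complement (the probe then targets the
#' antisense strand); hits only in plus/minus -- retained unchanged; hits
#' in both orientations -- rejected.
#'
#' @param oligos candidate data.frame.
#' @param unsplicedIndex index over the unspliced transcriptome (genomic
#'   transcript spans, strand-corrected).
#' @param params a [DesignParameters-class] object.
#' @return Retained oligos with \code{sequence} possibly
#'   reverse-complemented and a logical \code{revcomped} column.
#' @export
antisenseFilter <- function(oligos, unsplicedIndex,
                            params = designParameters()) {
  oligos <- .checkCandidates(oligos)
  if (!nrow(oligos)) return(cbind(oligos, revcomped = logical()))
  hits <- .hitsFor(oligos$sequence, unsplicedIndex, params)
  keep <- logical(nrow(oligos))
  flip <- logical(nrow(oligos))
  for (i in seq_len(nrow(oligos))) {
    ori <- unique(hits[[i]]$orientation)
    pp <- "plus/plus" %in% ori
    pm <- "plus/minus" %in% ori
    if (!pp && !pm) { keep[i] <- TRUE
    } else if (pp && !pm) { keep[i] <- TRUE; flip[i] <- TRUE
    } else if (!pp && pm) { keep[i] <- TRUE
    }  # both orientations: rejected
  }
  out <- oligos[keep, , drop = FALSE]
  out$revcomped <- flip[keep]
  if (any(flip[keep]))
    out$sequence[out$revcomped] <- reverseComplementStr(
      out$sequence[out$revcomped])
  rownames(out) <- NULL
  out
}

#' Exon avoidance filter (chromatin tracing combined with RNA FISH)
#'
#' Rejects oligos with any alignment (either orientation) to the spliced
#' transcriptome, protecting combined DNA+RNA experiments from
#' DNA-probe/RNA cross-talk.
#'
#' @param oligos candidate data.frame.
#' @param splicedIndex index over the spliced transcriptome.
#' @param params a [DesignParameters-class] object.
#' @return The retained subset of \code{oligos}.
#' @export
exonAvoidanceFilter <- function(oligos, splicedIndex,
                                params = designParameters()) {
  oligos <- .checkCandidates(oligos)
  if (!nrow(oligos)) return(oligos)
  hits <- .hitsFor(oligos$sequence, splicedIndex, params)
  keep <- vapply(hits, nrow, integer(1)) == 0L
  out <- oligos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Isoform specificity filter (RNA FISH / MERFISH)
#'
#' Retains oligos that bind only transcript isoforms of their own gene.
#' Only plus/plus hits are considered: the probe, being the oligo's
#' reverse complement, binds an RNA wherever the oligo matches a
#' transcript in the plus/plus orientation. Every oligo must hit at least
#' its own transcript.
#'
#' @param oligos candidate data.frame (from scanning a transcript of
#'   \code{targetGene}).
#' @param splicedIndex index over the spliced transcriptome, built with a
#'   gene map.
#' @param targetGene gene id owning the scanned transcript.
#' @param params a [DesignParameters-class] object.
#' @return The retained subset of \code{oligos}.
#' @export
isoformSpecificityFilter <- function(oligos, splicedIndex, targetGene,
                                     params = designParameters()) {
  oligos <- .checkCandidates(oligos)
  gm <- geneMap(splicedIndex)
  if (!length(gm))
    stop("splicedIndex was built without a gene map", call. = FALSE)
  if (!nrow(oligos)) return(oligos)
  hits <- .hitsFor(oligos$sequence, splicedIndex, params)
  keep <- logical(nrow(oligos))
  for (i in seq_len(nrow(oligos))) {
    h <- hits[[i]]
    h <- h[h$orientation == "plus/plus", , drop = FALSE]
    if (!nrow(h))
      stop("oligo with no plus/plus transcriptome hit (must at least hit ",
           "its own transcript): ", oligos$sequence[i], call. = FALSE)
    keep[i] <- all(gm[h$sequence_id] == targetGene)
  }
  out <- oligos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
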