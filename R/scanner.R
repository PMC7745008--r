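# Sliding-window oligo generation over target sequences.

# Core advance-rule engine, independent of the filter stack: `accept` is
# called with the 0-based window offset and must return TRUE/FALSE. On
# accept the window advances by `windowLength`, on reject by 1 nt; the
# scan stops when fewer than `windowLength` nt remain. Returns the
# accepted 0-based offsets in 5'->3' order.
.slidingWindowScan <- function(targetLength, windowLength, accept) {
  offsets <- integer()
  pos <- 0L
  while (pos + windowLength <= targetLength) {
    if (isTRUE(accept(pos))) {
      offsets <- c(offsets, pos)
      pos <- pos + windowLength
    } else {
      pos <- pos + 1L
    }
  }
  offsets
}

#' Scan one target sequence for probe candidates
#'
#' Slides a window of \code{windowLength(params)} nt from the 5' end of
#' the target. Each window is tested with [passesPhysicalFilters()]
#' against the cross-hybridization pool formed by \code{acceptedPool} plus
#' the oligos already accepted in this scan. An accepted window advances
#' the scan by one full window length (adjacent, non-overlapping probes);
#' a rejected window advances it by 1 nt. Oligos are reported on the same
#' strand as the input target.
#'
#' @param label target label.
#' @param sequence target nucleotide sequence (A/C/G/T/N; windows
#'   containing N are rejected).
#' @param params a [DesignParameters-class] object.
#' @param acceptedPool character vector of oligos accepted from earlier
#'   targets (shared cross-hybridization pool).
#' @return data.frame of accepted candidates with columns
#'   \code{target_label}, \code{offset} (0-based position in the target),
#'   \code{sequence}, \code{tm}, \code{gc}, in 5'->3' order. A target
#'   shorter than the window yields zero rows.
#' @examples
#' params <- designParameters()
#' scanTarget("t", paste(rep("ACGTG", 18), collapse = ""), params)
#' @export
scanTarget <- function(label, sequence, params = designParameters(),
                       acceptedPool = character()) {
  seq <- toupper(sequence)
  L <- params@windowLength
  pool <- if (inherits(acceptedPool, "CrossHybPool")) acceptedPool
  else {
    p <- .newCrossPool()
    for (s in as.character(acceptedPool)) .addToPool(p, toupper(s))
    p
  }
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  accept <- function(offset) {
    w <- substr(seq, offset + 1L, offset + L)
    v <- passesPhysicalFilters(w, params, pool)
    if (v$passed) {
      .addToPool(pool, w)
      acc$rows[[length(acc$rows) + 1L]] <-
        data.frame(target_label = label, offset = offset, sequence = w,
                   tm = unname(v$measured["tm"]), gc = unname(v$measured["gc"]),
                   stringsAsFactors = FALSE)
    }
    v$passed
  }
  .slidingWindowScan(nchar(seq), L, accept)
  if (!length(acc$rows))
    return(data.frame(target_label = character(), offset = integer(),
                      sequence = character(), tm = numeric(), gc = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, acc$rows)
}

#' Scan multiple targets with a shared cross-hybridization pool
#'
#' Targets are scanned in input order; every accepted oligo joins the
#' shared pool immediately, so later windows (including those of later
#' targets) are screened against all earlier acceptances in the library.
#'
#' @param targets named character vector of target sequences (names =
#'   labels).
#' @param params a [DesignParameters-class] object.
#' @param acceptedPool optional character vector seeding the pool.
#' @return data.frame as in [scanTarget()], rows grouped by target in
#'   input order.
#' @export
scanTargets <- function(targets, params = designParameters(),
                        acceptedPool = character()) {
  stopifnot(!is.null(names(targets)))
  pool <- .newCrossPool()
  for (s in as.character(acceptedPool)) .addToPool(pool, toupper(s))
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    # scanTarget adds its acceptances to the shared pool in place
    out[[i]] <- scanTarget(names(targets)[i], targets[[i]], params, pool)
  }
  do.call(rbind, out)
}
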