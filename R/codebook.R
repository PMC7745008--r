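# MHD4 barcode codebook: construction, verification, and
# expression-aware assignment of codewords to genes.

# internal: minimum pairwise Hamming distance of a binary matrix
.minPairwiseDistance <- function(bits) {
  n <- nrow(bits)
  if (n < 2L) return(Inf)
  w <- rowSums(bits)
  ov <- tcrossprod(bits)
  d <- outer(w, w, "+") - 2 * ov
  min(d[upper.tri(d)])
}

#' Generate the default MHD4 codebook
#'
#' Constructs all Hamming-weight-4 codewords of the extended Hamming
#' [16,11,4] code: 140 binary words of length 16 with exactly four on-bits
#' and minimum pairwise Hamming distance 4 (the maximum constant-weight
#' (16, 4, 4) code used for MERFISH barcoding). Codewords are ordered by
#' their big-endian integer value, so the construction is deterministic.
#'
#' @param readoutIds character vector of length 16 naming the readout
#'   sequence for each bit position (default \code{R01..R16}).
#' @return An unassigned [Codebook-class].
#' @examples
#' cb <- generateMHD4Codebook()
#' nrow(codewords(cb))  # 140
#' @export
generateMHD4Codebook <- function(readoutIds = sprintf("R%02d", 1:16)) {
  stopifnot(length(readoutIds) == 16L)
  # Hamming(15,11): parity positions 1,2,4,8; data in the other 11.
  dataPos <- setdiff(1:15, c(1L, 2L, 4L, 8L))
  encode15 <- function(msg) {
    cw <- integer(15)
    cw[dataPos] <- msg
    for (p in c(1L, 2L, 4L, 8L)) {
      covered <- which(bitwAnd(1:15, p) != 0L & (1:15) != p)
      cw[p] <- sum(cw[covered]) %% 2L
    }
    cw
  }
  msgs <- as.matrix(expand.grid(rep(list(0:1), 11)))[, 11:1, drop = FALSE]
  words <- t(apply(msgs, 1L, encode15))
  words <- cbind(words, rowSums(words) %% 2L)  # overall parity -> [16,11,4]
  words <- words[rowSums(words) == 4L, , drop = FALSE]
  ord <- order(apply(words, 1L, function(b) sum(b * 2^(15:0))))
  bits <- words[ord, , drop = FALSE]
  storage.mode(bits) <- "integer"
  dimnames(bits) <- list(NULL, readoutIds)
  new("Codebook", bits = bits, assignment = integer(),
      readoutIds = readoutIds)
}

#' Verify codebook structure
#'
#' Checks bit-vector length, constant weight 4, and minimum pairwise
#' Hamming distance 4 over all codeword pairs. An empty return value means
#' the codebook is valid.
#'
#' @param cb a [Codebook-class] object (or a 0/1 matrix of codewords).
#' @return Character vector of human-readable violations (empty when
#'   valid).
#' @export
verifyCodebook <- function(cb) {
  bits <- if (is(cb, "Codebook")) cb@bits else cb
  msg <- character()
  if (!is.matrix(bits) || !all(bits %in% c(0L, 1L)))
    return("codewords must form a 0/1 matrix")
  if (nrow(bits) == 0L) return(msg)
  w <- rowSums(bits)
  if (any(w != 4L))
    msg <- c(msg, sprintf("weight violation: codeword %s has weight %d",
                          paste(which(w != 4L), collapse = ","),
                          w[which(w != 4L)[1L]]))
  if (nrow(bits) >= 2L) {
    wv <- rowSums(bits)
    d <- outer(wv, wv, "+") - 2 * tcrossprod(bits)
    bad <- which(upper.tri(d) & d < 4, arr.ind = TRUE)
    if (nrow(bad))
      msg <- c(msg, sprintf(
        "distance violation: codewords %d and %d at Hamming distance %d",
        bad[1L, 1L], bad[1L, 2L], d[bad[1L, 1L], bad[1L, 2L]]))
  }
  msg
}

#' Bit-sharing cost of a codeword assignment
#'
#' The rearrangement objective: for each of the 16 bit positions, sum the
#' expression of all genes whose codeword sets that bit, square it, and
#' add up over bits. Genes sharing bits contribute cross terms, so
#' minimizing this cost pushes highly expressed genes onto disjoint bits.
#'
#' @param cb an assigned [Codebook-class].
#' @param expr named numeric vector of non-negative expression values
#'   (e.g. FPKM), covering every assigned gene.
#' @return Non-negative scalar cost.
#' @export
bitSharingCost <- function(cb, expr) {
  stopifnot(is(cb, "Codebook"))
  a <- cb@assignment
  if (!length(a)) return(0)
  if (anyNA(match(names(a), names(expr))))
    stop("expression value(s) missing for gene(s): ",
         paste(setdiff(names(a), names(expr)), collapse = ", "),
         call. = FALSE)
  e <- expr[names(a)]
  if (any(!is.finite(e) | e < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  loads <- colSums(cb@bits[a, , drop = FALSE] * as.numeric(e))
  sum(loads^2)
}

#' Assign codewords to genes with expression-aware rearrangement
#'
#' Greedy assignment that reduces bit sharing among highly expressed
#' genes: genes are processed in decreasing expression order (ties broken
#' by gene id), and each takes the unused codeword minimizing the
#' incremental bit-sharing cost (ties broken by codeword index). For a
#' gene of expression e the increment of codeword w is
#' \eqn{\sum_{b \in on(w)} (2 L_b e + e^2)}, where \eqn{L_b} is the
#' accumulated expression load on bit b, so the chosen codeword is the one
#' whose on-bits carry the least load.
#'
#' @param genes character vector of gene ids (at most 140).
#' @param expr named numeric vector of expression values covering
#'   \code{genes}.
#' @param cb an unassigned [Codebook-class] (default the generated MHD4
#'   codebook).
#' @return The codebook with its \code{assignment} slot filled.
#' @export
assignCodewords <- function(genes, expr, cb = generateMHD4Codebook()) {
  stopifnot(is(cb, "Codebook"))
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene ids", call. = FALSE)
  if (length(genes) > nrow(cb@bits))
    stop("gene count (", length(genes), ") exceeds codebook capacity (",
         nrow(cb@bits), ")", call. = FALSE)
  if (anyNA(match(genes, names(expr))))
    stop("expression value(s) missing for gene(s): ",
         paste(setdiff(genes, names(expr)), collapse = ", "), call. = FALSE)
  e <- as.numeric(expr[genes])
  if (any(!is.finite(e) | e < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  ord <- order(-e, genes)
  loads <- numeric(ncol(cb@bits))
  used <- logical(nrow(cb@bits))
  assignment <- integer(length(genes))
  names(assignment) <- genes
  for (i in ord) {
    inc <- as.numeric(cb@bits %*% loads)  # e_i-independent part of the cost
    inc[used] <- Inf
    j <- which.min(inc)                   # ties resolve to lowest index
    used[j] <- TRUE
    assignment[genes[i]] <- j
    loads <- loads + cb@bits[j, ] * e[i]
  }
  new("Codebook", bits = cb@bits, assignment = assignment,
      readoutIds = cb@readoutIds)
}

#' Readout triplet carried by one probe
#'
#' Each probe targeting a barcoded transcript carries three of the four
#' readout sequences assigned to that transcript. Probes cycle
#' deterministically through the four leave-one-out 3-subsets of the
#' codeword's on-bits: probe \code{probeIndex} (0-based) omits on-bit
#' number \code{probeIndex mod 4} (in ascending bit order), so over any
#' four consecutive probes every readout appears exactly three times.
#'
#' @param codeword integer 0/1 vector of length 16 (one codebook row), or
#'   a vector of 4 on-bit positions.
#' @param probeIndex 0-based probe index within its transcript.
#' @return Integer vector of the 3 retained on-bit positions, ascending.
#' @export
probeReadoutTriplet <- function(codeword, probeIndex) {
  stopifnot(probeIndex >= 0)
  on <- if (length(codeword) == 4L) sort(as.integer(codeword))
        else sort(which(codeword == 1L))
  if (length(on) != 4L)
    stop("codeword must have exactly 4 on-bits", call. = FALSE)
  on[-((probeIndex %% 4L) + 1L)]
}

#' Write a codebook table
#'
#' One row per assigned gene: gene id, 16-character bit string, and the
#' readout ids of the four on-bits.
#'
#' @param cb an assigned [Codebook-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCodebook <- function(cb, path) {
  stopifnot(is(cb, "Codebook"))
  a <- cb@assignment
  if (!length(a)) stop("codebook is unassigned", call. = FALSE)
  rows <- lapply(names(a), function(g) {
    b <- cb@bits[a[[g]], ]
    data.frame(gene_id = g,
               barcode = paste0(b, collapse = ""),
               readouts = paste(cb@readoutIds[which(b == 1L)],
                                collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
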