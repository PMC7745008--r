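# Independent oracles used to check the package's core computations.
# These re-derive each quantity from first principles along a different
# code path than the implementation.

# ---- nearest-neighbor Tm oracle -------------------------------------------
# Unified NN parameters transcribed independently: only the 10 canonical
# dimers are tabulated; the other 6 are resolved through reverse
# complementation, and the summation is an explicit base-by-base loop.
.oracleNN <- list(
  AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
  CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
  GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
  GG = c(-8.0, -19.9))
.oracleComp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracleRevComp <- function(s) {
  paste(rev(.oracleComp[strsplit(s, "")[[1]]]), collapse = "")
}

oracleTm <- function(seq, conc = 1e-6) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    dimer <- paste0(ch[i], ch[i + 1])
    pars <- .oracleNN[[dimer]]
    if (is.null(pars)) pars <- .oracleNN[[oracleRevComp(dimer)]]
    dH <- dH + pars[1]; dS <- dS + pars[2]
  }
  for (end in c(ch[1], ch[n])) {
    if (end %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  x <- 4
  if (n %% 2 == 0 && seq == oracleRevComp(seq)) { dS <- dS - 1.4; x <- 1 }
  dH * 1000 / (dS + 1.987 * log(conc / x)) - 273.15
}

# ---- exhaustive hairpin stem oracle ---------------------------------------
# Triple loop over all substring pairs; returns -Inf when no stem exists.
oracleStemTm <- function(seq, minStem = 4, minLoop = 3) {
  n <- nchar(seq)
  best <- -Inf
  for (m in minStem:max(minStem, n)) {
    if (2 * m + minLoop > n) break
    for (i in 1:(n - m + 1)) {
      s1 <- substr(seq, i, i + m - 1)
      for (j in (i + m + minLoop):(n - m + 1)) {
        if (j > n - m + 1) break
        s2 <- substr(seq, j, j + m - 1)
        if (s2 == oracleRevComp(s1)) best <- max(best, oracleTm(s1))
      }
    }
  }
  best
}

# ---- exhaustive affine-gap Smith-Waterman oracle --------------------------
# Full DP with traceback; a gap of length L costs open + L * ext (the
# convention of the implementation's alignment engine). Returns the
# concatenated exactly-matching columns of the best local alignment.
oracleSWMatched <- function(a, b, match = 5, mismatch = -4,
                            open = 8, ext = 6) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  H <- matrix(0, na + 1, nb + 1)
  E <- matrix(-Inf, na + 1, nb + 1)  # gap in a (move along b)
  F <- matrix(-Inf, na + 1, nb + 1)  # gap in b (move along a)
  from <- matrix("", na + 1, nb + 1)
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      diag <- H[i - 1, j - 1] +
        if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, diag, E[i, j], F[i, j])
      from[i, j] <- if (H[i, j] == 0) "" else
        c("d", "e", "f")[which.max(c(diag, E[i, j], F[i, j]))]
    }
  }
  bestPos <- which(H == max(H), arr.ind = TRUE)[1, , drop = TRUE]
  i <- bestPos[1]; j <- bestPos[2]
  matched <- character()
  while (i > 1 && j > 1 && H[i, j] > 0) {
    mv <- from[i, j]
    if (mv == "d") {
      if (av[i - 1] == bv[j - 1]) matched <- c(av[i - 1], matched)
      i <- i - 1; j <- j - 1
    } else if (mv == "e") {
      # walk the whole gap back along b
      while (j > 1 && E[i, j] == E[i, j - 1] - ext &&
             E[i, j] != H[i, j - 1] - open - ext) j <- j - 1
      j <- j - 1
    } else if (mv == "f") {
      while (i > 1 && F[i, j] == F[i - 1, j] - ext &&
             F[i, j] != H[i - 1, j] - open - ext) i <- i - 1
      i <- i - 1
    } else break
  }
  list(score = max(H), matched = paste(matched, collapse = ""))
}

# ---- exhaustive specificity hit oracle ------------------------------------
# Slides the oligo across every diagonal of every database sequence in
# both orientations. A diagonal is a hit when it carries an exact run of
# at least k matches and its best window with <= maxMM mismatches covers
# at least minMatched matching bases. Returns the unmerged hit list as
# (sequence_id, orientation, matched) rows.
oracleHits <- function(oligo, db, k = 12, minMatched = 18, maxMM = 2) {
  enc <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  out <- list()
  for (ori in c("plus/plus", "plus/minus")) {
    q <- if (ori == "plus/plus") oligo else oracleRevComp(oligo)
    qv <- enc(q)
    Lq <- length(qv)
    for (sid in names(db)) {
      sv <- enc(db[[sid]])
      N <- length(sv)
      # total matches per diagonal via shifted comparisons
      acc <- integer(N + Lq - 1L)  # index = d + Lq, d = dbpos - qpos
      for (i in seq_len(Lq)) {
        cmp <- sv == qv[i]
        cmp[is.na(cmp)] <- FALSE
        acc[(1:N) - i + Lq] <- acc[(1:N) - i + Lq] + cmp
      }
      for (d in which(acc >= minMatched) - Lq) {
        i1 <- max(1L, 1L - d); i2 <- min(Lq, N - d)
        m <- qv[i1:i2] == sv[d + (i1:i2)]
        m[is.na(m)] <- FALSE
        r <- rle(m)
        if (!any(r$values) || max(r$lengths[r$values]) < k) next
        # best <=maxMM-mismatch window by direct enumeration
        best <- 0L
        idx <- seq_along(m)
        for (lo in idx) for (hi in lo:length(m)) {
          w <- m[lo:hi]
          if (sum(!w) <= maxMM) best <- max(best, sum(w))
        }
        if (best >= minMatched)
          out[[length(out) + 1L]] <- data.frame(
            sequence_id = sid, orientation = ori, matched = best,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sequence_id = character(), orientation = character(),
                      matched = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# ---- advance-rule reference scan ------------------------------------------
# Direct transcription of the scanning rule: accept -> jump one window
# length; reject -> step 1 nt; stop when fewer than a window remains.
oracleScanOffsets <- function(targetLength, windowLength, acceptVec) {
  offsets <- integer()
  pos <- 0L
  while (pos + windowLength <= targetLength) {
    if (acceptVec[pos + 1L]) {
      offsets <- c(offsets, pos)
      pos <- pos + windowLength
    } else pos <- pos + 1L
  }
  offsets
}

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste0(sample(letters, n, replace = TRUE), collapse = "")
}
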