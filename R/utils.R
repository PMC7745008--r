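# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @importFrom methods is new validObject slot
#' @importFrom stats setNames
NULL

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
}

# Uppercase and validate a nucleotide string; `allowN` relaxes to {A,C,G,T,N}.
.normalizeSeq <- function(seq, allowN = TRUE, what = "sequence") {
  .assertScalarString(seq, what)
  s <- toupper(seq)
  pat <- if (allowN) "[^ACGTN]" else "[^ACGT]"
  bad <- regmatches(s, regexpr(pat, s))
  if (length(bad) && nchar(bad))
    stop(what, " contains non-nucleotide character '", bad, "'", call. = FALSE)
  s
}

.seqChars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# integer encoding A=1 C=2 G=3 T=4 N=0, vectorised over one string
.seqInts <- function(seq) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(seq)]
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# longest run of identical characters (used by filters and readout generator)
.maxRunLength <- function(seq) {
  r <- rle(.seqChars(seq))
  max(r$lengths)
}
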