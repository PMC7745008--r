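#' Design parameters for probe generation and screening
#'
#' Holds every tunable threshold of the probe design pipeline: the sliding
#' window length, melting temperature and GC bounds, the homopolymer,
#' hairpin-stem and cross-hybridization limits, the thermodynamic reference
#' conditions (salt and probe concentration), and the specificity-search
#' knobs (seed length, minimum matched bases, tolerated mismatches, local
#' alignment scoring).
#'
#' Melting temperatures are computed with the unified nearest-neighbor
#' parameter set (SantaLucia-style dinucleotide stacks with initiation
#' terms) at the 1 M Na+ reference state, so no salt correction is applied
#' by default.
#'
#' @slot windowLength integer, targeting-region length in nt (default 30).
#' @slot tmMin numeric, minimum duplex melting temperature in degrees C
#'   (default 66); a window with Tm exactly at the bound passes.
#' @slot gcMin,gcMax numeric, inclusive GC-content bounds in percent
#'   (defaults 30 and 90).
#' @slot maxRun integer, longest tolerated homopolymer run in nt (default
#'   5; a run of \code{maxRun + 1} identical bases is rejected).
#' @slot stemTmMax numeric, maximum tolerated hairpin stem Tm in degrees C
#'   (default 76).
#' @slot crossHybTmMax numeric, maximum tolerated Tm of the concatenated
#'   exactly-matching region between a candidate and any accepted oligo
#'   (default 72).
#' @slot naConc numeric, monovalent salt concentration in mol/L (default 1;
#'   the nearest-neighbor reference state).
#' @slot probeConc numeric, total probe strand concentration CT in mol/L
#'   (default 1e-6).
#' @slot nnTable character, name of the nearest-neighbor parameter set
#'   (currently \code{"santalucia1998"}).
#' @slot seedK integer, k-mer seed length of the specificity index
#'   (default 12).
#' @slot minMatched integer, minimum matched bases for a specificity hit
#'   (default 18).
#' @slot maxMismatch integer, mismatches tolerated inside an extended
#'   specificity alignment (default 2).
#' @slot alnMatch,alnMismatch,alnGapOpen,alnGapExtend numeric, local
#'   alignment scoring used by the cross-hybridization filter (defaults
#'   +5/-4/8/6; gap penalties are positive costs).
#'
#' @seealso [designParameters()], [readParameterTable()]
#' @export
setClass("DesignParameters",
  representation(
    windowLength = "integer",
    tmMin = "numeric",
    gcMin = "numeric",
    gcMax = "numeric",
    maxRun = "integer",
    stemTmMax = "numeric",
    crossHybTmMax = "numeric",
    naConc = "numeric",
    probeConc = "numeric",
    nnTable = "character",
    seedK = "integer",
    minMatched = "integer",
    maxMismatch = "integer",
    alnMatch = "numeric",
    alnMismatch = "numeric",
    alnGapOpen = "numeric",
    alnGapExtend = "numeric"
  ),
  prototype(
    windowLength = 30L, tmMin = 66, gcMin = 30, gcMax = 90, maxRun = 5L,
    stemTmMax = 76, crossHybTmMax = 72, naConc = 1, probeConc = 1e-6,
    nnTable = "santalucia1998", seedK = 12L, minMatched = 18L,
    maxMismatch = 2L, alnMatch = 5, alnMismatch = -4, alnGapOpen = 8,
    alnGapExtend = 6
  )
)

setValidity("DesignParameters", function(object) {
  msg <- character()
  if (object@windowLength < 10L)
    msg <- c(msg, "windowLength must be >= 10 nt")
  if (object@gcMin > object@gcMax)
    msg <- c(msg, "gcMin must not exceed gcMax")
  if (object@naConc <= 0 || object@probeConc <= 0)
    msg <- c(msg, "concentrations must be > 0")
  if (object@maxRun < 1L)
    msg <- c(msg, "maxRun must be >= 1")
  if (object@seedK < 8L)
    msg <- c(msg, "seedK must be >= 8")
  if (object@seedK > object@windowLength)
    msg <- c(msg, "seedK must not exceed windowLength")
  if (object@minMatched < object@seedK)
    msg <- c(msg, "minMatched must be >= seedK")
  if (object@maxMismatch < 0L)
    msg <- c(msg, "maxMismatch must be >= 0")
  if (!identical(object@nnTable, "santalucia1998"))
    msg <- c(msg, "unknown nearest-neighbor table")
  if (length(msg)) msg else TRUE
})

#' Construct design parameters
#'
#' Returns a [DesignParameters-class] object with the default probe design
#' thresholds (30-nt window, Tm >= 66 C, GC 30-90 percent, homopolymer runs
#' of at most 5 nt, hairpin stem Tm <= 76 C, cross-hybridization Tm <= 72 C,
#' 1 M Na+, 1e-6 M probe), any of which can be overridden by name.
#'
#' @param ... named values overriding individual slots, e.g.
#'   \code{designParameters(tmMin = 70)}.
#' @return A validated \code{DesignParameters} object.
#' @examples
#' designParameters()
#' designParameters(windowLength = 40, gcMax = 80)
#' @export
designParameters <- function(...) {
  args <- list(...)
  intSlots <- c("windowLength", "maxRun", "seedK", "minMatched", "maxMismatch")
  for (nm in intersect(names(args), intSlots)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("DesignParameters"), args))
}

setMethod("show", "DesignParameters", function(object) {
  cat("DesignParameters\n")
  cat(sprintf("  window %d nt | Tm >= %g C | GC %g-%g%% | max run %d nt\n",
              object@windowLength, object@tmMin, object@gcMin, object@gcMax,
              object@maxRun))
  cat(sprintf("  stem Tm <= %g C | cross-hyb Tm <= %g C | [Na+] %g M | [probe] %g M\n",
              object@stemTmMax, object@crossHybTmMax, object@naConc,
              object@probeConc))
  cat(sprintf("  specificity: seed k=%d, min matched %d, <=%d mismatches\n",
              object@seedK, object@minMatched, object@maxMismatch))
  invisible(NULL)
})

#' k-mer specificity index over a sequence database
#'
#' A strand-aware seed index: every k-mer occurrence of every database
#' sequence is recorded so candidate oligos can be screened by ungapped
#' seed-and-extend search in both orientations. An optional gene map
#' (sequence id to gene id) supports isoform-aware transcriptome screens.
#'
#' @slot databaseName character, label of the indexed database.
#' @slot k integer, seed length in nt.
#' @slot seeds environment hashing each k-mer to an integer matrix of
#'   (sequence index, 1-based position) occurrences.
#' @slot sequences named character vector, the indexed sequences.
#' @slot seqInts list of integer-encoded sequences (internal fast path).
#' @slot geneMap named character vector mapping sequence id to gene id, or
#'   empty when no gene map applies.
#' @seealso [buildSpecificityIndex()], [findHits()]
#' @export
setClass("SpecificityIndex",
  representation(
    databaseName = "character",
    k = "integer",
    seeds = "environment",
    sequences = "character",
    seqInts = "list",
    geneMap = "character"
  )
)

setValidity("SpecificityIndex", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a positive scalar")
  if (length(object@sequences) &&
      (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences))))
    msg <- c(msg, "sequences must have unique names")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpecificityIndex", function(object) {
  cat(sprintf("SpecificityIndex '%s': %d sequence(s), %s nt, k=%d, %d distinct seeds\n",
              object@databaseName, length(object@sequences),
              format(sum(nchar(object@sequences)), big.mark = ","),
              object@k, length(ls(object@seeds))))
  if (length(object@geneMap))
    cat(sprintf("  gene map: %d sequence ids over %d gene(s)\n",
                length(object@geneMap), length(unique(object@geneMap))))
  invisible(NULL)
})

#' MERFISH barcode codebook
#'
#' Binary barcodes used to encode transcript identity over sequential
#' imaging rounds: length-16 words of Hamming weight 4 with minimum
#' pairwise Hamming distance 4 (the weight-4 shell of the extended Hamming
#' [16,11,4] code; exactly 140 words). Each bit position corresponds to a
#' readout sequence; an assignment maps gene ids to codeword rows.
#'
#' @slot bits integer matrix (codewords x 16) of 0/1 entries, weight 4 per
#'   row, pairwise distance >= 4.
#' @slot assignment named integer vector mapping gene id to codeword row
#'   (empty until [assignCodewords()] is run); injective.
#' @slot readoutIds character vector of length 16 naming the readout
#'   sequence attached to each bit position.
#' @seealso [generateMHD4Codebook()], [assignCodewords()],
#'   [verifyCodebook()]
#' @export
setClass("Codebook",
  representation(
    bits = "matrix",
    assignment = "integer",
    readoutIds = "character"
  )
)

setValidity("Codebook", function(object) {
  msg <- c(
    verifyCodebook(object),
    if (length(object@assignment)) {
      a <- object@assignment
      c(if (is.null(names(a)) || anyDuplicated(names(a)))
          "assignment gene ids must be unique",
        if (anyDuplicated(a)) "assignment must be injective",
        if (any(a < 1L | a > nrow(object@bits)))
          "assignment indexes outside the codebook")
    },
    if (length(object@readoutIds) != ncol(object@bits))
      "readoutIds must name every bit position"
  )
  if (length(msg)) msg else TRUE
})

setMethod("show", "Codebook", function(object) {
  d <- .minPairwiseDistance(object@bits)
  cat(sprintf("Codebook: %d codewords, %d bits, weight %s, min distance %s\n",
              nrow(object@bits), ncol(object@bits),
              paste(unique(rowSums(object@bits)), collapse = "/"),
              ifelse(is.finite(d), d, NA)))
  if (length(object@assignment))
    cat(sprintf("  %d gene(s) assigned\n", length(object@assignment)))
  else cat("  unassigned\n")
  invisible(NULL)
})

#' Pipeline run configuration
#'
#' Bundles the probe type, feature flags, input paths and output options of
#' one end-to-end design run. See [runDesign()] for the pipeline itself.
#'
#' @slot probeType one of \code{"chromatin"}, \code{"merfish"},
#'   \code{"smfish"}.
#' @slot antisenseOnly logical; chromatin tracing only: keep only oligos
#'   whose probe targets the antisense strand of genes (RNase-free
#'   experiments).
#' @slot avoidExons logical; chromatin tracing only: additionally reject
#'   oligos hitting the spliced transcriptome.
#' @slot probesPerTarget integer, number of probes to keep per target, or
#'   \code{NA} for all.
#' @slot outputMode \code{"template"} (primers appended) or
#'   \code{"primary"} (no primers; sequences reverse-complemented).
#' @slot genome,spliced,unspliced,geneMapFile,targets,params,readouts,primers
#'   character file paths (empty string when unused).
#' @slot outDir character, output directory.
#' @slot backend \code{"builtin"} k-mer engine or \code{"blast"} (requires
#'   BLAST+ on the PATH).
#' @slot seed integer, recorded in the run report (the pipeline itself is
#'   deterministic).
#' @export
setClass("RunConfig",
  representation(
    probeType = "character",
    antisenseOnly = "logical",
    avoidExons = "logical",
    probesPerTarget = "integer",
    outputMode = "character",
    genome = "character",
    spliced = "character",
    unspliced = "character",
    geneMapFile = "character",
    targets = "character",
    params = "character",
    readouts = "character",
    primers = "character",
    outDir = "character",
    backend = "character",
    seed = "integer"
  ),
  prototype(
    probeType = "chromatin", antisenseOnly = FALSE, avoidExons = FALSE,
    probesPerTarget = NA_integer_, outputMode = "template",
    genome = "", spliced = "", unspliced = "", geneMapFile = "",
    targets = "", params = "", readouts = "", primers = "",
    outDir = "", backend = "builtin", seed = 1L
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@probeType %in% c("chromatin", "merfish", "smfish"))
    msg <- c(msg, "probeType must be chromatin, merfish or smfish")
  if (!object@outputMode %in% c("template", "primary"))
    msg <- c(msg, "outputMode must be template or primary")
  if (!object@backend %in% c("builtin", "blast"))
    msg <- c(msg, "backend must be builtin or blast")
  if ((object@antisenseOnly || object@avoidExons) &&
      object@probeType != "chromatin")
    msg <- c(msg, "antisenseOnly/avoidExons apply to chromatin tracing only")
  if (!is.na(object@probesPerTarget) && object@probesPerTarget < 1L)
    msg <- c(msg, "probesPerTarget must be >= 1 or NA for all")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %s probes, output %s, backend %s\n",
              object@probeType, object@outputMode, object@backend))
  if (object@probeType == "chromatin")
    cat(sprintf("  antisenseOnly=%s avoidExons=%s\n",
                object@antisenseOnly, object@avoidExons))
  cat(sprintf("  probes/target: %s | out: %s\n",
              ifelse(is.na(object@probesPerTarget), "all",
                     object@probesPerTarget), object@outDir))
  invisible(NULL)
})

#' @rdname RunConfig-class
#' @param ... named slot values; see the class documentation. Integer-like
#'   values are coerced; \code{probesPerTarget = "all"} maps to \code{NA}.
#' @return A validated \code{RunConfig}.
#' @export
runConfig <- function(...) {
  args <- list(...)
  if (!is.null(args$probesPerTarget)) {
    p <- args$probesPerTarget
    args$probesPerTarget <-
      if (identical(p, "all") || is.null(p) || is.na(p)) NA_integer_
      else as.integer(p)
  }
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(new, c(list("RunConfig"), args))
}
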