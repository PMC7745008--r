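# Deterministic synthetic genome/transcriptome generator: mini assemblies
# with planted genes (exon structure, strand) and planted duplications, so
# every pipeline stage can be exercised offline with known ground truth.

.parseExons <- function(exons, start, end) {
  if (is.na(exons) || !nzchar(exons))
    return(matrix(c(start, end), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(strsplit(exons, ";", fixed = TRUE)[[1L]], "-",
                    fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
  colnames(m) <- c("start", "end")
  m[order(m[, 1L]), , drop = FALSE]
}

#' Generate a synthetic genome/transcriptome fixture
#'
#' Samples contigs base-wise at a target GC content, plants gene models
#' (yielding strand-corrected unspliced transcripts over the genomic span
#' and spliced transcripts as exon concatenations) and then copies
#' duplication source intervals verbatim to their destinations. The same
#' seed always produces a byte-identical fixture. The returned truth
#' table records every planted feature so tests can assert against the
#' construction rather than the generator's internal path.
#'
#' @param seed integer RNG seed (the caller's RNG stream is preserved).
#' @param contigLengths named integer vector of contig lengths in nt.
#' @param gcTarget target GC content in percent (default 50).
#' @param genes optional data.frame with columns \code{gene_id},
#'   \code{transcript_id}, \code{contig}, \code{start}, \code{end}
#'   (1-based inclusive genomic span), \code{strand} (\code{"+"} or
#'   \code{"-"}), and optional \code{exons} (absolute genomic intervals
#'   \code{"s1-e1;s2-e2"}; default one exon covering the span). Two rows
#'   sharing a \code{gene_id} are isoforms.
#' @param duplications optional data.frame with columns \code{contig},
#'   \code{start}, \code{end}, \code{destContig}, \code{destStart}: each
#'   source interval is copied verbatim (applied after gene placement).
#' @return List with elements \code{genome}, \code{spliced},
#'   \code{unspliced} (named character vectors), \code{geneMap} (named
#'   character: transcript id to gene id) and \code{truth} (list of the
#'   planted gene/duplication tables with realized sequences).
#' @examples
#' fx <- generateFixture(seed = 1, contigLengths = c(chr1 = 2000))
#' nchar(fx$genome)
#' @export
generateFixture <- function(seed, contigLengths, gcTarget = 50,
                            genes = NULL, duplications = NULL) {
  stopifnot(!is.null(names(contigLengths)), all(contigLengths > 0))
  pGC <- gcTarget / 100
  probs <- c(A = (1 - pGC) / 2, C = pGC / 2, G = pGC / 2, T = (1 - pGC) / 2)
  genome <- .withLocalSeed(as.integer(seed), {
    vapply(contigLengths, function(n)
      paste0(sample(names(probs), n, replace = TRUE, prob = probs),
             collapse = ""), character(1))
  })

  # overlap screening among planted features (isoforms of one gene may
  # overlap; distinct genes and duplication targets may not)
  feat <- data.frame(contig = character(), start = integer(),
                     end = integer(), owner = character(),
                     stringsAsFactors = FALSE)
  addFeature <- function(contig, start, end, owner) {
    same <- feat[feat$contig == contig & feat$owner != owner, , drop = FALSE]
    if (any(start <= same$end & end >= same$start))
      stop("overlapping planted features: ", owner, " at ", contig, ":",
           start, "-", end, call. = FALSE)
    feat[nrow(feat) + 1L, ] <<- list(contig, start, end, owner)
  }

  spliced <- character(); unspliced <- character(); gmap <- character()
  truthGenes <- NULL
  if (!is.null(genes) && nrow(genes)) {
    need <- c("gene_id", "transcript_id", "contig", "start", "end", "strand")
    stopifnot(all(need %in% names(genes)))
    if (!"exons" %in% names(genes)) genes$exons <- NA_character_
    rows <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      ctg <- as.character(g$contig)
      if (!ctg %in% names(genome)) stop("unknown contig: ", ctg, call. = FALSE)
      n <- nchar(genome[[ctg]])
      s <- as.integer(g$start); e <- as.integer(g$end)
      if (s < 1L || e > n || s > e)
        stop("gene span out of bounds: ", g$transcript_id, call. = FALSE)
      addFeature(ctg, s, e, as.character(g$gene_id))
      ex <- .parseExons(g$exons, s, e)
      if (any(ex[, 1L] < s | ex[, 2L] > e | ex[, 1L] > ex[, 2L]))
        stop("exon outside transcript span: ", g$transcript_id, call. = FALSE)
      span <- substr(genome[[ctg]], s, e)
      spl <- paste0(substring(genome[[ctg]], ex[, 1L], ex[, 2L]),
                    collapse = "")
      if (identical(as.character(g$strand), "-")) {
        span <- reverseComplementStr(span)
        spl <- reverseComplementStr(spl)
      } else if (!identical(as.character(g$strand), "+"))
        stop("strand must be '+' or '-': ", g$transcript_id, call. = FALSE)
      tx <- as.character(g$transcript_id)
      unspliced[tx] <- span
      spliced[tx] <- spl
      gmap[tx] <- as.character(g$gene_id)
      rows[[i]] <- data.frame(g, exon_table = I(list(ex)),
                              spliced_sequence = spl,
                              stringsAsFactors = FALSE)
    }
    truthGenes <- do.call(rbind, rows)
  }

  truthDup <- NULL
  if (!is.null(duplications) && nrow(duplications)) {
    need <- c("contig", "start", "end", "destContig", "destStart")
    stopifnot(all(need %in% names(duplications)))
    rows <- list()
    for (i in seq_len(nrow(duplications))) {
      d <- duplications[i, ]
      src <- as.character(d$contig); dst <- as.character(d$destContig)
      s <- as.integer(d$start); e <- as.integer(d$end)
      ds <- as.integer(d$destStart); de <- ds + (e - s)
      if (!src %in% names(genome) || !dst %in% names(genome))
        stop("unknown contig in duplication ", i, call. = FALSE)
      if (s < 1L || e > nchar(genome[[src]]) || s > e ||
          ds < 1L || de > nchar(genome[[dst]]))
        stop("duplication ", i, " out of bounds", call. = FALSE)
      addFeature(dst, ds, de, sprintf("dup%d", i))
      segment <- substr(genome[[src]], s, e)
      substr(genome[[dst]], ds, de) <- segment
      rows[[i]] <- data.frame(d, destEnd = de, sequence = segment,
                              stringsAsFactors = FALSE)
    }
    truthDup <- do.call(rbind, rows)
  }

  list(genome = genome, spliced = spliced, unspliced = unspliced,
       geneMap = gmap,
       truth = list(genes = truthGenes, duplications = truthDup,
                    seed = as.integer(seed), gcTarget = gcTarget))
}

#' Write a fixture to standard files
#'
#' Emits \code{genome.fa}, \code{spliced.fa}, \code{unspliced.fa}, a
#' two-column \code{gene_map.tsv}, and a BED of planted features, in the
#' formats [runDesign()] consumes.
#'
#' @param fixture a fixture list from [generateFixture()].
#' @param dir output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             spliced = file.path(dir, "spliced.fa"),
             unspliced = file.path(dir, "unspliced.fa"),
             geneMap = file.path(dir, "gene_map.tsv"),
             bed = file.path(dir, "features.bed"))
  writeFastaSeqs(fixture$genome, paths[["genome"]])
  if (length(fixture$spliced)) {
    writeFastaSeqs(fixture$spliced, paths[["spliced"]])
    writeFastaSeqs(fixture$unspliced, paths[["unspliced"]])
  }
  utils::write.table(
    data.frame(transcript_id = names(fixture$geneMap),
               gene_id = unname(fixture$geneMap)),
    paths[["geneMap"]], sep = "\t", row.names = FALSE, quote = FALSE)
  tg <- fixture$truth$genes
  bed <- if (!is.null(tg))
    data.frame(tg$contig, tg$start - 1L, tg$end, tg$transcript_id, 0L,
               tg$strand)
  else data.frame(character(), integer(), integer(), character(),
                  integer(), character())
  utils::write.table(bed, paths[["bed"]], sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(paths)
}
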