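# Accessor generics for the package's S4 classes.

#' @rdname DesignParameters-class
#' @param x a \code{DesignParameters} object.
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))
#' @rdname DesignParameters-class
#' @export
setMethod("windowLength", "DesignParameters", function(x) x@windowLength)

#' @rdname SpecificityIndex-class
#' @param x a \code{SpecificityIndex} (or \code{Codebook}) object.
#' @export
setGeneric("seedLength", function(x) standardGeneric("seedLength"))
#' @rdname SpecificityIndex-class
#' @export
setMethod("seedLength", "SpecificityIndex", function(x) x@k)

#' @rdname SpecificityIndex-class
#' @export
setGeneric("indexedSequences", function(x) standardGeneric("indexedSequences"))
#' @rdname SpecificityIndex-class
#' @export
setMethod("indexedSequences", "SpecificityIndex", function(x) x@sequences)

#' @rdname SpecificityIndex-class
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))
#' @rdname SpecificityIndex-class
#' @export
setMethod("geneMap", "SpecificityIndex", function(x) x@geneMap)

#' @rdname Codebook-class
#' @param x a \code{Codebook} object.
#' @export
setGeneric("codewords", function(x) standardGeneric("codewords"))
#' @rdname Codebook-class
#' @export
setMethod("codewords", "Codebook", function(x) x@bits)

#' @rdname Codebook-class
#' @export
setGeneric("geneAssignment", function(x) standardGeneric("geneAssignment"))
#' @rdname Codebook-class
#' @export
setMethod("geneAssignment", "Codebook", function(x) x@assignment)

#' @rdname Codebook-class
#' @export
setGeneric("readoutIds", function(x) standardGeneric("readoutIds"))
#' @rdname Codebook-class
#' @export
setMethod("readoutIds", "Codebook", function(x) x@readoutIds)
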