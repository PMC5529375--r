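#' @name mitochar-accessors
#' @title Accessors for MitoGenome and GeneOrder objects
#' @param x a \linkS4class{MitoGenome} or \linkS4class{GeneOrder}.
#' @return \code{genomeID}: the identifier; \code{genomeSeq}: the
#'   \code{DNAString}; \code{genomeLength}: integer length in bp;
#'   \code{features}: the feature \code{data.frame}; \code{orderLabels}:
#'   the signed label vector; \code{orderAnchor}: the anchor label.
NULL

#' @rdname mitochar-accessors
#' @export
setGeneric("genomeID", function(x) standardGeneric("genomeID"))
#' @rdname mitochar-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname mitochar-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname mitochar-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname mitochar-accessors
#' @export
setGeneric("orderLabels", function(x) standardGeneric("orderLabels"))
#' @rdname mitochar-accessors
#' @export
setGeneric("orderAnchor", function(x) standardGeneric("orderAnchor"))

#' @rdname mitochar-accessors
#' @export
setMethod("genomeID", "MitoGenome", function(x) x@id)
#' @rdname mitochar-accessors
#' @export
setMethod("genomeSeq", "MitoGenome", function(x) x@seq)
#' @rdname mitochar-accessors
#' @export
setMethod("genomeLength", "MitoGenome", function(x) length(x@seq))
#' @rdname mitochar-accessors
#' @export
setMethod("features", "MitoGenome", function(x) x@features)
#' @rdname mitochar-accessors
#' @export
setMethod("orderLabels", "GeneOrder", function(x) x@labels)
#' @rdname mitochar-accessors
#' @export
setMethod("orderAnchor", "GeneOrder", function(x) x@anchor)
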