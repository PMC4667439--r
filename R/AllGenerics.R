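#' @name cx3sig-generics
#' @title Accessor generics used across cx3sig classes
#' @description Small accessor generics in the Bioconductor style: slot
#'   access always goes through these, never through `@`.
#' @param x an object of a cx3sig class
#' @param ... passed to methods
#' @return the accessed component; see the class pages for details.
NULL

#' @rdname cx3sig-generics
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname cx3sig-generics
#' @export
setGeneric("scaleType", function(x, ...) standardGeneric("scaleType"))

#' @rdname cx3sig-generics
#' @export
setGeneric("signatureGenes", function(x, ...) standardGeneric("signatureGenes"))

#' @rdname cx3sig-generics
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @rdname cx3sig-generics
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @rdname cx3sig-generics
#' @export
setGeneric("modules", function(x, ...) standardGeneric("modules"))

#' @rdname cx3sig-generics
#' @export
setGeneric("eigengenes", function(x, ...) standardGeneric("eigengenes"))

#' @rdname cx3sig-generics
#' @export
setGeneric("clusters", function(x, ...) standardGeneric("clusters"))

#' @rdname cx3sig-generics
#' @export
setGeneric("unassigned", function(x, ...) standardGeneric("unassigned"))

#' @rdname cx3sig-generics
#' @export
setGeneric("enrichTable", function(x, ...) standardGeneric("enrichTable"))

#' @rdname cx3sig-generics
#' @export
setGeneric("networkNodes", function(x, ...) standardGeneric("networkNodes"))

#' @rdname cx3sig-generics
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname cx3sig-generics
#' @export
setGeneric("moduleMap", function(x, ...) standardGeneric("moduleMap"))

#' @rdname cx3sig-generics
#' @export
setGeneric("somAssignment", function(x, ...) standardGeneric("somAssignment"))

#' @rdname cx3sig-generics
#' @export
setGeneric("deTable", function(x, ...) standardGeneric("deTable"))

#' @rdname cx3sig-generics
#' @export
setGeneric("foldChanges", function(x, ...) standardGeneric("foldChanges"))
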