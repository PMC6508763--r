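#' @rdname discretize
#' @export
setGeneric("discretize", function(x, ...) standardGeneric("discretize"))

#' Accessors for TernaryMatrix and BooleanNetwork objects
#'
#' `codes()` returns the integer call matrix (0 low, 1 intermediate,
#' 2 high, NA missing); `thresholds()` the per-probe step-fit table;
#' `dynamicGenes()` the ids of genes passing the dynamic-range gate;
#' `edges()` the classified relationship table; `networkGenes()` the
#' dynamic-gene universe of a network.
#'
#' @param x a [TernaryMatrix-class] or [BooleanNetwork-class] object.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("dynamicGenes", function(x) standardGeneric("dynamicGenes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @rdname accessors
#' @export
setMethod("codes", "TernaryMatrix", function(x) x@codes)

#' @rdname accessors
#' @export
setMethod("thresholds", "TernaryMatrix", function(x) x@thresholds)

#' @rdname accessors
#' @export
setMethod("dynamicGenes", "TernaryMatrix", function(x) {
  x@thresholds$probe_id[x@thresholds$dynamic]
})

#' @rdname accessors
#' @export
setMethod("edges", "BooleanNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("networkGenes", "BooleanNetwork", function(x) x@genes)
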