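#' @import methods
NULL

## Integer codes used throughout for ternary calls. Missing values stay NA.
CODE_LOW <- 0L
CODE_INT <- 1L
CODE_HIGH <- 2L

RELATIONSHIP_LEVELS <- c("lolo", "lohi", "hilo", "hihi", "eqv", "opo")

#' StepFit: a fitted rising one-step function for one gene
#'
#' Produced by [fitStep()]. The step is fitted to the gene's sorted
#' expression values; the threshold separating the low and high regimes is
#' the midpoint of the two fitted segment means.
#'
#' @slot threshold numeric(1). Discretization threshold t (log2 units).
#' @slot breakpoint integer(1). Number of values in the low segment,
#'   in `[1, n - 1]`.
#' @slot lowMean,highMean numeric(1). Fitted segment means
#'   (`lowMean <= highMean`).
#' @slot sse numeric(1). Residual sum of squares of the two-segment fit.
#' @slot n integer(1). Number of non-missing values used.
#' @slot degenerate logical(1). TRUE when the input had zero variance.
#'
#' @export
setClass("StepFit",
  representation(
    threshold = "numeric",
    breakpoint = "integer",
    lowMean = "numeric",
    highMean = "numeric",
    sse = "numeric",
    n = "integer",
    degenerate = "logical"
  )
)

setValidity("StepFit", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (object@lowMean > object@highMean + 1e-9)
    msg <- c(msg, "lowMean must not exceed highMean (rising step)")
  if (object@sse < -1e-9)
    msg <- c(msg, "sse must be non-negative")
  if (object@threshold < object@lowMean - 1e-9 ||
      object@threshold > object@highMean + 1e-9)
    msg <- c(msg, "threshold must lie in [lowMean, highMean]")
  if (length(msg)) msg else TRUE
})

#' TernaryMatrix: discretized low/intermediate/high calls
#'
#' Produced by [discretize()]. Holds one code per cell of the source
#' expression matrix (same dimensions and dimnames), the per-probe step-fit
#' table, and the dynamic-range gate results.
#'
#' Codes are stored as integers: 0 = low, 1 = intermediate, 2 = high,
#' NA = missing.
#'
#' @slot codes integer matrix, probes x samples.
#' @slot thresholds data.frame with one row per probe: `probe_id`,
#'   `threshold`, `breakpoint`, `low_mean`, `high_mean`, `sse`, `n`,
#'   `degenerate`, `n_low`, `n_high`, `dynamic`.
#' @slot margin numeric(1). Half-width of the intermediate band around the
#'   threshold (default 0.5 log2 units).
#' @slot minLow,minHigh integer(1). Minimum low/high call counts for a gene
#'   to count as dynamic.
#'
#' @seealso [discretize()], [codes()], [thresholds()], [dynamicGenes()]
#' @export
setClass("TernaryMatrix",
  representation(
    codes = "matrix",
    thresholds = "data.frame",
    margin = "numeric",
    minLow = "integer",
    minHigh = "integer"
  )
)

setValidity("TernaryMatrix", function(object) {
  msg <- character()
  cd <- object@codes
  if (!is.integer(cd)) msg <- c(msg, "codes must be an integer matrix")
  ok <- cd[!is.na(cd)]
  if (length(ok) && !all(ok %in% c(CODE_LOW, CODE_INT, CODE_HIGH)))
    msg <- c(msg, "codes must be 0 (low), 1 (intermediate) or 2 (high)")
  if (is.null(rownames(cd)) || is.null(colnames(cd)))
    msg <- c(msg, "codes must carry probe and sample ids as dimnames")
  if (anyDuplicated(rownames(cd))) msg <- c(msg, "duplicate probe ids")
  if (anyDuplicated(colnames(cd))) msg <- c(msg, "duplicate sample ids")
  if (nrow(object@thresholds) != nrow(cd))
    msg <- c(msg, "thresholds must have one row per probe")
  if (!identical(object@thresholds$probe_id, rownames(cd)))
    msg <- c(msg, "thresholds rows must match probe order")
  if (length(object@margin) != 1L || object@margin < 0)
    msg <- c(msg, "margin must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' BooleanNetwork: classified Boolean implication relationships
#'
#' Produced by [buildNetwork()]. Stores every ordered pair of dynamic genes
#' whose quadrant pattern passed the sparseness test, together with the
#' parameters the network was built under. Symmetric classes (eqv, opo)
#' appear in both orders, as do the contrapositive pairs of the asymmetric
#' classes (A lolo B is stored alongside B hihi A).
#'
#' @slot edges data.frame with columns `geneA`, `geneB`, `relationship`,
#'   `statistic`, `error_rate`, `a00`, `a01`, `a10`, `a11`. `statistic` is
#'   the smallest sparse-quadrant statistic supporting the relationship and
#'   `error_rate` the largest supporting error rate.
#' @slot genes character. The dynamic-gene universe the pairs were drawn
#'   from.
#' @slot params list. `margin`, `sMin`, `eMax`, `minLow`, `minHigh`.
#'
#' @seealso [buildNetwork()], [edges()], [networkGenes()]
#' @export
setClass("BooleanNetwork",
  representation(
    edges = "data.frame",
    genes = "character",
    params = "list"
  )
)

setValidity("BooleanNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("geneA", "geneB", "relationship", "statistic", "error_rate",
            "a00", "a01", "a10", "a11")
  if (!all(need %in% names(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(ed) && !all(ed$relationship %in% RELATIONSHIP_LEVELS))
      msg <- c(msg, "edge relationships must be one of the six classes")
    if (nrow(ed) && !all(c(ed$geneA, ed$geneB) %in% object@genes))
      msg <- c(msg, "edges must only involve genes in the network universe")
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  if (length(msg)) msg else TRUE
})

#' @describeIn StepFit-class Compact display of a fitted step.
#' @param object a `StepFit`.
#' @export
setMethod("show", "StepFit", function(object) {
  cat(sprintf(
    "StepFit: threshold %.4g (low %.4g | high %.4g), breakpoint %d/%d, sse %.4g%s\n",
    object@threshold, object@lowMean, object@highMean,
    object@breakpoint, object@n, object@sse,
    if (object@degenerate) " [degenerate]" else ""
  ))
})

#' @describeIn TernaryMatrix-class Summary display of call composition.
#' @param object a `TernaryMatrix`.
#' @export
setMethod("show", "TernaryMatrix", function(object) {
  cd <- object@codes
  tab <- c(
    low = sum(cd == CODE_LOW, na.rm = TRUE),
    intermediate = sum(cd == CODE_INT, na.rm = TRUE),
    high = sum(cd == CODE_HIGH, na.rm = TRUE),
    missing = sum(is.na(cd))
  )
  cat(sprintf("TernaryMatrix: %d probes x %d samples (margin %.3g)\n",
              nrow(cd), ncol(cd), object@margin))
  cat(sprintf("  calls: %d low, %d intermediate, %d high, %d missing\n",
              tab[1], tab[2], tab[3], tab[4]))
  cat(sprintf("  dynamic genes: %d of %d (min low %d, min high %d)\n",
              sum(object@thresholds$dynamic), nrow(cd),
              object@minLow, object@minHigh))
})

#' @describeIn BooleanNetwork-class Summary display of edge composition.
#' @param object a `BooleanNetwork`.
#' @export
setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork: %d genes, %d directed relationships\n",
              length(object@genes), nrow(object@edges)))
  if (nrow(object@edges)) {
    tab <- table(factor(object@edges$relationship, RELATIONSHIP_LEVELS))
    cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " "), "\n", sep = "")
  }
  p <- object@params
  cat(sprintf("  params: margin %.3g, statistic > %.3g, error rate < %.3g\n",
              p$margin, p$sMin, p$eMax))
})
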