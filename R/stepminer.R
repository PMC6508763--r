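#' Fit a rising one-step function to a gene's expression values
#'
#' Sorts the values ascending and, for every breakpoint `k` in
#' `[1, n - 1]`, fits a two-segment constant model (mean of the first `k`
#' values, mean of the rest) and scores it by the residual sum of squares
#' `SSE(k) = sum((left - m1)^2) + sum((right - m2)^2)`. The fit with
#' minimal SSE wins; ties go to the smallest `k`. The discretization
#' threshold is the midpoint `(m1 + m2) / 2` of the two segment means at
#' the optimum, which makes the threshold shift by exactly `c` when `c` is
#' added to every value.
#'
#' A constant input has SSE 0 at every breakpoint; it is returned with the
#' common value as threshold and flagged degenerate.
#'
#' @param values Numeric vector; NAs are dropped. At least 2 non-missing
#'   values are required.
#' @return A [StepFit-class] object.
#' @examples
#' fitStep(c(1, 1, 1, 5, 5, 5))  # breakpoint 3, threshold 3, sse 0
#' @export
fitStep <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L)
    stop("step fit needs at least 2 non-missing values (got ", n, ")")
  if (!all(is.finite(x))) stop("step fit requires finite values")
  x <- unname(sort(x))
  if (x[n] == x[1L]) {
    return(new("StepFit", threshold = x[1L], breakpoint = 1L,
               lowMean = x[1L], highMean = x[n], sse = 0,
               n = n, degenerate = TRUE))
  }
  # SSE(k) = sum(x^2) - k*m1(k)^2 - (n-k)*m2(k)^2, via cumulative sums
  k <- seq_len(n - 1L)
  cs <- cumsum(x)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  sse <- sum(x^2) - k * m1^2 - (n - k) * m2^2
  best <- which.min(sse)  # which.min takes the first (smallest k) on ties
  lo <- m1[best]
  hi <- m2[best]
  new("StepFit",
      threshold = (lo + hi) / 2, breakpoint = as.integer(best),
      lowMean = lo, highMean = hi, sse = max(sse[best], 0),
      n = n, degenerate = FALSE)
}

#' Discretize an expression matrix into ternary calls
#'
#' Fits a step threshold `t` per gene with [fitStep()] and calls each
#' non-missing value high (`> t + margin`), low (`< t - margin`) or
#' intermediate (inside the band). Intermediate calls are excluded from
#' implication counting downstream; the band absorbs values too close to
#' the threshold to call confidently.
#'
#' A gene enters network building only if it has at least `minLow` low and
#' `minHigh` high calls (the dynamic-range gate): a gene with no low (or
#' no high) calls can only produce vacuous implications. The default gate
#' `max(3, ceiling(0.025 * n))` scales with sample count.
#'
#' @param x Numeric probe x sample matrix (log2 scale, dimnames required),
#'   or a `SummarizedExperiment` (the first assay is used).
#' @param margin Half-width of the intermediate band (default 0.5).
#' @param minLow,minHigh Dynamic-range gate; `NULL` for the default.
#' @param ... passed between methods.
#' @return A [TernaryMatrix-class].
#' @examples
#' m <- rbind(g1 = c(2, 2.1, 1.9, 8, 8.2, 7.9),
#'            g2 = c(5, 5.1, 4.9, 5.2, 4.8, 5.05))
#' colnames(m) <- paste0("s", 1:6)
#' tern <- discretize(m, minLow = 2, minHigh = 2)
#' codes(tern)["g1", ]  # 0 0 0 2 2 2
#' dynamicGenes(tern)   # "g1"
#' @rdname discretize
#' @export
setMethod("discretize", "matrix",
          function(x, margin = 0.5, minLow = NULL, minHigh = NULL, ...) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry probe and sample ids as dimnames")
  stopifnot(is.numeric(x), margin >= 0)
  n <- ncol(x)
  if (is.null(minLow)) minLow <- max(3L, ceiling(0.025 * n))
  if (is.null(minHigh)) minHigh <- max(3L, ceiling(0.025 * n))
  minLow <- as.integer(minLow)
  minHigh <- as.integer(minHigh)

  fits <- apply(x, 1L, function(v) {
    if (sum(!is.na(v)) < 2L)
      stop("gene with fewer than 2 non-missing values; drop it first")
    fitStep(v)
  })
  th <- data.frame(
    probe_id = rownames(x),
    threshold = vapply(fits, slot, numeric(1L), "threshold"),
    breakpoint = vapply(fits, slot, integer(1L), "breakpoint"),
    low_mean = vapply(fits, slot, numeric(1L), "lowMean"),
    high_mean = vapply(fits, slot, numeric(1L), "highMean"),
    sse = vapply(fits, slot, numeric(1L), "sse"),
    n = vapply(fits, slot, integer(1L), "n"),
    degenerate = vapply(fits, slot, logical(1L), "degenerate"),
    stringsAsFactors = FALSE, row.names = NULL
  )

  cd <- matrix(CODE_INT, nrow(x), ncol(x), dimnames = dimnames(x))
  cd[x > th$threshold + margin] <- CODE_HIGH
  cd[x < th$threshold - margin] <- CODE_LOW
  cd[is.na(x)] <- NA_integer_
  storage.mode(cd) <- "integer"

  th$n_low <- as.integer(rowSums(cd == CODE_LOW, na.rm = TRUE))
  th$n_high <- as.integer(rowSums(cd == CODE_HIGH, na.rm = TRUE))
  th$dynamic <- th$n_low >= minLow & th$n_high >= minHigh

  new("TernaryMatrix", codes = cd, thresholds = th,
      margin = margin, minLow = minLow, minHigh = minHigh)
})

#' @rdname discretize
#' @export
setMethod("discretize", "SummarizedExperiment",
          function(x, margin = 0.5, minLow = NULL, minHigh = NULL, ...) {
  discretize(as.matrix(SummarizedExperiment::assay(x)),
             margin = margin, minLow = minLow, minHigh = minHigh, ...)
})

#' Dynamic-range gate for one gene's ternary calls
#'
#' A gene is dynamic when it has at least `minLow` low calls and
#' `minHigh` high calls; only dynamic genes enter network building.
#'
#' @param ternaryRow Integer code vector for one gene (0 low, 1
#'   intermediate, 2 high, NA missing).
#' @param minLow,minHigh Minimum call counts.
#' @return logical(1).
#' @export
isDynamic <- function(ternaryRow, minLow = 3L, minHigh = 3L) {
  stopifnot(minLow >= 0, minHigh >= 0)
  sum(ternaryRow == CODE_LOW, na.rm = TRUE) >= minLow &&
    sum(ternaryRow == CODE_HIGH, na.rm = TRUE) >= minHigh
}

#' Write a TernaryMatrix as tab-delimited text
#'
#' Two files: the code matrix (`0`/`1`/`2`/`NA`) at `path`, and the
#' per-gene threshold side table (`probe_id`, `threshold`, `breakpoint`,
#' `sse`, `dynamic`, ...) at `thresholdsPath`.
#'
#' @param ternary a [TernaryMatrix-class].
#' @param path Output path for the code matrix.
#' @param thresholdsPath Output path for the threshold table (default:
#'   `path` with a `.thresholds.tsv` suffix).
#' @return Invisibly, `c(path, thresholdsPath)`.
#' @export
writeTernaryMatrix <- function(ternary, path,
                               thresholdsPath = paste0(path, ".thresholds.tsv")) {
  stopifnot(is(ternary, "TernaryMatrix"))
  cd <- codes(ternary)
  con <- file(path, "w")
  writeLines(sprintf(
    "# boolimpl %s ternary codes (0=low,1=intermediate,2=high): margin=%g minLow=%d minHigh=%d",
    as.character(utils::packageVersion("boolimpl")),
    ternary@margin, ternary@minLow, ternary@minHigh), con)
  writeLines(paste(c("ProbeID", colnames(cd)), collapse = "\t"), con)
  body <- apply(cd, 1L, function(v) {
    s <- as.character(v)
    s[is.na(v)] <- "NA"
    paste(s, collapse = "\t")
  })
  writeLines(paste(rownames(cd), body, sep = "\t"), con)
  close(con)
  utils::write.table(thresholds(ternary), thresholdsPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, thresholdsPath))
}
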