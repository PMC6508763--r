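#' Build tissue universes from a sample annotation table
#'
#' A universe is a coherent subset of samples — typically all samples of
#' one tissue — within which a Boolean relationship can be evaluated as a
#' candidate logical invariant. This returns one universe per requested
#' tissue label plus the all-samples universe (named `"all"`). Tissue
#' matching is by exact label after case-folding and whitespace trimming;
#' a requested label matching no samples is dropped with a warning.
#'
#' @param annotation data.frame with columns `sample_id` and `tissue`
#'   (see [readSampleAnnotation()]).
#' @param tissueLabels Character vector of tissue labels to form
#'   universes for; default: every distinct tissue in the annotation.
#' @return Named list of character vectors of sample ids. The `"all"`
#'   universe contains every annotated sample.
#' @examples
#' ann <- data.frame(sample_id = paste0("s", 1:6),
#'                   tissue = c("root", "Root ", "leaf", "leaf", "leaf", "seed"))
#' names(makeUniverses(ann, c("root", "leaf")))  # "root" "leaf" "all"
#' @export
makeUniverses <- function(annotation, tissueLabels = NULL) {
  stopifnot(is.data.frame(annotation),
            all(c("sample_id", "tissue") %in% names(annotation)))
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate sample_id in annotation")
  tis <- tolower(trimws(annotation$tissue))
  if (is.null(tissueLabels)) tissueLabels <- sort(unique(tis))
  labs <- tolower(trimws(tissueLabels))
  out <- list()
  for (i in seq_along(labs)) {
    ids <- annotation$sample_id[tis == labs[i]]
    if (!length(ids)) {
      warning("no samples with tissue '", tissueLabels[i],
              "'; universe omitted")
      next
    }
    out[[labs[i]]] <- ids
  }
  out[["all"]] <- annotation$sample_id
  out
}

#' Evaluate a candidate logical invariant across universes
#'
#' For one ordered gene pair, classifies the Boolean relationship within
#' each universe and reports whether the relationship qualifies as a
#' candidate invariant there. True invariance over all possible samples
#' of a universe is unverifiable from finite data; the candidate flag
#' simply records that the relationship passes the sparseness thresholds
#' inside that universe.
#'
#' By default the global discretization thresholds are reused within each
#' universe, so the quadrant composition of a universe can be read off
#' the global scatter; `rediscretize = TRUE` refits the step thresholds
#' on the universe's samples instead.
#'
#' The violation count is the number of the universe's samples falling in
#' the sparse quadrant(s) of the *globally* assigned relationship — the
#' samples that break the global rule inside that universe.
#'
#' @param pair Character vector of two gene ids `c(geneA, geneB)`.
#' @param x Numeric expression matrix (probes x samples, dimnames
#'   required).
#' @param universes Named list of sample-id vectors from
#'   [makeUniverses()].
#' @param rediscretize Refit thresholds within each universe
#'   (default FALSE).
#' @param margin Intermediate band half-width for [discretize()].
#' @param sMin,eMax Sparseness thresholds.
#' @return data.frame with one row per universe: `universe`, `n`
#'   (samples), `n_counted` (pairwise-complete non-intermediate),
#'   `relationship`, `statistic`, `error_rate`, `violations`,
#'   `candidate`, `untestable`.
#' @export
evaluateInvariant <- function(pair, x, universes, rediscretize = FALSE,
                              margin = 0.5, sMin = 3, eMax = 0.1) {
  stopifnot(length(pair) == 2L, is.matrix(x))
  missing_genes <- setdiff(pair, rownames(x))
  if (length(missing_genes))
    stop("gene(s) not in matrix: ", paste(missing_genes, collapse = ", "))
  sub <- x[pair, , drop = FALSE]
  glob <- discretize(sub, margin = margin, minLow = 0L, minHigh = 0L)
  gcd <- codes(glob)
  gimp <- pairImplication(gcd[1L, ], gcd[2L, ], sMin = sMin, eMax = eMax)
  sparseQ <- .sparseQuadrantsOf(gimp$relationship)

  rows <- lapply(names(universes), function(uname) {
    ids <- intersect(universes[[uname]], colnames(x))
    n <- length(ids)
    vals <- sub[, ids, drop = FALSE]
    enough <- min(rowSums(!is.na(vals))) >= 2L
    if (!n || !enough) {
      return(data.frame(universe = uname, n = n, n_counted = 0L,
                        relationship = NA_character_, statistic = NA_real_,
                        error_rate = NA_real_, violations = NA_integer_,
                        candidate = FALSE, untestable = TRUE,
                        stringsAsFactors = FALSE))
    }
    cd <- if (rediscretize) {
      codes(discretize(vals, margin = margin, minLow = 0L, minHigh = 0L))
    } else {
      gcd[, ids, drop = FALSE]
    }
    imp <- pairImplication(cd[1L, ], cd[2L, ], sMin = sMin, eMax = eMax)
    viol <- if (length(sparseQ)) {
      sum(vapply(sparseQ, function(q) imp$tests[[q]]$observed, numeric(1L)))
    } else NA_integer_
    supp <- .supportStats(imp, imp$relationship)
    data.frame(universe = uname, n = n,
               n_counted = as.integer(imp$counts[["total"]]),
               relationship = imp$relationship,
               statistic = supp$statistic, error_rate = supp$error_rate,
               violations = as.integer(viol),
               candidate = imp$relationship != "none", untestable = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Quadrants forbidden by each relationship class (keys of the test list).
.sparseQuadrantsOf <- function(relationship) {
  switch(relationship,
         lolo = "01", lohi = "00", hilo = "11", hihi = "10",
         eqv = c("01", "10"), opo = c("00", "11"),
         character())
}

## Weakest supporting statistic / worst supporting error rate for the
## assigned class (NA for "none").
.supportStats <- function(imp, relationship) {
  qs <- .sparseQuadrantsOf(relationship)
  if (!length(qs))
    return(list(statistic = NA_real_, error_rate = NA_real_))
  list(
    statistic = min(vapply(qs, function(q) imp$tests[[q]]$statistic,
                           numeric(1L))),
    error_rate = max(vapply(qs, function(q) imp$tests[[q]]$error_rate,
                            numeric(1L)))
  )
}
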