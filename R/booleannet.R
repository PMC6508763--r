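#' Count quadrant occupancy for an ordered gene pair
#'
#' Counts samples in the four quadrants of the discretized joint scatter
#' of two genes. Only samples where both genes are called low or high
#' contribute; intermediate and missing calls in either gene drop the
#' sample from the pair.
#'
#' Quadrants are named by (A state, B state) with 0 = low, 1 = high:
#' `a01` is A low & B high, `a10` is A high & B low.
#'
#' @param ternaryA,ternaryB Equal-length integer code vectors over the
#'   same samples (0 low, 1 intermediate, 2 high, NA missing).
#' @return Named integer vector `c(a00, a01, a10, a11, total)`.
#' @examples
#' A <- c(0L, 0L, 2L, 2L); B <- c(0L, 2L, 0L, 2L)
#' countQuadrants(A, B)  # one sample per quadrant
#' @export
countQuadrants <- function(ternaryA, ternaryB) {
  if (length(ternaryA) != length(ternaryB))
    stop("code vectors differ in length (", length(ternaryA), " vs ",
         length(ternaryB), ")")
  keep <- !is.na(ternaryA) & !is.na(ternaryB) &
    ternaryA != CODE_INT & ternaryB != CODE_INT
  a <- ternaryA[keep] == CODE_HIGH
  b <- ternaryB[keep] == CODE_HIGH
  counts <- c(
    a00 = sum(!a & !b), a01 = sum(!a & b),
    a10 = sum(a & !b), a11 = sum(a & b)
  )
  c(counts, total = sum(counts))
}

## Vectorized sparse-quadrant test over parallel count vectors.
## Returns, per quadrant, observed, expected, statistic and error rate,
## plus the sparse flag under (sMin, eMax). Quadrants with a zero row or
## column margin are untestable and never sparse.
.quadrantStats <- function(a00, a01, a10, a11, sMin = 3, eMax = 0.1) {
  total <- a00 + a01 + a10 + a11
  rlow <- a00 + a01   # samples with A low
  rhigh <- a10 + a11  # samples with A high
  clow <- a00 + a10   # samples with B low
  chigh <- a01 + a11  # samples with B high
  out <- list()
  obs <- list(`00` = a00, `01` = a01, `10` = a10, `11` = a11)
  rmar <- list(`00` = rlow, `01` = rlow, `10` = rhigh, `11` = rhigh)
  cmar <- list(`00` = clow, `01` = chigh, `10` = clow, `11` = chigh)
  for (q in names(obs)) {
    O <- obs[[q]]
    R <- rmar[[q]]
    C <- cmar[[q]]
    testable <- total > 0 & R > 0 & C > 0
    E <- ifelse(testable, R * C / total, NA_real_)
    S <- ifelse(testable, (E - O) / sqrt(E), NA_real_)
    e <- ifelse(testable, (O / R + O / C) / 2, NA_real_)
    out[[q]] <- list(observed = O, expected = E, statistic = S,
                     error_rate = e,
                     sparse = testable & !is.na(S) & S > sMin & e < eMax)
  }
  out
}

#' Sparse-quadrant statistic and error rate for one quadrant
#'
#' For quadrant (A = i, B = j) with observed count `O`, row margin `R`
#' (samples with A = i), column margin `C` (samples with B = j) and
#' pairwise-complete total `n`, computes the expected count under
#' independence `E = R * C / n`, the depletion statistic
#' `S = (E - O) / sqrt(E)` and the error rate
#' `e = (O / R + O / C) / 2`. A quadrant is sparse — evidence for the
#' implication that forbids it — when `S > sMin` and `e < eMax`.
#'
#' A quadrant whose row or column margin is zero is untestable (the gene
#' has no dynamic range on that side) and is reported with NA test values
#' and `sparse = FALSE`.
#'
#' @param counts Named count vector from [countQuadrants()] (or any
#'   vector with elements `a00`, `a01`, `a10`, `a11`).
#' @param quadrant One of `"00"`, `"01"`, `"10"`, `"11"` (A state then
#'   B state, 0 = low, 1 = high).
#' @param sMin,eMax Sparseness thresholds (defaults 3 and 0.1).
#' @return Named list: `observed`, `expected`, `statistic`, `error_rate`,
#'   `sparse`.
#' @examples
#' q <- quadrantTest(c(a00 = 40, a01 = 0, a10 = 30, a11 = 30), "01")
#' q$statistic  # (12 - 0) / sqrt(12) = 3.46
#' @export
quadrantTest <- function(counts, quadrant = c("00", "01", "10", "11"),
                         sMin = 3, eMax = 0.1) {
  quadrant <- match.arg(quadrant)
  counts <- .checkCounts(counts)
  st <- .quadrantStats(counts[["a00"]], counts[["a01"]],
                       counts[["a10"]], counts[["a11"]],
                       sMin = sMin, eMax = eMax)[[quadrant]]
  lapply(st, unname)
}

.checkCounts <- function(counts) {
  need <- c("a00", "a01", "a10", "a11")
  if (!all(need %in% names(counts)))
    stop("counts must be named a00, a01, a10, a11")
  counts <- counts[need]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("quadrant counts must be non-negative integers")
  counts
}

## Vectorized classifier: maps sparse-flag patterns to the six classes.
## Exactly one sparse quadrant gives an asymmetric implication; the two
## diagonal pairs give eqv/opo; anything else (none sparse, an adjacent
## pair, or >= 3 sparse) is "none".
.classifyFromFlags <- function(s00, s01, s10, s11) {
  nsparse <- s00 + s01 + s10 + s11
  rel <- rep("none", length(s00))
  rel[nsparse == 1L & s01] <- "lolo"
  rel[nsparse == 1L & s00] <- "lohi"
  rel[nsparse == 1L & s11] <- "hilo"
  rel[nsparse == 1L & s10] <- "hihi"
  rel[nsparse == 2L & s01 & s10] <- "eqv"
  rel[nsparse == 2L & s00 & s11] <- "opo"
  rel
}

#' Classify an ordered gene pair into a Boolean implication class
#'
#' Tests all four quadrants for sparseness (see [quadrantTest()]) and
#' maps the sparse pattern onto the six implication classes:
#'
#' * sparse A-low/B-high only -> `lolo` (A low implies B low)
#' * sparse A-low/B-low only -> `lohi` (A low implies B high)
#' * sparse A-high/B-high only -> `hilo` (A high implies B low)
#' * sparse A-high/B-low only -> `hihi` (A high implies B high)
#' * both off-diagonal quadrants sparse -> `eqv` (equivalent)
#' * both diagonal quadrants sparse -> `opo` (opposite)
#'
#' Any other pattern — no sparse quadrant, an adjacent (non-diagonal)
#' sparse pair, or three or more sparse quadrants — is `"none"`: the six
#' classes are the only meaningful outcomes and ambiguous patterns are
#' not guessed.
#'
#' @inheritParams quadrantTest
#' @return character(1): one of `"lolo"`, `"lohi"`, `"hilo"`, `"hihi"`,
#'   `"eqv"`, `"opo"`, `"none"`.
#' @examples
#' classifyPair(c(a00 = 40, a01 = 0, a10 = 30, a11 = 30))  # "lolo"
#' classifyPair(c(a00 = 50, a01 = 0, a10 = 0, a11 = 50))   # "eqv"
#' classifyPair(c(a00 = 25, a01 = 25, a10 = 25, a11 = 25)) # "none"
#' @export
classifyPair <- function(counts, sMin = 3, eMax = 0.1) {
  counts <- .checkCounts(counts)
  st <- .quadrantStats(counts[["a00"]], counts[["a01"]],
                       counts[["a10"]], counts[["a11"]],
                       sMin = sMin, eMax = eMax)
  .classifyFromFlags(st[["00"]]$sparse, st[["01"]]$sparse,
                     st[["10"]]$sparse, st[["11"]]$sparse)
}

#' Full Boolean implication analysis of one ordered pair
#'
#' Convenience wrapper returning the quadrant counts, all four quadrant
#' tests and the assigned class for one ordered pair of code vectors.
#'
#' @inheritParams countQuadrants
#' @inheritParams quadrantTest
#' @return Named list: `counts`, `tests` (list of four quadrant-test
#'   results keyed `"00"`..`"11"`), `relationship`.
#' @export
pairImplication <- function(ternaryA, ternaryB, sMin = 3, eMax = 0.1) {
  counts <- countQuadrants(ternaryA, ternaryB)
  st <- .quadrantStats(counts[["a00"]], counts[["a01"]],
                       counts[["a10"]], counts[["a11"]],
                       sMin = sMin, eMax = eMax)
  list(
    counts = counts,
    tests = lapply(st, function(q) lapply(q, unname)),
    relationship = .classifyFromFlags(st[["00"]]$sparse, st[["01"]]$sparse,
                                      st[["10"]]$sparse, st[["11"]]$sparse)
  )
}

#' Build the full Boolean implication network
#'
#' Classifies every ordered pair of dynamic genes in a discretized matrix
#' and stores the pairs whose class is not `"none"`. Quadrant counts for
#' all pairs are accumulated with indicator-matrix products, so the cost
#' is two matrix multiplications per quadrant rather than a loop over
#' pairs.
#'
#' Symmetric classes appear in both orders, and each asymmetric edge is
#' accompanied by its contrapositive (A lolo B is stored with B hihi A),
#' so per-gene relationship counting over ordered pairs is well defined.
#'
#' @param ternary a [TernaryMatrix-class].
#' @param sMin,eMax Sparseness thresholds (defaults 3 and 0.1).
#' @return A [BooleanNetwork-class]. With fewer than 2 dynamic genes an
#'   empty network is returned with a warning.
#' @export
buildNetwork <- function(ternary, sMin = 3, eMax = 0.1) {
  stopifnot(is(ternary, "TernaryMatrix"))
  genes <- dynamicGenes(ternary)
  params <- list(margin = ternary@margin, sMin = sMin, eMax = eMax,
                 minLow = ternary@minLow, minHigh = ternary@minHigh)
  empty <- data.frame(
    geneA = character(), geneB = character(), relationship = character(),
    statistic = numeric(), error_rate = numeric(),
    a00 = integer(), a01 = integer(), a10 = integer(), a11 = integer(),
    stringsAsFactors = FALSE
  )
  if (length(genes) < 2L) {
    warning("fewer than 2 dynamic genes; returning an empty network")
    return(new("BooleanNetwork", edges = empty, genes = genes,
               params = params))
  }
  cd <- codes(ternary)[genes, , drop = FALSE]
  L <- (cd == CODE_LOW)
  H <- (cd == CODE_HIGH)
  L[is.na(L)] <- FALSE
  H[is.na(H)] <- FALSE
  storage.mode(L) <- "double"
  storage.mode(H) <- "double"
  a00 <- L %*% t(L)
  a01 <- L %*% t(H)
  a10 <- H %*% t(L)
  a11 <- H %*% t(H)

  ng <- length(genes)
  off <- which(row(a00) != col(a00))
  st <- .quadrantStats(a00[off], a01[off], a10[off], a11[off],
                       sMin = sMin, eMax = eMax)
  rel <- .classifyFromFlags(st[["00"]]$sparse, st[["01"]]$sparse,
                            st[["10"]]$sparse, st[["11"]]$sparse)
  hit <- rel != "none"
  if (!any(hit)) {
    return(new("BooleanNetwork", edges = empty, genes = genes,
               params = params))
  }
  idx <- off[hit]
  # supporting statistic: weakest sparse quadrant; error rate: worst
  smat <- cbind(st[["00"]]$statistic, st[["01"]]$statistic,
                st[["10"]]$statistic, st[["11"]]$statistic)[hit, , drop = FALSE]
  emat <- cbind(st[["00"]]$error_rate, st[["01"]]$error_rate,
                st[["10"]]$error_rate, st[["11"]]$error_rate)[hit, , drop = FALSE]
  flg <- cbind(st[["00"]]$sparse, st[["01"]]$sparse,
               st[["10"]]$sparse, st[["11"]]$sparse)[hit, , drop = FALSE]
  smat[!flg] <- NA
  emat[!flg] <- NA
  ed <- data.frame(
    geneA = genes[row(a00)[idx]],
    geneB = genes[col(a00)[idx]],
    relationship = rel[hit],
    statistic = apply(smat, 1L, min, na.rm = TRUE),
    error_rate = apply(emat, 1L, max, na.rm = TRUE),
    a00 = as.integer(a00[idx]), a01 = as.integer(a01[idx]),
    a10 = as.integer(a10[idx]), a11 = as.integer(a11[idx]),
    stringsAsFactors = FALSE
  )
  ed <- ed[order(ed$geneA, ed$geneB, method = "radix"), , drop = FALSE]
  rownames(ed) <- NULL
  new("BooleanNetwork", edges = ed, genes = genes, params = params)
}
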