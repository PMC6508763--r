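# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, residual sums computed directly)
# and share no code with the package internals they check.

# Exhaustive breakpoint scan for the rising one-step fit: for every k,
# compute both segment means and the residual SSE by direct summation.
oracleFitStep <- function(values) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  best <- NULL
  for (k in 1:(n - 1)) {
    m1 <- mean(x[1:k])
    m2 <- mean(x[(k + 1):n])
    sse <- sum((x[1:k] - m1)^2) + sum((x[(k + 1):n] - m2)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(k = k, m1 = m1, m2 = m2, sse = sse,
                   threshold = (m1 + m2) / 2)
    }
  }
  best
}

# Brute-force sparse-quadrant classifier from the written-out formulas:
# E = R*C/total, S = (E - O)/sqrt(E), e = (O/R + O/C)/2; sparse iff both
# margins positive, S > sMin and e < eMax; then the pattern lookup.
oracleClassify <- function(a00, a01, a10, a11, sMin = 3, eMax = 0.1) {
  total <- a00 + a01 + a10 + a11
  sparse <- function(O, R, C) {
    if (total == 0 || R == 0 || C == 0) return(FALSE)
    E <- R * C / total
    S <- (E - O) / sqrt(E)
    e <- (O / R + O / C) / 2
    S > sMin && e < eMax
  }
  s00 <- sparse(a00, a00 + a01, a00 + a10)
  s01 <- sparse(a01, a00 + a01, a01 + a11)
  s10 <- sparse(a10, a10 + a11, a00 + a10)
  s11 <- sparse(a11, a10 + a11, a01 + a11)
  pattern <- paste0(as.integer(c(s00, s01, s10, s11)), collapse = "")
  switch(pattern,
         "0100" = "lolo", "1000" = "lohi", "0001" = "hilo",
         "0010" = "hihi", "0110" = "eqv", "1001" = "opo",
         "none")
}

# All non-negative count quadruples with 1 <= total <= maxTotal.
enumerateCountTables <- function(maxTotal) {
  g <- expand.grid(a00 = 0:maxTotal, a01 = 0:maxTotal,
                   a10 = 0:maxTotal, a11 = 0:maxTotal)
  g[rowSums(g) >= 1 & rowSums(g) <= maxTotal, , drop = FALSE]
}

randomCountTable <- function(maxCount = 60) {
  c(a00 = sample(0:maxCount, 1), a01 = sample(0:maxCount, 1),
    a10 = sample(0:maxCount, 1), a11 = sample(0:maxCount, 1))
}

# Small expression matrix with two clean co-expressed bimodal genes and
# one flat gene. 20 samples per mode so the diagonal quadrants can reach
# the sparseness statistic (E = 10, S = 10/sqrt(10) > 3).
toyMatrix <- function() {
  set.seed(99)
  m <- rbind(
    gA = c(rnorm(20, 2, 0.2), rnorm(20, 8, 0.2)),
    gB = c(rnorm(20, 2, 0.2), rnorm(20, 8, 0.2)),
    gF = rnorm(40, 5, 0.1)
  )
  colnames(m) <- sprintf("s%02d", 1:40)
  m
}
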