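#' Specification for the synthetic expression generator
#'
#' Describes a synthetic study: sample count and tissue composition,
#' numbers of dynamic (bimodal) and flat (unimodal) genes, the two mode
#' means on the log2 scale, the within-mode noise, and a list of gene
#' pairs planted with a known Boolean implication class.
#'
#' The defaults emulate RMA-style normalized two-color-free microarray
#' output: dynamic genes switch between a low mode at 4 and a high mode
#' at 9 log2 units with within-mode standard deviation 0.5, so the two
#' modes sit far outside each other's `t +/- 0.5` intermediate band. Flat
#' genes emulate unexpressed or constitutive probes whose residual
#' variation (sd 0.2 by default) stays almost entirely within the band.
#'
#' @param nSamples Number of samples.
#' @param tissueProps Named numeric vector of tissue fractions summing
#'   to 1.
#' @param nDynamic,nFlat Numbers of dynamic and flat genes (planted
#'   pairs claim dynamic genes from this pool).
#' @param lowMean,highMean Mode means, log2 units (defaults 4 and 9).
#' @param noiseSd Within-mode standard deviation for dynamic genes
#'   (default 0.5).
#' @param flatSd Standard deviation of flat genes (default 0.2).
#' @param plantedPairs data.frame with columns `geneA`, `geneB`,
#'   `relationship` (one of lolo, lohi, hilo, hihi, eqv, opo) and
#'   `leakage` (violation probability, in `[0, 0.5)`), or NULL.
#' @param activationProbs Optional gene x tissue matrix of per-tissue
#'   activation probabilities for dynamic genes (rownames = gene ids,
#'   colnames = tissue labels). Genes not listed get probabilities drawn
#'   at random (active in a random subset of tissues at 0.9, 0.1
#'   elsewhere), which creates tissue-driven co-activation blocks.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A validated list of class `"GeneratorSpec"`.
#' @seealso [generateExpression()]
#' @export
generatorSpec <- function(nSamples = 300L,
                          tissueProps = c(root = 0.3, shoot = 0.2,
                                          leaf = 0.3, flower = 0.2),
                          nDynamic = 20L, nFlat = 5L,
                          lowMean = 4, highMean = 9,
                          noiseSd = 0.5, flatSd = 0.2,
                          plantedPairs = NULL,
                          activationProbs = NULL,
                          seed = 1L) {
  spec <- list(nSamples = as.integer(nSamples), tissueProps = tissueProps,
               nDynamic = as.integer(nDynamic), nFlat = as.integer(nFlat),
               lowMean = lowMean, highMean = highMean,
               noiseSd = noiseSd, flatSd = flatSd,
               plantedPairs = plantedPairs,
               activationProbs = activationProbs,
               seed = as.integer(seed))
  class(spec) <- "GeneratorSpec"
  .validateGeneratorSpec(spec)
  spec
}

.validateGeneratorSpec <- function(spec, margin = 0.5) {
  if (spec$nSamples < 1L) stop("nSamples must be positive")
  if (is.null(names(spec$tissueProps)) || any(spec$tissueProps < 0))
    stop("tissueProps must be a named vector of non-negative fractions")
  if (abs(sum(spec$tissueProps) - 1) > 1e-8)
    stop("tissue fractions must sum to 1 (got ", sum(spec$tissueProps), ")")
  if (spec$highMean - spec$lowMean <= 2 * margin + 4 * spec$noiseSd)
    stop("modes not separable: require highMean - lowMean > ",
         "2*margin + 4*noiseSd")
  pp <- spec$plantedPairs
  if (!is.null(pp)) {
    need <- c("geneA", "geneB", "relationship", "leakage")
    if (!is.data.frame(pp) || !all(need %in% names(pp)))
      stop("plantedPairs needs columns geneA, geneB, relationship, leakage")
    if (!all(pp$relationship %in% RELATIONSHIP_LEVELS))
      stop("unknown planted relationship label(s)")
    if (any(pp$leakage < 0 | pp$leakage >= 0.5))
      stop("leakage must be in [0, 0.5)")
    claimed <- c(pp$geneA, pp$geneB)
    if (anyDuplicated(claimed))
      stop("a gene may appear in at most one planted pair ",
           "(overlapping constraints could contradict each other)")
    if (length(unique(claimed)) > spec$nDynamic)
      stop("planted pairs claim more genes than nDynamic provides")
  }
  invisible(spec)
}

#' Generate a synthetic expression study with known ground truth
#'
#' Draws a probe x sample log2 expression matrix, a sample annotation
#' table, and a ground-truth table, reproducibly from the spec's seed.
#'
#' Each sample gets a tissue by the spec's proportions (largest-remainder
#' rounding, then shuffled). Each dynamic gene has a per-tissue
#' activation probability; its binary state per sample is Bernoulli in
#' that probability, giving bimodal expression with tissue-driven
#' co-activation. For each planted pair, gene B's states are overwritten
#' to satisfy the planted implication given gene A's states, except that
#' each sample *covered by the implication* independently violates it
#' with probability `leakage`, the violation landing in the quadrant the
#' relationship forbids — so leakage is the direct analogue of the
#' classifier's error rate. Expression is the state's mode mean plus
#' Gaussian noise; flat genes are unimodal Gaussian around a mid-scale
#' mean.
#'
#' @param spec a [generatorSpec()].
#' @return Named list: `matrix` (numeric, genes x samples), `annotation`
#'   (data.frame `sample_id`, `tissue`, `accession`), `truth`
#'   (data.frame per gene: `gene`, `kind` ("dynamic"/"flat"),
#'   `planted_pair`, `planted_relationship`, `leakage`), and `states`
#'   (logical genes x samples matrix of the true binary states, NA for
#'   flat genes).
#' @export
generateExpression <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  .validateGeneratorSpec(spec)
  set.seed(spec$seed)
  n <- spec$nSamples
  tissues <- names(spec$tissueProps)

  # largest-remainder apportionment of samples to tissues, then shuffle
  quota <- spec$tissueProps * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  tissue_of <- sample(rep(tissues, times = base))
  sample_ids <- sprintf("S%04d", seq_len(n))

  dyn_ids <- if (spec$nDynamic) sprintf("DG%03d", seq_len(spec$nDynamic)) else character()
  flat_ids <- if (spec$nFlat) sprintf("FG%03d", seq_len(spec$nFlat)) else character()
  pp <- spec$plantedPairs
  # gene names given via planted pairs or activationProbs rownames claim
  # the first dynamic ids
  named <- unique(c(if (!is.null(pp)) c(pp$geneA, pp$geneB),
                    rownames(spec$activationProbs)))
  if (length(named)) {
    if (length(named) > length(dyn_ids))
      stop("named genes exceed nDynamic")
    dyn_ids[seq_along(named)] <- named
  }

  # per-gene per-tissue activation probabilities
  probs <- matrix(NA_real_, length(dyn_ids), length(tissues),
                  dimnames = list(dyn_ids, tissues))
  if (!is.null(spec$activationProbs)) {
    given <- spec$activationProbs
    keep <- intersect(rownames(given), dyn_ids)
    probs[keep, colnames(given)] <- given[keep, , drop = FALSE]
  }
  planted_genes <- if (is.null(pp)) character() else unique(c(pp$geneA, pp$geneB))
  for (g in dyn_ids) {
    if (!anyNA(probs[g, ])) next
    if (g %in% planted_genes) {
      # balanced antecedent: leakage then maps directly onto the
      # classifier's error rate, independent of tissue composition
      probs[g, ] <- 0.5
      next
    }
    on_tissues <- runif(length(tissues)) < 0.5
    if (!any(on_tissues)) on_tissues[sample(length(tissues), 1L)] <- TRUE
    probs[g, ] <- ifelse(on_tissues, 0.9, 0.1)
  }

  # binary states: tissue-driven Bernoulli draws
  states <- matrix(NA, length(dyn_ids), n,
                   dimnames = list(dyn_ids, sample_ids))
  for (g in dyn_ids)
    states[g, ] <- runif(n) < probs[g, tissue_of]

  # planted pairs override B's states given A's
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      a <- states[pp$geneA[i], ]
      states[pp$geneB[i], ] <- .plantStates(a, pp$relationship[i],
                                            pp$leakage[i])
    }
  }

  gene_ids <- c(dyn_ids, flat_ids)
  mat <- matrix(NA_real_, length(gene_ids), n,
                dimnames = list(gene_ids, sample_ids))
  for (g in dyn_ids) {
    mu <- ifelse(states[g, ], spec$highMean, spec$lowMean)
    mat[g, ] <- mu + rnorm(n, 0, spec$noiseSd)
  }
  flat_means <- runif(length(flat_ids), spec$lowMean, spec$highMean)
  for (i in seq_along(flat_ids))
    mat[flat_ids[i], ] <- rnorm(n, flat_means[i], spec$flatSd)

  truth <- data.frame(
    gene = gene_ids,
    kind = c(rep("dynamic", length(dyn_ids)), rep("flat", length(flat_ids))),
    planted_pair = NA_character_, planted_relationship = NA_character_,
    leakage = NA_real_, stringsAsFactors = FALSE
  )
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      for (g in c(pp$geneA[i], pp$geneB[i])) {
        j <- match(g, truth$gene)
        truth$planted_pair[j] <- paste(pp$geneA[i], pp$geneB[i], sep = "~")
        truth$planted_relationship[j] <- pp$relationship[i]
        truth$leakage[j] <- pp$leakage[i]
      }
    }
  }

  all_states <- matrix(NA, length(gene_ids), n,
                       dimnames = list(gene_ids, sample_ids))
  all_states[dyn_ids, ] <- states

  list(
    matrix = mat,
    annotation = data.frame(sample_id = sample_ids, tissue = tissue_of,
                            accession = "synthetic",
                            stringsAsFactors = FALSE),
    truth = truth,
    states = all_states
  )
}

## Gene B states satisfying `relationship` given A's states, with each
## covered sample violating independently with probability `leakage`
## (violations land in the forbidden quadrant). Samples not covered by an
## asymmetric implication (e.g. A high under lolo) are drawn fair-coin so
## the permitted quadrants stay populated.
.plantStates <- function(aHigh, relationship, leakage) {
  n <- length(aHigh)
  b <- runif(n) < 0.5
  viol <- runif(n) < leakage
  switch(relationship,
    lolo = { b[!aHigh] <- viol[!aHigh] },          # A low => B low
    lohi = { b[!aHigh] <- !viol[!aHigh] },         # A low => B high
    hilo = { b[aHigh] <- viol[aHigh] },            # A high => B low
    hihi = { b[aHigh] <- !viol[aHigh] },           # A high => B high
    eqv  = { b <- xor(aHigh, viol) },              # B tracks A
    opo  = { b <- xor(!aHigh, viol) },             # B mirrors A
    stop("unknown relationship: ", relationship)
  )
  b
}

#' Write a directory of files with planted byte-identical duplicates
#'
#' Generates `nFiles` small files of random bytes; for each requested
#' group size, that many files share identical content. The manifest
#' records the planted groups, so [findDuplicates()] can be checked
#' against ground truth. Regeneration with the same seed is
#' byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param nFiles Total number of files.
#' @param dupGroups Integer vector of duplicate group sizes (each >= 2);
#'   their sum must not exceed `nFiles`.
#' @param seed Integer seed.
#' @param fileSize Bytes per file (default 256).
#' @return Named list: `paths` (all files written), `manifest`
#'   (data.frame `path`, `group`; group 0 = unique content).
#' @export
generateDuplicateFixture <- function(dir, nFiles, dupGroups = integer(),
                                     seed = 1L, fileSize = 256L) {
  stopifnot(nFiles >= 0, all(dupGroups >= 2) || !length(dupGroups))
  if (sum(dupGroups) > nFiles)
    stop("duplicate groups claim more files than nFiles")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- file.path(dir, sprintf("sample_%03d.CEL", seq_len(nFiles)))
  group <- integer(nFiles)
  slot_ <- 1L
  for (gi in seq_along(dupGroups)) {
    members <- seq.int(slot_, length.out = dupGroups[gi])
    group[members] <- gi
    slot_ <- slot_ + dupGroups[gi]
  }
  content_for <- function(idx) {
    as.raw(sample.int(256L, fileSize, replace = TRUE) - 1L)
  }
  # one content draw per duplicate group, one per unique file
  group_content <- lapply(seq_along(dupGroups), content_for)
  for (i in seq_len(nFiles)) {
    bytes <- if (group[i] > 0L) group_content[[group[i]]] else content_for(i)
    writeBin(bytes, paths[i])
  }
  list(paths = paths,
       manifest = data.frame(path = paths, group = group,
                             stringsAsFactors = FALSE))
}
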