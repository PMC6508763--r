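#' Per-gene relationship counts in a Boolean implication network
#'
#' For each gene A in the network's universe, counts its partners X by
#' the relationship type of the ordered pair (A, X). Because the network
#' stores ordered pairs (symmetric classes in both orders, asymmetric
#' classes with their contrapositives), each gene's row is its complete
#' relationship profile: a gene with one equivalent partner has `eqv` 1,
#' and the partner does too.
#'
#' @param network a [BooleanNetwork-class].
#' @return data.frame with columns `probe_id`, `lolo`, `lohi`, `hilo`,
#'   `hihi`, `eqv`, `opo`; one row per network gene (all zero for genes
#'   with no classified partner).
#' @export
countRelationships <- function(network) {
  stopifnot(is(network, "BooleanNetwork"))
  genes <- networkGenes(network)
  ed <- edges(network)
  tab <- table(factor(ed$geneA, levels = genes),
               factor(ed$relationship, levels = RELATIONSHIP_LEVELS))
  out <- data.frame(probe_id = genes, stringsAsFactors = FALSE)
  for (r in RELATIONSHIP_LEVELS) out[[r]] <- as.integer(tab[, r])
  rownames(out) <- NULL
  out
}

#' Head-to-head comparison of two Boolean implication networks
#'
#' Compares per-gene relationship counts between two networks built over
#' a shared identifier space — e.g. the same platform processed with two
#' normalization schemes. Probes are matched by exact shared identifier;
#' a probe present in only one table gets zero counts in the other. For
#' each of the six relationship types the paired per-probe counts are
#' compared with a two-sided Wilcoxon signed-rank test (zero-difference
#' pairs dropped), and log2(count + 1) pairs are returned for a log-log
#' scatter.
#'
#' The sign convention is Y minus X: a positive `median_diff_sign` means
#' network Y found more relationships of that type.
#'
#' @param tableX,tableY data.frames from [countRelationships()] (X is
#'   the reference network, Y the comparison network).
#' @param alpha Significance level for the `significant` flag
#'   (default 0.001).
#' @return Named list: `summary` (data.frame per relationship type with
#'   `n_probes`, `n_nonzero_pairs`, `total_x`, `total_y`, `p_value`,
#'   `median_diff_sign`, `significant`) and `scatter` (data.frame
#'   `probe_id`, `relationship`, `log2_x`, `log2_y`).
#' @export
compareNetworks <- function(tableX, tableY, alpha = 0.001) {
  need <- c("probe_id", RELATIONSHIP_LEVELS)
  stopifnot(all(need %in% names(tableX)), all(need %in% names(tableY)))
  shared <- union(tableX$probe_id, tableY$probe_id)
  common <- intersect(tableX$probe_id, tableY$probe_id)
  if (!length(common))
    stop("no shared probe ids between the two count tables")
  shared <- sort(shared, method = "radix")
  xi <- match(shared, tableX$probe_id)
  yi <- match(shared, tableY$probe_id)

  summary_rows <- list()
  scatter_rows <- list()
  for (r in RELATIONSHIP_LEVELS) {
    cx <- ifelse(is.na(xi), 0L, tableX[[r]][xi])
    cy <- ifelse(is.na(yi), 0L, tableY[[r]][yi])
    d <- cy - cx
    nz <- d != 0L
    p <- if (any(nz)) {
      suppressWarnings(
        stats::wilcox.test(cy, cx, paired = TRUE, exact = FALSE)$p.value
      )
    } else NA_real_
    med <- stats::median(d[nz])
    summary_rows[[r]] <- data.frame(
      relationship = r,
      n_probes = length(shared),
      n_nonzero_pairs = sum(nz),
      total_x = sum(cx), total_y = sum(cy),
      p_value = p,
      median_diff_sign = if (!any(nz)) 0L else as.integer(sign(med)),
      significant = isTRUE(!is.na(p) && p < alpha),
      stringsAsFactors = FALSE
    )
    scatter_rows[[r]] <- data.frame(
      probe_id = shared, relationship = r,
      log2_x = log2(cx + 1), log2_y = log2(cy + 1),
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, summary_rows)
  scatter <- do.call(rbind, scatter_rows)
  rownames(summary) <- rownames(scatter) <- NULL
  list(summary = summary, scatter = scatter)
}
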