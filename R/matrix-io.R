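#' Read a normalized expression matrix
#'
#' Reads a tab-delimited probe x sample matrix of normalized log2
#' expression values. The first row is a header of sample ids; the first
#' column holds probe ids. The `pcl` dialect additionally skips the
#' standard second header row (EWEIGHT) and drops the GWEIGHT/description
#' columns that follow the id column.
#'
#' Cells equal to `NA`, `na` or the empty string become missing values.
#' Ragged rows and duplicate probe ids are errors, not warnings: a
#' malformed matrix silently truncated is worse than no matrix.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (plain matrix) or `"pcl"`.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames; missing cells are `NA`.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' writeExpressionMatrix(m, tmp)
#' m2 <- readExpressionMatrix(tmp)
#' stopifnot(all.equal(m, m2))
#' @export
readExpressionMatrix <- function(path, dialect = c("tsv", "pcl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty matrix file: ", path)
  # sentinel keeps trailing empty fields that strsplit would drop
  fields <- strsplit(paste0(lines, "\x1e"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x1e$", "", f[length(f)])
    f
  })
  header <- fields[[1L]]
  skip_cols <- 1L
  if (dialect == "pcl") {
    # PCL: ID <tab> NAME <tab> GWEIGHT <tab> samples...; row 2 is EWEIGHT
    extra <- which(toupper(header) %in% c("NAME", "GWEIGHT", "DESCRIPTION"))
    skip_cols <- if (length(extra)) max(extra) else 1L
    if (length(fields) >= 2L &&
        toupper(fields[[2L]][1L]) %in% c("EWEIGHT", "EWEIGHTS"))
      fields <- fields[-2L]
  }
  sample_ids <- header[-seq_len(skip_cols)]
  if (!length(sample_ids)) stop("no sample columns in ", path)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header of ", path)
  body <- fields[-1L]
  if (!length(body)) stop("matrix has a header but no data rows: ", path)
  ncol_expect <- skip_cols + length(sample_ids)
  nf <- lengths(body)
  if (any(nf != ncol_expect)) {
    bad <- which(nf != ncol_expect)[1L]
    stop(sprintf(
      "ragged row: line %d has %d fields, expected %d (file %s)",
      bad + 1L + (dialect == "pcl"), nf[bad], ncol_expect, path))
  }
  probe_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  cells <- vapply(body, function(f) f[-seq_len(skip_cols)],
                  character(length(sample_ids)))
  cells <- if (is.matrix(cells)) t(cells) else matrix(cells, ncol = 1L)
  cells[cells %in% c("NA", "na", "")] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- !is.na(cells) & is.na(values)
  if (any(bad_cell))
    stop("non-numeric cell(s), e.g. '", cells[which(bad_cell)[1L]],
         "' in ", path)
  if (any(is.infinite(values)))
    stop("non-finite expression value(s) in ", path)
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [readExpressionMatrix()] for the `tsv` dialect; the round
#' trip preserves values to within 1e-9 and id order exactly.
#'
#' @param x Numeric matrix with probe/sample dimnames.
#' @param path Output path.
#' @param id_header Label for the id column (default `"ProbeID"`).
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path, id_header = "ProbeID") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# boolimpl %s expression matrix: %d probes x %d samples",
                     as.character(utils::packageVersion("boolimpl")),
                     nrow(x), ncol(x)), con)
  writeLines(paste(c(id_header, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v) {
    s <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    s[is.na(v)] <- "NA"
    paste(s, collapse = "\t")
  })
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-delimited with header columns `sample_id`, `tissue`, `accession`
#' (accession may be missing or empty).
#'
#' @param path Path to the file.
#' @return data.frame with character columns `sample_id`, `tissue`,
#'   `accession`.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, comment.char = "#")
  need <- c("sample_id", "tissue")
  if (!all(need %in% names(df)))
    stop("annotation must have columns sample_id and tissue: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (is.null(df$accession)) df$accession <- ""
  df[c("sample_id", "tissue", "accession")]
}

#' Piecewise log transform for RNA-seq TPM values
#'
#' Maps a non-negative TPM abundance to the log2 expression scale used for
#' Boolean analysis: `log2(tpm)` when `tpm > 1` and `tpm - 1` when
#' `tpm < 1`. Both branches equal 0 at `tpm = 1`, so the transform is
#' continuous and monotonically non-decreasing on `[0, Inf)`; values below
#' 1 TPM are compressed into `[-1, 0)` instead of diverging to `-Inf`.
#'
#' @param tpm Numeric vector of non-negative TPM values (NA allowed).
#' @return Numeric vector of transformed values.
#' @examples
#' transformTPM(c(0, 0.25, 1, 8))  # -1 -0.75 0 3
#' @export
transformTPM <- function(tpm) {
  if (!is.numeric(tpm)) stop("tpm must be numeric")
  if (any(tpm < 0, na.rm = TRUE)) stop("tpm values must be non-negative")
  out <- tpm - 1
  hi <- !is.na(tpm) & tpm > 1
  out[hi] <- log2(tpm[hi])
  out
}

#' Write a network's relationships as a tab-delimited edge list
#'
#' One row per classified ordered pair, columns `geneA`, `geneB`,
#' `relationship`, `statistic`, `error_rate`, `a00`, `a01`, `a10`, `a11`,
#' in lexicographic order by geneA then geneB. Comment lines (prefix `#`)
#' record the build parameters.
#'
#' @param network a [BooleanNetwork-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [readEdgeList()]
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "BooleanNetwork"))
  ed <- edges(network)
  ed <- ed[order(ed$geneA, ed$geneB, method = "radix"), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  p <- network@params
  writeLines(c(
    sprintf("# boolimpl %s edge list", as.character(utils::packageVersion("boolimpl"))),
    sprintf("# margin=%g sMin=%g eMax=%g minLow=%d minHigh=%d genes=%d",
            p$margin, p$sMin, p$eMax, p$minLow, p$minHigh,
            length(networkGenes(network)))
  ), con)
  utils::write.table(ed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an edge list written by [writeEdgeList()]
#'
#' @param path Path to the file.
#' @return data.frame with the edge-list columns.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = c(geneA = "character",
                                         geneB = "character"))
  need <- c("geneA", "geneB", "relationship")
  if (!all(need %in% names(df)))
    stop("not an edge list (missing geneA/geneB/relationship): ", path)
  if (nrow(df) && !all(df$relationship %in% RELATIONSHIP_LEVELS))
    stop("unknown relationship label(s) in ", path)
  df
}
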