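#' Content-hash a set of files
#'
#' Computes one digest per file, treating each file as opaque bytes and
#' streaming it (no whole-file memory requirement). Byte-identical files
#' get identical digests regardless of their names; a single changed byte
#' changes the digest.
#'
#' md5 is the default: for catching accidental re-submissions of the same
#' array scan its (cryptographic) weaknesses are irrelevant, but sha256
#' is offered for the cautious.
#'
#' @param paths Character vector of file paths.
#' @param algorithm `"md5"` or `"sha256"`.
#' @return Named character vector: digest per path (names are the input
#'   paths, in input order). Empty input gives an empty vector.
#' @export
hashFiles <- function(paths, algorithm = c("md5", "sha256")) {
  algorithm <- match.arg(algorithm)
  if (!length(paths)) return(setNames(character(), character()))
  bad <- paths[!file.exists(paths) | dir.exists(paths)]
  if (length(bad))
    stop("unreadable or missing file(s): ", paste(bad, collapse = ", "))
  dg <- if (algorithm == "md5") {
    unname(tools::md5sum(paths))
  } else {
    vapply(paths, function(p) digest::digest(file = p, algo = "sha256"),
           character(1L), USE.NAMES = FALSE)
  }
  if (anyNA(dg))
    stop("failed to hash file(s): ", paste(paths[is.na(dg)], collapse = ", "))
  setNames(dg, paths)
}

#' Find byte-identical files under different names
#'
#' Groups files by content digest and reports every group of two or more.
#' A collection of array scans assembled from many submissions can
#' contain the same file deposited twice under different names; such
#' duplicates bias any downstream meta-analysis and should be removed
#' before building a network.
#'
#' `duplicate_count` counts *redundant copies* — group size minus one,
#' summed over groups — so removing `duplicate_count` files from the
#' collection leaves `unique_count` distinct files, and
#' `unique_count + duplicate_count` always equals the number of files
#' scanned.
#'
#' @inheritParams hashFiles
#' @return Named list: `groups` (list of lists, each with `digest` and
#'   lexicographically sorted `paths`, ordered by digest),
#'   `duplicate_count`, `unique_count`, `n_files`, `algorithm`.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines("a", file.path(d, "x1.CEL"))
#' writeLines("a", file.path(d, "x2.CEL"))
#' writeLines("b", file.path(d, "y.CEL"))
#' rep <- findDuplicates(list.files(d, full.names = TRUE))
#' rep$duplicate_count  # 1 redundant copy
#' rep$unique_count     # 2 distinct files
#' @export
findDuplicates <- function(paths, algorithm = c("md5", "sha256")) {
  algorithm <- match.arg(algorithm)
  digests <- hashFiles(paths, algorithm)
  by_digest <- split(names(digests), digests)
  dup <- by_digest[lengths(by_digest) >= 2L]
  dup <- dup[order(names(dup), method = "radix")]
  groups <- lapply(names(dup), function(dg) {
    list(digest = dg, paths = sort(dup[[dg]], method = "radix"))
  })
  duplicate_count <- sum(lengths(dup) - 1L)
  list(
    groups = groups,
    duplicate_count = as.integer(duplicate_count),
    unique_count = as.integer(length(paths) - duplicate_count),
    n_files = length(paths),
    algorithm = algorithm
  )
}

#' Write a duplicate report as tab-delimited text
#'
#' Columns: `digest`, `group_size`, `member_paths` (semicolon-joined).
#'
#' @param report List from [findDuplicates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDuplicateReport <- function(report, path) {
  df <- data.frame(
    digest = vapply(report$groups, `[[`, character(1L), "digest"),
    group_size = vapply(report$groups, function(g) length(g$paths),
                        integer(1L)),
    member_paths = vapply(report$groups, function(g)
      paste(g$paths, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d files scanned (%s): %d redundant, %d unique",
                     report$n_files, report$algorithm,
                     report$duplicate_count, report$unique_count), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
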