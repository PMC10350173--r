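#' Region-by-subject c-Fos count matrix
#'
#' The root input of the pipeline: a matrix of non-negative integer c-Fos
#' positive-cell counts with brain regions in rows (Allen-atlas style
#' acronyms) and subjects in columns, together with per-subject metadata
#' (phenotype such as AGG/NON, sex, virus group).
#'
#' @param counts numeric matrix of non-negative integers, regions x subjects,
#'   with rownames (region acronyms) and colnames (subject ids).
#' @param subjects data.frame with one row per subject. Must contain an `id`
#'   column matching `colnames(counts)`; typically also `phenotype`, `sex`,
#'   `virus_group`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `region_ids`, `subjects`.
#' @export
count_matrix <- function(counts, subjects) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have region rownames and subject colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate region acronyms in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate subject ids in `counts`")
  if (!is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  if (!"id" %in% names(subjects)) stop("`subjects` must have an `id` column")
  if (anyDuplicated(subjects$id)) stop("duplicate subject ids in `subjects`")
  if (!setequal(subjects$id, colnames(counts)) ||
      nrow(subjects) != ncol(counts))
    stop("subject metadata ids must match count matrix columns")
  subjects <- subjects[match(colnames(counts), subjects$id), , drop = FALSE]
  rownames(subjects) <- NULL
  structure(
    list(counts = counts,
         region_ids = rownames(counts),
         subjects = subjects),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d regions x %d subjects\n",
              nrow(x$counts), ncol(x$counts)))
  meta <- setdiff(names(x$subjects), "id")
  for (m in meta) {
    tab <- table(x$subjects[[m]], useNA = "no")
    if (length(tab) <= 8)
      cat(sprintf("  %s: %s\n", m,
                  paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by subject metadata
#'
#' @param x a [count_matrix()].
#' @param subjects character vector of subject ids, logical vector over
#'   subjects, or NULL (keep all).
#' @param regions character vector of region ids or NULL.
#' @return A `count_matrix` restricted to the requested subjects/regions.
#' @export
subset_counts <- function(x, subjects = NULL, regions = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  keep_s <- if (is.null(subjects)) x$subjects$id
            else if (is.logical(subjects)) x$subjects$id[subjects]
            else subjects
  if (!all(keep_s %in% x$subjects$id)) stop("unknown subject ids")
  keep_r <- regions %||% x$region_ids
  if (!all(keep_r %in% x$region_ids)) stop("unknown region ids")
  count_matrix(x$counts[keep_r, keep_s, drop = FALSE],
               x$subjects[match(keep_s, x$subjects$id), , drop = FALSE])
}

#' Write a count matrix to delimited text
#'
#' Counts go to a tab-separated table with a `region` first column and one
#' column per subject; metadata to a second tab-separated table.
#'
#' @param x a [count_matrix()].
#' @param counts_file,metadata_file output paths.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, counts_file, metadata_file) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(region = x$region_ids, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$subjects, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a count matrix from delimited text
#'
#' @param counts_file,metadata_file paths written by [write_count_matrix()].
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_file, metadata_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  subjects <- utils::read.delim(metadata_file, stringsAsFactors = FALSE,
                                colClasses = c(id = "character"))
  count_matrix(counts, subjects)
}
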