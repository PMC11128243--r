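#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two labelings agree (same cluster in
#' both, or different cluster in both). Used to score how well a dendrogram
#' cut recovers known region labels.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# Read a TSV with '#'-prefixed comment lines ignored; UTF-8 throughout.
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_file <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# Matrix samples x features from a long table.
long_to_matrix <- function(df, row_col, col_col, value_col) {
  rows <- sort(unique(df[[row_col]]))
  cols <- sort(unique(df[[col_col]]))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(df[[row_col]], rows), match(df[[col_col]], cols))] <-
    df[[value_col]]
  m
}
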