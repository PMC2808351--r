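#' Clone-by-replicate log-ratio matrix
#'
#' Container for one pairwise two-color comparison: rows are spotted cDNA
#' clones, columns are replicate hybridizations (biological replicates and
#' their dye swaps, orientation-corrected so that every column shares one
#' sign convention).  Missing spots are `NA`; the presence mask is implicit
#' in the non-`NA` pattern.
#'
#' @param values Numeric matrix of log2 ratios; `NA` marks a missing spot.
#' @param clone_ids Character vector of unique clone identifiers, one per
#'   row.  Defaults to `rownames(values)`.
#' @param orientation Label naming the condition in which a positive log
#'   ratio means higher expression.
#' @return An object of class `ratio_matrix` with elements `values`
#'   (rownames set to the clone ids) and `orientation`.
#' @export
ratio_matrix <- function(values, clone_ids = rownames(values),
                         orientation = "comparison") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(clone_ids)) {
    stop("clone_ids are required (or set rownames on `values`)")
  }
  clone_ids <- as.character(clone_ids)
  if (length(clone_ids) != nrow(values)) {
    stop("length(clone_ids) must equal nrow(values)")
  }
  if (anyDuplicated(clone_ids)) {
    stop("clone_ids must be unique")
  }
  if (ncol(values) < 2L) {
    stop("a ratio matrix needs at least 2 replicate columns")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("present values must be finite (use NA for missing spots)")
  }
  rownames(values) <- clone_ids
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  }
  structure(list(values = values, orientation = as.character(orientation)),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("ratio_matrix: %d clones x %d replicates (orientation: %s)\n",
              nrow(v), ncol(v), x$orientation))
  cat(sprintf("  missing spots: %d (%.1f%%)\n",
              sum(is.na(v)), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

#' Per-clone count of present replicates
#'
#' @param matrix A [ratio_matrix()].
#' @return Named integer vector of present (non-`NA`) replicate counts.
#' @export
n_present <- function(matrix) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  rowSums(!is.na(matrix$values))
}

#' Write / read a ratio matrix as TSV
#'
#' The on-disk form is `clone_id` plus one column per replicate, with the
#' literal string `NA` marking a missing spot.
#'
#' @param matrix A [ratio_matrix()].
#' @param path File path.
#' @return `write_ratio_tsv()` returns `path` invisibly;
#'   `read_ratio_tsv()` returns a [ratio_matrix()].
#' @export
write_ratio_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  df <- data.frame(clone_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_ratio_tsv
#' @param orientation Orientation label to attach on read.
#' @export
read_ratio_tsv <- function(path, orientation = "comparison") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"clone_id" %in% names(df)) {
    stop("ratio TSV must have a clone_id column: ", path)
  }
  vals <- as.matrix(df[setdiff(names(df), "clone_id")])
  ratio_matrix(vals, clone_ids = df$clone_id, orientation = orientation)
}
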