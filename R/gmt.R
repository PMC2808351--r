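#' Read a GMT gene-set file
#'
#' GMT is the tab-delimited gene-set format: one set per line, with the set
#' name, a free-text description, and then the member gene identifiers.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (the gene sets).  Descriptions
#'   are kept in the `"descriptions"` attribute, parallel to the list.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("malformed GMT line(s) ", paste(bad, collapse = ", "),
         " in ", path, ": need at least name and description")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <-
    setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled from the `"descriptions"` attribute of `sets` if present,
#'   else empty strings).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
  }
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
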