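#' Resolve each clone to its best-matching gene
#'
#' Raw mapping rows list zero, one, or several candidate genes per clone
#' with a numeric match score (e.g. a BLAST bit score).  Each clone keeps
#' exactly its highest-scoring candidate; ties are broken by the
#' lexicographically smallest gene id so resolution is deterministic.
#' Clones with no candidate gene are kept and marked unmapped.
#'
#' @param rows Data.frame with columns `clone_id`, `gene_id` (`NA` or empty
#'   string when the row records an unmapped clone), `score` (non-negative;
#'   may be `NA` for unmapped rows), and optionally `has_sequence`.
#' @return A `clone_mapping` object: a data.frame with one row per clone
#'   (`clone_id`, `gene_id` — `NA` if unmapped — and `score`), plus a
#'   `has_sequence` column when the input carried one.
#' @export
resolve_best_match <- function(rows) {
  required <- c("clone_id", "gene_id", "score")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols)) {
    stop("mapping rows lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows$gene_id[!is.na(rows$gene_id) & rows$gene_id == ""] <- NA_character_
  if (!is.numeric(rows$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(rows$score))) &
                   !is.na(rows$score))
    if (length(bad)) {
      stop("malformed mapping row(s) at line ",
           paste(head(bad, 5), collapse = ", "), ": non-numeric score")
    }
    rows$score <- as.numeric(rows$score)
  }
  neg <- which(!is.na(rows$score) & rows$score < 0)
  if (length(neg)) {
    stop("negative match score at row(s) ",
         paste(head(neg, 5), collapse = ", "))
  }
  has_seq_col <- "has_sequence" %in% names(rows)

  cand <- rows[!is.na(rows$gene_id), , drop = FALSE]
  if (any(is.na(cand$score))) {
    stop("candidate rows with a gene_id must carry a numeric score")
  }
  ## highest score first, then lexicographically smallest gene id
  cand <- cand[order(cand$clone_id, -cand$score, cand$gene_id), , drop = FALSE]
  best <- cand[!duplicated(cand$clone_id), , drop = FALSE]

  all_clones <- unique(rows$clone_id)
  out <- data.frame(clone_id = all_clones, stringsAsFactors = FALSE)
  idx <- match(all_clones, best$clone_id)
  out$gene_id <- best$gene_id[idx]
  out$score <- best$score[idx]
  if (has_seq_col) {
    seq_by_clone <- tapply(rows$has_sequence, rows$clone_id, any)
    out$has_sequence <- as.logical(seq_by_clone[all_clones])
  }
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clone_mapping", "data.frame")
  out
}

#' Collapse a clone list to a non-redundant gene set
#'
#' Maps each clone to its resolved gene and removes duplicate gene ids;
#' unmapped clones contribute nothing.  This is the clone-list-to-gene-list
#' step that turns a differential clone list C into its gene set G.
#'
#' @param clone_ids Character vector of clone ids (a clone list).
#' @param mapping A [resolve_best_match()] result.
#' @return Sorted character vector of unique gene ids.
#' @export
collapse_to_genes <- function(clone_ids, mapping) {
  stopifnot(inherits(mapping, "clone_mapping"))
  clone_ids <- as.character(clone_ids)
  idx <- match(clone_ids, mapping$clone_id)
  if (anyNA(idx)) {
    offenders <- unique(clone_ids[is.na(idx)])
    stop("unknown clone id(s): ", paste(head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) sprintf(" (and %d more)",
                                             length(offenders) - 10) else "")
  }
  genes <- mapping$gene_id[idx]
  sort(unique(genes[!is.na(genes)]))
}

#' Summarize a clone-to-gene mapping
#'
#' Reports the mapping funnel: total clones, clones with a retrievable
#' sequence, clones with a best-matching gene, unique genes, and the mean
#' clones per mapped gene.  Formatting helpers reproduce the conventional
#' display: percentages as round-half-up integers and redundancy to one
#' decimal; full precision is retained in the object.
#'
#' @param mapping A [resolve_best_match()] result.
#' @param raw_rows The raw mapping rows the mapping was resolved from
#'   (used for the sequence/no-sequence distinction when present).
#' @return A `mapping_summary` object with fields `n_clones`,
#'   `n_with_sequence`, `n_mapped`, `n_genes`, `clones_per_gene`.
#' @export
mapping_summary <- function(mapping, raw_rows = NULL) {
  stopifnot(inherits(mapping, "clone_mapping"))
  n_clones <- nrow(mapping)
  n_mapped <- sum(!is.na(mapping$gene_id))
  if ("has_sequence" %in% names(mapping)) {
    n_with_sequence <- sum(mapping$has_sequence, na.rm = TRUE)
  } else if (!is.null(raw_rows) && "has_sequence" %in% names(raw_rows)) {
    n_with_sequence <- sum(tapply(raw_rows$has_sequence,
                                  raw_rows$clone_id, any))
  } else {
    n_with_sequence <- n_mapped  # no sequence info: mapped implies sequence
  }
  n_genes <- length(unique(mapping$gene_id[!is.na(mapping$gene_id)]))
  mapping_summary_counts(n_clones, n_with_sequence, n_mapped, n_genes)
}

#' @rdname mapping_summary
#' @param n_clones,n_with_sequence,n_mapped,n_genes Direct counts, for
#'   summarizing a mapping known only through its published totals.
#' @export
mapping_summary_counts <- function(n_clones, n_with_sequence, n_mapped,
                                   n_genes) {
  stopifnot(n_mapped <= n_with_sequence, n_with_sequence <= n_clones)
  structure(list(
    n_clones = as.integer(n_clones),
    n_with_sequence = as.integer(n_with_sequence),
    n_mapped = as.integer(n_mapped),
    n_genes = as.integer(n_genes),
    clones_per_gene = if (n_genes > 0) n_mapped / n_genes else NA_real_
  ), class = "mapping_summary")
}

## round-half-up display helpers (round() half-to-even would print 2.4 for
## 2.45 and 85% for 85.5%; the conventional display rounds half up)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @rdname mapping_summary
#' @param x A `mapping_summary`.
#' @param ... Unused.
#' @export
format.mapping_summary <- function(x, ...) {
  pct_seq <- if (x$n_clones > 0)
    round_half_up(100 * x$n_with_sequence / x$n_clones) else NA_real_
  pct_mapped <- if (x$n_with_sequence > 0)
    round_half_up(100 * x$n_mapped / x$n_with_sequence) else NA_real_
  cpg <- if (is.na(x$clones_per_gene)) "NA" else
    sprintf("%.1f", round_half_up(x$clones_per_gene, 1))
  c(sprintf("clones on array:      %d", x$n_clones),
    sprintf("with sequence:        %d (%s%%)", x$n_with_sequence,
            format(pct_seq)),
    sprintf("with best-match gene: %d (%s%%)", x$n_mapped,
            format(pct_mapped)),
    sprintf("unique genes:         %d", x$n_genes),
    sprintf("clones per gene:      %s", cpg))
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Displayed (rounded) summary figures
#'
#' @param x A `mapping_summary`.
#' @return Named numeric vector: `pct_with_sequence`, `pct_mapped` (of
#'   those with sequence), and `clones_per_gene` as displayed (one
#'   decimal, half-up).
#' @export
summary_display <- function(x) {
  stopifnot(inherits(x, "mapping_summary"))
  c(pct_with_sequence = round_half_up(100 * x$n_with_sequence / x$n_clones),
    pct_mapped = round_half_up(100 * x$n_mapped / x$n_with_sequence),
    clones_per_gene = round_half_up(x$clones_per_gene, 1))
}

#' Write / read mapping rows as TSV
#'
#' On disk: columns `clone_id`, `gene_id` (empty = unmapped), `score`, and
#' optionally `has_sequence`.
#'
#' @param rows Raw mapping rows or a resolved `clone_mapping`.
#' @param path File path.
#' @return `write_mapping_tsv()` returns `path` invisibly;
#'   `read_mapping_tsv()` returns a data.frame of raw mapping rows.
#' @export
write_mapping_tsv <- function(rows, path) {
  out <- as.data.frame(rows)
  out$gene_id[is.na(out$gene_id)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @export
read_mapping_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(clone_id = "character",
                                  gene_id = "character"))
  if (!all(c("clone_id", "gene_id", "score") %in% names(df))) {
    stop("mapping TSV must have columns clone_id, gene_id, score: ", path)
  }
  df$gene_id[df$gene_id == ""] <- NA_character_
  df
}
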