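#' External study gene lists
#'
#' An external expression study contributes the genes it reported as
#' upregulated in the stem-cell population and the full set of genes its
#' platform tested (its universe).
#'
#' @param name Study label.
#' @param up_genes Genes reported upregulated (deduplicated).
#' @param tested_genes Genes the study's platform could have detected;
#'   must contain `up_genes`.
#' @return An `external_study` object.
#' @export
external_study <- function(name, up_genes, tested_genes) {
  up_genes <- sort(unique(as.character(up_genes)))
  tested_genes <- sort(unique(as.character(tested_genes)))
  bad <- setdiff(up_genes, tested_genes)
  if (length(bad)) {
    stop("study `", name, "`: up_genes not within tested_genes: ",
         paste(head(bad, 10), collapse = ", "))
  }
  structure(list(name = as.character(name), up_genes = up_genes,
                 tested_genes = tested_genes),
            class = "external_study")
}

#' @export
print.external_study <- function(x, ...) {
  cat(sprintf("external_study `%s`: %d up of %d tested genes\n",
              x$name, length(x$up_genes), length(x$tested_genes)))
  invisible(x)
}

#' Read external studies from a GMT of NAME_up / NAME_tested pairs
#'
#' @param path GMT file with two sets per study: `<name>_up` and
#'   `<name>_tested`.
#' @return Named list of [external_study()] objects.
#' @export
read_external_studies <- function(path) {
  sets <- read_gmt(path)
  up_names <- grep("_up$", names(sets), value = TRUE)
  studies <- lapply(up_names, function(un) {
    nm <- sub("_up$", "", un)
    tn <- paste0(nm, "_tested")
    if (!tn %in% names(sets)) {
      stop("study `", nm, "` has an _up set but no _tested set in ", path)
    }
    external_study(nm, sets[[un]], sets[[tn]])
  })
  setNames(studies, sub("_up$", "", up_names))
}

#' Restrict a signature comparison to commonly tested genes
#'
#' A fair cross-study comparison counts only genes both platforms could
#' have found: the signature and its universe are intersected with the
#' external study's tested set before any probability is computed.
#'
#' @param signature A [gene_list()] (or character vector), a subset of
#'   `own_universe`.
#' @param study An [external_study()].
#' @param own_universe A [gene_universe()].
#' @return List with `signature` (restricted, the "testable" part of the
#'   signature), `universe` (restricted universe), `n_testable`, and
#'   `n_signature` (the unrestricted signature size).  Refuses with an
#'   error when nothing is commonly tested.
#' @export
restrict_common <- function(signature, study, own_universe) {
  stopifnot(inherits(study, "external_study"),
            inherits(own_universe, "gene_universe"))
  sig <- unclass(signature)
  bad <- setdiff(sig, unclass(own_universe))
  if (length(bad)) {
    stop("signature is not a subset of its own universe: ",
         paste(head(bad, 10), collapse = ", "))
  }
  common_universe <- intersect(unclass(own_universe), study$tested_genes)
  common_sig <- intersect(sig, study$tested_genes)
  if (length(common_universe) == 0 || length(common_sig) == 0) {
    stop("study `", study$name, "` shares no tested genes with the ",
         "signature/universe; comparison refused")
  }
  list(signature = sort(common_sig),
       universe = gene_universe(common_universe),
       n_testable = length(common_sig),
       n_signature = length(sig))
}

#' Compare the signature to one external study
#'
#' After restriction to commonly tested genes, counts the signature genes
#' the study also called upregulated and computes the hypergeometric
#' upper-tail probability of that overlap within the restricted universe
#' (the study's up list is likewise intersected with the restricted
#' universe).  The p-value is computed in log space and reported as
#' -log10(p), so extreme significance survives numerically.
#'
#' @param signature A [gene_list()] or character vector.
#' @param study An [external_study()].
#' @param own_universe A [gene_universe()].
#' @return A `comparison_row`: one-row data.frame with `study`,
#'   `n_common`, `n_testable`, `n_signature`, `n_study_up` (restricted
#'   size of the study's up list) and `neg_log10_p`.
#' @export
compare_study <- function(signature, study, own_universe) {
  res <- restrict_common(signature, study, own_universe)
  up_restricted <- intersect(study$up_genes, unclass(res$universe))
  n_common <- length(intersect(res$signature, up_restricted))
  log_p <- hypergeom_upper_tail(n_common, res$n_testable,
                                length(up_restricted),
                                length(res$universe), log_p = TRUE)
  row <- data.frame(study = study$name,
                    n_common = n_common,
                    n_testable = res$n_testable,
                    n_signature = res$n_signature,
                    n_study_up = length(up_restricted),
                    neg_log10_p = -log_p / log(10),
                    stringsAsFactors = FALSE)
  class(row) <- c("comparison_row", "data.frame")
  row
}

#' Compare the signature to several studies
#'
#' @param signature A [gene_list()] or character vector.
#' @param studies List of [external_study()] objects.
#' @param own_universe A [gene_universe()].
#' @return Data.frame of [compare_study()] rows, most significant first.
#' @export
compare_studies <- function(signature, studies, own_universe) {
  rows <- do.call(rbind, lapply(studies, compare_study,
                                signature = signature,
                                own_universe = own_universe))
  rows <- rows[order(-rows$neg_log10_p), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Format a comparison row in the conventional table layout
#'
#' Renders "genes in common (testable)" as e.g. `35 (89)`, the testable
#' fraction as `89/93`, and -log10(p) to four decimals.
#'
#' @param row A `comparison_row` (or any data.frame with the same
#'   columns).
#' @return Character data.frame with columns `study`, `genes_in_common`,
#'   `max_identifiable`, `neg_log10_p`.
#' @export
format_comparison_table <- function(row) {
  data.frame(
    study = row$study,
    genes_in_common = sprintf("%d (%d)", row$n_common, row$n_testable),
    max_identifiable = sprintf("%d/%d", row$n_testable, row$n_signature),
    neg_log10_p = sprintf("%.4f", row$neg_log10_p),
    stringsAsFactors = FALSE)
}

#' Three-state presence matrix of the signature across studies
#'
#' Per (signature gene, study): `1` if the study called the gene
#' upregulated, `0` if it tested the gene without calling it up, `NA` if
#' the gene was not on the study's platform.
#'
#' @param signature A [gene_list()] or character vector.
#' @param studies List of [external_study()] objects (at least one).
#' @return Integer matrix, rows = signature genes, columns = study names,
#'   entries in `{1, 0, NA}`.
#' @export
presence_matrix <- function(signature, studies) {
  stopifnot(length(studies) >= 1)
  sig <- sort(unique(unclass(signature)))
  m <- vapply(studies, function(st) {
    v <- rep(NA_integer_, length(sig))
    v[sig %in% st$tested_genes] <- 0L
    v[sig %in% st$up_genes] <- 1L
    v
  }, integer(length(sig)))
  m <- matrix(m, nrow = length(sig),
              dimnames = list(sig, vapply(studies, `[[`, "", "name")))
  m
}

#' Write a presence matrix as TSV
#'
#' @param m Matrix from [presence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
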