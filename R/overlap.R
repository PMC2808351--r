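#' Directional gene list
#'
#' A deduplicated gene set derived from a differential clone list, labelled
#' with the comparison it came from and its direction of regulation.
#'
#' @param genes Character vector of gene ids (deduplicated, sorted).
#' @param source Comparison label.
#' @param direction `"down"` or `"up"`.
#' @return A `gene_list` object (character vector with attributes).
#' @export
gene_list <- function(genes, source = "", direction = c("down", "up")) {
  direction <- match.arg(direction)
  genes <- sort(unique(as.character(genes)))
  structure(genes, source = source, direction = direction,
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list `%s` (%s): %d genes\n",
              attr(x, "source"), attr(x, "direction"), length(x)))
  invisible(x)
}

#' Detectability-defined gene universe
#'
#' @param genes Character vector of gene ids.
#' @return A `gene_universe` object.
#' @export
gene_universe <- function(genes) {
  structure(sort(unique(as.character(genes))), class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("gene_universe: %d detectable genes\n", length(x)))
  invisible(x)
}

#' Build the detectable-gene universe
#'
#' A clone is detectable if its spot was present (above background) in at
#' least `min_present` of the replicate hybridizations in at least one of
#' the datasets; a gene is detectable if at least one of its mapped clones
#' is.  The universe is global across datasets, and it is the reference
#' set for every hypergeometric overlap test.
#'
#' @param matrices List of [ratio_matrix()] objects (or logical presence
#'   matrices with clone-id rownames), one per dataset.
#' @param mapping A [resolve_best_match()] result.
#' @param min_present Detectability threshold per dataset (default 5).
#' @return A `gene_universe`.  Clones absent from every matrix are treated
#'   as undetectable (a message reports how many).
#' @export
detectable_universe <- function(matrices, mapping, min_present = 5L) {
  stopifnot(inherits(mapping, "clone_mapping"), length(matrices) >= 1)
  present_counts <- lapply(matrices, function(m) {
    if (inherits(m, "ratio_matrix")) {
      rowSums(!is.na(m$values))
    } else {
      rowSums(m != 0 & !is.na(m))
    }
  })
  detectable <- character(0)
  for (pc in present_counts) {
    detectable <- union(detectable, names(pc)[pc >= min_present])
  }
  covered <- unique(unlist(lapply(present_counts, names)))
  n_uncovered <- sum(!mapping$clone_id %in% covered)
  if (n_uncovered > 0) {
    message(n_uncovered,
            " clone(s) absent from every dataset treated as undetectable")
  }
  idx <- match(detectable, mapping$clone_id)
  genes <- mapping$gene_id[idx[!is.na(idx)]]
  gene_universe(genes[!is.na(genes)])
}

#' Hypergeometric upper-tail overlap probability
#'
#' Probability that two gene lists of sizes `n_i` and `n_j`, drawn without
#' replacement from a universe of `n_u` genes, share `o` or more genes:
#' P(X >= o) for X hypergeometric.  Computed through the survival function
#' in log space, so it is numerically safe far into the tail, and is
#' symmetric in `(n_i, n_j)`.
#'
#' @param o Observed overlap count.
#' @param n_i,n_j List sizes.
#' @param n_u Universe size.
#' @param log_p If `TRUE`, return the natural log of the p-value.
#' @return The upper-tail probability in (0, 1\] (`o = 0` gives exactly 1).
#' @export
hypergeom_upper_tail <- function(o, n_i, n_j, n_u, log_p = FALSE) {
  vals <- c(o = o, n_i = n_i, n_j = n_j, n_u = n_u)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("o, n_i, n_j, n_u must be non-negative integers")
  }
  if (o > min(n_i, n_j)) {
    stop("overlap o (", o, ") exceeds min(n_i, n_j) = ", min(n_i, n_j))
  }
  if (max(n_i, n_j) > n_u) {
    stop("list sizes must not exceed the universe size n_u = ", n_u)
  }
  if (o == 0) {
    return(if (log_p) 0 else 1)
  }
  p <- phyper(o - 1, m = n_i, n = n_u - n_i, k = n_j,
              lower.tail = FALSE, log.p = log_p)
  if (!log_p) min(p, 1) else min(p, 0)
}

#' Pairwise gene-list overlap test
#'
#' The binary overlap score between two gene lists: the overlap count
#' O = |G_i ∩ G_j| and the hypergeometric probability of an overlap at
#' least that large within the detectable universe.
#'
#' @param g_i,g_j [gene_list()] objects (or character vectors), both
#'   subsets of the universe.
#' @param u A [gene_universe()].
#' @param alpha Significance level (default 0.001); significance is
#'   strictly `p < alpha`.
#' @return A `pairwise_overlap` object: `o_ij`, `p_value`, `significant`,
#'   list sizes, universe size, and the pair labels.
#' @export
pairwise_overlap <- function(g_i, g_j, u, alpha = 0.001) {
  stopifnot(inherits(u, "gene_universe"))
  if (length(u) == 0) {
    stop("empty universe: no detectable genes; overlap testing refused")
  }
  check_subset <- function(g, who) {
    bad <- setdiff(unclass(g), unclass(u))
    if (length(bad)) {
      stop("gene list ", who, " is not a subset of the universe; ",
           "offending gene(s): ", paste(head(bad, 10), collapse = ", "))
    }
  }
  check_subset(g_i, attr(g_i, "source") %||% "i")
  check_subset(g_j, attr(g_j, "source") %||% "j")
  o <- length(intersect(unclass(g_i), unclass(g_j)))
  p <- hypergeom_upper_tail(o, length(g_i), length(g_j), length(u))
  structure(list(o_ij = o, p_value = p, significant = p < alpha,
                 alpha = alpha, n_i = length(g_i), n_j = length(g_j),
                 n_u = length(u),
                 labels = c(attr(g_i, "source") %||% "i",
                            attr(g_j, "source") %||% "j")),
            class = "pairwise_overlap")
}

#' @export
print.pairwise_overlap <- function(x, ...) {
  cat(sprintf("overlap %s ~ %s: O = %d (|i|=%d, |j|=%d, |U|=%d), p = %.3g%s\n",
              x$labels[1], x$labels[2], x$o_ij, x$n_i, x$n_j, x$n_u,
              x$p_value,
              if (x$significant) sprintf(" *significant at %g*", x$alpha)
              else ""))
  invisible(x)
}

#' Trinary overlap indicator
#'
#' True if and only if all three pairwise overlaps among the lists are
#' significant at level `alpha` — the criterion for a meaningful three-way
#' intersection.
#'
#' @param g_i,g_j,g_k [gene_list()] objects, subsets of the universe.
#' @param u A [gene_universe()].
#' @param alpha Significance level (default 0.001).
#' @return A `trinary_overlap` object: `indicator` (logical),
#'   `constituents` (the three [pairwise_overlap()]s) and `alpha`.
#' @export
trinary_indicator <- function(g_i, g_j, g_k, u, alpha = 0.001) {
  constituents <- list(ij = pairwise_overlap(g_i, g_j, u, alpha),
                       ik = pairwise_overlap(g_i, g_k, u, alpha),
                       jk = pairwise_overlap(g_j, g_k, u, alpha))
  structure(list(indicator = all(vapply(constituents, `[[`, TRUE,
                                        "significant")),
                 constituents = constituents, alpha = alpha),
            class = "trinary_overlap")
}

#' @export
print.trinary_overlap <- function(x, ...) {
  cat(sprintf("trinary overlap indicator: %s (alpha = %g)\n",
              x$indicator, x$alpha))
  for (co in x$constituents) print(co)
  invisible(x)
}

#' Collapse DE clone calls to directional gene lists
#'
#' Turns a comparison's up/down clone lists into deduplicated gene lists.
#' A gene called up through one clone and down through another within the
#' same comparison is excluded from both directional lists (and reported),
#' so a discordant gene cannot inflate opposing lists.
#'
#' @param calls A `de_calls` object (from [sam_de()]).
#' @param mapping A [resolve_best_match()] result.
#' @param source Comparison label for the resulting lists.
#' @return List with `up` and `down` [gene_list()]s and `conflicted` (the
#'   excluded gene ids).
#' @export
directional_gene_lists <- function(calls, mapping, source = "") {
  stopifnot(inherits(calls, "de_calls"))
  up_genes <- collapse_to_genes(calls$up_clones, mapping)
  down_genes <- collapse_to_genes(calls$down_clones, mapping)
  conflicted <- intersect(up_genes, down_genes)
  if (length(conflicted)) {
    message(length(conflicted), " direction-conflicted gene(s) excluded ",
            "from both lists in ", source)
  }
  list(up = gene_list(setdiff(up_genes, conflicted), source, "up"),
       down = gene_list(setdiff(down_genes, conflicted), source, "down"),
       conflicted = conflicted)
}

#' Gene- and clone-level intersection of directional lists
#'
#' Intersects the gene lists (any mix of directions across sources is
#' allowed — e.g. up-in-MPP with down-in-Mob and down-in-LSC) and counts
#' the clones behind the intersection: the unique clones, across the
#' supplied clone lists, whose resolved gene lies in the intersection.
#'
#' @param lists List of [gene_list()]s (at least one).
#' @param mapping A [resolve_best_match()] result.
#' @param clone_lists Optional list of clone-id vectors parallel to
#'   `lists` (each source's differential clone list); when given, the
#'   clone-level count is reported.
#' @return List with `genes`, `n_genes`, and `n_clones` (`NA` if no clone
#'   lists were supplied).
#' @export
intersect_region <- function(lists, mapping, clone_lists = NULL) {
  if (length(lists) == 0) {
    stop("need at least one gene list to intersect")
  }
  genes <- Reduce(intersect, lapply(lists, unclass))
  genes <- sort(genes)
  n_clones <- NA_integer_
  if (!is.null(clone_lists)) {
    clones <- unique(unlist(clone_lists, use.names = FALSE))
    gene_of <- mapping$gene_id[match(clones, mapping$clone_id)]
    n_clones <- sum(gene_of %in% genes, na.rm = TRUE)
  }
  list(genes = genes, n_genes = length(genes), n_clones = n_clones)
}

#' Venn region counts at gene and clone level
#'
#' For each direction, partitions the three comparisons' gene lists into
#' the seven Venn regions and counts member genes, plus the unique clones
#' (from the region's comparisons' clone lists) whose gene lies in the
#' region.
#'
#' @param gene_lists Named list, one element per comparison, each with
#'   `up` and `down` [gene_list()]s (as from [directional_gene_lists()]).
#' @param clone_lists Named list parallel to `gene_lists`, each with `up`
#'   and `down` clone-id vectors.
#' @param mapping A [resolve_best_match()] result.
#' @return Data.frame with columns `direction`, `region` (digit key over
#'   the comparison order), `comparisons`, `n_genes`, `n_clones`.
#' @export
venn_counts <- function(gene_lists, clone_lists, mapping) {
  k <- length(gene_lists)
  stopifnot(k >= 2, setequal(names(gene_lists), names(clone_lists)))
  labels <- names(gene_lists)
  keys <- venn_region_keys(k)
  out <- list()
  for (dir in c("down", "up")) {
    sets <- lapply(gene_lists, function(gl) unclass(gl[[dir]]))
    all_genes <- unique(unlist(sets, use.names = FALSE))
    member <- vapply(sets, function(s) all_genes %in% s,
                     logical(length(all_genes)))
    member <- matrix(member, nrow = length(all_genes))
    for (key in keys) {
      in_cmp <- as.integer(strsplit(key, "")[[1]])
      want <- rep(FALSE, k)
      want[in_cmp] <- TRUE
      hit <- if (length(all_genes)) {
        apply(member, 1L, function(row) all(row == want))
      } else logical(0)
      region_genes <- all_genes[hit]
      region_clones <- unique(unlist(
        lapply(in_cmp, function(i) clone_lists[[labels[i]]][[dir]]),
        use.names = FALSE))
      gene_of <- mapping$gene_id[match(region_clones, mapping$clone_id)]
      out[[length(out) + 1L]] <- data.frame(
        direction = dir, region = key,
        comparisons = paste(labels[in_cmp], collapse = "&"),
        n_genes = length(region_genes),
        n_clones = sum(gene_of %in% region_genes, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
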