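#' Configuration for the synthetic microarray study
#'
#' Defines the simulated experimental design: a clone library spotted on a
#' two-color cDNA array, three pairwise competitive hybridization
#' comparisons, each replicated six times (three biological replicates,
#' each with a dye swap, orientation-corrected at generation), with planted
#' differentially expressed gene sets arranged in a known Venn structure.
#'
#' The defaults emulate a study of hematopoietic stem cell (HSC) fates:
#' three comparisons (differentiation to multipotent progenitors,
#' cytokine-induced mobilization, leukemic transformation), an average
#' probe redundancy of 2.5 clones per gene, a strong bias towards
#' down-regulation in the perturbed state, and a 93-gene three-way
#' down-regulated region — the planted quiescent-HSC signature.  Positive
#' log ratios mean higher expression in the perturbed (differentiated /
#' mobilized / leukemic) state, so signature genes are "down".
#'
#' @param n_genes Number of genes in the library.
#' @param clone_mean Mean clones per mapped gene (> 0); clone counts are
#'   drawn from a zero-truncated Poisson with this mean (degenerate at 1
#'   when `clone_mean = 1`).
#' @param unmapped_fraction Fraction of all clones carrying no gene
#'   assignment, in `[0, 1)`.
#' @param n_comparisons Number of pairwise comparisons (default 3).
#' @param n_replicates Replicate hybridizations per comparison (>= 2).
#' @param planted_sizes Named list with elements `down` and `up`, each a
#'   named integer vector of gene counts for every non-empty Venn region
#'   (for 3 comparisons: regions `"1"`, `"2"`, `"3"`, `"12"`, `"13"`,
#'   `"23"`, `"123"`, digits indexing comparisons).  Regions are disjoint;
#'   their per-direction sums must not exceed `n_genes`.
#' @param effect_size Mean absolute log2 ratio of planted genes (> 0).
#' @param noise_sd Replicate noise standard deviation (> 0).
#' @param missing_rate Independent per-spot missingness probability in
#'   `[0, 1)`.
#' @param comparisons Labels for the comparisons (perturbed state names).
#' @param seed Integer seed; all randomness in the generator flows from it
#'   through fixed per-stage substreams.
#' @return A validated `sim_config` object (a classed list).
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1,
#'                   planted_sizes = planted_sizes(down3 = 10))
#' study <- simulate_study(cfg)
#' @export
sim_config <- function(n_genes = 3000,
                       clone_mean = 2.5,
                       unmapped_fraction = 0.1,
                       n_comparisons = 3,
                       n_replicates = 6,
                       planted_sizes = stemsig::planted_sizes(),
                       effect_size = 1.5,
                       noise_sd = 0.5,
                       missing_rate = 0.05,
                       comparisons = NULL,
                       seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid sim_config field `", field, "`: ", msg,
                  call. = FALSE)
  }
  chk(is.numeric(n_genes) && length(n_genes) == 1 && n_genes >= 1 &&
        n_genes == round(n_genes), "n_genes", "must be a positive count")
  chk(is.numeric(clone_mean) && length(clone_mean) == 1 && clone_mean >= 1,
      "clone_mean", "must be a real >= 1 (mean of a zero-truncated count)")
  chk(is.numeric(unmapped_fraction) && unmapped_fraction >= 0 &&
        unmapped_fraction < 1, "unmapped_fraction", "must lie in [0, 1)")
  chk(is.numeric(n_comparisons) && n_comparisons >= 1 &&
        n_comparisons == round(n_comparisons),
      "n_comparisons", "must be a positive count")
  chk(is.numeric(n_replicates) && n_replicates >= 2 &&
        n_replicates == round(n_replicates),
      "n_replicates", "must be a count >= 2")
  chk(is.numeric(effect_size) && effect_size >= 0, "effect_size",
      "must be a non-negative real")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd",
      "must be a positive real")
  chk(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
      "missing_rate", "must lie in [0, 1)")
  chk(is.numeric(seed) && length(seed) == 1 && seed == round(seed),
      "seed", "must be an integer")

  if (is.null(comparisons)) {
    comparisons <- if (n_comparisons == 3) c("MPP", "Mob", "LSC") else
      paste0("cmp", seq_len(n_comparisons))
  }
  chk(length(comparisons) == n_comparisons && !anyDuplicated(comparisons),
      "comparisons", "need one unique label per comparison")

  regions <- venn_region_keys(n_comparisons)
  chk(is.list(planted_sizes) &&
        all(c("down", "up") %in% names(planted_sizes)),
      "planted_sizes", "must be a list with elements `down` and `up`")
  for (dir in c("down", "up")) {
    ps <- planted_sizes[[dir]]
    chk(!is.null(names(ps)) && all(names(ps) %in% regions),
        "planted_sizes",
        paste0("`", dir, "` region names must be among: ",
               paste(regions, collapse = ", ")))
    chk(all(ps >= 0) && all(ps == round(ps)), "planted_sizes",
        "region sizes must be non-negative counts")
    full <- setNames(rep(0, length(regions)), regions)
    full[names(ps)] <- ps
    planted_sizes[[dir]] <- full
  }
  total_planted <- sum(planted_sizes$down) + sum(planted_sizes$up)
  chk(total_planted <= n_genes, "planted_sizes",
      sprintf("planted gene total (%d) exceeds n_genes (%d)",
              total_planted, n_genes))

  structure(list(
    n_genes = as.integer(n_genes), clone_mean = clone_mean,
    unmapped_fraction = unmapped_fraction,
    n_comparisons = as.integer(n_comparisons),
    n_replicates = as.integer(n_replicates),
    planted_sizes = planted_sizes, effect_size = effect_size,
    noise_sd = noise_sd, missing_rate = missing_rate,
    comparisons = as.character(comparisons), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default planted Venn region sizes
#'
#' Gene counts for each region of the three-comparison Venn diagram, per
#' direction.  The defaults carry a strong down-regulation bias and a
#' 93-gene three-way down-regulated region (the planted signature), scaled
#' to a library of a few thousand genes.
#'
#' @param down3,up3 Convenience overrides for the three-way regions.
#' @param down,up Full named vectors overriding every region (names among
#'   `"1","2","3","12","13","23","123"`).
#' @return A list with elements `down` and `up`.
#' @export
planted_sizes <- function(down3 = 93, up3 = 2, down = NULL, up = NULL) {
  if (is.null(down)) {
    down <- c(`1` = 250, `2` = 400, `3` = 200,
              `12` = 60, `13` = 40, `23` = 50, `123` = down3)
  }
  if (is.null(up)) {
    up <- c(`1` = 40, `2` = 25, `3` = 10,
            `12` = 5, `13` = 4, `23` = 3, `123` = up3)
  }
  list(down = down, up = up)
}

#' Venn region keys for k comparisons
#'
#' Region `"13"` means "in comparisons 1 and 3 and in no other".
#'
#' @param k Number of comparisons.
#' @return Character vector of the 2^k - 1 non-empty region keys, ordered
#'   by region size then lexicographically.
#' @export
venn_region_keys <- function(k) {
  subsets <- unlist(lapply(seq_len(k), function(m) {
    combn(k, m, FUN = function(ix) paste(ix, collapse = ""), simplify = TRUE)
  }))
  subsets
}

## mean of a zero-truncated Poisson is lambda / (1 - exp(-lambda));
## invert numerically (degenerate point mass at 1 when the mean is 1)
ztp_lambda <- function(mean) {
  if (mean <= 1 + 1e-12) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - mean,
          lower = 1e-9, upper = max(10, 3 * mean), tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  x <- rpois(n, lambda)
  while (any(zero <- x == 0L)) {
    x[zero] <- rpois(sum(zero), lambda)
  }
  x
}

#' Generate a synthetic clone library and raw mapping rows
#'
#' Each gene receives a zero-truncated-Poisson number of clones with the
#' configured mean; each mapped clone gets a high-scoring candidate row for
#' its true gene and, for a quarter of clones, an extra lower-scoring decoy
#' candidate (so best-match resolution is exercised).  An
#' `unmapped_fraction` of all clones carry no candidate gene: half of those
#' have no retrievable sequence at all (score `NA`), half have a sequence
#' but no matching transcript (score 0), mirroring the two attrition steps
#' of a real EST-to-gene mapping funnel.
#'
#' @param config A [sim_config()].
#' @return A data.frame of raw mapping rows with columns `clone_id`,
#'   `gene_id` (`NA` when unmapped), `score`, and `has_sequence`.
#'   Deterministic for a fixed seed.
#' @export
generate_clone_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lambda <- ztp_lambda(config$clone_mean)
  n_clones_per_gene <- rztpois(config$n_genes, lambda)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  n_mapped <- sum(n_clones_per_gene)
  genes_of_clone <- rep(gene_ids, n_clones_per_gene)

  f <- config$unmapped_fraction
  n_unmapped <- round(f / (1 - f) * n_mapped)
  n_total <- n_mapped + n_unmapped
  clone_ids <- sprintf("cl%06d", seq_len(n_total))
  mapped_clones <- clone_ids[seq_len(n_mapped)]
  unmapped_clones <- clone_ids[seq_len(n_unmapped) + n_mapped]

  rows <- data.frame(clone_id = mapped_clones,
                     gene_id = genes_of_clone,
                     score = round(runif(n_mapped, 200, 500), 1),
                     has_sequence = TRUE,
                     stringsAsFactors = FALSE)

  ## decoy candidates: lower score, different gene
  n_decoy <- floor(n_mapped / 4)
  if (n_decoy > 0 && config$n_genes > 1) {
    pick <- sample.int(n_mapped, n_decoy)
    decoy_gene <- gene_ids[
      1L + (match(genes_of_clone[pick], gene_ids) +
              sample.int(config$n_genes - 1L, n_decoy, replace = TRUE) - 1L) %%
        config$n_genes]
    decoys <- data.frame(clone_id = mapped_clones[pick],
                         gene_id = decoy_gene,
                         score = round(rows$score[pick] -
                                         runif(n_decoy, 10, 150), 1),
                         has_sequence = TRUE,
                         stringsAsFactors = FALSE)
    rows <- rbind(rows, decoys)
  }

  if (n_unmapped > 0) {
    no_seq <- seq_len(n_unmapped) <= n_unmapped / 2
    rows <- rbind(rows, data.frame(clone_id = unmapped_clones,
                                   gene_id = NA_character_,
                                   score = ifelse(no_seq, NA_real_, 0),
                                   has_sequence = !no_seq,
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$clone_id, -xtfrm(rows$score)), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Plant the differential-expression truth
#'
#' Assigns disjoint gene subsets to every Venn region of every direction
#' (down and up regions are globally disjoint, so no gene is planted in
#' opposing directions).  The all-comparisons down region is the planted
#' signature.
#'
#' @param config A [sim_config()].
#' @return A list with elements `regions` (per direction, named list of
#'   gene-id vectors keyed by Venn region), `per_comparison` (per
#'   comparison label, `down` and `up` gene vectors), and `signature` (the
#'   all-comparisons down region).
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  sizes <- config$planted_sizes
  keys <- venn_region_keys(config$n_comparisons)
  total <- sum(sizes$down) + sum(sizes$up)
  pool <- sample(gene_ids, total)
  regions <- list(down = list(), up = list())
  at <- 0L
  for (dir in c("down", "up")) {
    for (key in keys) {
      n <- sizes[[dir]][[key]]
      regions[[dir]][[key]] <-
        if (n > 0) sort(pool[at + seq_len(n)]) else character(0)
      at <- at + n
    }
  }
  per_comparison <- lapply(seq_len(config$n_comparisons), function(i) {
    in_region <- keys[grepl(as.character(i), keys, fixed = TRUE)]
    list(down = sort(unlist(regions$down[in_region], use.names = FALSE)),
         up = sort(unlist(regions$up[in_region], use.names = FALSE)))
  })
  names(per_comparison) <- config$comparisons
  all_key <- paste(seq_len(config$n_comparisons), collapse = "")
  list(regions = regions, per_comparison = per_comparison,
       signature = regions$down[[all_key]])
}

#' Simulate replicate log-ratio matrices
#'
#' For each comparison, every clone of a planted gene receives replicate
#' log2 ratios centred at the signed effect size (negative for "down"
#' genes, i.e. lower in the perturbed state); null clones are pure noise.
#' Each spot is independently missing with `missing_rate`.  Dye-swap
#' replicates are sign-corrected at generation, so all columns share one
#' orientation.
#'
#' @param config A [sim_config()].
#' @param truth Output of [plant_truth()] for the same config.
#' @param clone_library Output of [generate_clone_library()] for the same
#'   config.
#' @return A named list of [ratio_matrix()] objects, one per comparison.
#' @export
simulate_ratios <- function(config, truth, clone_library) {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(names(truth$per_comparison), config$comparisons)) {
    stop("truth does not match config: comparison labels differ")
  }
  resolved <- resolve_best_match(clone_library)
  clone_ids <- resolved$clone_id
  gene_of <- resolved$gene_id
  if (length(clone_ids) == 0) stop("clone library is empty")
  set.seed(config$seed + 2L)
  n <- length(clone_ids)
  r <- config$n_replicates
  out <- lapply(config$comparisons, function(label) {
    tr <- truth$per_comparison[[label]]
    mu <- numeric(n)
    mu[gene_of %in% tr$up] <- config$effect_size
    mu[gene_of %in% tr$down] <- -config$effect_size
    vals <- matrix(rnorm(n * r, mean = mu, sd = config$noise_sd),
                   nrow = n, ncol = r)
    if (config$missing_rate > 0) {
      vals[runif(n * r) < config$missing_rate] <- NA_real_
    }
    ratio_matrix(vals, clone_ids = clone_ids,
                 orientation = paste0(label, "_vs_ref"))
  })
  names(out) <- config$comparisons
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: clone library, planted truth, and one ratio matrix
#' per comparison, all driven by the config seed.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_study` object: list with `mapping` (raw mapping
#'   rows), `ratios` (named list of [ratio_matrix()]), `truth` (see
#'   [plant_truth()]), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mapping <- generate_clone_library(config)
  truth <- plant_truth(config)
  ratios <- simulate_ratios(config, truth, mapping)
  structure(list(mapping = mapping, ratios = ratios, truth = truth,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d genes, %d clones, ",
                     "%d comparisons x %d replicates\n"),
              x$config$n_genes, length(unique(x$mapping$clone_id)),
              x$config$n_comparisons, x$config$n_replicates))
  cat(sprintf("  planted signature: %d genes\n", length(x$truth$signature)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the mapping table as TSV (`clone_id`, `gene_id`, `score`,
#' `has_sequence`; empty `gene_id` = unmapped), one ratio-matrix TSV per
#' comparison, and the planted truth as a GMT file whose set names encode
#' Venn region and direction (e.g. `down|123`).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mapping = file.path(dir, "mapping.tsv"))
  write_mapping_tsv(study$mapping, paths[["mapping"]])
  for (label in names(study$ratios)) {
    p <- file.path(dir, paste0("ratios_", label, ".tsv"))
    write_ratio_tsv(study$ratios[[label]], p)
    paths[[paste0("ratios_", label)]] <- p
  }
  truth_sets <- c(
    setNames(study$truth$regions$down,
             paste0("down|", names(study$truth$regions$down))),
    setNames(study$truth$regions$up,
             paste0("up|", names(study$truth$regions$up))))
  paths[["truth"]] <- file.path(dir, "truth.gmt")
  write_gmt(truth_sets, paths[["truth"]],
            descriptions = rep("planted Venn region", length(truth_sets)))
  invisible(paths)
}
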