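#' Pipeline configuration
#'
#' Bundles everything an end-to-end run needs.  All randomness flows from
#' the single `seed` (the simulator derives fixed per-stage substreams
#' from it), so identical configs give byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()] (its seed is overridden by `seed` when one
#'   is given here).
#' @param sam A [sam_params()].
#' @param alpha Overlap significance level (default 0.001).
#' @param min_present Reproducibility/detectability threshold (default 5).
#' @param stages Character vector of stages to run, in pipeline order,
#'   from `c("simulate", "map", "de", "overlap", "compare")`.
#' @param external_studies Optional: list of [external_study()] objects or
#'   a path to a GMT of `NAME_up` / `NAME_tested` pairs (required when the
#'   `compare` stage is enabled).
#' @param seed Optional integer overriding the simulator seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            sam = sam_params(),
                            alpha = 0.001,
                            min_present = 5L,
                            stages = c("simulate", "map", "de", "overlap"),
                            external_studies = NULL,
                            seed = NULL) {
  known <- c("simulate", "map", "de", "overlap", "compare")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
  }
  cfg <- structure(list(out_dir = out_dir, sim = sim, sam = sam,
                        alpha = alpha, min_present = as.integer(min_present),
                        stages = stages,
                        external_studies = external_studies),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$sim, "sim_config"), inherits(cfg$sam, "sam_params"))
  need <- list(map = "simulate", de = "map", overlap = "de",
               compare = "overlap")
  for (st in names(need)) {
    if (st %in% cfg$stages && !need[[st]] %in% cfg$stages) {
      stop("stage `", st, "` requires stage `", need[[st]],
           "` (inputs from disk are not wired through run_pipeline; ",
           "use the stage functions directly)")
    }
  }
  if ("compare" %in% cfg$stages && is.null(cfg$external_studies)) {
    stop("stage `compare` enabled but no external_studies given")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `out_dir`, `seed`, `alpha`, `min_present`, `stages`,
#' `external_studies` (a GMT path), `sim` (fields of [sim_config()];
#' `planted_sizes` as `down`/`up` maps keyed by Venn region), and `sam`
#' (fields of [sam_params()]).
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$planted_sizes)) {
    sim_args$planted_sizes <- lapply(sim_args$planted_sizes, unlist)
  }
  sim <- do.call(sim_config, sim_args)
  sam <- do.call(sam_params, y$sam %||% list())
  pipeline_config(
    out_dir = out_dir %||% y$out_dir %||% stop("config needs out_dir"),
    sim = sim, sam = sam,
    alpha = y$alpha %||% 0.001,
    min_present = y$min_present %||% 5L,
    stages = y$stages %||% c("simulate", "map", "de", "overlap"),
    external_studies = y$external_studies,
    seed = y$seed)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order — simulate, map, de, overlap,
#' compare — writing every intermediate to `out_dir` and finishing with a
#' manifest (`manifest.json`) that records the parameters and the MD5
#' checksum of every output file.  Identical configs (same seed) produce
#' identical manifests.
#'
#' @param config A [pipeline_config()] or a YAML path for
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory stage `results` and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  paths <- character(0)

  if ("simulate" %in% config$stages) {
    res$study <- simulate_study(config$sim)
    paths <- c(paths, write_study(res$study, config$out_dir))
  }

  if ("map" %in% config$stages) {
    res$mapping <- resolve_best_match(res$study$mapping)
    res$mapping_summary <- mapping_summary(res$mapping)
    p <- file.path(config$out_dir, "mapping_resolved.tsv")
    write_mapping_tsv(res$mapping, p)
    paths <- c(paths, mapping_resolved = p)
    p <- file.path(config$out_dir, "mapping_summary.json")
    ms <- res$mapping_summary
    jsonlite::write_json(
      c(ms[c("n_clones", "n_with_sequence", "n_mapped", "n_genes",
             "clones_per_gene")],
        as.list(summary_display(ms))),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, mapping_summary = p)
  }

  if ("de" %in% config$stages) {
    res$de <- lapply(res$study$ratios, sam_de, params = config$sam,
                     min_present = config$min_present)
    for (label in names(res$de)) {
      p <- file.path(config$out_dir, paste0("de_", label, ".tsv"))
      write_de_calls(res$de[[label]], p)
      paths <- c(paths, setNames(p, paste0("de_", label)))
    }
  }

  if ("overlap" %in% config$stages) {
    res$universe <- detectable_universe(res$study$ratios, res$mapping,
                                        min_present = config$min_present)
    res$gene_lists <- mapply(directional_gene_lists,
                             res$de, names(res$de),
                             MoreArgs = list(mapping = res$mapping),
                             SIMPLIFY = FALSE)
    clone_lists <- lapply(res$de, function(d)
      list(up = d$up_clones, down = d$down_clones))
    res$venn <- venn_counts(res$gene_lists, clone_lists, res$mapping)
    p <- file.path(config$out_dir, "venn_counts.tsv")
    write.table(res$venn, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, venn_counts = p)

    down_lists <- lapply(res$gene_lists, `[[`, "down")
    ## overlap lists are bound to the detectable universe before testing
    down_in_u <- lapply(down_lists, function(g)
      gene_list(intersect(unclass(g), unclass(res$universe)),
                source = attr(g, "source"), direction = "down"))
    res$trinary <- if (length(down_in_u) == 3) {
      trinary_indicator(down_in_u[[1]], down_in_u[[2]], down_in_u[[3]],
                        res$universe, alpha = config$alpha)
    }
    res$signature <- intersect_region(
      down_lists, res$mapping,
      clone_lists = lapply(res$de, `[[`, "down_clones"))
    sig_sets <- list(signature = res$signature$genes)
    attr(sig_sets, "descriptions") <-
      sprintf("3-way down intersection: %d clones / %d genes",
              res$signature$n_clones, res$signature$n_genes)
    p <- file.path(config$out_dir, "signature.gmt")
    write_gmt(sig_sets, p)
    paths <- c(paths, signature = p)

    gmt_sets <- unlist(lapply(names(res$gene_lists), function(label) {
      gl <- res$gene_lists[[label]]
      setNames(list(as.character(gl$down), as.character(gl$up)),
               paste0(label, c("_down", "_up")))
    }), recursive = FALSE)
    p <- file.path(config$out_dir, "gene_lists.gmt")
    write_gmt(gmt_sets, p)
    paths <- c(paths, gene_lists = p)

    if (!is.null(res$trinary)) {
      ov <- res$trinary
      p <- file.path(config$out_dir, "overlap.json")
      jsonlite::write_json(list(
        alpha = ov$alpha, trinary_indicator = ov$indicator,
        universe_size = length(res$universe),
        pairwise = lapply(ov$constituents, function(co)
          co[c("o_ij", "p_value", "significant", "n_i", "n_j", "n_u")]),
        signature_n_genes = res$signature$n_genes,
        signature_n_clones = res$signature$n_clones),
        p, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, overlap = p)
    }
  }

  if ("compare" %in% config$stages) {
    studies <- config$external_studies
    if (is.character(studies)) {
      studies <- read_external_studies(studies)
    }
    sig <- gene_list(res$signature$genes, "signature", "down")
    res$comparison <- compare_studies(sig, studies, res$universe)
    p <- file.path(config$out_dir, "comparison.tsv")
    write.table(format_comparison_table(res$comparison), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, comparison = p)
    res$presence <- presence_matrix(sig, studies)
    p <- file.path(config$out_dir, "presence_matrix.tsv")
    write_presence_tsv(res$presence, p)
    paths <- c(paths, presence_matrix = p)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stemsig")),
    seed = config$sim$seed,
    stages = config$stages,
    parameters = list(
      alpha = config$alpha, min_present = config$min_present,
      target_fdr = config$sam$target_fdr,
      s0_strategy = config$sam$s0_strategy,
      permutation_mode = config$sam$permutation_mode,
      n_genes = config$sim$n_genes, clone_mean = config$sim$clone_mean,
      effect_size = config$sim$effect_size,
      noise_sd = config$sim$noise_sd,
      missing_rate = config$sim$missing_rate),
    outputs = as.list(setNames(unname(tools::md5sum(paths)),
                               basename(paths))))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = res, manifest = manifest,
                 manifest_path = mp, paths = paths))
}
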