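# End-to-end orchestration: simulate (or load) -> prioritize -> landscape
# -> signatures -> drivers -> druggability -> cohort summary, written as a
# deterministic artifact bundle.

#' Pipeline run configuration
#'
#' @param out_dir directory the artifact bundle is written to.
#' @param seed integer seed governing every stochastic stage.
#' @param cohort a [cohort_config()] to simulate from, or `NULL` when
#'   `tumour`/`normal`/`meta` are supplied directly.
#' @param tumour,normal,meta pre-loaded [variant_calls()] /
#'   [sample_meta()] for analysis-only runs (paths to TSV files are also
#'   accepted).
#' @param filter a [filter_config()].
#' @param reference a [signature_matrix()] or a path readable by
#'   [read_signature_matrix()].
#' @param rules druggability rules table or TSV path.
#' @param panel gene panel data.frame or TSV path.
#' @param signature_mode `"refit"` (non-negative least squares against the
#'   reference) or `"denovo"` (NMF extraction then cosine matching).
#' @param k number of signatures for de novo extraction.
#' @param hypermutation_threshold mutations/Mb above which a sample is
#'   hypermutated.
#' @param smg_background_rate uniform background mutation rate per bp per
#'   sample for the burden test.
#' @param fdr_threshold driver significance threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed, cohort = NULL, tumour = NULL,
                       normal = NULL, meta = NULL,
                       filter = filter_config(),
                       reference = reference_signatures(),
                       rules = fixture_rules(),
                       panel = fixture_gene_panel(),
                       signature_mode = c("refit", "denovo"), k = 3L,
                       hypermutation_threshold = 12,
                       smg_background_rate = 5e-6,
                       fdr_threshold = 0.1) {
  signature_mode <- match.arg(signature_mode)
  if (missing(seed)) stop("run_config requires an explicit seed")
  if (is.null(cohort) && (is.null(tumour) || is.null(meta))) {
    stop("supply either a cohort config to simulate, or tumour calls + metadata")
  }
  if (is.character(reference)) reference <- read_signature_matrix(reference)
  if (is.character(rules)) rules <- read_table(rules, "rules")
  if (is.character(panel)) panel <- utils::read.delim(panel,
                                                      stringsAsFactors = FALSE)
  if (is.character(tumour)) tumour <- read_table(tumour, "variants")
  if (is.character(normal)) normal <- read_table(normal, "variants")
  if (is.character(meta)) meta <- read_table(meta, "metadata")
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 tumour = tumour, normal = normal, meta = meta,
                 filter = filter, reference = reference, rules = rules,
                 panel = panel, signature_mode = signature_mode,
                 k = as.integer(k),
                 hypermutation_threshold = hypermutation_threshold,
                 smg_background_rate = smg_background_rate,
                 fdr_threshold = fdr_threshold),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] map directly from YAML keys;
#' `reference`, `rules`, `panel`, `tumour`, `normal` and `meta` are file
#' paths; `cohort` is a mapping of [cohort_config()] arguments.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    y$cohort$seed <- y$cohort$seed %||% y$seed
    for (nm in c("msi_proportions", "rate_median", "mss_outlier_weights")) {
      if (!is.null(y$cohort[[nm]])) y$cohort[[nm]] <- unlist(y$cohort[[nm]])
    }
    y$cohort <- do.call(cohort_config, y$cohort)
  }
  if (!is.null(y$filter)) y$filter <- do.call(filter_config, y$filter)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in a fixed, single-process order and writes the
#' artifact bundle to `config$out_dir`: `survivors.tsv`, `trace.tsv`,
#' `burden.tsv`, `recurrent.tsv`, `signature_fit.tsv`, `smg.tsv`,
#' `actionability.tsv` and `summary.json`. Identical configuration and
#' seed produce a byte-identical bundle; every number in the summary is
#' re-derivable from the stage outputs next to it.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with the in-memory stage results and the
#'   written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()
  out <- function(name) file.path(config$out_dir, name)

  if (!is.null(config$cohort)) {
    sim <- stage("simulate", simulate_cohort(config$cohort, config$reference,
                                             config$panel))
    tumour <- sim$tumour; normal <- sim$normal; meta <- sim$meta
    truth <- sim$truth
  } else {
    tumour <- config$tumour
    normal <- config$normal %||% tumour[0, , drop = FALSE]
    meta <- config$meta
    truth <- NULL
  }
  say("input: ", nrow(tumour), " tumour calls, ", nrow(normal),
      " normal calls, ", nrow(meta), " samples")

  pri <- stage("prioritize", run_prioritization(tumour, normal, config$filter))
  say("prioritize: ", nrow(tumour), " -> ", nrow(pri$calls), " survivors")
  paths$survivors <- write_table(pri$calls, out("survivors.tsv"))
  paths$trace <- write_table(pri$trace, out("trace.tsv"))

  burden <- stage("landscape", burden_table(pri$calls, meta,
                                            config$hypermutation_threshold))
  stats <- msi_group_stats(burden)
  recurrent <- recurrent_variants(pri$calls, config = config$filter)
  paths$burden <- write_table(burden, out("burden.tsv"))
  paths$recurrent <- write_table(recurrent, out("recurrent.tsv"))
  say("landscape: ", sum(burden$hypermutated), " hypermutated samples, ",
      nrow(recurrent), " recurrent variants")

  # only substitutions with a trinucleotide context contribute to catalogs
  ctx_calls <- pri$calls[!is.na(pri$calls$context3), , drop = FALSE]
  catalog <- stage("signatures", build_catalog(ctx_calls, "cohort"))
  sig_df <- if (sum(catalog) == 0L) {
    data.frame(signature = character(), exposure = numeric(),
               exposure_prop = numeric(), cosine_to_catalog = numeric(),
               stringsAsFactors = FALSE)
  } else if (config$signature_mode == "refit") {
    fit <- refit_exposures(catalog, config$reference)
    data.frame(signature = names(fit$exposures),
               exposure = unname(fit$exposures),
               exposure_prop = unname(fit$exposures_prop),
               cosine_to_catalog = unname(fit$cosine_to_reference),
               stringsAsFactors = FALSE)
  } else {
    per_sample <- lapply(split(ctx_calls, ctx_calls$sample_id),
                         build_catalog)
    fit <- extract_denovo(per_sample, k = config$k, seed = config$seed,
                          reference = config$reference)
    data.frame(signature = fit$match$signature,
               reference = fit$match$reference,
               cosine = fit$match$cosine, stringsAsFactors = FALSE)
  }
  paths$signature_fit <- write_table(sig_df, out("signature_fit.tsv"))
  say("signatures: mode ", config$signature_mode)

  smg <- stage("drivers", smg_binomial(pri$calls, config$panel, nrow(meta),
                                       config$smg_background_rate))
  hot <- hotspot_driver_score(pri$calls, config$panel, nrow(meta),
                              fdr_threshold = config$fdr_threshold,
                              seed = config$seed)
  paths$smg <- write_table(smg, out("smg.tsv"))
  paths$hotspot <- write_table(hot, out("hotspot.tsv"))
  say("drivers: ", sum(smg$q_value < config$fdr_threshold),
      " genes below FDR ", config$fdr_threshold)

  report <- stage("druggability", match_rules(pri$calls, config$rules))
  act <- summarize_actionability(report, nrow(meta))
  paths$actionability <- write_table(report$matches, out("actionability.tsv"))
  say("druggability: ", act$n_actionable, "/", nrow(meta),
      " patients with >=1 match")

  pathogenic <- count_pathogenic(pri$calls)
  summary <- list(
    n_samples = nrow(meta),
    n_input_calls = nrow(tumour),
    n_survivors = nrow(pri$calls),
    n_hypermutated = sum(burden$hypermutated),
    median_rate_per_mb = stats$medians,
    msi_rank_p = stats$rank_p,
    msi_hypermutation_fisher_p = stats$fisher_p,
    n_recurrent_variants = nrow(recurrent),
    n_recurrent_genes = length(unique(recurrent$gene)),
    pathogenic_variants = unname(pathogenic["variants"]),
    pathogenic_genes = unname(pathogenic["genes"]),
    n_novel_flagged = sum(classify_novel(pri$calls, config$filter)$novel),
    fraction_actionable = act$fraction_actionable,
    seed = config$seed)
  paths$summary <- out("summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(calls = pri$calls, trace = pri$trace, burden = burden,
                 msi_stats = stats, recurrent = recurrent, catalog = catalog,
                 signature_fit = sig_df, smg = smg, hotspot = hot,
                 actionability = report, actionability_summary = act,
                 truth = truth, summary = summary, paths = paths))
}
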