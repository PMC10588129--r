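#' Default pipeline configuration
#'
#' Study-scale defaults: 8 virtual tumors of 2000 cells, three bulk
#' protocols per tumor at 5e6 reads, four pseudo-bulk scenarios of 50
#' samples each, reference ladder 2000/1000/500/200, demultiplexing
#' thresholds 0.90/0.85/0.80, NNLS deconvolution.
#'
#' @param ... overrides of the default fields
#' @return named list of class `run_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    cohort = list(),
    bulk_depth = 5e6,
    scenarios = c("realistic", "even", "sparse", "weighted"),
    n_pseudobulk = 50,
    pseudobulk_cells = 2000,
    noise_sd = 0.01,
    ladder = c(2000, 1000, 500, 200),
    thresholds = c(0.90, 0.85, 0.80),
    hash_adhesion = 0.9,
    doublet_rate = 0.05,
    methods = "nnls",
    pseudobulk_sources = NULL,
    anova_factors = c("method", "enrichment", "reference_size",
                      "dissociated")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_config("unknown config fields: ",
                                   paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file whose top-level keys are the fields of
#' [pipeline_config()] and validates it against the known schema before
#' any stage runs; unknown keys are a configuration error.
#'
#' @param path YAML file path
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_config("config file must hold a mapping")
  do.call(pipeline_config, raw)
}

#' Run the full benchmark pipeline
#'
#' Executes simulate (reference, matched bulk, demultiplexing tables) ->
#' demultiplexing calls and summaries -> pseudo-bulk scenarios ->
#' reference ladder and hash-subset reference -> deconvolution of every
#' (bulk x reference x method) and (pseudo-bulk x method) combination ->
#' evaluation (RMSE, differences, variance across protocols and
#' references, accuracy-vs-robustness summary, factor ANOVA). A rerun
#' with the same configuration is bit-identical. When `out_dir` is set,
#' all tables are written as TSV with a provenance JSON.
#'
#' @param config a [pipeline_config()]
#' @return list of class `evaluation_report` with elements `reference`,
#'   `bulk`, `demux`, `pseudobulk_rmse`, `differences`,
#'   `variance_protocol`, `variance_reference`, `stepwise`, `summary`,
#'   `anova`, `config`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  for (m in config$methods) get_method(m)  # fail fast on unknown methods
  seed <- config$seed

  cohort <- do.call(cohort_config, config$cohort)
  ref <- generate_reference(cohort, seed = seed)
  tumors <- sort(unique(ref$sample_id))
  blocks <- gene_blocks(ref$gene_ids)

  bulks <- list()
  for (tm in tumors) {
    set <- generate_bulk_set(ref, tm, depth = config$bulk_depth,
                             seed = seed, blocks = blocks)
    for (b in set) bulks[[paste(tm, b$protocol, sep = ".")]] <- b
  }

  demux_tabs <- generate_assignment_tables(
    ref, hash_adhesion = config$hash_adhesion,
    doublet_rate = config$doublet_rate, seed = seed)
  demux_summaries <- list()
  concordances <- list()
  hash_labels <- list()
  for (pn in names(demux_tabs)) {
    for (th in config$thresholds) {
      lab <- call_assignments(demux_tabs[[pn]]$hash, th)
      demux_summaries[[sprintf("%s_hash_%.2f", pn, th)]] <-
        summarize_assignments(lab)
      if (th == config$thresholds[1]) hash_labels[[pn]] <- lab
    }
    gen <- call_assignments(demux_tabs[[pn]]$genetic,
                            config$thresholds[1])
    demux_summaries[[sprintf("%s_genetic_%.2f", pn,
                             config$thresholds[1])]] <-
      summarize_assignments(gen)
    concordances[[pn]] <- concordance(hash_labels[[pn]], gen)
  }
  all_hash <- structure(list(
    label = unlist(lapply(hash_labels, `[[`, "label"), use.names = FALSE),
    barcodes = unlist(lapply(hash_labels, `[[`, "barcodes"),
                      use.names = FALSE),
    threshold = config$thresholds[1], modality = "hash"),
    class = "demux_labels")
  hash_ref <- subset_by_labels(ref, all_hash)

  pb_sources <- config$pseudobulk_sources
  if (is.null(pb_sources)) pb_sources <- tumors
  pb_sets <- lapply(config$scenarios, function(sc) {
    cfg <- scenario_config(sc, n_cells = config$pseudobulk_cells,
                           n_samples = config$n_pseudobulk,
                           noise_sd = config$noise_sd)
    build_scenario_dataset(ref, cfg, seed = child_seed(seed, sc),
                           source_samples = pb_sources)
  })
  names(pb_sets) <- config$scenarios

  ladder <- config$ladder[config$ladder < nrow(ref$counts)]
  refs <- c(list(full = ref),
            stats::setNames(lapply(ladder, function(sz) {
              downsample_reference(ref, sz, seed = seed)
            }), paste0("size", ladder)),
            list(hash_subset = hash_ref))
  sigs <- lapply(names(refs), function(tag) {
    build_signature(refs[[tag]], reference_tag = tag)
  })
  names(sigs) <- names(refs)

  bulk_results <- list()
  for (m in config$methods) {
    for (tag in names(sigs)) {
      for (bn in names(bulks)) {
        bulk_results[[paste(m, tag, bn, sep = "|")]] <-
          deconvolve(sigs[[tag]], bulks[[bn]], method = m)
      }
    }
  }
  pb_results <- list()
  pb_truths <- list()
  for (m in config$methods) {
    for (sc in names(pb_sets)) {
      for (nm in names(pb_sets[[sc]])) {
        r <- deconvolve(sigs$full, pb_sets[[sc]][[nm]], method = m)
        r$sample_id <- paste(sc, nm, sep = ".")
        pb_results[[paste(m, sc, nm, sep = "|")]] <- r
      }
      pb_truths[[sc]] <- truth_table(pb_sets[[sc]],
                                     ids = paste(sc, names(pb_sets[[sc]]),
                                                 sep = "."))
    }
  }

  pb_est <- do.call(rbind, lapply(names(pb_sets), function(sc) {
    sub <- pb_results[grepl(paste0("\\|", sc, "\\|"),
                            names(pb_results), fixed = FALSE)]
    results_table(sub, extra = list(scenario = sc))
  }))
  pb_truth_all <- do.call(rbind, pb_truths)
  pb_rmse <- rmse(pb_est, pb_truth_all, group = "scenario")
  pb_diff <- proportion_differences(pb_est, pb_truth_all,
                                    group = "scenario")

  bulk_est <- results_table(bulk_results)
  var_protocol <- robustness_variance(
    bulk_est[bulk_est$reference_tag == "full", ], vary = "protocol")
  var_reference <- robustness_variance(bulk_est, vary = "reference_tag")
  step <- if (length(ladder) >= 1) {
    stepwise_variance(bulk_est, order = c("full", paste0("size", ladder)))
  } else NULL
  summary_pts <- accuracy_robustness_summary(pb_rmse,
                                             var_protocol$by_method)

  meta <- do.call(rbind, lapply(bulk_results, function(r) {
    data.frame(method = r$method,
               enrichment = bulks[[paste(r$sample_id, r$protocol,
                                         sep = ".")]]$effects$enrichment,
               reference_size = r$reference_tag,
               dissociated = bulks[[paste(r$sample_id, r$protocol,
                                          sep = ".")]]$effects$dissociated,
               estimate = unname(r$fractions["epithelial"]))
  }))
  anova_tab <- withCallingHandlers(
    anova_factors(meta, factors = config$anova_factors),
    warning = function(w) invokeRestart("muffleWarning"))

  report <- structure(list(
    reference = ref, bulk = bulks,
    demux = list(summaries = demux_summaries, concordance = concordances,
                 hash_subset_retained_pct = attr(hash_ref, "retained_pct")),
    pseudobulk_rmse = pb_rmse, differences = pb_diff$means,
    variance_protocol = var_protocol, variance_reference = var_reference,
    stepwise = step, summary = summary_pts, anova = anova_tab,
    config = config
  ), class = "evaluation_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Write the report's tables and provenance under out_dir.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$pseudobulk_rmse, "pseudobulk_rmse")
  wt(report$differences, "differences")
  wt(report$variance_protocol$table, "variance_protocol")
  wt(report$variance_reference$table, "variance_reference")
  if (!is.null(report$stepwise)) wt(report$stepwise, "stepwise_variance")
  wt(report$summary, "accuracy_robustness")
  wt(report$anova, "anova")
  demux_df <- do.call(rbind, lapply(names(report$demux$summaries),
    function(nm) {
      s <- report$demux$summaries[[nm]]
      data.frame(table = nm, class = names(s$counts),
                 count = as.integer(s$counts), pct = as.numeric(s$pct))
    }))
  wt(demux_df, "demux_summaries")
  prov <- list(config = unclass(report$config),
               n_cells = nrow(report$reference$counts),
               n_genes = ncol(report$reference$counts),
               hash_subset_retained_pct =
                 report$demux$hash_subset_retained_pct)
  prov$config$out_dir <- NULL
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
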