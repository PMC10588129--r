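#' Flatten deconvolution results into a long table
#'
#' @param results list of [deconvolve()] results
#' @param extra named list of constant columns to add (e.g. scenario)
#' @return data.frame with columns method, reference_tag, protocol,
#'   sample, cell_type, estimate
#' @export
results_table <- function(results, extra = NULL) {
  rows <- lapply(results, function(r) {
    d <- data.frame(method = r$method,
                    reference_tag = r$reference_tag,
                    protocol = r$protocol,
                    sample = r$sample_id,
                    cell_type = names(r$fractions),
                    estimate = as.numeric(r$fractions),
                    stringsAsFactors = FALSE)
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Ground-truth table from pseudo-bulk or bulk samples
#'
#' @param samples list of [sample_pseudobulk()] or [generate_bulk()]
#'   results; pseudo-bulk truth is the RNA read-share
#'   (`truth_rna_fraction`), bulk truth the post-retention RNA fractions
#' @param ids optional sample ids (default: list names)
#' @return data.frame with columns sample, cell_type, truth
#' @export
truth_table <- function(samples, ids = names(samples)) {
  if (is.null(ids)) ids <- as.character(seq_along(samples))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    tr <- if (!is.null(s$truth_rna_fraction)) s$truth_rna_fraction
          else s$true_composition
    data.frame(sample = ids[i], cell_type = names(tr),
               truth = as.numeric(tr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Merge estimates with truths, asserting per-sample cell-type alignment.
align_truth <- function(estimates, truths) {
  merged <- merge(estimates, truths, by = c("sample", "cell_type"),
                  all.x = TRUE)
  if (anyNA(merged$truth)) {
    bad <- unique(merged$cell_type[is.na(merged$truth)])
    stop(errorCondition(
      paste0("cell types without ground truth: ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = c("deconvbench_alignment_error", "error")))
  }
  merged
}

#' Average root mean squared error of composition estimates
#'
#' Per-sample RMSE is the root of the mean squared error over cell
#' types; the reported value averages per-sample RMSE over all samples
#' within each (method, group) cell.
#'
#' @param estimates long table as [results_table()]
#' @param truths long table as [truth_table()]
#' @param group extra grouping columns of `estimates` (e.g.
#'   `"scenario"`, `"protocol"`)
#' @return data.frame with grouping columns and `rmse`
#' @export
rmse <- function(estimates, truths, group = character(0)) {
  merged <- align_truth(estimates, truths)
  merged$err2 <- (merged$estimate - merged$truth)^2
  keys <- c("method", group, "sample")
  per_sample <- stats::aggregate(err2 ~ ., data = merged[c(keys, "err2")],
                                 FUN = mean)
  per_sample$rmse <- sqrt(per_sample$err2)
  out_keys <- c("method", group)
  out <- stats::aggregate(rmse ~ ., data = per_sample[c(out_keys, "rmse")],
                          FUN = mean)
  out[do.call(order, unname(as.list(out[out_keys]))), , drop = FALSE]
}

#' Signed estimate-minus-truth differences by cell type
#'
#' Keeps every per-observation signed difference (for distribution
#' plots) and reports per-(method, group, cell type) means. A value of 0
#' marks perfect concordance between estimate and truth.
#'
#' @inheritParams rmse
#' @return list with `observations` (long table plus `difference`) and
#'   `means` (per-group mean difference)
#' @export
proportion_differences <- function(estimates, truths, group = character(0)) {
  merged <- align_truth(estimates, truths)
  merged$difference <- merged$estimate - merged$truth
  keys <- c("method", group, "cell_type")
  means <- stats::aggregate(difference ~ .,
                            data = merged[c(keys, "difference")], FUN = mean)
  list(observations = merged,
       means = means[do.call(order, unname(as.list(means[keys]))), ,
                     drop = FALSE])
}

#' Variance of estimates across an experimental condition
#'
#' For each (method, sample, cell type) key, the unbiased (n-1) sample
#' variance of the estimated fraction across the levels of the varied
#' condition — bulk protocol, reference profile, or any other column of
#' the results table. Keys observed under fewer than two levels are
#' excluded with a warning. Aggregates to per-method and
#' per-(method, cell type) means.
#'
#' @param results long table as [results_table()]
#' @param vary column name of the varied condition (e.g. `"protocol"`,
#'   `"reference_tag"`)
#' @return list with `table` (per-key variance), `by_method`,
#'   `by_method_cell_type`
#' @export
robustness_variance <- function(results, vary) {
  if (!vary %in% names(results)) stop_config("no column '", vary, "'")
  keys <- c("method", "sample", "cell_type")
  key <- interaction(results[keys], drop = TRUE)
  n_lev <- tapply(results[[vary]], key, function(v) length(unique(v)))
  singletons <- names(n_lev)[n_lev < 2]
  if (length(singletons)) {
    warning(length(singletons),
            " (method, sample, cell_type) keys observed under a single '",
            vary, "' level were excluded")
    results <- results[!(key %in% singletons), , drop = FALSE]
  }
  if (!nrow(results)) stop_config("no keys with >= 2 levels of ", vary)
  tab <- stats::aggregate(estimate ~ method + sample + cell_type,
                          data = results[c(keys, "estimate")],
                          FUN = stats::var)
  names(tab)[names(tab) == "estimate"] <- "variance"
  by_method <- stats::aggregate(variance ~ method, data = tab, FUN = mean)
  by_mct <- stats::aggregate(variance ~ method + cell_type, data = tab,
                             FUN = mean)
  list(table = tab, by_method = by_method, by_method_cell_type = by_mct)
}

#' Stepwise variance across a reference-size ladder
#'
#' Recomputes the across-reference variance cumulatively, adding one
#' smaller reference profile at a time, to show how robustness degrades
#' as smaller references enter.
#'
#' @param results long table as [results_table()]
#' @param order condition levels from largest to smallest
#' @param vary column holding the condition (default `"reference_tag"`)
#' @return data.frame with `step`, `levels_used`, `method`, `variance`
#' @export
stepwise_variance <- function(results, order,
                              vary = "reference_tag") {
  steps <- lapply(2:length(order), function(k) {
    sub <- results[results[[vary]] %in% order[seq_len(k)], , drop = FALSE]
    v <- robustness_variance(sub, vary)$by_method
    data.frame(step = k, levels_used = paste(order[seq_len(k)],
                                             collapse = "+"),
               method = v$method, variance = v$variance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  out
}

#' Accuracy-versus-robustness summary coordinates
#'
#' One point per method: mean variance across bulk protocols
#' (robustness, x) and mean RMSE against truth (accuracy, y).
#'
#' @param rmse_table output of [rmse()] aggregated per method (column
#'   `rmse`)
#' @param variance_table `by_method` table of [robustness_variance()]
#' @return data.frame with `method`, `mean_variance`, `mean_rmse`
#' @export
accuracy_robustness_summary <- function(rmse_table, variance_table) {
  r <- stats::aggregate(rmse ~ method, data = rmse_table, FUN = mean)
  v <- stats::aggregate(variance ~ method, data = variance_table, FUN = mean)
  if (!setequal(r$method, v$method)) {
    stop(errorCondition(
      "method sets of the RMSE and variance tables differ",
      class = c("deconvbench_coverage_error", "error")))
  }
  out <- merge(v, r, by = "method")
  names(out) <- c("method", "mean_variance", "mean_rmse")
  out[order(out$method), , drop = FALSE]
}

#' Fixed-effects ANOVA over experimental factors
#'
#' Explains a single cell type's estimated proportion (typically
#' epithelial, the most variable type) by the experimental factors:
#' deconvolution method, mRNA enrichment chemistry, reference-profile
#' size, and dissociation status. Sequential (Type I) sums of squares in
#' the given factor order; F = MS_factor / MS_residual.
#'
#' @param data data.frame with the response column and factor columns
#' @param response response column name (default `"estimate"`)
#' @param factors factor columns in the sequential order to test
#' @return data.frame with `term`, `df`, `sum_sq`, `mean_sq`,
#'   `statistic`, `p_value` (residual row included with NA statistic);
#'   attribute `degenerate` is TRUE for a zero-variance response
#' @export
anova_factors <- function(data, response = "estimate",
                          factors = c("method", "enrichment",
                                      "reference_size", "dissociated")) {
  factors <- factors[factors %in% names(data)]
  usable <- character(0)
  for (f in factors) {
    if (length(unique(data[[f]])) < 2) {
      warning("factor '", f, "' has a single level and was excluded")
    } else usable <- c(usable, f)
  }
  if (!length(usable)) stop_config("no factor with >= 2 levels")
  y <- data[[response]]
  if (stats::var(y) == 0) {
    out <- data.frame(term = c(usable, "Residuals"),
                      df = NA_integer_, sum_sq = 0, mean_sq = 0,
                      statistic = c(rep(0, length(usable)), NA),
                      p_value = NA_real_, stringsAsFactors = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  df <- data.frame(.y = y)
  for (f in usable) df[[f]] <- factor(data[[f]])
  form <- stats::as.formula(paste(".y ~", paste(usable, collapse = " + ")))
  a <- stats::anova(stats::lm(form, data = df))
  out <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, statistic = a$`F value`,
                    p_value = a$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  out
}
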