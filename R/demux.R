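#' Call per-cell sample assignments from a posterior table
#'
#' Applies the threshold rule of droplet demultiplexers: a cell whose
#' maximum posterior falls on the multiplet class is called `multiplet`
#' (never rescued as a singlet); otherwise the cell is assigned to its
#' best sample if that posterior reaches the threshold, and left
#' `unassigned` below it. Ties between samples break by lexicographic
#' sample id.
#'
#' @param table an [assignment_table()]
#' @param threshold posterior probability threshold in (0, 1]
#'   (default 0.90, the common demultiplexer default)
#' @return object of class `demux_labels`: list with `label` (per-cell
#'   character), `barcodes`, `threshold`, `modality`
#' @export
call_assignments <- function(table, threshold = 0.90) {
  stopifnot(inherits(table, "assignment_table"))
  if (threshold <= 0 || threshold > 1) {
    stop_config("threshold must lie in (0, 1]")
  }
  post <- table$posterior
  bad <- which(abs(rowSums(post) - 1) > 1e-6)
  if (length(bad)) {
    stop(errorCondition(
      paste0("malformed posterior rows (do not sum to 1): ",
             paste(utils::head(table$barcodes[bad], 5), collapse = ", ")),
      class = c("deconvbench_malformed_table", "error")))
  }
  s <- ncol(post) - 1L
  samples <- colnames(post)[seq_len(s)]
  ord <- order(samples)  # lexicographic tie-break
  sample_post <- post[, samples[ord], drop = FALSE]
  best_idx <- apply(sample_post, 1, which.max)
  best_p <- sample_post[cbind(seq_len(nrow(post)), best_idx)]
  mult_p <- post[, "multiplet"]
  label <- unname(ifelse(mult_p > best_p, "multiplet",
                         ifelse(best_p >= threshold,
                                samples[ord][best_idx], "unassigned")))
  structure(list(label = label, barcodes = table$barcodes,
                 threshold = threshold, modality = table$modality),
            class = "demux_labels")
}

#' Summarize assignment calls
#'
#' Exact integer counts of assigned / multiplet / unassigned cells and
#' per-sample assigned counts, with percentages rounded half away from
#' zero to one decimal.
#'
#' @param labels a [call_assignments()] result, or any character vector
#'   of labels in which `multiplet` / `unassigned` are the non-sample
#'   classes
#' @return object of class `demux_summary`: list with `n_total`,
#'   `counts` (assigned, multiplet, unassigned), `pct` (same keys,
#'   1-decimal), `per_sample` (named assigned counts)
#' @export
summarize_assignments <- function(labels) {
  lab <- if (inherits(labels, "demux_labels")) labels$label else labels
  if (length(lab) == 0) stop_config("no labels to summarize")
  n <- length(lab)
  n_mult <- sum(lab == "multiplet")
  n_un <- sum(lab == "unassigned")
  n_asn <- n - n_mult - n_un
  per_sample <- table(lab[!(lab %in% c("multiplet", "unassigned"))])
  structure(list(
    n_total = n,
    counts = c(assigned = n_asn, multiplet = n_mult, unassigned = n_un),
    pct = c(assigned = pct1(n_asn, n),
            multiplet = pct1(n_mult, n),
            unassigned = pct1(n_un, n)),
    per_sample = per_sample
  ), class = "demux_summary")
}

#' @export
print.demux_summary <- function(x, ...) {
  cat(sprintf("%d cells: %d assigned (%.1f%%), %d multiplet (%.1f%%), %d unassigned (%.1f%%)\n",
              x$n_total, x$counts["assigned"], x$pct["assigned"],
              x$counts["multiplet"], x$pct["multiplet"],
              x$counts["unassigned"], x$pct["unassigned"]))
  invisible(x)
}

#' Cross-modality assignment concordance
#'
#' Confusion matrix of two label sets over the same barcodes (samples
#' plus multiplet/unassigned margins) and the percent of cells assigned
#' to the same sample among cells assigned to a sample by both
#' modalities. With zero doubly-assigned cells the percentage is
#' reported as NA with `percent_available = FALSE`.
#'
#' @param a,b [call_assignments()] results over the same barcodes
#' @return object of class `concordance_report`: list with `matrix`
#'   (a-labels x b-labels counts), `percent_same`, `percent_available`,
#'   `n_doubly_assigned`
#' @export
concordance <- function(a, b) {
  if (length(a$barcodes) != length(b$barcodes) ||
      !setequal(a$barcodes, b$barcodes)) {
    stop_config("label sets cover different barcodes")
  }
  bl <- b$label[match(a$barcodes, b$barcodes)]
  al <- a$label
  special <- c("multiplet", "unassigned")
  samples <- sort(unique(c(setdiff(al, special), setdiff(bl, special))))
  lev <- c(samples, special)
  m <- table(factor(al, levels = lev), factor(bl, levels = lev))
  both <- !(al %in% special) & !(bl %in% special)
  n_both <- sum(both)
  pct <- if (n_both > 0) round_half_up(100 * sum(al[both] == bl[both]) / n_both, 1) else NA_real_
  structure(list(
    matrix = m,
    percent_same = pct,
    percent_available = n_both > 0,
    n_doubly_assigned = n_both
  ), class = "concordance_report")
}
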