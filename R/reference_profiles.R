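#' Default reference-profile size ladder
#'
#' Strictly decreasing target cell counts for reduced reference
#' profiles.
#'
#' @param sizes integer vector (default 2000, 1000, 500, 200)
#' @return validated integer vector of class `size_ladder`
#' @export
size_ladder <- function(sizes = c(2000, 1000, 500, 200)) {
  sizes <- as.integer(sizes)
  if (any(sizes <= 0) || any(diff(sizes) >= 0)) {
    stop_config("ladder sizes must be strictly decreasing positive integers")
  }
  structure(sizes, class = "size_ladder")
}

#' Downsample a reference to a target cell count
#'
#' Mirrors the full dataset's cell-type proportions at a reduced size:
#' per-type quotas come from largest-remainder apportionment of the
#' target, every type is then guaranteed at least one cell (taking the
#' slot from the largest quota), and cells are drawn without replacement
#' within type. Because of integer rounding and the minimum-one rule the
#' realized size can differ slightly from the target.
#'
#' @param dataset an [sc_dataset()]
#' @param target desired total cell count
#' @param seed integer seed
#' @return downsampled [sc_dataset()]
#' @export
downsample_reference <- function(dataset, target, seed = 1) {
  types <- sort(unique(dataset$cell_type))
  n_by_type <- vapply(types, function(t) sum(dataset$cell_type == t),
                      integer(1))
  if (target < length(types)) {
    stop(errorCondition(
      paste0("target ", target, " below the number of cell types (",
             length(types), "): cannot give each type one cell"),
      class = c("deconvbench_infeasible_minimum", "error")))
  }
  if (target > sum(n_by_type)) stop_config("target exceeds total cells")
  quota <- apportion_largest_remainder(n_by_type / sum(n_by_type), target)
  for (z in which(quota == 0)) {
    donor <- which.max(quota)
    quota[donor] <- quota[donor] - 1L
    quota[z] <- 1L
  }
  quota <- pmin(quota, n_by_type)  # cannot exceed availability
  with_seed(child_seed(seed, paste0("downsample_", target)), {
    idx <- unlist(lapply(seq_along(types), function(k) {
      pool <- which(dataset$cell_type == types[k])
      pool[sample.int(length(pool), quota[k])]
    }))
    subset_cells(dataset, sort(idx))
  })
}

#' Subset a reference to demultiplexing-assigned cells
#'
#' Retains exactly the cells whose demultiplexing label is a sample
#' (dropping multiplet and unassigned cells); counts are unmodified.
#' The retained fraction (1-decimal percent) is attached as attribute
#' `retained_pct`.
#'
#' @param dataset an [sc_dataset()]
#' @param labels a [demux_labels] object covering the dataset's barcodes
#' @return subset [sc_dataset()]
#' @export
subset_by_labels <- function(dataset, labels) {
  lab <- labels$label[match(dataset$barcodes, labels$barcodes)]
  if (anyNA(lab)) {
    stop_config("labels do not cover all dataset barcodes")
  }
  keep <- !(lab %in% c("multiplet", "unassigned"))
  if (!any(keep)) {
    stop(errorCondition("no cells retained: empty reference",
         class = c("deconvbench_empty_reference", "error")))
  }
  out <- subset_cells(dataset, which(keep))
  attr(out, "retained_pct") <- pct1(sum(keep), length(keep))
  out
}
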