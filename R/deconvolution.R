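#' Build a cell-type signature matrix from a single-cell reference
#'
#' Normalizes each cell to counts-per-million, averages within cell
#' type, and drops genes with zero expression across all types. Records
#' the number of cells behind each column so downstream methods can
#' enforce their minimum-cell requirements.
#'
#' @param reference an annotated [sc_dataset()]
#' @return object of class `signature_matrix`: list with `profile`
#'   (genes x cell-types CPM matrix), `gene_ids`, `cell_types`,
#'   `n_cells` (named per-type cell counts), `reference_tag`
#' @param reference_tag label identifying the reference (size, subset)
#' @export
build_signature <- function(reference, reference_tag = "full") {
  if (anyNA(reference$cell_type) || any(reference$cell_type == "")) {
    stop_config("reference contains unannotated cells")
  }
  types <- sort(unique(reference$cell_type))
  totals <- reference$total_reads
  if (any(totals == 0)) stop_config("reference contains empty cells")
  cpm <- reference$counts / totals * 1e6
  profile <- vapply(types, function(t) {
    rows <- which(reference$cell_type == t)
    Matrix::colMeans(cpm[rows, , drop = FALSE])
  }, numeric(ncol(cpm)))
  keep <- rowSums(profile) > 0
  n_cells <- vapply(types, function(t) sum(reference$cell_type == t),
                    integer(1))
  structure(list(
    profile = profile[keep, , drop = FALSE],
    gene_ids = reference$gene_ids[keep],
    cell_types = types,
    n_cells = n_cells,
    reference_tag = reference_tag
  ), class = "signature_matrix")
}

# --- method registry -------------------------------------------------------

.method_registry <- new.env(parent = emptyenv())

#' Register a deconvolution method
#'
#' Methods plug into [deconvolve()] through a uniform interface: a
#' function taking the gene-intersected signature matrix (genes x types,
#' CPM) and the bulk CPM vector, returning non-negative raw weights per
#' type. `min_cells` records the method's minimum reference cells per
#' type; types below it are reported as absent rather than zero.
#'
#' @param name method name
#' @param fn function(signature_profile, bulk_cpm) -> numeric weights
#' @param min_cells minimum cells per type the method will quantify
#' @export
register_method <- function(name, fn, min_cells = 1L) {
  assign(name, list(fn = fn, min_cells = as.integer(min_cells)),
         envir = .method_registry)
  invisible(name)
}

#' List registered deconvolution methods
#' @return character vector of method names
#' @export
list_methods <- function() ls(.method_registry)

get_method <- function(name) {
  if (!exists(name, envir = .method_registry)) {
    stop(errorCondition(
      paste0("unknown deconvolution method '", name, "'; registered: ",
             paste(list_methods(), collapse = ", ")),
      class = c("deconvbench_registry_error", "error")))
  }
  get(name, envir = .method_registry)
}

#' Estimate cell-type RNA fractions of a bulk sample
#'
#' Intersects the signature and bulk gene universes, per-million
#' normalizes the bulk vector, dispatches to the registered method,
#' clamps negative weights at zero, and renormalizes to sum 1. The
#' estimates are RNA fractions (share of transcripts per cell type), the
#' same convention as the pseudo-bulk ground truth; no mRNA-content
#' back-correction is applied. Cell types whose reference falls below
#' the method's minimum-cell requirement are excluded from the solve and
#' reported in `absent` with a reason.
#'
#' @param signature a [build_signature()] result
#' @param bulk a [generate_bulk()] / [sample_pseudobulk()] result, or a
#'   named count vector
#' @param method registered method name (default `"nnls"`)
#' @param min_overlap minimum gene overlap required (default 200)
#' @return object of class `deconvolution_result`: list with `method`,
#'   `sample_id`, `protocol`, `reference_tag`, `fractions` (named, sums
#'   to 1 over quantified types), `absent` (named reasons), `n_genes`
#' @export
deconvolve <- function(signature, bulk, method = "nnls",
                       min_overlap = 200) {
  m <- get_method(method)
  counts <- if (is.list(bulk)) bulk$counts else bulk
  sample_id <- if (is.list(bulk) && !is.null(bulk$sample_id)) bulk$sample_id
               else if (is.list(bulk) && !is.null(bulk$source_sample)) bulk$source_sample
               else NA_character_
  protocol <- if (is.list(bulk) && !is.null(bulk$protocol)) {
    if (is.character(bulk$protocol)) bulk$protocol else bulk$protocol$protocol
  } else NA_character_
  genes <- intersect(signature$gene_ids, names(counts))
  if (length(genes) < min_overlap) {
    stop(errorCondition(
      sprintf("gene overlap %d below the required minimum %d",
              length(genes), min_overlap),
      class = c("deconvbench_overlap_error", "error")))
  }
  eligible <- signature$n_cells >= m$min_cells
  absent <- stats::setNames(
    rep(sprintf("fewer than %d reference cells", m$min_cells),
        sum(!eligible)),
    signature$cell_types[!eligible])
  prof <- signature$profile[match(genes, signature$gene_ids),
                            eligible, drop = FALSE]
  b <- counts[genes] / sum(counts) * 1e6
  raw <- m$fn(prof, b)
  raw <- pmax(as.numeric(raw), 0)
  if (sum(raw) == 0) raw <- rep(1 / length(raw), length(raw))
  frac <- stats::setNames(raw / sum(raw), colnames(prof))
  structure(list(
    method = method,
    sample_id = sample_id,
    protocol = protocol,
    reference_tag = signature$reference_tag,
    fractions = frac,
    absent = absent,
    n_genes = length(genes)
  ), class = "deconvolution_result")
}

# built-in method: non-negative least squares on CPM
register_method("nnls", function(profile, bulk_cpm) {
  nnls_solve(profile, bulk_cpm)$x
}, min_cells = 1L)
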