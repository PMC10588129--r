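#' Construct an annotated single-cell dataset
#'
#' Container for sparse cell x gene counts with per-cell cell-type and
#' sample-of-origin labels: the reference-profile role throughout the
#' benchmark.
#'
#' @param counts cells x genes matrix (coerced to sparse dgCMatrix);
#'   non-negative integers
#' @param cell_type character vector, one label per cell
#' @param sample_id character vector, tumor of origin per cell
#' @param gene_ids character vector of gene identifiers (defaults to
#'   `colnames(counts)`)
#' @param barcodes per-cell barcodes (generated when NULL)
#' @return object of class `sc_dataset` with fields `counts`, `cell_type`,
#'   `sample_id`, `gene_ids`, `barcodes`, `total_reads` (per-cell row sums)
#' @export
sc_dataset <- function(counts, cell_type, sample_id, gene_ids = NULL,
                       barcodes = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  n <- nrow(counts)
  if (length(cell_type) != n || length(sample_id) != n) {
    stop_config("cell_type and sample_id must label every cell")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_config("counts must be non-negative integers")
  }
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(ncol(counts)))
  if (is.null(barcodes)) barcodes <- sprintf("cell%06d", seq_len(n))
  if (anyDuplicated(barcodes)) stop_config("duplicate barcodes")
  colnames(counts) <- gene_ids
  rownames(counts) <- barcodes
  structure(list(
    counts = counts,
    cell_type = as.character(cell_type),
    sample_id = as.character(sample_id),
    gene_ids = gene_ids,
    barcodes = barcodes,
    total_reads = Matrix::rowSums(counts)
  ), class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d cells x %d genes, %d samples, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_id)), length(unique(x$cell_type))))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

# Subset cells by integer/logical index, keeping annotations aligned.
subset_cells <- function(dataset, idx) {
  sc_dataset(dataset$counts[idx, , drop = FALSE],
             dataset$cell_type[idx],
             dataset$sample_id[idx],
             gene_ids = dataset$gene_ids,
             barcodes = dataset$barcodes[idx])
}

#' Generate a virtual single-cell reference cohort
#'
#' Draws annotated cells for every tumor in the cohort from the
#' gamma-Poisson count model: expected expression is the cell-type
#' archetype times a per-tumor log-normal patient effect, scaled by a
#' per-cell library size whose mean carries the type's mRNA-content
#' scale. Cell numbers per type follow the tumor's composition prior via
#' largest-remainder apportionment; every type with positive prior gets
#' at least one cell.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed; output is deterministic given (config, seed)
#' @return an [sc_dataset()]
#' @export
generate_reference <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  types <- config$cell_types$name
  tumors <- rownames(config$baseline_composition)
  with_seed(child_seed(seed, "reference"), {
    per_tumor <- lapply(seq_along(tumors), function(ti) {
      props <- config$baseline_composition[ti, ]
      tally <- apportion_largest_remainder(props, config$cells_per_tumor)
      # guarantee representation of every positively weighted type
      zero <- which(tally == 0 & props > 0)
      for (z in zero) {
        tally[which.max(tally)] <- tally[which.max(tally)] - 1L
        tally[z] <- 1L
      }
      pat <- exp(stats::rnorm(config$n_genes, 0, config$patient_effect_sd))
      mats <- lapply(seq_along(types), function(k) {
        n_k <- tally[k]
        if (n_k == 0) return(NULL)
        rate <- config$archetypes[, k] * pat
        rate <- rate / sum(rate)
        scale_k <- config$cell_types$mrna_scale[k]
        mu_lib <- config$lib_size_mean * scale_k
        sdl <- config$lib_size_sdlog
        libs <- stats::rlnorm(n_k, meanlog = log(mu_lib) - sdl^2 / 2,
                              sdlog = sdl)
        mu <- outer(libs, rate)
        phi <- config$dispersion
        lambda <- if (phi > 0) {
          mu * stats::rgamma(length(mu), shape = 1 / phi, rate = 1 / phi)
        } else mu
        cnt <- stats::rpois(length(lambda), lambda)
        matrix(cnt, nrow = n_k)
      })
      keep <- !vapply(mats, is.null, logical(1))
      m <- do.call(rbind, mats[keep])
      list(counts = m,
           cell_type = rep(types[keep], tally[keep]),
           sample_id = rep(tumors[ti], sum(tally)))
    })
    counts <- Matrix::Matrix(do.call(rbind, lapply(per_tumor, `[[`, "counts")),
                             sparse = TRUE)
    sc_dataset(counts,
               cell_type = unlist(lapply(per_tumor, `[[`, "cell_type")),
               sample_id = unlist(lapply(per_tumor, `[[`, "sample_id")),
               gene_ids = config$gene_ids)
  })
}
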