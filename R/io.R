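#' Write a single-cell dataset in the 10x-style triplet layout
#'
#' Emits `matrix.mtx` (MatrixMarket coordinate integer, genes x cells),
#' `features.tsv`, `barcodes.tsv`, and `cells.tsv` (barcode, sample_id,
#' cell_type) into `dir`.
#'
#' @param dataset an [sc_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_single_cell <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(dataset$counts)  # genes x cells, 10x orientation
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(dataset$gene_ids, file.path(dir, "features.tsv"))
  writeLines(dataset$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = dataset$barcodes,
               sample_id = dataset$sample_id,
               cell_type = dataset$cell_type),
    file.path(dir, "cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Resolve a triplet file that may be gzipped (10x convention).
resolve_file <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop_config("missing file ", base, " in ", dir)
}

#' Read a single-cell dataset from a triplet directory
#'
#' Accepts plain or gzipped `matrix.mtx` / `features.tsv` /
#' `barcodes.tsv` plus the annotation file `cells.tsv`. Round-trips
#' bit-exactly with [write_single_cell()]; every barcode must be
#' annotated and all matrix entries must be non-negative integers.
#'
#' @param dir directory holding the files
#' @return an [sc_dataset()]
#' @export
read_single_cell <- function(dir) {
  m <- Matrix::readMM(resolve_file(dir, "matrix.mtx"))
  genes <- readLines(resolve_file(dir, "features.tsv"))
  barcodes <- readLines(resolve_file(dir, "barcodes.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1)
  barcodes <- vapply(strsplit(barcodes, "\t"), `[[`, character(1), 1)
  ann <- utils::read.table(resolve_file(dir, "cells.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop_config("matrix dimensions do not match features/barcodes")
  }
  if (any(m@x != round(m@x)) || any(m@x < 0)) {
    stop_config("non-integer or negative matrix entries")
  }
  missing <- setdiff(barcodes, ann$barcode)
  if (length(missing)) {
    stop_config("barcodes missing from cells.tsv: ",
                paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- match(barcodes, ann$barcode)
  sc_dataset(Matrix::t(m), cell_type = ann$cell_type[idx],
             sample_id = ann$sample_id[idx], gene_ids = genes,
             barcodes = barcodes)
}

# Deterministic numeric formatting for TSV writers: 6 significant digits.
fmt_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         formatC(x, digits = 6, format = "g"))
}

#' Write bulk samples as a gene x sample TSV with protocol metadata
#'
#' @param bulks list of [generate_bulk()] results over the same gene
#'   universe
#' @param path output TSV path; a `<path>.protocols.tsv` sidecar records
#'   sample id, protocol, dissociation and enrichment
#' @return `path`, invisibly
#' @export
write_bulk <- function(bulks, path) {
  ids <- vapply(bulks, function(b) paste(b$sample_id, b$protocol, sep = "."),
                character(1))
  m <- do.call(cbind, lapply(bulks, `[[`, "counts"))
  colnames(m) <- ids
  df <- data.frame(gene = names(bulks[[1]]$counts), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- do.call(rbind, lapply(bulks, function(b) {
    data.frame(column = paste(b$sample_id, b$protocol, sep = "."),
               sample_id = b$sample_id, protocol = b$protocol,
               dissociated = b$effects$dissociated,
               enrichment = b$effects$enrichment)
  }))
  utils::write.table(meta, paste0(path, ".protocols.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bulk gene x sample TSV
#'
#' @param path TSV as written by [write_bulk()]
#' @return list with `counts` (gene x sample matrix) and `metadata`
#'   (protocol sidecar, NULL if absent)
#' @export
read_bulk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  side <- paste0(path, ".protocols.tsv")
  meta <- if (file.exists(side)) {
    utils::read.table(side, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  list(counts = m, metadata = meta)
}

#' Write an assignment posterior table as TSV
#'
#' Columns: barcode, one posterior column per sample, `multiplet`, and
#' `true_sample` when available.
#'
#' @param table an [assignment_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_assignment_table <- function(table, path) {
  df <- data.frame(barcode = table$barcodes,
                   apply(table$posterior, 2, fmt_num),
                   check.names = FALSE)
  if (!is.null(table$true_sample)) df$true_sample <- table$true_sample
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assignment posterior table from TSV
#'
#' @param path TSV as written by [write_assignment_table()]
#' @param modality `"hash"` or `"genetic"`
#' @return an [assignment_table()]
#' @export
read_assignment_table <- function(path, modality = "hash") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  truth <- if ("true_sample" %in% names(df)) df$true_sample else NULL
  post_cols <- setdiff(names(df), c("barcode", "true_sample"))
  post <- as.matrix(df[post_cols])
  # renormalize away formatting rounding
  post <- post / rowSums(post)
  assignment_table(post, modality, true_sample = truth,
                   barcodes = df$barcode)
}
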