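#' Default cell-type roster for a virtual HGSOC cohort
#'
#' Ten cell types typical of high-grade serous ovarian carcinoma tissue.
#' `mrna_scale` is the relative per-cell mRNA content (epithelial tumor
#' cells carry more transcripts than small lymphocytes); `fragile` marks
#' types destroyed by standard tissue dissociation (erythrocytes are lysed
#' by red-cell removal buffers, adipocytes rupture mechanically).
#'
#' @return data.frame with columns `name`, `mrna_scale`, `fragile`,
#'   `base_prop` (cohort-level mean cell proportion)
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("epithelial", "endothelial", "fibroblast", "macrophage",
             "T", "B", "NK", "plasma", "erythrocyte", "adipocyte"),
    mrna_scale = c(1.5, 0.9, 1.0, 1.0, 0.6, 0.6, 0.6, 1.3, 0.3, 0.8),
    fragile = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, TRUE, TRUE),
    base_prop = c(0.40, 0.08, 0.15, 0.10, 0.12,
                  0.04, 0.03, 0.02, 0.04, 0.02),
    stringsAsFactors = FALSE
  )
}

# Sizes of the named marker/technical gene blocks carved out of the gene
# universe. Hemoglobin marks erythrocytes; the mitochondrial block models
# the 13 protein-coding mtDNA transcripts; canonical histones are the
# non-polyadenylated replication-dependent cluster.
.block_sizes <- c(
  hemoglobin = 8, adipocyte = 12, endothelial = 15,
  stress = 20, histone = 40, mito = 13
)

#' Cohort configuration for the synthetic-data generator
#'
#' Defines a virtual tumor cohort: number of tumors, cell-type roster with
#' mRNA-content scales and dissociation-fragility flags, gene universe with
#' named marker/technical gene blocks, per-tumor composition priors, and
#' the count-model parameters.
#'
#' The count model is gamma-Poisson (negative binomial): each cell type has
#' an expression archetype (log-normal gene draws plus additive marker
#' blocks), perturbed per tumor by a log-normal patient effect, scaled by a
#' per-cell library size whose mean carries the type's mRNA-content scale.
#'
#' @param n_tumors number of virtual tumors (default 8)
#' @param cell_types data.frame as [default_cell_types()]
#' @param n_genes size of the gene universe (must exceed the total marker
#'   block size; default 2000)
#' @param cells_per_tumor cells generated per tumor (default 2000)
#' @param patient_effect_sd sd of per-tumor per-gene log-fold perturbation
#' @param dispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson counts
#' @param lib_size_mean mean library size (reads) of an mrna_scale = 1 cell
#' @param lib_size_sdlog log-sd of the per-cell library size
#' @param composition_concentration Dirichlet concentration of the
#'   per-tumor composition prior around `cell_types$base_prop`
#' @param baseline_composition optional tumors x types matrix of cell-type
#'   proportion priors (rows sum to 1); generated from the Dirichlet prior
#'   when NULL
#' @param rng_seed seed used for the archetypes and composition priors
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_tumors = 8,
                          cell_types = default_cell_types(),
                          n_genes = 2000,
                          cells_per_tumor = 2000,
                          patient_effect_sd = 0.15,
                          dispersion = 0.3,
                          lib_size_mean = 2500,
                          lib_size_sdlog = 0.35,
                          composition_concentration = 60,
                          baseline_composition = NULL,
                          rng_seed = 20260101) {
  if (n_genes < sum(.block_sizes) + 100) {
    stop_config("n_genes too small for the marker blocks")
  }
  stopifnot(is.data.frame(cell_types),
            all(c("name", "mrna_scale", "fragile") %in% names(cell_types)))
  types <- cell_types$name
  blocks <- make_gene_blocks(n_genes)

  if (is.null(baseline_composition)) {
    baseline_composition <- with_seed(child_seed(rng_seed, "composition"), {
      alpha <- cell_types$base_prop * composition_concentration
      t(vapply(seq_len(n_tumors), function(i) {
        g <- stats::rgamma(length(alpha), shape = alpha)
        g / sum(g)
      }, numeric(length(alpha))))
    })
    rownames(baseline_composition) <- sprintf("tumor%02d", seq_len(n_tumors))
    colnames(baseline_composition) <- types
  }
  if (any(baseline_composition < 0) ||
      any(abs(rowSums(baseline_composition) - 1) > 1e-9)) {
    stop_config("baseline composition rows must be non-negative and sum to 1")
  }
  if (nrow(baseline_composition) != n_tumors ||
      ncol(baseline_composition) != length(types)) {
    stop_config("baseline composition has wrong dimensions")
  }

  archetypes <- with_seed(child_seed(rng_seed, "archetypes"),
                          make_archetypes(n_genes, types, blocks))

  structure(list(
    n_tumors = n_tumors,
    cell_types = cell_types,
    n_genes = n_genes,
    cells_per_tumor = cells_per_tumor,
    patient_effect_sd = patient_effect_sd,
    dispersion = dispersion,
    lib_size_mean = lib_size_mean,
    lib_size_sdlog = lib_size_sdlog,
    baseline_composition = baseline_composition,
    gene_ids = blocks$gene_ids,
    blocks = blocks$blocks,
    archetypes = archetypes,
    rng_seed = rng_seed
  ), class = "cohort_config")
}

# Lay out the gene universe: named blocks occupy the leading indices,
# remaining genes are background. Blocks are disjoint by construction.
make_gene_blocks <- function(n_genes) {
  sizes <- .block_sizes
  prefixes <- c(hemoglobin = "HBL", adipocyte = "ADI", endothelial = "ENDM",
                stress = "STR", histone = "HIST", mito = "MTL")
  blocks <- list()
  ids <- character(n_genes)
  pos <- 1L
  for (b in names(sizes)) {
    idx <- seq.int(pos, pos + sizes[[b]] - 1L)
    blocks[[b]] <- idx
    ids[idx] <- sprintf("%s%02d", prefixes[[b]], seq_along(idx))
    pos <- pos + sizes[[b]]
  }
  bg <- seq.int(pos, n_genes)
  ids[bg] <- sprintf("G%04d", seq_along(bg))
  list(gene_ids = ids, blocks = blocks)
}

# Per-type expected relative expression (columns sum to 1). Background
# genes get independent log-normal draws per type (types are mutually
# distinguishable); block genes are set so each block accounts for a
# controlled share of the type's reads.
make_archetypes <- function(n_genes, types, layout) {
  blocks <- layout$blocks
  # block read-share targets by cell type
  share <- function(type, block) {
    switch(block,
      hemoglobin = if (type == "erythrocyte") 0.85 else 0.001,
      adipocyte = if (type == "adipocyte") 0.45 else 5e-4,
      endothelial = if (type == "endothelial") 0.25 else 0.001,
      stress = 0.010,
      histone = 0.018,
      mito = 0.11
    )
  }
  arch <- matrix(0, nrow = n_genes, ncol = length(types),
                 dimnames = list(layout$gene_ids, types))
  all_block_idx <- unlist(blocks, use.names = FALSE)
  bg_idx <- setdiff(seq_len(n_genes), all_block_idx)
  for (t in types) {
    raw <- stats::rlnorm(length(bg_idx), meanlog = 0, sdlog = 1.2)
    shares <- vapply(names(blocks), function(b) share(t, b), numeric(1))
    bg_share <- 1 - sum(shares)
    col <- numeric(n_genes)
    col[bg_idx] <- raw / sum(raw) * bg_share
    for (b in names(blocks)) {
      idx <- blocks[[b]]
      w <- stats::rlnorm(length(idx), meanlog = 0, sdlog = 0.5)
      col[idx] <- w / sum(w) * shares[[b]]
    }
    arch[, t] <- col
  }
  arch
}
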