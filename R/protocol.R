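#' Experimental protocol effects for bulk sample generation
#'
#' Describes how a bulk library preparation distorts the tissue's
#' expression profile. Dissociation removes fragile cell types
#' (erythrocytes are lysed during red-cell removal, adipocytes rupture)
#' and induces a stress-response program; the mRNA enrichment chemistry
#' biases gene classes: poly-A capture loses non-polyadenylated canonical
#' histone transcripts, while the common rRNA-depletion kit co-depletes
#' mitochondrial transcripts off-target.
#'
#' `histone_polyA_retention` is the fraction of histone-block signal
#' surviving poly-A capture; `mito_depletion_rRNA` the fraction of
#' mitochondrial signal surviving rRNA depletion. Their defaults sit at
#' the geometric midpoints of the observed fold-change windows
#' (histone rRNA/polyA in [1.7, 10], mito polyA/rRNA in [10, 30]);
#' [generate_bulk_set()] replaces them with per-tumor calibrated values.
#'
#' @param protocol one of `"rRNA_chunk"`, `"rRNA_dissociated"`,
#'   `"polyA_dissociated"`, or NULL to set fields directly
#' @param dissociated logical
#' @param enrichment `"rRNA_depletion"` or `"polyA"`
#' @param erythrocyte_retention,adipocyte_retention fraction of the
#'   fragile type surviving preparation (default 0 when dissociated,
#'   1 for intact chunk tissue)
#' @param stress_induction multiplicative factor >= 1 on stress-response
#'   genes when dissociated
#' @param histone_polyA_retention fraction in (0, 1]
#' @param mito_depletion_rRNA fraction in (0, 1]
#' @return object of class `protocol_effects`
#' @export
protocol_effects <- function(protocol = NULL,
                             dissociated = FALSE,
                             enrichment = c("rRNA_depletion", "polyA"),
                             erythrocyte_retention = NULL,
                             adipocyte_retention = NULL,
                             stress_induction = NULL,
                             histone_polyA_retention = 1 / sqrt(1.7 * 10),
                             mito_depletion_rRNA = 1 / sqrt(10 * 30)) {
  if (!is.null(protocol)) {
    protocol <- match.arg(protocol,
                          c("rRNA_chunk", "rRNA_dissociated",
                            "polyA_dissociated"))
    dissociated <- protocol != "rRNA_chunk"
    enrichment <- if (protocol == "polyA_dissociated") "polyA"
                  else "rRNA_depletion"
  } else {
    enrichment <- match.arg(enrichment)
    protocol <- if (!dissociated) "rRNA_chunk"
                else if (enrichment == "polyA") "polyA_dissociated"
                else "rRNA_dissociated"
  }
  if (is.null(erythrocyte_retention)) {
    erythrocyte_retention <- if (dissociated) 0 else 1
  }
  if (is.null(adipocyte_retention)) {
    adipocyte_retention <- if (dissociated) 0 else 1
  }
  if (is.null(stress_induction)) stress_induction <- if (dissociated) 3 else 1
  ret <- c(erythrocyte_retention, adipocyte_retention,
           histone_polyA_retention, mito_depletion_rRNA)
  if (any(ret < 0) || any(ret > 1)) {
    stop_config("retention/depletion factors must lie in [0, 1]")
  }
  if (histone_polyA_retention <= 0 || mito_depletion_rRNA <= 0) {
    stop_config("enrichment retention factors must be positive")
  }
  if (stress_induction < 1) stop_config("stress_induction must be >= 1")
  structure(list(
    protocol = protocol,
    dissociated = dissociated,
    enrichment = enrichment,
    erythrocyte_retention = erythrocyte_retention,
    adipocyte_retention = adipocyte_retention,
    stress_induction = stress_induction,
    histone_polyA_retention = histone_polyA_retention,
    mito_depletion_rRNA = mito_depletion_rRNA
  ), class = "protocol_effects")
}

#' Locate the named gene blocks of a dataset
#'
#' Resolves the marker/technical gene blocks (hemoglobin, adipocyte
#' markers, endothelial markers, stress response, canonical histones,
#' mitochondrial transcripts) from gene identifier prefixes as laid out
#' by [cohort_config()]. User data with different identifiers can pass
#' an explicit block list to the generators instead.
#'
#' @param gene_ids character vector of gene identifiers
#' @return named list of integer index vectors
#' @export
gene_blocks <- function(gene_ids) {
  list(
    hemoglobin = grep("^HBL", gene_ids),
    adipocyte = grep("^ADI", gene_ids),
    endothelial = grep("^ENDM", gene_ids),
    stress = grep("^STR", gene_ids),
    histone = grep("^HIST", gene_ids),
    mito = grep("^MTL", gene_ids)
  )
}

# Per-type retention under a protocol: fragile types take their dedicated
# retention factor, all other types pass through unchanged.
type_retention <- function(types, effects) {
  r <- rep(1, length(types))
  names(r) <- types
  if ("erythrocyte" %in% types) {
    r["erythrocyte"] <- effects$erythrocyte_retention
  }
  if ("adipocyte" %in% types) r["adipocyte"] <- effects$adipocyte_retention
  r
}

# Expected expression mixture of a tumor before enrichment effects:
# composition-weighted sum of per-type total count vectors with fragile
# retention, plus stress induction when dissociated. Returns the raw
# expected vector and the post-retention RNA fractions.
expected_mixture <- function(dataset, tumor, effects, blocks) {
  in_tumor <- dataset$sample_id == tumor
  if (!any(in_tumor)) stop_config("tumor '", tumor, "' not in dataset")
  types <- sort(unique(dataset$cell_type[in_tumor]))
  ret <- type_retention(types, effects)
  e <- numeric(ncol(dataset$counts))
  rna <- numeric(length(types))
  names(rna) <- types
  for (k in seq_along(types)) {
    sel <- in_tumor & dataset$cell_type == types[k]
    s_k <- Matrix::colSums(dataset$counts[sel, , drop = FALSE])
    e <- e + ret[k] * s_k
    rna[k] <- ret[k] * sum(s_k)
  }
  if (sum(rna) == 0) {
    stop(errorCondition(
      paste0("all retention-adjusted weights are zero for tumor ", tumor),
      class = c("deconvbench_degenerate_composition", "error")))
  }
  if (effects$dissociated && length(blocks$stress)) {
    e[blocks$stress] <- e[blocks$stress] * effects$stress_induction
  }
  list(expected = e, true_composition = rna / sum(rna))
}

#' Generate a bulk RNA-seq sample from a virtual tumor
#'
#' Composes the tumor's expected expression as a composition-weighted
#' mixture of its cell-type profiles (weights = cell-type abundance x
#' fragile-type retention, renormalized), applies stress induction and the
#' enrichment chemistry's gene-block multipliers, then draws integer
#' counts multinomially at the requested depth. The post-retention RNA
#' fractions are stored as `true_composition` for evaluation.
#'
#' @param dataset an [sc_dataset()] holding the virtual tumors
#' @param tumor sample id present in `dataset`
#' @param protocol a [protocol_effects()]
#' @param depth total read count (default 5e6)
#' @param seed integer seed
#' @param blocks gene-block list (default resolved from gene ids)
#' @return object of class `bulk_sample` with fields `counts` (named
#'   integer vector summing to `depth`), `sample_id`, `protocol`,
#'   `effects`, `true_composition`
#' @export
generate_bulk <- function(dataset, tumor, protocol, depth = 5e6, seed = 1,
                          blocks = gene_blocks(dataset$gene_ids)) {
  stopifnot(inherits(protocol, "protocol_effects"), depth > 0)
  mix <- expected_mixture(dataset, tumor, protocol, blocks)
  e <- mix$expected
  if (protocol$enrichment == "polyA" && length(blocks$histone)) {
    e[blocks$histone] <- e[blocks$histone] * protocol$histone_polyA_retention
  }
  if (protocol$enrichment == "rRNA_depletion" && length(blocks$mito)) {
    e[blocks$mito] <- e[blocks$mito] * protocol$mito_depletion_rRNA
  }
  p <- e / sum(e)
  counts <- with_seed(child_seed(seed, paste0("bulk_", tumor,
                                              "_", protocol$protocol)),
                      as.integer(stats::rmultinom(1, depth, p)))
  names(counts) <- dataset$gene_ids
  structure(list(
    counts = counts,
    sample_id = tumor,
    protocol = protocol$protocol,
    effects = protocol,
    true_composition = mix$true_composition
  ), class = "bulk_sample")
}

#' Calibrate enrichment retention factors to target fold changes
#'
#' The observed depth-normalized fold change between two enrichment
#' chemistries involves both libraries' normalizing constants: scaling a
#' block down re-inflates every other gene's share. Given the histone and
#' mitochondrial read shares of the common pre-enrichment profile and
#' target ratios (histone rRNA/polyA and mito polyA/rRNA), this solves
#' the two-variable fixed point so the expected depth-normalized ratios
#' equal the targets exactly.
#'
#' @param hist_share,mito_share block read shares of the pre-enrichment
#'   expected profile
#' @param ratio_hist target histone fold change (rRNA-depleted / poly-A)
#' @param ratio_mito target mitochondrial fold change (poly-A /
#'   rRNA-depleted)
#' @return list with `histone_polyA_retention` and `mito_depletion_rRNA`
#' @export
calibrate_enrichment <- function(hist_share, mito_share,
                                 ratio_hist, ratio_mito) {
  stopifnot(ratio_hist >= 1, ratio_mito >= 1,
            hist_share >= 0, mito_share >= 0, hist_share + mito_share < 1)
  h <- 1 / ratio_hist
  m <- 1 / ratio_mito
  for (i in 1:100) {
    s_p <- 1 - hist_share * (1 - h)   # polyA normalizer
    s_r <- 1 - mito_share * (1 - m)   # rRNA-depletion normalizer
    h_new <- min(1, s_p / (s_r * ratio_hist))
    m_new <- min(1, s_r / (s_p * ratio_mito))
    if (abs(h_new - h) < 1e-12 && abs(m_new - m) < 1e-12) break
    h <- h_new
    m <- m_new
  }
  list(histone_polyA_retention = h, mito_depletion_rRNA = m)
}

#' Generate the matched three-protocol bulk set for a tumor
#'
#' Emits the three bulk library types measured per tumor — intact chunk
#' with rRNA depletion, dissociated with rRNA depletion, and dissociated
#' with poly-A capture — with per-tumor enrichment effects calibrated so
#' the expected histone fold change (rRNA-depleted vs poly-A, dissociated
#' pair) and mitochondrial fold change (poly-A vs rRNA-depleted) land on
#' targets drawn uniformly inside the observed windows [1.7, 10] and
#' [10, 30].
#'
#' @inheritParams generate_bulk
#' @param histone_window,mito_window fold-change windows for the
#'   per-tumor jitter
#' @return named list of three [generate_bulk()] results
#'   (`rRNA_chunk`, `rRNA_dissociated`, `polyA_dissociated`)
#' @export
generate_bulk_set <- function(dataset, tumor, depth = 5e6, seed = 1,
                              blocks = gene_blocks(dataset$gene_ids),
                              histone_window = c(1.7, 10),
                              mito_window = c(10, 30)) {
  targets <- with_seed(child_seed(seed, paste0("enrich_", tumor)), {
    c(hist = stats::runif(1, histone_window[1], histone_window[2]),
      mito = stats::runif(1, mito_window[1], mito_window[2]))
  })
  # calibrate on the dissociated pre-enrichment profile, where the paired
  # fold changes are measured
  base <- expected_mixture(dataset, tumor,
                           protocol_effects("rRNA_dissociated"), blocks)
  tot <- sum(base$expected)
  cal <- calibrate_enrichment(
    hist_share = sum(base$expected[blocks$histone]) / tot,
    mito_share = sum(base$expected[blocks$mito]) / tot,
    ratio_hist = targets[["hist"]],
    ratio_mito = targets[["mito"]]
  )
  protos <- list(
    rRNA_chunk = protocol_effects(
      "rRNA_chunk",
      mito_depletion_rRNA = cal$mito_depletion_rRNA),
    rRNA_dissociated = protocol_effects(
      "rRNA_dissociated",
      mito_depletion_rRNA = cal$mito_depletion_rRNA),
    polyA_dissociated = protocol_effects(
      "polyA_dissociated",
      histone_polyA_retention = cal$histone_polyA_retention)
  )
  lapply(protos, function(p) {
    generate_bulk(dataset, tumor, p, depth = depth, seed = seed,
                  blocks = blocks)
  })
}

#' Depth-normalized gene-block fold change between two bulk samples
#'
#' @param a,b [generate_bulk()] results (numerator `a`, denominator `b`)
#' @param block integer gene indices
#' @return aggregate block count ratio after per-sample depth
#'   normalization
#' @export
block_ratio <- function(a, b, block) {
  (sum(a$counts[block]) / sum(a$counts)) /
    (sum(b$counts[block]) / sum(b$counts))
}
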