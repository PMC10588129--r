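#' Pseudo-bulk scenario configuration
#'
#' Four composition scenarios drive the benchmark: `realistic` mirrors
#' the cell-type proportions observed in the source single-cell sample;
#' `even` gives every type the same proportion; `sparse` puts random
#' proportions on a fixed support of common tumor cell types only;
#' `weighted` fixes the epithelial fraction at 70% (mimicking
#' epithelial-dominated tumors) and splits the rest randomly.
#'
#' @param scenario one of `"realistic"`, `"even"`, `"sparse"`,
#'   `"weighted"`
#' @param n_cells cells aggregated per pseudo-bulk sample (default 2000)
#' @param n_samples pseudo-bulk samples per source sample (default 50)
#' @param epithelial_weight fixed epithelial fraction of the weighted
#'   scenario (default 0.70)
#' @param sparse_types support of the sparse scenario
#' @param noise_sd sd of the Gaussian proportion perturbation applied to
#'   each scenario draw (default 0.01)
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(scenario = c("realistic", "even", "sparse",
                                         "weighted"),
                            n_cells = 2000, n_samples = 50,
                            epithelial_weight = 0.70,
                            sparse_types = c("epithelial", "endothelial",
                                             "fibroblast", "macrophage",
                                             "T"),
                            noise_sd = 0.01) {
  scenario <- match.arg(scenario)
  if (epithelial_weight <= 0 || epithelial_weight >= 1) {
    stop_config("epithelial_weight must lie in (0, 1)")
  }
  if (length(sparse_types) == 0) stop_config("sparse_types must be non-empty")
  if (n_cells < 1 || n_samples < 1) stop_config("counts must be positive")
  structure(list(scenario = scenario, n_cells = n_cells,
                 n_samples = n_samples,
                 epithelial_weight = epithelial_weight,
                 sparse_types = sparse_types, noise_sd = noise_sd),
            class = "scenario_config")
}

#' Draw scenario target proportions
#'
#' @param cfg a [scenario_config()]
#' @param observed named composition vector of cell-type proportions
#'   observed in the source single-cell sample
#' @param seed integer seed
#' @return named composition vector over the same types as `observed`
#' @export
scenario_proportions <- function(cfg, observed, seed = 1) {
  check_composition(observed, what = "observed composition")
  types <- names(observed)
  out <- switch(cfg$scenario,
    realistic = observed,
    even = stats::setNames(rep(1 / length(types), length(types)), types),
    sparse = {
      missing <- setdiff(cfg$sparse_types, types)
      if (length(missing)) {
        stop_config("sparse_types not in dataset: ",
                    paste(missing, collapse = ", "))
      }
      with_seed(child_seed(seed, "sparse"), {
        g <- stats::rgamma(length(cfg$sparse_types), shape = 1)
        p <- stats::setNames(rep(0, length(types)), types)
        p[cfg$sparse_types] <- g / sum(g)
        p
      })
    },
    weighted = {
      if (!"epithelial" %in% types) {
        stop_config("weighted scenario requires an epithelial cell type")
      }
      with_seed(child_seed(seed, "weighted"), {
        rest <- setdiff(types, "epithelial")
        g <- stats::rgamma(length(rest), shape = 1)
        p <- stats::setNames(rep(0, length(types)), types)
        p["epithelial"] <- cfg$epithelial_weight
        p[rest] <- (1 - cfg$epithelial_weight) * g / sum(g)
        p
      })
    })
  check_composition(out, what = "scenario proportions")
  out
}

#' Perturb a composition with Gaussian noise
#'
#' Adds independent Gaussian noise to each represented (positive) entry,
#' clamps negatives at zero, and renormalizes to sum 1 — the
#' recompute-to-one noise step of the pseudo-bulk simulation. Zero-mass
#' types stay at zero so scenarios with deliberately absent cell types
#' keep their support.
#'
#' @param props named composition vector
#' @param noise_sd standard deviation of the perturbation
#' @param seed integer seed
#' @return perturbed composition vector
#' @export
perturb_proportions <- function(props, noise_sd, seed = 1) {
  check_composition(props, what = "proportions")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  if (noise_sd == 0) return(props)
  with_seed(child_seed(seed, "noise"), {
    noise <- stats::rnorm(length(props), 0, noise_sd)
    noise[props == 0] <- 0
    p <- pmax(props + noise, 0)
    if (sum(p) == 0) {
      stop(errorCondition("all proportions clamped to zero",
           class = c("deconvbench_degenerate_composition", "error")))
    }
    p / sum(p)
  })
}

#' Convert proportions to integer cell tallies
#'
#' Largest-remainder apportionment: multiplies the proportions by the
#' desired total and rounds so the tallies sum exactly to `n_cells`.
#'
#' @param props named composition vector
#' @param n_cells positive integer total
#' @return named integer vector summing to `n_cells`
#' @export
integer_cell_counts <- function(props, n_cells) {
  check_composition(props, what = "proportions")
  if (n_cells < 1) stop_config("n_cells must be positive")
  apportion_largest_remainder(props, n_cells)
}

#' Assemble one pseudo-bulk sample
#'
#' Draws the tallied number of cells of each type with replacement from
#' the labeled cells of the source sample, sums their count rows, and
#' records the ground truth as the fraction of transcriptional reads
#' contributed by each cell type (RNA fraction, not cell fraction). No
#' mRNA scaling factors are applied; integer counts are preserved.
#'
#' @param dataset an [sc_dataset()]
#' @param source_sample sample id to draw cells from
#' @param props named composition vector (target cell proportions)
#' @param cfg a [scenario_config()] (supplies `n_cells`)
#' @param seed integer seed
#' @return object of class `pseudobulk_sample` with fields `counts`,
#'   `truth_rna_fraction`, `cell_tally`, `source_sample`, `cell_index`
#'   (the drawn cell rows, for audit)
#' @export
sample_pseudobulk <- function(dataset, source_sample, props, cfg, seed = 1) {
  tally <- integer_cell_counts(props, cfg$n_cells)
  in_src <- dataset$sample_id == source_sample
  if (!any(in_src)) stop_config("source sample '", source_sample,
                                "' not in dataset")
  with_seed(child_seed(seed, paste0("pb_", source_sample)), {
    drawn <- integer(0)
    drawn_type <- character(0)
    for (k in names(tally)) {
      if (tally[[k]] == 0) next
      pool <- which(in_src & dataset$cell_type == k)
      if (length(pool) == 0) {
        stop(errorCondition(
          paste0("cell type '", k, "' absent from source sample ",
                 source_sample),
          class = c("deconvbench_missing_type", "error")))
      }
      pick <- pool[sample.int(length(pool), tally[[k]], replace = TRUE)]
      drawn <- c(drawn, pick)
      drawn_type <- c(drawn_type, rep(k, tally[[k]]))
    }
    counts <- Matrix::colSums(dataset$counts[drawn, , drop = FALSE])
    reads <- dataset$total_reads[drawn]
    by_type <- tapply(reads, factor(drawn_type, levels = names(tally)), sum)
    by_type[is.na(by_type)] <- 0
    truth <- as.numeric(by_type) / sum(reads)
    names(truth) <- names(tally)
    structure(list(
      counts = counts,
      truth_rna_fraction = truth,
      cell_tally = tally,
      source_sample = source_sample,
      cell_index = drawn
    ), class = "pseudobulk_sample")
  })
}

#' Build a full pseudo-bulk scenario dataset
#'
#' For each source sample of the dataset, draws `n_samples` pseudo-bulk
#' samples: fresh scenario proportions, Gaussian perturbation, integer
#' tally, and sampling with replacement. Deterministic given
#' (dataset, cfg, seed).
#'
#' @inheritParams sample_pseudobulk
#' @param cfg a [scenario_config()]
#' @param source_samples sample ids to simulate from (default: all)
#' @param seed integer seed
#' @return list of [sample_pseudobulk()] results with names
#'   `<source>_<replicate>`
#' @export
build_scenario_dataset <- function(dataset, cfg, seed = 1,
                                   source_samples = NULL) {
  if (is.null(source_samples)) source_samples <- sort(unique(dataset$sample_id))
  out <- list()
  for (src in source_samples) {
    in_src <- dataset$sample_id == src
    obs <- table(factor(dataset$cell_type[in_src],
                        levels = sort(unique(dataset$cell_type))))
    observed <- as.numeric(obs) / sum(obs)
    names(observed) <- names(obs)
    for (i in seq_len(cfg$n_samples)) {
      s_i <- child_seed(seed, paste0(src, "_rep", i))
      target <- scenario_proportions(cfg, observed, seed = s_i)
      noisy <- perturb_proportions(target, cfg$noise_sd, seed = s_i)
      pb <- sample_pseudobulk(dataset, src, noisy, cfg, seed = s_i)
      pb$scenario <- cfg$scenario
      pb$target_proportions <- target
      out[[paste0(src, "_", i)]] <- pb
    }
  }
  out
}
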