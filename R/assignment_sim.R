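#' Construct an assignment posterior table
#'
#' Per-cell posterior over the pooled samples plus a multiplet class,
#' as produced by hash (antibody-tag) or genetic demultiplexing.
#'
#' @param posterior cells x (samples + 1) matrix; last column must be
#'   named `multiplet`; rows sum to 1
#' @param modality `"hash"` or `"genetic"`
#' @param true_sample per-cell ground-truth sample label (simulated
#'   tables), or NULL for real data
#' @param barcodes per-cell barcodes
#' @return object of class `assignment_table`
#' @export
assignment_table <- function(posterior, modality = c("hash", "genetic"),
                             true_sample = NULL, barcodes = NULL) {
  modality <- match.arg(modality)
  if (colnames(posterior)[ncol(posterior)] != "multiplet") {
    stop_config("last posterior column must be 'multiplet'")
  }
  if (any(posterior < 0) || any(abs(rowSums(posterior) - 1) > 1e-6)) {
    stop_config("posterior rows must be non-negative and sum to 1")
  }
  if (is.null(barcodes)) barcodes <- sprintf("cell%06d", seq_len(nrow(posterior)))
  rownames(posterior) <- barcodes
  structure(list(
    posterior = posterior,
    modality = modality,
    true_sample = true_sample,
    barcodes = barcodes
  ), class = "assignment_table")
}

#' Simulate paired hash and genetic demultiplexing posterior tables
#'
#' For each pool of samples, emits one hash table and one genetic table
#' over the pool's cells. Hash posteriors follow a Dirichlet whose
#' concentration on the true sample grows with that sample's antibody
#' adhesion (`1 + k a / (1 - a)`, diverging to a point mass at adhesion
#' 1, so perfect adhesion gives certain assignment); genetic posteriors
#' are near-deterministic on the true sample. A `doublet_rate` fraction
#' of cells is injected as multiplets and carries high multiplet mass in
#' both modalities.
#'
#' @param dataset an [sc_dataset()]
#' @param pools list of character vectors partitioning the dataset's
#'   sample ids (default: split in two halves, mirroring a
#'   two-batches-of-four pooling design)
#' @param hash_adhesion per-sample antibody adhesion efficiency in
#'   \[0, 1\]; scalar or named vector (default 0.9)
#' @param doublet_rate fraction of cells injected as multiplets
#' @param seed integer seed
#' @param hash_kappa concentration gain of the hash model
#' @return named list, one element per pool, each a list with `hash` and
#'   `genetic` [assignment_table()]s
#' @export
generate_assignment_tables <- function(dataset, pools = NULL,
                                       hash_adhesion = 0.9,
                                       doublet_rate = 0.05,
                                       seed = 1, hash_kappa = 4) {
  samples <- sort(unique(dataset$sample_id))
  if (is.null(pools)) {
    half <- ceiling(length(samples) / 2)
    pools <- list(A = samples[seq_len(half)],
                  B = samples[-seq_len(half)])
    pools <- Filter(length, pools)
  }
  pooled <- sort(unlist(pools, use.names = FALSE))
  if (length(pooled) != length(samples) || any(pooled != samples)) {
    stop_config("pools must partition the dataset's sample ids")
  }
  if (is.null(names(pools))) names(pools) <- LETTERS[seq_along(pools)]
  if (length(hash_adhesion) == 1 && is.null(names(hash_adhesion))) {
    hash_adhesion <- stats::setNames(rep(hash_adhesion, length(samples)),
                                     samples)
  }
  if (any(hash_adhesion < 0 | hash_adhesion > 1) ||
      doublet_rate < 0 || doublet_rate > 1) {
    stop_config("adhesion and doublet_rate must lie in [0, 1]")
  }

  lapply(stats::setNames(names(pools), names(pools)), function(pn) {
    pool <- sort(pools[[pn]])
    idx <- which(dataset$sample_id %in% pool)
    truth <- dataset$sample_id[idx]
    bc <- dataset$barcodes[idx]
    n <- length(idx)
    s <- length(pool)
    with_seed(child_seed(seed, paste0("demux_", pn)), {
      is_doublet <- stats::runif(n) < doublet_rate
      other <- vapply(truth, function(ts) {
        if (s == 1) ts else sample(setdiff(pool, ts), 1)
      }, character(1))

      hash <- matrix(0, n, s + 1, dimnames = list(NULL, c(pool, "multiplet")))
      genetic <- hash
      for (i in seq_len(n)) {
        a <- hash_adhesion[[truth[i]]]
        if (is_doublet[i]) {
          mm <- stats::runif(1, 0.85, 0.99)
          split2 <- stats::runif(1)
          for (tab in c("hash", "genetic")) {
            row <- numeric(s + 1)
            row[s + 1] <- mm
            if (other[i] == truth[i]) {
              row[match(truth[i], pool)] <- 1 - mm
            } else {
              row[match(truth[i], pool)] <- (1 - mm) * split2
              row[match(other[i], pool)] <- (1 - mm) * (1 - split2)
            }
            if (tab == "hash") hash[i, ] <- row else genetic[i, ] <- row
          }
        } else {
          # hash: Dirichlet over samples, then a small multiplet leak
          eps <- stats::runif(1, 0, 0.008)
          if (a >= 1 - 1e-12) {
            p <- numeric(s)
            p[match(truth[i], pool)] <- 1
            eps <- 0
          } else {
            alpha <- rep(1, s)
            alpha[match(truth[i], pool)] <- 1 + hash_kappa * a / (1 - a)
            g <- stats::rgamma(s, shape = alpha)
            p <- g / sum(g)
          }
          hash[i, ] <- c(p * (1 - eps), eps)
          # genetic: near-deterministic on the true sample
          e <- stats::rbeta(1, 1, 200)
          row <- numeric(s + 1)
          spread <- if (s > 1) stats::runif(s - 1) else numeric(0)
          row[-c(match(truth[i], pool), s + 1)] <-
            if (s > 1) e * 0.8 * spread / sum(spread) else numeric(0)
          row[s + 1] <- e * 0.2
          row[match(truth[i], pool)] <- 1 - sum(row)
          genetic[i, ] <- row
        }
      }
      true_lab <- ifelse(is_doublet, "multiplet", truth)
      list(
        hash = assignment_table(hash, "hash", true_sample = true_lab,
                                barcodes = bc),
        genetic = assignment_table(genetic, "genetic", true_sample = true_lab,
                                   barcodes = bc)
      )
    })
  })
}
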