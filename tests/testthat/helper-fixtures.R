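# Shared fixtures, built in code at test time.

# Small virtual cohort: fast to generate, all ten default cell types.
tiny_cohort <- function(n_tumors = 2, cells = 200, genes = 600,
                        seed = 101) {
  cfg <- cohort_config(n_tumors = n_tumors, cells_per_tumor = cells,
                       n_genes = genes)
  generate_reference(cfg, seed = seed)
}

# Random valid posterior table: Dirichlet rows over s samples + multiplet.
random_posterior_table <- function(n, s, seed = 1, modality = "hash",
                                   mult_alpha = 0.2) {
  set.seed(seed)
  alpha <- c(rep(1, s), mult_alpha)
  post <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(s + 1, shape = alpha)
    g / sum(g)
  }, numeric(s + 1)))
  colnames(post) <- c(sprintf("sample_%d", seq_len(s)), "multiplet")
  assignment_table(post, modality)
}

# Hand-rolled cell x gene dataset with fixed per-type library sizes.
fixed_libsize_dataset <- function(n_a = 5, n_b = 5, lib_a = 100,
                                  lib_b = 300, genes = 10) {
  counts <- rbind(
    matrix(lib_a / genes, nrow = n_a, ncol = genes),
    matrix(lib_b / genes, nrow = n_b, ncol = genes)
  )
  sc_dataset(counts,
             cell_type = c(rep("A", n_a), rep("B", n_b)),
             sample_id = rep("s1", n_a + n_b))
}
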