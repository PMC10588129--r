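obs10 <- setNames(rep(0.1, 10), default_cell_types()$name)

test_that("scenario proportions honor their contracts", {
  cfg_even <- scenario_config("even")
  expect_equal(scenario_proportions(cfg_even, obs10),
               setNames(rep(0.1, 10), names(obs10)))

  cfg_w <- scenario_config("weighted")
  for (s in 1:20) {
    p <- scenario_proportions(cfg_w, obs10, seed = s)
    expect_identical(unname(p["epithelial"]), 0.70)
    expect_equal(sum(p[names(p) != "epithelial"]), 0.30)
  }

  cfg_s <- scenario_config("sparse")
  for (s in 1:20) {
    p <- scenario_proportions(cfg_s, obs10, seed = s)
    expect_true(all(p[setdiff(names(p), cfg_s$sparse_types)] == 0))
    expect_equal(sum(p), 1)
  }

  obs_real <- setNames(c(0.5, 0.2, 0.3), c("epithelial", "T", "B"))
  expect_identical(scenario_proportions(scenario_config("realistic"),
                                        obs_real), obs_real)
  expect_error(scenario_proportions(cfg_s, obs_real),
               class = "deconvbench_config_error")
})

test_that("proportion perturbation is a clamped, renormalized Gaussian", {
  p <- setNames(c(0.3, 0.7), c("A", "B"))
  expect_identical(perturb_proportions(p, 0), p)
  for (s in 1:25) {
    q <- perturb_proportions(p, 0.3, seed = s)
    expect_true(all(q >= 0))
    expect_equal(sum(q), 1)
  }
  # symmetric input stays centered under heavy noise (Monte Carlo)
  half <- setNames(c(0.5, 0.5), c("A", "B"))
  draws <- vapply(1:4000, function(s) {
    # rare all-clamped draws raise the degenerate-composition error
    tryCatch(perturb_proportions(half, 0.25, seed = s)[1],
             error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(mean(draws, na.rm = TRUE) - 0.5), 0.02)
})

test_that("integer tallies use largest-remainder apportionment", {
  expect_equal(unname(integer_cell_counts(c(A = 0.5, B = 0.5), 2000)),
               c(1000L, 1000L))
  t3 <- integer_cell_counts(setNames(rep(1, 3) / 3, c("a", "b", "c")), 100)
  expect_equal(sum(t3), 100L)
  expect_true(all(t3 %in% c(33L, 34L)))
  tz <- integer_cell_counts(c(A = 0.6, B = 0.4, C = 0), 10)
  expect_identical(unname(tz["C"]), 0L)
})

test_that("pseudo-bulk truth is the RNA read share of the drawn cells", {
  ds <- fixed_libsize_dataset(n_a = 20, n_b = 20, lib_a = 100, lib_b = 300)
  cfg <- scenario_config("realistic", n_cells = 2000, noise_sd = 0)
  pb <- sample_pseudobulk(ds, "s1", c(A = 0.5, B = 0.5), cfg, seed = 9)
  expect_equal(unname(pb$cell_tally), c(1000L, 1000L))
  expect_equal(unname(pb$truth_rna_fraction), c(0.25, 0.75))
  expect_equal(sum(pb$counts), 1000 * 100 + 1000 * 300)

  # delta composition puts all truth mass on one type
  pb1 <- sample_pseudobulk(ds, "s1", c(A = 1, B = 0),
                           scenario_config("realistic", n_cells = 50), 1)
  expect_equal(unname(pb1$truth_rna_fraction), c(1, 0))

  expect_error(
    sample_pseudobulk(ds, "s1", c(A = 0.5, B = 0.3, C = 0.2),
                      scenario_config("realistic", n_cells = 10), 1),
    class = "deconvbench_missing_type")
})

test_that("read conservation and truth consistency hold exactly", {
  ref <- tiny_cohort(seed = 37)
  cfg <- scenario_config("realistic", n_cells = 400, noise_sd = 0.01)
  obs <- prop.table(table(ref$cell_type[ref$sample_id == "tumor01"]))
  p <- scenario_proportions(cfg, setNames(as.numeric(obs), names(obs)), 3)
  pb <- sample_pseudobulk(ref, "tumor01", p, cfg, seed = 3)
  expect_identical(sum(pb$counts), sum(ref$total_reads[pb$cell_index]))
  # recompute truth from the drawn-cell log, bit for bit
  reads <- ref$total_reads[pb$cell_index]
  types <- ref$cell_type[pb$cell_index]
  recomputed <- vapply(names(pb$cell_tally), function(k) {
    sum(reads[types == k]) / sum(reads)
  }, numeric(1))
  expect_identical(unname(recomputed), unname(pb$truth_rna_fraction))
})

test_that("census draw of every cell reproduces the aggregate counts", {
  ds <- tiny_cohort(n_tumors = 1, cells = 80, seed = 41)
  types <- sort(unique(ds$cell_type))
  # one cell per type: drawing each exactly once is a census
  one_each <- sort(vapply(types, function(t) which(ds$cell_type == t)[1],
                          integer(1)))
  census <- sc_dataset(ds$counts[one_each, , drop = FALSE],
                       ds$cell_type[one_each], ds$sample_id[one_each],
                       gene_ids = ds$gene_ids,
                       barcodes = ds$barcodes[one_each])
  cfg <- scenario_config("even", n_cells = length(types), noise_sd = 0)
  p <- setNames(rep(1 / length(types), length(types)), types)
  pb <- sample_pseudobulk(census, "tumor01", p, cfg, seed = 2)
  expect_equal(unname(pb$counts),
               unname(Matrix::colSums(census$counts)))
})

test_that("scenario datasets have the configured shape and are deterministic", {
  ref <- tiny_cohort(seed = 43)
  cfg <- scenario_config("even", n_cells = 300, n_samples = 4)
  out <- build_scenario_dataset(ref, cfg, seed = 5)
  expect_length(out, 4 * 2)  # n_samples per source sample
  expect_true(all(vapply(out, function(s) sum(s$cell_tally),
                         integer(1)) == 300L))
  out2 <- build_scenario_dataset(ref, cfg, seed = 5)
  expect_identical(out, out2)

  # noise-free realistic single sample tracks the source read shares
  cfg1 <- scenario_config("realistic", n_cells = 3000, n_samples = 1,
                          noise_sd = 0)
  pb <- build_scenario_dataset(ref, cfg1, seed = 7,
                               source_samples = "tumor01")[[1]]
  in_t <- ref$sample_id == "tumor01"
  shares <- tapply(ref$total_reads[in_t], ref$cell_type[in_t], sum)
  shares <- shares / sum(shares)
  expect_equal(as.numeric(pb$truth_rna_fraction[names(shares)]),
               as.numeric(shares), tolerance = 0.05)
})
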