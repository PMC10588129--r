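test_that("degenerate single-type, noise-free config recovers the archetype", {
  ct <- data.frame(name = "epithelial", mrna_scale = 1, fragile = FALSE,
                   base_prop = 1)
  cfg <- cohort_config(n_tumors = 1, cell_types = ct, n_genes = 600,
                       cells_per_tumor = 1500, patient_effect_sd = 0,
                       dispersion = 0, lib_size_sdlog = 0,
                       baseline_composition = matrix(1, 1, 1,
                         dimnames = list("tumor01", "epithelial")))
  ref <- generate_reference(cfg, seed = 3)
  emp <- Matrix::colSums(ref$counts) / sum(ref$counts)
  arch <- cfg$archetypes[, 1]
  hi <- arch > 5e-4  # genes with enough signal for a mean comparison
  expect_lt(mean(abs(emp[hi] - arch[hi]) / arch[hi]), 0.05)
})

test_that("mRNA-content scale doubles mean library size", {
  ct <- data.frame(name = c("epithelial", "T"),
                   mrna_scale = c(2, 1), fragile = FALSE,
                   base_prop = c(0.5, 0.5))
  cfg <- cohort_config(n_tumors = 1, cell_types = ct, n_genes = 600,
                       cells_per_tumor = 2000,
                       baseline_composition = matrix(c(0.5, 0.5), 1, 2,
                         dimnames = list("tumor01", ct$name)))
  ref <- generate_reference(cfg, seed = 11)
  mean_lib <- tapply(ref$total_reads, ref$cell_type, mean)
  expect_equal(unname(mean_lib["epithelial"] / mean_lib["T"]), 2,
               tolerance = 0.05)
})

test_that("default cohort structure has 8 tumors and 10 cell types", {
  ref <- tiny_cohort(n_tumors = 8, cells = 40)
  expect_setequal(unique(ref$sample_id), sprintf("tumor%02d", 1:8))
  expect_setequal(unique(ref$cell_type), default_cell_types()$name)
  # every type present in every tumor (positive priors)
  tab <- table(ref$sample_id, ref$cell_type)
  expect_true(all(tab > 0))
})

test_that("generated counts conserve library sizes and reproduce bit-identically", {
  ref <- tiny_cohort(cells = 150, seed = 5)
  expect_identical(unname(ref$total_reads),
                   unname(Matrix::rowSums(ref$counts)))
  ref2 <- tiny_cohort(cells = 150, seed = 5)
  expect_identical(as.matrix(ref$counts), as.matrix(ref2$counts))
  expect_identical(ref$cell_type, ref2$cell_type)
})

test_that("invalid composition priors raise a configuration error", {
  bad <- matrix(c(0.7, 0.4), 1, 2,
                dimnames = list("tumor01", c("epithelial", "T")))
  ct <- data.frame(name = c("epithelial", "T"), mrna_scale = 1,
                   fragile = FALSE, base_prop = c(0.5, 0.5))
  expect_error(cohort_config(n_tumors = 1, cell_types = ct, n_genes = 600,
                             baseline_composition = bad),
               class = "deconvbench_config_error")
})

test_that("identity protocol leaves the mixture and truth untouched", {
  ref <- tiny_cohort(seed = 7)
  neutral <- protocol_effects(dissociated = FALSE,
                              enrichment = "rRNA_depletion",
                              erythrocyte_retention = 1,
                              adipocyte_retention = 1,
                              stress_induction = 1,
                              histone_polyA_retention = 1,
                              mito_depletion_rRNA = 1)
  b <- generate_bulk(ref, "tumor01", neutral, depth = 5e5, seed = 2)
  expect_equal(sum(b$counts), 5e5)
  # truth equals the tumor's observed RNA read shares
  in_t <- ref$sample_id == "tumor01"
  shares <- tapply(ref$total_reads[in_t], ref$cell_type[in_t], sum)
  shares <- shares / sum(shares)
  expect_equal(as.numeric(b$true_composition[names(shares)]),
               as.numeric(shares), tolerance = 1e-12)
  # sampled counts track the unmodified expected mixture
  e <- Matrix::colSums(ref$counts[in_t, , drop = FALSE])
  expect_gt(cor(as.numeric(b$counts), as.numeric(e)), 0.999)
})

test_that("dissociation depletes hemoglobin and its fraction is monotone in retention", {
  ref <- tiny_cohort(seed = 13)
  blocks <- gene_blocks(ref$gene_ids)
  chunk <- generate_bulk(ref, "tumor01", protocol_effects("rRNA_chunk"),
                         depth = 5e5, seed = 4)
  diss <- generate_bulk(ref, "tumor01",
                        protocol_effects("rRNA_dissociated"),
                        depth = 5e5, seed = 4)
  expect_lt(sum(diss$counts[blocks$hemoglobin]),
            sum(chunk$counts[blocks$hemoglobin]))
  # in-expectation monotonicity over 10 replicate draws
  hb <- function(retention, rep) {
    p <- protocol_effects(dissociated = TRUE,
                          enrichment = "rRNA_depletion",
                          erythrocyte_retention = retention)
    mean(vapply(seq_len(rep), function(i) {
      sum(generate_bulk(ref, "tumor01", p, depth = 2e5,
                        seed = 100 + i)$counts[blocks$hemoglobin])
    }, numeric(1)))
  }
  levels <- c(1, 0.5, 0.1, 0)
  means <- vapply(levels, hb, numeric(1), rep = 10)
  expect_true(all(diff(means) <= 0))
})

test_that("stress induction monotonically raises the stress-block fraction", {
  ref <- tiny_cohort(seed = 17)
  blocks <- gene_blocks(ref$gene_ids)
  frac <- vapply(c(1, 2, 4, 8), function(s) {
    p <- protocol_effects(dissociated = TRUE,
                          enrichment = "rRNA_depletion",
                          stress_induction = s)
    b <- generate_bulk(ref, "tumor01", p, depth = 5e5, seed = 6)
    sum(b$counts[blocks$stress]) / sum(b$counts)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("matched bulk sets respect the enrichment fold-change windows", {
  ref <- tiny_cohort(n_tumors = 3, cells = 250, seed = 19)
  blocks <- gene_blocks(ref$gene_ids)
  for (tm in sprintf("tumor%02d", 1:3)) {
    bs <- generate_bulk_set(ref, tm, depth = 1e6, seed = 8,
                            blocks = blocks)
    expect_gte(block_ratio(bs$rRNA_dissociated, bs$polyA_dissociated,
                           blocks$histone), 1.7)
    expect_gte(block_ratio(bs$polyA_dissociated, bs$rRNA_dissociated,
                           blocks$mito), 10)
  }
})

test_that("enrichment calibration hits target ratios in expectation", {
  cal <- calibrate_enrichment(hist_share = 0.02, mito_share = 0.12,
                              ratio_hist = 4, ratio_mito = 20)
  h <- cal$histone_polyA_retention
  m <- cal$mito_depletion_rRNA
  s_p <- 1 - 0.02 * (1 - h)
  s_r <- 1 - 0.12 * (1 - m)
  expect_equal(s_p / (s_r * h), 4, tolerance = 1e-9)
  expect_equal(s_r / (s_p * m), 20, tolerance = 1e-9)
})

test_that("perfect adhesion yields certain hash assignment", {
  ref <- tiny_cohort(n_tumors = 4, cells = 60, seed = 23)
  tabs <- generate_assignment_tables(ref, hash_adhesion = 1,
                                     doublet_rate = 0, seed = 2)
  for (pool in tabs) {
    post <- pool$hash$posterior
    truth <- pool$hash$true_sample
    p_true <- post[cbind(seq_len(nrow(post)), match(truth, colnames(post)))]
    expect_true(all(p_true >= 0.99))
  }
})

test_that("low-adhesion sample drives unassignment, relaxing the threshold recovers cells", {
  ref <- tiny_cohort(n_tumors = 4, cells = 150, seed = 29)
  adhesion <- c(tumor01 = 0.2, tumor02 = 0.9, tumor03 = 0.9,
                tumor04 = 0.9)
  tabs <- generate_assignment_tables(ref, pools = list(A = names(adhesion)),
                                     hash_adhesion = adhesion,
                                     doublet_rate = 0, seed = 3)
  tab <- tabs$A$hash
  unassigned_rate <- function(th) {
    lab <- call_assignments(tab, th)
    vapply(names(adhesion), function(s) {
      sel <- tab$true_sample == s
      mean(lab$label[sel] == "unassigned")
    }, numeric(1))
  }
  r90 <- unassigned_rate(0.90)
  expect_equal(names(which.max(r90)), "tumor01")
  totals <- vapply(c(0.90, 0.85, 0.80),
                   function(th) sum(unassigned_rate(th)), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("pooling design emits one hash/genetic pair per pool", {
  ref <- tiny_cohort(n_tumors = 8, cells = 30, seed = 31)
  tabs <- generate_assignment_tables(ref, seed = 5)
  expect_length(tabs, 2)
  expect_named(tabs[[1]], c("hash", "genetic"))
  for (pool in tabs) {
    expect_equal(ncol(pool$hash$posterior), 4 + 1)
    expect_true(all(abs(rowSums(pool$hash$posterior) - 1) < 1e-9))
    expect_true(all(abs(rowSums(pool$genetic$posterior) - 1) < 1e-9))
  }
  expect_error(generate_assignment_tables(
    ref, pools = list(A = "tumor01")), class = "deconvbench_config_error")
})
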