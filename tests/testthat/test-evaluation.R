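make_est <- function(df) {
  df$reference_tag <- "full"
  df$protocol <- NA_character_
  df
}

test_that("rmse matches the closed form and a two-loop recomputation", {
  est <- make_est(data.frame(method = "m", sample = "s1",
                             cell_type = c("A", "B"),
                             estimate = c(0.5, 0.5)))
  truth <- data.frame(sample = "s1", cell_type = c("A", "B"),
                      truth = c(0.7, 0.3))
  expect_equal(rmse(est, truth)$rmse, 0.2)
  expect_equal(rmse(make_est(transform(est, estimate = truth$truth)),
                    truth)$rmse, 0)

  # 3-sample fixture vs independent double loop
  set.seed(103)
  samples <- paste0("s", 1:3)
  types <- c("A", "B", "C")
  est3 <- make_est(expand.grid(method = "m", sample = samples,
                               cell_type = types,
                               stringsAsFactors = FALSE))
  est3$estimate <- runif(nrow(est3))
  truth3 <- expand.grid(sample = samples, cell_type = types,
                        stringsAsFactors = FALSE)
  truth3$truth <- runif(nrow(truth3))
  got <- rmse(est3, truth3)$rmse
  per_sample <- numeric(0)
  for (s in samples) {
    errs <- numeric(0)
    for (t in types) {
      e <- est3$estimate[est3$sample == s & est3$cell_type == t]
      tr <- truth3$truth[truth3$sample == s & truth3$cell_type == t]
      errs <- c(errs, (e - tr)^2)
    }
    per_sample <- c(per_sample, sqrt(mean(errs)))
  }
  expect_equal(got, mean(per_sample))

  # order invariance
  shuf <- est3[sample(nrow(est3)), ]
  expect_equal(rmse(shuf, truth3)$rmse, got)

  est_bad <- est3
  est_bad$cell_type[1] <- "unknown"
  expect_error(rmse(est_bad, truth3),
               class = "deconvbench_alignment_error")
})

test_that("signed differences keep the simplex structure", {
  truth <- data.frame(sample = rep(paste0("s", 1:2), each = 2),
                      cell_type = rep(c("A", "B"), 2),
                      truth = c(0.4, 0.6, 0.4, 0.6))
  est <- make_est(data.frame(method = "m",
                             sample = truth$sample,
                             cell_type = truth$cell_type,
                             estimate = c(0.5, 0.5, 0.5, 0.5)))
  d <- proportion_differences(est, truth)
  expect_equal(d$means$difference[d$means$cell_type == "A"], 0.1)
  expect_equal(d$means$difference[d$means$cell_type == "B"], -0.1)
  # per-sample differences sum to zero under the simplex constraint
  sums <- tapply(d$observations$difference, d$observations$sample, sum)
  expect_equal(as.numeric(sums), c(0, 0))

  perfect <- make_est(data.frame(method = "m", sample = truth$sample,
                                 cell_type = truth$cell_type,
                                 estimate = truth$truth))
  expect_true(all(proportion_differences(perfect,
                                         truth)$means$difference == 0))
})

test_that("robustness variance is the unbiased sample variance per key", {
  res <- data.frame(method = "m", sample = "s1", cell_type = "A",
                    protocol = c("p1", "p2", "p3"),
                    estimate = c(0.1, 0.2, 0.3))
  v <- robustness_variance(res, "protocol")
  expect_equal(v$table$variance, 0.01)

  same <- transform(res, estimate = 0.2)
  expect_equal(robustness_variance(same, "protocol")$table$variance, 0)

  # two-axis fixture vs direct recomputation
  set.seed(107)
  grid <- expand.grid(method = c("m1", "m2"), sample = paste0("s", 1:2),
                      cell_type = c("A", "B"), protocol = c("p1", "p2"),
                      stringsAsFactors = FALSE)
  grid$estimate <- runif(nrow(grid))
  v2 <- robustness_variance(grid, "protocol")
  for (i in seq_len(nrow(v2$table))) {
    key <- v2$table[i, ]
    vals <- grid$estimate[grid$method == key$method &
                          grid$sample == key$sample &
                          grid$cell_type == key$cell_type]
    expect_equal(key$variance, var(vals))
  }
  expect_equal(v2$by_method$variance,
               tapply(v2$table$variance, v2$table$method, mean),
               ignore_attr = TRUE)

  single <- rbind(grid, data.frame(method = "m3", sample = "s1",
                                   cell_type = "A", protocol = "p1",
                                   estimate = 0.5))
  expect_warning(robustness_variance(single, "protocol"),
                 "single")
})

test_that("variance vanishes as estimates converge across conditions", {
  base <- expand.grid(method = "m", sample = "s1", cell_type = "A",
                      protocol = c("p1", "p2", "p3"),
                      stringsAsFactors = FALSE)
  vv <- vapply(c(0.3, 0.1, 0.01, 0), function(spread) {
    base$estimate <- 0.5 + spread * c(-1, 0, 1)
    robustness_variance(base, "protocol")$table$variance
  }, numeric(1))
  expect_true(all(diff(vv) < 0 | vv[-1] == 0))
  expect_equal(vv[4], 0)
})

test_that("stepwise variance accumulates reference sizes", {
  grid <- expand.grid(method = "m", sample = "s1", cell_type = "A",
                      reference_tag = c("full", "size500", "size200"),
                      stringsAsFactors = FALSE)
  grid$estimate <- c(0.5, 0.5, 0.9)
  st <- stepwise_variance(grid, order = c("full", "size500", "size200"))
  expect_equal(st$variance[st$step == 2], 0)
  expect_gt(st$variance[st$step == 3], 0)
})

test_that("accuracy-robustness summary pairs methods and enforces coverage", {
  r <- data.frame(method = c("m1", "m2"), rmse = c(0, 0.2))
  v <- data.frame(method = c("m1", "m2"), variance = c(0, 0.05))
  s <- accuracy_robustness_summary(r, v)
  expect_equal(s[s$method == "m1", c("mean_variance", "mean_rmse")],
               data.frame(mean_variance = 0, mean_rmse = 0),
               ignore_attr = TRUE)
  # dominance preserved: m1 no worse on both axes
  expect_true(all(s[s$method == "m1", -1] <= s[s$method == "m2", -1]))
  expect_error(
    accuracy_robustness_summary(r, v[v$method == "m1", , drop = FALSE]),
    class = "deconvbench_coverage_error")
})

test_that("sequential ANOVA reproduces hand-computed sums of squares", {
  toy <- data.frame(estimate = c(1, 2, 3, 4, 5, 6),
                    method = rep(c("g1", "g2"), each = 3))
  a <- anova_factors(toy, factors = "method")
  expect_equal(a$statistic[1], 13.5)
  expect_equal(a$df, c(1, 4))
  expect_equal(a$p_value[1], pf(13.5, 1, 4, lower.tail = FALSE))

  flat <- transform(toy, estimate = 1)
  d <- anova_factors(flat, factors = "method")
  expect_true(attr(d, "degenerate"))
  expect_equal(d$sum_sq, rep(0, 2))

  one_level <- transform(toy, method = "g1")
  expect_warning(expect_error(anova_factors(one_level,
                                            factors = "method"),
                              class = "deconvbench_config_error"),
                 "single level")
})
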