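bias_rows <- function(deltas_a, deltas_b = NULL, base = 30) {
  mk <- function(deltas, model, off) {
    data.frame(sample_id = paste0(model, "_", seq_along(deltas)),
               treatment = "alectinib", host_model = model,
               n_cells = 1000L, k_positive = 100L,
               obs_median = base + off + deltas,
               obs_mean = base + off + deltas,
               null_median = base + off, null_mean = base + off,
               delta_median = deltas, delta_mean = deltas,
               ks_d = 0.1, p_left = 0.5, R = 199L, seed = 1L)
  }
  out <- mk(deltas_a, "NSG", 0)
  if (!is.null(deltas_b)) out <- rbind(out, mk(deltas_b, "NSGhHGF", 5))
  out
}

test_that("per-sample bias summaries behave at the null and under bias", {
  # f = 1: positives are all cells, deltas exactly zero
  cfg1 <- small_config(seed = 61, n_cells = 400, positive_fraction = 1,
                       width = 96, height = 96)
  b1 <- sample_bias(generate_dataset(cfg1)$sample, R = 49, seed = 3)
  expect_identical(b1$delta_median, 0)
  expect_identical(b1$delta_mean, 0)
  expect_identical(b1$k_positive, 400L)

  # unbiased sample: delta within the central 95% null band
  cfg2 <- small_config(seed = 62)
  s2 <- generate_dataset(cfg2)$sample
  b2 <- sample_bias(s2, R = 199, seed = 4)
  ens <- null_ensemble(cell_distances(s2), R = 199, seed = 4)
  band <- quantile(ens$replicates$median_um - b2$null_median,
                   c(0.025, 0.975))
  expect_true(b2$delta_median >= band[1] && b2$delta_median <= band[2])

  # strong proximity bias: negative delta, small left-tail p
  cfg3 <- small_config(seed = 63, bias_length = 10)
  b3 <- sample_bias(generate_dataset(cfg3)$sample, R = 199, seed = 5)
  expect_lt(b3$delta_median, 0)
  expect_lte(b3$p_left, 0.05)

  none <- generate_dataset(small_config(seed = 64, n_cells = 200,
                                        positive_fraction = 0,
                                        width = 96, height = 96))$sample
  expect_error(sample_bias(none, R = 9, seed = 1), "no marker-positive")
})

test_that("paired test equals the one-sample t on deltas", {
  su <- bias_rows(c(-5, -3, -4, -6))
  res <- paired_observed_vs_predicted(su, "median")
  d <- c(-5, -3, -4, -6)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(t_oracle), df = 3),
               tolerance = 1e-12)
  expect_identical(res$df, 3)

  # sign flip preserves |t| and p
  res2 <- paired_observed_vs_predicted(bias_rows(-c(-5, -3, -4, -6)),
                                       "median")
  expect_equal(abs(res2$t), abs(res$t))
  expect_equal(res2$p.value, res$p.value)

  # degenerate conventions
  z <- paired_observed_vs_predicted(bias_rows(c(0, 0, 0)), "median")
  expect_identical(z$t, 0)
  expect_identical(z$p.value, 1)
  cz <- paired_observed_vs_predicted(bias_rows(c(-2, -2, -2)), "median")
  expect_true(cz$degenerate)
  expect_lte(cz$p.value, .Machine$double.xmin)

  expect_error(paired_observed_vs_predicted(bias_rows(-1), "median"),
               "at least 2")
})

test_that("interaction test separates differentially biased models", {
  # identical per-model data: no interaction by construction
  su0 <- bias_rows(c(-1, 2, 0, 1), c(-1, 2, 0, 1))
  it0 <- interaction_test(su0, "median")
  expect_equal(it0$F, 0, tolerance = 1e-12)
  expect_equal(it0$p.value, 1, tolerance = 1e-9)

  # paired form == one-way ANOVA of deltas between models
  su <- bias_rows(c(-6, -4, -5, -7), c(-1, 1, 0, -2))
  it <- interaction_test(su, "median")
  f_oracle <- summary(aov(delta_median ~ host_model, data = su))[[1]]
  expect_equal(it$F, f_oracle[1, "F value"], tolerance = 1e-9)
  expect_equal(it$p.value, f_oracle[1, "Pr(>F)"], tolerance = 1e-9)

  expect_error(interaction_test(bias_rows(c(-1, 0, 1)), "median"),
               "exactly two host models")
  expect_error(interaction_test(bias_rows(c(-1, 0, 1), -1), "median"),
               "fewer than 2")
})

test_that("fixed-effects ANOVA matches a hand sum-of-squares decomposition", {
  # balanced 2x2: models A/B x conditions observed/predicted, 3 values each
  su <- bias_rows(c(-6, -4, -5), c(-1, 1, 0))
  it <- interaction_test(su, "median", paired = FALSE)

  long <- expand.grid(s = 1:3, model = c("A", "B"),
                      cond = c("obs", "pred"))
  long$value <- c(su$obs_median[1:3], su$obs_median[4:6],
                  su$null_median[1:3], su$null_median[4:6])
  gm <- mean(long$value)
  mi <- tapply(long$value, long$model, mean)
  cj <- tapply(long$value, long$cond, mean)
  cellm <- tapply(long$value, interaction(long$model, long$cond), mean)
  ss_int <- 3 * sum((cellm - rep(mi, 2) - rep(cj, each = 2) + gm)^2)
  ss_res <- sum((long$value -
                   cellm[interaction(long$model, long$cond)])^2)
  f_hand <- (ss_int / 1) / (ss_res / 8)
  expect_equal(it$F, f_hand, tolerance = 1e-9)
})

test_that("shuffling host-model labels destroys a simulated interaction", {
  su <- bias_rows(c(-12, -10, -11, -13, -9, -12), c(-1, 1, 0, -2, 2, 1))
  p0 <- interaction_test(su, "median")$p.value
  expect_lt(p0, 0.01)
  set.seed(31)
  p_perm <- replicate(60, {
    sh <- su
    sh$host_model <- sample(sh$host_model)
    if (length(unique(sh$host_model)) == 2 &&
        all(table(sh$host_model) >= 2)) {
      interaction_test(sh, "median")$p.value
    } else NA_real_
  })
  p_perm <- p_perm[!is.na(p_perm)]
  # permuted labels should rarely look as extreme as the true labeling
  expect_lt(mean(p_perm <= p0), 0.1)
  expect_gt(median(p_perm), 0.1)
})

test_that("group_result aggregates paired tests and optional interaction", {
  su <- bias_rows(c(-6, -4, -5, -7), c(-1, 1, 0, -2))
  gr <- group_result(su, "median")
  expect_identical(nrow(gr$paired), 2L)
  expect_false(is.null(gr$interaction))

  single <- bias_rows(c(-6, -4, -5, -7))
  gr1 <- group_result(single, "median")
  expect_identical(nrow(gr1$paired), 1L)
  expect_null(gr1$interaction)
})
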