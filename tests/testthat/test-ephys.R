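test_that("omission and tone responses implement the two-window statistic", {
  expect_equal(omission_response(numeric(0), 1000), 0)
  # 3 spikes in the response window, none in the baseline
  sp <- c(1010, 1050, 1100)
  expect_equal(omission_response(sp, 1000), 3 / 0.115, tolerance = 1e-12)
  # 3 in response, 1 in baseline
  sp2 <- c(990, 1010, 1050, 1100)
  expect_equal(omission_response(sp2, 1000), 3 / 0.115 - 1 / 0.029,
               tolerance = 1e-12)
  expect_equal(tone_response(c(1010, 1020, 1030, 1040, 1110), 1000),
               5 / 0.115, tolerance = 1e-12)
  # windows are half-open: a spike exactly at onset+120 is excluded,
  # at onset+5 it belongs to the response window, not the baseline
  expect_equal(omission_response(c(1120), 1000), 0)
  expect_equal(omission_response(c(1005), 1000), 1 / 0.115, tolerance = 1e-12)
})

test_that("trial splitting and subsampling follow the stated conventions", {
  s <- split_trials(1:50)
  expect_equal(length(s$odd), 25L)
  expect_equal(length(s$even), 25L)
  expect_equal(split_trials(paste0("t", 1:4)),
               list(odd = c("t1", "t3"), even = c("t2", "t4")))
  expect_equal(split_trials(1)$even, integer(0) + numeric(0))
  expect_equal(length(split_trials(1)$odd), 1L)

  expect_equal(subsample_trials(1:100), seq(1, 99, by = 2))
  expect_equal(subsample_trials(1:200), seq(1, by = 4, length.out = 50))
  expect_equal(subsample_trials(1:50), 1:50)
  expect_equal(length(subsample_trials(1:137)), 50L)
})

test_that("probability correlation identifies the preferred tone", {
  probs <- rep(c(0.95, 0.9, 0.85, 0.75, 0.5, 0.2, 0.1, 0), each = 25)
  pc <- probability_correlation(probs * 3, probs)
  expect_equal(pc$rho, 1)
  expect_equal(pc$o_p_tone, "A")
  pc_b <- probability_correlation(-probs * 3, probs)
  expect_equal(pc_b$o_p_tone, "B")
  expect_equal(pc_b$rho, 1)
  # tied responses are flagged undefined
  expect_true(probability_correlation(rep(1, 200), probs)$flagged)
  # permuted responses are usually non-significant
  set.seed(7)
  fp <- mean(replicate(100, {
    probability_correlation(sample(probs * 3), probs)$p < 0.05
  }))
  expect_lt(fp, 0.15)
})

test_that("WCSS knee selects the visible cluster structure", {
  set.seed(2)
  rhos <- c(rnorm(120, 0.02, 0.04), rnorm(60, 0.5, 0.04))
  cl <- cluster_correlation_coeffs(rhos, seed = 2)
  expect_equal(cl$k_opt, 2L)
  expect_equal(sort(table(cl$assignments), decreasing = TRUE),
               sort(c(120L, 60L), decreasing = TRUE), ignore_attr = TRUE)
  cl1 <- cluster_correlation_coeffs(rep(0.3, 15))
  expect_equal(cl1$k_opt, 1L)
})

test_that("overlap expectation matches the hypergeometric mean", {
  ov <- overlap_statistics(123, 145, 990, observed = 61)
  expect_equal(round(ov$expected), 18)
  expect_lt(ov$p, 0.001)
  expect_equal(overlap_statistics(10, 10, 20)$expected, 5)
  expect_equal(overlap_statistics(7, 0, 100)$expected, 0)
  expect_error(overlap_statistics(5, 5, 0), "positive")
  # exhaustive enumeration oracle for small populations: with the odd set
  # fixed, averaging the overlap over all possible even sets
  n_total <- 12; n_odd <- 5; n_even <- 4
  sets <- utils::combn(n_total, n_even)
  mean_overlap <- mean(apply(sets, 2, function(s) sum(s <= n_odd)))
  expect_equal(overlap_statistics(n_odd, n_even, n_total)$expected,
               mean_overlap, tolerance = 1e-12)
})

test_that("buildup fit recovers a noiseless logistic exactly", {
  a <- 4.95; b <- 0.012; cc <- 223.28
  centers <- seq(25, 975, by = 50)
  y <- a / (1 + exp(-b * (centers - cc)))
  fit <- buildup_fit(centers, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), c(a, b, cc), tolerance = 0.01)
  expect_gt(fit$r_squared, 0.9999)
  # logistic midpoint identity: FR(c) = a / 2
  co <- fit$coef
  expect_equal(co[["a"]] / (1 + exp(-co[["b"]] * (co[["c"]] - co[["c"]]))),
               co[["a"]] / 2)
})

test_that("adaptation fit recovers a noiseless exponential exactly", {
  d <- 2.91; e <- 396.36; f <- 2.25
  n <- 1:50
  y <- d + e * exp(-f * n)
  fit <- adaptation_fit(n, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), c(d, e, f), tolerance = 0.01)
  expect_gt(fit$r_squared, 0.9999)
  co <- fit$coef
  # first-trial rate implied by the fit, and the asymptote
  expect_equal(co[["d"]] + co[["e"]] * exp(-co[["f"]]), d + e * exp(-f),
               tolerance = 0.01)
  expect_equal(co[["d"]], d, tolerance = 0.01)
  expect_error(adaptation_fit(1:3, c(5, 4, 3)), "4 trials")
})

test_that("selectivity indices are normalized differences", {
  s <- selectivity_indices(10, 5, 8, 2)
  expect_equal(s$tsi, 1 / 3)
  expect_equal(s$osi, 0.6)
  expect_equal(selectivity_indices(4, 4, 1, 1)$tsi, 0)
  expect_equal(selectivity_indices(10, 0, 1, 1)$tsi, 1)
  expect_true(selectivity_indices(0, 0, 1, 1)$flagged)
  # invariance under uniform rate scaling
  s2 <- selectivity_indices(20, 10, 16, 4)
  expect_equal(s2$tsi, s$tsi)
  expect_equal(s2$osi, s$osi)
})

test_that("correlation without positive omission responses is not a PEON", {
  # condition-monotone responses centred at zero in the standard conditions
  probs <- rep(c(0.95, 0.9, 0.85, 0.75, 0.5, 0.2, 0.1, 0), each = 25)
  lv <- rep(c(1.5, 0.5, -0.5, -1.5, -3, -5, -6, -7), each = 25)
  set.seed(1)
  resp <- lv + rnorm(length(lv), 0, 0.1)
  pc <- probability_correlation(resp, probs)
  expect_lt(pc$p, 0.05)                       # criterion 1 passes
  wp <- peonr:::wilcoxon_greater_p(resp[probs >= 0.75])
  expect_gt(wp, 0.05)                         # criterion 2 fails
})

test_that("group bootstrap calibrates against the permutation null", {
  groups <- rep(c("a", "b"), each = 100)
  # flags concentrated entirely in one group of a balanced design
  flags <- c(rep(TRUE, 20), rep(FALSE, 180))
  bt <- group_bootstrap(flags, groups, n_boot = 2000, seed = 1)
  expect_equal(bt$observed[bt$group == "a"], 20L)
  expect_lt(bt$p[bt$group == "a"], 0.01)
  expect_equal(bt$null_mean[bt$group == "a"], 10, tolerance = 0.1)
  # observation at the null mean gives p near 1
  flags2 <- rep(c(TRUE, FALSE, FALSE, FALSE), 50)   # 10 per group by design
  bt2 <- group_bootstrap(flags2[order(groups)], groups, n_boot = 2000, seed = 1)
  expect_gt(min(bt2$p), 0.5)
})

test_that("depth-to-layer assignment uses the stated bands", {
  expect_equal(layer_from_depth(c(0, 599, 600, 899, 900, 1400)),
               c("supragranular", "supragranular", "granular", "granular",
                 "infragranular", "infragranular"))
  expect_true(is.na(layer_from_depth(1500)))
})
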