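test_that("trial responses count spikes in half-open windows per trial", {
  sim <- fake_sim(c(3, 40, 160))
  expect_equal(trial_response(sim, 2, "PE-"), c(2L, 1L, 0L))
  # a silent neuron yields zero everywhere
  expect_equal(trial_response(sim, 3, "PE-"), c(0L, 0L, 0L))
  # restricted window, half-open: the trial-2 spike at relative time 10 ms
  # falls outside [0, 10)
  expect_equal(trial_response(sim, 2, "PE-", window = c(0, 10)), c(1L, 0L, 0L))
  expect_equal(trial_response(sim, 2, "PE-", window = c(0, 10.1)), c(1L, 1L, 0L))
  expect_error(trial_response(sim, 2, "PE-", window = c(0, 200)), "window")
})

test_that("probability sweeps have the documented trial composition", {
  sw <- probability_sweep(circuit_config("none"), grid = 0.9, seed = 1,
                          n_items = 500)
  expect_equal(sum(sw$trials$label == "O"), 25L)
  expect_equal(sum(sw$trials$label == "A"), 450L)
  expect_equal(nrow(sw$trials), 500L)
  expect_error(probability_sweep(circuit_config("none"), grid = 0.97),
               "0.95")
})

test_that("sweep correlations flag constant responses", {
  sw <- structure(list(trials = data.frame(
    prob_a = rep(c(0.1, 0.9), each = 10),
    label = "O", trial_index = 1:20, count = 0L)), class = "peon_sweep")
  cc <- sweep_correlations(sw)
  expect_true(cc$flagged[cc$label == "O"])
  expect_equal(cc$rho[cc$label == "O"], 0)
})

test_that("steady prediction averages the stationary window", {
  tms <- seq(0, 75000, by = 100)
  expect_equal(steady_prediction(rep(0.4, length(tms)), tms), 0.4)
  tr <- ifelse(tms < 25000, 0, 0.6)
  expect_equal(steady_prediction(tr, tms), 0.6)
  expect_error(steady_prediction(rep(0, 10), seq(0, 900, by = 100)), "window")
})

test_that("prediction contrast is a decibel ratio with floored zeros", {
  expect_equal(as.numeric(prediction_contrast(0.3, 0.3)), 0)
  expect_equal(as.numeric(prediction_contrast(0.6, 0.06)), 10)
  z <- prediction_contrast(0, 0.5)
  expect_true(attr(z, "flagged"))
  expect_equal(mean_prediction_energy(c(0.5, 0.1, 0.1, 0.1, 0.2)), 0.2)
  expect_equal(mean_prediction_energy(rep(0.3, 5)), 0.3)
  expect_error(mean_prediction_energy(numeric(0)), "stream")
})

test_that("a base firing factor of 1 reproduces the unadapted sweep", {
  grid <- c(0.15, 0.75)
  plain <- probability_sweep(circuit_config("lateral_pe_to_pe"), grid,
                             seed = 4, n_items = 100)
  ad <- adaptation_sweep(circuit_config("lateral_pe_to_pe"), a_values = 0.1,
                         b_values = 1, grid = grid, seed = 4, n_items = 100)
  cc <- sweep_correlations(plain)
  expect_equal(ad$rho, cc$rho)
  expect_equal(ad$n, cc$n)
  # default lists span 12 (a, b) combinations
  expect_equal(nrow(expand.grid(a = c(0.01, 0.05, 0.1, 0.5),
                                b = c(0.1, 0.3, 0.5))), 12L)
})
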