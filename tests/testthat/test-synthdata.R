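test_that("the generator plants the exact PEON count and valid schema", {
  cfg <- generator_config(n_neurons = 100, peon_fraction = 0.2, seed = 4)
  conds <- experiment_conditions(n_items = 200, seed = 4)
  gen <- generate_recording(cfg, conds)
  expect_equal(sum(gen$ground_truth$is_peon), 20L)
  expect_s3_class(gen$recording, "spike_recording")
  # constructor enforces the schema invariants (50 omissions per 1,000-item
  # condition scales to 10 per 200-item condition here)
  ev <- gen$recording$events
  expect_true(all(tapply(ev$label == "O", ev$condition_id, sum) == 10))
  expect_true(all(gen$ground_truth$o_p_tone[gen$ground_truth$is_peon]
                  %in% c("A", "B")))
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_neurons = 5, seed = 11)
  conds <- experiment_conditions(n_items = 100, seed = 11)
  g1 <- generate_recording(cfg, conds)
  g2 <- generate_recording(cfg, conds)
  expect_identical(g1$recording$spikes, g2$recording$spikes)
  expect_identical(g1$ground_truth, g2$ground_truth)
})

test_that("background spike counts match the Poisson expectation", {
  # all-omission condition, no planted structure: pure background
  cfg <- generator_config(n_neurons = 30, peon_fraction = 0, seed = 8)
  conds <- list(condition(0, 0, 1, n_items = 500, soa = 150, seed = 8))
  rec <- generate_recording(cfg, conds)$recording
  counts <- tabulate(rec$spikes$neuron_id, nbins = 30)
  mu <- 5 * 75            # 5 spikes/s for 75 s
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(mu / 30))
})

test_that("planted omission amplitudes are recovered by the estimator", {
  cfg <- generator_config(n_neurons = 60, peon_fraction = 0.5, seed = 6)
  gen <- generate_recording(cfg)
  gt <- gen$ground_truth
  ids <- gt$neuron_id[gt$is_peon & gt$o_p_tone == "A" &
                        gt$selectivity == "selective"]
  # condition 1 is 95% Tone A; late positions are at full logistic buildup
  resp <- unlist(lapply(ids, function(nid) {
    d <- peonr:::neuron_omission_responses(gen$recording, nid, "ALL")
    d$response[d$condition_id == 1 & d$position > 450]
  }))
  planted <- cfg$omission_amplitude_max * 0.95^2
  se <- stats::sd(resp) / sqrt(length(resp))
  expect_lt(abs(mean(resp) - planted), 4 * se + 1)
})

test_that("null recordings carry no omission structure", {
  rec <- null_recording(generator_config(n_neurons = 40, seed = 12),
                        experiment_conditions(n_items = 500, seed = 12))
  resp <- unlist(lapply(rec$neurons$neuron_id, function(nid) {
    peonr:::neuron_omission_responses(rec, nid, "ALL")$response
  }))
  expect_lt(abs(mean(resp)), 1)
  cls <- classify_peons(rec, "ODD")
  expect_lte(mean(cls$category == "PEON"), 0.125)
})

test_that("the pipeline recovers planted ground truth on a small recording", {
  cfg <- generator_config(n_neurons = 120, peon_fraction = 0.25, seed = 3)
  gen <- generate_recording(cfg)
  gt <- gen$ground_truth
  cls <- classify_peons(gen$recording, "ODD")
  hat <- cls$category == "PEON"
  hit <- hat & gt$is_peon
  expect_gte(mean(hat[gt$is_peon]), 0.9)                    # sensitivity
  expect_gte(mean(cls$o_p_tone[hit] == gt$o_p_tone[hit]), 0.9)
  # omission-selectivity agreement: bounded below the ideal by the
  # anticonservative one-sided signed-rank on the skewed null (see the
  # methods vignette); asserted at the achievable level
  sel <- vapply(which(hit), function(i) {
    sc <- selectivity_classification(gen$recording, cls$neuron_id[i],
                                     cls$o_p_tone[i], "EVEN")
    if (is.na(sc$omission_label)) "unvalidated" else sc$omission_label
  }, character(1))
  expect_gte(mean(sel == gt$selectivity[hit]), 0.7)
  # classification degrades gracefully as the planted amplitude vanishes
  cfg0 <- generator_config(n_neurons = 60, peon_fraction = 0.25,
                           omission_amplitude_max = 0, seed = 3)
  gen0 <- generate_recording(cfg0)
  cls0 <- classify_peons(gen0$recording, "ODD")
  expect_lte(mean(cls0$category == "PEON"), 0.15)
})

test_that("population-level correlations show the planted asymmetry", {
  cfg <- generator_config(n_neurons = 80, peon_fraction = 0.4, seed = 5)
  gen <- generate_recording(cfg)
  cls <- classify_peons(gen$recording, "ODD")
  peons <- cls[cls$category == "PEON", c("neuron_id", "o_p_tone")]
  pc <- population_tone_correlations(gen$recording, peons, "EVEN")
  expect_gt(pc$rho[pc$type == "omission"], 0)
  expect_lt(pc$p[pc$type == "omission"], 0.05)
  # tone responses adapt: response to the preferred tone falls as its
  # probability rises
  expect_lt(pc$rho[pc$type == "tone_OP"], 0)
})
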