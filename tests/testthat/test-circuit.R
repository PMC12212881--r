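test_that("lateral weight and delay follow the distance laws", {
  expect_equal(lateral_weight(2, 3), 1.2)
  expect_equal(lateral_weight(1, 3), 0.3)      # 1.2 / 4
  expect_equal(lateral_delay(2, 3), 5)
  expect_equal(lateral_delay(1, 5), 20)
  expect_error(lateral_weight(2, 2), "self")
  expect_error(lateral_delay(3, 3), "self")
})

test_that("build_network produces the documented topology", {
  net_none <- build_network(circuit_config("none"))
  expect_equal(sum(net_none$lateral), 0L)
  expect_equal(nrow(net_none), 5 * 6)          # six intra synapses per module

  net <- build_network(circuit_config("lateral_pe_to_pe"))
  lat <- net[net$lateral, ]
  expect_equal(nrow(lat), 20L)                 # 5 x 4 ordered pairs
  expect_true(all(!lat$inhibitory))
  # presynaptic role is PE+ (role index 3 within each 6-neuron module)
  expect_true(all((lat$pre - 1) %% 6 + 1 == 3))
  expect_true(all((lat$post - 1) %% 6 + 1 == 4))   # postsynaptic PE-

  net_i <- build_network(circuit_config("lateral_i_to_pe"))
  lat_i <- net_i[net_i$lateral, ]
  expect_true(all((lat_i$pre - 1) %% 6 + 1 == 1))  # presynaptic I
  # weights/delays follow the distance laws
  d <- abs(ceiling(lat$pre / 6) - ceiling(lat$post / 6))
  expect_equal(lat$weight, 1.2 / d^2)
  expect_equal(lat$delay, 5 * d)
})

test_that("adapted input strengths decay with probability toward the floor", {
  expect_equal(unname(adapted_strength(0, 0.3, 0.2)["S_A"]), 1)
  expect_equal(unname(adapted_strength(0.5, 0.1, 0.1)["S_A"]),
               0.9 * exp(-5) + 0.1, tolerance = 1e-10)
  expect_equal(unname(adapted_strength(0.95, 0.5, 0.3)["S_A"]),
               0.7 * exp(-1.9) + 0.3, tolerance = 1e-10)
  s <- adapted_strength(0.5, 0.1, 0.1)
  expect_true(all(s >= 0.1 & s <= 1))
  # b = 1 disables adaptation entirely
  expect_equal(unname(adapted_strength(0.7, 0.2, 1)), c(1, 1))
  expect_error(adapted_strength(0.5, 0, 0.1), "positive")
})

test_that("drive currents are 20-ms pulses scaled by gain and prediction", {
  expect_equal(unname(drive_currents(5, 0, s_gain = 0, p_strength = 0)),
               c(0, 0))                                  # omission: no input
  expect_equal(unname(drive_currents(5, 0, 1, 0)["I_stim"]), 0.2)
  expect_equal(unname(drive_currents(10, 0, 1, 0.5)["I_pred"]), 0.1)
  expect_equal(unname(drive_currents(30, 0, 1, 1)), c(0, 0))  # after the pulse
})

test_that("prediction updates are per-spike impulses with clipping", {
  expect_equal(update_prediction(0, 10, 0), 0.01)
  expect_equal(update_prediction(0.9999, 10, 0), 1)
  expect_equal(update_prediction(1e-04, 0, 5), 0)
})

test_that("the integrator matches the closed-form constant-current solution", {
  # constant 0.2 uA onto the stream-2 input neuron (Rm I = 200 mV)
  cfg <- circuit_config("none", stim_duration = 150)
  sim <- simulate_circuit(cfg,
    generate_sequence(condition(1, 0, 0, n_items = 1, soa = 150, seed = 1)))
  sp <- sim_spikes(sim, 2, "I")
  t_star <- -30 * log(1 - 10 / 200)
  expect_lt(abs(sp[1] - t_star), cfg$dt + 1e-9)
  # subsequent interspike intervals: refractory period + fresh rise time,
  # identical up to one-step discretisation jitter
  expect_lte(max(diff(sp)) - min(diff(sp)), cfg$dt + 1e-9)
  expect_true(all(abs(diff(sp) - (cfg$t_ref + t_star)) <= 2 * cfg$dt))
})

test_that("refractory period bounds every interspike interval", {
  sim <- simulate_circuit(circuit_config("lateral_pe_to_pe"), short_sequence())
  isis <- unlist(lapply(sim$spikes, diff))
  expect_true(all(isis >= sim$config$t_ref))
  # spike times strictly increasing per neuron
  expect_true(all(vapply(sim$spikes,
                         function(s) !is.unsorted(s, strictly = TRUE),
                         logical(1))))
})

test_that("prediction strength stays within [0, 1] for every stream", {
  sim <- simulate_circuit(circuit_config("lateral_pe_to_pe"), short_sequence())
  expect_true(all(sim$p_strength >= 0 & sim$p_strength <= 1))
})

test_that("zero-weight lateral network reproduces the no-lateral variant", {
  seq <- short_sequence()
  s0 <- simulate_circuit(circuit_config("lateral_pe_to_pe",
                                        lateral_base_weight = 0), seq)
  sn <- simulate_circuit(circuit_config("none"), seq)
  expect_identical(s0$spikes, sn$spikes)
  expect_identical(s0$p_strength, sn$p_strength)
})

test_that("an all-omission sequence leaves the network silent", {
  sim <- simulate_circuit(circuit_config("lateral_pe_to_pe"),
    generate_sequence(condition(0, 0, 1, n_items = 20, soa = 150, seed = 1)))
  expect_equal(sum(lengths(sim$spikes)), 0L)
  expect_true(all(sim$p_strength == 0))
})

test_that("halving the integration step changes PE- counts by under 5%", {
  seq <- short_sequence()
  s1 <- simulate_circuit(circuit_config("lateral_pe_to_pe", dt = 0.1), seq)
  s2 <- simulate_circuit(circuit_config("lateral_pe_to_pe", dt = 0.05), seq,
                         p_record_every = 20)
  m1 <- mean(trial_response(s1, 2, "PE-"))
  m2 <- mean(trial_response(s2, 2, "PE-"))
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("the calibrated synapse table satisfies its operating constraints", {
  expect_true(all(calibrate_check()))
})

test_that("the stream-2 PE- neuron shows the asymmetric receptive field", {
  # 90% A: once the prediction is established, responses to omissions and
  # Tone B but none to the expected Tone A
  sa <- simulate_circuit(circuit_config("lateral_pe_to_pe"),
    generate_sequence(condition(0.9, 0.05, 0.05, 500, seed = 42)))
  cnt <- trial_response(sa, 2, "PE-")
  lab <- sa$sequence$items
  late <- seq_along(lab) > 250
  means <- tapply(cnt[late], lab[late], mean)
  expect_equal(unname(means["A"]), 0)
  expect_gt(means["O"], 0)
  expect_gt(means["B"], 0)
  # 90% B: responses to tones but not to omissions (no prediction for A)
  sb <- simulate_circuit(circuit_config("lateral_pe_to_pe"),
    generate_sequence(condition(0.05, 0.9, 0.05, 500, seed = 9)))
  cntb <- trial_response(sb, 2, "PE-")
  labb <- sb$sequence$items
  lateb <- seq_along(labb) > 250
  mb <- tapply(cntb[lateb], labb[lateb], mean)
  expect_equal(unname(mb["O"]), 0)
  expect_gt(mb["A"] + mb["B"], 0)
})

test_that("prediction plateaus in the tone-A streams with stream 2 highest", {
  sim <- simulate_circuit(circuit_config("lateral_pe_to_pe"),
    generate_sequence(condition(0.9, 0.05, 0.05, 500, seed = 42)))
  steady <- apply(sim$p_strength, 2, steady_prediction, p_times = sim$p_times)
  expect_equal(which.max(steady), 2L, ignore_attr = TRUE)
  expect_true(min(steady[1:3]) > max(steady[4:5]))
})
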