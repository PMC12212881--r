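# Build a minimal peon_sim object around hand-written spike trains so the
# response-extraction operations can be tested against interval counting
# done by hand.
fake_sim <- function(spike_times, n_items = 3, soa = 150,
                     stream = 2, role = "PE-") {
  cond <- condition(0, 0, 1, n_items = n_items, soa = soa, seed = 1L)
  seq <- structure(list(items = rep("O", n_items),
                        onsets = (seq_len(n_items) - 1) * soa,
                        condition = cond),
                   class = "peon_sequence")
  spikes <- stats::setNames(
    rep(list(numeric(0)), 5 * 6),
    paste0("s", rep(1:5, each = 6), "_",
           rep(c("I", "P", "PE+", "PE-", "I+", "I-"), 5)))
  spikes[[paste0("s", stream, "_", role)]] <- sort(spike_times)
  structure(list(spikes = spikes, p_strength = matrix(0, 2, 5),
                 p_times = c(0, n_items * soa),
                 sequence = seq,
                 config = circuit_config("none")),
            class = "peon_sim")
}

# Short oddball sequence whose expected counts are integers.
short_sequence <- function(prob_a = 0.9, n_items = 200, seed = 3) {
  generate_sequence(condition(prob_a, 0.95 - prob_a, 0.05,
                              n_items = n_items, soa = 150, seed = seed))
}
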