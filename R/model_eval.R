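#' Per-trial spike counts of one neuron
#'
#' Attributes each spike to the trial whose `[onset, onset + soa)` window
#' contains it and counts spikes inside a window relative to trial onset.
#'
#' @param sim A `peon_sim`.
#' @param stream Stream index.
#' @param role Neuron role (e.g., `"PE-"`).
#' @param window Length-2 numeric, counting window in ms relative to trial
#'   onset, half-open. Default `c(0, soa)` (the full trial).
#' @return Integer vector of spike counts, one per trial.
#' @export
trial_response <- function(sim, stream, role, window = NULL) {
  stopifnot(inherits(sim, "peon_sim"))
  soa <- sim$sequence$condition$soa
  if (is.null(window)) window <- c(0, soa)
  if (window[1] < 0 || window[2] > soa || window[1] >= window[2])
    stop("window must lie within [0, soa)")
  sp <- sim_spikes(sim, stream, role)
  onsets <- sim$sequence$onsets
  n <- length(onsets)
  counts <- integer(n)
  if (length(sp)) {
    trial <- floor(sp / soa) + 1
    rel <- sp - (trial - 1) * soa
    keep <- trial >= 1 & trial <= n & rel >= window[1] & rel < window[2]
    tab <- table(trial[keep])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

#' Sweep the model over a grid of Tone A probabilities
#'
#' Runs one fresh 500-item simulation per grid point (omission rate fixed at
#' 5%, Tone B filling the complement to 0.95, prediction strength reset to 0
#' for every condition) and records the Stream-2 PE- spike count for every
#' trial together with the trial's label. The default 5%-step grid (0 to
#' 0.95) pools 500 omission trials and 4,750 trials per tone.
#'
#' @param config A `peon_circuit_config`.
#' @param grid Numeric vector of Prob(A) values, each `<= 0.95`.
#' @param seed Integer seed; each condition gets a derived child seed.
#' @param n_items Items per condition (default 500).
#' @param stream,role Neuron whose responses are recorded (defaults: the
#'   Stream-2 PE- neuron, the modelled PEON).
#' @return A `"peon_sweep"`: list with `trials` (data.frame `prob_a`,
#'   `label`, `trial_index`, `count`), `p_traces` (list of per-condition
#'   prediction-strength matrices), `p_times`, `grid`, `variant`, `config`.
#' @export
probability_sweep <- function(config, grid = seq(0, 0.95, by = 0.05),
                              seed = 1L, n_items = 500L,
                              stream = 2L, role = "PE-") {
  stopifnot(inherits(config, "peon_circuit_config"))
  if (any(grid < 0 | grid > 0.95))
    stop("grid probabilities must lie in [0, 0.95] (omission rate is fixed at 5%)")
  seeds <- derive_seeds(seed, length(grid))
  trials <- vector("list", length(grid))
  p_traces <- vector("list", length(grid))
  p_times <- NULL
  for (i in seq_along(grid)) {
    pa <- grid[i]
    cond <- condition(pa, 0.95 - pa, 0.05, n_items = n_items, soa = 150,
                      seed = seeds[i])
    sim <- simulate_circuit(config, generate_sequence(cond))
    trials[[i]] <- data.frame(
      prob_a = pa, label = sim$sequence$items,
      trial_index = seq_len(n_items) - 1L,
      count = trial_response(sim, stream, role)
    )
    p_traces[[i]] <- sim$p_strength
    p_times <- sim$p_times
  }
  structure(
    list(trials = do.call(rbind, trials), p_traces = p_traces,
         p_times = p_times, grid = grid, variant = config$variant,
         config = config),
    class = "peon_sweep"
  )
}

#' Trial-level rank correlations of a sweep
#'
#' Spearman rank correlation between the recorded neuron's per-trial spike
#' counts and the condition's Prob(A), computed separately for omission,
#' Tone-A and Tone-B trials. Constant responses leave rho undefined; these
#' are reported as 0 with `flagged = TRUE`. Pearson correlations are also
#' reported for reference.
#'
#' @param sweep A `peon_sweep`.
#' @return data.frame with one row per label: `label`, `rho`, `p`, `n`,
#'   `pearson_r`, `flagged`.
#' @export
sweep_correlations <- function(sweep) {
  stopifnot(inherits(sweep, "peon_sweep"))
  if (length(unique(sweep$trials$prob_a)) < 2)
    stop("need at least 2 distinct prob_a values")
  do.call(rbind, lapply(c("O", "A", "B"), function(lab) {
    d <- sweep$trials[sweep$trials$label == lab, ]
    n <- nrow(d)
    if (n < 3 || length(unique(d$count)) < 2 || length(unique(d$prob_a)) < 2) {
      return(data.frame(label = lab, rho = 0, p = NA_real_, n = n,
                        pearson_r = 0, flagged = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(d$count, d$prob_a, method = "spearman", exact = FALSE))
    data.frame(label = lab, rho = unname(ct$estimate), p = ct$p.value, n = n,
               pearson_r = stats::cor(d$count, d$prob_a), flagged = FALSE)
  }))
}

#' Steady-state prediction strength
#'
#' Mean of a prediction-strength trace over the stationary window (by
#' default the last 50 s of a 75-s simulation, 25-75 s).
#'
#' @param p_trace Numeric vector, one stream's trace.
#' @param p_times Sample times in ms.
#' @param t_start,t_end Window in ms (defaults 25,000 and 75,000).
#' @return Mean prediction strength on the window.
#' @export
steady_prediction <- function(p_trace, p_times, t_start = 25000, t_end = 75000) {
  if (max(p_times) < t_end || min(p_times) > t_start)
    stop("trace does not cover the averaging window")
  keep <- p_times >= t_start & p_times <= t_end
  mean(p_trace[keep])
}

#' Prediction-strength contrast between two streams, in dB
#'
#' `10 * log10(p_stream2 / p_stream1)`. Non-positive inputs are floored at
#' machine epsilon and flagged via an attribute.
#'
#' @param p_stream2,p_stream1 Steady prediction strengths.
#' @return Contrast in dB (attribute `flagged` if a floor was applied).
#' @export
prediction_contrast <- function(p_stream2, p_stream1) {
  flagged <- p_stream2 <= 0 || p_stream1 <= 0
  p2 <- max(p_stream2, .Machine$double.eps)
  p1 <- max(p_stream1, .Machine$double.eps)
  structure(10 * log10(p2 / p1), flagged = flagged)
}

#' Mean prediction strength across streams
#'
#' The network's prediction "energy": arithmetic mean of the steady
#' prediction strengths of all streams.
#'
#' @param steady_values Numeric vector, one value per stream.
#' @return Mean across streams.
#' @export
mean_prediction_energy <- function(steady_values) {
  if (!length(steady_values)) stop("need at least one stream")
  mean(steady_values)
}

#' Steady prediction strengths of all streams in a sweep
#'
#' @param sweep A `peon_sweep`.
#' @param t_start,t_end Averaging window in ms; by default the final two
#'   thirds of the simulation (25-75 s for 500-item conditions).
#' @return Matrix, conditions x streams, of steady prediction strengths.
#' @export
sweep_steady_predictions <- function(sweep, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(sweep, "peon_sweep"))
  if (is.null(t_end)) t_end <- max(sweep$p_times)
  if (is.null(t_start)) t_start <- t_end / 3
  t(vapply(sweep$p_traces, function(m) {
    apply(m, 2, steady_prediction, p_times = sweep$p_times,
          t_start = t_start, t_end = t_end)
  }, numeric(ncol(sweep$p_traces[[1]]))))
}

#' Probability sweeps under graded sensory adaptation
#'
#' Re-runs [probability_sweep()] with the sensory gains scaled by
#' [adapted_strength()] for every combination of the adaptation factor `a`
#' and base firing factor `b`, and reports the per-label correlations.
#'
#' @param config A `peon_circuit_config` (its `adaptation` field is
#'   overridden per combination).
#' @param a_values Adaptation factors (default `c(0.01, 0.05, 0.1, 0.5)`).
#' @param b_values Base firing factors (default `c(0.1, 0.3, 0.5)`).
#' @param grid Prob(A) grid per sweep.
#' @param seed Integer seed.
#' @param n_items Items per condition.
#' @return data.frame with one row per (a, b, label): columns `a`, `b`,
#'   `variant`, `label`, `rho`, `p`, `n`, `flagged`.
#' @export
adaptation_sweep <- function(config, a_values = c(0.01, 0.05, 0.1, 0.5),
                             b_values = c(0.1, 0.3, 0.5),
                             grid = seq(0, 0.95, by = 0.05), seed = 1L,
                             n_items = 500L) {
  stopifnot(length(a_values) > 0, length(b_values) > 0)
  combos <- expand.grid(a = a_values, b = b_values)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- config
    cfg$adaptation <- c(a = combos$a[i], b = combos$b[i])
    sw <- probability_sweep(cfg, grid = grid, seed = seed, n_items = n_items)
    cc <- sweep_correlations(sw)
    cbind(a = combos$a[i], b = combos$b[i], variant = cfg$variant,
          cc[, c("label", "rho", "p", "n", "flagged")])
  })
  do.call(rbind, out)
}
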