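#' Configuration of the synthetic spike-train generator
#'
#' The generator emulates the statistical structure of the recordings that
#' the analysis pipeline targets: Poisson background firing, tone-evoked
#' responses that adapt over repeated presentations and scale inversely with
#' the tone's probability (deviance detection), and -- for planted PEONs --
#' omission responses in the 5-120 ms post-omission window whose amplitude
#' grows with the omitted tone's probability and builds up logistically over
#' the sequence.
#'
#' Default planted parameters echo the shapes the analysis is designed to
#' recover: logistic buildup midpoint near sequence position 223 with slope
#' 0.012, and a fast exponential tone adaptation (rate 2.25 per trial) onto
#' a low plateau.
#'
#' @param n_neurons Number of neurons (default 200).
#' @param peon_fraction Fraction of neurons planted as PEONs; the count is
#'   exact (`round(peon_fraction * n_neurons)`).
#' @param baseline_rate Background rate in spikes/s (default 5).
#' @param tone_floor,tone_amplitude,tone_decay Exponential tone-response
#'   model `floor + amplitude * exp(-decay * n)` over presentation index `n`
#'   (defaults 2.91, 396.36, 2.25 spikes/s and per-trial).
#' @param tone_prob_slope Linear deviance modulation of tone responses:
#'   the amplitude is scaled by `1 - slope * prob(tone)` (default 0.5).
#' @param omission_amplitude_max Peak omission-response amplitude in
#'   spikes/s at probability 1 and full buildup (default 25).
#' @param omission_probability_exponent Shape of amplitude vs Prob(O_P)
#'   (default 2: amplitude grows quadratically, concentrating omission
#'   responses in the conditions where the preferred tone is the standard).
#' @param buildup_b,buildup_c Logistic buildup slope and midpoint over
#'   sequence position (defaults 0.012 and 223.28).
#' @param nonselective_fraction Fraction of PEONs that also respond to
#'   omissions of their non-preferred tone (default 1/3).
#' @param nonselective_onp_weight Relative amplitude of the non-preferred
#'   omission kernel in non-selective PEONs (default 0.4): their response
#'   still grows with the preferred tone's probability but is also clearly
#'   positive when the non-preferred tone is the standard.
#' @param kernel_shape Temporal profile of evoked spikes within the 5-120 ms
#'   response window: `"flat"` or `"alpha"`.
#' @param baseline_modulation Amplitude in `[0, 1)` of an optional slow
#'   sinusoidal baseline fluctuation (default 0 = off; period 10 s).
#' @param layer_probs,field_probs Sampling probabilities for layer
#'   (supragranular, granular, infragranular) and field (A1, VAF, AAF)
#'   labels.
#' @param seed Integer seed; the recording is deterministic given the seed.
#' @return An object of class `"peon_generator_config"`.
#' @export
generator_config <- function(n_neurons = 200L, peon_fraction = 0.15,
                             baseline_rate = 5,
                             tone_floor = 2.91, tone_amplitude = 396.36,
                             tone_decay = 2.25, tone_prob_slope = 0.5,
                             omission_amplitude_max = 25,
                             omission_probability_exponent = 2,
                             buildup_b = 0.012, buildup_c = 223.28,
                             nonselective_fraction = 1 / 3,
                             nonselective_onp_weight = 0.4,
                             kernel_shape = c("flat", "alpha"),
                             baseline_modulation = 0,
                             layer_probs = c(supragranular = 0.40,
                                             granular = 0.25,
                                             infragranular = 0.35),
                             field_probs = c(A1 = 0.5, VAF = 0.3, AAF = 0.2),
                             seed = 1L) {
  kernel_shape <- match.arg(kernel_shape)
  stopifnot(n_neurons >= 1, peon_fraction >= 0, peon_fraction <= 1,
            baseline_rate >= 0, omission_amplitude_max >= 0,
            baseline_modulation >= 0, baseline_modulation < 1)
  structure(as.list(environment()), class = "peon_generator_config")
}

# Spike times of an inhomogeneous response kernel: `count` spikes inside
# [onset+5, onset+120), flat or alpha-shaped (rising then decaying) profile.
kernel_times <- function(count, onset, shape) {
  if (count == 0) return(numeric(0))
  if (shape == "flat") return(onset + stats::runif(count, 5, 115 + 5))
  # alpha profile: t * exp(-t / 25) on [0, 115), sampled by rejection
  out <- numeric(0)
  peak <- 25 * exp(-1)
  while (length(out) < count) {
    t <- stats::runif(count, 0, 115)
    u <- stats::runif(count, 0, peak)
    out <- c(out, t[u < t * exp(-t / 25)])
  }
  onset + 5 + out[seq_len(count)]
}

logistic_buildup <- function(position, b, c) 1 / (1 + exp(-b * (position - c)))

#' Generate a synthetic spike recording with planted ground truth
#'
#' Draws every neuron's spike train from an inhomogeneous Poisson process:
#' a homogeneous background everywhere, an additive tone-evoked kernel on
#' every tone event (adapting over presentations and modulated by the
#' tone's probability), and -- for the planted PEONs -- an additive omission
#' kernel whose amplitude follows
#' `omission_amplitude_max * Prob(O_P)^exponent * logistic(position)`.
#' Non-selective PEONs receive a second omission kernel driven by the
#' non-preferred tone's probability.
#'
#' @param config A `peon_generator_config`.
#' @param conditions List of `peon_condition` objects (default: the eight
#'   experimental conditions from [experiment_conditions()]).
#' @return List with elements `recording` (a [spike_recording()]) and
#'   `ground_truth` (data.frame: `neuron_id`, `is_peon`, `o_p_tone`,
#'   `selectivity`, `depth_um`, `layer`, `field`).
#' @export
generate_recording <- function(config,
                               conditions = experiment_conditions(seed = config$seed)) {
  stopifnot(inherits(config, "peon_generator_config"))
  seqs <- lapply(conditions, generate_sequence)
  events <- event_table(seqs)
  cond_tab <- data.frame(
    condition_id = seq_along(conditions),
    prob_a = vapply(conditions, `[[`, numeric(1), "prob_a"),
    prob_b = vapply(conditions, `[[`, numeric(1), "prob_b"),
    prob_omission = vapply(conditions, `[[`, numeric(1), "prob_omission"))

  n <- config$n_neurons
  n_peon <- as.integer(round(config$peon_fraction * n))
  out <- with_seed(config$seed, {
    depth <- stats::runif(n, 0, 1400)
    gt <- data.frame(
      neuron_id = seq_len(n),
      is_peon = c(rep(TRUE, n_peon), rep(FALSE, n - n_peon)),
      o_p_tone = NA_character_,
      selectivity = NA_character_,
      depth_um = depth,
      layer = sample(names(config$layer_probs), n, replace = TRUE,
                     prob = config$layer_probs),
      field = sample(names(config$field_probs), n, replace = TRUE,
                     prob = config$field_probs),
      stringsAsFactors = FALSE)
    if (n_peon > 0) {
      gt$o_p_tone[seq_len(n_peon)] <- sample(c("A", "B"), n_peon, replace = TRUE)
      gt$selectivity[seq_len(n_peon)] <- ifelse(
        stats::runif(n_peon) < config$nonselective_fraction,
        "non_selective", "selective")
    }
    spikes <- vector("list", n * length(conditions))
    li <- 1L
    for (ci in seq_along(conditions)) {
      sq <- seqs[[ci]]
      cond <- conditions[[ci]]
      dur <- cond$n_items * cond$soa
      tone_ev <- lapply(c(A = "A", B = "B"), function(lab) {
        idx <- which(sq$items == lab)
        list(onsets = sq$onsets[idx], pres = seq_along(idx),
             prob = if (lab == "A") cond$prob_a else cond$prob_b)
      })
      om_idx <- which(sq$items == "O")
      om_onsets <- sq$onsets[om_idx]
      om_pos <- om_idx - 1L
      build <- logistic_buildup(om_pos, config$buildup_b, config$buildup_c)
      for (ni in seq_len(n)) {
        # background
        n_bg <- stats::rpois(1, config$baseline_rate * dur / 1000)
        bg <- stats::runif(n_bg, 0, dur)
        if (config$baseline_modulation > 0) {
          keep <- stats::runif(n_bg) <
            (1 + config$baseline_modulation * sin(2 * pi * bg / 10000)) /
            (1 + config$baseline_modulation)
          bg <- bg[keep]
        }
        st <- bg
        # tone-evoked kernels
        for (lab in c("A", "B")) {
          te <- tone_ev[[lab]]
          if (!length(te$onsets)) next
          amp <- (config$tone_floor +
                    config$tone_amplitude * exp(-config$tone_decay * te$pres)) *
            (1 - config$tone_prob_slope * te$prob)
          cnt <- stats::rpois(length(amp), pmax(amp, 0) * 0.115)
          if (sum(cnt) > 0) {
            ks <- unlist(lapply(which(cnt > 0), function(j)
              kernel_times(cnt[j], te$onsets[j], config$kernel_shape)))
            st <- c(st, ks)
          }
        }
        # omission kernels for planted PEONs
        if (gt$is_peon[ni] && length(om_onsets)) {
          p_op <- if (gt$o_p_tone[ni] == "A") cond$prob_a else cond$prob_b
          p_onp <- if (gt$o_p_tone[ni] == "A") cond$prob_b else cond$prob_a
          amp <- config$omission_amplitude_max *
            p_op^config$omission_probability_exponent * build
          if (identical(gt$selectivity[ni], "non_selective"))
            amp <- amp + config$nonselective_onp_weight *
              config$omission_amplitude_max *
              p_onp^config$omission_probability_exponent * build
          cnt <- stats::rpois(length(amp), amp * 0.115)
          if (sum(cnt) > 0) {
            ks <- unlist(lapply(which(cnt > 0), function(j)
              kernel_times(cnt[j], om_onsets[j], config$kernel_shape)))
            st <- c(st, ks)
          }
        }
        st <- sort(st[st >= 0 & st < dur])
        spikes[[li]] <- data.frame(neuron_id = ni, condition_id = ci,
                                   spike_time_ms = st)
        li <- li + 1L
      }
    }
    list(spikes = do.call(rbind, spikes), gt = gt)
  })
  neurons <- out$gt[, c("neuron_id", "depth_um", "layer", "field")]
  rec <- spike_recording(out$spikes, events, neurons, cond_tab)
  list(recording = rec, ground_truth = out$gt)
}

#' Generate a null recording with no omission structure
#'
#' Same generator with `peon_fraction = 0`: homogeneous Poisson trains plus
#' tone kernels only. Used to calibrate the false-positive rate of the
#' classification pipeline.
#'
#' @param config A `peon_generator_config` (its `peon_fraction` is forced
#'   to 0).
#' @param conditions Condition list, as in [generate_recording()].
#' @return A `spike_recording`.
#' @export
null_recording <- function(config,
                           conditions = experiment_conditions(seed = config$seed)) {
  config$peon_fraction <- 0
  generate_recording(config, conditions)$recording
}
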