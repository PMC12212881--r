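#' Construct a spike recording
#'
#' Container for multi-neuron spike trains plus the trial/event and neuron
#' metadata needed by the analysis pipeline. The same schema is used for
#' synthetic and experimental data; spike times are in ms relative to the
#' start of each condition block.
#'
#' @param spikes data.frame with columns `neuron_id`, `condition_id`,
#'   `spike_time_ms`.
#' @param events data.frame with columns `condition_id`, `item_index`
#'   (0-based), `label` (`"A"`, `"B"`, `"O"`), `onset_ms`.
#' @param neurons data.frame with columns `neuron_id`, `depth_um`, `layer`,
#'   `field`.
#' @param conditions data.frame with columns `condition_id`, `prob_a`,
#'   `prob_b`, `prob_omission`.
#' @return An object of class `"spike_recording"`.
#' @export
spike_recording <- function(spikes, events, neurons, conditions) {
  rec <- structure(list(spikes = spikes, events = events, neurons = neurons,
                        conditions = conditions, cache = new.env(parent = emptyenv())),
                   class = "spike_recording")
  validate_recording(rec)
  rec
}

#' Validate a spike recording against its schema invariants
#'
#' Checks that every spike's neuron exists in the metadata, that event
#' onsets are strictly increasing within each condition, and that each
#' condition's omission count equals `prob_omission * n_items` exactly.
#'
#' @param rec A `spike_recording`.
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "spike_recording"))
  need <- function(df, cols, what)
    if (!all(cols %in% names(df))) stop("missing columns in ", what)
  need(rec$spikes, c("neuron_id", "condition_id", "spike_time_ms"), "spikes")
  need(rec$events, c("condition_id", "item_index", "label", "onset_ms"), "events")
  need(rec$neurons, c("neuron_id", "depth_um", "layer", "field"), "neurons")
  need(rec$conditions, c("condition_id", "prob_a", "prob_b", "prob_omission"),
       "conditions")
  if (!all(rec$spikes$neuron_id %in% rec$neurons$neuron_id))
    stop("spikes reference unknown neuron ids")
  for (cid in unique(rec$events$condition_id)) {
    ev <- rec$events[rec$events$condition_id == cid, ]
    if (is.unsorted(ev$onset_ms, strictly = TRUE))
      stop("event onsets must be strictly increasing within condition ", cid)
    cond <- rec$conditions[rec$conditions$condition_id == cid, ]
    n_om <- sum(ev$label == "O")
    if (nrow(cond) == 1 &&
        abs(n_om - cond$prob_omission * nrow(ev)) > 1e-9)
      stop("omission count does not match prob_omission in condition ", cid)
  }
  invisible(rec)
}

#' Assign cortical layers from recording depth
#'
#' Depth bands: supragranular 0-600 um, granular 600-900 um, infragranular
#' 900-1,400 um (half-open on the right except the deepest band).
#'
#' @param depth_um Numeric depths in micrometres.
#' @return Character vector of layer labels.
#' @export
layer_from_depth <- function(depth_um) {
  out <- ifelse(depth_um < 600, "supragranular",
                ifelse(depth_um < 900, "granular", "infragranular"))
  out[depth_um < 0 | depth_um > 1400] <- NA_character_
  out
}

# Cached per-(neuron, condition) spike index. Recordings carry an
# environment so the split is computed once per object.
spike_index <- function(rec) {
  if (is.null(rec$cache)) return(build_spike_index(rec))
  if (is.null(rec$cache$by_nc))
    rec$cache$by_nc <- build_spike_index(rec)
  rec$cache$by_nc
}

build_spike_index <- function(rec) {
  s <- rec$spikes
  o <- order(s$neuron_id, s$condition_id, s$spike_time_ms)
  split(s$spike_time_ms[o],
        paste(s$neuron_id[o], s$condition_id[o], sep = "."))
}

# #{spikes < t} for sorted spike vector; windows are half-open [a, b).
n_before <- function(sp, t) findInterval(t, sp, left.open = TRUE)

window_rate <- function(sp, a, b) {
  (n_before(sp, b) - n_before(sp, a)) / ((b - a) / 1000)
}

#' Baseline-corrected omission response
#'
#' Firing rate in the 5-120 ms window after the expected (omitted) tone
#' onset, minus the local baseline rate in the -24 to +5 ms window around
#' the expected onset. Both windows are half-open in ms; the result is in
#' spikes/s and may be negative.
#'
#' @param spikes Sorted numeric vector of one neuron's spike times (ms).
#' @param expected_onset Expected tone onset(s) in ms (vectorized).
#' @return Numeric vector of baseline-corrected rates, one per onset.
#' @export
omission_response <- function(spikes, expected_onset) {
  spikes <- sort(spikes)
  window_rate(spikes, expected_onset + 5, expected_onset + 120) -
    window_rate(spikes, expected_onset - 24, expected_onset + 5)
}

#' Baseline-corrected tone response
#'
#' Same two-window statistic as [omission_response()], applied at a tone
#' onset so tone and omission responses are directly comparable.
#'
#' @inheritParams omission_response
#' @param onset Tone onset(s) in ms.
#' @return Numeric vector of baseline-corrected rates in spikes/s.
#' @export
tone_response <- function(spikes, onset) {
  omission_response(spikes, onset)
}

#' Split trials into odd- and even-indexed halves
#'
#' Trials ordered by occurrence are alternately assigned: the 1st, 3rd, ...
#' form the ODD set and the 2nd, 4th, ... the EVEN set, so 50 omission
#' trials per condition yield 25/25 halves.
#'
#' @param trials Vector of trial identifiers, ordered by occurrence.
#' @return List with elements `odd` and `even`.
#' @export
split_trials <- function(trials) {
  idx <- seq_along(trials)
  list(odd = trials[idx %% 2 == 1], even = trials[idx %% 2 == 0])
}

#' Subsample trials to a fixed count
#'
#' Keeps every k-th trial starting from the first, with
#' `k = floor(n / target)`, truncated to `target` trials; fewer than
#' `target` trials are returned unchanged. This equalizes statistical power
#' across conditions with different trial counts.
#'
#' @param trials Vector of trial identifiers, ordered by occurrence.
#' @param target Number of trials to keep (default 50).
#' @return Subsampled vector.
#' @export
subsample_trials <- function(trials, target = 50L) {
  n <- length(trials)
  if (n <= target) return(trials)
  k <- floor(n / target)
  trials[seq(1, by = k, length.out = target)]
}

#' Trial-level probability correlation of omission responses
#'
#' Spearman rank correlation between a neuron's single-trial omission
#' responses and the presentation probability of each tone. The tone whose
#' probability correlates positively is the neuron's omission-preferred
#' (O_P) tone. P-values use the t approximation; ties get average ranks.
#'
#' @param responses Numeric vector of omission responses (one per trial).
#' @param prob_a Probability of Tone A for each trial's condition.
#' @return List with `rho` (against Prob(O_P), non-negative by
#'   construction), `p` (two-sided), `o_p_tone` (`"A"` or `"B"`), `n`, and
#'   `flagged` (`TRUE` when responses are all tied and rho is undefined).
#' @export
probability_correlation <- function(responses, prob_a) {
  n <- length(responses)
  if (n < 3 || length(unique(prob_a)) < 2 || length(unique(responses)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, o_p_tone = NA_character_,
                n = n, flagged = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(responses, prob_a, method = "spearman", exact = FALSE))
  rho_a <- unname(ct$estimate)
  o_p <- if (rho_a >= 0) "A" else "B"
  list(rho = abs(rho_a), p = ct$p.value, o_p_tone = o_p, n = n,
       flagged = FALSE)
}

#' Cluster correlation coefficients and pick k by the WCSS knee
#'
#' Runs k-means (10 restarts per k by default) on a vector of per-neuron
#' correlation coefficients for k = 1..`k_max` and selects the knee of the
#' within-cluster sum of squares curve: the k with maximum perpendicular
#' distance to the chord joining the endpoints of the WCSS-vs-k plot.
#'
#' @param rhos Numeric vector of correlation coefficients.
#' @param k_max Largest k considered (default 10).
#' @param replicates k-means restarts per k (default 10).
#' @param seed Integer seed for the k-means initialisations.
#' @return List with `k_opt`, `assignments` (for `k_opt`), `centers`, and
#'   `wcss` (length `k_max`).
#' @export
cluster_correlation_coeffs <- function(rhos, k_max = 10L, replicates = 10L,
                                       seed = 1L) {
  rhos <- rhos[is.finite(rhos)]
  if (length(rhos) < k_max + 1) stop("need at least k_max + 1 values")
  if (length(unique(rhos)) == 1) {
    return(list(k_opt = 1L, assignments = rep(1L, length(rhos)),
                centers = rhos[1], wcss = rep(0, k_max)))
  }
  x <- matrix(rhos, ncol = 1)
  fits <- with_seed(seed, lapply(seq_len(k_max), function(k) {
    if (k >= length(unique(rhos)))
      return(stats::kmeans(x, centers = length(unique(rhos))))
    stats::kmeans(x, centers = k, nstart = replicates, iter.max = 50)
  }))
  wcss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  k_opt <- wcss_knee(wcss)
  list(k_opt = k_opt, assignments = fits[[k_opt]]$cluster,
       centers = as.numeric(fits[[k_opt]]$centers), wcss = wcss)
}

# Knee of a decreasing curve: max perpendicular distance to the chord from
# (1, wcss[1]) to (k_max, wcss[k_max]).
wcss_knee <- function(wcss) {
  k <- seq_along(wcss)
  x1 <- 1; y1 <- wcss[1]; x2 <- length(wcss); y2 <- wcss[length(wcss)]
  denom <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  if (denom == 0) return(1L)
  d <- abs((y2 - y1) * k - (x2 - x1) * wcss + x2 * y1 - y2 * x1) / denom
  as.integer(which.max(d))
}

# ---- internal: response extraction -----------------------------------------

# Per-neuron sorted spike times for one condition.
neuron_cond_spikes <- function(rec, nid, cid) {
  sp <- spike_index(rec)[[paste(nid, cid, sep = ".")]]
  if (is.null(sp)) numeric(0) else sp
}

# Omission trials of one condition with split applied; returns onsets.
omission_onsets <- function(rec, cid, split = c("ALL", "ODD", "EVEN")) {
  split <- match.arg(split)
  ev <- rec$events[rec$events$condition_id == cid & rec$events$label == "O", ]
  ev <- ev[order(ev$onset_ms), ]
  halves <- split_trials(seq_len(nrow(ev)))
  idx <- switch(split, ALL = seq_len(nrow(ev)), ODD = halves$odd,
                EVEN = halves$even)
  list(onsets = ev$onset_ms[idx], position = ev$item_index[idx])
}

# Tone trials of one condition for one label, subsampled to `target` then
# split-matched; returns onsets (and presentation order).
tone_onsets <- function(rec, cid, label, split = c("ALL", "ODD", "EVEN"),
                        target = 50L) {
  split <- match.arg(split)
  ev <- rec$events[rec$events$condition_id == cid & rec$events$label == label, ]
  ev <- ev[order(ev$onset_ms), ]
  keep <- subsample_trials(seq_len(nrow(ev)), target)
  halves <- split_trials(keep)
  idx <- switch(split, ALL = keep, ODD = halves$odd, EVEN = halves$even)
  list(onsets = ev$onset_ms[idx], position = ev$item_index[idx])
}

# All omission responses of one neuron across conditions for a split.
neuron_omission_responses <- function(rec, nid, split) {
  cond <- rec$conditions
  out <- lapply(cond$condition_id, function(cid) {
    om <- omission_onsets(rec, cid, split)
    if (!length(om$onsets)) return(NULL)
    sp <- neuron_cond_spikes(rec, nid, cid)
    data.frame(condition_id = cid,
               prob_a = cond$prob_a[cond$condition_id == cid],
               prob_b = cond$prob_b[cond$condition_id == cid],
               position = om$position,
               response = omission_response(sp, om$onsets))
  })
  do.call(rbind, out)
}

# Wilcoxon signed-rank p for responses > 0; exact for <= 25 non-zero values.
wilcoxon_greater_p <- function(x) {
  x <- x[is.finite(x)]
  nz <- sum(x != 0)
  if (nz == 0) return(1)
  suppressWarnings(stats::wilcox.test(x, mu = 0, alternative = "greater",
                                      exact = nz <= 25,
                                      correct = TRUE)$p.value)
}

#' Classify probability encoding omission neurons (PEONs)
#'
#' Applies the two split-half criteria to every neuron on the chosen
#' training split: (1) a significant trial-level Spearman correlation
#' (p < `alpha`) between omission responses and the probability of the
#' neuron's omission-preferred (O_P) tone, and (2) a significant positive
#' omission response (one-sided Wilcoxon signed-rank, p < `alpha`) pooled
#' over the conditions where the O_P tone is the standard (probability
#' 0.75-0.95). Neurons passing both are PEONs; those passing only (1) are
#' `correlation_only`; the rest are `none`.
#'
#' @param rec A `spike_recording` containing the eight standard conditions.
#' @param split Training split: `"ODD"`, `"EVEN"` or `"ALL"`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame, one row per neuron: `neuron_id`, `split`,
#'   `o_p_tone`, `rho_train`, `p_train`, `wilcoxon_p_train`, `category`,
#'   `n_trials`, `flagged`.
#' @export
classify_peons <- function(rec, split = c("ODD", "EVEN", "ALL"), alpha = 0.05) {
  split <- match.arg(split)
  stopifnot(inherits(rec, "spike_recording"))
  nids <- rec$neurons$neuron_id
  rows <- lapply(nids, function(nid) {
    d <- neuron_omission_responses(rec, nid, split)
    if (is.null(d) || nrow(d) == 0) {
      return(data.frame(neuron_id = nid, split = split,
                        o_p_tone = NA_character_, rho_train = NA_real_,
                        p_train = NA_real_, wilcoxon_p_train = NA_real_,
                        category = "none", n_trials = 0L, flagged = TRUE))
    }
    pc <- probability_correlation(d$response, d$prob_a)
    if (pc$flagged) {
      return(data.frame(neuron_id = nid, split = split,
                        o_p_tone = NA_character_, rho_train = NA_real_,
                        p_train = NA_real_, wilcoxon_p_train = NA_real_,
                        category = "none", n_trials = nrow(d), flagged = TRUE))
    }
    prob_op <- if (pc$o_p_tone == "A") d$prob_a else d$prob_b
    wp <- wilcoxon_greater_p(d$response[prob_op >= 0.75])
    crit1 <- is.finite(pc$p) && pc$p < alpha
    crit2 <- is.finite(wp) && wp < alpha
    category <- if (crit1 && crit2) "PEON"
      else if (crit1) "correlation_only" else "none"
    data.frame(neuron_id = nid, split = split, o_p_tone = pc$o_p_tone,
               rho_train = pc$rho, p_train = pc$p, wilcoxon_p_train = wp,
               category = category, n_trials = nrow(d), flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Expected overlap and hypergeometric test for two classifications
#'
#' For `n_odd` and `n_even` neurons selected independently out of
#' `n_total`, the chance overlap has a hypergeometric distribution with
#' mean `n_odd * n_even / n_total`. The p-value is the upper-tail
#' probability of observing at least `observed` neurons in both sets.
#'
#' @param n_odd,n_even Sizes of the two selected sets.
#' @param n_total Population size.
#' @param observed Observed overlap (optional; p is `NA` without it).
#' @return List with `expected` and `p`.
#' @export
overlap_statistics <- function(n_odd, n_even, n_total, observed = NULL) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_odd > n_total || n_even > n_total)
    stop("set sizes cannot exceed n_total")
  expected <- n_odd * n_even / n_total
  p <- if (is.null(observed)) NA_real_ else
    stats::phyper(observed - 1, n_odd, n_total - n_odd, n_even,
                  lower.tail = FALSE)
  list(expected = expected, p = p)
}

# ---- curve fits -------------------------------------------------------------

#' Logistic growth fit of omission-response buildup
#'
#' Bins omission responses by sequence position (number of preceding items),
#' then fits `FR(n) = a / (1 + exp(-b (n - c)))` to the bin means by
#' nonlinear least squares.
#'
#' @param positions Sequence positions of the omission trials.
#' @param responses Corresponding omission responses (spikes/s).
#' @param bin_width Bin width in sequence positions (default 50).
#' @return List of class `"peon_fit"`: `model = "logistic"`, `coef`
#'   (named `a`, `b`, `c`), `r_squared` (on bin means), `binned`
#'   (data.frame `center`, `mean`, `sem`, `n`), `converged`.
#' @export
buildup_fit <- function(positions, responses, bin_width = 50) {
  bins <- floor(positions / bin_width)
  agg <- do.call(rbind, lapply(split(responses, bins), function(x) {
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  }))
  centers <- (as.numeric(rownames(agg)) + 0.5) * bin_width
  binned <- data.frame(center = centers, mean = agg[, "mean"],
                       sem = agg[, "sem"], n = agg[, "n"])
  binned <- binned[order(binned$center), ]
  if (nrow(binned) < 6) stop("need at least 6 bins with data")
  fit <- tryCatch(
    minpack.lm::nlsLM(mean ~ a / (1 + exp(-b * (center - cc))),
                      data = binned,
                      start = list(a = max(binned$mean),
                                   b = 0.01, cc = stats::median(binned$center)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  finish_fit(fit, binned, "logistic", c("a", "b", "c"))
}

#' Exponential decay fit of early tone-response adaptation
#'
#' Fits `FR(n) = d + e * exp(-f n)` to mean tone responses across the first
#' trials of a sequence (stimulus-specific adaptation of the standard).
#'
#' @param trial_numbers Trial numbers (1-based presentation index).
#' @param responses Corresponding tone responses (spikes/s).
#' @return List of class `"peon_fit"`: `model = "exponential"`, `coef`
#'   (named `d`, `e`, `f`), `r_squared`, `binned` (per-trial means),
#'   `converged`.
#' @export
adaptation_fit <- function(trial_numbers, responses) {
  if (length(unique(trial_numbers)) < 4) stop("need at least 4 trials")
  means <- tapply(responses, trial_numbers, mean)
  binned <- data.frame(center = as.numeric(names(means)),
                       mean = as.numeric(means))
  binned <- binned[order(binned$center), ]
  d0 <- min(binned$mean)
  amp <- binned$mean - d0 + 1e-9
  f0 <- tryCatch({
    early <- binned[seq_len(min(5, nrow(binned))), ]
    -stats::coef(stats::lm(log(pmax(early$mean - d0, 1e-9)) ~ early$center))[2]
  }, error = function(e) 1)
  f0 <- if (is.finite(f0) && f0 > 0) f0 else 1
  e0 <- max(amp) * exp(f0 * binned$center[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(mean ~ d + e * exp(-f * center), data = binned,
                      start = list(d = d0, e = e0, f = f0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  finish_fit(fit, binned, "exponential", c("d", "e", "f"))
}

finish_fit <- function(fit, binned, model, par_names) {
  if (is.null(fit)) {
    return(structure(list(model = model,
                          coef = stats::setNames(rep(NA_real_, 3), par_names),
                          r_squared = NA_real_, binned = binned,
                          converged = FALSE), class = "peon_fit"))
  }
  pred <- stats::predict(fit)
  ss_res <- sum((binned$mean - pred)^2)
  ss_tot <- sum((binned$mean - mean(binned$mean))^2)
  structure(list(model = model,
                 coef = stats::setNames(as.numeric(stats::coef(fit)), par_names),
                 r_squared = 1 - ss_res / ss_tot, binned = binned,
                 converged = TRUE), class = "peon_fit")
}

# ---- selectivity ------------------------------------------------------------

#' Tone and omission selectivity indices
#'
#' `TSI = (T_OP - T_ONP) / (T_OP + T_ONP)` from mean tone-evoked rates, and
#' `OSI = (O_OP - O_ONP) / (O_OP + O_ONP)` from mean omission rates in the
#' sequences where each tone is the standard. Both lie in `[-1, 1]` for
#' non-negative rates and are invariant under uniform rate scaling.
#'
#' @param t_op,t_onp Mean rates to the O_P and O_NP tones.
#' @param o_op,o_onp Mean omission rates when O_P / O_NP is the standard.
#' @return List with `tsi`, `osi` (NA with `flagged = TRUE` when a
#'   denominator is zero).
#' @export
selectivity_indices <- function(t_op, t_onp, o_op, o_onp) {
  tsi <- if ((t_op + t_onp) == 0) NA_real_ else (t_op - t_onp) / (t_op + t_onp)
  osi <- if ((o_op + o_onp) == 0) NA_real_ else (o_op - o_onp) / (o_op + o_onp)
  list(tsi = tsi, osi = osi, flagged = is.na(tsi) || is.na(osi))
}

#' Selectivity classification of a PEON on the testing split
#'
#' On the held-out split, a PEON is omission-\emph{selective} if its pooled
#' omission responses are significantly positive in the conditions where its
#' O_P tone is the standard but not where the O_NP tone is the standard.
#' Tone responses (subsampled and split-matched) are tested the same way,
#' yielding labels `both`, `OP_only`, `ONP_only` or `neither`.
#'
#' @param rec A `spike_recording`.
#' @param neuron_id Neuron to classify.
#' @param o_p_tone The neuron's O_P tone (`"A"` or `"B"`) from training.
#' @param split Testing split (`"ODD"`, `"EVEN"` or `"ALL"`).
#' @param alpha Significance level (default 0.05).
#' @return List with `validated` (significant O_P omission response on the
#'   testing split), `omission_label` (`"selective"` / `"non_selective"`),
#'   `tone_label`, and the underlying p-values.
#' @export
selectivity_classification <- function(rec, neuron_id, o_p_tone,
                                       split = c("EVEN", "ODD", "ALL"),
                                       alpha = 0.05) {
  split <- match.arg(split)
  d <- neuron_omission_responses(rec, neuron_id, split)
  if (is.null(d) || nrow(d) == 0) stop("neuron has no omission trials")
  prob_op <- if (o_p_tone == "A") d$prob_a else d$prob_b
  prob_onp <- if (o_p_tone == "A") d$prob_b else d$prob_a
  p_om_op <- wilcoxon_greater_p(d$response[prob_op >= 0.75])
  p_om_onp <- wilcoxon_greater_p(d$response[prob_onp >= 0.75])
  validated <- p_om_op < alpha
  omission_label <- if (p_om_op < alpha && p_om_onp >= alpha) "selective"
    else if (p_om_op < alpha && p_om_onp < alpha) "non_selective"
    else NA_character_
  tone_p <- function(label) {
    resp <- unlist(lapply(rec$conditions$condition_id, function(cid) {
      cond <- rec$conditions[rec$conditions$condition_id == cid, ]
      prob <- if (label == "A") cond$prob_a else cond$prob_b
      if (prob <= 0) return(NULL)
      ev <- tone_onsets(rec, cid, label, split)
      if (!length(ev$onsets)) return(NULL)
      tone_response(neuron_cond_spikes(rec, neuron_id, cid), ev$onsets)
    }))
    if (!length(resp)) return(1)
    wilcoxon_greater_p(resp)
  }
  p_t_op <- tone_p(o_p_tone)
  p_t_onp <- tone_p(setdiff(c("A", "B"), o_p_tone))
  tone_label <- if (p_t_op < alpha && p_t_onp < alpha) "both"
    else if (p_t_op < alpha) "OP_only"
    else if (p_t_onp < alpha) "ONP_only" else "neither"
  list(validated = validated, omission_label = omission_label,
       tone_label = tone_label, p_omission_op = p_om_op,
       p_omission_onp = p_om_onp, p_tone_op = p_t_op, p_tone_onp = p_t_onp)
}

# ---- group enrichment -------------------------------------------------------

#' Bootstrap test for group enrichment of PEONs
#'
#' Builds the null by permuting PEON status across neurons: each iteration
#' draws `sum(is_peon)` neurons without replacement and counts them per
#' group. The two-sided p-value per group is twice the smaller tail
#' probability of the observed count under this null, floored at
#' `1 / n_boot` and capped at 1.
#'
#' @param is_peon Logical vector, one element per neuron.
#' @param groups Group label per neuron (layer, field, ...).
#' @param n_boot Number of bootstrap samples (default 300,000).
#' @param seed Integer seed.
#' @return data.frame per group: `group`, `n_group`, `observed`,
#'   `null_mean`, `p`.
#' @export
group_bootstrap <- function(is_peon, groups, n_boot = 300000L, seed = 1L) {
  stopifnot(length(is_peon) == length(groups))
  ok <- !is.na(groups)
  is_peon <- is_peon[ok]; groups <- factor(groups[ok])
  n <- length(is_peon); k <- sum(is_peon)
  g <- as.integer(groups); ng <- nlevels(groups)
  observed <- tabulate(g[is_peon], nbins = ng)
  null_counts <- with_seed(seed, {
    m <- matrix(0L, n_boot, ng)
    for (i in seq_len(n_boot))
      m[i, ] <- tabulate(g[sample.int(n, k)], nbins = ng)
    m
  })
  do.call(rbind, lapply(seq_len(ng), function(j) {
    lo <- mean(null_counts[, j] <= observed[j])
    hi <- mean(null_counts[, j] >= observed[j])
    p <- min(1, max(2 * min(lo, hi), 1 / n_boot))
    data.frame(group = levels(groups)[j], n_group = sum(g == j),
               observed = observed[j], null_mean = mean(null_counts[, j]),
               p = p)
  }))
}

#' Population-level probability correlations of the PEON set
#'
#' Pools per-neuron per-condition mean responses across the classified
#' PEONs on the testing split and computes Spearman correlations against
#' the O_P-tone probability: omission responses over all 8 conditions, and
#' tone responses to the O_P and O_NP tones over the 7 conditions where
#' each tone is present (tone trials subsampled and split-matched).
#'
#' @param rec A `spike_recording`.
#' @param peons data.frame with columns `neuron_id` and `o_p_tone` (e.g.,
#'   PEON rows from [classify_peons()]).
#' @param split Testing split.
#' @return data.frame per response type (`omission`, `tone_OP`,
#'   `tone_ONP`): `type`, `rho`, `p`, `n`.
#' @export
population_tone_correlations <- function(rec, peons,
                                         split = c("EVEN", "ODD", "ALL")) {
  split <- match.arg(split)
  conds <- rec$conditions
  rows_om <- list(); rows_op <- list(); rows_onp <- list()
  for (i in seq_len(nrow(peons))) {
    nid <- peons$neuron_id[i]; op <- peons$o_p_tone[i]
    onp <- setdiff(c("A", "B"), op)
    d <- neuron_omission_responses(rec, nid, split)
    prob_op <- if (op == "A") d$prob_a else d$prob_b
    rows_om[[i]] <- data.frame(
      prob = as.numeric(tapply(prob_op, d$condition_id, unique)),
      resp = as.numeric(tapply(d$response, d$condition_id, mean)))
    tone_means <- function(label) {
      do.call(rbind, lapply(conds$condition_id, function(cid) {
        cond <- conds[conds$condition_id == cid, ]
        prob <- if (label == "A") cond$prob_a else cond$prob_b
        if (prob <= 0) return(NULL)
        ev <- tone_onsets(rec, cid, label, split)
        if (!length(ev$onsets)) return(NULL)
        resp <- tone_response(neuron_cond_spikes(rec, nid, cid), ev$onsets)
        p_op <- if (op == "A") cond$prob_a else cond$prob_b
        data.frame(prob = p_op, resp = mean(resp))
      }))
    }
    rows_op[[i]] <- tone_means(op)
    rows_onp[[i]] <- tone_means(onp)
  }
  corr_row <- function(type, df) {
    df <- do.call(rbind, df)
    if (is.null(df) || nrow(df) < 3 || length(unique(df$resp)) < 2)
      return(data.frame(type = type, rho = NA_real_, p = NA_real_,
                        n = if (is.null(df)) 0L else nrow(df)))
    ct <- suppressWarnings(stats::cor.test(df$resp, df$prob,
                                           method = "spearman", exact = FALSE))
    data.frame(type = type, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(df))
  }
  rbind(corr_row("omission", rows_om), corr_row("tone_OP", rows_op),
        corr_row("tone_ONP", rows_onp))
}
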