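#' Define a stimulus condition
#'
#' A condition fixes the composition of one oddball-with-omission sequence:
#' the probabilities of Tone A, Tone B and omissions, the number of items,
#' and the stimulus onset asynchrony (SOA). Sequences are count-exact: each
#' label occurs exactly `round(prob * n_items)` times, so a 1,000-item
#' condition at 5% omissions contains exactly 50 omission trials (the
#' split-half classifier relies on the 25/25 halves this yields).
#'
#' @param prob_a Probability of Tone A in `[0, 1]`.
#' @param prob_b Probability of Tone B in `[0, 1]`.
#' @param prob_omission Probability of an omission in `[0, 1]`. The three
#'   probabilities must sum to 1 (within 1e-12).
#' @param n_items Number of stimulus items (1,000 in the experiment, 500 in
#'   the circuit simulations).
#' @param soa Stimulus onset asynchrony in ms (default 150).
#' @param seed Integer seed controlling the random order of items.
#' @return An object of class `"peon_condition"`.
#' @examples
#' cond <- condition(0.95, 0, 0.05, n_items = 1000)
#' seq <- generate_sequence(cond)
#' table(seq$items)
#' @export
condition <- function(prob_a, prob_b, prob_omission, n_items = 1000L,
                      soa = 150, seed = 1L) {
  stopifnot(is.numeric(prob_a), is.numeric(prob_b), is.numeric(prob_omission))
  if (prob_a < 0 || prob_b < 0 || prob_omission < 0 ||
      prob_a > 1 || prob_b > 1 || prob_omission > 1)
    stop("probabilities must lie in [0, 1]")
  if (abs(prob_a + prob_b + prob_omission - 1) > 1e-12)
    stop("prob_a + prob_b + prob_omission must equal 1")
  if (n_items <= 0) stop("n_items must be positive")
  if (soa <= 0) stop("soa must be positive")
  structure(
    list(prob_a = prob_a, prob_b = prob_b, prob_omission = prob_omission,
         n_items = as.integer(n_items), soa = soa, seed = as.integer(seed)),
    class = "peon_condition"
  )
}

#' The eight experimental conditions
#'
#' Returns the standard condition grid used in the recordings: Tone A at
#' 95, 90, 85, 75, 50, 20, 10 and 0 percent, Tone B filling the complement
#' to 95%, and a fixed 5% omission rate, 1,000 items per condition at an
#' SOA of 150 ms.
#'
#' @param n_items Items per condition (default 1000).
#' @param soa SOA in ms (default 150).
#' @param seed Base seed; condition `i` uses `seed + i - 1`.
#' @return A list of eight `peon_condition` objects.
#' @export
experiment_conditions <- function(n_items = 1000L, soa = 150, seed = 1L) {
  probs_a <- c(0.95, 0.90, 0.85, 0.75, 0.50, 0.20, 0.10, 0)
  lapply(seq_along(probs_a), function(i) {
    condition(probs_a[i], 0.95 - probs_a[i], 0.05,
              n_items = n_items, soa = soa, seed = seed + i - 1L)
  })
}

#' Generate a tone/omission sequence for a condition
#'
#' Draws a seeded uniform random permutation of the exact label multiset
#' implied by the condition's probabilities. Expected counts
#' `prob * n_items` must be integers; no constraint is placed on consecutive
#' omissions.
#'
#' @param cond A `peon_condition`.
#' @return A `"peon_sequence"`: list with `items` (character vector of
#'   `"A"`, `"B"`, `"O"`), `onsets` (ms, `k * soa` for item `k`, 0-based) and
#'   `condition`.
#' @export
generate_sequence <- function(cond) {
  stopifnot(inherits(cond, "peon_condition"))
  n <- cond$n_items
  counts <- c(A = cond$prob_a, B = cond$prob_b, O = cond$prob_omission) * n
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("probabilities times n_items must give integer label counts")
  counts <- as.integer(round(counts))
  labels <- rep(c("A", "B", "O"), times = counts)
  items <- with_seed(cond$seed, sample(labels, length(labels)))
  structure(
    list(items = items, onsets = (seq_len(n) - 1) * cond$soa, condition = cond),
    class = "peon_sequence"
  )
}

#' Event onset times of a sequence
#'
#' @param seq A `peon_sequence`.
#' @return Numeric vector of onsets in ms; item `k` (0-based) starts at
#'   `k * soa`, so 500 items at 150 ms span 75 s.
#' @export
event_onsets <- function(seq) {
  stopifnot(inherits(seq, "peon_sequence"))
  seq$onsets
}

#' Event table of one or more sequences
#'
#' @param seqs A `peon_sequence` or list of them.
#' @return data.frame with columns `condition_id`, `item_index` (0-based),
#'   `label` and `onset_ms`.
#' @export
event_table <- function(seqs) {
  if (inherits(seqs, "peon_sequence")) seqs <- list(seqs)
  do.call(rbind, lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    data.frame(condition_id = i, item_index = seq_along(s$items) - 1L,
               label = s$items, onset_ms = s$onsets)
  }))
}

# Run expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive reproducible child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
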