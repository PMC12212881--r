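#' Write a spike recording to CSV files
#'
#' Writes `spikes.csv`, `events.csv`, `neurons.csv` and `conditions.csv`
#' into a directory, the on-disk interchange schema shared by synthetic and
#' experimental data.
#'
#' @param rec A `spike_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "spike_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("spikes", "events", "neurons", "conditions"))
    utils::write.csv(rec[[part]], file.path(dir, paste0(part, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a spike recording from CSV files
#'
#' @param dir Directory written by [write_recording()].
#' @return A `spike_recording`.
#' @export
read_recording <- function(dir) {
  parts <- lapply(c("spikes", "events", "neurons", "conditions"),
                  function(p) utils::read.csv(file.path(dir, paste0(p, ".csv"))))
  spike_recording(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
}

write_manifest <- function(dir, seed, config) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "peonr",
    version = as.character(utils::packageVersion("peonr")),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Run the model probability sweeps and benefit analyses
#'
#' Runs the 20-condition probability sweep for the three connectivity
#' variants, the steady-prediction contrast and mean-energy comparisons
#' between the full and no-lateral models, and writes summary CSVs plus a
#' correlation-sign report and a run manifest.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param grid Prob(A) grid (default 0 to 0.95 in 0.05 steps).
#' @param n_items Items per simulated condition (default 500).
#' @return Invisibly, a list with `correlations`, `sign_report`,
#'   `benefit` data.frames.
#' @export
reproduce_model_figures <- function(out_dir, seed = 1L,
                                    grid = seq(0, 0.95, by = 0.05),
                                    n_items = 500L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- c("lateral_pe_to_pe", "lateral_i_to_pe", "none")
  sweeps <- lapply(variants, function(v)
    probability_sweep(circuit_config(v), grid = grid, seed = seed,
                      n_items = n_items))
  names(sweeps) <- variants
  correlations <- do.call(rbind, lapply(variants, function(v)
    cbind(variant = v, sweep_correlations(sweeps[[v]]))))
  utils::write.csv(correlations, file.path(out_dir, "sweep_correlations.csv"),
                   row.names = FALSE)
  trials <- do.call(rbind, lapply(variants, function(v)
    cbind(variant = v, sweeps[[v]]$trials)))
  utils::write.csv(trials, file.path(out_dir, "sweep_trials.csv"),
                   row.names = FALSE)
  # sign report: which variant reproduces (O: +, A: -, B: +)
  sign_report <- do.call(rbind, lapply(variants, function(v) {
    cc <- correlations[correlations$variant == v, ]
    rho <- stats::setNames(cc$rho, cc$label)
    fl <- stats::setNames(cc$flagged, cc$label)
    data.frame(variant = v,
               matches_experiment = isTRUE(rho[["O"]] > 0 && !fl[["O"]] &&
                                           rho[["A"]] < 0 && !fl[["A"]] &&
                                           rho[["B"]] > 0 && !fl[["B"]]))
  }))
  utils::write.csv(sign_report, file.path(out_dir, "sign_report.csv"),
                   row.names = FALSE)
  # benefit analyses: contrast and mean energy, lateral vs none
  steady <- lapply(sweeps[c("lateral_pe_to_pe", "none")],
                   sweep_steady_predictions)
  benefit <- do.call(rbind, lapply(names(steady), function(v) {
    s <- steady[[v]]
    data.frame(variant = v, prob_a = grid,
               p_stream1 = s[, 1], p_stream2 = s[, 2],
               contrast_db = vapply(seq_along(grid), function(i)
                 as.numeric(prediction_contrast(s[i, 2], s[i, 1])), numeric(1)),
               mean_energy = apply(s, 1, mean_prediction_energy))
  }))
  utils::write.csv(benefit, file.path(out_dir, "benefit.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, seed, list(grid = grid, n_items = n_items,
                                     variants = variants))
  invisible(list(correlations = correlations, sign_report = sign_report,
                 benefit = benefit))
}

#' Run the full analysis pipeline on a synthetic recording
#'
#' Generates a planted recording, classifies PEONs on the ODD, EVEN and ALL
#' splits, quantifies the ODD/EVEN overlap against its hypergeometric
#' expectation, fits the buildup and adaptation curves of the recovered
#' PEONs on the testing split, classifies selectivity, runs the laminar and
#' areal bootstrap tests, and writes per-split classification tables plus a
#' recovery report against the planted ground truth.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config A `peon_generator_config` (default configuration with the
#'   given seed).
#' @param n_boot Bootstrap samples for the enrichment tests (default 10,000
#'   here; raise towards 300,000 for publication-grade floors).
#' @return Invisibly, a list with `classification`, `overlap`, `recovery`,
#'   `fits`, `bootstrap`.
#' @export
reproduce_ephys_pipeline <- function(out_dir, seed = 1L,
                                     config = generator_config(seed = seed),
                                     n_boot = 10000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_recording(config)
  rec <- gen$recording
  gt <- gen$ground_truth
  cls <- do.call(rbind, lapply(c("ODD", "EVEN", "ALL"), function(s)
    classify_peons(rec, s)))
  utils::write.csv(cls, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  odd <- cls[cls$split == "ODD", ]
  even <- cls[cls$split == "EVEN", ]
  odd_set <- odd$neuron_id[odd$category == "PEON"]
  even_set <- even$neuron_id[even$category == "PEON"]
  ov <- overlap_statistics(length(odd_set), length(even_set),
                           nrow(rec$neurons),
                           observed = length(intersect(odd_set, even_set)))
  # recovery against ground truth (ODD training split)
  is_peon_hat <- odd$category == "PEON"
  tp <- sum(is_peon_hat & gt$is_peon)
  sens <- if (any(gt$is_peon)) tp / sum(gt$is_peon) else NA_real_
  fpr <- if (any(!gt$is_peon))
    sum(is_peon_hat & !gt$is_peon) / sum(!gt$is_peon) else NA_real_
  hit <- is_peon_hat & gt$is_peon
  op_acc <- if (any(hit))
    mean(odd$o_p_tone[hit] == gt$o_p_tone[hit]) else NA_real_
  recovery <- data.frame(sensitivity = sens, false_positive_rate = fpr,
                         o_p_accuracy = op_acc,
                         n_planted = sum(gt$is_peon),
                         n_detected = sum(is_peon_hat))
  utils::write.csv(recovery, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  # buildup + adaptation fits on the testing (EVEN) split of PEON_ODD
  peons <- odd[odd$category == "PEON", c("neuron_id", "o_p_tone")]
  fits <- NULL
  if (nrow(peons) > 0) {
    bu <- do.call(rbind, lapply(seq_len(nrow(peons)), function(i) {
      d <- neuron_omission_responses(rec, peons$neuron_id[i], "EVEN")
      p_op <- if (peons$o_p_tone[i] == "A") d$prob_a else d$prob_b
      d[p_op >= 0.75, c("position", "response")]
    }))
    fit_b <- buildup_fit(bu$position, bu$response)
    ad <- do.call(rbind, lapply(seq_len(nrow(peons)), function(i) {
      nid <- peons$neuron_id[i]
      do.call(rbind, lapply(rec$conditions$condition_id, function(cid) {
        ev <- rec$events[rec$events$condition_id == cid &
                           rec$events$label != "O", ]
        ev <- ev[order(ev$onset_ms), ]
        ev <- ev[ev$item_index < 50, ]
        if (!nrow(ev)) return(NULL)
        data.frame(n = ev$item_index + 1,
                   response = tone_response(
                     neuron_cond_spikes(rec, nid, cid), ev$onset_ms))
      }))
    }))
    fit_a <- adaptation_fit(ad$n, ad$response)
    fits <- list(buildup = fit_b[c("model", "coef", "r_squared", "converged")],
                 adaptation = fit_a[c("model", "coef", "r_squared", "converged")])
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  # laminar/areal bootstrap on the ODD classification
  flags <- odd$category == "PEON"
  boot <- rbind(
    cbind(grouping = "layer",
          group_bootstrap(flags, rec$neurons$layer, n_boot, seed)),
    cbind(grouping = "field",
          group_bootstrap(flags, rec$neurons$field, n_boot, seed + 1L)))
  utils::write.csv(boot, file.path(out_dir, "bootstrap.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, seed,
                 config[setdiff(names(config), c("layer_probs", "field_probs"))])
  invisible(list(classification = cls, overlap = ov, recovery = recovery,
                 fits = fits, bootstrap = boot))
}
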