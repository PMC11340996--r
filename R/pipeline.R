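## Orchestration of the full workflow: prior construction -> MAP
## inversion (with sensor bootstrap) -> epileptogenicity values -> EZN
## decision -> comparison across prior strategies.

#' Run the VEP pipeline for one seizure
#'
#' Builds the per-region excitability prior for the requested strategy,
#' runs the MAP inversion with the sensor-sensitivity bootstrap, computes
#' epileptogenicity values and the EZN decision, and returns a
#' clinical-report table with goodness metrics and full provenance.
#'
#' @param recording An [seeg_recording()].
#' @param conn A `connectome`.
#' @param gain A `gain_matrix`.
#' @param s2s A `sensor_to_source` matrix (needed for the SEEG prior
#'   strategies).
#' @param strategy One of "clinical", "none", "vep-m", "vep-w", or a
#'   ready-made `region_prior` (e.g., a sodium-MRI prediction from
#'   [predict_to_prior()]).
#' @param clinical_ezn Clinician-listed EZN regions (strategy
#'   "clinical").
#' @param n_bootstrap Sensor-bootstrap runs (default 100).
#' @param median_thr,confidence_thr EZN decision thresholds (defaults
#'   0.6, 75).
#' @param seed Master seed; per-stage seeds are derived as
#'   seed + fixed offsets.
#' @param sim_opts Passed to [run_map()].
#' @param n_windows Envelope windows for the data feature (default 200).
#' @param max_steps L-BFGS iteration cap per inversion (default 20000).
#' @return List of class `vep_run`: `prior`, `inversion` (full-sensor
#'   MAP), `ev_dist`, `estimate`, `report` (data.frame), `goodness`,
#'   `seed`, `strategy`.
#' @export
run_vep <- function(recording, conn, gain, s2s = NULL,
                    strategy = "none", clinical_ezn = NULL,
                    n_bootstrap = 100, median_thr = 0.6,
                    confidence_thr = 75, seed = 0, sim_opts = list(),
                    n_windows = 200, max_steps = 20000) {
  region_ids <- conn$region_ids
  prior <- if (inherits(strategy, "region_prior")) strategy
  else switch(strategy,
    none = prior_none(region_ids),
    clinical = {
      if (is.null(clinical_ezn)) stop("clinical strategy needs clinical_ezn")
      prior_clinical(region_ids, clinical_ezn)
    },
    `vep-m` = , `vep-w` = {
      if (is.null(s2s)) stop("SEEG prior strategies need s2s")
      spec <- compute_log_spectrogram(recording)
      onsets <- band_onset_values(spec)
      if (identical(strategy, "vep-m")) map_prior_vep_m(onsets, s2s)
      else map_prior_vep_w(onsets, s2s)
    },
    stop("unknown prior strategy: ", strategy))

  feature <- extract_data_feature(recording, n_windows = n_windows)
  pspec <- prior_spec(prior$x0_prior)
  inv <- run_map(pspec, feature, conn, gain, max_steps = max_steps,
                 sim_opts = sim_opts)

  dt <- sim_opts$dt %||% 0.1
  invert_subset <- function(keep) {
    sub_gain <- structure(list(values = gain$values[, keep, drop = FALSE],
                               region_ids = gain$region_ids,
                               sensor_names = gain$sensor_names[keep]),
                          class = "gain_matrix")
    sub_rec <- seeg_recording(recording$data[keep, , drop = FALSE],
                              recording$fs,
                              recording$channel_names[keep])
    sub_feat <- extract_data_feature(sub_rec, n_windows = n_windows)
    # bootstrap runs perturb the sensor set only slightly: warm-start
    # from the full-sensor MAP estimate
    r <- run_map(pspec, sub_feat, conn, sub_gain, max_steps = max_steps,
                 sim_opts = sim_opts, init = inv$estimates)
    ev <- compute_ev(detect_onsets(.x_on_windows(r$traj, n_windows)))
    attr(ev, "converged") <- r$converged
    ev
  }
  ev_dist <- bootstrap_sensor_sensitivity(
    invert_subset, n_sensors = nrow(recording$data),
    n_runs = n_bootstrap, seed = seed + 101L, ev_thr = median_thr)
  estimate <- decide_ezn(ev_dist, median_thr, confidence_thr)
  report <- ev_report_table(ev_dist, estimate, region_ids)
  structure(list(prior = prior, inversion = inv, ev_dist = ev_dist,
                 estimate = estimate, report = report,
                 goodness = list(fit = inv$goodness_of_fit,
                                 convergence = inv$converged),
                 seed = seed,
                 strategy = if (inherits(strategy, "region_prior"))
                   strategy$strategy else strategy),
            class = "vep_run")
}

# resample the estimated fast variable onto the feature window grid so
# onset indices live on the same 1..n_windows scale as the data feature
.x_on_windows <- function(traj, n_windows) {
  idx <- round(seq(1, ncol(traj$x), length.out = n_windows))
  traj$x[, idx, drop = FALSE]
}

#' Compare VEP runs across prior strategies
#'
#' Scores each run's EZN estimate against the reference strategy's
#' estimate (balanced accuracy and F0.5 per seizure) and reports
#' pairwise bootstrapped paired t tests with significance flags at 0.05
#' and 0.01.
#'
#' @param runs_by_prior Named list (per prior strategy) of lists (per
#'   seizure) of `vep_run`s (or `ezn_estimate`s).
#' @param reference Name of the reference strategy in `runs_by_prior`
#'   (default "clinical").
#' @param n_resamples,seed Passed to [compare_priors()].
#' @return A `prior_comparison`.
#' @export
compare_runs <- function(runs_by_prior, reference = "clinical",
                         n_resamples = 1e4, seed = 0) {
  stopifnot(reference %in% names(runs_by_prior))
  get_est <- function(x) {
    if (inherits(x, "vep_run")) x$estimate else x
  }
  n_seiz <- vapply(runs_by_prior, length, integer(1))
  if (length(unique(n_seiz)) != 1)
    stop("all strategies must cover the same seizure set")
  ests <- lapply(runs_by_prior, function(rs) lapply(rs, get_est))
  ref <- ests[[reference]]
  compare_priors(ests[names(ests) != reference], ref,
                 n_resamples = n_resamples, seed = seed)
}
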