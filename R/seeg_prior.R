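#' Construct an SEEG seizure recording
#'
#' @param data Channels x samples matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional channel labels.
#' @param window Optional c(start, end) sample indices of the analysis
#'   (seizure) window; defaults to the full recording.
#' @return Object of class `seeg_recording`.
#' @export
seeg_recording <- function(data, fs, channel_names = NULL, window = NULL) {
  data <- as.matrix(data)
  stopifnot(fs > 0)
  if (is.null(channel_names))
    channel_names <- if (!is.null(rownames(data))) rownames(data)
                     else paste0("ch", seq_len(nrow(data)))
  if (is.null(window)) window <- c(1L, ncol(data))
  if (diff(window) + 1 < 200)
    stop("analysis window must contain at least 200 samples")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 window = as.integer(window)),
            class = "seeg_recording")
}

#' Log-spectrogram over 200 consecutive windows
#'
#' The analysis window is cut into 200 equal non-overlapping segments
#' (remainder samples at the end are dropped). Per segment and channel the
#' magnitude-squared FFT gives the power per frequency bin, then the
#' natural log of (power + eps) is taken.
#'
#' @param rec A [seeg_recording()].
#' @param n_windows Number of segments (default 200).
#' @param eps Floor added before the log (default 1e-12).
#' @return List of class `log_spectrogram`: `values` (channels x
#'   frequencies x windows array), `freqs` (Hz), `n_windows`.
#' @export
compute_log_spectrogram <- function(rec, n_windows = 200, eps = 1e-12) {
  stopifnot(inherits(rec, "seeg_recording"))
  seg <- rec$data[, rec$window[1]:rec$window[2], drop = FALSE]
  w <- ncol(seg) %/% n_windows
  if (w < 1) stop("analysis window shorter than the number of segments")
  nch <- nrow(seg)
  nf <- w %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * rec$fs / w
  out <- array(0, dim = c(nch, nf, n_windows))
  for (t in seq_len(n_windows)) {
    block <- seg[, ((t - 1) * w + 1):(t * w), drop = FALSE]
    ft <- stats::mvfft(t(block))         # w x channels
    p <- Mod(ft[seq_len(nf), , drop = FALSE])^2
    out[, , t] <- t(p)
  }
  structure(list(values = log(out + eps), freqs = freqs,
                 n_windows = n_windows, channel_names = rec$channel_names),
            class = "log_spectrogram")
}

#' Enumerate the onset-detection frequency bands
#'
#' Lower bounds range from 10 to 90 Hz and upper bounds from
#' (lower + 10) Hz to `upper_max`, both in 10 Hz steps. The literal rule
#' with `upper_max = 120` yields 63 bands; `upper_max = 110` yields 54.
#'
#' @param upper_max Upper bound cap in Hz (default 120).
#' @return Two-column matrix (low, high) in Hz.
#' @export
enumerate_bands <- function(upper_max = 120) {
  bands <- list()
  for (lo in seq(10, 90, by = 10))
    for (hi in seq(lo + 10, upper_max, by = 10))
      bands[[length(bands) + 1]] <- c(lo, hi)
  m <- do.call(rbind, bands)
  colnames(m) <- c("low", "high")
  m
}

#' Multi-band seizure-onset values per channel
#'
#' Per channel and band: spectrogram rows with bin frequency inside the
#' band are averaged into a 200-point series, thresholded at its 90th
#' percentile; the onset is the first window index strictly above the
#' threshold (1-based). The raw value is the reciprocal of the onset,
#' normalized per band by the maximum across channels. Channels that never
#' cross get 0.
#'
#' @param spec A `log_spectrogram`.
#' @param bands Band matrix from [enumerate_bands()].
#' @return Channels x bands matrix with entries in \[0, 1\].
#' @export
band_onset_values <- function(spec, bands = enumerate_bands()) {
  stopifnot(inherits(spec, "log_spectrogram"))
  v <- spec$values
  nch <- dim(v)[1]
  out <- matrix(0, nch, nrow(bands),
                dimnames = list(spec$channel_names, NULL))
  for (b in seq_len(nrow(bands))) {
    sel <- spec$freqs >= bands[b, 1] & spec$freqs <= bands[b, 2]
    if (!any(sel)) next
    for (ch in seq_len(nch)) {
      series <- if (sum(sel) == 1) v[ch, sel, ] else colMeans(v[ch, sel, ])
      thr <- stats::quantile(series, 0.9, names = FALSE)
      onset <- which(series > thr)[1]
      out[ch, b] <- if (is.na(onset)) 0 else 1 / onset
    }
    mx <- max(out[, b])
    if (mx > 0) out[, b] <- out[, b] / mx
  }
  out
}

.region_prior <- function(strategy, region_values, region_ids) {
  x0 <- binarize_to_x0(region_values)
  structure(list(strategy = strategy,
                 region_values = region_values,
                 x0_prior = x0, region_ids = region_ids),
            class = "region_prior")
}

#' Map sensor onset values to regions: strongest-projection rule (VEP-M)
#'
#' Per band, each sensor's onset value is assigned to the region with the
#' strongest projection to that sensor in the sensor-to-source matrix; a
#' region receiving several sensors keeps the maximum. Band results are
#' averaged, divided by the maximum across regions, and binarized into x0.
#'
#' @param onsets Channels x bands matrix from [band_onset_values()].
#' @param s2s A `sensor_to_source` matrix.
#' @return A `region_prior` (strategy "VEP-M").
#' @export
map_prior_vep_m <- function(onsets, s2s) {
  w <- s2s$values
  stopifnot(ncol(w) == nrow(onsets))
  nreg <- nrow(w)
  per_band <- matrix(0, nreg, ncol(onsets))
  for (b in seq_len(ncol(onsets))) {
    for (k in seq_len(ncol(w))) {
      if (all(w[, k] == 0)) next       # sensor sees nothing; skip
      r <- which.max(w[, k])
      per_band[r, b] <- max(per_band[r, b], onsets[k, b])
    }
  }
  vals <- rowMeans(per_band)
  if (max(vals) > 0) vals <- vals / max(vals)
  .region_prior("VEP-M", stats::setNames(vals, s2s$region_ids),
                s2s$region_ids)
}

#' Map sensor onset values to regions: weighted rule (VEP-W)
#'
#' Per band, each region's value is the sensor-to-source-weighted mean of
#' the sensor onset values; band results are averaged and divided by the
#' maximum across regions, then binarized into x0.
#'
#' @inheritParams map_prior_vep_m
#' @param normalize_weights Weighted mean (default TRUE) vs raw weighted
#'   sum.
#' @return A `region_prior` (strategy "VEP-W").
#' @export
map_prior_vep_w <- function(onsets, s2s, normalize_weights = TRUE) {
  w <- s2s$values
  stopifnot(ncol(w) == nrow(onsets))
  denom <- rowSums(w)
  per_band <- w %*% onsets               # regions x bands
  if (normalize_weights) {
    ok <- denom > 0
    per_band[ok, ] <- per_band[ok, ] / denom[ok]
    per_band[!ok, ] <- 0
  }
  vals <- rowMeans(per_band)
  if (max(vals) > 0) vals <- vals / max(vals)
  .region_prior("VEP-W", stats::setNames(vals, s2s$region_ids),
                s2s$region_ids)
}

#' Binarize region scores into excitability prior values
#'
#' Scores strictly above 0.5 map to x0 = -1.5 (epileptogenic), all others
#' (including exactly 0.5) to x0 = -3.
#'
#' @param region_values Per-region scores in \[0, 1\].
#' @return Numeric vector of x0 prior means in \{-1.5, -3\}.
#' @export
binarize_to_x0 <- function(region_values) {
  stopifnot(all(region_values >= 0), all(region_values <= 1))
  ifelse(region_values > 0.5, -1.5, -3)
}

#' Uninformative and clinical excitability priors
#'
#' `prior_none` assigns x0 = -3 everywhere; `prior_clinical` assigns
#' x0 = -1.5 exactly on the clinician-listed regions and -3 elsewhere.
#'
#' @param region_ids Region identifiers.
#' @return A `region_prior`.
#' @export
prior_none <- function(region_ids) {
  vals <- stats::setNames(rep(0, length(region_ids)), region_ids)
  .region_prior("none", vals, region_ids)
}

#' @rdname prior_none
#' @param ezn_regions Regions clinically diagnosed as epileptogenic.
#' @export
prior_clinical <- function(region_ids, ezn_regions) {
  vals <- stats::setNames(as.numeric(region_ids %in% ezn_regions),
                          region_ids)
  .region_prior("clinical", vals, region_ids)
}
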