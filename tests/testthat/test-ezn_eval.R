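test_that("onset detection uses first crossing with a 200 sentinel", {
  x <- rbind(c(rep(-1, 9), 1, rep(-1, 40)),
             c(rep(-1, 29), 2, rep(-1, 20)),
             rep(-1, 50))
  on <- detect_onsets(x)
  expect_equal(unname(on$t), c(10, 30, 200))
  expect_equal(on$t0, 10)

  silent <- detect_onsets(matrix(-1, 2, 50))
  expect_equal(unname(silent$t), c(200, 200))
  expect_equal(silent$t0, 200)

  # threshold above max(x) everywhere behaves like silence
  high <- detect_onsets(x, threshold = 10)
  expect_true(all(high$t == 200))
})

test_that("epileptogenicity values follow the log-delay formula", {
  ev <- compute_ev(c(10, 30, 200))
  raw <- -log(c(10, 30, 200) - 10 + 1)
  expect_equal(unname(ev), (raw - min(raw)) / (max(raw) - min(raw)),
               ignore_attr = TRUE)
  expect_equal(unname(ev[1]), 1)
  expect_equal(unname(ev[3]), 0)
  expect_equal(unname(ev[2]), 1 - log(21) / log(191), tolerance = 1e-12)

  # two regions with equal earliest onset both score 1
  ev2 <- compute_ev(c(5, 5, 80))
  expect_equal(unname(ev2[1:2]), c(1, 1))

  # all-equal onsets give a flagged all-zero vector
  ev3 <- compute_ev(c(50, 50))
  expect_true(attr(ev3, "flat"))
  expect_true(all(ev3 == 0))

  # min-max normalization is invariant to affine raw-EV rescaling, so
  # any constant divisor in the raw formula is inert
  t_i <- c(10, 25, 60, 200)
  raw <- -log(t_i - min(t_i) + 1)
  for (div in c(1, 2, 20)) {
    r2 <- raw / div
    expect_equal((r2 - min(r2)) / (max(r2) - min(r2)),
                 (raw - min(raw)) / (max(raw) - min(raw)),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with an exhaustive confusion-matrix oracle", {
  # all 2^4 confusion patterns over a 4-sample truth/prediction grid
  truth <- c(1, 1, 0, 0)
  for (mask in 0:15) {
    pred <- as.integer(intToBits(mask)[1:4])
    tp <- sum(pred & truth); fn <- sum(!pred & truth)
    tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
    expect_equal(balanced_accuracy(pred, truth),
                 (tp / (tp + fn) + tn / (tn + fp)) / 2)
    if (tp + fp > 0 || tp + fn > 0) {
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- tp / (tp + fn)
      fb <- if (p == 0 && r == 0) 0
            else (1 + 0.25) * p * r / (0.25 * p + r)
      expect_equal(suppressWarnings(f_beta(pred, truth, 0.5)), fb)
    }
  }
  # spot values: TP=1 FN=1 TN=8 FP=0 -> (0.5 + 1) / 2
  expect_equal(balanced_accuracy(c(1, 0, rep(0, 8)), c(1, 1, rep(0, 8))),
               0.75)
  p <- 1; r <- 0.5
  expect_equal(1.25 * p * r / (0.25 * p + r), 0.8333333, tolerance = 1e-6)
  expect_equal(f_beta(c(1, 0, 0), c(1, 1, 0), 0.5), 0.833333333333,
               tolerance = 1e-9)
  # beta = 1 reduces to the plain F1 harmonic mean
  expect_equal(f_beta(c(1, 1, 0, 0), c(1, 0, 1, 0), 1),
               2 * 0.5 * 0.5 / (0.5 + 0.5))
  expect_true(is.na(suppressWarnings(balanced_accuracy(c(1, 0), c(1, 1)))))
})

test_that("bootstrapped paired t test behaves at its edge cases", {
  a <- c(0.7, 0.8, 0.6, 0.9)
  expect_equal(bootstrap_paired_ttest(a, a)$p_value, 1)

  set.seed(1)
  b <- stats::runif(26, 0.4, 0.6)
  res <- bootstrap_paired_ttest(b + 0.3, b, n_resamples = 2e4, seed = 2)
  expect_lt(res$p_value, 0.01)

  # swapping the arguments negates t and preserves p
  x <- c(0.5, 0.62, 0.55, 0.71, 0.49, 0.66)
  y <- c(0.52, 0.58, 0.60, 0.65, 0.50, 0.60)
  r1 <- bootstrap_paired_ttest(x, y, n_resamples = 5e3, seed = 3)
  r2 <- bootstrap_paired_ttest(y, x, n_resamples = 5e3, seed = 3)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("sensor bootstrap aggregates EV runs into medians/confidence", {
  # deterministic toy: every sensor subset yields identical onsets
  ev_fixed <- compute_ev(c(5, 20, 200))
  dist <- bootstrap_sensor_sensitivity(function(keep) ev_fixed,
                                       n_sensors = 4, n_runs = 20,
                                       seed = 1)
  expect_true(all(apply(dist$ev_runs, 2, stats::sd) == 0))
  expect_equal(unname(dist$confidence[1]), 100)
  expect_equal(unname(dist$confidence[3]), 0)
  expect_equal(unname(dist$median), unname(ev_fixed), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a region seen by a single sensor degrades exactly when it is dropped
  invert <- function(keep) {
    onsets <- c(5, if (2 %in% keep) 15 else 200, 200)
    compute_ev(onsets)
  }
  d2 <- bootstrap_sensor_sensitivity(invert, n_sensors = 3, n_runs = 30,
                                     seed = 4)
  set.seed(4)
  dropped <- sample.int(3, 30, replace = TRUE)
  expect_equal(d2$dropped_sensor, dropped)
  affected <- dropped == 2
  expect_true(all(d2$ev_runs[affected, 2] == 0))
  expect_true(all(d2$ev_runs[!affected, 2] > 0))

  # reproducible under the seed
  d3 <- bootstrap_sensor_sensitivity(invert, n_sensors = 3, n_runs = 30,
                                     seed = 4)
  expect_identical(d2$ev_runs, d3$ev_runs)
})

test_that("EZN decision applies both thresholds strictly", {
  dist <- structure(list(median = c(0.7, 0.7, 0.3),
                         confidence = c(80, 60, 90)),
                    class = "ev_distribution")
  est <- decide_ezn(dist)
  expect_equal(unname(est$member), c(TRUE, FALSE, FALSE))

  # all medians below threshold: empty EZN
  low <- structure(list(median = c(0.5, 0.2), confidence = c(99, 99)),
                   class = "ev_distribution")
  expect_false(any(decide_ezn(low)$member))

  # monotone: raising a median never removes membership
  up <- structure(list(median = c(0.9, 0.7, 0.3),
                       confidence = c(80, 60, 90)),
                  class = "ev_distribution")
  expect_true(all(decide_ezn(up)$member >= decide_ezn(dist)$member))

  # the alternative reported threshold is configurable
  alt <- decide_ezn(dist, median_thr = 0.5, confidence_thr = 50)
  expect_equal(unname(alt$member), c(TRUE, TRUE, FALSE))
})

test_that("prior comparison scores estimates against a reference", {
  ref <- list(c(TRUE, FALSE, FALSE, TRUE), c(FALSE, TRUE, FALSE, FALSE))
  same <- list(a = ref, b = list(c(TRUE, TRUE, FALSE, TRUE),
                                 c(FALSE, TRUE, TRUE, FALSE)))
  cmp <- compare_priors(same, ref, n_resamples = 1e3, seed = 1)
  sa <- cmp$scores[cmp$scores$prior == "a", ]
  expect_true(all(sa$balanced_accuracy == 1))
  expect_true(all(sa$f_half == 1))
  sb <- cmp$scores[cmp$scores$prior == "b", ]
  expect_true(all(sb$balanced_accuracy < 1))
  expect_true(all(c("sig_05", "sig_01") %in% names(cmp$tests)))

  # report table round-trips through TSV exactly
  dist <- structure(list(median = c(0.8, 0.1), confidence = c(90, 10)),
                    class = "ev_distribution")
  est <- decide_ezn(dist)
  tab <- ev_report_table(dist, est, c("rA", "rB"))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE)
  back <- utils::read.delim(path)
  expect_equal(back$median_ev, tab$median_ev)
  expect_equal(back$ezn, tab$ezn)
})
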