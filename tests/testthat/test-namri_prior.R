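test_that("polynomial expansion yields the documented column counts", {
  tab <- separable_cohort(4, seed = 1)
  X <- expand_polynomial(tab)
  expect_equal(ncol(X), 17L)
  expect_equal(ncol(expand_polynomial(tab, with_categorical = FALSE)), 15L)

  # one feature x expands to (1, x, x^2)
  m1 <- vepna:::.poly_expand(matrix(1:3, 3, 1), "x")
  expect_equal(colnames(m1), c("1", "x", "x^2"))
  expect_equal(unname(m1[, 3]), c(1, 4, 9))

  # n features -> choose(n + 2, 2) columns
  for (n in 1:5) {
    m <- vepna:::.poly_expand(matrix(stats::rnorm(4 * n), 4, n),
                              paste0("x", seq_len(n)))
    expect_equal(ncol(m), choose(n + 2, 2))
  }
})

test_that("standardization uses training statistics only", {
  tr <- cbind(`1` = rep(1, 3), a = c(1, 2, 3))
  out <- standardize(tr)
  expect_equal(unname(out$train[, "a"]),
               c(-1, 0, 1) * 1.2247448714, tolerance = 1e-9)
  # the constant column passes through unchanged
  expect_equal(unname(out$train[, "1"]), rep(1, 3))
  # train statistics applied to the train set: mean 0, unit variance
  expect_equal(mean(out$train[, "a"]), 0)
  expect_equal(mean(out$train[, "a"]^2), 1)
  # a test row at the training mean maps to zero
  ap <- standardize(tr, apply = cbind(`1` = 1, a = 2))
  expect_equal(unname(ap$apply[, "a"]), 0)
})

test_that("spectral split recovers generated pattern groups", {
  hits <- 0
  n_runs <- 10
  for (s in seq_len(n_runs)) {
    spec <- cohort_spec(n_patients = 8, seed = 100 + s)
    tab <- gen_cohort_sodium(spec)
    sp <- spectral_split(tab, seed = s)
    truth <- tapply(tab$pattern_group, tab$patient_id, function(g) g[1])
    agree <- mean(sp$subset == truth[names(sp$subset)])
    hits <- hits + (max(agree, 1 - agree) == 1)
  }
  expect_gte(hits / n_runs, 0.9)

  # duplicating every row leaves assignments unchanged
  spec <- cohort_spec(n_patients = 6, seed = 77)
  tab <- gen_cohort_sodium(spec)
  sp1 <- spectral_split(tab, seed = 1)
  sp2 <- spectral_split(feature_table(rbind(tab, tab)), seed = 1)
  same <- mean(sp1$subset == sp2$subset[names(sp1$subset)])
  expect_true(same == 1 || same == 0)  # up to subset relabelling
})

test_that("fold resampling hits the published targets before ENN", {
  set.seed(33)
  X <- rbind(matrix(stats::rnorm(12 * 4, mean = 5), 12, 4),
             matrix(stats::rnorm(150 * 4), 150, 4))
  y <- c(rep(1, 12), rep(0, 150))
  rs <- resample_fold(X, y, seed = 1)
  expect_equal(unname(rs$counts_before_enn), c(60, 180))
  expect_lte(sum(rs$counts), 240)

  # perfectly separated classes: ENN removes nothing
  Xs <- rbind(matrix(stats::rnorm(10 * 2, mean = 50), 10, 2),
              matrix(stats::rnorm(40 * 2), 40, 2))
  ys <- c(rep(1, 10), rep(0, 40))
  rs2 <- resample_fold(Xs, ys, seed = 2)
  expect_equal(unname(rs2$counts), c(60, 180))

  # deterministic under the seed
  rs3 <- resample_fold(X, y, seed = 1)
  expect_identical(rs$X, rs3$X)
})

test_that("permutation importance separates signal from noise features", {
  # probe table in which the f column encodes the target as +/-1 (so its
  # square is constant and no other column is informative), while the
  # remaining base features are independent noise
  set.seed(5)
  n_pat <- 8; n_reg <- 10
  rows <- expand.grid(region_id = paste0("R", 1:n_reg),
                      patient_id = paste0("P", 1:n_pat))
  target <- rep(c(1, rep(0, n_reg - 1)), n_pat)
  tab <- feature_table(data.frame(
    patient_id = rows$patient_id, region_id = rows$region_id,
    f = ifelse(target == 1, 1, -1),
    na_sf = stats::rnorm(nrow(rows)),
    na_lf = stats::rnorm(nrow(rows)),
    tsc = stats::rnorm(nrow(rows)),
    lesional_patient = 0L, lesional_zone = 0L,
    label = ifelse(target == 1, "EZN", "NIZ")))
  # (constant probe columns trigger the zero-variance pass-through note)
  out <- suppressWarnings(permutation_importance_cv(tab, seed = 3))
  # the feature that equals the target is decisively important
  expect_gt(out$importance[["f"]], 0.2)
  # independent noise features fall below the selection threshold
  expect_lt(abs(out$importance[["na_lf"]]), 0.05)
  # constant columns are exactly inert under permutation
  expect_equal(unname(out$importance[["lesional_patient"]]), 0)
  expect_equal(unname(out$importance[["1"]]), 0)
  expect_true(all(out$importance[out$selected] >= 0.05))
  expect_true("f" %in% out$selected)
})

test_that("grid search scores candidates and honours Table-style params", {
  tab <- separable_cohort(8, sep = 8, seed = 7)
  gs <- grid_search_tune(tab, seed = 2)
  cand <- gs$candidates
  expect_true(all(c("lbfgs", "saga") %in% cand$solver))
  expect_true(all(c("3:0.6", "4:0.57") %in% cand$weight))
  expect_true(10 %in% cand$C)
  # separable data: the best validation balanced accuracy reaches 1
  expect_equal(max(cand$cv_val, na.rm = TRUE), 1)
  # ties broken by smallest C then solver name
  top <- cand[cand$cv_val == max(cand$cv_val, na.rm = TRUE), ]
  expect_equal(cand$C[1], min(top$C))

  # label shuffling collapses validation scores towards chance
  set.seed(11)
  sh <- tab
  sh$target <- sample(sh$target)
  sh$label <- ifelse(sh$target == 1, "EZN", "NIZ")
  gss <- grid_search_tune(feature_table(as.data.frame(sh)), seed = 2)
  expect_lt(mean(gss$candidates$cv_val, na.rm = TRUE), 0.62)
})

test_that("model selection applies the published filter rules", {
  fake <- structure(list(candidates = data.frame(
    solver = "lbfgs", C = c(1, 1, 1), weight = "3:0.6",
    cv_train = c(0.71, 0.65, 1.00),
    cv_val = c(0.66, 0.64, 0.80)),
    models = list("m1", "m2", "m3")), class = "grid_search")
  out <- select_models(fake)
  # kept: val 0.66 / gap 0.05; dropped: val 0.64; dropped: gap 0.20
  expect_equal(nrow(out$kept), 1L)
  expect_equal(out$kept$cv_val, 0.66)
  expect_equal(out$status, "ok")

  none <- select_models(structure(list(candidates = data.frame(
    solver = "a", C = 1, weight = "3:0.6", cv_train = 0.9, cv_val = 0.5),
    models = list("m")), class = "grid_search"))
  expect_equal(none$status, "empty")
})

test_that("threshold optimization sweeps probability midpoints", {
  out <- optimize_threshold(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_equal(out$threshold, 0.5)          # largest optimal midpoint
  expect_equal(out$balanced_accuracy, 1)
  expect_false(out$fallback)

  # exhaustive-sweep oracle on a random case
  set.seed(8)
  p <- stats::runif(30)
  y <- as.integer(p + stats::rnorm(30, sd = 0.3) > 0.5)
  if (length(unique(y)) == 2) {
    out2 <- optimize_threshold(p, y)
    grid <- sort(unique(p))
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    bas <- vapply(mids, function(th) {
      pr <- as.integer(p >= th)
      (mean(pr[y == 1] == 1) + mean(pr[y == 0] == 0)) / 2
    }, numeric(1))
    expect_equal(out2$balanced_accuracy, max(bas))
    expect_equal(out2$threshold, max(mids[bas == max(bas)]))
  }

  # constant probabilities fall back to 0.5
  out3 <- optimize_threshold(rep(0.4, 5), c(1, 0, 1, 0, 1))
  expect_true(out3$fallback)
  expect_equal(out3$threshold, 0.5)
})

test_that("predictions convert to excitability priors with defaults", {
  tab <- separable_cohort(8, sep = 8, seed = 9)
  gs <- grid_search_tune(tab, seed = 4)
  fit <- gs$models[[1]]
  pat <- tab[tab$patient_id == tab$patient_id[1], ]
  ids <- c(as.character(pat$region_id), "R999")   # an uninvestigated region
  pr <- predict_to_prior(fit, pat, threshold = 0.5, region_ids = ids)
  expect_s3_class(pr, "region_prior")
  expect_true(all(pr$x0_prior %in% c(-1.5, -3)))
  # never-investigated regions default to non-epileptogenic
  expect_equal(unname(pr$x0_prior[["R999"]]), -3)
  # separable cohort: predicted EZN regions are the labelled ones
  probs <- attr(pr, "probability")
  expect_gt(mean(probs[pat$label == "EZN"]), mean(probs[pat$label == "NIZ"]))
})

test_that("class-weight scale invariance holds up to regularization", {
  tab <- separable_cohort(6, sep = 8, seed = 12)
  X <- expand_polynomial(tab)
  std <- standardize(X)
  y <- tab$target
  f1 <- vepna:::.logistic_fit(std$train, y, C = 10,
                              class_weights = c(pos = 3, neg = 0.6))
  f2 <- vepna:::.logistic_fit(std$train, y, C = 5,
                              class_weights = c(pos = 6, neg = 1.2))
  # doubling weights while halving C keeps the objective, hence the fit
  expect_equal(f1$coef, f2$coef, tolerance = 1e-4)
})
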