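#' Sodium feature table for EZN classification
#'
#' Validates a cohort feature table: one row per (patient, region)
#' investigated by SEEG, with the four sodium features, the two
#' categorical lesion indicators and the clinical label.
#'
#' @param df data.frame with columns `patient_id`, `region_id`, `f`,
#'   `na_sf`, `na_lf`, `tsc`, `lesional_patient`, `lesional_zone`,
#'   `label` (one of "EZN", "PZ", "NIZ").
#' @return The validated data.frame (class `feature_table`) with a
#'   `target` column: 1 iff label == "EZN".
#' @export
feature_table <- function(df) {
  need <- c("patient_id", "region_id", "f", "na_sf", "na_lf", "tsc",
            "lesional_patient", "lesional_zone", "label")
  stopifnot(all(need %in% names(df)))
  if (!all(df$label %in% c("EZN", "PZ", "NIZ")))
    stop("labels must be EZN, PZ or NIZ")
  base <- as.matrix(df[, c("f", "na_sf", "na_lf", "tsc")])
  if (any(!is.finite(base))) stop("non-finite base features")
  df$target <- as.integer(df$label == "EZN")
  class(df) <- c("feature_table", class(df))
  df
}

.base_features <- c("f", "na_sf", "na_lf", "tsc")

#' Degree-2 polynomial feature expansion
#'
#' Expands the four base sodium features into constant + linear + squared
#' + pairwise-interaction columns (15 columns), then appends the two
#' categorical lesion indicators (17 altogether). Column order and naming
#' are deterministic.
#'
#' @param table A [feature_table()] (or data.frame with the base and
#'   categorical columns).
#' @param with_categorical Append `lesional_patient`/`lesional_zone`
#'   (default TRUE).
#' @return Numeric matrix (rows x 15 or 17 columns).
#' @export
expand_polynomial <- function(table, with_categorical = TRUE) {
  X <- as.matrix(table[, .base_features])
  if (any(!is.finite(X))) stop("non-finite inputs in base features")
  out <- .poly_expand(X, colnames(X))
  if (with_categorical) {
    cat <- as.matrix(table[, c("lesional_patient", "lesional_zone")])
    out <- cbind(out, cat)
  }
  out
}

# degree-2 expansion with interaction terms for an arbitrary matrix:
# 1, x_i, then x_i x_j for i <= j (lexicographic) -> choose(n + 2, 2) cols
.poly_expand <- function(X, nms) {
  n <- ncol(X)
  cols <- list(`1` = rep(1, nrow(X)))
  for (i in seq_len(n)) cols[[nms[i]]] <- X[, i]
  for (i in seq_len(n)) for (j in i:n) {
    nm <- if (i == j) paste0(nms[i], "^2") else paste0(nms[i], "*", nms[j])
    cols[[nm]] <- X[, i] * X[, j]
  }
  do.call(cbind, cols)
}

#' Standardize feature matrices with training statistics
#'
#' Per-column (x - mean) / sd using the training matrix only, with the
#' population (1/n) standard deviation as is conventional for feature
#' scaling; columns with zero training variance (e.g., the constant
#' polynomial column) are passed through unchanged (with a warning for
#' non-constant-by-design columns).
#'
#' @param train Training matrix.
#' @param apply Optional matrix to transform with the training statistics.
#' @return List with `train`, `apply` (or NULL), `center`, `scale`.
#' @export
standardize <- function(train, apply = NULL) {
  ctr <- colMeans(train)
  n <- nrow(train)
  scl <- sqrt(vapply(seq_len(ncol(train)), function(j)
    mean((train[, j] - ctr[j])^2), numeric(1)))
  names(scl) <- colnames(train)
  fixed <- !is.finite(scl) | scl == 0
  if (any(fixed & !(colnames(train) %in% "1")))
    warning("zero-variance column(s) passed through: ",
            paste(colnames(train)[fixed & colnames(train) != "1"],
                  collapse = ", "))
  ctr[fixed] <- 0
  scl[fixed] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  ap <- if (!is.null(apply)) sweep(sweep(apply, 2, ctr), 2, scl, "/")
  list(train = tr, apply = ap, center = ctr, scale = scl)
}

# symmetrized kNN affinity + normalized Laplacian eigenmap (2-D)
.laplacian_eigenmap <- function(X, n_neighbors, ndim = 2) {
  n <- nrow(X)
  k <- min(n_neighbors, n - 1)
  D2 <- as.matrix(stats::dist(X))^2
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                     # mutual symmetrization
  d <- rowSums(A)
  d[d == 0] <- 1
  Dn <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dn * A) %*% diag(Dn)
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ord <- order(e$values)                 # ascending; first ~0 is trivial
  emb <- e$vectors[, ord[2:(1 + ndim)], drop = FALSE] * Dn
  # deterministic sign: entry with largest |loading| is positive
  for (j in seq_len(ncol(emb))) {
    i0 <- which.max(abs(emb[, j]))
    if (emb[i0, j] < 0) emb[, j] <- -emb[, j]
  }
  emb
}

#' Split a training cohort by spectral embedding
#'
#' Region rows are embedded into 2 dimensions by Laplacian eigenmaps over
#' a nearest-neighbour affinity graph built from the standardized base
#' features. Each patient's mean first-coordinate over their EZN-labelled
#' rows decides the subset: subset 1 if the mean is above 0, else subset
#' 2. The eigenvector sign is fixed so the row with the largest absolute
#' loading is positive, making the rule reproducible.
#'
#' @param table A [feature_table()].
#' @param n_neighbors Affinity-graph neighbour count (default 10).
#' @param seed Integer seed (embedding is deterministic; kept for
#'   interface stability).
#' @return List of class `split_assignment`: `subset` (named 1/2 per
#'   patient), `ev_mean` (per-patient first-eigenvector mean),
#'   `embedding`, `flagged` (patients without EZN rows).
#' @export
spectral_split <- function(table, n_neighbors = 10, seed = 0) {
  set.seed(seed)
  X <- scale(as.matrix(table[, .base_features]))
  emb <- .laplacian_eigenmap(X, n_neighbors)
  pats <- unique(table$patient_id)
  ev_mean <- numeric(length(pats)); names(ev_mean) <- pats
  flagged <- character(0)
  for (p in pats) {
    rows <- table$patient_id == p & table$label == "EZN"
    if (!any(rows)) {
      rows <- table$patient_id == p
      flagged <- c(flagged, as.character(p))
    }
    ev_mean[as.character(p)] <- mean(emb[rows, 1])
  }
  subset <- ifelse(ev_mean > 0, 1L, 2L)
  structure(list(subset = subset, ev_mean = ev_mean, embedding = emb,
                 flagged = flagged),
            class = "split_assignment")
}

## ---- class-weighted L2 logistic regression -------------------------------

# minimizes 0.5 ||beta||^2 + C * sum_i w_i log(1 + exp(-y_i eta_i)),
# intercept unpenalized, y in {-1, +1}; deterministic L-BFGS-B fit.
.logistic_fit <- function(X, y01, C, class_weights) {
  y <- ifelse(y01 == 1, 1, -1)
  w <- ifelse(y01 == 1, class_weights[["pos"]], class_weights[["neg"]])
  p <- ncol(X)
  obj <- function(th) {
    eta <- th[1] + X %*% th[-1]
    m <- -y * eta
    0.5 * sum(th[-1]^2) + C * sum(w * log1p(exp(pmin(m, 30))) +
                                    w * pmax(m - 30, 0))
  }
  grd <- function(th) {
    eta <- drop(th[1] + X %*% th[-1])
    s <- 1 / (1 + exp(y * eta))          # sigma(-y eta)
    g0 <- -C * sum(w * y * s)
    gb <- th[-1] - C * drop(t(X) %*% (w * y * s))
    c(g0, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = 2000, factr = 1e4))
  list(intercept = fit$par[1], coef = fit$par[-1],
       converged = fit$convergence == 0, value = fit$value)
}

.logistic_prob <- function(model, X) {
  eta <- drop(model$intercept + X %*% model$coef)
  1 / (1 + exp(-eta))
}

#' Balanced-accuracy helper used across the ML pipeline
#' @noRd
.ba <- function(pred, truth) {
  if (length(unique(truth)) < 2) return(NA_real_)
  tpr <- mean(pred[truth == 1] == 1)
  tnr <- mean(pred[truth == 0] == 0)
  (tpr + tnr) / 2
}

## ---- resampling ----------------------------------------------------------

# SMOTE-style interpolation of one class to `target` points
.smote_class <- function(Xc, target, k = 5) {
  n <- nrow(Xc)
  if (n >= target) return(Xc[seq_len(target), , drop = FALSE])
  n_new <- target - n
  if (n == 1) {                          # jittered duplication fallback
    scl <- pmax(abs(Xc[1, ]), 1) * 0.01
    new <- matrix(rep(Xc[1, ], n_new), n_new, ncol(Xc), byrow = TRUE) +
      matrix(stats::rnorm(n_new * ncol(Xc)), n_new) %*% diag(scl, ncol(Xc))
    return(rbind(Xc, new))
  }
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(Xc))
  nbrs <- t(apply(D, 1, function(d) setdiff(order(d), which(d == 0)[1])[seq_len(k)]))
  if (k == 1) nbrs <- matrix(nbrs, ncol = 1)
  base <- rep(seq_len(n), length.out = n_new)
  pick <- sample.int(k, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  new <- Xc[base, , drop = FALSE] +
    u * (Xc[nbrs[cbind(base, pick)], , drop = FALSE] - Xc[base, , drop = FALSE])
  rbind(Xc, new)
}

# edited nearest neighbours: drop points misclassified by majority vote
# of their k nearest neighbours (self excluded); applied to both classes
.enn_edit <- function(X, y, k = 3) {
  n <- nrow(X)
  if (n <= k + 1) return(rep(TRUE, n))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  keep <- logical(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k)]
    keep[i] <- mean(y[nb] == y[i]) > 0.5
  }
  keep
}

#' Resample a cross-validation fold for imbalance-aware training
#'
#' Synthetic (SMOTE-style) oversampling of the minority class to exactly
#' `minority_target` points and the majority class to `majority_target`
#' points, followed by edited-nearest-neighbour cleaning, which only
#' removes points — so the relative imbalance is preserved.
#'
#' @param X Feature matrix of the fold's training part.
#' @param y Binary target (1 = minority/EZN).
#' @param minority_target,majority_target Oversampling targets
#'   (defaults 60, 180).
#' @param seed Integer seed; resampling is deterministic given it.
#' @param enn_k ENN neighbour count (default 3).
#' @param apply_enn Set FALSE to stop after oversampling.
#' @return List with `X`, `y`, `counts_before_enn`, `counts`.
#' @export
resample_fold <- function(X, y, minority_target = 60,
                          majority_target = 180, seed = 0, enn_k = 3,
                          apply_enn = TRUE) {
  stopifnot(length(unique(y)) == 2)
  set.seed(seed)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  min_cls <- if (n1 <= n0) 1 else 0
  tgt <- c(`1` = NA, `0` = NA)
  tgt[as.character(min_cls)] <- minority_target
  tgt[as.character(1 - min_cls)] <- majority_target
  X1 <- .smote_class(X[y == 1, , drop = FALSE], tgt[["1"]])
  X0 <- .smote_class(X[y == 0, , drop = FALSE], tgt[["0"]])
  Xr <- rbind(X1, X0)
  yr <- c(rep(1L, nrow(X1)), rep(0L, nrow(X0)))
  before <- c(pos = nrow(X1), neg = nrow(X0))
  if (apply_enn) {
    keep <- .enn_edit(Xr, yr, k = enn_k)
    Xr <- Xr[keep, , drop = FALSE]; yr <- yr[keep]
  }
  list(X = Xr, y = yr, counts_before_enn = before,
       counts = c(pos = sum(yr == 1), neg = sum(yr == 0)))
}

## ---- cross-validation scaffolding ----------------------------------------

# outer folds of `per_fold` patients (seeded order); returns list of
# character vectors of held-out patient ids
.patient_folds <- function(patients, per_fold = 2, seed = 0) {
  set.seed(seed)
  patients <- sample(as.character(unique(patients)))
  split(patients, ceiling(seq_along(patients) / per_fold))
}

# fit on resampled fold-train, return model + standardizer; categorical
# columns are routinely constant within small patient folds, so the
# zero-variance pass-through note is muted here
.fit_fold <- function(Xtr, ytr, C, class_weights, seed,
                      resample = TRUE) {
  std <- suppressWarnings(standardize(Xtr))
  Xs <- std$train
  if (resample && length(unique(ytr)) == 2) {
    rs <- resample_fold(Xs, ytr, seed = seed)
    Xs <- rs$X; ytr <- rs$y
  }
  model <- .logistic_fit(Xs, ytr, C, class_weights)
  list(model = model, center = std$center, scale = std$scale)
}

.apply_fold <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  .logistic_prob(fit$model, Xs)
}

#' Cross-validated permutation feature importance
#'
#' Patient-level cross-validation; per fold the training part is
#' resampled ([resample_fold()]) and fitted, the reference balanced
#' accuracy computed on the validation part, and each feature permuted
#' `n_repeats` times in the validation part, recording the score drop.
#' Importance is the mean drop across permutations and folds; features
#' with importance at or above `threshold` are selected.
#'
#' @param table A [feature_table()] restricted to one training subset.
#' @param C,class_weights Model hyper-parameters for the probe model.
#' @param n_repeats Permutations per feature per fold (default 10).
#' @param threshold Selection threshold on the mean score drop
#'   (default 0.05).
#' @param seed Integer seed.
#' @return List: `importance` (named), `selected` (feature names),
#'   `skipped_folds`.
#' @export
permutation_importance_cv <- function(table, C = 10,
                                      class_weights = c(pos = 3, neg = 0.6),
                                      n_repeats = 10, threshold = 0.05,
                                      seed = 0) {
  X <- expand_polynomial(table)
  y <- table$target
  folds <- .patient_folds(table$patient_id, 2, seed)
  drops <- matrix(0, 0, ncol(X), dimnames = list(NULL, colnames(X)))
  skipped <- 0
  for (f in seq_along(folds)) {
    hold <- table$patient_id %in% folds[[f]]
    if (length(unique(y[hold])) < 2 || length(unique(y[!hold])) < 2) {
      skipped <- skipped + 1; next
    }
    fit <- .fit_fold(X[!hold, , drop = FALSE], y[!hold], C, class_weights,
                     seed = seed + f)
    Xv <- X[hold, , drop = FALSE]; yv <- y[hold]
    thr_p <- 0.5
    ref <- .ba(as.integer(.apply_fold(fit, Xv) >= thr_p), yv)
    set.seed(seed + 1000 + f)
    fold_drops <- matrix(0, n_repeats, ncol(X))
    for (j in seq_len(ncol(X))) {
      if (length(unique(Xv[, j])) == 1) next   # constant: permuting is a no-op
      for (r in seq_len(n_repeats)) {
        Xp <- Xv
        Xp[, j] <- Xp[sample(nrow(Xp)), j]
        fold_drops[r, j] <-
          ref - .ba(as.integer(.apply_fold(fit, Xp) >= thr_p), yv)
      }
    }
    drops <- rbind(drops, fold_drops)
  }
  if (nrow(drops) == 0) stop("no usable folds for permutation importance")
  imp <- colMeans(drops)
  names(imp) <- colnames(X)
  list(importance = imp, selected = names(imp)[imp >= threshold],
       skipped_folds = skipped)
}

#' Default hyper-parameter grid for the EZN logistic regression
#'
#' Includes the reachable published configurations: C = 10, L2 penalty,
#' class weights EZN:3 / rest:0.6 and EZN:4 / rest:0.57, with solver
#' labels "lbfgs" and "saga" (both map to the same deterministic
#' optimizer of the identical objective).
#'
#' @return data.frame grid with columns solver, C, w_pos, w_neg.
#' @export
default_param_grid <- function() {
  expand.grid(solver = c("lbfgs", "saga"),
              C = c(0.1, 1, 10),
              weight = c("3:0.6", "4:0.57"),
              stringsAsFactors = FALSE)
}

.parse_weight <- function(s) {
  v <- as.numeric(strsplit(s, ":")[[1]])
  c(pos = v[1], neg = v[2])
}

#' Cross-validated grid search for the EZN classifier
#'
#' Patient-level nested cross-validation (outer folds of two patients,
#' per-fold resampling) over a hyper-parameter grid; records mean CV
#' train and validation balanced accuracy per grid point and fits each
#' candidate on the full (resampled) training subset. Ties in validation
#' score break by smallest C, then lexicographic solver name.
#'
#' @param table A [feature_table()] restricted to one training subset.
#' @param features Column names of [expand_polynomial()] output to use
#'   (default: all 17).
#' @param grid data.frame as [default_param_grid()].
#' @param seed Integer seed.
#' @return List of class `grid_search` with `candidates` (data.frame:
#'   solver, C, weights, cv_train, cv_val) and `models` (fitted fits).
#' @export
grid_search_tune <- function(table, features = NULL,
                             grid = default_param_grid(), seed = 0) {
  Xall <- expand_polynomial(table)
  if (!is.null(features)) Xall <- Xall[, features, drop = FALSE]
  y <- table$target
  folds <- .patient_folds(table$patient_id, 2, seed)
  cand <- grid
  cand$cv_train <- NA_real_; cand$cv_val <- NA_real_
  models <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cw <- .parse_weight(grid$weight[g])
    tr_scores <- c(); va_scores <- c()
    ok <- TRUE
    for (f in seq_along(folds)) {
      hold <- table$patient_id %in% folds[[f]]
      if (length(unique(y[hold])) < 2 || length(unique(y[!hold])) < 2) next
      fit <- tryCatch(
        .fit_fold(Xall[!hold, , drop = FALSE], y[!hold], grid$C[g], cw,
                  seed = seed + f),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pv <- .apply_fold(fit, Xall[hold, , drop = FALSE])
      pt <- .apply_fold(fit, Xall[!hold, , drop = FALSE])
      va_scores <- c(va_scores, .ba(as.integer(pv >= 0.5), y[hold]))
      tr_scores <- c(tr_scores, .ba(as.integer(pt >= 0.5), y[!hold]))
    }
    if (!ok || length(va_scores) == 0) next
    cand$cv_train[g] <- mean(tr_scores, na.rm = TRUE)
    cand$cv_val[g] <- mean(va_scores, na.rm = TRUE)
    models[[g]] <- .fit_fold(Xall, y, grid$C[g], cw, seed = seed)
    models[[g]]$C <- grid$C[g]; models[[g]]$class_weights <- cw
    models[[g]]$solver <- grid$solver[g]
    models[[g]]$features <- colnames(Xall)
  }
  ord <- order(-cand$cv_val, cand$C, cand$solver)
  structure(list(candidates = cand[ord, ], models = models[ord],
                 seed = seed),
            class = "grid_search")
}

#' Filter grid-search candidates by the published selection rules
#'
#' Keeps candidates with mean CV validation balanced accuracy above 0.65
#' and train-validation gap below 0.1 (removing chance-level and
#' overfitted models). When a test evaluator is supplied, the retained
#' model maximizing mean test balanced accuracy is marked as selected.
#'
#' @param gs A `grid_search` result.
#' @param test_eval Optional function(model) returning a test balanced
#'   accuracy.
#' @param val_min Validation floor (default 0.65).
#' @param gap_max Overfit gap ceiling (default 0.1).
#' @return List: `kept` (candidate rows), `models`, `best` (index into
#'   kept, or NULL), `status` ("ok" or "empty").
#' @export
select_models <- function(gs, test_eval = NULL, val_min = 0.65,
                          gap_max = 0.1) {
  cc <- gs$candidates
  keep <- !is.na(cc$cv_val) & cc$cv_val > val_min &
    (cc$cv_train - cc$cv_val) < gap_max
  if (!any(keep))
    return(list(kept = cc[0, ], models = list(), best = NULL,
                status = "empty"))
  kept <- cc[keep, ]
  models <- gs$models[keep]
  best <- NULL
  if (!is.null(test_eval)) {
    ts <- vapply(models, test_eval, numeric(1))
    kept$test_ba <- ts
    best <- which.max(ts)
  }
  list(kept = kept, models = models, best = best, status = "ok")
}

#' Optimize the decision threshold on predicted probabilities
#'
#' Sweeps the midpoints of consecutive sorted unique probabilities and
#' returns the threshold maximizing balanced accuracy (prediction = 1
#' when probability >= threshold); ties resolve to the largest
#' threshold. Single-class truth or constant probabilities fall back to
#' 0.5.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param truth Binary reference labels.
#' @return List: `threshold`, `balanced_accuracy`, `fallback`.
#' @export
optimize_threshold <- function(probabilities, truth) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  u <- sort(unique(probabilities))
  if (length(unique(truth)) < 2 || length(u) < 2)
    return(list(threshold = 0.5, balanced_accuracy = 0.5, fallback = TRUE))
  mids <- (u[-1] + u[-length(u)]) / 2
  ba <- vapply(mids, function(th)
    .ba(as.integer(probabilities >= th), truth), numeric(1))
  best <- max(ba)
  th <- max(mids[ba == best])            # largest optimal midpoint
  list(threshold = th, balanced_accuracy = best, fallback = FALSE)
}

#' Convert classifier predictions into an excitability prior
#'
#' Regions predicted EZN (probability at or above the threshold) get
#' x0 = -1.5, all others -3; regions never investigated default to -3.
#'
#' @param fit A fitted model from [grid_search_tune()] (`models` entry).
#' @param patient_table Feature-table rows of one patient.
#' @param threshold Decision threshold (default 0.5).
#' @param region_ids Full region universe (default: the patient's rows).
#' @param strategy Prior name (default "Na-MRI-1").
#' @return A `region_prior`; the `probability` attribute carries the
#'   per-region probabilities.
#' @export
predict_to_prior <- function(fit, patient_table, threshold = 0.5,
                             region_ids = NULL, strategy = "Na-MRI-1") {
  X <- expand_polynomial(patient_table)[, fit$features, drop = FALSE]
  p <- .apply_fold(fit, X)
  names(p) <- as.character(patient_table$region_id)
  if (is.null(region_ids)) region_ids <- names(p)
  vals <- stats::setNames(rep(0, length(region_ids)), region_ids)
  vals[names(p)] <- as.numeric(p >= threshold)
  rp <- .region_prior(strategy, vals, region_ids)
  attr(rp, "probability") <- p
  attr(rp, "threshold") <- threshold
  rp
}
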