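#' Normalize a structural connectome
#'
#' Zeroes self-connections, then rescales so the maximum off-diagonal
#' entry equals one. An all-zero matrix (after removing the diagonal) is
#' returned unchanged with a warning.
#'
#' @param raw Square non-negative weight matrix.
#' @param region_ids Optional region labels (default from dimnames or
#'   integer sequence).
#' @return Object of class `connectome` with fields `weights`,
#'   `region_ids`.
#' @export
normalize_connectome <- function(raw, region_ids = NULL) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("connectome must be square")
  if (any(raw < 0)) stop("connectome weights must be non-negative")
  diag(raw) <- 0
  mx <- max(raw)
  if (mx == 0) warning("connectome has no off-diagonal weights")
  else raw <- raw / mx
  if (is.null(region_ids))
    region_ids <- if (!is.null(rownames(raw))) rownames(raw)
                  else as.character(seq_len(nrow(raw)))
  dimnames(raw) <- list(region_ids, region_ids)
  structure(list(weights = raw, region_ids = region_ids),
            class = "connectome")
}

#' Parameters of the 2D-reduced Epileptor network model
#'
#' The model for region i is
#' \deqn{\dot x_i = I_1 - x_i^3 - 2 x_i^2 - z_i}
#' \deqn{\dot z_i = \frac{1}{\tau_0}\big(4 (x_i - x_{i,0}) - z_i
#'       + K \sum_j C_{ij} (x_j - x_i)\big)}
#' `x0` controls excitability: around -1.5 a node seizes autonomously,
#' around -3 it rests at a stable equilibrium. `tau0` scales seizure
#' length, `K` the network coupling. Time is in the model's arbitrary
#' (slow-variable) units.
#'
#' @param x0 Excitability, scalar or per-region vector.
#' @param tau0 Slow time scale (> 0), default 20.
#' @param K Global coupling (>= 0), default 1.
#' @param I1 External input, default 3.1.
#' @param noise_sd Additive state-noise standard deviation (default 0).
#' @param dt Integration step, default 0.05.
#' @param duration Total simulated time, default 6000 time units.
#' @param coupling_sign +1 (as printed in the model definition) or -1
#'   (the alternative convention); default +1.
#' @return List of class `epileptor_params`.
#' @export
epileptor_params <- function(x0, tau0 = 20, K = 1, I1 = 3.1,
                             noise_sd = 0, dt = 0.05, duration = 6000,
                             coupling_sign = 1) {
  stopifnot(tau0 > 0, K >= 0, dt > 0, duration > 0,
            coupling_sign %in% c(-1, 1))
  structure(list(x0 = as.numeric(x0), tau0 = tau0, K = K, I1 = I1,
                 noise_sd = noise_sd, dt = dt, duration = duration,
                 coupling_sign = coupling_sign),
            class = "epileptor_params")
}

# Per-region noise streams: region i's increments depend only on
# (seed, i), so a K = 0 network run reproduces single-region runs exactly.
.epileptor_noise <- function(seed, n_regions, n_steps) {
  nx <- matrix(0, n_regions, n_steps)
  nz <- matrix(0, n_regions, n_steps)
  for (i in seq_len(n_regions)) {
    set.seed(seed + i)
    nx[i, ] <- stats::rnorm(n_steps)
    nz[i, ] <- stats::rnorm(n_steps)
  }
  list(x = nx, z = nz)
}

#' Simulate seizure dynamics on a brain network
#'
#' Stochastic Heun integration of the 2D Epileptor network (compiled
#' core). Runs are bitwise reproducible for a given seed; with `K = 0`
#' each region reproduces the corresponding single-region simulation run
#' with the matching seed stream.
#'
#' @param params An [epileptor_params()]; `x0` is recycled to the number
#'   of regions.
#' @param conn A `connectome` (or square matrix, normalized on the fly).
#' @param init Optional list with `x`, `z` per-region initial states
#'   (defaults: x = -2, z = 3.5).
#' @param seed Integer seed for the state noise (required when
#'   `noise_sd > 0`).
#' @return Object of class `source_trajectory`: `times`, matrices `x`,
#'   `z` (regions x times), `params`.
#' @export
simulate_network <- function(params, conn, init = NULL, seed = NULL) {
  stopifnot(inherits(params, "epileptor_params"))
  if (!inherits(conn, "connectome")) conn <- normalize_connectome(conn)
  L <- nrow(conn$weights)
  x0 <- rep_len(params$x0, L)
  if (is.null(init)) init <- list(x = rep(-2, L), z = rep(3.5, L))
  stopifnot(length(init$x) == L, length(init$z) == L)
  n_steps <- ceiling(params$duration / params$dt)

  if (params$noise_sd > 0) {
    if (is.null(seed)) stop("seed required for stochastic simulation")
    nz <- .epileptor_noise(seed, L, n_steps)
  } else {
    nz <- list(x = matrix(0, 1, 1), z = matrix(0, 1, 1))
  }

  out <- .epileptor_heun(x0, params$tau0, params$K, params$I1,
                         conn$weights, init$x, init$z, params$dt, n_steps,
                         params$noise_sd, nz$x, nz$z, params$coupling_sign)
  if (isTRUE(out$diverged))
    stop(sprintf("simulation diverged (|x| > 1e3) at step %d", out$div_step))
  structure(list(times = seq(0, by = params$dt, length.out = n_steps + 1),
                 x = out$x, z = out$z, params = params,
                 region_ids = conn$region_ids),
            class = "source_trajectory")
}

#' Fixed points of the single-node 2D Epileptor
#'
#' Solves the nullcline intersection
#' `I1 - x^3 - 2 x^2 - 4 (x - x0) = 0`, `z = 4 (x - x0)`, and classifies
#' linear stability from the Jacobian eigenvalues.
#'
#' @param x0 Excitability.
#' @param I1 External input (default 3.1).
#' @param tau0 Slow time scale used in the Jacobian (default 20).
#' @return data.frame with columns `x`, `z`, `stable`, `eig_re_max`.
#' @export
find_fixed_points <- function(x0, I1 = 3.1, tau0 = 20) {
  # -x^3 - 2x^2 - 4x + (I1 + 4 x0) = 0
  roots <- polyroot(c(I1 + 4 * x0, -4, -2, -1))
  xs <- Re(roots[abs(Im(roots)) < 1e-8])
  xs <- sort(unique(round(xs, 12)))
  if (length(xs) == 0)
    return(data.frame(x = numeric(0), z = numeric(0),
                      stable = logical(0), eig_re_max = numeric(0)))
  res <- lapply(xs, function(x) {
    z <- 4 * (x - x0)
    J <- matrix(c(-3 * x^2 - 4 * x, -1,
                  4 / tau0, -1 / tau0), 2, 2, byrow = TRUE)
    ev <- eigen(J, only.values = TRUE)$values
    data.frame(x = x, z = z, stable = all(Re(ev) < 0),
               eig_re_max = max(Re(ev)))
  })
  do.call(rbind, res)
}

#' Read / write a connectome as a delimited text matrix
#'
#' @param path File path (TSV; optional header row/col of region ids).
#' @return `read_connectome`: a `connectome`.
#' @export
read_connectome <- function(path) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", row.names = 1,
                                   check.names = FALSE))
  normalize_connectome(m)
}

#' @rdname read_connectome
#' @param conn A `connectome`.
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(conn$weights, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
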