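## Synthetic generators for every pipeline input: connectomes, surfaces
## and sensors, seizure recordings, sodium decay curves and labelled
## cohorts. All generators are pure functions of (spec, seed).

#' Generate a random structural connectome
#'
#' Sparse non-negative weights (log-normal magnitudes), zero diagonal,
#' max-normalized.
#'
#' @param n_regions Number of regions (>= 2).
#' @param density Fraction of off-diagonal connections present, in
#'   (0, 1\].
#' @param seed Integer seed.
#' @return A `connectome`.
#' @export
gen_connectome <- function(n_regions, density = 0.5, seed = 0) {
  stopifnot(n_regions >= 2)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  set.seed(seed)
  w <- matrix(0, n_regions, n_regions)
  off <- which(row(w) != col(w))
  on <- sample(off, ceiling(length(off) * density))
  w[on] <- exp(stats::rnorm(length(on), 0, 0.5))
  normalize_connectome(w)
}

#' Generate a region-labelled spherical surface with SEEG-like sensors
#'
#' Region centers are spread over a sphere (Fibonacci lattice); each
#' region is a small triangulated cap (central vertex plus a ring,
#' fan-triangulated). Sensors are placed just outside chosen region
#' centroids so sensor-region coverage is known ground truth.
#'
#' @param n_regions Number of regions.
#' @param vertices_per_region Vertices per cap (>= 3 ring vertices + 1).
#' @param n_sensors Number of sensors (placed over the first `n_sensors`
#'   regions, recycled if more).
#' @param seed Integer seed.
#' @param radius Sphere radius in mm (default 60).
#' @param sensor_offset Radial sensor lift in mm (default 3).
#' @return List: `surface` (a `tri_surface`), `sensors`
#'   (a `sensor_array`), `sensor_region` (the region each sensor
#'   covers).
#' @export
gen_surface_sensors <- function(n_regions, vertices_per_region = 12,
                                n_sensors = n_regions, seed = 0,
                                radius = 60, sensor_offset = 3) {
  stopifnot(vertices_per_region >= 4)
  set.seed(seed)
  # Fibonacci lattice of region centers
  i <- seq_len(n_regions) - 0.5
  phi <- acos(1 - 2 * i / n_regions)
  theta <- pi * (1 + sqrt(5)) * i
  ctr <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                        cos(phi))
  cap_r <- radius * sqrt(2 / n_regions) * 0.6   # cap angular radius
  verts <- NULL; tris <- NULL; labels <- integer(0)
  for (r in seq_len(n_regions)) {
    n_ring <- vertices_per_region - 1L
    c0 <- ctr[r, ]
    # local tangent frame
    u <- c(-c0[2], c0[1], 0)
    if (sum(u^2) < 1e-9) u <- c(1, 0, 0)
    u <- u / sqrt(sum(u^2))
    v <- c(c0[2] * u[3] - c0[3] * u[2], c0[3] * u[1] - c0[1] * u[3],
           c0[1] * u[2] - c0[2] * u[1]) / radius
    ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    ring <- t(c0 + t(cap_r * (outer(cos(ang), u) + outer(sin(ang), v))))
    ring <- ring * radius / sqrt(rowSums(ring^2))   # reproject to sphere
    base <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, rbind(c0, ring))
    fan <- cbind(base + 1L, base + 1L + seq_len(n_ring),
                 base + 1L + c(seq_len(n_ring)[-1], 1L))
    tris <- rbind(tris, fan)
    labels <- c(labels, rep(r, n_ring + 1L))
  }
  surface <- tri_surface(verts, tris, labels)
  sr <- rep_len(seq_len(n_regions), n_sensors)
  pos <- ctr[sr, , drop = FALSE] * (1 + sensor_offset / radius)
  sensors <- sensor_array(pos, paste0("S", seq_len(n_sensors)))
  list(surface = surface, sensors = sensors, sensor_region = sr)
}

#' Define a synthetic seizure scenario
#'
#' @param conn A `connectome`.
#' @param x0 Per-region true excitability (at least one region at
#'   -1.5).
#' @param surface,sensors,sensor_region From [gen_surface_sensors()].
#' @param noise_sd State-noise sd for the simulation (default 0.01).
#' @param obs_noise_sd Measurement noise added to the projected SEEG
#'   (default 0).
#' @param duration,dt Simulation horizon and step (defaults 200, 0.05).
#' @param tau0,K Model constants (defaults 20, 1).
#' @param init Initial states (defaults x = -2, z = 4.5: starting the
#'   slow variable above its prior mean leaves a pre-ictal baseline
#'   before the first onset).
#' @param seed Integer seed.
#' @return List of class `seizure_scenario`.
#' @export
seizure_scenario <- function(conn, x0, surface, sensors,
                             sensor_region = NULL, noise_sd = 0.01,
                             obs_noise_sd = 0, duration = 200, dt = 0.05,
                             tau0 = 20, K = 1,
                             init = list(x = -2, z = 4.5), seed = 0) {
  stopifnot(any(x0 == -1.5))
  L <- length(x0)
  init <- list(x = rep_len(init$x, L), z = rep_len(init$z, L))
  structure(list(conn = conn, x0 = x0, surface = surface,
                 sensors = sensors, sensor_region = sensor_region,
                 noise_sd = noise_sd, obs_noise_sd = obs_noise_sd,
                 duration = duration, dt = dt, tau0 = tau0, K = K,
                 init = init, seed = seed),
            class = "seizure_scenario")
}

#' Generate a synthetic SEEG seizure recording
#'
#' Simulates the Epileptor network for the scenario, projects the
#' sources through the inverse-square gain matrix, adds measurement
#' noise and packages the result as an [seeg_recording()] together with
#' the ground-truth source onsets.
#'
#' @param scn A [seizure_scenario()].
#' @param fs Nominal sampling rate attached to the recording (Hz,
#'   default 1000 samples per model time unit / dt).
#' @return List: `recording`, `gain`, `s2s`, `trajectory`,
#'   `true_onsets` (sample indices), `seized` (logical per region).
#' @export
gen_seizure_recording <- function(scn, fs = NULL) {
  stopifnot(inherits(scn, "seizure_scenario"))
  params <- epileptor_params(x0 = scn$x0, tau0 = scn$tau0, K = scn$K,
                             noise_sd = scn$noise_sd, dt = scn$dt,
                             duration = scn$duration)
  traj <- simulate_network(params, scn$conn, init = scn$init,
                           seed = scn$seed)
  gain <- compute_gain(scn$surface, scn$sensors)
  s2s <- compute_sensor_to_source(scn$surface, scn$sensors)
  proj <- project_sources_to_sensors(traj, gain)
  if (scn$obs_noise_sd > 0) {
    set.seed(scn$seed + 7919L)
    proj <- proj + matrix(stats::rnorm(length(proj), 0, scn$obs_noise_sd),
                          nrow(proj))
  }
  if (is.null(fs)) fs <- 1 / scn$dt
  rec <- seeg_recording(proj, fs = fs)
  on <- detect_onsets(traj, threshold = 0,
                      no_seizure = ncol(traj$x))
  seized <- on$t < ncol(traj$x)
  if (!any(seized)) warning("no seizure occurred within the horizon")
  list(recording = rec, gain = gain, s2s = s2s, trajectory = traj,
       true_onsets = on$t, seized = seized)
}

#' Specify a synthetic sodium-MRI cohort
#'
#' Defaults emulate a highly imbalanced SEEG-sampled cohort: per patient
#' 3 EZN, 5 PZ and 20 NIZ regions, two pattern groups with distinct
#' feature directions, and an EZN > PZ > NIZ gradient on the shifted
#' features.
#'
#' @param n_patients Number of patients (default 16).
#' @param ezn_per_patient,pz_per_patient,niz_per_patient Regions per
#'   label per patient (defaults 3, 5, 20).
#' @param ezn_shift,pz_shift Mean shifts (in feature units) added to
#'   (na_sf, na_lf) for EZN and PZ rows; PZ must not exceed EZN.
#' @param noise_sd Feature noise sd (mM) for (na_sf, na_lf).
#' @param noise_cor Correlation between the two feature noises.
#' @param group_sep Separation (mM) between the two pattern-group
#'   baselines.
#' @param seed Integer seed (mandatory).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16, ezn_per_patient = 3,
                        pz_per_patient = 5, niz_per_patient = 20,
                        ezn_shift = c(na_sf = 6, na_lf = 4),
                        pz_shift = c(na_sf = 3, na_lf = 2),
                        noise_sd = 1.5, noise_cor = 0.3,
                        group_sep = 8, seed = 0) {
  stopifnot(ezn_per_patient >= 1)
  if (any(pz_shift > ezn_shift))
    stop("PZ shift must not exceed EZN shift (gradient demanded)")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a labelled synthetic sodium-feature cohort
#'
#' Per (patient, region): baseline (na_sf, na_lf) drawn from the
#' patient's pattern-group center with correlated Gaussian noise; EZN
#' and PZ rows receive the configured mean shifts (EZN > PZ > NIZ by
#' construction). `tsc` and `f` are derived, so the sodium identities
#' hold exactly. Pattern group 1 expresses the shift mainly through the
#' short fraction, group 2 through the long fraction. Optionally
#' synthesizes matching 24-echo decay curves whose biexponential fit
#' reproduces the drawn features.
#'
#' @param spec A [cohort_spec()].
#' @param with_curves Also emit per-row decay curves (default FALSE).
#' @param calib Calibration used to synthesize curves (default slope 2,
#'   intercept 0).
#' @return A [feature_table()] with extra columns `pattern_group`;
#'   attribute `curves` (named list) when `with_curves`.
#' @export
gen_cohort_sodium <- function(spec, with_curves = FALSE,
                              calib = list(slope = 2, intercept = 0)) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_reg <- spec$ezn_per_patient + spec$pz_per_patient + spec$niz_per_patient
  labels <- c(rep("EZN", spec$ezn_per_patient),
              rep("PZ", spec$pz_per_patient),
              rep("NIZ", spec$niz_per_patient))
  # correlated noise factor
  S <- matrix(c(1, spec$noise_cor, spec$noise_cor, 1), 2) * spec$noise_sd^2
  Ch <- chol(S)
  base_niz <- c(na_sf = 15, na_lf = 25)   # healthy-tissue baseline (mM)
  rows <- list()
  for (p in seq_len(spec$n_patients)) {
    grp <- if (p <= ceiling(spec$n_patients / 2)) 1L else 2L
    # the two cohorts differ in their baseline pattern and in which
    # component carries the epileptogenic shift
    gshift <- if (grp == 1) c(spec$group_sep, 0) else c(0, spec$group_sep)
    mix <- if (grp == 1) c(1.3, 0.7) else c(0.7, 1.3)
    lesional_patient <- as.integer(p %% 3 == 0)
    for (r in seq_len(n_reg)) {
      lab <- labels[r]
      shift <- switch(lab, EZN = spec$ezn_shift * mix,
                      PZ = spec$pz_shift * mix, NIZ = c(0, 0))
      mu <- base_niz + gshift + shift
      xy <- mu + drop(stats::rnorm(2) %*% Ch)
      xy <- pmax(xy, 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%02d", p), region_id = sprintf("R%03d", r),
        na_sf = xy[1], na_lf = xy[2], tsc = xy[1] + xy[2],
        f = xy[1] / (xy[1] + xy[2]),
        lesional_patient = lesional_patient,
        lesional_zone = as.integer(lesional_patient == 1 && lab == "EZN"),
        label = lab, pattern_group = grp)
    }
  }
  tab <- feature_table(do.call(rbind, rows))
  if (with_curves) {
    curves <- list()
    for (i in seq_len(nrow(tab))) {
      m0_sf <- calib$slope * tab$na_sf[i] + calib$intercept
      m0_lf <- calib$slope * tab$na_lf[i] + calib$intercept
      A <- m0_sf + m0_lf
      f_fit <- m0_sf / A
      t2s <- stats::runif(1, 3, 6); t2l <- stats::runif(1, 25, 40)
      te <- sodium_te_grid()
      curves[[paste(tab$patient_id[i], tab$region_id[i], sep = "_")]] <-
        decay_curve(tab$region_id[i], te,
                    biexp_model(te, A, f_fit, t2s, t2l, 0))
    }
    attr(tab, "curves") <- curves
  }
  tab
}
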