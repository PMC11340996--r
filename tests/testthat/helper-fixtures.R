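# Shared fixture builders. Everything is generated in code; sizes are
# kept small so the whole suite runs quickly on one CPU.

# random triangulated surface (not closed; fine for area/gain oracles)
random_surface <- function(n_vertices = 50, n_regions = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_vertices * 3, sd = 20), ncol = 3)
  # triangles over consecutive index triples, plus a few random ones
  tr <- cbind(1:(n_vertices - 2), 2:(n_vertices - 1), 3:n_vertices)
  tri_surface(v, tr, rep_len(seq_len(n_regions), n_vertices))
}

random_sensors <- function(n = 3, seed = 2, offset = 100) {
  set.seed(seed)
  sensor_array(matrix(stats::rnorm(n * 3, mean = offset, sd = 5), ncol = 3))
}

# minimal seizure setup reused by inversion/pipeline tests
tiny_seizure_setup <- function(L = 4, n_ezn = 1, seed = 5,
                               duration = 60, obs_noise_sd = 0.2) {
  conn <- gen_connectome(L, density = 0.6, seed = seed)
  gs <- gen_surface_sensors(L, vertices_per_region = 8, n_sensors = L,
                            seed = seed + 1)
  x0 <- rep(-3, L)
  x0[seq_len(n_ezn)] <- -1.5
  scn <- seizure_scenario(conn, x0, gs$surface, gs$sensors,
                          noise_sd = 0.02, obs_noise_sd = obs_noise_sd,
                          duration = duration, dt = 0.05, seed = seed + 2)
  gen <- gen_seizure_recording(scn)
  list(conn = conn, gs = gs, x0 = x0, scn = scn, gen = gen)
}

# separable two-class feature table for classifier tests: EZN rows are
# shifted by `sep` standard deviations on na_sf/na_lf
separable_cohort <- function(n_patients = 8, sep = 6, seed = 3) {
  spec <- cohort_spec(n_patients = n_patients,
                      ezn_per_patient = 3, pz_per_patient = 2,
                      niz_per_patient = 7,
                      ezn_shift = c(na_sf = sep, na_lf = sep),
                      pz_shift = c(na_sf = 0.5, na_lf = 0.5),
                      noise_sd = 1, group_sep = 0, seed = seed)
  gen_cohort_sodium(spec)
}
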