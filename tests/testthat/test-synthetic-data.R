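test_that("task designs are balanced, deterministic, and zero-indexed", {
  d <- make_task_design(20, seed = 3)
  expect_identical(d, make_task_design(20, seed = 3))
  expect_identical(d$trial_id, 0:19)
  counts <- table(d$cue_angle_deg)
  expect_lte(max(counts) - min(counts), 1)
  expect_true(all(d$seed >= 1 & d$seed < 2^31))
  # per-trial seeds are distinct
  expect_equal(anyDuplicated(d$seed), 0)
})

test_that("task design generation restores the global RNG state", {
  set.seed(77); before <- runif(3)
  set.seed(77); invisible(make_task_design(10, seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("generator configuration validates its inputs", {
  expect_error(generator_config(n_trials = 0), "positive")
  expect_error(generator_config(n_channels = 2), "n_channels")
  expect_error(generator_config(cue_angles_deg = numeric(0)), "non-empty")
  expect_error(generator_config(coupling = -1), "non-negative")
  expect_error(generator_config(ephaptic = TRUE), "field_params")
  cfg <- generator_config(n_trials = 4, n_channels = 8, delay_ms = 50)
  expect_s3_class(cfg, "generator_config")
  expect_length(cfg$positions_mm, 8)
  expect_equal(range(cfg$positions_mm), c(0, cfg$span_mm))
})

test_that("simulation is a pure function of config and seed", {
  cfg <- generator_config(n_trials = 3, n_channels = 8, delay_ms = 60,
                          master_seed = 9)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$trials, r2$trials)
  expect_equal(dim(r1$data), c(3, 8, 60))
  r3 <- simulate_recording(generator_config(n_trials = 3, n_channels = 8,
                                            delay_ms = 60, master_seed = 10))
  expect_false(identical(r1$data, r3$data))
})

test_that("ephaptic coupling forced to zero reproduces the non-ephaptic run bit for bit", {
  fp <- fixture_field_params()
  base <- list(n_trials = 2, n_channels = 8, delay_ms = 50, master_seed = 21)
  r_ne <- simulate_recording(do.call(generator_config, base))
  r_e0 <- simulate_recording(do.call(generator_config,
                                     c(base, list(ephaptic = TRUE,
                                                  field_params = fp,
                                                  coupling = 0))))
  expect_identical(r_ne$data, r_e0$data)
})

test_that("unstable parameterizations are refused with the eigenvalue named", {
  pos <- fixture_positions(8)
  bad <- ensemble_model(20, 1, 0, gaussian_kernel(pos, 2, 0.5), noise_sd = 0.1)
  cfg <- generator_config(n_trials = 2, n_channels = 8, delay_ms = 50,
                          ensemble = bad)
  expect_error(simulate_recording(cfg), "eigenvalue")
})

test_that("baseline fluctuations are stationary over the second half of trials", {
  rec <- memo("rec_stationarity", {
    cfg <- generator_config(n_trials = 20, n_channels = 16, delay_ms = 400,
                            master_seed = 5)
    simulate_recording(cfg)
  })
  n_time <- dim(rec$data)[3]
  half <- (n_time %/% 2):n_time
  ps <- vapply(seq_len(20), function(i) {
    v <- apply(rec$data[i, , half], 2, var)
    summary(stats::lm(v ~ seq_along(v)))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(mean(ps), 0.01)
})

test_that("recording container enforces its shape invariants", {
  data <- array(0, c(2, 4, 10))
  trials <- make_task_design(2, cue_angles_deg = c(0, 180), seed = 1)
  rec <- lfp_recording(data, 1, fixture_positions(4), trials)
  expect_s3_class(rec, "lfp_recording")
  expect_error(lfp_recording(data, 1, fixture_positions(5), trials))
  expect_error(lfp_recording(data, 1, fixture_positions(4), trials[1, ]))
})

test_that("coupled spatial fixtures are deterministic with the stated coupling", {
  p1 <- make_coupled_spatial_pair(24, "a_to_b", coupling = 0.8,
                                  n_snapshots = 5, seed = 4)
  p2 <- make_coupled_spatial_pair(24, "a_to_b", coupling = 0.8,
                                  n_snapshots = 5, seed = 4)
  expect_identical(p1, p2)
  expect_equal(dim(p1$a), c(5, 24))
  # under "none" the two series are independent: cross-correlation is small
  pn <- make_coupled_spatial_pair(500, "none", n_snapshots = 1, seed = 6)
  expect_lt(abs(cor(pn$a[1, ], pn$b[1, ])), 0.15)
  expect_error(make_coupled_spatial_pair(2, "none"), "n_points")
})

test_that("null RDM pairs are valid and deterministic", {
  pair <- make_null_rdm_pair(6, seed = 2)
  expect_identical(pair, make_null_rdm_pair(6, seed = 2))
  for (m in list(pair$a$matrix, pair$b$matrix)) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 6))
    expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 2))
  }
  expect_error(make_null_rdm_pair(2), "n_conditions")
})

test_that("recordings round-trip through the on-disk layout", {
  rec <- fixture_recording()
  dir <- file.path(tempdir(), "rec_roundtrip")
  write_recording(rec, dir)
  expect_true(all(file.exists(file.path(dir, c("meta.json", "trials.csv",
                                               "data.csv")))))
  back <- read_recording(dir)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$time_step_ms, rec$time_step_ms)
  expect_equal(back$channel_positions_mm, rec$channel_positions_mm)
  expect_equal(as.data.frame(back$trials)[c("trial_id", "cue_angle_deg")],
               as.data.frame(rec$trials)[c("trial_id", "cue_angle_deg")])
  unlink(dir, recursive = TRUE)
})
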