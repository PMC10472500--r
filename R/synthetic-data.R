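# Synthetic data generation: cue-conditioned multi-trial LFP-like recordings
# from the non-ephaptic and ephaptic neural field models, plus small
# calibration fixtures for the spatial Granger-causality and RSA modules.
# These stand in for the in vivo delayed-saccade recordings the analysis was
# designed around (chronic 32-electrode arrays, 750 ms delay, 1 kHz sampling,
# six cue angles).

#' Randomized balanced task design
#'
#' Assigns cue angles to trials with near-balanced counts (maximum imbalance
#' one trial) in a randomized order, and draws an independent RNG seed per
#' trial. Deterministic given `seed`.
#'
#' @param n_trials number of trials (>= 1).
#' @param cue_angles_deg set of cue angles in degrees (non-empty).
#' @param seed integer seed.
#' @return a tibble with columns `trial_id` (0-based, contiguous),
#'   `cue_angle_deg`, and `seed` (per-trial RNG seed).
#' @export
#' @examples
#' make_task_design(6, seed = 1)
make_task_design <- function(n_trials,
                             cue_angles_deg = c(0, 60, 120, 180, 240, 300),
                             seed = 1) {
  if (length(cue_angles_deg) == 0) stop("cue angle set must be non-empty", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  angles <- sample(cue_angles_deg)             # randomize which angles get the extra trial
  assignment <- rep(angles, length.out = n_trials)
  assignment <- sample(assignment)             # randomize order over trials
  tibble::tibble(
    trial_id = seq_len(n_trials) - 1L,
    cue_angle_deg = assignment,
    seed = sample.int(2147483646L, n_trials)
  )
}

#' Generator configuration for synthetic recordings
#'
#' Bundles every knob of the synthetic LFP generator. Defaults mirror the
#' recording setup the analysis targets: 32 channels on a 2 mm linear patch,
#' a 750 ms delay period sampled at 1 kHz, and six cue angles 60 degrees
#' apart. The cue enters as a smooth Gaussian spatial input bump whose center
#' moves linearly with the angle along the patch.
#'
#' @param n_trials number of trials.
#' @param n_channels number of electrodes (default 32).
#' @param delay_ms delay-period duration (default 750 ms).
#' @param time_step_ms sampling interval / integration step (default 1 ms).
#' @param cue_angles_deg cue angle set (degrees).
#' @param ensemble an [ensemble_model()]; a stable default Gaussian-kernel
#'   model on the configured grid is built when `NULL`.
#' @param span_mm length of the linear patch (default 2 mm).
#' @param input_amplitude amplitude of the cue input bump (potential/ms).
#' @param input_width_mm width of the cue bump (mm).
#' @param input_dur_ms duration of the cue input from trial onset; `NULL`
#'   keeps it on for the whole delay.
#' @param ephaptic logical; simulate the ephaptic model (field feedback onto
#'   the recurrent drive)?
#' @param field_params a [bidomain_params()] object; required when
#'   `ephaptic = TRUE`.
#' @param coupling dimensionless scale of the ephaptic feedback (the boundary
#'   field entering the transfer function is `coupling * V0e`); 0 reproduces
#'   the non-ephaptic trajectories bit-identically.
#' @param master_seed integer master seed; the per-trial seeds derive from it.
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_trials = 60,
                             n_channels = 32,
                             delay_ms = 750,
                             time_step_ms = 1,
                             cue_angles_deg = c(0, 60, 120, 180, 240, 300),
                             ensemble = NULL,
                             span_mm = 2,
                             input_amplitude = 0.06,
                             input_width_mm = 0.3,
                             input_dur_ms = NULL,
                             ephaptic = FALSE,
                             field_params = NULL,
                             coupling = 1,
                             master_seed = 1) {
  if (n_trials < 1 || n_channels < 3 || delay_ms <= 0 || time_step_ms <= 0) {
    stop("counts and durations must be positive (and n_channels >= 3)", call. = FALSE)
  }
  if (length(cue_angles_deg) == 0) stop("cue angle set must be non-empty", call. = FALSE)
  if (coupling < 0) stop("coupling must be non-negative", call. = FALSE)
  positions <- seq(0, span_mm, length.out = n_channels)
  if (is.null(ensemble)) {
    ensemble <- default_ensemble(positions)
  }
  if (nrow(ensemble$kernel$matrix) != n_channels) {
    stop("ensemble kernel size must match n_channels", call. = FALSE)
  }
  if (ephaptic && is.null(field_params)) {
    stop("ephaptic = TRUE requires field_params (bidomain_params)", call. = FALSE)
  }
  structure(
    list(n_trials = n_trials, n_channels = n_channels, delay_ms = delay_ms,
         time_step_ms = time_step_ms, cue_angles_deg = cue_angles_deg,
         ensemble = ensemble, span_mm = span_mm,
         positions_mm = positions,
         input_amplitude = input_amplitude, input_width_mm = input_width_mm,
         input_dur_ms = input_dur_ms,
         ephaptic = ephaptic, field_params = field_params, coupling = coupling,
         master_seed = as.integer(master_seed)),
    class = "generator_config"
  )
}

# stable default ensemble: Gaussian kernel scaled so the linearized leading
# eigenvalue stays safely negative on the given grid
default_ensemble <- function(positions_mm, tau_ms = 20, gain = 1, threshold = 0,
                             width_mm = 0.5, noise_sd = 0.5) {
  k0 <- gaussian_kernel(positions_mm, amplitude = 1, width_mm = width_mm)
  slope <- transfer_function_deriv(0, gain, threshold)
  # leading eigenvalue of slope * amplitude * K0 must stay below 1/tau
  lead <- max(Re(eigen(k0$matrix, only.values = TRUE)$values))
  amplitude <- 0.75 / (tau_ms * slope * lead)
  ensemble_model(tau_ms, gain, threshold,
                 gaussian_kernel(positions_mm, amplitude, width_mm),
                 noise_sd = noise_sd)
}

# Gaussian cue-input bump: center moves linearly with angle along the patch
cue_input_profile <- function(angle_deg, config) {
  centre <- config$span_mm * (angle_deg %% 360) / 360
  config$input_amplitude *
    exp(-(config$positions_mm - centre)^2 / (2 * config$input_width_mm^2))
}

#' Simulate a cue-conditioned multi-trial recording
#'
#' Integrates the configured neural field model (Euler-Maruyama, step equal to
#' the sampling interval) independently for each trial of a balanced
#' randomized task design. The cue enters as an angle-specific spatial input
#' bump; the endogenous input is spatially white Gaussian noise. In the
#' ephaptic variant the boundary extracellular potential is recomputed from
#' the current membrane-potential snapshot at every step (bidomain operator at
#' the fiber surface) and added, scaled by `coupling`, inside the recurrent
#' drive. The raw simulated potential is stored (no demeaning).
#'
#' Unstable ensemble parameters (see [is_stable()]) are refused with the
#' leading eigenvalue in the message.
#'
#' @param config a [generator_config()].
#' @param ff_input optional external feedforward drive, an array
#'   `[n_trials, n_channels, n_time]` added to the input at each step (used by
#'   the two-area pipeline to drive the downstream area).
#' @return an [lfp_recording()] object.
#' @export
simulate_recording <- function(config, ff_input = NULL) {
  stopifnot(inherits(config, "generator_config"))
  st <- is_stable(config$ensemble)
  if (!st$stable) {
    stop(sprintf("unstable ensemble parameters: leading eigenvalue %.4g 1/ms >= 0",
                 st$leading_eigenvalue), call. = FALSE)
  }
  dt <- config$time_step_ms
  n_time <- round(config$delay_ms / dt)
  n_ch <- config$n_channels
  design <- make_task_design(config$n_trials, config$cue_angles_deg,
                             seed = config$master_seed)
  if (!is.null(ff_input)) {
    stopifnot(all(dim(ff_input) == c(config$n_trials, n_ch, n_time)))
  }
  B <- NULL
  if (config$ephaptic && config$coupling > 0) {
    B <- config$coupling *
      bidomain_operator(config$positions_mm, config$field_params,
                        y = config$field_params$a_mm)
  }
  model <- config$ensemble
  K <- model$kernel$matrix
  f0 <- transfer_function(0, model$gain, model$threshold)
  input_steps <- if (is.null(config$input_dur_ms)) n_time else
    min(n_time, round(config$input_dur_ms / dt))
  data <- array(0, dim = c(config$n_trials, n_ch, n_time))
  for (i in seq_len(config$n_trials)) {
    set.seed(design$seed[i])
    U_det <- cue_input_profile(design$cue_angle_deg[i], config)
    noise <- matrix(rnorm(n_ch * n_time, sd = model$noise_sd * sqrt(dt)), n_ch, n_time)
    V <- numeric(n_ch)
    for (t in seq_len(n_time)) {
      h <- if (is.null(B)) V else V + as.vector(B %*% V)
      drive <- -V / model$tau_ms +
        as.vector(K %*% (transfer_function(h, model$gain, model$threshold) - f0))
      if (t <= input_steps) drive <- drive + U_det
      if (!is.null(ff_input)) drive <- drive + ff_input[i, , t]
      V <- V + dt * drive + noise[, t]
      data[i, , t] <- V
    }
  }
  lfp_recording(data, time_step_ms = dt,
                channel_positions_mm = config$positions_mm,
                trials = design,
                provenance = list(generator = "neural_field",
                                  ephaptic = config$ephaptic,
                                  coupling = config$coupling,
                                  master_seed = config$master_seed))
}

#' Multi-trial LFP-like recording container
#'
#' @param data numeric array `[n_trials, n_channels, n_time]` (no NaN/Inf).
#' @param time_step_ms sampling interval (ms).
#' @param channel_positions_mm strictly increasing channel positions (mm).
#' @param trials trial table (tibble with `trial_id`, `cue_angle_deg`, ...).
#' @param provenance free-form list recording how the data were produced.
#' @return an `lfp_recording` object.
#' @export
lfp_recording <- function(data, time_step_ms, channel_positions_mm, trials,
                          provenance = list()) {
  dims <- dim(data)
  if (length(dims) != 3) stop("data must be a trials x channels x time array", call. = FALSE)
  check_finite(data, "recording data")
  if (length(channel_positions_mm) != dims[2]) {
    stop("channel_positions_mm must have one entry per channel", call. = FALSE)
  }
  if (any(diff(channel_positions_mm) <= 0)) {
    stop("channel positions must be strictly increasing", call. = FALSE)
  }
  if (nrow(trials) != dims[1]) stop("trial table must have one row per trial", call. = FALSE)
  structure(
    list(data = data, time_step_ms = time_step_ms,
         channel_positions_mm = channel_positions_mm,
         trials = tibble::as_tibble(trials), provenance = provenance),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lfp_recording> %d trials x %d channels x %d samples (dt = %g ms)\n",
              d[1], d[2], d[3], x$time_step_ms))
  cat(sprintf("  cue angles: %s\n", paste(sort(unique(x$trials$cue_angle_deg)), collapse = ", ")))
  invisible(x)
}

#' Unidirectionally coupled spatial autoregressive fixture
#'
#' Generates paired spatial profiles for calibrating the spatial
#' Granger-causality machinery: each snapshot is a pair of lag-1 spatial
#' autoregressions over the channel index, with optional unidirectional
#' cross-coupling (the target at position `x` receives `coupling` times the
#' source at `x - 1`). Innovations are independent across snapshots and
#' positions.
#'
#' @param n_points spatial points per snapshot (>= 3).
#' @param direction one of `"none"`, `"a_to_b"`, `"b_to_a"`.
#' @param coupling cross-coupling coefficient (>= 0).
#' @param innovation_sd innovation standard deviation (> 0).
#' @param n_snapshots number of snapshots.
#' @param seed integer seed.
#' @param ar within-series spatial lag-1 coefficient (default 0.4).
#' @return list with matrices `a` and `b` (`n_snapshots x n_points`).
#' @export
make_coupled_spatial_pair <- function(n_points, direction = c("none", "a_to_b", "b_to_a"),
                                      coupling = 0, innovation_sd = 1,
                                      n_snapshots = 100, seed = 1, ar = 0.4) {
  direction <- match.arg(direction)
  if (n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  if (coupling < 0) stop("coupling must be non-negative", call. = FALSE)
  if (innovation_sd <= 0) stop("innovation_sd must be positive", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  a <- matrix(0, n_snapshots, n_points)
  b <- matrix(0, n_snapshots, n_points)
  ea <- matrix(rnorm(n_snapshots * n_points, sd = innovation_sd), n_snapshots, n_points)
  eb <- matrix(rnorm(n_snapshots * n_points, sd = innovation_sd), n_snapshots, n_points)
  a[, 1] <- ea[, 1]; b[, 1] <- eb[, 1]
  for (x in 2:n_points) {
    a[, x] <- ar * a[, x - 1] + ea[, x]
    b[, x] <- ar * b[, x - 1] + eb[, x]
    if (direction == "a_to_b") b[, x] <- b[, x] + coupling * a[, x - 1]
    if (direction == "b_to_a") a[, x] <- a[, x] + coupling * b[, x - 1]
  }
  list(a = a, b = b)
}

#' Independent random dissimilarity-matrix pair (RSA null fixture)
#'
#' Two symmetric, zero-diagonal matrices whose off-diagonal entries are
#' independent uniform draws on `[0, 2]` — the null case of unrelated
#' representational structure.
#'
#' @param n_conditions number of conditions (>= 3).
#' @param seed integer seed.
#' @return list with `rdm` objects `a` and `b`.
#' @export
make_null_rdm_pair <- function(n_conditions, seed = 1) {
  if (n_conditions < 3) stop("n_conditions must be >= 3", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  rand_rdm <- function() {
    m <- matrix(0, n_conditions, n_conditions)
    m[upper.tri(m)] <- runif(n_conditions * (n_conditions - 1) / 2, 0, 2)
    m <- m + t(m)
    new_rdm(m, labels = as.character(seq_len(n_conditions)), source = "synthetic")
  }
  list(a = rand_rdm(), b = rand_rdm())
}
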