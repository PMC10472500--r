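# Deep neural field model of ensemble activity on a 1-D cortical patch:
# sigmoid transfer function, Gaussian connectivity kernel, Euler stepping of
# the field equation (with optional ephaptic boundary-potential term), linear
# stability about baseline, and the Gaussian-linear-model (GLM) reformulation
# with spatial-derivative principal axes.

#' Sigmoid transfer function mapping depolarization to firing rate
#'
#' `f(h) = 1 / (1 + exp(gain * (threshold - h)))`: the fraction of maximum
#' firing rate produced by depolarization `h`. Strictly increasing in `h` for
#' positive `gain`; `f(threshold) = 0.5`. Saturates gracefully for extreme
#' arguments.
#'
#' @param h depolarization (numeric vector or matrix), arbitrary potential units.
#' @param gain synaptic gain (slope parameter), 1/potential units.
#' @param threshold half-activation potential.
#' @return rates in (0, 1), same shape as `h`.
#' @export
#' @examples
#' transfer_function(0, gain = 1, threshold = 0)    # 0.5
#' transfer_function(log(3), gain = 1, threshold = 0) # 0.75
transfer_function <- function(h, gain = 1, threshold = 0) {
  check_finite(gain, "gain"); check_finite(threshold, "threshold")
  out <- stats::plogis(gain * (h - threshold))
  if (is.matrix(h)) dim(out) <- dim(h)
  out
}

# derivative of the transfer function, used for linearization
transfer_function_deriv <- function(h, gain = 1, threshold = 0) {
  f <- transfer_function(h, gain, threshold)
  gain * f * (1 - f)
}

#' Gaussian connectivity kernel over electrode positions
#'
#' Inter-electrode connection strengths follow an isotropic Gaussian profile
#' of the distance between channel positions:
#' `K[i, j] = amplitude * exp(-(x_i - x_j)^2 / (2 * width_mm^2))`.
#'
#' @param positions_mm strictly increasing channel positions on the patch (mm).
#' @param amplitude peak connection strength (value at zero distance).
#' @param width_mm Gaussian width (mm), must be positive. `Inf` gives a flat
#'   all-to-all kernel equal to `amplitude`.
#' @return a `connectivity_kernel` object: a list with the weight `matrix`,
#'   `positions_mm`, and the generating `params`.
#' @export
gaussian_kernel <- function(positions_mm, amplitude, width_mm) {
  if (any(diff(positions_mm) <= 0)) {
    stop("channel positions must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(amplitude)) stop("amplitude must be finite", call. = FALSE)
  if (width_mm <= 0) stop("kernel width must be positive", call. = FALSE)
  d <- outer(positions_mm, positions_mm, "-")
  K <- if (is.infinite(width_mm)) {
    matrix(amplitude, length(positions_mm), length(positions_mm))
  } else {
    amplitude * exp(-d^2 / (2 * width_mm^2))
  }
  structure(
    list(matrix = K, positions_mm = positions_mm,
         params = list(amplitude = amplitude, width_mm = width_mm)),
    class = "connectivity_kernel"
  )
}

#' Local (diffusive) connectivity kernel
#'
#' Short-range coupling expressed directly in the derivative expansion:
#' `K = a0 I + a2 D2` with `D2` the discrete second-derivative (Laplacian)
#' operator on the channel grid. Unlike a broad Gaussian kernel, this
#' operator lies exactly in the span of the GLM's spatial-derivative
#' regressors, which makes it the reference coupling for model-recovery
#' studies (no truncation mismatch between generator and analysis model).
#'
#' @param positions_mm strictly increasing channel positions (mm).
#' @param a0 local (identity) coupling strength.
#' @param a2 diffusive coupling strength multiplying the Laplacian (mm^2
#'   units); positive values smooth.
#' @return a `connectivity_kernel` object.
#' @export
local_kernel <- function(positions_mm, a0, a2 = 0) {
  if (any(diff(positions_mm) <= 0)) {
    stop("channel positions must be strictly increasing", call. = FALSE)
  }
  check_finite(c(a0, a2), "kernel coefficients")
  D <- deriv_matrix(positions_mm)
  K <- a0 * diag(length(positions_mm)) + a2 * (D %*% D)
  structure(
    list(matrix = K, positions_mm = positions_mm,
         params = list(a0 = a0, a2 = a2)),
    class = "connectivity_kernel"
  )
}

#' @export
print.connectivity_kernel <- function(x, ...) {
  cat(sprintf("<connectivity_kernel> %d channels, amplitude %.4g, width %.4g mm\n",
              nrow(x$matrix), x$params$amplitude %||% NA, x$params$width_mm %||% NA))
  invisible(x)
}

as_kernel_matrix <- function(kernel) {
  if (inherits(kernel, "connectivity_kernel")) kernel$matrix else as.matrix(kernel)
}

#' Neural field model parameters for one ensemble
#'
#' Bundles the ingredients of the field equation
#' `dV/dt = -V / tau + K f(V) + U`: postsynaptic time constant, sigmoid gain
#' and threshold, discretized connectivity kernel over the channel grid, and
#' the scale of the stochastic endogenous input.
#'
#' @param tau_ms postsynaptic time constant (ms), positive.
#' @param gain synaptic gain of the transfer function.
#' @param threshold half-activation potential of the transfer function.
#' @param kernel a [gaussian_kernel()] object or a square numeric matrix with
#'   one row/column per channel.
#' @param noise_sd standard deviation of the white stochastic input per
#'   sqrt(ms), non-negative.
#' @return an `ensemble_model` object.
#' @export
ensemble_model <- function(tau_ms, gain, threshold, kernel, noise_sd = 0) {
  if (!is.finite(tau_ms) || tau_ms <= 0) stop("tau_ms must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  K <- as_kernel_matrix(kernel)
  if (nrow(K) != ncol(K)) stop("connectivity kernel must be square", call. = FALSE)
  check_finite(K, "connectivity kernel")
  structure(
    list(tau_ms = tau_ms, gain = gain, threshold = threshold,
         kernel = if (inherits(kernel, "connectivity_kernel")) kernel else
           structure(list(matrix = K, positions_mm = NULL, params = list()),
                     class = "connectivity_kernel"),
         noise_sd = noise_sd),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_model> %d channels | tau = %.3g ms, gain = %.3g, ",
                     "threshold = %.3g, noise sd = %.3g\n"),
              nrow(x$kernel$matrix), x$tau_ms, x$gain, x$threshold, x$noise_sd))
  invisible(x)
}

#' One explicit Euler step of the neural field equation
#'
#' Advances the depolarization profile by
#' `V <- V + dt * (-V / tau + K f(V + V0e) + U)`. Passing the boundary
#' extracellular potential `V0e` gives the ephaptic variant; `V0e = 0` (or
#' `NULL`) recovers the non-ephaptic model exactly, bit for bit.
#'
#' With `center = TRUE` the recurrent drive is `K (f(V + V0e) - f(0))`, the
#' fluctuation-around-baseline convention under which `V = 0` is exactly the
#' noise-free fixed point; the simulator uses this form.
#'
#' @param V depolarization, one value per channel.
#' @param model an [ensemble_model()].
#' @param V0e boundary extracellular potential per channel (ephaptic term), or
#'   `NULL` for the non-ephaptic model.
#' @param U exogenous input per channel (deterministic part), or `NULL`.
#' @param dt_ms time step (ms), positive.
#' @param center logical; subtract the baseline transfer output `f(0)` from the
#'   recurrent drive.
#' @return the next depolarization profile.
#' @export
step_field <- function(V, model, V0e = NULL, U = NULL, dt_ms = 1, center = FALSE) {
  stopifnot(inherits(model, "ensemble_model"))
  if (dt_ms <= 0) stop("dt_ms must be positive", call. = FALSE)
  K <- model$kernel$matrix
  n <- length(V)
  if (nrow(K) != n) stop("shape mismatch between V and connectivity kernel", call. = FALSE)
  h <- V
  if (!is.null(V0e)) {
    if (length(V0e) != n) stop("shape mismatch between V and V0e", call. = FALSE)
    h <- h + V0e
  }
  rate <- transfer_function(h, model$gain, model$threshold)
  if (center) {
    rate <- rate - transfer_function(0, model$gain, model$threshold)
  }
  drive <- -V / model$tau_ms + as.vector(K %*% rate)
  if (!is.null(U)) {
    if (length(U) != n) stop("shape mismatch between V and U", call. = FALSE)
    drive <- drive + U
  }
  V + dt_ms * drive
}

#' Linear stability of the ensemble about baseline
#'
#' Linearizes the field equation about the baseline fixed point (`V = 0` under
#' the fluctuation convention): the Jacobian is `-I / tau + f'(0) K` with
#' `f'(0)` the transfer-function slope at baseline. The model is stable when
#' every eigenvalue has a negative real part.
#'
#' @param model an [ensemble_model()].
#' @param baseline potential about which to linearize (default 0).
#' @return a list with `stable` (logical), `leading_eigenvalue` (largest real
#'   part, 1/ms) and the full complex `eigenvalues`.
#' @export
is_stable <- function(model, baseline = 0) {
  stopifnot(inherits(model, "ensemble_model"))
  K <- model$kernel$matrix
  slope <- transfer_function_deriv(baseline, model$gain, model$threshold)
  J <- -diag(nrow(K)) / model$tau_ms + slope * K
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  list(stable = lead < 0, leading_eigenvalue = lead, eigenvalues = ev)
}

#' Principal axes: spatial derivatives of the mean potential profile
#'
#' Computes the GLM regressor stack `H_j`, `j = 0..order_J`, where `H_0` is
#' the mean potential itself and `H_j` is its j-th spatial derivative across
#' the channel grid (second-order central differences, one-sided second-order
#' at the boundaries; exact for quadratic profiles). As the order grows the
#' axes describe fluctuations at progressively finer spatial scales.
#'
#' @param V_mean channels x time matrix of the trial-mean potential.
#' @param positions_mm strictly increasing channel positions (mm).
#' @param order_J maximum derivative order (>= 0); requires at least
#'   `order_J + 2` channels.
#' @return a list of `order_J + 1` channels x time matrices `H_0 .. H_J`.
#' @export
spatial_axes <- function(V_mean, positions_mm, order_J = 4) {
  V_mean <- as.matrix(V_mean)
  if (nrow(V_mean) != length(positions_mm)) {
    stop("V_mean must have one row per channel position", call. = FALSE)
  }
  ops <- deriv_matrix_powers(positions_mm, order_J)
  axes <- lapply(ops, function(D) D %*% V_mean)
  names(axes) <- paste0("H", 0:order_J)
  axes
}

#' GLM reformulation of a recording: demeaned data and principal axes
#'
#' Rewrites a multi-trial recording in the Gaussian-linear-model form
#' `Y = sum_j H_j w_j + e`: `Y` is the per-trial data minus the across-trial
#' sample mean at matched (channel, time) samples, and the axes `H_j` are the
#' spatial derivatives of the trial-mean potential ([spatial_axes()]). The
#' connectivity components `w_j` are left unfitted; [reml_fit()] fills them.
#'
#' @param rec an [lfp_recording()] with at least two trials.
#' @param order_J maximum derivative order for the axes (default 4).
#' @return a `glm_decomposition` object with elements `Y` (trials x channels x
#'   time demeaned array), `mean` (channels x time), `axes` (list of `H_j`),
#'   `positions_mm`, `order_J`, and unfitted `components`, `noise_precision`,
#'   `free_energy`.
#' @export
glm_decompose <- function(rec, order_J = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  dims <- dim(rec$data)
  if (dims[1] < 2) {
    stop("glm_decompose needs at least 2 trials (mean removal is degenerate otherwise)",
         call. = FALSE)
  }
  m <- apply(rec$data, c(2, 3), mean)
  Y <- sweep(rec$data, c(2, 3), m, "-")
  axes <- spatial_axes(m, rec$channel_positions_mm, order_J)
  structure(
    list(Y = Y, mean = m, axes = axes,
         positions_mm = rec$channel_positions_mm,
         order_J = order_J, components = NULL,
         noise_precision = NULL, free_energy = NULL),
    class = "glm_decomposition"
  )
}

#' @export
print.glm_decomposition <- function(x, ...) {
  d <- dim(x$Y)
  cat(sprintf("<glm_decomposition> %d trials x %d channels x %d samples, axes order 0..%d%s\n",
              d[1], d[2], d[3], x$order_J,
              if (is.null(x$components)) " (unfitted)" else " (fitted)"))
  invisible(x)
}
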