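# Fourier-mode formulation of the field-activity coupling: mode projection,
# the coupled mode evolution equations, the slaved (adiabatic) quasi-steady
# solution, a tracking-error diagnostic, and the two-area linearized block
# system with its determinant identities.

#' Fourier-mode projection of a spatial profile
#'
#' Discrete Fourier coefficients of a profile sampled on a uniform grid
#' covering one period: `c_n = mean(V * exp(-i n x))` for orders
#' `0..n_modes`. [reconstruct_modes()] inverts the projection exactly for
#' profiles band-limited to the requested orders.
#'
#' @param V real profile on a uniform grid over `[0, 2*pi)`.
#' @param n_modes highest mode order (must stay below the Nyquist order
#'   `floor((length(V) - 1) / 2)`).
#' @return complex vector of coefficients, names `"0"`, `"1"`, ...
#' @export
project_modes <- function(V, n_modes) {
  n <- length(V)
  if (n_modes > floor((n - 1) / 2)) {
    stop("n_modes exceeds the Nyquist order for this grid", call. = FALSE)
  }
  x <- 2 * pi * (seq_len(n) - 1) / n
  co <- vapply(0:n_modes, function(m) mean(V * exp(-1i * m * x)), complex(1))
  names(co) <- as.character(0:n_modes)
  co
}

#' @rdname project_modes
#' @param coefficients complex coefficients from [project_modes()].
#' @param n_points grid size of the reconstruction.
#' @export
reconstruct_modes <- function(coefficients, n_points) {
  x <- 2 * pi * (seq_len(n_points) - 1) / n_points
  orders <- as.integer(names(coefficients))
  out <- numeric(n_points)
  for (j in seq_along(orders)) {
    m <- orders[j]
    term <- coefficients[j] * exp(1i * m * x)
    out <- out + if (m == 0) Re(term) else 2 * Re(term)
  }
  out
}

#' Coupled field/activity mode state
#'
#' State container for the mode evolution equations: field modes `xi_n` relax
#' at rate `1/tau_EP` and are driven by `Z n^2 psi_n`; activity modes `psi_n`
#' relax at rate `1/tau_NA` and receive the kernel-coupled drive
#' `gain * sum_q K_hat[n, q] (psi_q + xi0_q)`, where `xi0_q` are the boundary
#' field modes.
#'
#' @param xi complex field modes (orders 1..N).
#' @param psi complex activity modes, same length.
#' @param xi0 boundary field modes; defaults to `xi` (the boundary values are
#'   identified with the field modes).
#' @param K_hat transformed kernel matrix `K_hat[n, q]` (N x N).
#' @param tau_EP_ms,tau_NA_ms field and activity time constants (ms), positive.
#' @param gain synaptic gain `delta`.
#' @param Z multipole drive coefficient (see [multipole_coefficient()]).
#' @return a `mode_state` object.
#' @export
mode_state <- function(xi, psi, xi0 = NULL, K_hat, tau_EP_ms, tau_NA_ms,
                       gain = 1, Z = 1) {
  if (length(xi) != length(psi)) stop("xi and psi must have matching mode counts", call. = FALSE)
  K_hat <- as.matrix(K_hat)
  if (nrow(K_hat) != length(psi) || ncol(K_hat) != length(psi)) {
    stop("K_hat must be square with side length(psi)", call. = FALSE)
  }
  if (tau_EP_ms <= 0 || tau_NA_ms <= 0) stop("time constants must be positive", call. = FALSE)
  structure(list(xi = as.complex(xi), psi = as.complex(psi),
                 xi0 = as.complex(xi0 %||% xi), K_hat = K_hat,
                 tau_EP_ms = tau_EP_ms, tau_NA_ms = tau_NA_ms,
                 gain = gain, Z = Z),
            class = "mode_state")
}

#' One explicit Euler step of the mode evolution equations
#'
#' `xi_n <- xi_n + dt * (-xi_n / tau_EP + Z * n^2 * psi_n)` and
#' `psi_n <- psi_n + dt * (-psi_n / tau_NA + gain * K_hat (psi + xi0) + U)`.
#' The `n^2` factor multiplies the field drive of mode `n`. The boundary
#' modes `xi0` are updated to the new `xi` (they track the field).
#'
#' @param state a [mode_state()].
#' @param U stochastic/exogenous input per mode (complex or real), default 0.
#' @param dt_ms time step (ms).
#' @return the advanced `mode_state`.
#' @export
step_modes <- function(state, U = 0, dt_ms = 0.5) {
  stopifnot(inherits(state, "mode_state"))
  if (dt_ms <= 0) stop("dt_ms must be positive", call. = FALSE)
  N <- length(state$psi)
  if (length(U) != 1 && length(U) != N) stop("U must be scalar or one value per mode", call. = FALSE)
  n2 <- (seq_len(N))^2
  xi_new <- state$xi + dt_ms * (-state$xi / state$tau_EP_ms + state$Z * n2 * state$psi)
  drive <- state$gain * as.vector(state$K_hat %*% (state$psi + state$xi0))
  psi_new <- state$psi + dt_ms * (-state$psi / state$tau_NA_ms + drive + U)
  state$xi <- xi_new
  state$psi <- psi_new
  state$xi0 <- xi_new
  state
}

#' Slaved (quasi-steady) solution of the activity modes
#'
#' Under the adiabatic approximation the fast activity modes equilibrate to
#' the instantaneous boundary field: setting the activity derivative to zero
#' gives the linear system `(I - c K_hat) psi = c K_hat xi0` with
#' `c = gain * tau_NA` (the fixed point of the mode evolution equations).
#'
#' @param xi0 boundary field modes.
#' @param K_hat transformed kernel matrix.
#' @param gain synaptic gain.
#' @param tau_NA_ms activity time constant (ms).
#' @return the slaved activity modes `psi`.
#' @export
slaved_solution <- function(xi0, K_hat, gain, tau_NA_ms) {
  K_hat <- as.matrix(K_hat)
  N <- length(xi0)
  cc <- gain * tau_NA_ms
  A <- diag(N) - cc * K_hat
  if (abs(det(A)) < 1e-12 * max(1, max(abs(cc * K_hat)))^N) {
    stop("slaved system is singular: gain * tau_NA * K_hat has a unit eigenvalue (resonance)",
         call. = FALSE)
  }
  solve(A, cc * as.vector(K_hat %*% xi0))
}

#' Adiabatic tracking error of the slaved solution
#'
#' Simulates the coupled mode equations with activity relaxing `ratio` times
#' faster than the field (`tau_NA^-1 / tau_EP^-1 = ratio`), then measures how
#' closely the activity modes track the slaved quasi-steady solution
#' evaluated at the instantaneous field: after a transient of `5 tau_NA`, the
#' time-averaged relative error `||psi(t) - psi_slaved(xi0(t))|| / ||psi(t)||`.
#' Larger timescale separation gives smaller tracking error.
#'
#' @param timescale_ratio ratio of relaxation rates (> 1 for separation; 1 is
#'   allowed for the no-separation probe).
#' @param tau_NA_ms fast (activity) time constant (ms).
#' @param K_hat transformed kernel (default `diag(-0.04, -0.03)`; negative
#'   diagonal keeps the fast subsystem stable).
#' @param gain synaptic gain (default 1).
#' @param Z field drive coefficient (default 1e-4; kept small so the
#'   activity-to-field feedback does not shorten the field's relaxation and
#'   the configured timescale ratio is the realized one).
#' @param noise_sd standard deviation of the white input to the activity
#'   modes, per sqrt(ms).
#' @param xi_init initial field mode amplitude.
#' @param horizon_ms simulation horizon; default `transient + 2 * tau_EP`.
#' @param dt_ms integration step (default `tau_NA / 25`).
#' @param seed integer seed.
#' @return list with `relative_error`, `timescale_ratio`, `horizon_ms`.
#' @export
adiabatic_tracking_error <- function(timescale_ratio, tau_NA_ms = 10,
                                     K_hat = diag(c(-0.04, -0.03)),
                                     gain = 1, Z = 1e-4, noise_sd = 1e-4,
                                     xi_init = 1, horizon_ms = NULL,
                                     dt_ms = tau_NA_ms / 25, seed = 1) {
  if (timescale_ratio < 1) stop("timescale_ratio must be >= 1", call. = FALSE)
  tau_EP <- tau_NA_ms * timescale_ratio
  N <- nrow(as.matrix(K_hat))
  # fast-subsystem stability: -1/tau_NA + gain * K_hat must be a stable matrix
  fast <- -diag(N) / tau_NA_ms + gain * as.matrix(K_hat)
  if (max(Re(eigen(fast, only.values = TRUE)$values)) >= 0) {
    stop("unstable configuration: fast activity subsystem has a non-negative eigenvalue",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  transient <- 5 * tau_NA_ms
  horizon_ms <- horizon_ms %||% (transient + 2 * tau_EP)
  st <- mode_state(xi = rep(xi_init, N), psi = rep(0, N), K_hat = K_hat,
                   tau_EP_ms = tau_EP, tau_NA_ms = tau_NA_ms, gain = gain, Z = Z)
  n_steps <- ceiling(horizon_ms / dt_ms)
  err_num <- 0; err_den <- 0
  for (s in seq_len(n_steps)) {
    U <- complex(real = rnorm(N, sd = noise_sd / sqrt(dt_ms)),
                 imaginary = rnorm(N, sd = noise_sd / sqrt(dt_ms)))
    st <- step_modes(st, U = U, dt_ms = dt_ms)
    if (s * dt_ms > transient) {
      target <- slaved_solution(st$xi0, st$K_hat, gain, tau_NA_ms)
      err_num <- err_num + sum(Mod(st$psi - target)^2)
      err_den <- err_den + sum(Mod(st$psi)^2)
    }
  }
  list(relative_error = sqrt(err_num / err_den),
       timescale_ratio = timescale_ratio, horizon_ms = horizon_ms)
}

#' Two-area linearized block system
#'
#' Assembles the coefficient matrix `M` of the linearized two-area
#' field/activity system, truncated at two Fourier modes per area, in the
#' block form `M = [A B; C D]` with `D = [E L; G J]`. Per-area ordering is
#' `(xi_1, psi_1, xi_2, psi_2)`. The diagonal blocks follow the same template
#' as the printed second-mode matrix `J`:
#' field rows carry `beta + 1/tau_EP` on the diagonal and `n^2 Z` on their
#' activity column; activity rows carry `gain * K_hat[n, q]` on the field and
#' cross-mode activity columns and `beta + 1/tau_NA + gain * K_hat[n, n]` on
#' the diagonal. The feedforward coupling from area 1 to area 2 enters block
#' `C` (activity rows of area 2 against activity columns of area 1) as
#' `gain * W_ff[n, q]`; `B` is zero for a feedforward pair. Any block can be
#' overridden explicitly through `overrides`.
#'
#' @param tau_EP_ms,tau_NA_ms field and activity time constants (ms).
#' @param gain synaptic gain `delta`.
#' @param K1_hat,K2_hat 2 x 2 transformed kernels of areas 1 and 2 (entries
#'   `K_hat[n, q]`, modes `n, q` in 1..2).
#' @param W_ff feedforward connectivity area 1 -> area 2: scalar (applied to
#'   matching modes) or 2 x 2 matrix.
#' @param beta planar-wave growth-rate parameter added on every diagonal.
#' @param Z multipole coefficient (scalar or [farfield_params()]).
#' @param overrides optional named list of replacement blocks (`A`, `B`, `C`,
#'   `D`), each 4 x 4, restoring any externally specified exact forms.
#' @return a `two_area_system` with elements `M`, `A`, `B`, `C`, `D`, `E`,
#'   `L`, `G`, `J` and the parameters used.
#' @export
build_two_area_blocks <- function(tau_EP_ms = 1, tau_NA_ms = 1, gain = 1,
                                  K1_hat = diag(2), K2_hat = diag(2),
                                  W_ff = 0, beta = 0, Z = 1,
                                  overrides = NULL) {
  if (inherits(Z, "farfield_params")) Z <- multipole_coefficient(Z)
  if (is.null(Z) || is.null(tau_EP_ms) || is.null(tau_NA_ms)) {
    stop("Z and both rates are required", call. = FALSE)
  }
  K1_hat <- as.matrix(K1_hat); K2_hat <- as.matrix(K2_hat)
  stopifnot(all(dim(K1_hat) == c(2, 2)), all(dim(K2_hat) == c(2, 2)))
  Wm <- if (length(W_ff) == 1) diag(2) * W_ff else as.matrix(W_ff)
  stopifnot(all(dim(Wm) == c(2, 2)))
  area_block <- function(K_hat) {
    Mb <- matrix(0, 4, 4)
    for (n in 1:2) {
      xi_row <- 2 * n - 1; psi_row <- 2 * n
      Mb[xi_row, xi_row] <- beta + 1 / tau_EP_ms
      Mb[xi_row, psi_row] <- n^2 * Z
      for (q in 1:2) {
        Mb[psi_row, 2 * q - 1] <- gain * K_hat[n, q]        # boundary field modes
        Mb[psi_row, 2 * q] <- gain * K_hat[n, q] +          # activity modes
          if (q == n) beta + 1 / tau_NA_ms else 0
      }
    }
    Mb
  }
  A <- area_block(K1_hat)
  D <- area_block(K2_hat)
  B <- matrix(0, 4, 4)
  C <- matrix(0, 4, 4)
  for (n in 1:2) for (q in 1:2) {
    C[2 * n, 2 * q] <- gain * Wm[n, q]     # area-2 activity <- area-1 activity
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      stopifnot(nm %in% c("A", "B", "C", "D"),
                all(dim(overrides[[nm]]) == c(4, 4)))
      assign(nm, overrides[[nm]])
    }
  }
  M <- rbind(cbind(A, B), cbind(C, D))
  structure(
    list(M = M, A = A, B = B, C = C, D = D,
         E = D[1:2, 1:2], L = D[1:2, 3:4], G = D[3:4, 1:2], J = D[3:4, 3:4],
         params = list(tau_EP_ms = tau_EP_ms, tau_NA_ms = tau_NA_ms,
                       gain = gain, beta = beta, Z = Z, W_ff = Wm)),
    class = "two_area_system"
  )
}

#' @export
print.two_area_system <- function(x, ...) {
  cat("<two_area_system> 8x8 coefficient matrix M = [A B; C D], D = [E L; G J]\n")
  cat(sprintf("  det(M) = %.6g, det(A) = %.6g, det(J) = %.6g\n",
              det(x$M), det(x$A), det(x$J)))
  invisible(x)
}

#' Determinant identities and the shared-coupling implication
#'
#' Evaluates, for a two-area block system, the Schur-complement determinant
#' identity `det(M) = det(A - B D^-1 C) det(D)`, the three-factor form
#' `det(M) = det(A) det(E - L J^-1 G) det(J)` (exact for a feedforward pair,
#' where `B = 0`), and the implication that a solvable coupled system
#' (`det(M) != 0`) with field-activity coupling in one area
#' (`det(J) != 0`) forces coupling in the other (`det(A) != 0`).
#'
#' Singular `D` or `J` is reported in the result, not raised.
#'
#' @param sys a [build_two_area_blocks()] result.
#' @param tol relative threshold on scaled determinants (default 1e-10).
#' @return list with the determinants, relative factorization residuals,
#'   `implication_holds`, and a `degenerate` flag naming any singular factor.
#' @export
engram_condition <- function(sys, tol = 1e-10) {
  stopifnot(inherits(sys, "two_area_system"))
  det_M <- det(sys$M); det_A <- det(sys$A); det_D <- det(sys$D); det_J <- det(sys$J)
  scale_M <- max(abs(det_M), 1e-300)
  degenerate <- character(0)
  res_schur <- NA_real_; res_three <- NA_real_
  if (abs(det_D) > tol * max(1, norm(sys$D, "F")^4)) {
    schur <- sys$A - sys$B %*% solve(sys$D, sys$C)
    res_schur <- abs(det(schur) * det_D - det_M) / scale_M
  } else degenerate <- c(degenerate, "D")
  if (abs(det_J) > tol * max(1, norm(sys$J, "F")^2)) {
    inner <- sys$E - sys$L %*% solve(sys$J, sys$G)
    res_three <- abs(det_A * det(inner) * det_J - det_M) / scale_M
  } else degenerate <- c(degenerate, "J")
  nonzero <- function(d) abs(d) > tol * max(1, abs(det_M))
  implication <- if (nonzero(det_M) && nonzero(det_J)) nonzero(det_A) else NA
  list(det_M = det_M, det_A = det_A, det_D = det_D, det_J = det_J,
       schur_residual = res_schur, three_factor_residual = res_three,
       implication_holds = implication,
       degenerate = if (length(degenerate)) degenerate else NULL)
}
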