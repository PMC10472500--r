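# Bidomain forward model of the extracellular potential generated by ensemble
# activity: wavenumber-domain kernel with modified Bessel functions, FFT-based
# evaluation of V^e on an (x, y) grid, the electric field as the negative
# gradient, and the far-field differential-algebraic reduction with its
# multipole coefficient.

#' Bidomain model parameters
#'
#' The intra- and extracellular spaces are treated as coaxial conductive
#' domains with cylindrical symmetry: `a_mm` is the radius of the fiber
#' separating them (the membrane surrogate) and `y_mm` the perpendicular
#' distance(s) at which the extracellular potential is evaluated.
#'
#' @param sigma_e extracellular conductivity (arbitrary units), positive.
#' @param sigma_i intracellular conductivity, positive.
#' @param a_mm fiber radius (mm), positive.
#' @param y_mm evaluation distance(s) (mm), each `>= a_mm`.
#' @return a `bidomain_params` object.
#' @export
bidomain_params <- function(sigma_e = 1, sigma_i = 1, a_mm = 0.1, y_mm = a_mm) {
  if (sigma_e <= 0 || sigma_i <= 0) stop("conductivities must be positive", call. = FALSE)
  if (a_mm <= 0) stop("fiber radius a_mm must be positive", call. = FALSE)
  if (any(y_mm < a_mm)) stop("evaluation distance y_mm must be >= fiber radius a_mm", call. = FALSE)
  structure(list(sigma_e = sigma_e, sigma_i = sigma_i, a_mm = a_mm, y_mm = y_mm),
            class = "bidomain_params")
}

#' Bidomain wavenumber kernel W(k)
#'
#' The transfer kernel linking the Fourier transform of the transmembrane
#' potential to the extracellular potential at perpendicular distance `y`:
#'
#' `W(k) = I1(|k| a) K0(|k| y) / (I0(|k| a) K1(|k| a) + (sigma_i/sigma_e) I1(|k| a) K0(|k| a))`
#'
#' with `I`, `K` modified Bessel functions of the first and second kind.
#' `W(0) = 0` by the small-argument series limit (numerator `O(k ln k)`,
#' denominator `O(1/k)`), so DC offsets of the membrane potential do not
#' propagate. `W` is even in `k`. Exponentially scaled Bessel functions are
#' used internally so large `|k| y` underflows to 0 instead of producing
#' 0/Inf.
#'
#' @param k wavenumber(s), 1/mm (may be negative; only `|k|` enters).
#' @param params a [bidomain_params()] object.
#' @param y evaluation distance (mm), `>= a_mm`; defaults to `params$y_mm[1]`.
#' @return numeric vector `W(k)`.
#' @export
bidomain_kernel <- function(k, params, y = params$y_mm[1]) {
  stopifnot(inherits(params, "bidomain_params"))
  if (y < params$a_mm) stop("y must be >= fiber radius a_mm", call. = FALSE)
  a <- params$a_mm
  ratio <- params$sigma_i / params$sigma_e
  ka <- abs(k) * a
  ky <- abs(k) * y
  out <- numeric(length(k))
  nz <- ka > 0
  if (any(nz)) {
    # scaled forms: I*(x) = I(x) e^-x, K*(x) = K(x) e^x  =>
    # I1(ka) K0(ky) = I1*(ka) K0*(ky) e^{-(ky - ka)}; the denominator's
    # exponentials cancel exactly.
    i1 <- besselI(ka[nz], 1, expon.scaled = TRUE)
    i0 <- besselI(ka[nz], 0, expon.scaled = TRUE)
    k0a <- besselK(ka[nz], 0, expon.scaled = TRUE)
    k1a <- besselK(ka[nz], 1, expon.scaled = TRUE)
    k0y <- besselK(ky[nz], 0, expon.scaled = TRUE)
    out[nz] <- i1 * k0y * exp(-(ky[nz] - ka[nz])) / (i0 * k1a + ratio * i1 * k0a)
  }
  out
}

# FFT wavenumbers (angular, 1/mm) for n samples spaced dx apart
fft_wavenumbers <- function(n, dx) {
  idx <- c(0:floor(n / 2), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2))
  2 * pi * idx / (n * dx)
}

#' Extracellular potential of a membrane-potential snapshot
#'
#' Evaluates `V^e(x, y) = -(4 pi sigma_e / sigma_i) FT^-1[ FT(V^m)(k) W(k) ]`
#' on the channel grid: forward FFT of the snapshot, multiplication by the
#' bidomain kernel at distance `y`, inverse FFT. The operator is linear in
#' `V^m` and real-valued (the kernel is even in `k`).
#'
#' Non-uniform channel grids are resampled to a uniform grid by linear
#' interpolation before the FFT and the result interpolated back.
#'
#' @param Vm_snapshot membrane potential, one value per channel.
#' @param params a [bidomain_params()] object.
#' @param y evaluation distance (mm); defaults to `params$y_mm[1]`.
#' @param positions_mm channel positions (mm); default a unit-spaced grid.
#' @return extracellular potential at the channel positions.
#' @export
extracellular_potential <- function(Vm_snapshot, params, y = params$y_mm[1],
                                    positions_mm = seq_along(Vm_snapshot) - 1) {
  check_finite(Vm_snapshot, "Vm_snapshot")
  B <- bidomain_operator(positions_mm, params, y)
  as.vector(B %*% Vm_snapshot)
}

#' Bidomain operator as a matrix over the channel grid
#'
#' Materializes the linear map `V^m -> V^e(., y)` of
#' [extracellular_potential()] as a channels x channels matrix, so repeated
#' evaluations (e.g. inside a simulation loop) are a single matrix product.
#'
#' @inheritParams extracellular_potential
#' @return a dense matrix `B` with `V^e = B %*% V^m`.
#' @export
bidomain_operator <- function(positions_mm, params, y = params$y_mm[1]) {
  stopifnot(inherits(params, "bidomain_params"))
  n <- length(positions_mm)
  if (n < 2) stop("need at least 2 channels", call. = FALSE)
  dxs <- diff(positions_mm)
  uniform <- max(abs(dxs - dxs[1])) < 1e-9 * max(abs(dxs))
  xu <- if (uniform) positions_mm else seq(min(positions_mm), max(positions_mm), length.out = n)
  dx <- xu[2] - xu[1]
  kk <- fft_wavenumbers(n, dx)
  mult <- -(4 * pi * params$sigma_e / params$sigma_i) * bidomain_kernel(kk, params, y)
  # B_u = Re( F^-1 diag(mult) F ) built column-by-column on the uniform grid
  Fm <- stats::mvfft(diag(n))
  Bu <- Re(stats::mvfft(Fm * mult, inverse = TRUE)) / n
  if (uniform) return(Bu)
  # resample: data -> uniform grid (interp matrix P), result -> original grid (Q)
  P <- interp_matrix(positions_mm, xu)
  Q <- interp_matrix(xu, positions_mm)
  Q %*% Bu %*% P
}

# linear-interpolation matrix mapping values on grid `from` to grid `to`
interp_matrix <- function(from, to) {
  n <- length(from); m <- length(to)
  M <- matrix(0, m, n)
  for (i in seq_len(m)) {
    x <- min(max(to[i], from[1]), from[n])
    j <- findInterval(x, from, rightmost.closed = TRUE)
    if (j >= n) { M[i, n] <- 1 } else {
      t <- (x - from[j]) / (from[j + 1] - from[j])
      M[i, j] <- 1 - t; M[i, j + 1] <- t
    }
  }
  M
}

#' Extracellular potential and electric field on an (x, y, t) grid
#'
#' Applies the bidomain forward model to every time point of a membrane
#' potential series at each requested perpendicular distance, then computes
#' the electric field as the negative gradient.
#'
#' @param Vm channels x time matrix of membrane potential (e.g. the trial
#'   mean), or an [lfp_recording()] (its trial mean is used).
#' @param params a [bidomain_params()] object.
#' @param y_grid perpendicular distances (mm) at which to evaluate.
#' @param positions_mm channel positions; taken from the recording when `Vm`
#'   is one.
#' @return a `field_estimate` object: `Ve` array `[x, y, t]`, `Ee_x` and
#'   `Ee_y` arrays of the field components, `x_grid`, `y_grid`, `params`.
#' @export
field_estimate <- function(Vm, params, y_grid = params$y_mm,
                           positions_mm = NULL) {
  if (inherits(Vm, "lfp_recording")) {
    positions_mm <- Vm$channel_positions_mm
    Vm <- apply(Vm$data, c(2, 3), mean)
  }
  Vm <- as.matrix(Vm)
  if (is.null(positions_mm)) positions_mm <- seq_len(nrow(Vm)) - 1
  nt <- ncol(Vm); nx <- nrow(Vm); ny <- length(y_grid)
  Ve <- array(0, dim = c(nx, ny, nt))
  for (j in seq_len(ny)) {
    B <- bidomain_operator(positions_mm, params, y_grid[j])
    Ve[, j, ] <- B %*% Vm
  }
  ef <- electric_field(Ve, positions_mm, y_grid)
  structure(list(Ve = Ve, Ee_x = ef$Ex, Ee_y = ef$Ey,
                 x_grid = positions_mm, y_grid = y_grid, params = params),
            class = "field_estimate")
}

#' @export
print.field_estimate <- function(x, ...) {
  d <- dim(x$Ve)
  cat(sprintf("<field_estimate> %d x-points x %d y-points x %d time points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Electric field from a potential grid
#'
#' `E = -grad(V)` by central differences (one-sided second order at grid
#' boundaries) in `x` and, when the grid has more than one `y` level, in `y`.
#'
#' @param Ve potential: a matrix `[x, y]` or array `[x, y, t]`.
#' @param x_grid,y_grid grid coordinates (mm).
#' @return list with components `Ex` and `Ey` (same shape as `Ve`; `Ey` is
#'   `NULL` for a single `y` level).
#' @export
electric_field <- function(Ve, x_grid, y_grid = NULL) {
  dims <- dim(Ve)
  if (is.null(dims)) stop("Ve must be a matrix or array", call. = FALSE)
  if (length(x_grid) < 2) stop("cannot differentiate a single-point grid", call. = FALSE)
  if (length(dims) == 2) Ve <- array(Ve, dim = c(dims, 1))
  d3 <- dim(Ve)
  Dx <- deriv_matrix(x_grid)
  Ex <- array(0, d3)
  for (t in seq_len(d3[3])) Ex[, , t] <- -(Dx %*% Ve[, , t])
  Ey <- NULL
  if (!is.null(y_grid) && length(y_grid) >= 3) {
    Dy <- deriv_matrix(y_grid)
    Ey <- array(0, d3)
    for (t in seq_len(d3[3])) Ey[, , t] <- -(Ve[, , t] %*% t(Dy))
  }
  if (length(dims) == 2) {
    Ex <- Ex[, , 1]; if (!is.null(Ey)) Ey <- Ey[, , 1]
  }
  list(Ex = Ex, Ey = Ey)
}

#' Far-field reduction parameters
#'
#' Parameters of the differential-algebraic far-field form of the bidomain
#' model: relaxation time of the extracellular potential, drive coefficient,
#' source-observer distance, and source extent. When `L_mm / r_mm > 0.5` the
#' truncated multipole expansion becomes questionable and the object carries
#' `expansion_valid = FALSE`.
#'
#' @param tau_EP_ms field relaxation time (ms), positive.
#' @param gamma drive coefficient.
#' @param r_mm source-observer distance (mm), positive.
#' @param L_mm source extent (mm), non-negative.
#' @return a `farfield_params` object.
#' @export
farfield_params <- function(tau_EP_ms, gamma, r_mm, L_mm = 0) {
  if (tau_EP_ms <= 0) stop("tau_EP_ms must be positive", call. = FALSE)
  if (r_mm <= 0) stop("distance r_mm must be positive", call. = FALSE)
  if (L_mm < 0) stop("source extent L_mm must be non-negative", call. = FALSE)
  structure(list(tau_EP_ms = tau_EP_ms, gamma = gamma, r_mm = r_mm, L_mm = L_mm,
                 expansion_valid = (L_mm / r_mm) <= 0.5),
            class = "farfield_params")
}

#' Multipole coefficient of the far-field drive
#'
#' `Z = gamma * (1/r - L^2 / (12 r^3) + L^4 / (80 r^5))`: the truncated
#' multipole expansion of the coupling between the membrane-potential
#' Laplacian and the far-field extracellular potential. `L = 0` gives the
#' point-source limit `gamma / r`.
#'
#' @param p a [farfield_params()] object.
#' @return the scalar coefficient `Z`.
#' @export
multipole_coefficient <- function(p) {
  stopifnot(inherits(p, "farfield_params"))
  r <- p$r_mm; L <- p$L_mm
  p$gamma * (1 / r - L^2 / (12 * r^3) + L^4 / (80 * r^5))
}

#' One explicit Euler step of the far-field potential equation
#'
#' `Ve <- Ve + dt * (-Ve / tau_EP + Z * laplacian_Vm)` with `Z` the
#' [multipole_coefficient()]. Under a constant drive `D` the fixed point is
#' `tau_EP * Z * D`.
#'
#' @param Ve current extracellular potential (scalar or vector).
#' @param laplacian_Vm membrane-potential Laplacian drive, same shape as `Ve`.
#' @param p a [farfield_params()] object.
#' @param dt_ms time step (ms), positive.
#' @return the next extracellular potential.
#' @export
step_farfield <- function(Ve, laplacian_Vm, p, dt_ms = 1) {
  stopifnot(inherits(p, "farfield_params"))
  if (dt_ms <= 0) stop("dt_ms must be positive", call. = FALSE)
  if (length(laplacian_Vm) != length(Ve) && length(laplacian_Vm) != 1) {
    stop("laplacian_Vm must match Ve in shape (or be scalar)", call. = FALSE)
  }
  Ve + dt_ms * (-Ve / p$tau_EP_ms + multipole_coefficient(p) * laplacian_Vm)
}

#' Spatial Laplacian of a channel profile
#'
#' Second spatial derivative of a profile on the channel grid, computed as the
#' iterated second-order first-derivative stencil (exact for quadratics,
#' one-sided at the boundaries). This is the drive term of the far-field
#' equation.
#'
#' @param V one value per channel (at least 3 channels).
#' @param positions_mm strictly increasing channel positions.
#' @return the Laplacian profile.
#' @export
laplacian_on_grid <- function(V, positions_mm = seq_along(V) - 1) {
  if (length(V) < 3) stop("need at least 3 channels for a Laplacian", call. = FALSE)
  D <- deriv_matrix(positions_mm)
  as.vector(D %*% (D %*% V))
}
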