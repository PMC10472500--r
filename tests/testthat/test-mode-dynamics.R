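test_that("mode projection inverts exactly for band-limited profiles", {
  n <- 32
  x <- 2 * pi * (0:(n - 1)) / n
  V <- 1.5 + 2 * cos(3 * x + 0.7) - 0.8 * cos(x - 1.1)
  co <- project_modes(V, n_modes = 4)
  expect_named(co, as.character(0:4))
  expect_equal(reconstruct_modes(co, n), V, tolerance = 1e-12)
  # hand values: c_0 is the mean, c_3 = e^{i 0.7} (amplitude 2 -> coefficient 1)
  expect_equal(co[["0"]], 1.5 + 0i, tolerance = 1e-12)
  expect_equal(co[["3"]], complex(modulus = 1, argument = 0.7), tolerance = 1e-12)
  expect_error(project_modes(V, n_modes = 16), "Nyquist")
})

test_that("step_modes performs the literal Euler update of both equations", {
  K <- matrix(c(-0.04, 0.01, 0.02, -0.03), 2, 2)
  st <- mode_state(xi = c(1 + 0i, 0.5), psi = c(0.2, -0.1 + 0.3i), K_hat = K,
                   tau_EP_ms = 100, tau_NA_ms = 10, gain = 0.7, Z = 0.05)
  dt <- 0.4
  U <- c(0.01, -0.02)
  out <- step_modes(st, U = U, dt_ms = dt)
  n2 <- c(1, 4)
  xi_exp <- st$xi + dt * (-st$xi / 100 + 0.05 * n2 * st$psi)
  psi_exp <- st$psi + dt * (-st$psi / 10 +
    0.7 * as.vector(K %*% (st$psi + st$xi0)) + U)
  expect_equal(out$xi, xi_exp, tolerance = 1e-14)
  expect_equal(out$psi, psi_exp, tolerance = 1e-14)
  expect_identical(out$xi0, out$xi)   # boundary modes track the field
  expect_error(mode_state(1:2, 1:3, K_hat = K, tau_EP_ms = 1, tau_NA_ms = 1),
               "matching")
  expect_error(step_modes(st, U = 1:3), "per mode")
})

test_that("slaved solution is the exact fixed point of the activity equation", {
  set.seed(31)
  K <- matrix(rnorm(4, sd = 0.05), 2, 2)
  xi0 <- c(0.8 - 0.2i, 0.3 + 0.1i)
  psi <- slaved_solution(xi0, K, gain = 0.9, tau_NA_ms = 12)
  # residual of -psi/tau + gain K (psi + xi0) at the slaved value
  resid <- -psi / 12 + 0.9 * as.vector(K %*% (psi + xi0))
  expect_lt(max(Mod(resid)), 1e-12)
  # resonance: unit eigenvalue of c * K_hat
  expect_error(slaved_solution(c(1, 0), diag(2) / 12, gain = 1, tau_NA_ms = 12),
               "resonance")
})

test_that("adiabatic tracking error shrinks monotonically with timescale separation", {
  ratios <- c(1, 3, 10, 30, 100)
  errs <- vapply(ratios, function(r) {
    adiabatic_tracking_error(r, seed = 1)$relative_error
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 0.05)
  # deterministic given the seed
  expect_identical(adiabatic_tracking_error(10, seed = 4)$relative_error,
                   adiabatic_tracking_error(10, seed = 4)$relative_error)
  expect_error(adiabatic_tracking_error(0.5), ">= 1")
})

test_that("two-area blocks reproduce the hand-checked unit-parameter matrix", {
  sys <- build_two_area_blocks(tau_EP_ms = 1, tau_NA_ms = 1, gain = 1,
                               K1_hat = matrix(0, 2, 2),
                               K2_hat = matrix(0, 2, 2),
                               W_ff = 0, beta = 0, Z = 1)
  # with beta = 0, tau = 1, K_hat = 0, Z = 1 the second-mode block is
  # [[1, 4], [0, 1]] (field row: diagonal 1, activity column n^2 = 4)
  expect_equal(sys$J, matrix(c(1, 0, 4, 1), 2, 2))
  expect_equal(det(sys$J), 1)
  expect_equal(sys$B, matrix(0, 4, 4))        # feedforward pair: no feedback
  expect_equal(sys$M[1:4, 1:4], sys$A)
  expect_equal(sys$M[5:8, 5:8], sys$D)
})

test_that("feedforward coupling lands only on area-2 activity rows", {
  sys <- build_two_area_blocks(W_ff = 0.3, gain = 2)
  C <- sys$C
  expect_equal(C[2, 2], 0.6)
  expect_equal(C[4, 4], 0.6)
  C[cbind(c(2, 4), c(2, 4))] <- 0
  expect_equal(C, matrix(0, 4, 4))
  # overrides replace a block verbatim
  Bo <- matrix(seq(0.1, 1.6, by = 0.1), 4, 4)
  sys2 <- build_two_area_blocks(overrides = list(B = Bo))
  expect_equal(sys2$B, Bo)
  expect_equal(sys2$M[1:4, 5:8], Bo)
})

test_that("determinant identities hold on random stable systems", {
  ok <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    sys <- build_two_area_blocks(
      tau_EP_ms = runif(1, 0.5, 5), tau_NA_ms = runif(1, 0.5, 5),
      gain = runif(1, 0.2, 2),
      K1_hat = matrix(rnorm(4, sd = 0.3), 2, 2),
      K2_hat = matrix(rnorm(4, sd = 0.3), 2, 2),
      W_ff = matrix(rnorm(4, sd = 0.2), 2, 2),
      beta = rnorm(1, sd = 0.5), Z = runif(1, 0.1, 2))
    cond <- engram_condition(sys)
    cond$schur_residual < 1e-10 && cond$three_factor_residual < 1e-10 &&
      isTRUE(cond$implication_holds)
  }, logical(1))
  expect_true(all(ok))
})

test_that("degenerate blocks are flagged rather than inverted", {
  sys <- build_two_area_blocks()
  sys$D <- matrix(0, 4, 4)
  sys$J <- matrix(0, 2, 2)
  sys$M <- rbind(cbind(sys$A, sys$B), cbind(sys$C, sys$D))
  cond <- engram_condition(sys)
  expect_true(all(c("D", "J") %in% cond$degenerate))
  expect_true(is.na(cond$schur_residual))
  expect_true(is.na(cond$three_factor_residual))
})
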