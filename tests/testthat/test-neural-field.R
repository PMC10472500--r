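test_that("transfer function has the exact logistic values and monotonicity", {
  expect_equal(transfer_function(0, gain = 1, threshold = 0), 0.5)
  expect_equal(transfer_function(log(3), gain = 1, threshold = 0), 0.75)
  expect_equal(transfer_function(5, gain = 2, threshold = 5), 0.5)
  h <- seq(-6, 6, by = 0.1)
  expect_true(all(diff(transfer_function(h, 1.3, 0.4)) > 0))
  # graceful saturation
  expect_equal(transfer_function(1e6, 1, 0), 1)
  expect_equal(transfer_function(-1e6, 1, 0), 0)
})

test_that("transfer function derivative matches a numeric gradient", {
  h <- c(-2, -0.3, 0, 0.7, 2.5)
  eps <- 1e-6
  num <- (transfer_function(h + eps, 1.4, 0.2) -
            transfer_function(h - eps, 1.4, 0.2)) / (2 * eps)
  expect_equal(engramfield:::transfer_function_deriv(h, 1.4, 0.2), num,
               tolerance = 1e-7)
})

test_that("gaussian kernel is symmetric with the advertised profile", {
  pos <- fixture_positions(8)
  k <- gaussian_kernel(pos, amplitude = 2, width_mm = 0.5)
  expect_s3_class(k, "connectivity_kernel")
  expect_equal(k$matrix, t(k$matrix))
  expect_equal(diag(k$matrix), rep(2, 8))
  expect_equal(k$matrix[1, 2], 2 * exp(-(pos[2] - pos[1])^2 / (2 * 0.25)))
  flat <- gaussian_kernel(pos, 1.5, Inf)
  expect_true(all(flat$matrix == 1.5))
  expect_error(gaussian_kernel(rev(pos), 1, 0.5), "increasing")
  expect_error(gaussian_kernel(pos, 1, 0), "positive")
})

test_that("local kernel applies a0 + a2 * Laplacian exactly on quadratics", {
  pos <- fixture_positions(12)
  k <- local_kernel(pos, a0 = 0.3, a2 = 0.05)
  q <- 2 * pos^2 - pos + 1            # second derivative is 4 everywhere
  expect_equal(as.vector(k$matrix %*% q), 0.3 * q + 0.05 * 4 + 0 * q,
               tolerance = 1e-10)
  expect_error(local_kernel(c(1, 1, 2), 1), "increasing")
})

test_that("ensemble model validates its inputs", {
  pos <- fixture_positions(5)
  expect_error(ensemble_model(-1, 1, 0, gaussian_kernel(pos, 1, 1)), "positive")
  expect_error(ensemble_model(10, 1, 0, matrix(1, 2, 3)), "square")
  expect_error(ensemble_model(10, 1, 0, gaussian_kernel(pos, 1, 1),
                              noise_sd = -1), "non-negative")
  m <- ensemble_model(10, 1, 0, matrix(0.1, 5, 5))
  expect_s3_class(m$kernel, "connectivity_kernel")
})

test_that("step_field performs the literal Euler update", {
  pos <- fixture_positions(6)
  model <- ensemble_model(10, 1, 0, gaussian_kernel(pos, 0.2, 0.6))
  V <- c(0.1, -0.2, 0.3, 0, 0.05, -0.1)
  U <- rep(0.02, 6)
  expected <- V + 0.5 * (-V / 10 +
    as.vector(model$kernel$matrix %*% transfer_function(V, 1, 0)) + U)
  expect_equal(step_field(V, model, U = U, dt_ms = 0.5), expected)
})

test_that("zero boundary potential reproduces the non-ephaptic step bit for bit", {
  pos <- fixture_positions(6)
  model <- ensemble_model(10, 1, 0, gaussian_kernel(pos, 0.2, 0.6))
  V <- rnorm(6)
  expect_identical(step_field(V, model, V0e = rep(0, 6), dt_ms = 1),
                   step_field(V, model, dt_ms = 1))
})

test_that("centered stepping keeps the baseline an exact fixed point", {
  pos <- fixture_positions(6)
  model <- ensemble_model(10, 1, 0, gaussian_kernel(pos, 0.2, 0.6))
  V <- rep(0, 6)
  expect_identical(step_field(V, model, dt_ms = 1, center = TRUE), V)
})

test_that("linear stability matches the scalar analytic criterion", {
  # single channel: eigenvalue is -1/tau + f'(0) * K
  m <- ensemble_model(20, 1, 0, matrix(0.15, 1, 1))
  st <- is_stable(m)
  expect_equal(st$leading_eigenvalue, -1 / 20 + 0.25 * 0.15, tolerance = 1e-12)
  expect_true(st$stable)
  m2 <- ensemble_model(20, 1, 0, matrix(0.5, 1, 1))
  expect_false(is_stable(m2)$stable)
})

test_that("derivative matrix is exact on quadratics, including boundaries", {
  x <- c(0, 0.3, 0.7, 1.2, 1.6, 2.3)  # non-uniform
  D <- engramfield:::deriv_matrix(x)
  q <- 3 * x^2 - 2 * x + 5
  expect_equal(as.vector(D %*% q), 6 * x - 2, tolerance = 1e-10)
  D2 <- engramfield:::deriv_matrix(fixture_positions(9))
  expect_equal(as.vector(D2 %*% rep(1, 9)), rep(0, 9), tolerance = 1e-12)
})

test_that("spatial axes are successive derivatives of the mean profile", {
  pos <- fixture_positions(10)
  Vm <- outer(sin(pi * pos), c(1, 0.5, 0.25))   # channels x time
  ax <- spatial_axes(Vm, pos, order_J = 2)
  expect_length(ax, 3)
  expect_equal(ax[[1]], Vm)
  D <- engramfield:::deriv_matrix(pos)
  expect_equal(ax[[2]], D %*% Vm)
  expect_equal(ax[[3]], D %*% (D %*% Vm))
})

test_that("GLM decomposition removes the across-trial mean and keeps axes", {
  rec <- fixture_recording()
  dec <- glm_decompose(rec, order_J = 3)
  expect_s3_class(dec, "glm_decomposition")
  expect_equal(dim(dec$Y), dim(rec$data))
  expect_equal(apply(dec$Y, c(2, 3), mean),
               matrix(0, dim(rec$data)[2], dim(rec$data)[3]),
               tolerance = 1e-12)
  expect_length(dec$axes, 4)
  # single trial carries no across-trial deviations
  one <- lfp_recording(rec$data[1, , , drop = FALSE], rec$time_step_ms,
                       rec$channel_positions_mm, rec$trials[1, ])
  expect_error(glm_decompose(one), "trial")
})

test_that("configuration hash matches the FNV-1a reference value", {
  # standard FNV-1a 32-bit test vector
  expect_identical(engramfield:::fnv1a32("a"), "e40c292c")
  expect_identical(engramfield:::fnv1a32(""), "811c9dc5")
  expect_identical(engramfield:::fnv1a32("hello"), engramfield:::fnv1a32("hello"))
  expect_false(engramfield:::fnv1a32("hello") == engramfield:::fnv1a32("hellp"))
})

test_that("derived seeds are valid, deterministic, and leave the RNG alone", {
  s1 <- engramfield:::derive_seeds(99, 5)
  s2 <- engramfield:::derive_seeds(99, 5)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 < 2^31))
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(engramfield:::derive_seeds(7, 3)); after <- rnorm(1)
  expect_identical(before, after)
})
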