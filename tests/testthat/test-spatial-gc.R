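test_that("GC strength is a log RSS ratio matching the lm/anova oracle", {
  set.seed(41)
  n <- 40; p <- 2
  src <- as.vector(arima.sim(list(ar = 0.5), n))
  tgt <- as.vector(stats::filter(0.4 * c(0, src[-n]) + rnorm(n, sd = 0.5),
                                 0.3, method = "recursive"))
  st <- gc_strength(tgt, src, p = p)
  y <- tgt[(p + 1):n]
  l1t <- tgt[2:(n - 1)][-(1:(p - 1))]; l2t <- tgt[1:(n - 2)]
  l1s <- src[2:(n - 1)][-(1:(p - 1))]; l2s <- src[1:(n - 2)]
  fit_r <- lm(y ~ tgt[(p):(n - 1)] + tgt[1:(n - p)])
  fit_f <- lm(y ~ tgt[(p):(n - 1)] + tgt[1:(n - p)] +
                src[(p):(n - 1)] + src[1:(n - p)])
  expect_equal(st, log(sum(resid(fit_r)^2) / sum(resid(fit_f)^2)),
               tolerance = 1e-10)
  # F-test p-value agrees with the nested-model anova
  expect_equal(gc_significance(st, n_obs = n - p, p = p),
               anova(fit_r, fit_f)$`Pr(>F)`[2], tolerance = 1e-10)
  expect_gte(st, 0)
})

test_that("GC strength validates its inputs", {
  expect_error(gc_strength(1:10, 1:9), "same spatial grid")
  expect_error(gc_strength(1:10, 10:1, p = 0), ">= 1")
  expect_error(gc_strength(1:4, c(2, 1, 4, 3)), "too short")
  expect_error(gc_strength(rep(1, 20), rep(2, 20)), "rank-deficient")
  expect_error(gc_significance(0.5, n_obs = 3, p = 1), "insufficient")
})

test_that("order selection recovers a spatial AR(2) under all criteria", {
  set.seed(42)
  gen <- function() {
    t(replicate(8, as.vector(arima.sim(list(ar = c(0.5, -0.35)), 60))))
  }
  a <- gen(); b <- gen()
  expect_identical(select_order(a, b, max_order = 4, criterion = "BIC"), 2L)
  expect_identical(select_order(a, b, max_order = 4, criterion = "AIC"), 2L)
  expect_identical(select_order(a, b, max_order = 4, criterion = "CV"), 2L)
  expect_error(select_order(a, b, max_order = 25), "n_points")
  expect_error(select_order(matrix(1, 3, 30), b[, 1:30]), "constant")
})

test_that("coefficient of variation matches the hand value and rejects zero mean", {
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("directed coupling is detected in the coupled direction", {
  pair <- make_coupled_spatial_pair(64, "a_to_b", coupling = 0.8,
                                    n_snapshots = 30, seed = 7)
  gc <- gc_over_time(snapshot_series(pair$a, "field"),
                     snapshot_series(pair$b, "activity"), p = 1)
  expect_s3_class(gc$field_to_activity, "gc_result")
  expect_named(gc$field_to_activity$table,
               c("snapshot", "strength", "p_value", "significant"))
  expect_equal(nrow(gc$field_to_activity$table), 30)
  expect_gt(gc$field_to_activity$mean_strength,
            gc$activity_to_field$mean_strength)
  expect_gt(gc$field_to_activity$prop_significant, 0.9)
  td <- tidy(gc$field_to_activity)
  expect_true(all(c("source", "target", "order_p") %in% names(td)))
  gl <- glance(gc$field_to_activity)
  expect_identical(gl$source, "field")
  expect_identical(gl$target, "activity")
})

test_that("orientation handling reverses or averages the spatial axis", {
  pair <- make_coupled_spatial_pair(48, "a_to_b", coupling = 0.8,
                                    n_snapshots = 6, seed = 8)
  fl <- gc_over_time(pair$a, pair$b, orientation = "left")
  fr <- gc_over_time(pair$a, pair$b, orientation = "right")
  fb <- gc_over_time(pair$a, pair$b, orientation = "both")
  expect_equal(fb$field_to_activity$table$strength,
               (fl$field_to_activity$table$strength +
                  fr$field_to_activity$table$strength) / 2, tolerance = 1e-12)
  # explicit reversal oracle for one snapshot
  expect_equal(fr$field_to_activity$table$strength[1],
               gc_strength(rev(pair$b[1, ]), rev(pair$a[1, ]), p = 1),
               tolerance = 1e-12)
})

test_that("BH adjustment never lowers a p-value", {
  pair <- make_coupled_spatial_pair(48, "none", n_snapshots = 12, seed = 9)
  raw <- gc_over_time(pair$a, pair$b, p_adjust = "none")
  adj <- gc_over_time(pair$a, pair$b, p_adjust = "BH")
  expect_true(all(adj$field_to_activity$table$p_value >=
                    raw$field_to_activity$table$p_value - 1e-12))
})

test_that("independent profiles yield a near-nominal false-positive rate", {
  pair <- make_coupled_spatial_pair(64, "none", n_snapshots = 200, seed = 10)
  gc <- gc_over_time(pair$a, pair$b, alpha = 0.05)
  rate <- mean(c(gc$field_to_activity$table$significant,
                 gc$activity_to_field$table$significant))
  expect_lt(rate, 0.12)
})

test_that("significance windows correlate with axis magnitudes as cor.test does", {
  set.seed(43)
  mask <- rbinom(40, 1, 0.4)
  axes <- list(H0 = matrix(rnorm(8 * 40), 8, 40),
               H1 = matrix(rnorm(8 * 40), 8, 40))
  out <- window_axis_correlation(mask, axes)
  expect_named(out, c("axis", "correlation", "p_value", "significant"))
  ct <- cor.test(as.numeric(mask), colMeans(abs(axes$H1)))
  expect_equal(out$correlation[out$axis == "H1"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(out$p_value[out$axis == "H1"], ct$p.value, tolerance = 1e-12)
  expect_error(window_axis_correlation(rep(1, 40), axes), "constant")
})
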