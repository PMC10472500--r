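# Snapshot-based ("spatial") Granger causality: because field-activity
# interactions are effectively instantaneous in time, directed interactions
# are assessed within single-time-point snapshots by regressing over the
# spatial sample index, with the patch arbitrarily oriented left-to-right.

# lagged spatial design: rows are positions p+1..n, columns the p lags
spatial_lags <- function(v, p) {
  n <- length(v)
  out <- matrix(0, n - p, p)
  for (j in seq_len(p)) out[, j] <- v[(p + 1 - j):(n - j)]
  out
}

#' Spatial Granger-causality strength between two profiles
#'
#' Fits, by least squares over the interior points of one snapshot, the
#' restricted regression of the target profile on its own `p` spatial lags
#' and the full regression that adds the source profile's `p` spatial lags,
#' and returns the log generalized-variance ratio
#' `F_{source -> target} = ln(RSS_restricted / RSS_full)` (non-negative up to
#' numerical noise). Both regressions include an intercept.
#'
#' @param target,source numeric profiles on the same spatial grid.
#' @param p spatial lag order (>= 1).
#' @return the GC strength (scalar).
#' @export
gc_strength <- function(target, source, p = 1) {
  if (length(target) != length(source)) {
    stop("target and source must be on the same spatial grid", call. = FALSE)
  }
  if (p < 1) stop("lag order p must be >= 1", call. = FALSE)
  n <- length(target)
  if (n - p <= 2 * p + 1) stop("profile too short for this lag order", call. = FALSE)
  y <- target[(p + 1):n]
  Xr <- cbind(1, spatial_lags(target, p))
  Xf <- cbind(Xr, spatial_lags(source, p))
  if (qr(Xf)$rank < ncol(Xf)) {
    stop("rank-deficient spatial design (constant or collinear profiles)", call. = FALSE)
  }
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  log(rss(Xr) / rss(Xf))
}

#' F-test significance of a spatial GC strength
#'
#' Converts a GC strength (log RSS ratio) into the nested-regression F
#' statistic `((RSS_r - RSS_f) / p) / (RSS_f / (n_obs - 2p - 1))` with
#' `(p, n_obs - 2p - 1)` degrees of freedom, and returns its upper-tail
#' p-value. `n_obs` is the number of regression rows (spatial points minus
#' `p`).
#'
#' @param strength GC strength from [gc_strength()].
#' @param n_obs number of observations entering the regressions.
#' @param p spatial lag order.
#' @return the p-value.
#' @export
gc_significance <- function(strength, n_obs, p = 1) {
  df2 <- n_obs - 2 * p - 1
  if (df2 <= 0) stop("insufficient observations: need n_obs > 2p + 1", call. = FALSE)
  ratio <- exp(strength)
  Fstat <- (ratio - 1) * df2 / p
  stats::pf(Fstat, p, df2, lower.tail = FALSE)
}

#' Spatial lag-order selection
#'
#' Chooses the spatial VAR lag order by pooling all snapshots: for each
#' candidate order the own-lag regressions of both series (rows
#' `max_order + 1 .. n` of every snapshot, for comparability) are fit and the
#' information criterion of the pooled residual sums is minimized. `"CV"`
#' uses leave-one-snapshot-out prediction error instead.
#'
#' @param a,b matrices of snapshots (`n_snapshots x n_points`).
#' @param max_order largest order considered (must satisfy
#'   `max_order < n_points / 3`).
#' @param criterion `"BIC"` (default), `"AIC"`, or `"CV"`.
#' @return the selected order.
#' @export
select_order <- function(a, b, max_order = 4, criterion = c("BIC", "AIC", "CV")) {
  criterion <- match.arg(criterion)
  a <- as.matrix(a); b <- as.matrix(b)
  n_pts <- ncol(a)
  if (max_order >= n_pts / 3) stop("max_order must be < n_points / 3", call. = FALSE)
  if (max_order < 1) stop("max_order must be >= 1", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) stop("degenerate (constant) series", call. = FALSE)
  keep <- (max_order + 1):n_pts
  score <- function(p) {
    sc <- 0
    for (series in list(a, b)) {
      ys <- as.vector(t(series[, keep, drop = FALSE]))
      X <- do.call(rbind, lapply(seq_len(nrow(series)), function(s) {
        sl <- spatial_lags(series[s, ], max_order)
        cbind(1, sl[, seq_len(p), drop = FALSE])
      }))
      n <- length(ys); k <- ncol(X)
      if (criterion == "CV") {
        err <- 0
        for (s in seq_len(nrow(series))) {
          test_rows <- ((s - 1) * length(keep) + 1):(s * length(keep))
          fit <- stats::lm.fit(X[-test_rows, , drop = FALSE], ys[-test_rows])
          err <- err + sum((ys[test_rows] - X[test_rows, , drop = FALSE] %*% fit$coefficients)^2)
        }
        sc <- sc + err
      } else {
        rss <- sum(stats::lm.fit(X, ys)$residuals^2)
        pen <- if (criterion == "BIC") k * log(n) else 2 * k
        sc <- sc + n * log(rss / n) + pen
      }
    }
    sc
  }
  cand <- seq_len(max_order)
  cand[which.min(vapply(cand, score, numeric(1)))]
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(values) / mean(values)` with the sample standard deviation; used
#' to compare the temporal stability of directed interaction strengths.
#'
#' @param values numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || abs(m) < .Machine$double.eps * max(1, max(abs(values)))) {
    stop("coefficient of variation undefined for zero mean", call. = FALSE)
  }
  100 * stats::sd(values) / m
}

#' Snapshot series container
#'
#' @param values `n_snapshots x n_points` matrix, one spatial profile per
#'   time point.
#' @param label `"field"` or `"activity"` (or any identifier).
#' @param area optional area identifier.
#' @return a `snapshot_series` object.
#' @export
snapshot_series <- function(values, label = "activity", area = NULL) {
  values <- as.matrix(values)
  check_finite(values, "snapshot values")
  structure(list(values = values, label = label, area = area),
            class = "snapshot_series")
}

as_snapshot_matrix <- function(x) {
  if (inherits(x, "snapshot_series")) x$values else as.matrix(x)
}

#' Per-snapshot spatial GC in both directions
#'
#' Computes, for every snapshot (time point), the spatial GC strength and
#' F-test p-value in both directions between two snapshot series, with
#' significance masks at level `alpha` and coefficient-of-variation summaries
#' of the strengths.
#'
#' @param field,activity [snapshot_series()] objects (or plain matrices) with
#'   matched snapshot counts and grids. Names reflect the canonical use; any
#'   pair of series works.
#' @param p spatial lag order (default 1).
#' @param alpha significance level for the masks (default 0.05).
#' @param orientation `"left"` (default) processes profiles as given,
#'   `"right"` reverses them, `"both"` averages the strengths of the two
#'   orientations (p-values from the mean strength).
#' @param p_adjust optional multiple-testing adjustment across snapshots
#'   (`"none"` default, or `"BH"`).
#' @return list with two `gc_result` objects, `field_to_activity` and
#'   `activity_to_field`.
#' @export
gc_over_time <- function(field, activity, p = 1, alpha = 0.05,
                         orientation = c("left", "right", "both"),
                         p_adjust = c("none", "BH")) {
  orientation <- match.arg(orientation)
  p_adjust <- match.arg(p_adjust)
  A <- as_snapshot_matrix(field)
  Bm <- as_snapshot_matrix(activity)
  if (!all(dim(A) == dim(Bm))) stop("mismatched snapshot grids", call. = FALSE)
  lab_f <- if (inherits(field, "snapshot_series")) field$label else "field"
  lab_a <- if (inherits(activity, "snapshot_series")) activity$label else "activity"
  n_obs <- ncol(A) - p
  one_direction <- function(src, tgt, direction) {
    strengths <- vapply(seq_len(nrow(src)), function(s) {
      st <- switch(orientation,
        left = gc_strength(tgt[s, ], src[s, ], p),
        right = gc_strength(rev(tgt[s, ]), rev(src[s, ]), p),
        both = mean(c(gc_strength(tgt[s, ], src[s, ], p),
                      gc_strength(rev(tgt[s, ]), rev(src[s, ]), p))))
      st
    }, numeric(1))
    pvals <- gc_significance(strengths, n_obs, p)
    if (p_adjust == "BH") pvals <- stats::p.adjust(pvals, method = "BH")
    tbl <- tibble::tibble(snapshot = seq_len(nrow(src)),
                          strength = strengths, p_value = pvals,
                          significant = pvals < alpha)
    structure(
      list(table = tbl, direction = direction, order_p = p, alpha = alpha,
           cv_percent = if (abs(mean(strengths)) > 0) coefficient_of_variation(strengths) else NA_real_,
           mean_strength = mean(strengths),
           prop_significant = mean(tbl$significant)),
      class = "gc_result"
    )
  }
  list(
    field_to_activity = one_direction(A, Bm, c(lab_f, lab_a)),
    activity_to_field = one_direction(Bm, A, c(lab_a, lab_f))
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> %s -> %s | mean strength %.3f, CV %.1f%%, %d/%d significant at alpha = %g\n",
              x$direction[1], x$direction[2], x$mean_strength, x$cv_percent,
              sum(x$table$significant), nrow(x$table), x$alpha))
  invisible(x)
}

#' @method tidy gc_result
#' @export
tidy.gc_result <- function(x, ...) {
  dplyr::mutate(x$table,
                source = x$direction[1], target = x$direction[2],
                order_p = x$order_p)
}

#' @method glance gc_result
#' @export
glance.gc_result <- function(x, ...) {
  tibble::tibble(source = x$direction[1], target = x$direction[2],
                 mean_strength = x$mean_strength, cv_percent = x$cv_percent,
                 prop_significant = x$prop_significant,
                 n_snapshots = nrow(x$table), order_p = x$order_p)
}

#' Correlate significant-GC epochs with principal-axis magnitudes
#'
#' Tests whether the time windows of significant directed field interactions
#' follow the neural dynamics: Pearson correlation between the 0/1
#' significance mask over snapshots and the magnitude time course of each
#' principal axis (axis collapsed to `mean(abs(.))` over channels), with a
#' two-sided p-value per axis.
#'
#' @param mask logical or 0/1 vector over snapshots (must not be constant).
#' @param axes list of principal-axis matrices (channels x time), e.g. from
#'   [spatial_axes()]; time length must match `mask`.
#' @param alpha significance level used for the `significant` flag.
#' @return tibble with `axis`, `correlation`, `p_value`, `significant`.
#' @export
window_axis_correlation <- function(mask, axes, alpha = 0.05) {
  mask <- as.numeric(mask)
  if (sd(mask) == 0) {
    stop("mask is constant (all significant or none): correlation undefined", call. = FALSE)
  }
  purrr::imap_dfr(axes, function(H, nm) {
    mag <- colMeans(abs(as.matrix(H)))
    if (length(mag) != length(mask)) {
      stop("axis time course length must match mask length", call. = FALSE)
    }
    ct <- stats::cor.test(mask, mag)
    tibble::tibble(axis = nm, correlation = unname(ct$estimate),
                   p_value = ct$p.value, significant = ct$p.value < alpha)
  })
}
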