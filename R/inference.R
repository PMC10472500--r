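# Restricted maximum-likelihood fitting of the Gaussian linear reformulation
# of the neural field model, with the Free-Energy objective, and Bayesian
# model comparison between the ephaptic and non-ephaptic generative models.

#' Free Energy of a Gaussian linear model
#'
#' The ReML objective (log model evidence, up to the shared `n ln 2*pi`
#' constant, which is fixed to 0 and cancels in every Bayes-factor
#' difference) for `Y = H w + e`, `e ~ N(0, s_s^2 I)`, with a unit Gaussian
#' prior on the coefficients:
#'
#' `F = -1/2 [ (Y - Hw)'(Y - Hw) / s_s^2 + w'w + (n - p) ln(s_s^2) + ln|Pi| ]`
#'
#' with `Pi = s_s^2 I + H'H` the (unnormalized) posterior precision and
#' `Z = Pi^-1 H' Y` the posterior projection of the data. At `w = Z` this is
#' exactly the marginal likelihood `ln N(Y; 0, s_s^2 I + H H')`; with a `w`
#' estimated on other data it evaluates that model's held-out evidence. The
#' accuracy term rewards fit; the `w'w` and log-determinant terms penalize
#' complexity (each additional effective direction costs
#' `ln(1 + lambda / s_s^2)`).
#'
#' @param Y response vector.
#' @param H design matrix (rows match `Y`).
#' @param w coefficient vector.
#' @param s_s residual standard deviation (> 0).
#' @return list with `F`, `accuracy` (the residual term, negated and halved),
#'   `complexity` (so that `F = accuracy - complexity`), `Pi`, `Z`.
#' @export
free_energy <- function(Y, H, w, s_s) {
  Y <- as.vector(Y); H <- as.matrix(H)
  if (s_s <= 0) stop("s_s must be positive", call. = FALSE)
  if (nrow(H) != length(Y) || ncol(H) != length(w)) {
    stop("inconsistent shapes for Y, H, w", call. = FALSE)
  }
  s2 <- s_s^2
  n <- length(Y)
  p <- ncol(H)
  Pi <- s2 * diag(p) + crossprod(H)
  ch <- tryCatch(chol(Pi), error = function(e) {
    stop(sprintf("Pi is numerically singular (reciprocal condition ~ %.3g)",
                 rcond_sym(Pi)), call. = FALSE)
  })
  logdet_Pi <- 2 * sum(log(diag(ch)))
  Z <- backsolve(ch, forwardsolve(t(ch), crossprod(H, Y)))
  resid <- Y - H %*% w
  accuracy_term <- sum(resid^2) / s2
  complexity_term <- sum(w^2) + (n - p) * log(s2) + logdet_Pi
  list(F = -0.5 * (accuracy_term + complexity_term),
       accuracy = -0.5 * accuracy_term,
       complexity = 0.5 * complexity_term,
       Pi = Pi, Z = as.vector(Z))
}

rcond_sym <- function(M) {
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  min(abs(ev)) / max(abs(ev))
}

#' Fit a Gaussian linear model by ReML on the Free-Energy objective
#'
#' Coordinate ascent on [free_energy()]: (i) exact update of the coefficients
#' `w` given the residual variance -- the maximizer of `F` in `w` is the
#' posterior mean `(s_s^2 I + H'H)^-1 H'Y` -- then (ii) a one-dimensional
#' numerical maximization of `F` over `log(s_s^2)` given `w`, bracketed
#' around the residual-variance value `RSS / n`. Each half-step can only
#' increase `F`, so `F` is non-decreasing across iterations; iteration stops
#' when the change in `F` drops below `tol` or `max_iter` is reached
#' (non-convergence is flagged, not an error).
#'
#' @param x a `glm_decomposition` (per-channel block fits, summed Free
#'   Energy) or a numeric response vector.
#' @param ... passed to methods.
#' @return a `reml_result`; for the decomposition method the object also
#'   carries the fitted per-order connectivity `components`.
#' @export
reml_fit <- function(x, ...) UseMethod("reml_fit")

#' @rdname reml_fit
#' @param H design matrix for the default method.
#' @param tol convergence tolerance on the change in `F` (default 1e-8).
#' @param max_iter maximum number of iterations.
#' @export
reml_fit.default <- function(x, H, tol = 1e-8, max_iter = 50, ...) {
  Y <- as.vector(x); H <- as.matrix(H)
  n <- length(Y); p <- ncol(H)
  if (nrow(H) != n) stop("nrow(H) must match length(Y)", call. = FALSE)
  G <- crossprod(H)
  HtY <- crossprod(H, Y)
  ridge <- 1e-12 * mean(diag(G))
  w <- solve(G + ridge * diag(p), HtY)             # LS start
  s2 <- max(sum((Y - H %*% w)^2) / n, 1e-300)
  if (s2 == 1e-300) s2 <- max(mean(Y^2), 1e-12)  # perfectly noiseless fit
  f_of <- function(log_s2, w) free_energy(Y, H, w, sqrt(exp(log_s2)))$F
  F_old <- f_of(log(s2), w)
  n_iter <- 0L
  converged <- FALSE
  F_trace <- F_old
  repeat {
    n_iter <- n_iter + 1L
    # exact F-maximizer in w at fixed s2: the posterior mean
    w <- solve(s2 * diag(p) + G, HtY)
    rss <- sum((Y - H %*% w)^2)
    centre <- log(max(rss / n, 1e-300))
    opt <- stats::optimize(f_of, interval = c(centre - 8, centre + 8),
                           w = w, maximum = TRUE, tol = 1e-10)
    # keep the better of the closed-form residual variance and the 1-D optimum
    cand <- c(opt$maximum, centre, log(s2))
    vals <- vapply(cand, f_of, numeric(1), w = w)
    s2 <- exp(cand[which.max(vals)])
    F_new <- max(vals)
    F_trace <- c(F_trace, F_new)
    if (abs(F_new - F_old) < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
    F_old <- F_new
  }
  fe <- free_energy(Y, H, w, sqrt(s2))
  structure(
    list(components = as.vector(w), noise_precision = 1 / s2,
         s_s = sqrt(s2), projection = fe$Z, posterior_cov_factor = fe$Pi,
         free_energy = fe$F, complexity = fe$complexity,
         F_trace = F_trace, n_iter = n_iter, converged = converged,
         n_obs = n, n_par = p),
    class = "reml_result"
  )
}

#' @rdname reml_fit
#' @export
reml_fit.glm_decomposition <- function(x, tol = 1e-8, max_iter = 50, ...) {
  dims <- dim(x$Y)
  n_trials <- dims[1]; n_ch <- dims[2]; n_time <- dims[3]
  J1 <- x$order_J + 1
  comp <- matrix(NA_real_, n_ch, J1,
                 dimnames = list(NULL, paste0("w", 0:x$order_J)))
  F_total <- 0; C_total <- 0
  s2_all <- numeric(n_ch)
  converged <- TRUE
  for (c_idx in seq_len(n_ch)) {
    # stack trials: response is the demeaned trial data at this channel,
    # regressors the axes' time courses at this channel (common over trials)
    Xc <- vapply(x$axes, function(h) h[c_idx, ], numeric(n_time))
    H <- Xc[rep(seq_len(n_time), times = n_trials), , drop = FALSE]
    Y <- as.vector(t(x$Y[, c_idx, ]))          # time fastest within trial
    fit <- reml_fit.default(Y, H, tol = tol, max_iter = max_iter)
    comp[c_idx, ] <- fit$components
    F_total <- F_total + fit$free_energy
    C_total <- C_total + fit$complexity
    s2_all[c_idx] <- 1 / fit$noise_precision
    converged <- converged && fit$converged
  }
  x$components <- lapply(seq_len(J1), function(j) comp[, j])
  names(x$components) <- colnames(comp)
  x$noise_precision <- 1 / mean(s2_all)
  x$free_energy <- F_total
  structure(
    list(components = x$components, noise_precision = x$noise_precision,
         free_energy = F_total, complexity = C_total,
         per_channel_s2 = s2_all, converged = converged,
         decomposition = x),
    class = c("reml_result_glm", "reml_result")
  )
}

#' @export
print.reml_result <- function(x, ...) {
  cat(sprintf("<reml_result> F = %.4f, %s\n", x$free_energy,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @method tidy reml_result
#' @export
tidy.reml_result <- function(x, ...) {
  if (inherits(x, "reml_result_glm")) {
    purrr::imap_dfr(x$components, function(w, nm) {
      tibble::tibble(order = as.integer(sub("^w", "", nm)),
                     channel = seq_along(w), estimate = w)
    })
  } else {
    tibble::tibble(term = paste0("w", seq_along(x$components) - 1),
                   estimate = x$components)
  }
}

#' @method glance reml_result
#' @export
glance.reml_result <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 complexity = x$complexity %||% NA_real_,
                 noise_precision = x$noise_precision,
                 converged = isTRUE(x$converged))
}

#' Signed log Bayes factor between the ephaptic and non-ephaptic models
#'
#' `BF = F_non_ephaptic - F_ephaptic` on the log-evidence-difference scale:
#' positive values favour the non-ephaptic model, negative values the ephaptic
#' model, and magnitudes above 3 are treated as decisive.
#'
#' @param F_ephaptic Free Energy of the ephaptic fit.
#' @param F_non_ephaptic Free Energy of the non-ephaptic fit.
#' @return the signed (log) Bayes factor.
#' @export
bayes_factor <- function(F_ephaptic, F_non_ephaptic) {
  stopifnot(is.finite(F_ephaptic), is.finite(F_non_ephaptic))
  F_non_ephaptic - F_ephaptic
}

#' Decisive-threshold winner label for a mean Bayes factor
#'
#' `"ephaptic"` if `mean_bf < -threshold`, `"non_ephaptic"` if
#' `mean_bf > threshold`, otherwise `"inconclusive"` (strict inequalities).
#'
#' @param mean_bf signed (log) Bayes factor(s).
#' @param threshold decisiveness bound (default 3).
#' @return character vector of winner labels.
#' @export
bf_winner <- function(mean_bf, threshold = 3) {
  dplyr::case_when(mean_bf < -threshold ~ "ephaptic",
                   mean_bf > threshold ~ "non_ephaptic",
                   TRUE ~ "inconclusive")
}

# Build the drive-regression design for one trial: response is the Euler
# increment of V, regressors are the leak term plus spatial derivatives
# (orders 0..J) of the centred transfer output; the ephaptic variant appends
# spatial derivatives of f'(V) * V0e (the linearised ephaptic current).
# Returns per-channel lists of response vectors and design matrices.
drive_design_trial <- function(V, dt, positions, gain, threshold, order_J,
                               B = NULL) {
  n_ch <- nrow(V); n_time <- ncol(V)
  f0 <- transfer_function(0, gain, threshold)
  Vt <- V[, -n_time, drop = FALSE]                       # state at t
  resp <- (V[, -1, drop = FALSE] - Vt) / dt              # Euler increment
  g <- transfer_function(Vt, gain, threshold) - f0
  ops <- deriv_matrix_powers(positions, order_J)
  cols <- c(list(leak = Vt), lapply(ops, function(D) D %*% g))
  names(cols) <- c("leak", paste0("g", 0:order_J))
  if (!is.null(B)) {
    Ve <- B %*% Vt
    ge <- transfer_function_deriv(Vt, gain, threshold) * Ve
    eph <- lapply(ops, function(D) D %*% ge)
    names(eph) <- paste0("e", 0:order_J)
    cols <- c(cols, eph)
  }
  list(response = resp, columns = cols, n_obs = n_time - 1, n_ch = n_ch)
}

#' Bayesian model comparison: ephaptic vs non-ephaptic neural field model
#'
#' Compares the two generative models on a multi-trial recording via the
#' Free-Energy approximation to the log evidence. Both models are expressed
#' as Gaussian linear drive regressions (the kernel-moment expansion of the
#' recurrent term into spatial-derivative regressors); the ephaptic variant
#' augments the design with the field regressors `f'(V) * V0e` and their
#' spatial derivatives, where `V0e` is the boundary extracellular potential
#' from the bidomain operator. Per cue angle, trials are split (seeded) into
#' a training half used to fit coefficients and residual variance and a
#' held-out half on which per-trial Free Energies and Bayes factors are
#' evaluated, avoiding data leakage.
#'
#' @param rec an [lfp_recording()] with at least 2 trials per angle.
#' @param field_cfg a [bidomain_params()] object used to form the ephaptic
#'   regressor (the field is computed once per trial from the trial data).
#' @param order_J maximum spatial-derivative order in the designs (default 4).
#' @param train_fraction fraction of trials per angle used for fitting
#'   (default 0.5).
#' @param seed seed for the train/test split.
#' @param bf_threshold decisiveness threshold on the mean Bayes factor
#'   (default 3).
#' @return a `model_comparison` object: tibbles `bf_per_trial` and
#'   `by_angle` (mean BF, complexity difference, winner per angle), the
#'   overall `mean_bf` and `winner` (sign of the mean BF).
#' @export
compare_models <- function(rec, field_cfg, order_J = 4, train_fraction = 0.5,
                           seed = 1, bf_threshold = 3) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(field_cfg) || !inherits(field_cfg, "bidomain_params")) {
    stop("field_cfg must be a bidomain_params object (missing field parameters)",
         call. = FALSE)
  }
  counts <- table(rec$trials$cue_angle_deg)
  if (any(counts < 2)) stop("need at least 2 trials per cue angle", call. = FALSE)
  positions <- rec$channel_positions_mm
  dt <- rec$time_step_ms
  B <- bidomain_operator(positions, field_cfg, y = field_cfg$a_mm)
  # transfer parameters: taken from provenance when available, else defaults
  gain <- 1; threshold <- 0
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  rows <- list()
  for (ang in sort(unique(rec$trials$cue_angle_deg))) {
    idx <- which(rec$trials$cue_angle_deg == ang)
    n_tr <- length(idx)
    n_train <- max(1, floor(train_fraction * n_tr))
    if (n_train >= n_tr) n_train <- n_tr - 1
    train <- sort(sample(idx, n_train))
    test <- setdiff(idx, train)
    designs <- lapply(idx, function(i) {
      drive_design_trial(rec$data[i, , ], dt, positions, gain, threshold,
                         order_J, B = B)
    })
    names(designs) <- as.character(idx)
    n_ch <- designs[[1]]$n_ch
    col_names <- names(designs[[1]]$columns)
    # within-angle demeaning, per (channel, time) sample; the mean is taken
    # over the training trials only so held-out evaluation stays out-of-sample.
    # With a single training trial demeaning would zero that trial exactly
    # (and make the fit singular), so the evoked mean is left in place then.
    mean_of <- function(extract) {
      if (length(train) < 2) return(0 * extract(designs[[1]]))
      Reduce(`+`, lapply(as.character(train), function(i) extract(designs[[i]]))) /
        length(train)
    }
    resp_mean <- mean_of(function(d) d$response)
    col_means <- lapply(col_names, function(nm) mean_of(function(d) d$columns[[nm]]))
    names(col_means) <- col_names
    ne_cols <- c("leak", paste0("g", 0:order_J))
    eph_cols <- col_names
    fit_eval <- function(which_cols) {
      # connectivity components are global (kernel moments), so one shared
      # coefficient vector is fit over all channels and training trials,
      # then each held-out trial contributes one Free Energy
      get_H <- function(i) {
        vapply(which_cols, function(nm) {
          as.vector(t(designs[[as.character(i)]]$columns[[nm]] -
                        col_means[[nm]]))
        }, numeric(n_ch * designs[[1]]$n_obs))
      }
      get_Y <- function(i) {
        as.vector(t(designs[[as.character(i)]]$response - resp_mean))
      }
      H_train <- do.call(rbind, lapply(train, get_H))
      Y_train <- unlist(lapply(train, get_Y))
      G <- crossprod(H_train)
      HtY <- crossprod(H_train, Y_train)
      ridge <- 1e-10 * mean(diag(G))
      w <- solve(G + ridge * diag(ncol(G)), HtY)
      s2 <- max(sum((Y_train - H_train %*% w)^2) / length(Y_train), 1e-12)
      # posterior-mean refinement consistent with the evidence's unit prior
      w <- solve(s2 * diag(ncol(G)) + G, HtY)
      s2 <- max(sum((Y_train - H_train %*% w)^2) / length(Y_train), 1e-12)
      F_test <- numeric(length(test))
      C_test <- numeric(length(test))
      for (ti in seq_along(test)) {
        fe <- free_energy(get_Y(test[ti]), get_H(test[ti]), w, sqrt(s2))
        F_test[ti] <- fe$F
        C_test[ti] <- fe$complexity
      }
      list(F = F_test, complexity = C_test)
    }
    ne <- fit_eval(ne_cols)
    ep <- fit_eval(eph_cols)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cue_angle_deg = ang, trial_id = rec$trials$trial_id[test],
      F_ephaptic = ep$F, F_non_ephaptic = ne$F,
      bf = bayes_factor(ep$F, ne$F),
      complexity_diff = ep$complexity - ne$complexity
    )
  }
  per_trial <- dplyr::bind_rows(rows)
  by_angle <- per_trial |>
    dplyr::group_by(.data$cue_angle_deg) |>
    dplyr::summarise(mean_bf = mean(.data$bf),
                     mean_complexity_diff = mean(.data$complexity_diff),
                     n_test_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(winner = bf_winner(.data$mean_bf, bf_threshold))
  mean_bf <- mean(per_trial$bf)
  structure(
    list(bf_per_trial = per_trial, by_angle = by_angle,
         mean_bf = mean_bf,
         winner = if (mean_bf < 0) "ephaptic" else "non_ephaptic",
         bf_threshold = bf_threshold,
         posterior_prob_winner = 1 / (1 + exp(-abs(mean_bf)))),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> overall mean BF = %.3f (positive favours non-ephaptic)\n",
              x$mean_bf))
  print(x$by_angle)
  invisible(x)
}

#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$by_angle

#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(mean_bf = x$mean_bf, winner = x$winner,
                 n_trials = nrow(x$bf_per_trial),
                 posterior_prob_winner = x$posterior_prob_winner)
}
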