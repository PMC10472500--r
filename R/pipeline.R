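# End-to-end orchestration: simulate two coupled cortical areas, estimate
# extracellular fields, run Bayesian model comparison, snapshot Granger
# causality, representational similarity analysis, and the two-area
# stability (engram) condition, collecting everything in a run report.

pipeline_schema_version <- "1"

area_keys <- c("n_trials", "n_channels", "delay_ms", "time_step_ms",
               "cue_angles_deg", "span_mm", "input_amplitude",
               "input_width_mm", "input_dur_ms", "ephaptic", "coupling",
               "kernel", "kernel_a0", "kernel_a2", "tau_ms", "noise_sd")

# keys consumed by the pipeline itself (ensemble construction), not formals
# of generator_config()
area_pipeline_keys <- c("kernel", "kernel_a0", "kernel_a2", "tau_ms", "noise_sd")

#' Build a pipeline configuration
#'
#' Assembles and validates the full configuration of [run_pipeline()]: two
#' generator configurations on a shared grid (area 1 drives area 2 through
#' the feedforward strength `w_ff`), shared field parameters, and settings
#' for the inference, Granger-causality, and RSA stages. Defaults are sized
#' for desk-scale runs (minutes, not hours); scale the area settings up for
#' production use.
#'
#' @param area1,area2 named lists of [generator_config()] arguments
#'   (`n_trials`, `n_channels`, `delay_ms`, `time_step_ms`, `cue_angles_deg`,
#'   `span_mm`, `input_amplitude`, `input_width_mm`, `input_dur_ms`,
#'   `ephaptic`, `coupling`) plus ensemble options consumed by the pipeline:
#'   `kernel` (`"gaussian"` default, or `"local"` for the diffusive
#'   [local_kernel()] whose derivative expansion is exact -- use it for model
#'   recovery), `kernel_a0`, `kernel_a2`, `tau_ms`, `noise_sd`. Missing
#'   entries take the shared defaults.
#' @param w_ff feedforward drive strength from area 1 onto area 2 (>= 0; 0
#'   disconnects the areas).
#' @param field [bidomain_params()] shared by both areas.
#' @param farfield [farfield_params()] supplying the multipole coefficient
#'   for the stability stage.
#' @param inference list with `order_J`, `train_fraction`, `bf_threshold`.
#' @param gc list with `p` (spatial lag order) and `alpha`.
#' @param rsa list with `n_relabelings`.
#' @param out_dir optional output directory; when non-`NULL`,
#'   [run_pipeline()] writes recordings and a JSON report there.
#' @param master_seed master seed; all stage seeds are derived from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(area1 = list(), area2 = list(),
                            w_ff = 0.2,
                            field = bidomain_params(),
                            farfield = farfield_params(tau_EP_ms = 1, gamma = 1,
                                                       r_mm = 1, L_mm = 0.2),
                            inference = list(),
                            gc = list(),
                            rsa = list(),
                            out_dir = NULL,
                            master_seed = 1) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  area_defaults <- list(n_trials = 18, n_channels = 16, delay_ms = 250,
                        time_step_ms = 1,
                        cue_angles_deg = c(0, 60, 120, 180, 240, 300),
                        span_mm = 2, input_amplitude = 0.06,
                        input_width_mm = 0.3, input_dur_ms = NULL,
                        ephaptic = FALSE, coupling = 1,
                        kernel = "gaussian", kernel_a0 = 0.12,
                        kernel_a2 = 0.02, tau_ms = 20, noise_sd = 0.5)
  fill_area <- function(a, nm) {
    unknown <- setdiff(names(a), area_keys)
    if (length(unknown) > 0) {
      note(sprintf("%s: unknown keys: %s", nm, paste(unknown, collapse = ", ")))
    }
    out <- utils::modifyList(area_defaults, a[names(a) %in% area_keys],
                             keep.null = TRUE)
    if (!is.null(out$delay_ms) && out$delay_ms <= 0) {
      note(sprintf("%s: delay_ms must be positive", nm))
    }
    if (!is.null(out$time_step_ms) && out$time_step_ms <= 0) {
      note(sprintf("%s: time_step_ms must be positive", nm))
    }
    if (!out$kernel %in% c("gaussian", "local")) {
      note(sprintf("%s: kernel must be \"gaussian\" or \"local\"", nm))
    }
    if (!is.null(out$tau_ms) && out$tau_ms <= 0) {
      note(sprintf("%s: tau_ms must be positive", nm))
    }
    out
  }
  area1 <- fill_area(as.list(area1), "area1")
  area2 <- fill_area(as.list(area2), "area2")
  if (area1$n_channels != area2$n_channels || area1$span_mm != area2$span_mm ||
      area1$delay_ms != area2$delay_ms || area1$time_step_ms != area2$time_step_ms ||
      area1$n_trials != area2$n_trials) {
    note("areas must share trial count, grid, and time base for feedforward coupling")
  }

  if (!is.numeric(w_ff) || length(w_ff) != 1 || w_ff < 0) {
    note("w_ff must be a single non-negative number")
  }
  if (!inherits(field, "bidomain_params")) note("field must be bidomain_params")
  if (!inherits(farfield, "farfield_params")) note("farfield must be farfield_params")

  fill <- function(x, defaults, nm) {
    unknown <- setdiff(names(x), names(defaults))
    if (length(unknown) > 0) {
      note(sprintf("%s: unknown keys: %s", nm, paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, x[names(x) %in% names(defaults)])
  }
  inference <- fill(as.list(inference),
                    list(order_J = 4, train_fraction = 0.5, bf_threshold = 3),
                    "inference")
  gc <- fill(as.list(gc), list(p = 1, alpha = 0.05), "gc")
  rsa <- fill(as.list(rsa), list(n_relabelings = 1000), "rsa")
  if (inference$train_fraction <= 0 || inference$train_fraction >= 1) {
    note("inference$train_fraction must be in (0, 1)")
  }
  if (gc$alpha <= 0 || gc$alpha >= 1) note("gc$alpha must be in (0, 1)")
  if (rsa$n_relabelings < 1) note("rsa$n_relabelings must be >= 1")
  master_seed <- suppressWarnings(as.integer(master_seed))
  if (is.na(master_seed)) note("master_seed must be an integer")

  if (length(errors) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(
    list(schema = pipeline_schema_version,
         area1 = area1, area2 = area2, w_ff = w_ff,
         field = field, farfield = farfield,
         inference = inference, gc = gc, rsa = rsa,
         out_dir = out_dir, master_seed = master_seed),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> schema %s, seed %d, hash %s\n",
                     "  areas: %d trials x %d channels x %g ms",
                     " (area1 ephaptic: %s, area2 ephaptic: %s), w_ff = %g\n"),
              x$schema, x$master_seed, config_hash(x),
              x$area1$n_trials, x$area1$n_channels, x$area1$delay_ms,
              x$area1$ephaptic, x$area2$ephaptic, x$w_ff))
  invisible(x)
}

#' Configuration fingerprint
#'
#' Deterministic 8-hex-digit hash of a pipeline configuration, recorded in
#' every run report and output file so artifacts can be traced back to the
#' exact configuration.
#'
#' @param config a `pipeline_config`.
#' @return an 8-character hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL                      # output location is not part of identity
  fnv1a32(paste(deparse(x), collapse = "\n"))
}

config_to_list <- function(config) {
  list(schema = config$schema,
       area1 = config$area1, area2 = config$area2, w_ff = config$w_ff,
       field = unclass(config$field),
       farfield = unclass(config$farfield)[c("tau_EP_ms", "gamma", "r_mm", "L_mm")],
       inference = config$inference, gc = config$gc, rsa = config$rsa,
       out_dir = config$out_dir, master_seed = config$master_seed)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML file to write.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a plain list), checks it against the
#' configuration schema, fills in defaults, and returns the normalized
#' `pipeline_config`. All problems are aggregated into a single error
#' message. A minimal (even empty) YAML file yields the full default
#' configuration; `dump_config()` followed by `validate_config()` is
#' idempotent.
#'
#' @param x path to a YAML file, or a named list.
#' @return a `pipeline_config`.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(sprintf("config file not found: %s", x), call. = FALSE)
    x <- yaml::read_yaml(x) %||% list()
  }
  if (inherits(x, "pipeline_config")) x <- config_to_list(x)
  if (!is.list(x)) stop("config must be a YAML file path or a named list", call. = FALSE)
  known <- c("schema", "area1", "area2", "w_ff", "field", "farfield",
             "inference", "gc", "rsa", "out_dir", "master_seed")
  errors <- character(0)
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    errors <- c(errors, sprintf("unknown top-level keys: %s",
                                paste(unknown, collapse = ", ")))
  }
  if (!is.null(x$schema) && !identical(as.character(x$schema), pipeline_schema_version)) {
    errors <- c(errors, sprintf("unsupported schema version '%s' (expected '%s')",
                                x$schema, pipeline_schema_version))
  }
  field <- tryCatch(
    do.call(bidomain_params, as.list(x$field %||% list())),
    error = function(e) { errors <<- c(errors, paste0("field: ", conditionMessage(e))); NULL }
  )
  farfield <- if (is.null(x$farfield)) {
    farfield_params(tau_EP_ms = 1, gamma = 1, r_mm = 1, L_mm = 0.2)
  } else {
    tryCatch(
      do.call(farfield_params, as.list(x$farfield)),
      error = function(e) { errors <<- c(errors, paste0("farfield: ", conditionMessage(e))); NULL }
    )
  }
  if (length(errors) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  args <- list(area1 = x$area1 %||% list(), area2 = x$area2 %||% list(),
               inference = x$inference %||% list(), gc = x$gc %||% list(),
               rsa = x$rsa %||% list(), out_dir = x$out_dir)
  if (!is.null(x$w_ff)) args$w_ff <- x$w_ff
  if (!is.null(field)) args$field <- field
  if (!is.null(farfield)) args$farfield <- farfield
  if (!is.null(x$master_seed)) args$master_seed <- x$master_seed
  do.call(pipeline_config, args)
}

# project a channel-space kernel matrix onto the lowest circular Fourier
# modes of the patch: K_hat[n, q] = Re( e_n^H K e_q ) / N with
# e_n(x) = exp(i 2 pi n x / span)
kernel_mode_matrix <- function(K, positions_mm, modes = 1:2) {
  span <- max(positions_mm) - min(positions_mm)
  N <- length(positions_mm)
  basis <- vapply(modes, function(n) exp(2i * pi * n * positions_mm / span),
                  complex(N))
  Re(Conj(t(basis)) %*% K %*% basis) / N
}

run_stage <- function(report, name, depends_on, fn) {
  dep_status <- vapply(depends_on, function(d) report$stages[[d]]$status, character(1))
  if (length(dep_status) > 0 && any(dep_status != "completed")) {
    bad <- depends_on[dep_status != "completed"]
    report$stages[[name]] <- list(status = "skipped",
                                  reason = sprintf("upstream stage failed: %s",
                                                   paste(bad, collapse = ", ")))
    return(report)
  }
  out <- tryCatch(list(status = "completed", value = fn(), reason = NA_character_),
                  error = function(e) list(status = "failed", value = NULL,
                                           reason = conditionMessage(e)))
  report$stages[[name]] <- out[c("status", "reason")]
  report$results[[name]] <- out$value
  report
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) simulation of two areas, with area 2 receiving
#' area 1's transferred activity as feedforward drive scaled by `w_ff`;
#' (2) extracellular field estimation per area; (3) Bayesian model comparison
#' (ephaptic vs non-ephaptic) per area; (4) snapshot Granger causality,
#' field vs activity within each area and area 1 vs area 2 activity;
#' (5) RSA: per-area RDMs, their deviation, and a randomization test of
#' correspondence; (6) the two-area stability (engram) condition evaluated on
#' the mode-reduced system built from the configured kernels. A stage that
#' fails is recorded with its error message and all dependent stages are
#' skipped; the report always covers every stage.
#'
#' The run is a pure function of the configuration: all stage seeds are
#' derived from `master_seed`. When `config$out_dir` is set, recordings and a
#' JSON report (tagged with the config hash) are written there.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` object with `stages` (status/reason per stage),
#'   `results` (stage outputs), `summary` tables, `config_hash`, `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$master_seed, 6)
  names(seeds) <- c("area1", "area2", "bmc1", "bmc2", "rsa", "spare")
  report <- list(stages = list(), results = list(),
                 config = config, config_hash = config_hash(config),
                 seeds = seeds,
                 version = as.character(utils::packageVersion("engramfield")))
  gen_cfg <- function(area, seed) {
    positions <- seq(0, area$span_mm, length.out = area$n_channels)
    ensemble <- switch(area$kernel,
      gaussian = {
        e <- default_ensemble(positions, tau_ms = area$tau_ms)
        ensemble_model(e$tau_ms, e$gain, e$threshold, e$kernel,
                       noise_sd = area$noise_sd)
      },
      local = ensemble_model(area$tau_ms, gain = 1, threshold = 0,
                             kernel = local_kernel(positions, area$kernel_a0,
                                                   area$kernel_a2),
                             noise_sd = area$noise_sd)
    )
    gen_args <- area[setdiff(names(area), area_pipeline_keys)]
    do.call(generator_config,
            c(gen_args[!vapply(gen_args, is.null, logical(1))],
              list(ensemble = ensemble, master_seed = seed,
                   field_params = if (isTRUE(area$ephaptic)) config$field)))
  }

  report <- run_stage(report, "simulate", character(0), function() {
    cfg1 <- gen_cfg(config$area1, seeds[["area1"]])
    cfg2 <- gen_cfg(config$area2, seeds[["area2"]])
    rec1 <- simulate_recording(cfg1)
    ff <- NULL
    if (config$w_ff > 0) {
      f0 <- transfer_function(0, cfg1$ensemble$gain, cfg1$ensemble$threshold)
      ff <- config$w_ff *
        (transfer_function(rec1$data, cfg1$ensemble$gain, cfg1$ensemble$threshold) - f0)
    }
    rec2 <- simulate_recording(cfg2, ff_input = ff)
    list(area1 = rec1, area2 = rec2, cfg1 = cfg1, cfg2 = cfg2)
  })

  report <- run_stage(report, "field", "simulate", function() {
    sim <- report$results$simulate
    list(area1 = field_estimate(sim$area1, config$field),
         area2 = field_estimate(sim$area2, config$field))
  })

  report <- run_stage(report, "bmc", "simulate", function() {
    sim <- report$results$simulate
    inf <- config$inference
    list(area1 = compare_models(sim$area1, config$field, order_J = inf$order_J,
                                train_fraction = inf$train_fraction,
                                seed = seeds[["bmc1"]],
                                bf_threshold = inf$bf_threshold),
         area2 = compare_models(sim$area2, config$field, order_J = inf$order_J,
                                train_fraction = inf$train_fraction,
                                seed = seeds[["bmc2"]],
                                bf_threshold = inf$bf_threshold))
  })

  report <- run_stage(report, "gc", c("simulate", "field"), function() {
    sim <- report$results$simulate
    fld <- report$results$field
    within_area <- function(rec, fe, nm) {
      Vm <- apply(rec$data, c(2, 3), mean)          # channels x time
      y_idx <- 1L                                    # estimation depth nearest the sheet
      gc_over_time(
        snapshot_series(t(fe$Ve[, y_idx, ]), label = "field", area = nm),
        snapshot_series(t(Vm), label = "activity", area = nm),
        p = config$gc$p, alpha = config$gc$alpha
      )
    }
    between <- gc_over_time(
      snapshot_series(t(apply(sim$area1$data, c(2, 3), mean)), label = "area1"),
      snapshot_series(t(apply(sim$area2$data, c(2, 3), mean)), label = "area2"),
      p = config$gc$p, alpha = config$gc$alpha
    )
    list(area1 = within_area(sim$area1, fld$area1, "area1"),
         area2 = within_area(sim$area2, fld$area2, "area2"),
         between = between)
  })

  report <- run_stage(report, "rsa", "simulate", function() {
    sim <- report$results$simulate
    rdm1 <- build_rdm(sim$area1)
    rdm2 <- build_rdm(sim$area2)
    list(rdm_area1 = rdm1, rdm_area2 = rdm2,
         deviation = rdm_deviation(rdm1, rdm2),
         test = randomization_test(rdm1, rdm2,
                                   n_relabelings = config$rsa$n_relabelings,
                                   seed = seeds[["rsa"]]))
  })

  report <- run_stage(report, "stability", "simulate", function() {
    sim <- report$results$simulate
    K1 <- kernel_mode_matrix(sim$cfg1$ensemble$kernel$matrix,
                             sim$cfg1$positions_mm)
    K2 <- kernel_mode_matrix(sim$cfg2$ensemble$kernel$matrix,
                             sim$cfg2$positions_mm)
    sys <- build_two_area_blocks(
      tau_EP_ms = config$farfield$tau_EP_ms,
      tau_NA_ms = sim$cfg1$ensemble$tau_ms,
      gain = sim$cfg1$ensemble$gain,
      K1_hat = K1, K2_hat = K2,
      W_ff = config$w_ff * diag(2),
      Z = config$farfield
    )
    engram_condition(sys)
  })

  report$summary <- summarize_report(report)
  report <- structure(report, class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

summarize_report <- function(report) {
  s <- list()
  s$stages <- purrr::imap_dfr(report$stages, function(st, nm) {
    tibble::tibble(stage = nm, status = st$status,
                   reason = st$reason %||% NA_character_)
  })
  if (!is.null(report$results$bmc)) {
    s$bf <- dplyr::bind_rows(
      dplyr::mutate(tidy(report$results$bmc$area1), area = "area1"),
      dplyr::mutate(tidy(report$results$bmc$area2), area = "area2")
    )
  }
  if (!is.null(report$results$gc)) {
    gcs <- report$results$gc
    s$gc <- dplyr::bind_rows(
      dplyr::mutate(glance(gcs$area1$field_to_activity), pair = "area1"),
      dplyr::mutate(glance(gcs$area1$activity_to_field), pair = "area1"),
      dplyr::mutate(glance(gcs$area2$field_to_activity), pair = "area2"),
      dplyr::mutate(glance(gcs$area2$activity_to_field), pair = "area2"),
      dplyr::mutate(glance(gcs$between$field_to_activity), pair = "between"),
      dplyr::mutate(glance(gcs$between$activity_to_field), pair = "between")
    )
  }
  if (!is.null(report$results$rsa)) {
    s$rsa <- dplyr::mutate(tidy(report$results$rsa$test),
                           deviation_between_areas = report$results$rsa$deviation)
  }
  if (!is.null(report$results$stability)) {
    st <- report$results$stability
    s$stability <- tibble::tibble(
      det_M = st$det_M, schur_residual = st$schur_residual,
      three_factor_residual = st$three_factor_residual,
      implication_holds = st$implication_holds
    )
  }
  s
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> version %s, config %s, master seed %d\n",
              x$version, x$config_hash, x$config$master_seed))
  st <- x$summary$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-10s %s%s\n", st$stage[i], st$status[i],
                if (!is.na(st$reason[i])) paste0(" (", st$reason[i], ")") else ""))
  }
  if (!is.null(x$summary$bf)) {
    cat(sprintf("  BMC winners: area1 = %s, area2 = %s\n",
                x$results$bmc$area1$winner, x$results$bmc$area2$winner))
  }
  if (!is.null(x$summary$rsa)) {
    cat(sprintf("  RSA deviation between areas = %.3f (p = %.3g)\n",
                x$summary$rsa$deviation_between_areas, x$summary$rsa$p_value))
  }
  invisible(x)
}

#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    config_hash = x$config_hash, master_seed = x$config$master_seed,
    n_completed = sum(x$summary$stages$status == "completed"),
    n_failed = sum(x$summary$stages$status == "failed"),
    n_skipped = sum(x$summary$stages$status == "skipped"),
    bmc_winner_area1 = if (!is.null(x$results$bmc)) x$results$bmc$area1$winner else NA_character_,
    bmc_winner_area2 = if (!is.null(x$results$bmc)) x$results$bmc$area2$winner else NA_character_,
    rsa_deviation = if (!is.null(x$results$rsa)) x$results$rsa$deviation else NA_real_
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- report$results$simulate
  if (!is.null(sim)) {
    write_recording(sim$area1, file.path(out_dir, "area1"))
    write_recording(sim$area2, file.path(out_dir, "area2"))
  }
  payload <- list(
    config_hash = report$config_hash, version = report$version,
    seeds = as.list(report$seeds),
    stages = report$summary$stages,
    bf = report$summary$bf, gc = report$summary$gc,
    rsa = report$summary$rsa, stability = report$summary$stability
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
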