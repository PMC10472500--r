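# Representational similarity analysis over delay-period population
# patterns: one pattern per remembered cue condition, representational
# dissimilarity matrices (RDMs) built from pattern correlations, and a
# randomization test of RDM correspondence between recordings.

#' Construct a representational dissimilarity matrix object
#'
#' Low-level constructor; validates that `m` is square, symmetric, with a
#' zero diagonal.
#'
#' @param m square numeric dissimilarity matrix.
#' @param labels condition labels (defaults to the dimnames or `1..n`).
#' @param source optional free-form identifier of the originating recording.
#' @return an `rdm` object.
#' @export
new_rdm <- function(m, labels = NULL, source = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RDM must be square", call. = FALSE)
  check_finite(m, "RDM")
  if (max(abs(m - t(m))) > 1e-8) stop("RDM must be symmetric", call. = FALSE)
  if (max(abs(diag(m))) > 1e-8) stop("RDM diagonal must be zero", call. = FALSE)
  labels <- labels %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, labels = as.character(labels), source = source),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  print(round(x$matrix, 3))
  invisible(x)
}

upper_vec <- function(m) m[upper.tri(m)]

#' Condition pattern from a recording
#'
#' The population pattern for one cue condition: for each trial of that
#' condition, the channels-by-channels Pearson correlation matrix of the
#' delay-period time courses is computed and its upper triangle vectorized;
#' the pattern is the across-trial mean of these vectors. Channel pairs thus
#' index the pattern, making it insensitive to channel ordering conventions
#' beyond pairing.
#'
#' @param rec an [lfp_recording()] object.
#' @param angle_deg the cue angle selecting the condition.
#' @return numeric pattern vector of length `n_channels * (n_channels - 1) / 2`.
#' @export
condition_pattern <- function(rec, angle_deg) {
  stopifnot(inherits(rec, "lfp_recording"))
  idx <- which(rec$trials$cue_angle_deg == angle_deg)
  if (length(idx) == 0) {
    stop(sprintf("no trials with cue angle %s deg", format(angle_deg)), call. = FALSE)
  }
  vecs <- vapply(idx, function(i) {
    cm <- stats::cor(t(rec$data[i, , ]))
    upper_vec(cm)
  }, numeric(dim(rec$data)[2] * (dim(rec$data)[2] - 1) / 2))
  rowMeans(as.matrix(vecs))
}

#' Build the RDM of a recording
#'
#' Dissimilarity between two conditions is `1 - Pearson correlation` of their
#' [condition_pattern()] vectors, over all pairs of distinct cue conditions.
#'
#' @param rec an [lfp_recording()] object.
#' @param angles_deg conditions to include (default: all cue angles present,
#'   sorted).
#' @return an [new_rdm()] object.
#' @export
build_rdm <- function(rec, angles_deg = NULL) {
  angles_deg <- angles_deg %||% sort(unique(rec$trials$cue_angle_deg))
  P <- vapply(angles_deg, function(a) condition_pattern(rec, a),
              numeric(dim(rec$data)[2] * (dim(rec$data)[2] - 1) / 2))
  m <- 1 - stats::cor(as.matrix(P))
  diag(m) <- 0
  m <- (m + t(m)) / 2
  new_rdm(m, labels = as.character(angles_deg))
}

#' Representational deviation between two RDMs
#'
#' `1 - Spearman rank correlation` of the vectorized upper triangles. Zero
#' means identical representational geometry; values near one mean unrelated
#' geometries.
#'
#' @param rdm_a,rdm_b [new_rdm()] objects (or square matrices) of equal size.
#' @return the deviation (scalar in `[0, 2]`).
#' @export
rdm_deviation <- function(rdm_a, rdm_b) {
  ma <- if (inherits(rdm_a, "rdm")) rdm_a$matrix else as.matrix(rdm_a)
  mb <- if (inherits(rdm_b, "rdm")) rdm_b$matrix else as.matrix(rdm_b)
  if (!all(dim(ma) == dim(mb))) stop("RDMs must have matching sizes", call. = FALSE)
  va <- upper_vec(ma); vb <- upper_vec(mb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("degenerate RDM (constant dissimilarities): rank correlation undefined",
         call. = FALSE)
  }
  1 - stats::cor(va, vb, method = "spearman")
}

#' Standard error of a mean deviation
#'
#' Sample standard error `sd(x) / sqrt(n)` for a set of per-pair or
#' per-session deviations.
#'
#' @param deviations numeric vector (length >= 2).
#' @return the standard error.
#' @export
deviation_stderr <- function(deviations) {
  if (length(deviations) < 2) stop("need at least two deviations", call. = FALSE)
  stats::sd(deviations) / sqrt(length(deviations))
}

#' Randomization test of RDM correspondence
#'
#' Tests whether two RDMs share representational geometry beyond chance. The
#' observed statistic is the Spearman correlation of the upper triangles
#' (i.e. `1 - rdm_deviation`). The null distribution relabels the conditions
#' of the second RDM: each relabeling applies one permutation jointly to its
#' rows and columns, preserving the RDM's internal structure while breaking
#' the condition correspondence. The p-value is
#' `(1 + #{null >= observed}) / (1 + n_relabelings)`.
#'
#' For small condition counts the test warns that the permutation space is
#' coarse (`n! = 720` for six conditions bounds the attainable resolution).
#'
#' @param rdm_a,rdm_b [new_rdm()] objects (or square matrices) of equal size.
#' @param n_relabelings number of random relabelings (default 10000).
#' @param seed optional RNG seed for the relabelings.
#' @return an `rsa_test` object with `observed` (Spearman correlation),
#'   `deviation`, `p_value`, `null` (null correlations), `n_relabelings`.
#' @export
randomization_test <- function(rdm_a, rdm_b, n_relabelings = 10000, seed = NULL) {
  ma <- if (inherits(rdm_a, "rdm")) rdm_a$matrix else as.matrix(rdm_a)
  mb <- if (inherits(rdm_b, "rdm")) rdm_b$matrix else as.matrix(rdm_b)
  if (!all(dim(ma) == dim(mb))) stop("RDMs must have matching sizes", call. = FALSE)
  n <- nrow(ma)
  if (n < 4) {
    warning("fewer than 4 conditions: the relabeling null is extremely coarse")
  }
  va_rank <- rank(upper_vec(ma))
  vb <- upper_vec(mb)
  if (stats::sd(va_rank) == 0 || stats::sd(vb) == 0) {
    stop("degenerate RDM (constant dissimilarities): rank correlation undefined",
         call. = FALSE)
  }
  observed <- stats::cor(va_rank, rank(vb))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  # precompute the upper-triangle index map once; each relabeling is then one
  # subscript + one rank correlation on a short vector
  ut <- which(upper.tri(ma), arr.ind = TRUE)
  null <- vapply(seq_len(n_relabelings), function(i) {
    perm <- sample.int(n)
    idx <- cbind(perm[ut[, 1]], perm[ut[, 2]])
    stats::cor(va_rank, rank(mb[idx]))
  }, numeric(1))
  p_value <- (1 + sum(null >= observed)) / (1 + n_relabelings)
  structure(
    list(observed = observed, deviation = 1 - observed, p_value = p_value,
         null = null, n_relabelings = n_relabelings, n_conditions = n),
    class = "rsa_test"
  )
}

#' @export
print.rsa_test <- function(x, ...) {
  cat(sprintf(paste0("<rsa_test> %d conditions, %d relabelings\n",
                     "  observed Spearman rho = %.4f (deviation %.4f), p = %.4g\n"),
              x$n_conditions, x$n_relabelings, x$observed, x$deviation,
              x$p_value))
  invisible(x)
}

#' @method tidy rsa_test
#' @export
tidy.rsa_test <- function(x, ...) {
  tibble::tibble(statistic = x$observed, deviation = x$deviation,
                 p_value = x$p_value, n_relabelings = x$n_relabelings,
                 n_conditions = x$n_conditions)
}

#' @method glance rsa_test
#' @export
glance.rsa_test <- function(x, ...) tidy.rsa_test(x, ...)
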