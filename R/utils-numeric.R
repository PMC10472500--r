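# Shared numerical helpers: finite differences on a (possibly non-uniform)
# monotone 1-D grid, and small validation utilities.

#' First-derivative matrix on a monotone grid
#'
#' Builds the linear operator `D` such that `D %*% v` is the second-order
#' finite-difference estimate of `dv/dx` on the grid `x`: three-point central
#' (Lagrange) weights at interior points and one-sided second-order weights at
#' the two boundary points. The stencil is exact for polynomials up to degree
#' two on any monotone grid, which is what the derivative-based principal axes
#' and the drive Laplacian rely on.
#'
#' @param x numeric vector of strictly increasing grid positions (length >= 3).
#' @return an `length(x)` x `length(x)` matrix.
#' @keywords internal
deriv_matrix <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 grid points for a derivative stencil", call. = FALSE)
  if (any(diff(x) <= 0)) stop("grid positions must be strictly increasing", call. = FALSE)
  D <- matrix(0, n, n)
  # three-point Lagrange derivative weights at point xi for nodes (x0, x1, x2)
  w3 <- function(xi, x0, x1, x2) {
    c((2 * xi - x1 - x2) / ((x0 - x1) * (x0 - x2)),
      (2 * xi - x0 - x2) / ((x1 - x0) * (x1 - x2)),
      (2 * xi - x0 - x1) / ((x2 - x0) * (x2 - x1)))
  }
  D[1, 1:3] <- w3(x[1], x[1], x[2], x[3])
  for (i in 2:(n - 1)) {
    D[i, (i - 1):(i + 1)] <- w3(x[i], x[i - 1], x[i], x[i + 1])
  }
  D[n, (n - 2):n] <- w3(x[n], x[n - 2], x[n - 1], x[n])
  D
}

#' Stack of spatial-derivative operators D^0, D^1, ..., D^J
#' @keywords internal
deriv_matrix_powers <- function(x, order_J) {
  n <- length(x)
  if (order_J < 0) stop("derivative order must be >= 0", call. = FALSE)
  if (n < order_J + 2) {
    stop(sprintf("need at least %d grid points for derivative order %d",
                 order_J + 2, order_J), call. = FALSE)
  }
  out <- vector("list", order_J + 1)
  out[[1]] <- diag(n)
  if (order_J >= 1) {
    D <- deriv_matrix(x)
    for (j in seq_len(order_J)) out[[j + 1]] <- D %*% out[[j]]
  }
  out
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 32-bit FNV-1a hash of a character scalar, as 8 hex digits;
# used to fingerprint configurations in run reports
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    # xor with one byte touches only the low 8 bits; done via arithmetic so h
    # can exceed the signed 32-bit range bitwXor() accepts
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay inside double precision
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  # split into two 16-bit halves so sprintf() sees integers
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# draw independent per-unit seeds below 2^31 from a master seed
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}
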