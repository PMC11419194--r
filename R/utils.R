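# Internal numerical helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Centre the DC bin of a 2D spectrum (DC moves to floor(n/2)+1).
#' @noRd
fftshift2 <- function(m) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1L + ceiling(d[1] / 2)) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L + ceiling(d[2] / 2)) %% d[2]) + 1L
  m[i, j, drop = FALSE]
}

#' @noRd
ifftshift2 <- function(m) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1L + floor(d[1] / 2)) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L + floor(d[2] / 2)) %% d[2]) + 1L
  m[i, j, drop = FALSE]
}

# Cholesky factor L of a complex Hermitian positive-definite matrix,
# L %*% Conj(t(L)) == A.  base::chol() is real-only.
#' @noRd
chol_complex <- function(A, tol = 1e-12) {
  n <- nrow(A)
  if (max(Mod(A - Conj(t(A)))) > 1e-8 * max(1, max(Mod(A)))) {
    stop("matrix is not Hermitian")
  }
  L <- matrix(0 + 0i, n, n)
  for (j in seq_len(n)) {
    jj <- seq_len(j - 1L)
    s <- Re(A[j, j]) - sum(Mod(L[j, jj])^2)
    if (s <= tol * max(1, Re(A[j, j]))) {
      stop("covariance matrix is not positive-definite")
    }
    L[j, j] <- sqrt(s)
    if (j < n) {
      for (i in seq(j + 1L, n)) {
        L[i, j] <- (A[i, j] - sum(L[i, jj] * Conj(L[j, jj]))) / L[j, j]
      }
    }
  }
  L
}

# n iid draws of a C-variate circular complex Gaussian with covariance Sigma
# (E[z z^H] = Sigma).  Returns a C x n complex matrix.
#' @noRd
rcnorm_mat <- function(n_channels, n, sigma_chol) {
  z <- matrix(
    complex(
      real = stats::rnorm(n_channels * n, sd = sqrt(0.5)),
      imaginary = stats::rnorm(n_channels * n, sd = sqrt(0.5))
    ),
    nrow = n_channels
  )
  sigma_chol %*% z
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' @noRd
stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive scalar", name))
  }
  invisible(x)
}
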