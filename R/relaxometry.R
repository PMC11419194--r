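# Companion proton quantification: voxelwise mono-exponential fits of ADC
# (multi-b DWI) and R2* (multi-echo gradient echo).

# Vectorized weighted log-linear fit of S = S0 * exp(-x * rate) over the
# third array dimension; weights proportional to S^2 (standard variance
# stabilization for log-transformed magnitude data).
#' @noRd
loglinear_decay_fit <- function(data, x, mask) {
  d <- dim(data)
  stopifnot(length(x) == d[3], all(dim(mask) == d[1:2]))
  if (!any(mask)) stop("all voxels masked out")
  nvox <- sum(mask)
  S <- matrix(0, nvox, d[3])
  for (k in seq_len(d[3])) S[, k] <- data[, , k][mask]
  valid <- rowSums(S <= 0) == 0L
  rate <- rep(NA_real_, nvox)
  s0 <- rep(NA_real_, nvox)
  if (any(valid)) {
    Sv <- S[valid, , drop = FALSE]
    Y <- log(Sv)
    W <- Sv^2
    sw <- rowSums(W)
    xw <- (W %*% x) / sw
    yw <- rowSums(W * Y) / sw
    sxx <- rowSums(W * (sweep(matrix(x, nrow(Sv), length(x), byrow = TRUE), 1, xw))^2)
    sxy <- rowSums(W * sweep(matrix(x, nrow(Sv), length(x), byrow = TRUE), 1, xw) *
                     (Y - yw))
    slope <- sxy / sxx
    rate[valid] <- -slope
    s0[valid] <- exp(yw - slope * xw)
  }
  rate_map <- matrix(NA_real_, d[1], d[2]); rate_map[mask] <- rate
  s0_map <- matrix(NA_real_, d[1], d[2]);   s0_map[mask] <- s0
  vmask <- matrix(FALSE, d[1], d[2]);       vmask[mask] <- valid
  list(rate = rate_map, s0 = s0_map, valid = vmask)
}

#' Voxelwise ADC fit from a multi-b diffusion series
#'
#' Weighted linear least squares on `ln S` versus `b` (weights `S^2`):
#' the negative slope is the apparent diffusion coefficient.  Voxels with a
#' nonpositive signal at any b-value are flagged invalid and returned as
#' `NA`, never zero.  No b = 0 image is required; S0 is the extrapolated
#' intercept.
#'
#' @param ds a [simulate_dwi()] result or a list with `data`
#'   (ny x nx x nb) and `b_values`.
#' @param mask logical fit region.
#' @return list: `adc` (mm^2/s map, NA where invalid/unmasked), `s0`,
#'   `valid` (logical).
#' @export
fit_adc <- function(ds, mask = NULL) {
  stopifnot(!is.null(ds$data), !is.null(ds$b_values))
  if (length(ds$b_values) < 2L) stop("need at least 2 b-values")
  if (is.null(mask)) mask <- matrix(TRUE, dim(ds$data)[1], dim(ds$data)[2])
  fit <- loglinear_decay_fit(ds$data, ds$b_values, mask)
  list(adc = fit$rate, s0 = fit$s0, valid = fit$valid)
}

#' Voxelwise R2* fit from a multi-echo series
#'
#' Same weighted log-linear estimator as [fit_adc()] on `ln S` versus echo
#' time; the negative slope is R2* in 1/s.
#'
#' @param ms a [simulate_multiecho()] result or list with `data` and
#'   `echo_times` (s).
#' @param mask logical fit region.
#' @return list: `r2star` (1/s map), `s0`, `valid`.
#' @export
fit_r2star <- function(ms, mask = NULL) {
  stopifnot(!is.null(ms$data), !is.null(ms$echo_times))
  if (length(ms$echo_times) < 2L) stop("need at least 2 echo times")
  if (is.null(mask)) mask <- matrix(TRUE, dim(ms$data)[1], dim(ms$data)[2])
  fit <- loglinear_decay_fit(ms$data, ms$echo_times, mask)
  list(r2star = fit$rate, s0 = fit$s0, valid = fit$valid)
}
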