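# Multi-coil reconstruction: pre-whitening, AUC-based sensitivity maps,
# matched-filter combination, and Fermi-filtered zero-fill interpolation.

#' Multi-channel dynamic metabolite series
#'
#' Container for raw (or whitened) per-channel complex dynamic data.  Layout
#' is (y, x, time, channel), column-major as native R arrays.
#'
#' @param data complex (or real, coerced) 4D array (ny, nx, nt, nchan).
#' @param metabolite metabolite label ("pyruvate", "lactate", "bicarbonate").
#' @param times frame timestamps in seconds; must be strictly increasing and
#'   uniformly spaced (tolerance 1e-6 s).  Defaults to unit spacing.
#' @param acq optional [acq_params()] carried as metadata.
#' @param whitened logical: has the series been noise pre-whitened?
#' @return object of class `multichannel_dynamic`.
#' @export
multichannel_dynamic <- function(data, metabolite = "pyruvate", times = NULL,
                                 acq = NULL, whitened = FALSE) {
  d <- dim(data)
  if (length(d) != 4L || d[4] < 1L) stop("data must be a (y, x, time, channel) array")
  if (is.null(times)) times <- seq_len(d[3]) - 1
  if (length(times) != d[3]) stop("times length must match the time dimension")
  dt <- diff(times)
  if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-6)) {
    stop("times must be strictly increasing and uniformly spaced")
  }
  storage.mode(data) <- "complex"
  structure(
    list(data = data, metabolite = metabolite, times = times, acq = acq,
         whitened = isTRUE(whitened)),
    class = "multichannel_dynamic"
  )
}

#' @export
print.multichannel_dynamic <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multichannel_dynamic> %s: %d x %d image, %d frames, %d channels%s\n",
              x$metabolite, d[1], d[2], d[3], d[4],
              if (x$whitened) " (whitened)" else ""))
  invisible(x)
}

#' Channel noise covariance from the signal-free tail of a dynamic series
#'
#' Hyperpolarized signal has decayed by the end of the acquisition, so the
#' last few frames sample (approximately) pure receiver noise.  The sample
#' covariance is taken over all voxels of the last `n_last_frames` frames
#' (mean-subtracted, normalized by the sample count).
#'
#' @param d a [multichannel_dynamic()].
#' @param n_last_frames number of trailing frames to use (default 5).
#' @return object of class `noise_covariance`: `matrix` (Hermitian
#'   channel x channel), `sigma` (scalar noise level after whitening, 1 by
#'   construction for a non-degenerate estimate), `source_window` (frame
#'   indices used), `degenerate` flag.
#' @export
estimate_noise_covariance <- function(d, n_last_frames = 5L) {
  stopifnot(inherits(d, "multichannel_dynamic"))
  nt <- dim(d$data)[3]
  if (!is_count(n_last_frames) || n_last_frames < 2 || n_last_frames >= nt) {
    stop("n_last_frames must be an integer in [2, n_frames)")
  }
  win <- seq(nt - n_last_frames + 1L, nt)
  # warn if the window is visibly signal-contaminated: per-frame median
  # magnitude (robust to focal signal) well above the quietest frame
  fr_med <- apply(Mod(d$data), 3, stats::median)
  if (mean(fr_med[win]) > 2 * min(fr_med)) {
    warning("noise window appears to overlap bolus signal; covariance may be contaminated")
  }
  x <- d$data[, , win, , drop = FALSE]
  nc <- dim(x)[4]
  xm <- matrix(x, ncol = nc)                 # samples x channels
  xm <- sweep(xm, 2, colMeans(xm))
  cov <- (t(xm) %*% Conj(xm)) / nrow(xm)     # C_ij = E[x_i conj(x_j)]
  cov <- (cov + Conj(t(cov))) / 2            # enforce Hermitian symmetry
  degenerate <- max(Mod(cov)) < .Machine$double.eps * 100
  structure(
    list(matrix = cov, sigma = if (degenerate) 0 else 1,
         source_window = win, degenerate = degenerate),
    class = "noise_covariance"
  )
}

#' Noise pre-whitening of a multi-channel series
#'
#' Applies the inverse Cholesky factor of the channel noise covariance,
#' `L^-1 data`, so whitened channels carry unit-variance uncorrelated noise.
#'
#' @param d a [multichannel_dynamic()].
#' @param nc a [estimate_noise_covariance()] result (positive-definite).
#' @return whitened [multichannel_dynamic()].
#' @export
prewhiten <- function(d, nc) {
  stopifnot(inherits(d, "multichannel_dynamic"), inherits(nc, "noise_covariance"))
  if (nc$degenerate) stop("noise covariance is degenerate (all-zero); cannot whiten")
  L <- chol_complex(nc$matrix)
  Linv <- solve(L)
  dm <- dim(d$data)
  xm <- matrix(d$data, ncol = dm[4])
  xw <- xm %*% t(Linv)                       # rows: voxels; t(Linv) right-multiplies
  out <- array(xw, dim = dm)
  multichannel_dynamic(out, metabolite = d$metabolite, times = d$times,
                       acq = d$acq, whitened = TRUE)
}

#' Coil sensitivity maps from the pyruvate AUC
#'
#' The per-channel pyruvate area-under-the-curve (complex sum over frames)
#' is self-normalized by its root-sum-of-squares across channels.  The
#' support mask keeps voxels whose RSS AUC exceeds `mask_threshold_k` times
#' the noise-propagated AUC level `sqrt(n_channels * n_frames) * sigma`;
#' outside the mask, maps are zero.
#'
#' @param pyr a whitened pyruvate [multichannel_dynamic()].
#' @param mask_threshold_k SNR multiple defining the support mask (default 3).
#' @param sigma per-channel per-frame noise SD (1 after pre-whitening).
#' @param smooth_sigma optional Gaussian smoothing SD in voxels (0 = off).
#' @param magnitude_only drop the phase of the maps (default FALSE).
#' @return object of class `sensitivity_maps`: `maps` (ny x nx x channel
#'   complex), `support_mask` (logical ny x nx).
#' @export
estimate_sensitivity <- function(pyr, mask_threshold_k = 3, sigma = 1,
                                 smooth_sigma = 0, magnitude_only = FALSE) {
  stopifnot(inherits(pyr, "multichannel_dynamic"))
  dm <- dim(pyr$data)
  nt <- dm[3]; nchan <- dm[4]
  auc <- array(0 + 0i, dim = c(dm[1], dm[2], nchan))
  for (c_ in seq_len(nchan)) {
    auc[, , c_] <- apply(pyr$data[, , , c_, drop = FALSE], c(1, 2), sum)
  }
  if (smooth_sigma > 0) {
    for (c_ in seq_len(nchan)) auc[, , c_] <- gauss_smooth2(auc[, , c_], smooth_sigma)
  }
  rss <- sqrt(apply(Mod(auc)^2, c(1, 2), sum))
  noise_auc <- sqrt(nchan * nt) * sigma
  support <- rss > mask_threshold_k * noise_auc
  if (!any(support)) stop("empty sensitivity support mask")
  maps <- array(0 + 0i, dim = dim(auc))
  for (c_ in seq_len(nchan)) {
    m <- auc[, , c_] / rss
    m[!support] <- 0 + 0i
    maps[, , c_] <- m
  }
  if (magnitude_only) maps <- Mod(maps) + 0i
  structure(list(maps = maps, support_mask = support),
            class = "sensitivity_maps")
}

# separable Gaussian smoothing of a (possibly complex) matrix, reflect edges
#' @noRd
gauss_smooth2 <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(v[pmin(r:1, n)], v, v[pmax(n - seq_len(r) + 1L, 1L)])
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  out <- apply(m, 2, pad_conv)
  t(apply(out, 1, pad_conv))
}

#' Matched-filter channel combination
#'
#' Inside the support mask the whitened channels are combined as
#' `sum(conj(s) * d) / sum(|s|^2)`; outside it, the root-sum-of-squares
#' magnitude is used as fallback.  Output stays complex inside the mask.
#'
#' @param d a whitened [multichannel_dynamic()].
#' @param s a [estimate_sensitivity()] result on the same geometry.
#' @return object of class `combined_dynamic`: `data` (ny x nx x time
#'   complex), `metabolite`, `times`, `acq`, `support_mask`.
#' @export
combine_channels <- function(d, s) {
  stopifnot(inherits(d, "multichannel_dynamic"), inherits(s, "sensitivity_maps"))
  dm <- dim(d$data)
  if (!all(dm[1:2] == dim(s$maps)[1:2]) || dm[4] != dim(s$maps)[3]) {
    stop("data and sensitivity map shapes do not match")
  }
  nt <- dm[3]
  ssq <- apply(Mod(s$maps)^2, c(1, 2), sum)
  out <- array(0 + 0i, dim = dm[1:3])
  for (k in seq_len(nt)) {
    num <- matrix(0 + 0i, dm[1], dm[2])
    rss <- matrix(0, dm[1], dm[2])
    for (c_ in seq_len(dm[4])) {
      num <- num + Conj(s$maps[, , c_]) * d$data[, , k, c_]
      rss <- rss + Mod(d$data[, , k, c_])^2
    }
    fr <- num
    fr[s$support_mask] <- num[s$support_mask] / ssq[s$support_mask]
    fr[!s$support_mask] <- sqrt(rss[!s$support_mask]) + 0i
    out[, , k] <- fr
  }
  structure(
    list(data = out, metabolite = d$metabolite, times = d$times, acq = d$acq,
         support_mask = s$support_mask),
    class = "combined_dynamic"
  )
}

#' Fermi-filtered zero-fill interpolation
#'
#' Transforms the image to k-space, applies a radial Fermi window
#' `1 / (1 + exp((r - r_c) / w))` (radii in units of the Nyquist radius),
#' zero-pads symmetrically to `target_shape`, and transforms back.  The DC
#' component (image mean) is preserved.  Real input returns the real part of
#' the interpolated image.
#'
#' @param img 2D real or complex matrix.
#' @param target_shape integer pair >= `dim(img)`.
#' @param cutoff_frac Fermi cutoff radius as a fraction of Nyquist (default
#'   0.85).
#' @param width_frac Fermi transition width as a fraction of Nyquist
#'   (default 0.05).
#' @return matrix of dimension `target_shape`.
#' @export
fermi_zero_fill <- function(img, target_shape, cutoff_frac = 0.85,
                            width_frac = 0.05) {
  src <- dim(img)
  target_shape <- as.integer(target_shape)
  if (any(target_shape < src)) stop("target_shape must be >= source shape")
  was_real <- is.numeric(img)
  ksp <- fftshift2(stats::fft(img))
  # radial Fermi window on the source grid, radius 1 = Nyquist
  fy <- (seq_len(src[1]) - (floor(src[1] / 2) + 1)) / (src[1] / 2)
  fx <- (seq_len(src[2]) - (floor(src[2] / 2) + 1)) / (src[2] / 2)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  w <- 1 / (1 + exp((r - cutoff_frac) / width_frac))
  ksp <- ksp * w
  big <- matrix(0 + 0i, target_shape[1], target_shape[2])
  off <- floor(target_shape / 2) - floor(src / 2)
  big[off[1] + seq_len(src[1]), off[2] + seq_len(src[2])] <- ksp
  out <- stats::fft(ifftshift2(big), inverse = TRUE) / prod(src)
  if (was_real) Re(out) else out
}

#' Reconstruct one metabolite series: whiten, estimate/combine, return maps
#'
#' Convenience wrapper chaining [prewhiten()], [estimate_sensitivity()] (on
#' the pyruvate series) and [combine_channels()].
#'
#' @param study an `hp_study` from [simulate_study()] or loaded data.
#' @param n_noise_frames trailing frames for covariance estimation.
#' @param mask_threshold_k support-mask SNR multiple.
#' @return list with `combined` (named list of `combined_dynamic`),
#'   `sensitivity`, `noise_cov`.
#' @export
reconstruct_study <- function(study, n_noise_frames = 5L, mask_threshold_k = 3) {
  stopifnot(inherits(study, "hp_study") || is.list(study$channels))
  ncov <- estimate_noise_covariance(study$channels$pyruvate, n_noise_frames)
  white <- lapply(study$channels, prewhiten, nc = ncov)
  sens <- estimate_sensitivity(white$pyruvate, mask_threshold_k = mask_threshold_k)
  combined <- lapply(white, combine_channels, s = sens)
  list(combined = combined, sensitivity = sens, noise_cov = ncov)
}
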