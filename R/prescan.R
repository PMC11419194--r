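# Real-time prescan emulation: bolus-arrival detection against an SNR
# threshold, and centre-frequency calibration from a pyruvate FID.

#' Detect bolus arrival from a dynamic pyruvate stream
#'
#' Scans frames in order and triggers at the first frame whose peak signal
#' reaches `threshold_factor` times the noise level (the clinical protocol
#' uses 2x).  `frames` may be a numeric vector of per-frame statistics, a 3D
#' array (y, x, time), or a 4D multi-channel array (y, x, time, channel); for
#' images the per-frame statistic is the maximum magnitude (channels are
#' root-sum-of-squares combined first).
#'
#' @param frames per-frame signals: vector, 3D or 4D array, or a
#'   [multichannel_dynamic()].
#' @param noise_level positive noise standard-deviation estimate in the same
#'   units as `frames`.
#' @param threshold_factor SNR multiple that triggers acquisition (default 2).
#' @param times optional frame timestamps (s from injection start).
#' @return object of class `bolus_detection`: `triggered`, `trigger_frame`
#'   (1-based index or NA), `trigger_time_s`, `peak_snr_at_trigger`.
#' @export
detect_bolus <- function(frames, noise_level, threshold_factor = 2,
                         times = NULL) {
  if (inherits(frames, "multichannel_dynamic")) {
    if (is.null(times)) times <- frames$times
    frames <- frames$data
  }
  stopifnot_scalar_pos(noise_level, "noise_level")
  if (is.array(frames) && length(dim(frames)) == 4L) {
    frames <- sqrt(apply(Mod(frames)^2, c(1, 2, 3), sum))  # coil RSS image
  }
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- apply(Mod(frames), 3, max)
  }
  if (is.array(frames)) frames <- as.vector(frames)
  stat <- Mod(frames)
  if (is.null(times)) times <- seq_along(stat) - 1
  snr <- stat / noise_level
  hit <- which(snr >= threshold_factor)
  if (length(hit) == 0L) {
    res <- list(triggered = FALSE, trigger_frame = NA_integer_,
                trigger_time_s = NA_real_, peak_snr_at_trigger = NA_real_)
  } else {
    k <- hit[1]
    res <- list(triggered = TRUE, trigger_frame = k,
                trigger_time_s = times[k], peak_snr_at_trigger = snr[k])
  }
  structure(res, class = "bolus_detection")
}

#' Noise level of a pre-injection frame set
#'
#' The reference level the 2x bolus threshold is compared against.  For
#' multi-channel magnitude (coil-RSS) data the noise floor has a large
#' positive mean, so the default estimator is the mean magnitude of the
#' pre-injection frames ("floor"); the standard deviation ("sd") is
#' available for single-channel or complex data.
#'
#' @param frames pre-injection frames: vector, 3D (y, x, time) or 4D
#'   (y, x, time, channel) array (channels RSS-combined).
#' @param method `"floor"` (mean magnitude) or `"sd"`.
#' @return scalar noise level.
#' @export
prescan_noise_level <- function(frames, method = c("floor", "sd")) {
  method <- match.arg(method)
  if (is.array(frames) && length(dim(frames)) == 4L) {
    frames <- sqrt(apply(Mod(frames)^2, c(1, 2, 3), sum))
  }
  v <- Mod(as.vector(frames))
  if (method == "floor") mean(v) else stats::sd(v)
}

#' Centre-frequency offset from a free-induction decay
#'
#' Locates the dominant peak of the FID spectrum and refines its position by
#' parabolic interpolation of the magnitude around the peak bin.  Returns the
#' signed offset in Hz in `(-fs/2, fs/2]` where `fs = 1/dwell_s`.
#'
#' @param fid complex time-domain samples (>= 16).
#' @param dwell_s sampling interval, s.
#' @return frequency offset in Hz.
#' @export
estimate_frequency_offset <- function(fid, dwell_s) {
  if (length(fid) < 16L) stop("need at least 16 FID samples")
  stopifnot_scalar_pos(dwell_s, "dwell_s")
  if (all(Mod(fid) == 0)) stop("all-zero FID")
  n <- length(fid)
  X <- stats::fft(as.complex(fid))
  k <- which.max(Mod(X))
  km <- if (k == 1L) n else k - 1L
  kp <- if (k == n) 1L else k + 1L
  # Jacobsen's bias-reduced interpolator on the complex spectrum
  denom <- 2 * X[k] - X[km] - X[kp]
  delta <- if (Mod(denom) < .Machine$double.eps * max(Mod(X))) 0 else
    -Re((X[kp] - X[km]) / denom)
  delta <- max(-0.5, min(0.5, delta))
  bin <- (k - 1) + delta
  f <- bin / (n * dwell_s)
  fs <- 1 / dwell_s
  if (f > fs / 2) f <- f - fs
  f
}
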