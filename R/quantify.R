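# AUC maps, the three normalizations (max-pyruvate, voxel size, noise
# level), the mean-time timing correction, and ROI / group statistics.

#' Area-under-the-curve map of a combined dynamic series
#'
#' Voxelwise sum of the magnitude signal over the retained frames.  Initial
#' frames may be removed for timing consistency (see [mean_time_correct()]).
#'
#' @param d a `combined_dynamic` (from [combine_channels()]) or a real/complex
#'   3D array (y, x, time).
#' @param frames_removed number of initial frames excluded from the sum.
#' @param voxel_area_cm2 in-plane voxel area recorded on the map (used later
#'   by [normalize_voxel_size()]).
#' @return object of class `auc_map`: `values` (nonnegative ny x nx),
#'   `metabolite`, `n_frames_used`, `frames_removed`, `voxel_area_cm2`.
#' @export
compute_auc_map <- function(d, frames_removed = 0L, voxel_area_cm2 = 1) {
  metab <- "unknown"
  if (inherits(d, "combined_dynamic")) {
    metab <- d$metabolite
    if (!is.null(d$acq)) {
      voxel_area_cm2 <- d$acq$inplane_res_cm[[d$metabolite]]^2
    }
    d <- d$data
  }
  nt <- dim(d)[3]
  if (!is_count(frames_removed) || frames_removed < 0 || frames_removed >= nt) {
    stop("frames_removed must be an integer in [0, n_frames)")
  }
  keep <- seq(frames_removed + 1L, nt)
  values <- apply(Mod(d[, , keep, drop = FALSE]), c(1, 2), sum)
  structure(
    list(values = values, metabolite = metab,
         n_frames_used = length(keep), frames_removed = as.integer(frames_removed),
         voxel_area_cm2 = voxel_area_cm2),
    class = "auc_map"
  )
}

#' Signal-weighted mean time ("centre of mass") of a dynamic curve
#'
#' `sum(t_i * s_i) / sum(s_i)` — the timing statistic used to align dynamic
#' acquisitions across studies.
#'
#' @param curve nonnegative signal vector, not all zero.
#' @param times timestamps (s), same length.
#' @return mean time in seconds.
#' @export
mean_time <- function(curve, times) {
  stopifnot(length(curve) == length(times))
  if (any(curve < 0)) stop("curve must be nonnegative")
  s <- sum(curve)
  if (s == 0) stop("all-zero curve has no mean time")
  sum(times * curve) / s
}

#' Align acquisition timing by trimming initial frames
#'
#' Computes the ROI-mean pyruvate curve, then picks the number of initial
#' frames to remove (from `candidates`, plus 0 if the untrimmed series is
#' already within `tolerance_s`) so that the mean time of the trimmed curve —
#' measured from the first retained frame — is closest to
#' `reference_mean_time`.  Ties go to fewer frames removed.  The chosen count
#' is meant to be applied to all metabolites of the study.
#'
#' @param d a `combined_dynamic` or 3D array (y, x, time) of pyruvate.
#' @param times frame timestamps (s); taken from `d` when available.
#' @param reference_mean_time target mean time (s), e.g. from a reference
#'   study.
#' @param roi optional logical mask for the ROI-mean curve (default: whole
#'   image).
#' @param candidates candidate removal counts (default `c(3, 4)`).
#' @param tolerance_s if the untrimmed mean time is within this of the
#'   reference, nothing is removed (default half a frame spacing).
#' @return list: `frames_removed`, `mean_time_s` (after trimming),
#'   `trimmed` (3D array), `times` (re-referenced to the first retained
#'   frame).
#' @export
mean_time_correct <- function(d, reference_mean_time, times = NULL, roi = NULL,
                              candidates = c(3L, 4L), tolerance_s = NULL) {
  if (inherits(d, "combined_dynamic")) {
    if (is.null(times)) times <- d$times
    d <- d$data
  }
  nt <- dim(d)[3]
  if (is.null(times)) times <- seq_len(nt) - 1
  if (is.null(tolerance_s)) tolerance_s <- diff(times)[1] / 2
  if (is.null(roi)) roi <- matrix(TRUE, dim(d)[1], dim(d)[2])
  curve <- vapply(seq_len(nt), function(k) mean(Mod(d[, , k])[roi]), 0)
  mt_of <- function(k) {
    idx <- seq(k + 1L, nt)
    mean_time(curve[idx], times[idx] - times[idx[1]])
  }
  if (abs(mt_of(0L) - reference_mean_time) <= tolerance_s) {
    chosen <- 0L
  } else {
    candidates <- sort(unique(as.integer(candidates)))
    if (any(nt - candidates < 3L)) stop("trimming would leave fewer than 3 frames")
    errs <- vapply(candidates, function(k) abs(mt_of(k) - reference_mean_time), 0)
    chosen <- candidates[which.min(errs)]   # which.min takes the first = fewest
  }
  idx <- seq(chosen + 1L, nt)
  list(frames_removed = chosen, mean_time_s = mt_of(chosen),
       trimmed = d[, , idx, drop = FALSE], times = times[idx] - times[idx][1])
}

#' Voxel-size normalization of an AUC map
#'
#' Divides by the acquired-to-reference voxel area ratio, e.g. the (2 cm)^2 /
#' (1 cm)^2 = 4 divisor applied to bicarbonate acquired at 2 cm against 1 cm
#' pyruvate.
#'
#' @param auc an [compute_auc_map()] result.
#' @param ref_area_cm2 reference voxel area (the pyruvate acquisition's).
#' @return the normalized `auc_map` (its `voxel_area_cm2` set to the
#'   reference).
#' @export
normalize_voxel_size <- function(auc, ref_area_cm2) {
  stopifnot(inherits(auc, "auc_map"))
  stopifnot_scalar_pos(ref_area_cm2, "ref_area_cm2")
  stopifnot_scalar_pos(auc$voxel_area_cm2, "voxel_area_cm2")
  auc$values <- auc$values / (auc$voxel_area_cm2 / ref_area_cm2)
  auc$voxel_area_cm2 <- ref_area_cm2
  auc
}

#' AUC map in noise-SD units
#'
#' Divides the AUC map by the noise level of the AUC (sigma of a single
#' frame propagated through the frame sum), yielding an AUC SNR image.
#'
#' @param auc an [compute_auc_map()] result.
#' @param noise_sigma positive noise level of the AUC map.
#' @return ny x nx SNR image.
#' @export
auc_snr <- function(auc, noise_sigma) {
  stopifnot(inherits(auc, "auc_map"))
  stopifnot_scalar_pos(noise_sigma, "noise_sigma")
  auc$values / noise_sigma
}

#' Noise level of an AUC map from the tail of the combined series
#'
#' Per-frame noise SD is estimated as the standard deviation of the combined
#' magnitude over the last `n_last_frames`, and propagated through the
#' n-frame magnitude sum as `sd * sqrt(n_frames_used)`.
#'
#' @param d a `combined_dynamic` or 3D array.
#' @param n_frames_used frames entering the AUC sum.
#' @param n_last_frames trailing frames sampled for noise (default 5).
#' @param mask optional logical mask restricting the sample (default: whole
#'   image).
#' @return scalar AUC noise sigma.
#' @export
estimate_auc_noise <- function(d, n_frames_used, n_last_frames = 5L, mask = NULL) {
  if (inherits(d, "combined_dynamic")) d <- d$data
  nt <- dim(d)[3]
  win <- seq(nt - n_last_frames + 1L, nt)
  if (is.null(mask)) mask <- matrix(TRUE, dim(d)[1], dim(d)[2])
  samples <- unlist(lapply(win, function(k) Mod(d[, , k])[mask]))
  stats::sd(samples) * sqrt(n_frames_used)
}

#' Normalized metabolite-to-pyruvate ratio map
#'
#' Divides the metabolite AUC map by a single scalar: the maximum of the
#' pyruvate AUC over the kidney mask.  Voxels outside the mask are set to
#' `NA` (never zero).  A per-voxel denominator mode is available behind
#' `per_voxel = TRUE`.
#'
#' @param met_auc metabolite [compute_auc_map()] result.
#' @param pyr_auc pyruvate [compute_auc_map()] result, same geometry.
#' @param kidney_mask non-empty logical mask.
#' @param per_voxel divide voxelwise by the pyruvate AUC instead of by its
#'   kidney maximum (default FALSE).
#' @return object of class `ratio_map`: `values` (NA outside mask),
#'   `numerator`, `denominator`, `normalization` (record of factors applied).
#' @export
metabolite_ratio_map <- function(met_auc, pyr_auc, kidney_mask,
                                 per_voxel = FALSE) {
  stopifnot(inherits(met_auc, "auc_map"), inherits(pyr_auc, "auc_map"))
  if (!any(kidney_mask)) stop("kidney mask is empty")
  if (!all(dim(met_auc$values) == dim(pyr_auc$values)) ||
      !all(dim(kidney_mask) == dim(pyr_auc$values))) {
    stop("AUC maps and mask must share one geometry")
  }
  pyr_max <- max(pyr_auc$values[kidney_mask])
  if (pyr_max <= 0) stop("maximum kidney pyruvate AUC is zero")
  values <- matrix(NA_real_, nrow(met_auc$values), ncol(met_auc$values))
  if (per_voxel) {
    den <- pyr_auc$values[kidney_mask]
    values[kidney_mask] <- ifelse(den > 0, met_auc$values[kidney_mask] / den, NA_real_)
  } else {
    values[kidney_mask] <- met_auc$values[kidney_mask] / pyr_max
  }
  structure(
    list(values = values, numerator = met_auc$metabolite,
         denominator = pyr_auc$metabolite,
         normalization = list(max_pyruvate_auc = pyr_max,
                              voxel_area_cm2 = met_auc$voxel_area_cm2,
                              per_voxel = per_voxel)),
    class = "ratio_map"
  )
}

#' ROI mean and standard deviation
#'
#' Population SD (divide by n) by default; set `sample_sd = TRUE` for the
#' n - 1 convention.
#'
#' @param map numeric image (NAs outside the analysis region are ignored
#'   only if `na.rm = TRUE`).
#' @param roi non-empty logical mask.
#' @param sample_sd use the sample (n-1) SD instead of population SD.
#' @param na.rm drop NA voxels inside the ROI.
#' @return object of class `roi_stats`: `mean`, `sd`, `n_voxels`.
#' @export
roi_stats <- function(map, roi, sample_sd = FALSE, na.rm = FALSE) {
  if (inherits(map, "ratio_map") || inherits(map, "auc_map")) map <- map$values
  if (!any(roi)) stop("empty ROI")
  v <- map[roi]
  if (na.rm) v <- v[!is.na(v)]
  if (length(v) == 0L) stop("ROI contains no usable voxels")
  n <- length(v)
  m <- mean(v)
  s <- if (n == 1L) 0 else sqrt(sum((v - m)^2) / if (sample_sd) (n - 1) else n)
  structure(list(mean = m, sd = s, n_voxels = n), class = "roi_stats")
}

#' Group-level summary of per-subject means
#'
#' @param subject_means numeric vector, length >= 1.
#' @return object of class `group_summary`: `mean`, `min`, `max`,
#'   `n_subjects`.
#' @export
group_summary <- function(subject_means) {
  if (length(subject_means) < 1L || any(!is.finite(subject_means))) {
    stop("subject_means must be a non-empty finite vector")
  }
  structure(
    list(mean = mean(subject_means), min = min(subject_means),
         max = max(subject_means), n_subjects = length(subject_means)),
    class = "group_summary"
  )
}

#' Nearest-neighbour upsampling of a mask or label image
#'
#' Maps ROI masks drawn on the acquisition grid onto the Fermi-zero-filled
#' grid.
#'
#' @param m matrix (logical or numeric).
#' @param target_shape integer pair, each a multiple-free >= source.
#' @return matrix of dimension `target_shape`, same mode as input.
#' @export
upsample_nearest <- function(m, target_shape) {
  src <- dim(m)
  iy <- pmin(src[1], pmax(1L, round((seq_len(target_shape[1]) - 0.5) * src[1] / target_shape[1] + 0.5)))
  ix <- pmin(src[2], pmax(1L, round((seq_len(target_shape[2]) - 0.5) * src[2] / target_shape[2] + 0.5)))
  m[iy, ix, drop = FALSE]
}
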