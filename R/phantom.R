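# Digital-kidney phantom: geometry, kinetics, coils, noise, and the companion
# proton (DWI / multi-echo) series.  Everything downstream is validated
# against data generated here, where the ground truth is known.

#' Digital-kidney phantom geometry
#'
#' Builds the label map the simulator and the quantification masks operate on:
#' `0` background, `1` renal cortex (outer rim of an ellipse), `2` medulla
#' (interior), `3` vascular input region (a small disc anterior to the
#' kidney).  The geometry is deterministic; `seed` is carried along for the
#' stochastic stages (noise) that consume it.
#'
#' @param grid_shape integer pair `(ny, nx)`; default 64 x 64.
#' @param fov_cm physical field of view in cm (isotropic); default 50.
#' @param seed integer seed recorded with the phantom.
#' @return An object of class `phantom_spec` with fields `grid_shape`,
#'   `fov_cm`, `labels` (ny x nx integer matrix), `seed`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L), fov_cm = 50, seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 16))
  stopifnot_scalar_pos(fov_cm, "fov_cm")
  ny <- as.integer(grid_shape[1]); nx <- as.integer(grid_shape[2])
  y <- matrix(seq_len(ny), ny, nx)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  # kidney: ellipse in the lower-central image, anterior (small y) side up
  cy <- 0.55 * ny; cx <- 0.5 * nx
  ay <- 0.28 * ny; ax <- 0.22 * nx
  r2 <- ((y - cy) / ay)^2 + ((x - cx) / ax)^2
  labels <- matrix(0L, ny, nx)
  labels[r2 <= 1] <- 1L                 # cortex (rim filled below)
  labels[r2 <= 0.45] <- 2L              # medulla
  # vascular input region: small disc anterior (above) the kidney
  vy <- 0.18 * ny; vx <- 0.5 * nx; vr <- 0.06 * min(ny, nx)
  labels[(y - vy)^2 + (x - vx)^2 <= vr^2] <- 3L
  stopifnot(any(labels == 1L), any(labels == 2L))
  structure(
    list(grid_shape = c(ny, nx), fov_cm = fov_cm, labels = labels,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Kidney mask of a phantom (cortex + medulla)
#' @param spec a [phantom_spec()].
#' @return logical ny x nx matrix.
#' @export
kidney_mask <- function(spec) spec$labels == 1L | spec$labels == 2L

#' Ground-truth kinetic and input-function parameters
#'
#' Apparent conversion rates and the gamma-variate arterial input function
#' (AIF) driving the two-site exchange simulation.  `kpl` and `kpb` may be
#' scalars or length-3 vectors giving distinct rates for cortex, medulla and
#' the vascular region (vascular conversion is typically 0).  Defaults are
#' the package's frozen ground truth for a normally functioning allograft
#' (see the methods vignette for the calibration rationale).
#'
#' @param kpl apparent pyruvate->lactate rate, 1/s (scalar or cortex/medulla/
#'   vascular triple).
#' @param kpb apparent pyruvate->bicarbonate rate, 1/s (same shape as `kpl`).
#' @param t1_pyr,t1_lac,t1_bic longitudinal relaxation times, s.
#' @param aif_t0 bolus arrival delay after injection start, s.
#' @param aif_alpha,aif_beta gamma-variate shape and scale (s).
#' @param aif_amplitude AIF amplitude, arbitrary signal units.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(kpl = c(0.13, 0.091, 0),
                           kpb = c(0.013, 0.0095, 0),
                           t1_pyr = 30, t1_lac = 25, t1_bic = 25,
                           aif_t0 = 18, aif_alpha = 2.5, aif_beta = 4.5,
                           aif_amplitude = 100) {
  expand3 <- function(v, name) {
    if (length(v) == 1L) v <- c(v, v, 0)
    if (length(v) != 3L || any(v < 0) || any(!is.finite(v))) {
      stop(sprintf("'%s' must be a nonnegative scalar or length-3 vector", name))
    }
    v
  }
  for (nm in c("t1_pyr", "t1_lac", "t1_bic", "aif_alpha", "aif_beta",
               "aif_amplitude")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (!is.numeric(aif_t0) || aif_t0 < 0) stop("'aif_t0' must be nonnegative")
  structure(
    list(kpl = expand3(kpl, "kpl"), kpb = expand3(kpb, "kpb"),
         t1_pyr = t1_pyr, t1_lac = t1_lac, t1_bic = t1_bic,
         aif_t0 = aif_t0, aif_alpha = aif_alpha, aif_beta = aif_beta,
         aif_amplitude = aif_amplitude),
    class = "kinetic_params"
  )
}

#' Acquisition parameters of the dynamic 13C protocol
#'
#' Defaults follow the clinical protocol this package emulates: 3.5 s
#' temporal resolution, 20 deg pyruvate / 60 deg lactate and bicarbonate flip
#' angles, 1 cm in-plane resolution for pyruvate and lactate and 2 cm for
#' bicarbonate, 50 cm FOV, 21 mm slice.  `excitations_per_frame` is the
#' *effective* per-frame RF consumption exponent N in cos(theta)^N (see the
#' methods vignette for why this is not the raw phase-encode count).
#'
#' @param temporal_resolution_s frame spacing in seconds.
#' @param n_timepoints number of dynamic frames.
#' @param flip_deg named numeric: flip angle per metabolite, degrees.
#' @param tr_ms named numeric: repetition time per metabolite, ms.
#' @param excitations_per_frame named numeric: consumption exponent per frame.
#' @param inplane_res_cm named numeric: in-plane resolution per metabolite.
#' @param slice_thickness_mm slice thickness, mm.
#' @param fov_cm field of view, cm.
#' @return object of class `acq_params`.
#' @export
acq_params <- function(temporal_resolution_s = 3.5,
                       n_timepoints = 30L,
                       flip_deg = c(pyruvate = 20, lactate = 60, bicarbonate = 60),
                       tr_ms = c(pyruvate = 80, lactate = 15.3, bicarbonate = 9.8),
                       excitations_per_frame = c(pyruvate = 4, lactate = 1, bicarbonate = 1),
                       inplane_res_cm = c(pyruvate = 1, lactate = 1, bicarbonate = 2),
                       slice_thickness_mm = 21,
                       fov_cm = 50) {
  stopifnot_scalar_pos(temporal_resolution_s, "temporal_resolution_s")
  stopifnot(is_count(n_timepoints), n_timepoints >= 2)
  mets <- c("pyruvate", "lactate", "bicarbonate")
  for (v in list(flip_deg, tr_ms, excitations_per_frame, inplane_res_cm)) {
    stopifnot(all(mets %in% names(v)))
  }
  if (any(flip_deg <= 0) || any(flip_deg > 90)) {
    stop("flip angles must lie in (0, 90] degrees")
  }
  structure(
    list(temporal_resolution_s = temporal_resolution_s,
         n_timepoints = as.integer(n_timepoints),
         flip_deg = flip_deg[mets], tr_ms = tr_ms[mets],
         excitations_per_frame = excitations_per_frame[mets],
         inplane_res_cm = inplane_res_cm[mets],
         slice_thickness_mm = slice_thickness_mm, fov_cm = fov_cm),
    class = "acq_params"
  )
}

#' Frame timestamps of an acquisition, seconds from injection start
#' @param acq an [acq_params()].
#' @return numeric vector of length `n_timepoints`.
#' @export
frame_times <- function(acq) {
  seq(0, by = acq$temporal_resolution_s, length.out = acq$n_timepoints)
}

#' Receive-coil model: sensitivity profiles and channel noise covariance
#'
#' Emulates a flexible receive array placed on the anterior body wall:
#' each channel's sensitivity falls off exponentially with distance from its
#' element centre along the anterior (top) image edge, so signal is brightest
#' toward that edge.  Profiles are complex (smooth per-channel phase) and
#' normalized so their root-sum-of-squares is 1 at the kidney centre.  The
#' channel noise covariance is Toeplitz with nearest-neighbour correlation
#' `rho`, scaled to `noise_sigma^2` on the diagonal.
#'
#' @param spec a [phantom_spec()].
#' @param n_channels number of receive channels; default 8.
#' @param noise_sigma per-channel complex noise standard deviation.
#' @param rho correlation between channels `i`, `j` decaying as `rho^|i-j|`.
#' @param falloff_frac sensitivity 1/e decay length as a fraction of the
#'   image height.
#' @param rss_norm `"centre"` (default): root-sum-of-squares scaled to 1 at
#'   the kidney centroid, leaving realistic anterior-posterior shading in the
#'   combined image; `"flat"`: unit RSS at every voxel (per-channel
#'   inhomogeneity retained), the configuration in which self-calibrated
#'   matched-filter combination is exactly transparent.
#' @return object of class `coil_model` with `profiles` (ny x nx x channel
#'   complex array) and `noise_covariance`.
#' @export
coil_model <- function(spec, n_channels = 8L, noise_sigma = 11, rho = 0.2,
                       falloff_frac = 0.55, rss_norm = c("centre", "flat")) {
  rss_norm <- match.arg(rss_norm)
  stopifnot(inherits(spec, "phantom_spec"), is_count(n_channels), n_channels >= 1)
  stopifnot_scalar_pos(noise_sigma, "noise_sigma")
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  y <- matrix(seq_len(ny), ny, nx)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  lambda <- falloff_frac * ny
  profiles <- array(0 + 0i, dim = c(ny, nx, n_channels))
  for (c_ in seq_len(n_channels)) {
    xc <- (c_ - 0.5) / n_channels * nx
    d <- sqrt((y - 1)^2 + (x - xc)^2)        # distance from element on top edge
    mag <- exp(-d / lambda)
    pha <- 2 * pi * (c_ - 1) / n_channels + 0.4 * (x - xc) / nx
    profiles[, , c_] <- mag * exp(1i * pha)
  }
  if (rss_norm == "flat") {
    rss <- sqrt(apply(Mod(profiles)^2, c(1, 2), sum))
    for (c_ in seq_len(n_channels)) profiles[, , c_] <- profiles[, , c_] / rss
  } else {
    # RSS = 1 at the kidney centroid; shading elsewhere retained
    km <- kidney_mask(spec)
    cy <- round(mean(y[km])); cx <- round(mean(x[km]))
    rss0 <- sqrt(sum(Mod(profiles[cy, cx, ])^2))
    profiles <- profiles / rss0
  }
  cov <- noise_sigma^2 * rho^abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  structure(
    list(n_channels = as.integer(n_channels),
         profiles = profiles,
         noise_covariance = cov + 0i),
    class = "coil_model"
  )
}

#' Gamma-variate arterial input function
#'
#' `amplitude * ((t - t0)/beta)^alpha * exp(-(t - t0)/beta)` for `t >= t0`,
#' zero before bolus arrival.  The peak sits at `t0 + alpha * beta`.
#'
#' @param kp a [kinetic_params()] carrying `aif_t0`, `aif_alpha`, `aif_beta`,
#'   `aif_amplitude`.
#' @param times nonnegative, strictly increasing time vector (s).
#' @return numeric vector of AIF values at `times`.
#' @export
gamma_variate_aif <- function(kp, times) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (any(times < 0)) stop("times must be nonnegative")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  tau <- pmax(times - kp$aif_t0, 0) / kp$aif_beta
  kp$aif_amplitude * tau^kp$aif_alpha * exp(-tau)
}

# One-way two-site exchange with T1 loss and per-frame RF consumption,
# integrated with fixed-step RK4 between frames.  `supply` is a function of
# time feeding the pyruvate pool; conversion draws on the longitudinal pool.
#' Metabolite kinetics along one dynamic acquisition
#'
#' Solves dP/dt = u(t) - (kpl + kpb + 1/T1p) P, dL/dt = kpl P - L/T1l,
#' dB/dt = kpb P - B/T1b between frame times; at each frame the longitudinal
#' magnetization is sampled as the signal and then multiplied by
#' `cos(theta)^N` (RF consumption).
#'
#' @param times frame timestamps (s), strictly increasing; integration starts
#'   at t = 0 with state `(p0, l0, b0)`.
#' @param supply function of time: pyruvate inflow rate (signal units / s).
#' @param kpl,kpb conversion rates (1/s).
#' @param t1_pyr,t1_lac,t1_bic T1 times (s); `Inf` disables relaxation.
#' @param flip_deg named flip angles (deg) as in [acq_params()]; they enter
#'   through the consumption term only — the excitation efficiency sin(theta)
#'   is a constant per metabolite and is absorbed into the arbitrary signal
#'   units.
#' @param nex named per-frame consumption exponents as in [acq_params()];
#'   0 disables consumption.
#' @param p0,l0,b0 initial longitudinal magnetizations.
#' @param n_substeps RK4 substeps per frame interval.
#' @return list with `times` and per-frame signal vectors `pyr`, `lac`, `bic`.
#' @export
metabolite_kinetics <- function(times, supply, kpl, kpb,
                                t1_pyr = 30, t1_lac = 25, t1_bic = 25,
                                flip_deg = c(pyruvate = 20, lactate = 60, bicarbonate = 60),
                                nex = c(pyruvate = 1, lactate = 1, bicarbonate = 1),
                                p0 = 0, l0 = 0, b0 = 0,
                                n_substeps = 40L) {
  stopifnot(is.function(supply), all(diff(times) > 0), kpl >= 0, kpb >= 0)
  rp <- kpl + kpb + 1 / t1_pyr
  rl <- 1 / t1_lac
  rb <- 1 / t1_bic
  deriv <- function(t, s) {
    c(supply(t) - rp * s[1], kpl * s[1] - rl * s[2], kpb * s[1] - rb * s[3])
  }
  rk4_to <- function(s, t_from, t_to) {
    h <- (t_to - t_from) / n_substeps
    t <- t_from
    for (i in seq_len(n_substeps)) {
      k1 <- deriv(t, s)
      k2 <- deriv(t + h / 2, s + h / 2 * k1)
      k3 <- deriv(t + h / 2, s + h / 2 * k2)
      k4 <- deriv(t + h, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    s
  }
  nt <- length(times)
  out <- matrix(0, nt, 3)
  s <- c(p0, l0, b0)
  th <- flip_deg[c("pyruvate", "lactate", "bicarbonate")] * pi / 180
  cons <- cos(th)^nex[c("pyruvate", "lactate", "bicarbonate")]
  t_prev <- 0
  for (k in seq_len(nt)) {
    if (times[k] > t_prev) s <- rk4_to(s, t_prev, times[k])
    out[k, ] <- s
    s <- s * cons
    t_prev <- times[k]
  }
  list(times = times, pyr = out[, 1], lac = out[, 2], bic = out[, 3])
}

#' Noiseless dynamic metabolite images of a phantom
#'
#' Runs the two-site exchange model per tissue label (the kinetics are linear
#' in the supply, so one solve per label suffices) and paints the resulting
#' curves into the label geometry.  The vascular region carries the AIF
#' directly (no conversion by default); cortex and medulla receive a
#' perfusion-weighted copy of the AIF as supply.
#'
#' @param spec a [phantom_spec()].
#' @param kp a [kinetic_params()].
#' @param acq an [acq_params()].
#' @param perfusion per-label supply weights `(cortex, medulla, vascular)`.
#' @return object of class `metab_dynamics`: list of ny x nx x time arrays
#'   `pyruvate`, `lactate`, `bicarbonate`, plus `times`, `spec`, `acq`, `kp`.
#' @export
simulate_dynamics <- function(spec, kp, acq,
                              perfusion = c(cortex = 1, medulla = 0.6, vascular = 3)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kp, "kinetic_params"),
            inherits(acq, "acq_params"))
  times <- frame_times(acq)
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]; nt <- length(times)
  supply <- function(t) gamma_variate_aif(kp, t)
  arr <- function() array(0, dim = c(ny, nx, nt))
  out <- list(pyruvate = arr(), lactate = arr(), bicarbonate = arr())
  for (lab in 1:3) {
    vox <- spec$labels == lab
    if (!any(vox)) next
    kin <- metabolite_kinetics(
      times, supply, kpl = kp$kpl[lab], kpb = kp$kpb[lab],
      t1_pyr = kp$t1_pyr, t1_lac = kp$t1_lac, t1_bic = kp$t1_bic,
      flip_deg = acq$flip_deg, nex = acq$excitations_per_frame
    )
    w <- perfusion[lab]
    for (k in seq_len(nt)) {
      sl <- out$pyruvate[, , k]; sl[vox] <- w * kin$pyr[k]; out$pyruvate[, , k] <- sl
      sl <- out$lactate[, , k];  sl[vox] <- w * kin$lac[k]; out$lactate[, , k] <- sl
      sl <- out$bicarbonate[, , k]; sl[vox] <- w * kin$bic[k]; out$bicarbonate[, , k] <- sl
    }
  }
  structure(c(out, list(times = times, spec = spec, acq = acq, kp = kp)),
            class = "metab_dynamics")
}

#' Project a dynamic image series onto receive channels and add noise
#'
#' Channel `c` receives `profile_c * image + n`, with `n` drawn from a
#' circular complex Gaussian with the coil's channel covariance, independent
#' across voxels and frames.  Reproducible under a fixed seed.
#'
#' @param images ny x nx x time real (or complex) array of noiseless signal.
#' @param coil a [coil_model()].
#' @param seed integer; set before drawing noise.
#' @param metabolite label stored with the result.
#' @param times frame timestamps (s).
#' @param acq an [acq_params()] (carried as metadata).
#' @return object of class `multichannel_dynamic`: complex array `data` of
#'   dim (ny, nx, time, channel) plus `metabolite`, `times`, `acq`.
#' @export
apply_coils_and_noise <- function(images, coil, seed, metabolite = "pyruvate",
                                  times = NULL, acq = NULL) {
  stopifnot(inherits(coil, "coil_model"))
  d <- dim(images)
  stopifnot(length(d) == 3L, all(d[1:2] == dim(coil$profiles)[1:2]))
  nc <- coil$n_channels
  L <- tryCatch(chol_complex(coil$noise_covariance), error = function(e) {
    if (max(Mod(coil$noise_covariance)) == 0) NULL else stop(e)
  })
  set.seed(as.integer(seed))
  out <- array(0 + 0i, dim = c(d, nc))
  nvox <- prod(d)
  noise <- if (is.null(L)) {
    matrix(0 + 0i, nc, nvox)
  } else {
    rcnorm_mat(nc, nvox, L)
  }
  for (c_ in seq_len(nc)) {
    out[, , , c_] <- as.complex(images) * as.vector(coil$profiles[, , c_]) +
      array(noise[c_, ], dim = d)
  }
  multichannel_dynamic(out, metabolite = metabolite, times = times, acq = acq)
}

#' Simulated diffusion-weighted series
#'
#' Mono-exponential decay `S(b) = S0 * exp(-b * ADC)` with optional Gaussian
#' noise on the magnitude signal.
#'
#' @param spec a [phantom_spec()] (geometry check only).
#' @param adc_map ny x nx map of apparent diffusion coefficients, mm^2/s.
#' @param s0_map ny x nx map of unweighted signal.
#' @param b_values distinct nonnegative b-values, s/mm^2; default the 8-value
#'   renal protocol 25-1000.
#' @param noise_sd Gaussian noise SD (signal units); 0 = noiseless.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return object of class `diffusion_series`: `data` (ny x nx x nb),
#'   `b_values`.
#' @export
simulate_dwi <- function(spec, adc_map, s0_map,
                         b_values = c(25, 50, 75, 100, 300, 600, 800, 1000),
                         noise_sd = 0, seed = 1L) {
  stopifnot(all(dim(adc_map) == spec$grid_shape), all(dim(s0_map) == spec$grid_shape))
  if (any(adc_map < 0)) stop("adc_map must be nonnegative")
  if (any(b_values < 0) || anyDuplicated(b_values)) {
    stop("b_values must be distinct and nonnegative")
  }
  b_values <- sort(b_values)
  nb <- length(b_values)
  data <- array(0, dim = c(dim(adc_map), nb))
  for (k in seq_len(nb)) {
    data[, , k] <- s0_map * exp(-b_values[k] * adc_map)
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    data <- data + array(stats::rnorm(length(data), sd = noise_sd), dim = dim(data))
  }
  structure(list(data = data, b_values = b_values), class = "diffusion_series")
}

#' Simulated multi-echo gradient-echo series
#'
#' `S(TE) = S0 * exp(-TE * R2*)`, optional Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param r2star_map ny x nx map of R2* rates, 1/s.
#' @param s0_map ny x nx map of TE = 0 signal.
#' @param echo_times at least two distinct positive echo times, s; default
#'   three echoes starting at 2.6 ms.
#' @param noise_sd,seed as in [simulate_dwi()].
#' @return object of class `multiecho_series`: `data` (ny x nx x necho),
#'   `echo_times`.
#' @export
simulate_multiecho <- function(spec, r2star_map, s0_map,
                               echo_times = c(2.6, 4.7, 6.8) / 1000,
                               noise_sd = 0, seed = 1L) {
  stopifnot(all(dim(r2star_map) == spec$grid_shape))
  if (length(unique(echo_times)) < 2) stop("need at least 2 distinct echo times")
  echo_times <- sort(echo_times)
  ne <- length(echo_times)
  data <- array(0, dim = c(dim(r2star_map), ne))
  for (k in seq_len(ne)) {
    data[, , k] <- s0_map * exp(-echo_times[k] * r2star_map)
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    data <- data + array(stats::rnorm(length(data), sd = noise_sd), dim = dim(data))
  }
  structure(list(data = data, echo_times = echo_times), class = "multiecho_series")
}

#' Ground-truth proton parameter maps of a phantom
#'
#' Typical renal values: ADC 2.0e-3 (cortex) / 1.8e-3 (medulla) mm^2/s,
#' R2* 15 / 25 1/s; background near-zero signal.
#'
#' @param spec a [phantom_spec()].
#' @return list of ny x nx maps `adc`, `r2star`, `s0`.
#' @export
phantom_parameter_maps <- function(spec) {
  lab <- spec$labels
  adc <- matrix(0.8e-3, nrow(lab), ncol(lab))   # background tissue
  adc[lab == 1L] <- 2.0e-3
  adc[lab == 2L] <- 1.8e-3
  adc[lab == 3L] <- 3.0e-3                      # blood
  r2s <- matrix(40, nrow(lab), ncol(lab))
  r2s[lab == 1L] <- 15
  r2s[lab == 2L] <- 25
  r2s[lab == 3L] <- 20
  s0 <- matrix(10, nrow(lab), ncol(lab))
  s0[lab != 0L] <- 100
  list(adc = adc, r2star = r2s, s0 = s0)
}

#' Simulate one complete study (13C dynamics + proton series)
#'
#' The one-call generator the pipeline, tests and analysis scripts use:
#' noiseless dynamics, coil projection with correlated complex noise for each
#' metabolite, and companion DWI / multi-echo series.  The coarser
#' bicarbonate acquisition is emulated by scaling its noiseless signal by the
#' voxel-area ratio relative to pyruvate before adding noise.
#'
#' @param spec a [phantom_spec()].
#' @param kp a [kinetic_params()].
#' @param acq an [acq_params()].
#' @param coil a [coil_model()]; default built from `spec`.
#' @param seed integer master seed (per-metabolite seeds derived from it).
#' @param dwi_noise_sd,me_noise_sd Gaussian noise for the proton series.
#' @return object of class `hp_study`: `channels` (named list of
#'   `multichannel_dynamic`), `truth` (noiseless images + parameter maps),
#'   `dwi`, `multiecho`, `spec`, `kp`, `acq`, `coil`, `seed`.
#' @export
simulate_study <- function(spec = phantom_spec(), kp = kinetic_params(),
                           acq = acq_params(), coil = NULL,
                           seed = spec$seed, dwi_noise_sd = 2, me_noise_sd = 2) {
  if (is.null(coil)) coil <- coil_model(spec)
  dyn <- simulate_dynamics(spec, kp, acq)
  area_ratio <- (acq$inplane_res_cm / acq$inplane_res_cm[["pyruvate"]])^2
  channels <- list()
  mets <- c("pyruvate", "lactate", "bicarbonate")
  for (i in seq_along(mets)) {
    m <- mets[i]
    img <- dyn[[m]] * area_ratio[[m]]
    channels[[m]] <- apply_coils_and_noise(
      img, coil, seed = as.integer(seed) + i, metabolite = m,
      times = dyn$times, acq = acq
    )
  }
  maps <- phantom_parameter_maps(spec)
  dwi <- simulate_dwi(spec, maps$adc, maps$s0, noise_sd = dwi_noise_sd,
                      seed = as.integer(seed) + 11L)
  me <- simulate_multiecho(spec, maps$r2star, maps$s0, noise_sd = me_noise_sd,
                           seed = as.integer(seed) + 12L)
  structure(
    list(channels = channels,
         truth = list(dynamics = dyn, maps = maps),
         dwi = dwi, multiecho = me,
         spec = spec, kp = kp, acq = acq, coil = coil,
         seed = as.integer(seed)),
    class = "hp_study"
  )
}
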