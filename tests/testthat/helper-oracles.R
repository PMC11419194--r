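# Shared fixtures and independent oracles.  Oracles are deliberately written
# as naive loops / explicit sums so they share no code path with the package.

tiny_spec <- function(n = 24L, seed = 7L) {
  phantom_spec(grid_shape = c(n, n), seed = seed)
}

tiny_acq <- function(nt = 12L, dt = 3.5) {
  acq_params(n_timepoints = nt, temporal_resolution_s = dt)
}

# A bare coil object with explicit profiles/covariance for unit tests.
make_coil <- function(profiles, covariance) {
  structure(
    list(n_channels = dim(profiles)[3], profiles = profiles,
         noise_covariance = covariance + 0i),
    class = "coil_model"
  )
}

# Pure-noise multi-channel series with channel covariance Sigma.
noise_series <- function(ny, nx, nt, sigma_mat, seed = 1L) {
  nc <- nrow(sigma_mat)
  profiles <- array(0 + 0i, dim = c(ny, nx, nc))
  coil <- make_coil(profiles, sigma_mat)
  img <- array(0, dim = c(ny, nx, nt))
  apply_coils_and_noise(img, coil, seed = seed)
}

# Forward Euler integration of the two-site exchange model, mirroring the
# frame sampling + RF consumption contract, at a very fine step.
euler_kinetics <- function(times, supply, kpl, kpb, t1p, t1l, t1b,
                           flip, nex, n_sub = 4000L) {
  s <- c(0, 0, 0)
  th <- flip * pi / 180
  cons <- cos(th)^nex
  out <- matrix(0, length(times), 3)
  t_prev <- 0
  for (k in seq_along(times)) {
    if (times[k] > t_prev) {
      h <- (times[k] - t_prev) / n_sub
      t <- t_prev
      for (i in seq_len(n_sub)) {
        d1 <- supply(t) - (kpl + kpb + 1 / t1p) * s[1]
        d2 <- kpl * s[1] - s[2] / t1l
        d3 <- kpb * s[1] - s[3] / t1b
        s <- s + h * c(d1, d2, d3)
        t <- t + h
      }
    }
    out[k, ] <- s
    s <- s * cons
    t_prev <- times[k]
  }
  out
}

# Explicit-sum 2D DFT oracle for the Fermi zero-fill: forward DFT, centred
# radial Fermi window, symmetric zero-pad, inverse DFT, 1/prod(src) scaling.
dft_fermi_zero_fill <- function(img, target, cutoff, width) {
  src <- dim(img)
  dft2 <- function(m, inverse = FALSE) {
    d <- dim(m)
    out <- matrix(0 + 0i, d[1], d[2])
    sgn <- if (inverse) 1 else -1
    for (u in 0:(d[1] - 1)) for (v in 0:(d[2] - 1)) {
      acc <- 0 + 0i
      for (y in 0:(d[1] - 1)) for (x in 0:(d[2] - 1)) {
        acc <- acc + m[y + 1, x + 1] *
          exp(sgn * 2i * pi * (u * y / d[1] + v * x / d[2]))
      }
      out[u + 1, v + 1] <- acc
    }
    out
  }
  ksp <- dft2(img)
  big <- matrix(0 + 0i, target[1], target[2])
  for (u in 0:(src[1] - 1)) for (v in 0:(src[2] - 1)) {
    # signed frequency of bin, in units of Nyquist
    fu <- if (u < ceiling(src[1] / 2)) u else u - src[1]
    fv <- if (v < ceiling(src[2] / 2)) v else v - src[2]
    r <- sqrt((fu / (src[1] / 2))^2 + (fv / (src[2] / 2))^2)
    w <- 1 / (1 + exp((r - cutoff) / width))
    ut <- if (fu >= 0) fu else fu + target[1]
    vt <- if (fv >= 0) fv else fv + target[2]
    big[ut + 1, vt + 1] <- ksp[u + 1, v + 1] * w
  }
  dft2(big, inverse = TRUE) / prod(src)
}

# Memoised expensive pipeline runs shared across test files.
.run_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(key, cfg) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- run_pipeline(cfg)
  .run_cache[[key]]
}

kpl_tier_ratios <- function(kpls = c(0.005, 0.01, 0.02), seed = 11L) {
  vapply(kpls, function(k) {
    cfg <- study_config(subject_id = sprintf("kpl-%g", k), seed = seed,
                        kinetics = list(kpl = c(k, 0.7 * k, 0)))
    cached_pipeline(sprintf("tier-%g-%d", k, seed), cfg)$report_row$lac_pyr_mean
  }, 0)
}

# Timing-jittered replicates of one phantom: identical post-bolus sampling,
# `lead` extra pre-bolus frames.  Returns cortical lactate-to-pyruvate
# ratios with or without mean-time correction.
jitter_replicate_ratios <- function(correct, leads = c(0L, 3L, 4L)) {
  ref <- cached_pipeline("jit-ref", study_config(
    subject_id = "jitref", seed = 41, kinetics = list(aif_t0 = 8),
    acquisition = list(n_timepoints = 26L)))
  ref_mt <- mean_time_correct(ref$recon$combined$pyruvate,
                              reference_mean_time = Inf,
                              roi = kidney_mask(ref$study$spec),
                              tolerance_s = Inf)$mean_time_s
  vapply(seq_along(leads), function(i) {
    L <- leads[i]
    cfg <- study_config(
      subject_id = sprintf("jit%d", i), seed = 40 + i,
      kinetics = list(aif_t0 = 8 + 3.5 * L),
      acquisition = list(n_timepoints = 26L + L),
      processing = list(mean_time_reference = if (correct) ref_mt else NULL,
                        candidates = c(3L, 4L), tolerance_s = 1.75))
    cached_pipeline(sprintf("jit-%d-%s", L, correct), cfg)$report_row$lac_pyr_mean
  }, 0)
}
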