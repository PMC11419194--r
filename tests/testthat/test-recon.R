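# Multi-coil reconstruction chain: covariance estimation, pre-whitening,
# sensitivity estimation, matched-filter combination, Fermi zero-fill.

test_that("noise covariance estimation: degenerate, single-channel, recovery", {
  # constant (noise-free) tail -> zero matrix, flagged degenerate
  const <- multichannel_dynamic(array(1 + 0i, dim = c(4, 4, 8, 2)))
  nc <- estimate_noise_covariance(const)
  expect_true(nc$degenerate)
  expect_equal(max(Mod(nc$matrix)), 0)
  expect_equal(nc$source_window, 4:8)

  # single channel with variance sigma^2
  set.seed(1)
  s2 <- 2.3
  x <- array(complex(real = rnorm(16 * 16 * 20, sd = sqrt(s2 / 2)),
                     imaginary = rnorm(16 * 16 * 20, sd = sqrt(s2 / 2))),
             dim = c(16, 16, 20, 1))
  nc1 <- estimate_noise_covariance(multichannel_dynamic(x), n_last_frames = 19)
  expect_equal(Re(nc1$matrix[1, 1]), s2, tolerance = 0.05)

  # known 3-channel covariance recovered within 5% Frobenius at >= 4096 samples
  sigma <- matrix(c(1, 0.3 + 0.1i, 0, 0.3 - 0.1i, 0.7, 0.2i, 0, -0.2i, 1.2), 3, 3)
  ns <- noise_series(32, 32, 10, sigma, seed = 4)    # 32*32*5 = 5120 tail samples
  est <- estimate_noise_covariance(ns, n_last_frames = 5)
  frob <- function(m) sqrt(sum(Mod(m)^2))
  expect_lt(frob(est$matrix - sigma) / frob(sigma), 0.05)
  expect_equal(est$sigma, 1)

  expect_error(estimate_noise_covariance(const, n_last_frames = 1), "n_last_frames")
})

test_that("pre-whitening: identity, diagonal scaling, decorrelation", {
  set.seed(2)
  x <- array(complex(real = rnorm(200), imaginary = rnorm(200)), dim = c(5, 5, 4, 2))
  d <- multichannel_dynamic(x)
  id <- structure(list(matrix = diag(2) + 0i, sigma = 1, source_window = 3:4,
                       degenerate = FALSE), class = "noise_covariance")
  expect_equal(prewhiten(d, id)$data, d$data, tolerance = 1e-12)

  di <- id; di$matrix <- diag(2) * 4 + 0i
  expect_equal(prewhiten(d, di)$data, d$data / 2, tolerance = 1e-12)

  sigma <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  ns <- noise_series(48, 48, 8, sigma, seed = 9)
  est <- estimate_noise_covariance(ns, n_last_frames = 7)
  w <- prewhiten(ns, est)
  xm <- matrix(w$data, ncol = 2)
  emp <- (t(xm) %*% Conj(xm)) / nrow(xm)
  frob <- function(m) sqrt(sum(Mod(m)^2))
  expect_lt(frob(emp - diag(2)) / frob(diag(2)), 0.05)

  sing <- id; sing$matrix <- matrix(1 + 0i, 2, 2)
  expect_error(prewhiten(d, sing), "positive-definite")
})

test_that("whitening is idempotent on pure noise (re-estimated covariance ~ identity)", {
  sigma <- matrix(c(1, 0.5, 0.5, 1.4), 2, 2)
  ns <- noise_series(48, 48, 10, sigma, seed = 21)
  w1 <- prewhiten(ns, estimate_noise_covariance(ns, n_last_frames = 9))
  w2 <- prewhiten(w1, estimate_noise_covariance(w1, n_last_frames = 9))
  rel <- sqrt(sum(Mod(w2$data - w1$data)^2)) / sqrt(sum(Mod(w1$data)^2))
  expect_lt(rel, 0.10)
})

test_that("sensitivity estimation: trivial normalizations and phantom accuracy", {
  # single channel -> sensitivity identically 1 inside mask
  x <- array(5 + 0i, dim = c(6, 6, 10, 1))
  s1 <- estimate_sensitivity(multichannel_dynamic(x), sigma = 0.01)
  expect_true(all(s1$support_mask))
  expect_equal(s1$maps[, , 1], matrix(1 + 0i, 6, 6), tolerance = 1e-12)

  # two channels with profiles (0.8, 0.6), noiseless
  x2 <- array(0 + 0i, dim = c(2, 2, 5, 2))
  x2[, , , 1] <- 0.8 * 10; x2[, , , 2] <- 0.6 * 10
  s2 <- estimate_sensitivity(multichannel_dynamic(x2), sigma = 0.01)
  expect_equal(Mod(s2$maps[1, 1, ]), c(0.8, 0.6), tolerance = 1e-12)

  # phantom with known profiles: mean |error| < 0.05 inside kidney at AUC SNR >= 20
  spec <- phantom_spec(seed = 3)
  coil <- coil_model(spec, noise_sigma = 0.4, rho = 0)   # white noise; no whitening needed
  study <- simulate_study(spec, kinetic_params(), acq_params(), coil, seed = 3)
  sens <- estimate_sensitivity(study$channels$pyruvate, sigma = 0.4)
  km <- kidney_mask(spec) & sens$support_mask
  expect_gt(sum(km), 0.9 * sum(kidney_mask(spec)))
  rss <- sqrt(apply(Mod(coil$profiles)^2, c(1, 2), sum))
  err <- 0
  for (c_ in seq_len(coil$n_channels)) {
    true_c <- coil$profiles[, , c_] / rss
    err <- err + mean(Mod(sens$maps[, , c_] - true_c)[km])
  }
  expect_lt(err / coil$n_channels, 0.05)

  expect_error(estimate_sensitivity(multichannel_dynamic(
    array(0 + 0i, dim = c(2, 2, 5, 1))), sigma = 1), "empty")
})

test_that("matched-filter combination: identity, coherent gain, noise optimality", {
  x <- array(3 + 4i, dim = c(2, 2, 3, 1))
  s <- structure(list(maps = array(1 + 0i, dim = c(2, 2, 1)),
                      support_mask = matrix(TRUE, 2, 2)),
                 class = "sensitivity_maps")
  expect_equal(combine_channels(multichannel_dynamic(x), s)$data, x[, , , 1],
               tolerance = 1e-12)

  # two equal channels, sensitivities (1,1)/sqrt(2): coherent gain sqrt(2)
  v <- 2 + 1i
  x2 <- array(v, dim = c(2, 2, 3, 2))
  s2 <- structure(list(maps = array((1 + 0i) / sqrt(2), dim = c(2, 2, 2)),
                       support_mask = matrix(TRUE, 2, 2)),
                  class = "sensitivity_maps")
  expect_equal(combine_channels(multichannel_dynamic(x2), s2)$data[1, 1, 1],
               sqrt(2) * v, tolerance = 1e-12)

  # combined noise SD never exceeds any single channel's on pure noise
  sigma <- diag(2) + 0i
  ns <- noise_series(32, 32, 12, sigma, seed = 13)
  maps <- array(0 + 0i, dim = c(32, 32, 2))
  maps[, , 1] <- 0.8; maps[, , 2] <- 0.6
  sm <- structure(list(maps = maps, support_mask = matrix(TRUE, 32, 32)),
                  class = "sensitivity_maps")
  comb <- combine_channels(ns, sm)
  sd_comb <- stats::sd(Re(comb$data))
  sd_ch <- apply(Re(ns$data), 4, stats::sd)
  expect_true(all(sd_comb <= sd_ch + 1e-12))
})

test_that("combination is insensitive to a common per-voxel phase", {
  set.seed(7)
  x <- array(complex(real = rnorm(4 * 4 * 3 * 2), imaginary = rnorm(96)),
             dim = c(4, 4, 3, 2))
  maps <- array(complex(real = rnorm(32), imaginary = rnorm(32)), dim = c(4, 4, 2))
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  for (c_ in 1:2) maps[, , c_] <- maps[, , c_] / rss
  sm <- structure(list(maps = maps, support_mask = matrix(TRUE, 4, 4)),
                  class = "sensitivity_maps")
  base <- combine_channels(multichannel_dynamic(x), sm)
  phase <- exp(1i * matrix(runif(16, 0, 2 * pi), 4, 4))
  xr <- x
  for (k in 1:3) for (c_ in 1:2) xr[, , k, c_] <- x[, , k, c_] * phase
  rot <- combine_channels(multichannel_dynamic(xr), sm)
  expect_lt(max(abs(Mod(rot$data) - Mod(base$data))), 1e-10)
})

test_that("Fermi zero-fill: passthrough, DC preservation, DFT oracle", {
  set.seed(11)
  img <- matrix(rnorm(64), 8, 8)
  # target = source with cutoff beyond Nyquist: identity within 1e-10
  out <- fermi_zero_fill(img, c(8, 8), cutoff_frac = 4, width_frac = 0.05)
  expect_lt(max(abs(out - img)), 1e-10)

  # constant image -> constant of target size, same mean
  cst <- matrix(3.7, 6, 6)
  oc <- fermi_zero_fill(cst, c(12, 12), cutoff_frac = 4, width_frac = 0.05)
  expect_equal(dim(oc), c(12L, 12L))
  expect_equal(mean(oc), 3.7, tolerance = 1e-9)
  expect_lt(max(abs(oc - 3.7)) / 3.7, 1e-6)

  # arbitrary 8x8 -> 16x16 against the explicit-DFT oracle
  orc <- dft_fermi_zero_fill(img, c(16, 16), cutoff = 0.85, width = 0.05)
  got <- fermi_zero_fill(img, c(16, 16), cutoff_frac = 0.85, width_frac = 0.05)
  expect_lt(max(Mod(got - Re(orc))), 1e-10)

  # odd sizes keep the DC alignment
  img5 <- matrix(rnorm(35), 5, 7)
  orc5 <- dft_fermi_zero_fill(img5, c(9, 11), cutoff = 0.85, width = 0.05)
  got5 <- fermi_zero_fill(img5, c(9, 11), cutoff_frac = 0.85, width_frac = 0.05)
  expect_lt(max(Mod(got5 - Re(orc5))), 1e-10)

  expect_error(fermi_zero_fill(img, c(4, 8)), "target_shape")
})

test_that("noiseless phantom survives the whole recon chain up to scale", {
  # flat-RSS coil + white noise: the configuration in which self-calibrated
  # matched filtering is exactly transparent (with shaded RSS the combined
  # image provably carries ||s(v)||, which the ratio normalization handles)
  spec <- phantom_spec(seed = 2)
  coil <- coil_model(spec, noise_sigma = 0.5, rho = 0, rss_norm = "flat")
  acq <- acq_params()
  dyn <- simulate_dynamics(spec, kinetic_params(), acq)
  # calibration covariance from a separate pure-noise acquisition
  calib <- noise_series(spec$grid_shape[1], spec$grid_shape[2], 12,
                        coil$noise_covariance, seed = 77)
  ncov <- estimate_noise_covariance(calib, n_last_frames = 11)
  noiseless <- apply_coils_and_noise(
    dyn$lactate, make_coil(coil$profiles, matrix(0 + 0i, 8, 8)),
    seed = 1, metabolite = "lactate", times = dyn$times, acq = acq)
  pyr0 <- apply_coils_and_noise(
    dyn$pyruvate, make_coil(coil$profiles, matrix(0 + 0i, 8, 8)),
    seed = 1, metabolite = "pyruvate", times = dyn$times, acq = acq)
  wl <- prewhiten(noiseless, ncov); wp <- prewhiten(pyr0, ncov)
  sens <- estimate_sensitivity(wp, sigma = 1)
  comb <- combine_channels(wl, sens)
  km <- kidney_mask(spec) & sens$support_mask
  truth <- apply(dyn$lactate, c(1, 2), sum)
  est <- apply(Mod(comb$data), c(1, 2), sum)
  expect_gt(stats::cor(truth[km], est[km]), 0.999)
})
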