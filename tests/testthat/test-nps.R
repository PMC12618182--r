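# NPS estimation: detrending, 2D spectrum scaling, radial averaging,
# polynomial smoothing.

make_rois <- function(tls, side = 64L) lapply(tls, square_roi, side = side)

test_that("detrending removes polynomial surfaces, never worsens residuals", {
  r <- matrix(seq_len(64), 64, 64)
  c <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  ramp <- 3 + 0.5 * r - 0.2 * c
  expect_lt(sqrt(mean(detrend_roi(ramp, 1)^2)), 1e-9)
  set.seed(2)
  noise <- matrix(stats::rnorm(64 * 64), 64, 64)
  centered <- noise - mean(noise)
  expect_equal(detrend_roi(centered, 0), centered, tolerance = 1e-12)
  # nested least squares: higher order never increases the RSS
  surf <- ramp + 0.01 * r^2 + noise
  rss <- vapply(0:2, function(o) sum(detrend_roi(surf, o)^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-6))
  expect_error(detrend_roi(surf, 3), "order")
})

test_that("2D NPS obeys the exact Parseval identity and white-noise level", {
  sigma <- 10
  stack <- white_noise_stack(n = 256, n_slices = 5, sd = sigma, seed = 4)
  tls <- list(c(20, 20), c(20, 100), c(100, 20), c(100, 100), c(160, 160))
  rois <- make_rois(tls)
  n2 <- nps_2d(stack, rois)
  # algebraic identity: integral of NPS = mean detrended-ROI variance
  vars <- numeric(0)
  for (s in 1:5) {
    for (roi in rois) {
      d <- extract_square(get_slice(stack, s), roi)
      vars <- c(vars, mean((d - mean(d))^2))
    }
  }
  expect_equal(nps_integral(n2), mean(vars), tolerance = 1e-9)
  # Parseval vs known sigma^2 within sampling error (25 realizations)
  expect_lt(abs(nps_integral(n2) - sigma^2) / sigma^2, 0.07)
  # point symmetry about DC for the interior grid (real input)
  v <- n2$values[-1, -1]
  flipped <- v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v)))]
  expect_lt(max(abs(v - flipped)) / max(v), 1e-6)
  # constant image -> NPS identically 0
  const <- ct_stack(matrix(100, 128, 128), PX)
  expect_equal(max(nps_2d(const, make_rois(list(c(10, 10))))$values), 0)
})

test_that("power at Nyquist shows up in the Nyquist bins", {
  img <- matrix(0, 128, 128)
  img[, seq(2, 128, by = 2)] <- 10 # alternating columns
  stack <- ct_stack(img, PX)
  n2 <- nps_2d(stack, make_rois(list(c(10, 10))))
  # mass concentrated at the +-u-Nyquist column (u = columns axis)
  nyq_col <- which.min(n2$u_axis) # most negative = -Nyquist for even n
  expect_gt(sum(n2$values[, nyq_col]), 0.99 * sum(n2$values))
})

test_that("radial averaging is exact for isotropic spectra", {
  freq <- fft_freq(64, PX)[fftshift_index(64)]
  fr <- sqrt(outer(freq^2, freq^2, "+"))
  g <- function(f) exp(-(f / 0.4)^2)
  n2 <- new_nps2d(g(fr), freq, freq, 1, 1, PX)
  n1 <- radial_average(n2)
  expect_lt(sqrt(mean((n1$values - g(n1$freq_mm))^2)), 0.005)
  # white-noise magnitude close to the generating SD
  stack <- white_noise_stack(n = 256, n_slices = 5, sd = 10, seed = 9)
  rois <- make_rois(list(c(20, 20), c(20, 100), c(100, 20), c(100, 100),
                         c(160, 160)))
  res <- radial_average(nps_2d(stack, rois))
  expect_lt(abs(res$noise_magnitude - 10) / 10, 0.05)
  # all-zero spectrum conventions
  z <- new_nps2d(matrix(0, 64, 64), freq, freq, 1, 1, PX)
  rz <- radial_average(z)
  expect_equal(rz$noise_magnitude, 0)
  expect_equal(rz$mean_freq, 0)
})

test_that("polynomial smoothing is idempotent on polynomials and clips at 0", {
  freq <- seq(0, 1, length.out = 33)
  vals <- 2 + 3 * freq - 2.5 * freq^2
  n1 <- new_nps1d(freq, vals, noise_magnitude = 1.5, peak_freq = 0.5,
                  mean_freq = 0.4)
  sm <- smooth_nps(n1, 2)
  expect_equal(sm$values, vals, tolerance = 1e-9)
  expect_equal(sm$noise_magnitude, 1.5) # kept from the 2D integral
  # nested models: higher order never increases residuals
  set.seed(3)
  noisy <- new_nps1d(freq, pmax(vals + stats::rnorm(33, 0, 0.3), 0),
                     1, 0.5, 0.4)
  rss <- vapply(1:4, function(o) {
    sum((smooth_nps(noisy, o)$values - noisy$values)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-9))
  # negative fit values are clipped
  steep <- new_nps1d(freq, pmax(1 - 3 * freq, 0) + 1e-3, 1, 0.1, 0.2)
  expect_gte(min(smooth_nps(steep, 1)$values), 0)
  expect_error(smooth_nps(n1, 33), "poly_order")
})

test_that("averaging over more realizations tightens per-bin scatter", {
  # chi^2 behaviour: relative per-bin SD shrinks like 1/sqrt(n)
  spectra <- function(n_slices) {
    stack <- white_noise_stack(256, n_slices, sd = 10, seed = 31)
    rois <- make_rois(list(c(20, 20), c(20, 100), c(100, 20), c(100, 100),
                           c(160, 160)))
    n2 <- nps_2d(stack, rois, slices = seq_len(n_slices))
    stats::sd(n2$values[-1, -1]) / mean(n2$values[-1, -1])
  }
  s1 <- spectra(1)
  s4 <- spectra(4)
  expect_lt(s4, s1 / 1.6) # ~ 1/sqrt(4) with slack
})

test_that("measure_nps runs the automated chain on a simulated module", {
  cfg <- scan_config(n_slices = 2, noise_sd = 4, seed = 3)
  res <- measure_nps(simulate_module3(cfg))
  expect_s3_class(res, "nps_result")
  expect_lt(abs(res$nps1d$noise_magnitude - 4) / 4, 0.15)
  expect_gt(res$nps1d$peak_freq, 0)
  # ramp-shaped noise peaks away from DC and rolls off by Nyquist
  expect_lt(res$nps1d$values[length(res$nps1d$values)],
            max(res$nps1d$values) / 2)
})
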