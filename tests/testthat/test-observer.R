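# Frequency-grid resampling, NPW/NPWE/NPWi detectability, synthetic
# nodule images.

ideal_transfer <- function(task, ttf_val = 1, nps_val = 25) {
  m <- length(task$u_axis)
  structure(list(ttf2d = matrix(ttf_val, m, m),
                 nps2d = matrix(nps_val, m, m),
                 support = matrix(TRUE, m, m),
                 provenance = list(ttf = "ideal", nps = "ideal")),
            class = "resampled_transfer")
}

tiny_task <- function(m = 8, dp = 0.5, contrast = 10) {
  # hand-built task on an m x m grid (bypasses the >= 64 constructor check
  # so the brute-force oracle stays small)
  spatial <- matrix(0, m, m)
  spatial[4:5, 4:5] <- contrast
  axis <- fft_freq(m, dp)[fftshift_index(m)]
  structure(list(spatial = spatial,
                 w2 = fftshift2(Mod(stats::fft(spatial))^2) * dp^4,
                 u_axis = axis, v_axis = axis,
                 spec = list(profile = "flat", diameter = 1,
                             contrast = contrast, matrix = m,
                             pixel_mm = dp)),
            class = "task_function")
}

test_that("resampling is exact on identical grids and fills 0 outside", {
  task <- make_task(task_spec("flat", 5, 15))
  # linear 1D source: interpolation is exact for linear functions
  fmax <- 1.2
  src <- list(freq_mm = seq(0, fmax, length.out = 200), material = "lin")
  src$ttf <- 1 - src$freq_mm / fmax
  nps1 <- new_nps1d(src$freq_mm, 30 * (1 - src$freq_mm / fmax), 1, 0, 0)
  tr <- resample_to_task(src, nps1, task)
  radius <- sqrt(outer(task$v_axis^2, task$u_axis^2, "+"))
  inside <- radius <= fmax
  expect_lt(max(abs(tr$ttf2d[inside] - (1 - radius[inside] / fmax))), 1e-6)
  expect_equal(tr$ttf2d[!inside], rep(0, sum(!inside)))
  expect_lt(max(abs(tr$nps2d[inside] - 30 * (1 - radius[inside] / fmax))),
            1e-6)
  # TTF == 1 up to f_Ny: ones inside the source band, 0 outside
  flat_src <- list(freq_mm = c(0, 1.089), ttf = c(1, 1), material = "one")
  tr2 <- resample_to_task(flat_src, nps1, task)
  expect_true(all(tr2$ttf2d[radius <= 1.089] == 1))
  expect_true(all(tr2$ttf2d[radius > 1.089] == 0))
  # 2D NPS source on the task grid itself: identity within float error
  n2 <- new_nps2d(matrix(7, length(task$u_axis), length(task$u_axis)),
                  task$u_axis, task$v_axis, 1, 1, 0.05)
  tr3 <- resample_to_task(flat_src, n2, task)
  expect_equal(max(abs(tr3$nps2d - 7)), 0, tolerance = 1e-9)
})

test_that("NPW d' matches the flat-disk closed form", {
  # ideal transfer: TTF == 1, NPS == N0 -> d' = c * r * sqrt(pi) / sqrt(N0)
  task <- make_task(task_spec("flat", 5, 15))
  d <- dprime_npw(task, ideal_transfer(task, 1, 25))$dprime
  expect_equal(d, 15 * 2.5 * sqrt(pi) / 5, tolerance = 0.01)
})

test_that("NPW d' obeys exact homogeneity and NPS scaling laws", {
  cfg <- fast_config(noise_sd = 4)
  meas <- measure_condition(cfg, slices = 1)
  task1 <- make_task(task_spec("flat", 5, 1))
  task7 <- make_task(task_spec("flat", 5, 7))
  tr <- resample_to_task(meas$ttf, meas$nps, task1)
  d1 <- dprime_npw(task1, tr)$dprime
  d7 <- dprime_npw(task7, tr)$dprime
  expect_equal(d7, 7 * d1, tolerance = 1e-12)
  # multiplying the NPS by k scales d' by k^(-1/2), exactly
  trk <- tr
  trk$nps2d <- 4 * tr$nps2d
  expect_equal(dprime_npw(task1, trk)$dprime, d1 / 2, tolerance = 1e-12)
  # contrast 0 -> d' = 0
  task0 <- make_task(task_spec("flat", 5, 0))
  expect_equal(dprime_npw(task0, tr)$dprime, 0)
  # noiseless input with signal is undefined
  tr0 <- tr
  tr0$nps2d[] <- 0
  expect_error(dprime_npw(task1, tr0), "noiseless")
})

test_that("implementation equals the explicit double-loop oracle", {
  task <- tiny_task()
  m <- 8
  set.seed(6)
  ttf2d <- matrix(stats::runif(m * m, 0.2, 1), m, m)
  nps2d <- matrix(stats::runif(m * m, 1, 5), m, m)
  tr <- structure(list(ttf2d = ttf2d, nps2d = nps2d,
                       support = matrix(TRUE, m, m),
                       provenance = list(ttf = "x", nps = "y")),
                  class = "resampled_transfer")
  d <- dprime_npw(task, tr)$dprime
  # independent oracle: explicit double loops over the grid
  du <- task$u_axis[2] - task$u_axis[1]
  num <- 0; den <- 0
  for (i in 1:m) {
    for (j in 1:m) {
      a <- task$w2[i, j] * ttf2d[i, j]^2
      num <- num + a * du * du
      den <- den + a * nps2d[i, j] * du * du
    }
  }
  d_oracle <- sqrt(num^2 / den)
  expect_equal(d, d_oracle, tolerance = 1e-12)
})

test_that("NPWE reduces to NPW for a unit eye filter and keeps scalings", {
  task <- make_task(task_spec("flat", 5, 15))
  tr <- ideal_transfer(task)
  d_npw <- dprime_npw(task, tr)$dprime
  expect_equal(dprime_npwe(task, tr, eye = NULL)$dprime, d_npw,
               tolerance = 1e-12)
  d_eye <- dprime_npwe(task, tr)$dprime
  expect_gt(d_eye, 0)
  trk <- tr
  trk$nps2d <- 9 * tr$nps2d
  expect_equal(dprime_npwe(task, trk)$dprime, d_eye / 3, tolerance = 1e-12)
  # an eye filter suppressing the whole band drives d' to 0
  crushed <- dprime_npwe(task, tr, eye_filter(n = 2, peak_cpd = 1e-4))$dprime
  expect_lt(crushed, 1e-3 * d_eye)
})

test_that("NPWi internal noise lowers d' monotonically to 0", {
  task <- make_task(task_spec("flat", 5, 15))
  tr <- ideal_transfer(task)
  d0 <- dprime_npw(task, tr)$dprime
  expect_equal(dprime_npwi(task, tr, 0)$dprime, d0, tolerance = 1e-12)
  fr <- c(0.2, 0.5, 1, 2, 10)
  ds <- vapply(fr, function(f) dprime_npwi(task, tr, f)$dprime, numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_lt(dprime_npwi(task, tr, 1e9)$dprime, 1e-3 * d0)
})

test_that("synthetic nodule images honour transfer, noise power and seed", {
  task <- make_task(task_spec("flat", 5, 15, matrix = 128, pixel_mm = 0.2))
  # TTF == 1, zero NPS: the image equals the task map
  tr0 <- ideal_transfer(task, 1, 0)
  img0 <- synthesize_nodule_image(task, tr0, seed = 1)
  expect_lt(max(abs(img0 - task$spatial)), 1e-9)
  # contrast 0: noise variance matches the NPS integral over seeds
  t0 <- make_task(task_spec("flat", 5, 0, matrix = 128, pixel_mm = 0.2))
  trn <- ideal_transfer(t0, 1, 25)
  du <- t0$u_axis[2] - t0$u_axis[1]
  target <- sum(trn$nps2d) * du^2
  vars <- vapply(1:20, function(s) {
    stats::var(as.vector(synthesize_nodule_image(t0, trn, seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(vars) - target) / target, 0.10)
  # determinism: same seed, identical image
  a <- synthesize_nodule_image(task, ideal_transfer(task), seed = 42)
  b <- synthesize_nodule_image(task, ideal_transfer(task), seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, synthesize_nodule_image(task, ideal_transfer(task),
                                                    seed = 43)))
})
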