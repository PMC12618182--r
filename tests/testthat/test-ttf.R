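# ESF sampling, alignment, logistic fit, TTF, CNR, edge MTF.

test_that("sample_esf counts pixels and bins angles as specified", {
  n <- 128
  img <- render_logistic_insert(n, w = 0.2, radius_mm = 8)
  ctr <- (n + 1) / 2
  insert <- circle_roi(c(ctr, ctr), 8 / PX)
  outer <- circle_roi(c(ctr, ctr), 8 / PX + 30)
  s <- sample_esf(img, insert, outer, PX)
  # counting oracle: number of pixel centres inside the outer circle
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  expect_equal(length(s$hu), sum(rr^2 + cc^2 <= outer$radius^2))
  expect_true(all(s$angle_bin %in% 0:35))
  # binning convention: bin 35 covers [350, 360) degrees
  theta <- (atan2(-(rr), cc) * 180 / pi) %% 360
  inside <- rr^2 + cc^2 <= outer$radius^2
  expect_equal(sum(s$angle_bin == 35), sum(theta[inside] >= 350))
  # rotational symmetry: every sample in every bin lies exactly on the
  # common radial profile, so bins are interchangeable at equal radii
  profile <- 955 * stats::plogis((8 - s$radius_mm) / 0.2)
  expect_lt(max(abs(s$hu - profile)), 1e-9 * 955)
  # out-of-bounds outer circle
  expect_error(sample_esf(img, insert, circle_roi(c(ctr, ctr), n), PX),
               "out of bounds")
})

test_that("align_esf removes a centre mis-estimate and drops noise bins", {
  n <- 256
  img <- render_logistic_insert(n, w = 0.2)
  ctr <- (n + 1) / 2
  # deliberately offset centre by 1 px: per-bin crossings spread by ~2 px
  insert <- circle_roi(c(ctr + 1, ctr), 12.5 / PX)
  outer <- circle_roi(c(ctr + 1, ctr), 12.5 / PX + 30)
  s <- sample_esf(img, insert, outer, PX)
  aligned <- align_esf(s)
  # after alignment the pooled 50% crossing spread across bins is < 0.1 px
  spread <- vapply(sort(unique(aligned$angle_bin)), function(b) {
    sel <- aligned$angle_bin == b
    ord <- order(aligned$radius_mm[sel])
    r <- aligned$radius_mm[sel][ord]; h <- aligned$hu[sel][ord]
    stats::approx(h, r, xout = 955 / 2, ties = mean)$y
  }, numeric(1))
  expect_lt(max(spread) - min(spread), 0.1 * PX)
  # fixed point: an already-aligned ideal edge shifts by ~0
  s0 <- sample_esf(img, circle_roi(c(ctr, ctr), 12.5 / PX),
                   circle_roi(c(ctr, ctr), 12.5 / PX + 30), PX)
  a0 <- align_esf(s0)
  expect_lt(max(abs(sort(a0$radius_mm) - sort(s0$radius_mm))), 0.05 * PX)
  # a pure-noise bin is dropped, others retained
  set.seed(5)
  s1 <- s0
  noisy_bin <- s1$angle_bin == 7
  s1$hu[noisy_bin] <- stats::rnorm(sum(noisy_bin), 400, 30)
  a1 <- align_esf(s1)
  expect_false(7 %in% a1$angle_bin)
  expect_equal(attr(a1, "dropped_bins"), 1)
  # all bins flat -> no edge
  flat <- s0
  flat$hu[] <- 0
  expect_error(align_esf(flat), "edge not detected")
})

test_that("fit_logistic recovers known parameters", {
  set.seed(11)
  x <- stats::runif(4000, 0, 25)
  truth <- list(base = -50, amplitude = 1000, center = 12.5, width = 0.2)
  y <- truth$base + truth$amplitude * stats::plogis((x - truth$center) / truth$width)
  noisy <- structure(list(radius_mm = x, hu = y + stats::rnorm(4000, 0, 5),
                          angle_bin = rep(0:35, length.out = 4000)),
                     class = "esf_samples")
  fit <- fit_logistic(noisy)
  # recovery within a generous multiple of the asymptotic SEs
  expect_lt(abs(fit$base - truth$base), 2)
  expect_lt(abs(fit$amplitude - truth$amplitude), 5)
  expect_lt(abs(fit$center - truth$center), 0.05)
  expect_lt(abs(fit$width - truth$width) / truth$width, 0.1)
  # noiseless data: residual RMS < 1e-6 * amplitude
  clean <- structure(list(radius_mm = x, hu = y,
                          angle_bin = rep(0L, 4000)),
                     class = "esf_samples")
  fit0 <- fit_logistic(clean)
  expect_lt(fit0$rms_residual, 1e-6 * truth$amplitude)
  # permutation invariance and positive width
  perm <- sample(4000)
  fitp <- fit_logistic(structure(list(radius_mm = x[perm], hu = y[perm],
                                      angle_bin = rep(0L, 4000)),
                                 class = "esf_samples"))
  expect_gt(fitp$width, 0)
  expect_equal(fitp$width, fit0$width, tolerance = 1e-6)
})

test_that("ttf_from_edge matches the closed-form logistic transfer", {
  for (w in c(0.1, 0.2, 0.4)) {
    edge <- structure(list(base = 0, amplitude = 1000, center = 10,
                           width = w), class = "logistic_edge")
    tr <- ttf_from_edge(edge, PX)
    ref <- logistic_ttf_reference(tr$freq_mm, w)
    expect_lt(sqrt(mean((tr$ttf - ref)^2)), 1e-4)
    expect_equal(tr$ttf[1], 1)
    expect_true(all(diff(tr$freq_mm) > 0))
    expect_gte(tr$f10, tr$f50)
  }
  # ideal-edge limit: w -> 0 gives TTF ~ 1 across the band
  sharp <- structure(list(base = 0, amplitude = 1000, center = 10,
                          width = 1e-6), class = "logistic_edge")
  expect_gte(min(ttf_from_edge(sharp, PX)$ttf), 0.999)
  # scaling law: doubling w halves f50
  f50 <- vapply(c(0.2, 0.4), function(w) {
    ttf_from_edge(structure(list(base = 0, amplitude = 1, center = 10,
                                 width = w), class = "logistic_edge"),
                  PX)$f50
  }, numeric(1))
  expect_equal(f50[1] / f50[2], 2, tolerance = 0.01)
})

test_that("cnr matches known moments and is offset-invariant", {
  set.seed(21)
  n <- 256
  ctr <- (n + 1) / 2
  img <- render_disk(n, 27, hu_in = 1000, hu_out = 0) +
    matrix(stats::rnorm(n * n, 0, 10), n, n)
  insert <- circle_roi(c(ctr, ctr), 27)
  outer <- circle_roi(c(ctr, ctr), 57)
  v <- cnr(img, insert, outer)
  expect_lt(abs(v - 100) / 100, 0.10)
  expect_equal(cnr(img + 500, insert, outer), v) # offset invariance
  flat <- matrix(stats::rnorm(n * n, 0, 10), n, n)
  expect_lt(cnr(flat, insert, outer), 0.5) # insert = background -> ~0
})

test_that("average_ttf renormalizes and interpolates sensibly", {
  e1 <- structure(list(base = 0, amplitude = 1, center = 5, width = 0.2),
                  class = "logistic_edge")
  e2 <- structure(list(base = 0, amplitude = 1, center = 5, width = 0.45),
                  class = "logistic_edge")
  t1 <- ttf_from_edge(e1, PX, cnr = 10)
  t2 <- ttf_from_edge(e2, PX, cnr = 20)
  same <- average_ttf(list(t1, t1, t1, t1, t1))
  expect_equal(same$ttf, t1$ttf, tolerance = 1e-12)
  expect_equal(same$f50, t1$f50, tolerance = 1e-12)
  avg <- average_ttf(list(t1, t2))
  expect_true(avg$f50 > t2$f50 && avg$f50 < t1$f50)
  expect_equal(avg$cnr, 15)
  expect_equal(avg$ttf[1], 1)
})

test_that("TTF is invariant to contrast polarity and decays with blur", {
  f50s <- vapply(c(0.3, 0.45, 0.65), function(sig) {
    cfg <- fast_config(noise_sd = 0, blur_sigma = sig)
    measure_ttf(simulate_module1(cfg), "bone")$f50
  }, numeric(1))
  expect_true(all(diff(f50s) < 0)) # f50 decreases with blur
  # polarity: air (negative contrast) vs bone (positive), equal blur
  cfg <- fast_config(noise_sd = 0, blur_sigma = 0.45)
  stack <- simulate_module1(cfg)
  ttf_air <- measure_ttf(stack, "air")
  ttf_bone <- measure_ttf(stack, "bone")
  expect_lt(sqrt(mean((ttf_air$ttf - ttf_bone$ttf)^2)), 0.02)
})

test_that("edge_mtf uses the phantom boundary and agrees with insert TTF", {
  cfg <- fast_config(noise_sd = 0, blur_sigma = 0.4)
  stack <- simulate_module1(cfg)
  slice <- get_slice(stack, 1)
  mask <- mask_phantom(slice)
  em <- edge_mtf(slice, mask, PX)
  expect_equal(em$material, "phantom-edge")
  ti <- measure_ttf(stack, "bone")
  expect_lt(abs(em$f50 - ti$f50) / ti$f50, 0.05) # same system blur
  # noiseless sharp phantom edge -> f50 beyond 0.8 of Nyquist
  sharp <- render_disk(512, 100)
  em2 <- edge_mtf(sharp, mask_phantom(sharp), PX)
  expect_gt(em2$f50, 0.8 / (2 * PX))
  # mask touching the image border cannot host the annulus
  big <- render_disk(128, 62)
  expect_error(edge_mtf(big, mask_phantom(big), PX), "out of bounds")
})

test_that("full chain recovers a logistic-edge transfer through noise", {
  img <- render_logistic_insert(256, w = 0.2)
  tr <- measure_logistic_chain(img, w = 0.2)
  ref <- logistic_ttf_reference(tr$freq_mm, 0.2)
  expect_lt(sqrt(mean((tr$ttf - ref)^2)), 0.01)
})
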