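# Fixtures built in code: small rendered slices and reference curves.

PX <- 0.459 # mm, default pixel size used by the fixtures

# Radial logistic-edge "insert": HU = amp * plogis((R - r) / w), centred in
# an n x n image. The exact ESF is a logistic of width w, so the full TTF
# chain can be checked against the closed form (2 pi^2 w f) / sinh(.).
render_logistic_insert <- function(n = 256, w = 0.2, amp = 955, radius_mm = 12.5,
                                   noise_sd = 0, center = c((n + 1) / 2, (n + 1) / 2),
                                   pixel_mm = PX) {
  rr <- (matrix(seq_len(n), n, n) - center[1]) * pixel_mm
  cc <- (matrix(seq_len(n), n, n, byrow = TRUE) - center[2]) * pixel_mm
  r <- sqrt(rr^2 + cc^2)
  img <- amp * stats::plogis((radius_mm - r) / w)
  if (noise_sd > 0) {
    img <- img + stats::rnorm(n * n, 0, noise_sd)
  }
  img
}

# Hard-edged disk of given HU in a background, pixel-centre rasterization.
render_disk <- function(n, radius_px, hu_in = 0, hu_out = -1000,
                        center = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n) - center[1]
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  ifelse(rr^2 + cc^2 <= radius_px^2, hu_in, hu_out)
}

# Closed-form transfer of a logistic edge of width w (mm).
logistic_ttf_reference <- function(freq_mm, w) {
  x <- 2 * pi^2 * w * freq_mm
  ifelse(x == 0, 1, x / sinh(x))
}

# White-noise stack on a uniform background (no phantom structure).
white_noise_stack <- function(n = 128, n_slices = 1, sd = 10, seed = 1,
                              pixel_mm = PX) {
  set.seed(seed)
  vox <- array(stats::rnorm(n * n * n_slices, 0, sd), c(n, n, n_slices))
  ct_stack(vox, pixel_spacing = rep(pixel_mm, 2))
}

# Full ESF -> align -> fit -> TTF chain on a rendered logistic insert.
measure_logistic_chain <- function(img, w = 0.2, radius_mm = 12.5,
                                   pixel_mm = PX,
                                   center = c((nrow(img) + 1) / 2,
                                              (nrow(img) + 1) / 2)) {
  insert <- circle_roi(center, radius_mm / pixel_mm)
  outer <- circle_roi(center, radius_mm / pixel_mm + 30)
  samples <- sample_esf(img, insert, outer, pixel_mm)
  aligned <- align_esf(samples)
  edge <- fit_logistic(aligned)
  ttf_from_edge(edge, pixel_mm)
}

# Tiny scan config for fast end-to-end tests.
fast_config <- function(...) {
  scan_config(n_slices = 1L, ...)
}
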