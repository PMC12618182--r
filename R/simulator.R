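# Synthetic ACR-464-style phantom stacks with known system blur, noise
# magnitude and noise colour. The geometry (water disk in air, four
# cylindrical inserts) is rendered analytically as Gaussian-blurred edges
# evaluated at pixel centres, so the system transfer function is exactly
# Gaussian by construction; stationary correlated noise is added after
# "reconstruction", shaped in the frequency domain.

#' Noise colour specification
#'
#' @param type `"white"` (flat spectrum), `"ramp"` (NPS proportional to
#'   `f * exp(-(f / cutoff)^2)`, the classic filtered-back-projection
#'   shape), or `"band"` (Gaussian bump centred at `f0`).
#' @param cutoff ramp roll-off frequency in mm^-1 (ramp type).
#' @param f0,width centre and width in mm^-1 (band type).
#' @return List of class `noise_color`.
#' @export
noise_color <- function(type = c("ramp", "white", "band"), cutoff = 0.35,
                        f0 = 0.35, width = 0.15) {
  type <- match.arg(type)
  structure(list(type = type, cutoff = cutoff, f0 = f0, width = width),
            class = "noise_color")
}

# Amplitude filter H(f) with NPS shape |H|^2.
noise_filter_amplitude <- function(color, f) {
  switch(color$type,
    white = rep(1, length(f)) + 0 * f,
    ramp = sqrt(f * exp(-(f / color$cutoff)^2)),
    band = sqrt(exp(-((f - color$f0) / color$width)^2 / 2))
  )
}

#' Scan configuration for the phantom simulator
#'
#' Defaults follow the nominal design of a 200 mm accreditation phantom:
#' four 25 mm inserts at 45/135/225/315 degrees, 60 mm from the centre, on
#' a 512 x 512 grid of 0.459 mm pixels. `blur_sigma` is the Gaussian system
#' PSF width (mm); `noise_sd` the noise standard deviation inside the
#' phantom (HU); `noise_color` the spectral shape of the noise.
#'
#' @param phantom_diameter,insert_diameter mm.
#' @param insert_hus named HU values for the four insert materials.
#' @param insert_angles named angles (degrees, counter-clockwise from the
#'   +x/column axis).
#' @param insert_offset_mm distance of insert centres from the phantom
#'   centre.
#' @param blur_sigma Gaussian system blur (mm).
#' @param noise_sd noise SD (HU).
#' @param noise_color a [noise_color()].
#' @param matrix image size in pixels.
#' @param pixel_mm pixel size (mm).
#' @param n_slices number of slices.
#' @param seed RNG seed.
#' @return List of class `scan_config`.
#' @examples
#' scan_config(noise_sd = 2, n_slices = 1)
#' @export
scan_config <- function(phantom_diameter = 200, insert_diameter = 25,
                        insert_hus = c(bone = 955, acrylic = 120,
                                       polyethylene = -95, air = -1000),
                        insert_angles = c(bone = 45, acrylic = 135,
                                          polyethylene = 225, air = 315),
                        insert_offset_mm = 60,
                        blur_sigma = 0.45, noise_sd = 4,
                        noise_color = ctiq::noise_color("ramp"),
                        matrix = 512L, pixel_mm = 0.459, n_slices = 5L,
                        seed = 1L) {
  stopifnot(phantom_diameter > 0, insert_diameter > 0, insert_offset_mm >= 0,
            blur_sigma >= 0, noise_sd >= 0, matrix >= 64, pixel_mm > 0,
            n_slices >= 1)
  stopifnot(all(names(insert_hus) %in% names(insert_angles)))
  # inserts must be disjoint and inside the phantom
  if (length(insert_hus) > 1) {
    ang <- insert_angles[names(insert_hus)] * pi / 180
    xs <- insert_offset_mm * cos(ang); ys <- insert_offset_mm * sin(ang)
    dmin <- min(stats::dist(cbind(xs, ys)))
    stopifnot(dmin > insert_diameter)
  }
  stopifnot(insert_offset_mm + insert_diameter / 2 < phantom_diameter / 2)
  structure(
    list(phantom_diameter = phantom_diameter,
         insert_diameter = insert_diameter,
         insert_hus = insert_hus, insert_angles = insert_angles,
         insert_offset_mm = insert_offset_mm,
         blur_sigma = blur_sigma, noise_sd = noise_sd,
         noise_color = noise_color, matrix = as.integer(matrix),
         pixel_mm = pixel_mm, n_slices = as.integer(n_slices),
         seed = as.integer(seed)),
    class = "scan_config"
  )
}

# Physical pixel-centre coordinates (mm), origin at the image centre.
sim_coords <- function(config) {
  m <- config$matrix
  ((seq_len(m)) - (m + 1) / 2) * config$pixel_mm
}

# Distance map (mm) from a centre given in (x right, y up) mm.
sim_radius_map <- function(config, x0 = 0, y0 = 0) {
  coord <- sim_coords(config)
  x <- coord # columns
  y <- -coord # rows increase downward
  sqrt(outer((y - y0)^2, (x - x0)^2, "+"))
}

# One stationary correlated-noise slice with unit variance.
sim_noise_slice <- function(config) {
  m <- config$matrix
  white <- matrix(stats::rnorm(m * m), m, m)
  if (config$noise_color$type == "white") {
    return(white)
  }
  f <- fft_freq(m, config$pixel_mm)
  fr <- sqrt(outer(f^2, f^2, "+"))
  H <- matrix(noise_filter_amplitude(config$noise_color, as.vector(fr)), m, m)
  scale <- sqrt(mean(H^2))
  Re(stats::fft(stats::fft(white) * H, inverse = TRUE)) / (m * m) / scale
}

sim_add_noise <- function(base, config) {
  m <- config$matrix
  vox <- array(0, c(m, m, config$n_slices))
  set.seed(config$seed)
  for (s in seq_len(config$n_slices)) {
    vox[, , s] <- base +
      if (config$noise_sd > 0) config$noise_sd * sim_noise_slice(config)
      else 0
  }
  ct_stack(vox, pixel_spacing = rep(config$pixel_mm, 2),
           slice_positions = (seq_len(config$n_slices) - 1) * 1.25)
}

#' Simulate the insert (TTF) module
#'
#' Renders a water-equivalent disk (0 HU) in air (-1000 HU) with the four
#' configured cylindrical inserts, all edges blurred by the Gaussian system
#' PSF (`blur_sigma`), and adds per-slice independent stationary noise of
#' the configured magnitude and colour. With `blur_sigma = 0` and
#' `noise_sd = 0` the image is piecewise constant at the exact configured
#' HU values.
#'
#' @param config a [scan_config()].
#' @return A [ct_stack()].
#' @export
simulate_module1 <- function(config = scan_config()) {
  sigma <- config$blur_sigma
  base <- -1000 +
    1000 * blurred_step(config$phantom_diameter / 2 -
                          sim_radius_map(config), sigma)
  r_ins <- config$insert_diameter / 2
  for (mat in names(config$insert_hus)) {
    ang <- config$insert_angles[[mat]] * pi / 180
    x0 <- config$insert_offset_mm * cos(ang)
    y0 <- config$insert_offset_mm * sin(ang)
    base <- base + config$insert_hus[[mat]] *
      blurred_step(r_ins - sim_radius_map(config, x0, y0), sigma)
  }
  sim_add_noise(base, config)
}

#' Simulate the homogeneous (NPS) module
#'
#' Renders a uniform water disk containing two small high-HU point objects
#' on the right half (so the default left-shifted NPS ROIs avoid them),
#' with the same blur and noise machinery as [simulate_module1()].
#'
#' @param config a [scan_config()].
#' @param point_hu HU of the point objects.
#' @param point_diameter_mm diameter of the point objects (mm).
#' @return A [ct_stack()].
#' @export
simulate_module3 <- function(config = scan_config(), point_hu = 500,
                             point_diameter_mm = 2) {
  sigma <- config$blur_sigma
  base <- -1000 +
    1000 * blurred_step(config$phantom_diameter / 2 -
                          sim_radius_map(config), sigma)
  offs <- 0.45 * config$phantom_diameter / 2
  for (y0 in c(-0.2, 0.2) * config$phantom_diameter / 2) {
    base <- base + point_hu *
      blurred_step(point_diameter_mm / 2 -
                     sim_radius_map(config, offs, y0), sigma)
  }
  sim_add_noise(base, config)
}

#' Reconstruction-kernel presets
#'
#' Maps a kernel name to a (blur_sigma, noise colour, noise SD multiplier)
#' triple ordered so that spatial resolution ranks Lung > Edge > Standard >
#' Soft while the noise penalty of the sharp kernels outweighs their
#' resolution benefit for low-contrast, low-frequency tasks (so the
#' Standard kernel maximizes d' and the Lung kernel minimizes it, as
#' observed on real scanners). The noise SD multipliers combine the ideal
#' ramp-bandwidth scaling (`(cutoff / 0.35)^1.5`) with an excess factor
#' (enhancement overshoot at the sharp end, an electronic-noise floor at
#' the soft end).
#'
#' @param name one of `"Standard"`, `"Edge"`, `"Lung"`, `"Soft"`.
#' @return List with `blur_sigma` (mm), `noise_color`, `noise_sd_multiplier`.
#' @export
kernel_preset <- function(name = c("Standard", "Edge", "Lung", "Soft")) {
  name <- match.arg(name)
  presets <- list(
    Lung = list(blur_sigma = 0.25, cutoff = 0.70, excess = 1.8),
    Edge = list(blur_sigma = 0.35, cutoff = 0.50, excess = 1.3),
    Standard = list(blur_sigma = 0.45, cutoff = 0.35, excess = 1.0),
    Soft = list(blur_sigma = 0.65, cutoff = 0.25, excess = 1.05)
  )
  p <- presets[[name]]
  list(
    blur_sigma = p$blur_sigma,
    noise_color = noise_color("ramp", cutoff = p$cutoff),
    noise_sd_multiplier = p$excess * (p$cutoff / 0.35)^1.5
  )
}

#' Scan configuration for a kernel / tube-current condition
#'
#' Applies a [kernel_preset()] and a tube-current surrogate to a base
#' configuration: the noise SD scales as `1 / sqrt(mA)` relative to the
#' 140 mA reference, times the kernel's noise multiplier.
#'
#' @param kernel kernel name, see [kernel_preset()].
#' @param ma tube current (mA).
#' @param base a [scan_config()] giving everything else; its `noise_sd` is
#'   the 140 mA Standard-kernel reference.
#' @param ma_ref reference tube current (default 140 mA).
#' @return A [scan_config()].
#' @export
scan_condition <- function(kernel = "Standard", ma = 140,
                           base = scan_config(), ma_ref = 140) {
  stopifnot(ma > 0)
  p <- kernel_preset(kernel)
  base$blur_sigma <- p$blur_sigma
  base$noise_color <- p$noise_color
  base$noise_sd <- base$noise_sd * p$noise_sd_multiplier * sqrt(ma_ref / ma)
  base
}
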