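# Circular task functions (flat and Gaussian profiles) and their
# frequency-domain representation.

#' Task function specification
#'
#' @param profile `"flat"` (homogeneous circular nodule) or `"gaussian"`
#'   (hepatic-nodule-like profile whose FWHM equals the nominal diameter).
#' @param diameter object diameter in mm.
#' @param contrast object contrast in HU.
#' @param matrix samples per side of the task grid (>= 64; default 300).
#' @param pixel_mm task grid pixel size in mm (default 0.05).
#' @return List of class `task_spec`.
#' @examples
#' task_spec("flat", diameter = 5, contrast = 15)
#' @export
task_spec <- function(profile = c("flat", "gaussian"), diameter = 5,
                      contrast = 15, matrix = 300L, pixel_mm = 0.05) {
  profile <- match.arg(profile)
  stopifnot(diameter > 0, matrix >= 64, pixel_mm > 0,
            diameter < matrix * pixel_mm)
  structure(
    list(profile = profile, diameter = diameter, contrast = contrast,
         matrix = as.integer(matrix), pixel_mm = pixel_mm),
    class = "task_spec"
  )
}

#' Build a circular task function
#'
#' The spatial map is centred on the task grid: the flat profile equals
#' `contrast` inside radius `diameter / 2` and 0 outside (pixel-centre
#' rule); the Gaussian profile is
#' `contrast * exp(-4 log(2) rho^2 / diameter^2)` (FWHM = diameter, no
#' truncation). The frequency-domain representation uses the continuous-FT
#' scale `W(u, v) = pixel_mm^2 * DFT2(spatial)`, so
#' `w2 = pixel_mm^4 * |DFT2(spatial)|^2`, DC-centred. With this scaling the
#' discrete Parseval identity
#' `sum(w2) * du * dv = pixel_mm^2 * sum(spatial^2)` holds exactly.
#'
#' @param spec a [task_spec()] (or arguments forwarded to it).
#' @param ... forwarded to [task_spec()] when `spec` is not a `task_spec`.
#' @return Object of class `task_function` with fields `spatial` (HU map),
#'   `w2` (`|W|^2`, DC-centred), `u_axis`, `v_axis` (mm^-1) and `spec`.
#' @examples
#' tf <- make_task(task_spec("flat", 5, 15))
#' max(tf$spatial)
#' @export
make_task <- function(spec = task_spec(), ...) {
  if (!inherits(spec, "task_spec")) {
    spec <- task_spec(spec, ...)
  }
  m <- spec$matrix
  dp <- spec$pixel_mm
  ctr <- floor(m / 2) + 1 # DC-centred grid position
  coord <- (seq_len(m) - ctr) * dp
  rho2 <- outer(coord^2, coord^2, "+")
  spatial <- if (spec$profile == "flat") {
    spec$contrast * (rho2 <= (spec$diameter / 2)^2)
  } else {
    spec$contrast * exp(-4 * log(2) * rho2 / spec$diameter^2)
  }
  w2 <- fftshift2(Mod(stats::fft(spatial))^2) * dp^4
  axis <- fft_freq(m, dp)[fftshift_index(m)]
  structure(
    list(spatial = spatial, w2 = w2, u_axis = axis, v_axis = axis,
         spec = spec),
    class = "task_function"
  )
}

#' @export
print.task_function <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<task_function> %s profile, %.3g mm diameter, %.3g HU contrast\n",
              s$profile, s$diameter, s$contrast))
  cat(sprintf("  grid: %d x %d at %.3g mm (Nyquist %.2f mm^-1)\n",
              s$matrix, s$matrix, s$pixel_mm, 1 / (2 * s$pixel_mm)))
  invisible(x)
}

#' @export
plot.task_function <- function(x, ...) {
  ext <- (x$spec$matrix / 2) * x$spec$pixel_mm
  graphics::image(seq(-ext, ext, length.out = x$spec$matrix),
                  seq(-ext, ext, length.out = x$spec$matrix),
                  t(x$spatial)[, rev(seq_len(nrow(x$spatial)))],
                  col = grDevices::gray.colors(256), asp = 1,
                  xlab = "mm", ylab = "mm",
                  main = sprintf("Task (%s)", x$spec$profile), ...)
  invisible(x)
}
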