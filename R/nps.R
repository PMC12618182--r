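# Noise power spectrum estimation from square ROIs.
#
# Per ROI and slice: polynomial detrend (mean subtraction by default),
# 2D DFT, squared magnitude, scaled by dx*dy / (Lx*Ly) with Lx = Ly = ROI
# side in samples; averaged over all ROI x slice realizations. With this
# scaling the integral of the 2D NPS equals the mean detrended-ROI variance
# exactly (discrete Parseval identity).

#' Detrend a square ROI
#'
#' @param roi_values 2D numeric matrix (HU).
#' @param order 0 (subtract the ROI mean, the default), 1 or 2 (remove a
#'   least-squares 2D polynomial surface of that order).
#' @return Detrended matrix of the same shape.
#' @export
detrend_roi <- function(roi_values, order = 0L) {
  stopifnot(is.matrix(roi_values), order %in% 0:2)
  if (order == 0L) {
    return(roi_values - mean(roi_values))
  }
  nr <- nrow(roi_values); nc <- ncol(roi_values)
  r <- as.vector(row(roi_values)) - (nr + 1) / 2
  c <- as.vector(col(roi_values)) - (nc + 1) / 2
  X <- cbind(1, r, c)
  if (order == 2L) {
    X <- cbind(X, r * c, r^2, c^2)
  }
  fit <- stats::lm.fit(X, as.vector(roi_values))
  matrix(fit$residuals, nr, nc)
}

new_nps2d <- function(values, u_axis, v_axis, n_rois_used, n_slices_used,
                      pixel_mm) {
  structure(
    list(values = values, u_axis = u_axis, v_axis = v_axis,
         n_rois_used = n_rois_used, n_slices_used = n_slices_used,
         pixel_mm = pixel_mm),
    class = "nps2d"
  )
}

#' 2D noise power spectrum
#'
#' Averages `dx*dy / (side^2) * |DFT2(detrended ROI)|^2` over every
#' ROI-and-slice realization. The returned spectrum is DC-centred; the DC
#' bin is ~0 by construction (mean subtraction).
#'
#' @param stack a [ct_stack()].
#' @param rois list of [square_roi()] (all the same side).
#' @param slices slice indices (default: all).
#' @param detrend_order passed to [detrend_roi()].
#' @return Object of class `nps2d` with `values` (HU^2 mm^2), DC-centred
#'   `u_axis`/`v_axis` (mm^-1), `n_rois_used`, `n_slices_used`.
#' @export
nps_2d <- function(stack, rois, slices = NULL, detrend_order = 0L) {
  stopifnot(length(rois) >= 1L)
  if (is.null(slices)) slices <- seq_len(n_slices(stack))
  side <- rois[[1]]$side
  stopifnot(all(vapply(rois, function(r) r$side, integer(1)) == side))
  dx <- stack$pixel_spacing[2]; dy <- stack$pixel_spacing[1]
  acc <- matrix(0, side, side)
  n <- 0L
  for (s in slices) {
    slice <- get_slice(stack, s)
    for (roi in rois) {
      vals <- detrend_roi(extract_square(slice, roi), detrend_order)
      acc <- acc + Mod(stats::fft(vals))^2
      n <- n + 1L
    }
  }
  values <- fftshift2(acc / n * (dx * dy) / (side * side))
  axis <- fft_freq(side, mean(c(dx, dy)))[fftshift_index(side)]
  new_nps2d(values, u_axis = axis, v_axis = axis,
            n_rois_used = length(rois), n_slices_used = length(slices),
            pixel_mm = mean(c(dx, dy)))
}

nps_integral <- function(nps2d) {
  du <- nps2d$u_axis[2] - nps2d$u_axis[1]
  dv <- nps2d$v_axis[2] - nps2d$v_axis[1]
  sum(nps2d$values) * du * dv
}

#' @export
print.nps2d <- function(x, ...) {
  cat(sprintf("<nps2d> %d x %d bins, %d ROI(s) x %d slice(s)\n",
              nrow(x$values), ncol(x$values), x$n_rois_used,
              x$n_slices_used))
  cat(sprintf("  integral: %.3f HU^2 (noise magnitude %.3f HU)\n",
              nps_integral(x), sqrt(nps_integral(x))))
  invisible(x)
}

new_nps1d <- function(freq_mm, values, noise_magnitude, peak_freq, mean_freq) {
  structure(
    list(freq_mm = freq_mm, values = values,
         noise_magnitude = noise_magnitude, peak_freq = peak_freq,
         mean_freq = mean_freq),
    class = "nps1d"
  )
}

#' Radially average a 2D NPS
#'
#' For each radial frequency (step equal to the 2D axis bin width, starting
#' at 0) the 2D spectrum is sampled by bilinear interpolation along 360
#' rays at 1-degree spacing and the 360 samples are averaged. The noise
#' magnitude is `sqrt(integral of the 2D NPS)` (computed from the 2D
#' spectrum, not the 1D curve); the mean frequency is the NPS-weighted mean
#' of the radial frequency, and the peak frequency is the argmax of the 1D
#' curve (DC bin excluded).
#'
#' @param nps2d an `nps2d` object.
#' @return Object of class `nps1d` with `freq_mm`, `values`,
#'   `noise_magnitude` (HU), `peak_freq`, `mean_freq` (mm^-1).
#' @export
radial_average <- function(nps2d) {
  u <- nps2d$u_axis; v <- nps2d$v_axis
  du <- u[2] - u[1]
  fmax <- min(max(u), max(v))
  freq <- seq(0, fmax, by = du)
  theta <- (0:359) * pi / 180
  ct <- cos(theta); st <- sin(theta)
  vals <- vapply(freq, function(f) {
    uu <- f * ct
    vv <- f * st
    s <- pracma::interp2(u, v, nps2d$values, uu, vv, method = "linear")
    mean(s, na.rm = TRUE)
  }, numeric(1))
  total <- nps_integral(nps2d)
  if (sum(vals) <= 0) {
    mean_freq <- 0
    peak_freq <- 0
  } else {
    mean_freq <- sum(freq * vals) / sum(vals)
    if (length(vals) > 1L) {
      peak_freq <- freq[-1][which.max(vals[-1])]
    } else {
      peak_freq <- 0
    }
  }
  new_nps1d(freq, vals, noise_magnitude = sqrt(max(total, 0)),
            peak_freq = peak_freq, mean_freq = mean_freq)
}

#' Polynomial smoothing of a 1D NPS
#'
#' Replaces the curve by its least-squares polynomial fit of the given
#' order, clipped at 0. Peak and mean frequency are recomputed from the
#' smoothed curve; the noise magnitude (which comes from the 2D spectrum)
#' is kept.
#'
#' @param nps1d an `nps1d` object.
#' @param poly_order polynomial order, less than the number of points.
#' @return A smoothed `nps1d`.
#' @export
smooth_nps <- function(nps1d, poly_order) {
  n <- length(nps1d$freq_mm)
  if (poly_order >= n) {
    stop("smooth_nps: poly_order must be smaller than the number of points")
  }
  fit <- stats::lm(y ~ stats::poly(x, poly_order, raw = TRUE),
                   data = data.frame(x = nps1d$freq_mm, y = nps1d$values))
  vals <- pmax(as.numeric(stats::fitted(fit)), 0)
  freq <- nps1d$freq_mm
  if (sum(vals) <= 0) {
    mean_freq <- 0; peak_freq <- 0
  } else {
    mean_freq <- sum(freq * vals) / sum(vals)
    peak_freq <- freq[-1][which.max(vals[-1])]
  }
  new_nps1d(freq, vals, noise_magnitude = nps1d$noise_magnitude,
            peak_freq = peak_freq, mean_freq = mean_freq)
}

#' @export
print.nps1d <- function(x, ...) {
  cat(sprintf("<nps1d> %d radial frequencies up to %.3f mm^-1\n",
              length(x$freq_mm), max(x$freq_mm)))
  cat(sprintf("  noise magnitude %.3f HU, peak %.3f mm^-1, mean %.3f mm^-1\n",
              x$noise_magnitude, x$peak_freq, x$mean_freq))
  invisible(x)
}

#' @export
plot.nps1d <- function(x, ...) {
  graphics::plot(x$freq_mm, x$values, type = "l",
                 xlab = expression(f ~ (mm^-1)),
                 ylab = expression(NPS ~ (HU^2 ~ mm^2)),
                 main = "Radially averaged NPS", ...)
  graphics::abline(v = c(x$peak_freq, x$mean_freq), lty = 3, col = "grey50")
  invisible(x)
}

#' Measure the NPS of a homogeneous module across slices
#'
#' Automated chain: phantom masking on the first selected slice, ROI
#' placement ([nps_rois()]), 2D NPS estimation and radial averaging.
#'
#' @param stack a [ct_stack()].
#' @param slices slice indices (default: all).
#' @param n_rois,shift,layout passed to [nps_rois()].
#' @param detrend_order passed to [detrend_roi()].
#' @param smooth_order optional polynomial order for [smooth_nps()].
#' @return List of class `nps_result` with elements `nps2d` and `nps1d`.
#' @examples
#' \donttest{
#' stack <- simulate_module3(scan_config(n_slices = 2))
#' measure_nps(stack)
#' }
#' @export
measure_nps <- function(stack, slices = NULL, n_rois = 5L, shift = "left",
                        layout = "cross", detrend_order = 0L,
                        smooth_order = NULL) {
  if (is.null(slices)) slices <- seq_len(n_slices(stack))
  mask <- mask_phantom(get_slice(stack, slices[1]))
  rois <- nps_rois(dim(stack)[1:2], mask, n_rois = n_rois, shift = shift,
                   layout = layout)
  n2 <- nps_2d(stack, rois, slices = slices, detrend_order = detrend_order)
  n1 <- radial_average(n2)
  if (!is.null(smooth_order)) {
    n1 <- smooth_nps(n1, smooth_order)
  }
  structure(list(nps2d = n2, nps1d = n1), class = "nps_result")
}

#' @export
print.nps_result <- function(x, ...) {
  print(x$nps1d)
  invisible(x)
}
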