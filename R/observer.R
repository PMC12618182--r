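# Resampling of measured TTF/NPS onto the task grid, model-observer
# detectability indices, and synthetic nodule-image rendering.

#' Resample measured TTF and NPS onto the task frequency grid
#'
#' Linear interpolation onto every task-grid frequency point, with a fill
#' value of 0 outside the source frequency support. A 1D TTF (assumed
#' radially symmetric, since the inserts are cylindrical) is expanded by
#' rotation: each task-grid point takes the value at radius
#' `sqrt(u^2 + v^2)`. The NPS may be a 2D spectrum (bilinear interpolation
#' on `(u, v)`) or a 1D curve (rotated like the TTF).
#'
#' @param ttf1d a `ttf_result` (or a list with `freq_mm` and `ttf`).
#' @param nps an `nps2d`, `nps_result` or `nps1d` object.
#' @param task a `task_function` from [make_task()].
#' @return Object of class `resampled_transfer` with `ttf2d`, `nps2d`
#'   (both on the task grid), `support` (logical: inside the TTF source
#'   band) and `provenance`.
#' @export
resample_to_task <- function(ttf1d, nps, task) {
  u <- task$u_axis; v <- task$v_axis
  radius <- sqrt(outer(v^2, u^2, "+"))
  ttf2d <- matrix(
    stats::approx(ttf1d$freq_mm, ttf1d$ttf, xout = as.vector(radius),
                  method = "linear", rule = 1)$y,
    nrow = length(v)
  )
  ttf2d[is.na(ttf2d)] <- 0
  support <- radius <= max(ttf1d$freq_mm)
  if (inherits(nps, "nps_result")) {
    nps <- nps$nps2d
  }
  if (inherits(nps, "nps2d")) {
    # pracma::interp2 needs in-range query points; apply the 0-fill manually
    uu <- as.vector(outer(rep(1, length(v)), u))
    vv <- as.vector(outer(v, rep(1, length(u))))
    inside <- uu >= min(nps$u_axis) & uu <= max(nps$u_axis) &
      vv >= min(nps$v_axis) & vv <= max(nps$v_axis)
    vals <- numeric(length(uu))
    vals[inside] <- pracma::interp2(nps$u_axis, nps$v_axis, nps$values,
                                    uu[inside], vv[inside],
                                    method = "linear")
    nps2d <- matrix(vals, nrow = length(v))
    nps_label <- sprintf("nps2d[%dx%d]", nrow(nps$values), ncol(nps$values))
  } else if (inherits(nps, "nps1d")) {
    nps2d <- matrix(
      stats::approx(nps$freq_mm, nps$values, xout = as.vector(radius),
                    method = "linear", rule = 1)$y,
      nrow = length(v)
    )
    nps2d[is.na(nps2d)] <- 0
    nps_label <- "nps1d"
  } else {
    stop("nps must be an nps2d, nps_result or nps1d object")
  }
  nps2d[nps2d < 0] <- 0
  structure(
    list(ttf2d = ttf2d, nps2d = nps2d, support = support,
         provenance = list(ttf = ttf1d$material %||% "ttf",
                           nps = nps_label)),
    class = "resampled_transfer"
  )
}

new_detectability <- function(dprime, observer, task, inputs) {
  structure(
    list(dprime = dprime, observer = observer, task = task$spec,
         inputs = inputs),
    class = "detectability_result"
  )
}

grid_steps <- function(task) {
  c(du = task$u_axis[2] - task$u_axis[1],
    dv = task$v_axis[2] - task$v_axis[1])
}

dprime_core <- function(task, transfer, num_weight = 1, den_weight = 1,
                        nps_offset = 0, observer = "NPW") {
  st <- grid_steps(task)
  A <- task$w2 * transfer$ttf2d^2
  num <- (sum(A * num_weight) * st["du"] * st["dv"])^2
  den <- sum(A * den_weight * (transfer$nps2d + nps_offset)) *
    st["du"] * st["dv"]
  if (num == 0) {
    d <- 0
  } else if (den <= 0) {
    stop("noiseless input: d' undefined (NPS identically 0 with nonzero signal)")
  } else {
    d <- sqrt(num / den)
  }
  new_detectability(unname(d), observer, task, transfer$provenance)
}

#' Non-pre-whitening (NPW) detectability index
#'
#' `d'^2 = [int |W|^2 TTF^2 du dv]^2 / [int |W|^2 TTF^2 NPS du dv]`, with
#' the integrals evaluated as Riemann sums on the task frequency grid
#' (`du = dv = 1 / (matrix * pixel_mm)`). A zero task contrast yields
#' `d' = 0`; a zero NPS with a nonzero signal is an error.
#'
#' @param task a `task_function`.
#' @param transfer a `resampled_transfer` from [resample_to_task()].
#' @return Object of class `detectability_result` with fields `dprime`,
#'   `observer`, `task`, `inputs`.
#' @export
dprime_npw <- function(task, transfer) {
  dprime_core(task, transfer, observer = "NPW")
}

#' Eye filter for the NPWE observer
#'
#' `E(f) = f_deg^n * exp(-c * f_deg^2)` with `f_deg` in cycles/degree,
#' mapped from mm^-1 in the image plane through the display zoom and
#' viewing distance; `c` is set so the filter peaks at `peak_cpd`
#' cycles/degree.
#'
#' @param n exponent (default 1.3).
#' @param peak_cpd peak frequency in cycles/degree (default 4).
#' @param distance_mm viewing distance (default 500 mm).
#' @param zoom display magnification: displayed mm per image mm (default 1).
#' @return List of class `eye_filter`.
#' @export
eye_filter <- function(n = 1.3, peak_cpd = 4, distance_mm = 500, zoom = 1) {
  stopifnot(n >= 0, peak_cpd > 0, distance_mm > 0, zoom > 0)
  structure(list(n = n, peak_cpd = peak_cpd, distance_mm = distance_mm,
                 zoom = zoom),
            class = "eye_filter")
}

eval_eye_filter <- function(eye, f_mm) {
  # cycles/mm on the display -> cycles/degree at the eye
  f_deg <- (f_mm / eye$zoom) * eye$distance_mm * pi / 180
  cc <- eye$n / (2 * eye$peak_cpd^2)
  ifelse(f_deg == 0 & eye$n > 0, 0, f_deg^eye$n * exp(-cc * f_deg^2))
}

#' NPWE detectability index (NPW with an eye filter)
#'
#' Eq. form: numerator `[int |W|^2 TTF^2 E^2]^2`, denominator
#' `int |W|^2 TTF^2 E^4 NPS`. With `E == 1` this reduces exactly to
#' [dprime_npw()].
#'
#' @param task a `task_function`.
#' @param transfer a `resampled_transfer`.
#' @param eye an [eye_filter()]; `NULL` means `E == 1`.
#' @return A `detectability_result` (observer `"NPWE"`).
#' @export
dprime_npwe <- function(task, transfer, eye = eye_filter()) {
  if (is.null(eye)) {
    e2 <- 1
  } else {
    radius <- sqrt(outer(task$v_axis^2, task$u_axis^2, "+"))
    e2 <- eval_eye_filter(eye, radius)^2
  }
  dprime_core(task, transfer, num_weight = e2, den_weight = e2^2,
              observer = "NPWE")
}

#' NPWi detectability index (NPW with internal noise)
#'
#' The denominator NPS is replaced by
#' `NPS + fraction * mean(NPS over the source support)`; a fraction of 0
#' reduces exactly to [dprime_npw()].
#'
#' @param task a `task_function`.
#' @param transfer a `resampled_transfer`.
#' @param internal_noise_fraction nonnegative scalar.
#' @return A `detectability_result` (observer `"NPWi"`).
#' @export
dprime_npwi <- function(task, transfer, internal_noise_fraction = 0.5) {
  stopifnot(internal_noise_fraction >= 0)
  base <- mean(transfer$nps2d[transfer$support])
  dprime_core(task, transfer,
              nps_offset = internal_noise_fraction * base,
              observer = "NPWi")
}

#' @export
print.detectability_result <- function(x, ...) {
  cat(sprintf("<detectability_result> d' = %.4f (%s observer)\n",
              x$dprime, x$observer))
  cat(sprintf("  task: %s, %.3g mm, %.3g HU on %d px / %.3g mm grid\n",
              x$task$profile, x$task$diameter, x$task$contrast,
              x$task$matrix, x$task$pixel_mm))
  cat(sprintf("  inputs: TTF = %s, NPS = %s\n",
              x$inputs$ttf, x$inputs$nps))
  invisible(x)
}

#' Render a synthetic nodule image
#'
#' The task's spatial map is blurred by the resampled TTF in the frequency
#' domain, and a stationary noise texture shaped by the resampled NPS is
#' added in the spatial domain. The noise field is the inverse DFT of a
#' white spectrum shaped by `sqrt(NPS)` (DC forced to 0), scaled so its
#' spatial variance equals the NPS integral; the result is reproducible for
#' a fixed seed.
#'
#' @param task a `task_function`.
#' @param transfer a `resampled_transfer`.
#' @param seed integer RNG seed.
#' @return Numeric matrix (HU) of the task grid size.
#' @export
synthesize_nodule_image <- function(task, transfer, seed = 1L) {
  m <- task$spec$matrix
  dp <- task$spec$pixel_mm
  ttf_u <- ifftshift2(transfer$ttf2d)
  signal <- Re(stats::fft(stats::fft(task$spatial) * ttf_u, inverse = TRUE)) /
    (m * m)
  s_u <- ifftshift2(transfer$nps2d)
  s_u[1, 1] <- 0
  set.seed(seed)
  white <- matrix(stats::rnorm(m * m), m, m)
  shaped <- stats::fft(white) * sqrt(s_u)
  noise <- Re(stats::fft(shaped, inverse = TRUE)) / (m * m) / dp
  signal + noise
}
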