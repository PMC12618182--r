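#' CT image stack in Hounsfield units
#'
#' Container for an axial CT series. Voxels are stored as a numeric 3D array
#' indexed `[row, col, slice]` and are always in Hounsfield units (HU): the
#' rescale slope/intercept of the source files are applied at read time and
#' downstream code never sees stored pixel values.
#'
#' @param voxels numeric 3D array `[row, col, slice]` of HU values (a matrix
#'   is accepted for a single slice).
#' @param pixel_spacing numeric length-2, mm per pixel along (row, col);
#'   both components must be positive.
#' @param slice_positions numeric, one position (mm along the scan axis) per
#'   slice, strictly monotonic. Defaults to `0, 1, 2, ...`.
#' @param source_meta optional list with one entry of per-slice metadata,
#'   retained for DICOM round-trips.
#'
#' @return An object of class `ct_stack` with fields `voxels`,
#'   `pixel_spacing`, `slice_positions`, `source_meta`.
#' @examples
#' s <- ct_stack(array(0, c(32, 32, 2)), pixel_spacing = c(0.5, 0.5))
#' dim(s$voxels)
#' @export
ct_stack <- function(voxels, pixel_spacing, slice_positions = NULL,
                     source_meta = NULL) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, c(dim(voxels), 1L))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) {
    stop("ct_stack: voxels must be finite")
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("ct_stack: pixel_spacing must be two positive numbers (mm)")
  }
  n_slices <- dim(voxels)[3L]
  if (is.null(slice_positions)) {
    slice_positions <- as.numeric(seq_len(n_slices) - 1L)
  }
  slice_positions <- as.numeric(slice_positions)
  if (length(slice_positions) != n_slices) {
    stop("ct_stack: one slice position per slice required")
  }
  if (n_slices > 1L) {
    d <- diff(slice_positions)
    if (!(all(d > 0) || all(d < 0))) {
      stop("ct_stack: slice_positions must be strictly monotonic")
    }
    if (all(d < 0)) { # normalize to ascending order
      ord <- order(slice_positions)
      voxels <- voxels[, , ord, drop = FALSE]
      slice_positions <- slice_positions[ord]
      if (!is.null(source_meta)) source_meta <- source_meta[ord]
    }
  }
  structure(
    list(voxels = voxels, pixel_spacing = pixel_spacing,
         slice_positions = slice_positions,
         source_meta = source_meta %||% vector("list", n_slices)),
    class = "ct_stack"
  )
}

#' @export
print.ct_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_stack> %d x %d pixels, %d slice(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing: %.4g x %.4g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3L]

get_slice <- function(stack, i) stack$voxels[, , i]

#' Circular region of interest
#'
#' @param center numeric length-2, (row, col) pixel coordinates (1-based,
#'   fractional values allowed).
#' @param radius radius in pixels, positive.
#' @return Object of class `circle_roi`.
#' @examples
#' circle_roi(c(128.5, 128.5), 27)
#' @export
circle_roi <- function(center, radius) {
  stopifnot(length(center) == 2L, is_scalar_number(radius), radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "circle_roi")
}

#' @export
print.circle_roi <- function(x, ...) {
  cat(sprintf("<circle_roi> center (%.2f, %.2f), radius %.2f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

roi_in_image <- function(roi, dims) {
  r <- roi$center[1]; c <- roi$center[2]; rad <- roi$radius
  r - rad >= 1 && r + rad <= dims[1] && c - rad >= 1 && c + rad <= dims[2]
}

# Logical mask of pixels whose centers fall inside the circle.
circle_mask <- function(roi, dims) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (rr - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2
}

#' Square region of interest
#'
#' @param top_left integer length-2, (row, col) of the top-left pixel
#'   (1-based).
#' @param side side length in pixels (>= 8).
#' @return Object of class `square_roi`.
#' @examples
#' square_roi(c(100, 100), 64)
#' @export
square_roi <- function(top_left, side = 64L) {
  stopifnot(length(top_left) == 2L, is_scalar_number(side), side >= 8)
  structure(list(top_left = as.integer(round(top_left)),
                 side = as.integer(side)),
            class = "square_roi")
}

#' @export
print.square_roi <- function(x, ...) {
  cat(sprintf("<square_roi> top-left (%d, %d), side %d px\n",
              x$top_left[1], x$top_left[2], x$side))
  invisible(x)
}

roi_rows <- function(roi) roi$top_left[1] + 0:(roi$side - 1L)
roi_cols <- function(roi) roi$top_left[2] + 0:(roi$side - 1L)

extract_square <- function(slice, roi) slice[roi_rows(roi), roi_cols(roi)]
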