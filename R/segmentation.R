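# Automated phantom / insert / ROI localization.
#
# The phantom is isolated by a global -200 HU threshold; inserts are found
# inside the phantom mask by material-specific HU windows; TTF and NPS ROIs
# are derived geometrically from the segmented components.

#' Material-specific insert definitions
#'
#' Default HU windows for the four cylindrical inserts of the TTF module of
#' an ACR-464-style phantom. Windows are disjoint and exclude the water
#' background by construction; they bracket nominal insert HU values of
#' roughly +955 (bone), +120 (acrylic), -95 (polyethylene) and -1000 (air).
#'
#' @param materials character vector, subset of
#'   `c("bone", "acrylic", "polyethylene", "air")`.
#' @param nominal_diameter_mm nominal insert diameter in mm.
#' @return A named list of insert specs, each with fields `material`,
#'   `hu_window` (low, high) and `nominal_diameter`.
#' @examples
#' insert_specs()$bone
#' @export
insert_specs <- function(materials = c("bone", "acrylic", "polyethylene", "air"),
                         nominal_diameter_mm = 25) {
  windows <- list(
    bone = c(200, 1500),
    acrylic = c(90, 200),
    polyethylene = c(-180, -60),
    air = c(-1100, -800)
  )
  materials <- match.arg(materials, names(windows), several.ok = TRUE)
  out <- lapply(materials, function(m) {
    list(material = m, hu_window = windows[[m]],
         nominal_diameter = nominal_diameter_mm)
  })
  names(out) <- materials
  out
}

#' Segment the phantom from surrounding air
#'
#' Thresholds the slice at `threshold_hu`, keeps the largest connected
#' component and fills interior holes (so that an air insert, which falls
#' below the threshold, remains part of the phantom mask).
#'
#' @param slice 2D numeric HU matrix.
#' @param threshold_hu global threshold separating phantom from air
#'   (default -200 HU).
#' @return Logical matrix: the phantom mask.
#' @export
mask_phantom <- function(slice, threshold_hu = -200) {
  stopifnot(is.matrix(slice), all(is.finite(slice)))
  bw <- slice > threshold_hu
  if (!any(bw)) {
    stop("phantom not found: no pixel above threshold")
  }
  lab <- EBImage::bwlabel(bw)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  matrix(as.numeric(filled) > 0.5, nrow(slice), ncol(slice))
}

largest_component <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

erode_mask <- function(mask, margin_px) {
  if (margin_px <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(margin_px) + 1L, shape = "disc")
  er <- EBImage::erode(EBImage::Image(mask * 1), brush)
  matrix(as.numeric(er) > 0.5, nrow(mask), ncol(mask))
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Locate material inserts inside the phantom
#'
#' For each insert spec, selects in-mask pixels inside the material's HU
#' window, keeps the largest connected component, and returns a circle with
#' the component's geometric (intensity-independent) centroid and
#' equivalent-area radius `sqrt(area / pi)`. The phantom mask is lightly
#' eroded first so that thin transition rings at the phantom boundary do not
#' masquerade as inserts.
#'
#' @param slice 2D HU matrix.
#' @param mask phantom mask from [mask_phantom()].
#' @param specs insert specs, see [insert_specs()].
#' @param erode_px erosion margin applied to the mask before windowing.
#' @return Named list of [circle_roi()], one per found material, with
#'   attribute `missing` listing materials whose component was not found.
#' @export
find_inserts <- function(slice, mask, specs = insert_specs(), erode_px = 3) {
  stopifnot(any(mask))
  m <- erode_mask(mask, erode_px)
  rois <- list()
  missing <- character(0)
  for (spec in specs) {
    win <- spec$hu_window
    bw <- m & slice > win[1] & slice < win[2]
    comp <- largest_component(bw)
    if (is.null(comp)) {
      missing <- c(missing, spec$material)
      next
    }
    idx <- which(comp, arr.ind = TRUE)
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
    radius <- sqrt(nrow(idx) / pi)
    rois[[spec$material]] <- circle_roi(center, radius)
  }
  if (length(missing) > 0) {
    attr(rois, "missing") <- missing
  }
  rois
}

require_insert <- function(rois, material) {
  if (is.null(rois[[material]])) {
    stop(sprintf("insert not found: %s", material))
  }
  rois[[material]]
}

#' Inner and outer TTF ROIs for an insert
#'
#' The inner ROI (insert circle shrunk to `inner_fraction` of its radius)
#' samples the insert mean away from edge blur; the outer ROI (insert
#' radius + `outer_margin_px`) bounds the edge-spread-function sampling
#' region and the background annulus.
#'
#' @param insert [circle_roi()] of the segmented insert.
#' @param dims image dimensions `c(rows, cols)`.
#' @param inner_fraction fraction of the insert radius used for the inner
#'   ROI (default 0.6).
#' @param outer_margin_px margin added to the insert radius for the outer
#'   ROI (default 30 pixels).
#' @return List with elements `inner` and `outer`, both [circle_roi()].
#' @export
ttf_rois <- function(insert, dims, inner_fraction = 0.6, outer_margin_px = 30) {
  outer <- circle_roi(insert$center, insert$radius + outer_margin_px)
  if (!roi_in_image(outer, dims)) {
    stop("ROI out of bounds: outer TTF circle exceeds the image")
  }
  list(inner = circle_roi(insert$center, insert$radius * inner_fraction),
       outer = outer)
}

nps_roi_offsets <- function(n_rois, layout = c("cross", "quincunx")) {
  layout <- match.arg(layout)
  if (layout == "quincunx" && n_rois == 5L) {
    return(rbind(c(0, 0), c(-32, -32), c(-32, 32), c(32, -32), c(32, 32)))
  }
  switch(as.character(n_rois),
    "1" = rbind(c(0, 0)),
    "2" = rbind(c(0, -32), c(0, 32)),
    "3" = rbind(c(0, -64), c(0, 0), c(0, 64)),
    "4" = rbind(c(-32, -32), c(-32, 32), c(32, -32), c(32, 32)),
    "5" = rbind(c(0, 0), c(-64, 0), c(64, 0), c(0, -64), c(0, 64)),
    "6" = rbind(c(-32, -64), c(-32, 0), c(-32, 64),
                c(32, -64), c(32, 0), c(32, 64)),
    "9" = as.matrix(expand.grid(r = c(-64, 0, 64), c = c(-64, 0, 64))),
    stop("n_rois must be one of 1, 2, 3, 4, 5, 6, 9")
  )
}

#' Place square NPS ROIs in the homogeneous module
#'
#' Places `n_rois` 64x64 ROIs in a fixed deterministic pattern around an
#' anchor displaced from the phantom-mask centroid by one quarter of the
#' phantom radius in the requested direction (avoiding the module's point
#' objects). Every ROI must lie fully inside the mask eroded by
#' `margin_px`.
#'
#' @param dims image dimensions `c(rows, cols)`.
#' @param mask phantom mask.
#' @param n_rois one of 1, 2, 3, 4, 5, 6, 9 (default 5).
#' @param shift anchor displacement direction:
#'   `"left"`, `"right"`, `"up"`, `"down"` or `"none"`.
#' @param side ROI side in pixels (default 64).
#' @param margin_px erosion margin keeping ROIs away from the phantom edge.
#' @param layout `"cross"` (non-overlapping, default) or `"quincunx"`
#'   (half-overlapping, n_rois = 5 only).
#' @return List of [square_roi()].
#' @export
nps_rois <- function(dims, mask, n_rois = 5L, shift = "left", side = 64L,
                     margin_px = 10, layout = c("cross", "quincunx")) {
  layout <- match.arg(layout)
  shift <- match.arg(shift, c("left", "right", "up", "down", "none"))
  if (sum(mask) < side * side) {
    stop("insufficient homogeneous area: mask smaller than one ROI")
  }
  centroid <- mask_centroid(mask)
  phantom_radius <- sqrt(sum(mask) / pi)
  step <- phantom_radius / 4
  anchor <- centroid + switch(shift,
    left = c(0, -step), right = c(0, step),
    up = c(-step, 0), down = c(step, 0),
    none = c(0, 0)
  )
  offs <- nps_roi_offsets(as.integer(n_rois), layout)
  eroded <- erode_mask(mask, margin_px)
  rois <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    tl <- round(anchor + offs[i, ] - (side / 2 - 1))
    roi <- square_roi(tl, side)
    rr <- roi_rows(roi); cc <- roi_cols(roi)
    if (min(rr) < 1 || min(cc) < 1 || max(rr) > dims[1] || max(cc) > dims[2] ||
        !all(eroded[rr, cc])) {
      stop("insufficient homogeneous area: ROI pattern does not fit inside the eroded mask")
    }
    rois[[i]] <- roi
  }
  rois
}
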