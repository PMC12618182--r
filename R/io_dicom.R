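# Minimal single-frame CT DICOM I/O: explicit VR little endian, uncompressed.
# Covers the attributes of a minimal CT IOD; enhanced/multi-frame objects,
# sequences and compressed transfer syntaxes are out of scope.

UID_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
UID_SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.9590"

.uid_counter <- new.env(parent = emptyenv())
.uid_counter$n <- 0L

new_uid <- function() {
  .uid_counter$n <- .uid_counter$n + 1L
  paste(UID_ROOT,
        format(round(as.numeric(Sys.time()) * 100), scientific = FALSE),
        Sys.getpid() %% 10000L, .uid_counter$n, sep = ".")
}

u16_raw <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
DCM_KNOWN_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                   "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                   "UI", "UL", "US", DCM_LONG_VRS)

dcm_element_raw <- function(group, element, vr, payload) {
  if (length(payload) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    payload <- c(payload, pad)
  }
  head <- c(u16_raw(group), u16_raw(element), charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), u32_raw(length(payload)), payload)
  } else {
    stopifnot(length(payload) <= 65534)
    c(head, u16_raw(length(payload)), payload)
  }
}

dcm_str <- function(group, element, vr, value) {
  dcm_element_raw(group, element, vr, charToRaw(as.character(value)))
}

dcm_us <- function(group, element, value) {
  dcm_element_raw(group, element, "US", u16_raw(as.integer(value)))
}

fmt_ds <- function(x) {
  # DS values are limited to 16 bytes
  s <- formatC(x, digits = 10, format = "g", width = 1)
  if (nchar(s) > 16) s <- formatC(x, digits = 8, format = "g", width = 1)
  s
}

write_dicom_slice <- function(path, stored, pixel_spacing, slope, intercept,
                              instance_number, position_mm, series_uid,
                              study_uid) {
  rows <- nrow(stored); cols <- ncol(stored)
  sop_uid <- new_uid()
  # pixel data is row-major in DICOM
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                  endian = "little")
  meta <- c(
    dcm_element_raw(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", UID_SOP_CLASS_CT),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", UID_TRANSFER_SYNTAX_ELE),
    dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_SOP_CLASS_CT),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0020, 0x000D, "UI", study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_str(0x0020, 0x0032, "DS",
            paste("0", "0", fmt_ds(position_mm), sep = "\\")),
    dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_str(0x0020, 0x1041, "DS", fmt_ds(position_mm)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, rows),
    dcm_us(0x0028, 0x0011, cols),
    dcm_str(0x0028, 0x0030, "DS",
            paste(fmt_ds(pixel_spacing[1]), fmt_ds(pixel_spacing[2]),
                  sep = "\\")),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 1L),
    dcm_str(0x0028, 0x1052, "DS", fmt_ds(intercept)),
    dcm_str(0x0028, 0x1053, "DS", fmt_ds(slope)),
    dcm_element_raw(0x7FE0, 0x0010, "OW", pix)
  )
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element_raw(0x0002, 0x0000, "UL", u32_raw(length(meta))),
           meta, body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

rd_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

rd_u32 <- function(bytes, pos) {
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) +
    16777216 * as.numeric(bytes[pos + 3L])
}

parse_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop(sprintf("not a DICOM file: %s", path))
  }
  pos <- 133L
  elems <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- rd_u16(bytes, pos)
    element <- rd_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!(vr %in% DCM_KNOWN_VRS)) {
      stop(sprintf("unsupported DICOM encoding (VR '%s') in %s", vr, path))
    }
    if (vr %in% DCM_LONG_VRS) {
      len <- rd_u32(bytes, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- rd_u16(bytes, pos + 6L)
      pos <- pos + 8L
    }
    if (vr == "SQ" || len == 4294967295) {
      stop(sprintf("sequences are not supported: %s", path))
    }
    key <- sprintf("%04X%04X", group, element)
    elems[[key]] <- list(vr = vr,
                         bytes = if (len > 0) bytes[pos:(pos + len - 1L)]
                                 else raw(0))
    pos <- pos + len
  }
  elems
}

elem_string <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  b <- e$bytes
  while (length(b) > 0 && (b[length(b)] == as.raw(0L) ||
                           b[length(b)] == as.raw(32L))) {
    b <- b[-length(b)]
  }
  rawToChar(b)
}

elem_numbers <- function(elems, key, default = NULL) {
  s <- elem_string(elems, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

elem_u16 <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  rd_u16(e$bytes, 1L)
}

parse_ct_slice <- function(path) {
  elems <- parse_dicom_file(path)
  rows <- elem_u16(elems, "00280010")
  cols <- elem_u16(elems, "00280011")
  pix <- elems[["7FE00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix)) {
    stop(sprintf("missing image attributes in %s", path))
  }
  signed <- (elem_u16(elems, "00280103", 1L) == 1L)
  stored <- readBin(pix$bytes, integer(), n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  slope <- elem_numbers(elems, "00281053", 1)[1]
  intercept <- elem_numbers(elems, "00281052", 0)[1]
  hu <- matrix(stored, nrow = rows, byrow = TRUE) * slope + intercept
  ipp <- elem_numbers(elems, "00200032")
  loc <- elem_numbers(elems, "00201041")
  inst <- elem_numbers(elems, "00200013")
  spacing <- elem_numbers(elems, "00280030", c(1, 1))
  list(hu = hu, pixel_spacing = spacing,
       position = if (!is.null(ipp) && length(ipp) >= 3) ipp[3]
                  else if (!is.null(loc)) loc[1] else NA_real_,
       instance_number = if (!is.null(inst)) inst[1] else NA_real_,
       slope = slope, intercept = intercept,
       sop_instance_uid = elem_string(elems, "00080018"))
}

#' Read a DICOM series into a CT stack
#'
#' Reads every file in `directory` as a single-frame CT image (explicit VR
#' little endian, uncompressed), converts stored pixel values to Hounsfield
#' units via each slice's rescale slope and intercept, and sorts slices by
#' position along the scan axis (falling back to instance number when
#' positions are absent). A series whose slices disagree in matrix size or
#' pixel spacing is rejected.
#'
#' @param directory path containing one DICOM file per slice.
#' @param slice_filter optional integer vector of slice indices (applied
#'   after position sorting), e.g. `1:5`.
#' @return A [ct_stack()].
#' @export
read_ct_series <- function(directory, slice_filter = NULL) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    stop(sprintf("no images found in %s", directory))
  }
  slices <- lapply(files, parse_ct_slice)
  dims <- vapply(slices, function(s) dim(s$hu), integer(2))
  spac <- vapply(slices, function(s) s$pixel_spacing, numeric(2))
  if (any(dims != dims[, 1]) || any(abs(spac - spac[, 1]) > 1e-9)) {
    stop("inhomogeneous series: matrix size or pixel spacing differs across slices")
  }
  pos <- vapply(slices, function(s) s$position, numeric(1))
  if (any(is.na(pos))) {
    key <- vapply(slices, function(s) s$instance_number, numeric(1))
    if (any(is.na(key))) key <- seq_along(slices)
    pos <- key
  }
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  if (any(duplicated(pos))) {
    stop("series has duplicated slice positions")
  }
  if (!is.null(slice_filter)) {
    slices <- slices[slice_filter]
    pos <- pos[slice_filter]
  }
  vox <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$hu
  meta <- lapply(slices, function(s) {
    s[c("instance_number", "slope", "intercept", "sop_instance_uid")]
  })
  ct_stack(vox, pixel_spacing = spac[, 1], slice_positions = pos,
           source_meta = meta)
}

#' Write a CT stack as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per slice. A
#' common rescale slope/intercept is chosen so the full HU range of the
#' stack is representable as signed 16-bit stored values; the round-trip
#' quantization error is at most `slope / 2`.
#'
#' @param stack a [ct_stack()].
#' @param directory output directory (created if missing).
#' @param slope,intercept optional rescale mapping `HU = stored * slope +
#'   intercept`; chosen automatically from the HU range when `NULL`.
#' @return Character vector of written file paths, in slice order.
#' @export
write_ct_series <- function(stack, directory, slope = NULL, intercept = NULL) {
  stopifnot(inherits(stack, "ct_stack"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory %s", directory))
  }
  lo <- min(stack$voxels); hi <- max(stack$voxels)
  if (is.null(slope)) {
    span <- max(hi - lo, 1e-3)
    slope <- as.numeric(fmt_ds(span / 60000))
  }
  if (is.null(intercept)) {
    intercept <- as.numeric(fmt_ds((lo + hi) / 2))
  }
  series_uid <- new_uid()
  study_uid <- new_uid()
  ns <- n_slices(stack)
  paths <- character(ns)
  for (i in seq_len(ns)) {
    stored <- round((stack$voxels[, , i] - intercept) / slope)
    stored[stored > 32767] <- 32767
    stored[stored < -32768] <- -32768
    paths[i] <- file.path(directory, sprintf("slice_%04d.dcm", i))
    write_dicom_slice(paths[i], stored, stack$pixel_spacing,
                      slope, intercept, instance_number = i,
                      position_mm = stack$slice_positions[i],
                      series_uid = series_uid, study_uid = study_uid)
  }
  invisible(paths)
}

#' Export a measurement curve as delimited text
#'
#' Writes a two-column comma-delimited file with a header row, keeping full
#' numeric precision (15 significant digits).
#'
#' @param xs,ys equal-length numeric vectors.
#' @param labels character pair used as the header row.
#' @param destination output file path.
#' @export
export_curve <- function(xs, ys, labels, destination) {
  if (length(xs) != length(ys)) {
    stop("export_curve: xs and ys must have equal length")
  }
  stopifnot(length(labels) == 2L)
  lines <- paste(labels[1], labels[2], sep = ",")
  if (length(xs) > 0) {
    lines <- c(lines, paste(formatC(xs, digits = 15, format = "g", width = 1),
                            formatC(ys, digits = 15, format = "g", width = 1),
                            sep = ","))
  }
  writeLines(lines, destination)
  invisible(destination)
}
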