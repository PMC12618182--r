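# End-to-end orchestration: simulate -> segment -> TTF -> NPS -> task -> d'
# -> report, plus the four parameter-sweep runners (tube current, kernel,
# task diameter, task contrast) and their trend fits.

#' Measure TTF and NPS for one scan condition
#'
#' Simulates the insert module and the homogeneous module under one scan
#' configuration (the homogeneous module uses `seed + 1` so the two
#' modules carry independent noise), then runs the automated TTF and NPS
#' measurements.
#'
#' @param config a [scan_config()].
#' @param ttf_material insert material (or `"phantom-edge"`).
#' @param slices slice indices used for both measurements (default: all).
#' @param n_rois,shift passed to [measure_nps()].
#' @return List with elements `ttf` (a `ttf_result`) and `nps` (an
#'   `nps_result`).
#' @export
measure_condition <- function(config, ttf_material = "bone", slices = NULL,
                              n_rois = 5L, shift = "left") {
  stack1 <- simulate_module1(config)
  config3 <- config
  config3$seed <- config$seed + 1L
  stack3 <- simulate_module3(config3)
  list(
    ttf = measure_ttf(stack1, ttf_material, slices = slices),
    nps = measure_nps(stack3, slices = slices, n_rois = n_rois,
                      shift = shift)
  )
}

#' d' from measured TTF/NPS and task parameters
#'
#' @param ttf a `ttf_result`.
#' @param nps an `nps_result`, `nps2d` or `nps1d`.
#' @param profile,diameter,contrast,matrix,pixel_mm task parameters, see
#'   [task_spec()].
#' @param observer `"NPW"` (default), `"NPWE"` or `"NPWi"`.
#' @param eye an [eye_filter()] for NPWE.
#' @param internal_noise_fraction for NPWi.
#' @return A `detectability_result`.
#' @export
dprime_for_task <- function(ttf, nps, profile = "flat", diameter = 5,
                            contrast = 15, matrix = 300L, pixel_mm = 0.05,
                            observer = c("NPW", "NPWE", "NPWi"),
                            eye = eye_filter(),
                            internal_noise_fraction = 0.5) {
  observer <- match.arg(observer)
  # enlarge the grid (fixed pixel size) when the object would not fit with
  # margin, e.g. for the largest diameters of a sweep
  matrix <- max(as.integer(matrix), 2L * ceiling(0.75 * diameter / pixel_mm))
  task <- make_task(task_spec(profile, diameter, contrast, matrix, pixel_mm))
  transfer <- resample_to_task(ttf, nps, task)
  switch(observer,
         NPW = dprime_npw(task, transfer),
         NPWE = dprime_npwe(task, transfer, eye),
         NPWi = dprime_npwi(task, transfer, internal_noise_fraction))
}

#' Ordinary least-squares line with R^2
#'
#' @param x,y numeric vectors.
#' @return List with `intercept`, `slope`, `r_squared`.
#' @export
fit_linear <- function(x, y) {
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Three-parameter exponential fit `a * exp(b * x) + c` with R^2
#'
#' Initialized from a log-linear regression on `y - min(y)` and refined by
#' nonlinear least squares.
#'
#' @param x,y numeric vectors (length >= 4).
#' @return List with `a`, `b`, `c`, `r_squared`.
#' @export
fit_exponential <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  c0 <- min(y) - 0.05 * diff(range(y)) - 1e-9
  ll <- stats::lm(log(y - c0) ~ x)
  start <- list(a = exp(unname(stats::coef(ll)[1])),
                b = unname(stats::coef(ll)[2]), c = c0)
  fit <- minpack.lm::nlsLM(y ~ a * exp(b * x) + c,
                           data = data.frame(x = x, y = y), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
       r_squared = 1 - ss_res / ss_tot)
}

sweep_domains <- list(
  tube_current = c(80, 100, 120, 140, 160, 200),
  kernel = c("Standard", "Edge", "Lung", "Soft"),
  diameter = seq(1, 15, by = 2),
  contrast = seq(1, 29, by = 2)
)

#' Run a parameter sweep of the detectability index
#'
#' Sweeps one variable (tube current in mA, reconstruction kernel, task
#' diameter in mm, or task contrast in HU) while holding everything else
#' fixed, and computes the NPW d' for both the flat and the Gaussian task
#' profile at each value. Tube-current and kernel sweeps re-simulate and
#' re-measure TTF/NPS per value; diameter and contrast sweeps hold one
#' measured TTF/NPS fixed. Trend fits are attached as attributes: a linear
#' fit (+ R^2) for contrast sweeps and a 3-parameter exponential fit
#' (+ R^2) for diameter sweeps, skipped for single-value sweeps.
#'
#' @param variable one of `"tube_current"`, `"kernel"`, `"diameter"`,
#'   `"contrast"`.
#' @param values sweep values (defaults: 80-200 mA, the four kernels,
#'   1-15 mm, 1-29 HU).
#' @param base a [scan_config()] for the fixed conditions.
#' @param ttf_material insert used for the TTF.
#' @param diameter,contrast task parameters held fixed when not swept.
#' @param slices slice indices used in the measurements.
#' @param measurement optional precomputed result of
#'   [measure_condition()] (diameter/contrast sweeps only).
#' @return `data.frame` with columns `value`, `dprime_flat`,
#'   `dprime_gaussian`; fit attributes `fit_flat` / `fit_gaussian` where
#'   applicable.
#' @export
run_sweep <- function(variable = c("tube_current", "kernel", "diameter",
                                   "contrast"),
                      values = NULL, base = scan_config(),
                      ttf_material = "bone", diameter = 5, contrast = 15,
                      slices = NULL, measurement = NULL) {
  variable <- match.arg(variable)
  if (is.null(values)) values <- sweep_domains[[variable]]
  stopifnot(length(values) >= 1)
  one_dprime <- function(meas, profile, d, c) {
    dprime_for_task(meas$ttf, meas$nps, profile, d, c)$dprime
  }
  if (variable %in% c("tube_current", "kernel")) {
    rows <- lapply(values, function(val) {
      cond <- if (variable == "tube_current") {
        scan_condition("Standard", ma = as.numeric(val), base = base)
      } else {
        scan_condition(as.character(val), ma = 140, base = base)
      }
      meas <- measure_condition(cond, ttf_material, slices = slices)
      c(flat = one_dprime(meas, "flat", diameter, contrast),
        gaussian = one_dprime(meas, "gaussian", diameter, contrast))
    })
  } else {
    if (is.null(measurement)) {
      measurement <- measure_condition(base, ttf_material, slices = slices)
    }
    rows <- lapply(values, function(val) {
      d <- if (variable == "diameter") as.numeric(val) else diameter
      c <- if (variable == "contrast") as.numeric(val) else contrast
      c(flat = one_dprime(measurement, "flat", d, c),
        gaussian = one_dprime(measurement, "gaussian", d, c))
    })
  }
  out <- data.frame(
    value = if (variable == "kernel") as.character(values)
            else as.numeric(values),
    dprime_flat = vapply(rows, function(r) r[["flat"]], numeric(1)),
    dprime_gaussian = vapply(rows, function(r) r[["gaussian"]], numeric(1))
  )
  if (length(values) > 1) {
    if (variable == "contrast") {
      attr(out, "fit_flat") <- fit_linear(out$value, out$dprime_flat)
      attr(out, "fit_gaussian") <- fit_linear(out$value, out$dprime_gaussian)
    } else if (variable == "diameter" && length(values) >= 4) {
      attr(out, "fit_flat") <- fit_exponential(out$value, out$dprime_flat)
      attr(out, "fit_gaussian") <- fit_exponential(out$value,
                                                   out$dprime_gaussian)
    }
  }
  out
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    scan = list(),
    ttf = list(material = "bone"),
    nps = list(n_rois = 5L, shift = "left"),
    task = list(diameter = 5, contrast = 15, matrix = 300L,
                pixel_mm = 0.05),
    observer = "NPW"
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full measurement pipeline
#'
#' Simulates (or, when `config$input` names DICOM directories, reads) the
#' insert and homogeneous modules, measures TTF and NPS, computes the NPW
#' d' for the flat and Gaussian task profiles, and returns a report with
#' every intermediate summary. Deterministic for a fixed config (the seed
#' is part of the config and is echoed in the report).
#'
#' @param config a named list, or the path of a YAML file with (subsets
#'   of) the keys `seed`, `scan` (forwarded to [scan_config()]), `input`
#'   (`module1` / `module3` DICOM directories), `ttf$material`,
#'   `nps$n_rois`, `nps$shift`, `task` (`diameter`, `contrast`, `matrix`,
#'   `pixel_mm`), `observer`.
#' @param export_dir optional directory; when given, the TTF/NPS curves
#'   are written as CSV and the report as JSON.
#' @return The report, a list of class `ctiq_report`.
#' @export
run_pipeline <- function(config = list(), export_dir = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  scan_args <- cfg$scan
  scan_args$seed <- scan_args$seed %||% cfg$seed
  scan <- do.call(scan_config, scan_args)
  if (!is.null(cfg$input)) {
    stack1 <- read_ct_series(cfg$input$module1)
    stack3 <- read_ct_series(cfg$input$module3)
    ttf <- measure_ttf(stack1, cfg$ttf$material)
    nps <- measure_nps(stack3, n_rois = cfg$nps$n_rois,
                       shift = cfg$nps$shift)
    meas <- list(ttf = ttf, nps = nps)
  } else {
    meas <- measure_condition(scan, cfg$ttf$material,
                              n_rois = cfg$nps$n_rois,
                              shift = cfg$nps$shift)
  }
  tk <- cfg$task
  dp <- lapply(c(flat = "flat", gaussian = "gaussian"), function(p) {
    dprime_for_task(meas$ttf, meas$nps, p, tk$diameter, tk$contrast,
                    tk$matrix, tk$pixel_mm, observer = cfg$observer)$dprime
  })
  report <- structure(list(
    seed = scan$seed,
    ttf = list(material = meas$ttf$material, f50 = meas$ttf$f50,
               f10 = meas$ttf$f10, cnr = meas$ttf$cnr),
    nps = list(noise_magnitude = meas$nps$nps1d$noise_magnitude,
               peak_freq = meas$nps$nps1d$peak_freq,
               mean_freq = meas$nps$nps1d$mean_freq,
               n_rois = meas$nps$nps2d$n_rois_used,
               n_slices = meas$nps$nps2d$n_slices_used),
    task = tk,
    observer = cfg$observer,
    dprime = dp
  ), class = "ctiq_report")
  attr(report, "measurement") <- meas
  if (!is.null(export_dir)) {
    if (!dir.exists(export_dir)) {
      dir.create(export_dir, recursive = TRUE)
    }
    export_curve(meas$ttf$freq_mm, meas$ttf$ttf,
                 c("f_mm^-1", "TTF"), file.path(export_dir, "ttf.csv"))
    export_curve(meas$nps$nps1d$freq_mm, meas$nps$nps1d$values,
                 c("f_mm^-1", "NPS_HU2mm2"),
                 file.path(export_dir, "nps1d.csv"))
    writeLines(report_json(report), file.path(export_dir, "report.json"))
  }
  report
}

report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA))
}

#' @export
print.ctiq_report <- function(x, ...) {
  cat("<ctiq_report>\n")
  cat(sprintf("  TTF (%s): f50 = %.3f, f10 = %.3f mm^-1, CNR = %.1f\n",
              x$ttf$material, x$ttf$f50, x$ttf$f10, x$ttf$cnr))
  cat(sprintf("  NPS: magnitude = %.2f HU, peak = %.3f, mean = %.3f mm^-1\n",
              x$nps$noise_magnitude, x$nps$peak_freq, x$nps$mean_freq))
  cat(sprintf("  d' (%s, %.3g mm, %.3g HU): flat = %.3f, gaussian = %.3f\n",
              x$observer, x$task$diameter, x$task$contrast,
              x$dprime$flat, x$dprime$gaussian))
  invisible(x)
}
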