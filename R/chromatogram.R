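# Extracted-ion chromatograms, peak integration, standard-curve fitting and
# product-fraction normalization — the quantification arithmetic behind a
# Table-1-style product report.

#' Construct a spectra series
#'
#' @param scans List of scans, each `list(rt = minutes, mz = numeric,
#'   intensity = numeric)` with strictly increasing retention times and
#'   non-negative intensities.
#' @return Object of class `SpectraSeries`.
#' @export
spectra_series <- function(scans) {
  if (length(scans) == 0L) stop("spectra series has no scans")
  rt <- vapply(scans, `[[`, numeric(1), "rt")
  if (any(diff(rt) <= 0)) stop("retention times must be strictly increasing")
  for (s in scans) {
    if (length(s$mz) != length(s$intensity)) {
      stop("scan mz and intensity lengths differ")
    }
    if (any(s$intensity < 0)) stop("negative intensities")
  }
  structure(list(scans = scans), class = "SpectraSeries")
}

#' @export
print.SpectraSeries <- function(x, ...) {
  rt <- vapply(x$scans, `[[`, numeric(1), "rt")
  cat(sprintf("SpectraSeries: %d scans, rt %.2f-%.2f min\n",
              length(x$scans), min(rt), max(rt)))
  invisible(x)
}

#' Read a spectra series from long-format CSV
#'
#' Expected columns: `rt` (minutes), `mz`, `intensity`; one row per peak.
#'
#' @param path CSV path.
#' @return A `SpectraSeries`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("rt", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("spectra CSV must have columns rt, mz, intensity")
  }
  rts <- sort(unique(df$rt))
  spectra_series(lapply(rts, function(t) {
    d <- df[df$rt == t, , drop = FALSE]
    list(rt = t, mz = d$mz, intensity = d$intensity)
  }))
}

#' Write a spectra series as long-format CSV
#'
#' @param s A `SpectraSeries`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "SpectraSeries"))
  df <- do.call(rbind, lapply(s$scans, function(sc) {
    if (length(sc$mz) == 0L) return(NULL)
    data.frame(rt = sc$rt, mz = sc$mz, intensity = sc$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract an ion chromatogram
#'
#' Per scan, the summed intensity of peaks within `target_mz * tol_ppm * 1e-6`
#' of the target.
#'
#' @param s A `SpectraSeries`.
#' @param target_mz Target m/z.
#' @param tol_ppm Mass tolerance in ppm; default 20.
#' @return Object of class `Chromatogram`: `times`, `intensities`,
#'   `target_mz`, `tol_ppm`.
#' @export
extract_eic <- function(s, target_mz, tol_ppm = 20) {
  stopifnot(inherits(s, "SpectraSeries"))
  tol <- target_mz * tol_ppm * 1e-6
  times <- vapply(s$scans, `[[`, numeric(1), "rt")
  ints <- vapply(s$scans, function(sc) {
    sel <- abs(sc$mz - target_mz) <= tol
    if (any(sel)) sum(sc$intensity[sel]) else 0
  }, numeric(1))
  structure(list(times = times, intensities = ints,
                 target_mz = target_mz, tol_ppm = tol_ppm),
            class = "Chromatogram")
}

#' @export
print.Chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: m/z %.4f +/- %g ppm, %d points, max %.3g\n",
              x$target_mz, x$tol_ppm, length(x$times), max(x$intensities)))
  invisible(x)
}

#' Trapezoidal peak area over a retention-time window
#'
#' Intensities at the window edges are obtained by linear interpolation, so
#' the integral is additive over adjacent windows.
#'
#' @param c A `Chromatogram`.
#' @param window `c(t_start, t_end)` in minutes, inside the time range.
#' @param baseline `"none"` (default) or `"constant"`, which subtracts the
#'   mean of the two window-edge intensities (floored at zero overall).
#' @return Peak area (intensity x minutes).
#' @export
integrate_peak <- function(c, window, baseline = c("none", "constant")) {
  stopifnot(inherits(c, "Chromatogram"))
  baseline <- match.arg(baseline)
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be (t_start, t_end) with t_start < t_end")
  }
  if (window[1L] < min(c$times) || window[2L] > max(c$times)) {
    stop("integration window outside the chromatogram time range")
  }
  inside <- c$times > window[1L] & c$times < window[2L]
  t <- c(window[1L], c$times[inside], window[2L])
  y <- c(stats::approx(c$times, c$intensities, xout = window[1L])$y,
         c$intensities[inside],
         stats::approx(c$times, c$intensities, xout = window[2L])$y)
  if (baseline == "constant") y <- y - mean(y[c(1L, length(y))])
  max(0, sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Fit a linear standard curve (area vs concentration)
#'
#' Ordinary least squares `area = slope * concentration + intercept`.
#'
#' @param points data.frame with columns `concentration` and `area`, at
#'   least two distinct concentrations.
#' @param compound Optional compound identifier stored with the curve.
#' @return Object of class `StandardCurve`: `slope`, `intercept`, `r2`,
#'   `compound`, `n`.
#' @export
fit_standard_curve <- function(points, compound = NA_character_) {
  if (!all(c("concentration", "area") %in% names(points))) {
    stop("points must have columns concentration and area")
  }
  if (length(unique(points$concentration)) < 2L) {
    stop("standard curve needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$area - mean(points$area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, compound = compound, n = nrow(points)),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve%s: area = %.4g * conc + %.4g (r2 = %.4f, n = %d)\n",
              if (is.na(x$compound)) "" else paste0(" [", x$compound, "]"),
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Concentrations from areas and product-fraction normalization
#'
#' Yield per compound is `(area - intercept) / slope`, floored at zero;
#' percentages are `100 * yield / total yield`. `shared_curve_map` lets
#' structurally similar compounds share one calibration (e.g. a hydroxylated
#' product quantified on the carbonyl standard's curve).
#'
#' @param areas Named numeric vector of peak areas per compound.
#' @param curves Named list of [fit_standard_curve()] results.
#' @param shared_curve_map Optional named character vector mapping compound
#'   name to the name of the curve in `curves` it should use; compounds not
#'   in the map use the curve of their own name.
#' @return List with `yields` and `percentages` (named numeric vectors;
#'   percentages sum to 100).
#' @export
quantify_and_normalize <- function(areas, curves, shared_curve_map = NULL) {
  cmap <- stats::setNames(names(areas), names(areas))
  if (!is.null(shared_curve_map)) {
    cmap[names(shared_curve_map)] <- shared_curve_map
  }
  missing <- setdiff(unname(cmap), names(curves))
  if (length(missing) > 0L) {
    stop("no standard curve for: ", paste(missing, collapse = ", "))
  }
  yields <- vapply(names(areas), function(cp) {
    cv <- curves[[cmap[[cp]]]]
    if (cv$slope <= 0) stop("non-positive slope in curve for ", cp)
    max(0, (areas[[cp]] - cv$intercept) / cv$slope)
  }, numeric(1))
  total <- sum(yields)
  if (total <= 0) stop("total yield is zero")
  list(yields = yields, percentages = 100 * yields / total)
}
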