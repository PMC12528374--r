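#' Force-time curve from a nanoindentation experiment
#'
#' A stress-relaxation record: force sampled over time while a spherical
#' probe indents the sample to a target depth and holds it.
#'
#' @param t times (s), strictly increasing.
#' @param F forces (nN), same length as `t`.
#' @param R probe radius (µm).
#' @param h target indentation depth (µm).
#' @param force_units,time_units unit labels stored with the curve.
#' @param normalized logical; TRUE after [preprocess_relaxation].
#' @param group optional grouping label (condition/replicate set).
#' @return An object of class `force_time_curve`.
#' @export
force_time_curve <- function(t, F, R = 27.5, h = 3,
                             force_units = "nN", time_units = "s",
                             normalized = FALSE, group = NA_character_) {
  stopifnot(length(t) == length(F), length(t) >= 2)
  if (any(!is.finite(t)) || any(!is.finite(F)))
    stop("non-finite values in curve")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  structure(list(t = as.numeric(t), F = as.numeric(F), R = R, h = h,
                 force_units = force_units, time_units = time_units,
                 normalized = normalized, group = group),
            class = "force_time_curve")
}

#' Force-depth indentation curve
#'
#' @param depth indentation depths (µm), non-negative.
#' @param F forces (nN), same length.
#' @param R probe radius (µm).
#' @return An object of class `indentation_curve`.
#' @export
indentation_curve <- function(depth, F, R = 27.5) {
  stopifnot(length(depth) == length(F), all(depth >= 0), R > 0)
  structure(list(depth = as.numeric(depth), F = as.numeric(F), R = R),
            class = "indentation_curve")
}

#' Indentation strain for a spherical probe
#'
#' Representative contact strain `0.2 * a / R` with contact radius
#' `a = sqrt(h * R)`, i.e. `0.2 * sqrt(h / R)`.
#'
#' @param h indentation depth (µm), `>= 0`.
#' @param R probe radius (µm), `> 0`.
#' @return Dimensionless strain. For the standard protocol (h = 3 µm,
#'   R = 27.5 µm) this is about 0.066, i.e. approximately 7%.
#' @examples
#' compute_strain(3, 27.5)
#' @export
compute_strain <- function(h, R) {
  if (any(R <= 0)) stop("probe radius must be > 0")
  if (any(h < 0)) stop("indentation depth must be >= 0")
  0.2 * sqrt(h * R) / R
}

#' Preprocess a stress-relaxation curve
#'
#' Standard preprocessing of a raw force-time record: (1) if the baseline
#' (median of the earliest samples) is negative, the whole signal is shifted
#' to zero force; (2) the force maximum and its time define the peak point
#' (t0, F0); (3) the curve is shifted so the peak sits at t = 0; (4) only
#' the hold phase (from the peak to the end of the record, or to `hold_end`
#' when a retraction is present) is retained; (5) force is normalised by F0.
#' The returned curve therefore starts at t = 0 with F = 1.
#'
#' @param curve a [force_time_curve].
#' @param hold_end optional time (in the shifted frame) at which the hold
#'   phase ends; defaults to the end of the record.
#' @param baseline_n number of leading samples whose median defines the
#'   baseline.
#' @return The normalised, cropped [force_time_curve] (with `normalized =
#'   TRUE` and the detected `F0` attached as attribute `"F0"`).
#' @export
preprocess_relaxation <- function(curve, hold_end = NULL, baseline_n = 5L) {
  stopifnot(inherits(curve, "force_time_curve"))
  FF <- curve$F
  baseline <- median(FF[seq_len(min(baseline_n, length(FF)))])
  if (baseline < 0) FF <- FF - baseline
  i0 <- which.max(FF)
  if (i0 == length(FF))
    stop("no hold phase: force is still rising at the last sample")
  F0 <- FF[i0]
  if (F0 <= 0) stop("non-positive peak force F0")
  t <- curve$t[i0:length(curve$t)] - curve$t[i0]
  FF <- FF[i0:length(FF)] / F0
  if (!is.null(hold_end)) {
    keep <- t <= hold_end
    t <- t[keep]; FF <- FF[keep]
  }
  out <- force_time_curve(t, FF, R = curve$R, h = curve$h,
                          force_units = "dimensionless",
                          time_units = curve$time_units,
                          normalized = TRUE, group = curve$group)
  attr(out, "F0") <- F0
  out
}

#' Average normalised relaxation curves
#'
#' Pointwise mean and standard deviation of a set of normalised curves on a
#' common time grid: the grid of the first curve restricted to the window
#' shared by all curves, with the others linearly interpolated onto it.
#'
#' @param curves list of `>= 2` normalised [force_time_curve]s with
#'   overlapping hold windows.
#' @return A [force_time_curve] holding the mean (with per-point SD in
#'   attribute `"sd"` and the curve count in `"n_curves"`).
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 2)
  for (cv in curves)
    if (!isTRUE(cv$normalized))
      stop("average_curves expects preprocessed (normalised) curves")
  lo <- max(vapply(curves, function(cv) min(cv$t), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$t), numeric(1)))
  if (hi <= lo) stop("curves have disjoint time windows")
  grid <- curves[[1]]$t
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) stop("shared time window too short")
  mat <- vapply(curves, function(cv) approx(cv$t, cv$F, xout = grid)$y,
                numeric(length(grid)))
  out <- force_time_curve(grid, rowMeans(mat), R = curves[[1]]$R,
                          h = curves[[1]]$h,
                          force_units = "dimensionless",
                          normalized = TRUE, group = curves[[1]]$group)
  attr(out, "sd") <- apply(mat, 1, sd)
  attr(out, "n_curves") <- length(curves)
  out
}

#' Time for the force to relax to 80% of its peak
#'
#' First crossing of the normalised force below `threshold`, linearly
#' interpolated between the bracketing samples. A curve that never relaxes
#' below the threshold yields an explicit "not reached" result rather than
#' NaN; a curve already below it at its first hold sample yields 0.
#'
#' @param curve a normalised [force_time_curve] (starting at F = 1).
#' @param threshold relative force level, default 0.8.
#' @return A list with `t80` (s, `NA` when not reached) and logical
#'   `reached`.
#' @export
time_to_80pct <- function(curve, threshold = 0.8) {
  stopifnot(inherits(curve, "force_time_curve"), isTRUE(curve$normalized))
  FF <- curve$F; t <- curve$t
  if (FF[1] <= threshold) return(list(t80 = 0, reached = TRUE))
  below <- which(FF <= threshold)
  if (length(below) == 0) return(list(t80 = NA_real_, reached = FALSE))
  i <- below[1]
  # linear interpolation between the bracketing samples (earliest crossing)
  t80 <- t[i - 1] + (t[i] - t[i - 1]) *
    (FF[i - 1] - threshold) / (FF[i - 1] - FF[i])
  list(t80 = t80, reached = TRUE)
}

#' Energy dissipation of a relaxation curve
#'
#' Relative dissipation of the hold phase, in percent. The default
#' (`"amplitude"`) definition is the relaxation amplitude of the normalised
#' curve, `100 * (1 - F_end)`, with `F_end` the mean of the trailing
#' samples: 0% for a purely elastic solid, 100% for a fully relaxing
#' (Maxwell) material held much longer than its relaxation time. The
#' `"area"` alternative is `100 * (1 - mean(F))`, the fraction of the
#' instantaneous-force impulse dissipated over the hold.
#'
#' @param curve a normalised [force_time_curve].
#' @param method `"amplitude"` (default) or `"area"`.
#' @param tail_n number of trailing samples averaged for `F_end`.
#' @return Percentage in `[0, 100]`.
#' @export
energy_dissipation_pct <- function(curve, method = c("amplitude", "area"),
                                   tail_n = 5L) {
  stopifnot(inherits(curve, "force_time_curve"), isTRUE(curve$normalized))
  method <- match.arg(method)
  val <- if (method == "amplitude") {
    f_end <- mean(tail(curve$F, tail_n))
    100 * (1 - f_end)
  } else {
    100 * (1 - mean(curve$F))
  }
  min(100, max(0, val))
}

#' Hertzian Young's modulus fit
#'
#' Least-squares Young's modulus from the Hertz contact model for a sphere,
#' `F = (4/3) * E/(1 - nu^2) * sqrt(R) * depth^(3/2)`, which is linear in E.
#' Units: depth and R in µm, F in nN, E returned in Pa.
#'
#' @param curve an [indentation_curve] with `>= 10` post-contact points.
#' @param poisson Poisson ratio, default 0.5 (incompressible gel).
#' @return Young's modulus in Pa (`>= 0`), with the fitted force curve in
#'   attribute `"fitted"`.
#' @export
hertz_fit <- function(curve, poisson = 0.5) {
  stopifnot(inherits(curve, "indentation_curve"))
  d <- curve$depth; FF <- curve$F
  keep <- d >= 0
  if (sum(keep) < 10) stop("need >= 10 post-contact points")
  x <- d[keep]^1.5
  y <- FF[keep]
  sxx <- sum(x^2)
  if (sxx == 0) stop("degenerate curve: no indentation depth")
  C <- sum(x * y) / sxx                # nN / µm^1.5
  if (all(y == 0)) return(structure(0, fitted = y))
  E <- 0.75 * (1 - poisson^2) * C * 1e3 / sqrt(curve$R)  # Pa
  if (E < 0)
    stop(sprintf(
      "non-physical negative modulus (E = %.3g Pa; mean force %.3g nN)",
      E, mean(y)))
  structure(E, fitted = C * x)
}

#' Write a force-time curve to a delimited text file
#'
#' Two-column tab-separated file with a small commented header carrying the
#' metadata (units, probe radius, target depth, group).
#'
#' @param curve a [force_time_curve].
#' @param path output file path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_time_curve"))
  hdr <- c(sprintf("# probe_radius_um: %g", curve$R),
           sprintf("# depth_um: %g", curve$h),
           sprintf("# force_units: %s", curve$force_units),
           sprintf("# time_units: %s", curve$time_units),
           sprintf("# normalized: %s", curve$normalized),
           sprintf("# group: %s", curve$group),
           "t\tF")
  body <- sprintf("%.6g\t%.6g", curve$t, curve$F)
  writeLines(c(hdr, body), path)
}

#' Read a force-time curve written by [write_curve]
#'
#' @param path input file path.
#' @return A [force_time_curve].
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (hl in hdr_lines) {
    kv <- sub("^#\\s*", "", hl)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  dat <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  if (!all(c("t", "F") %in% names(dat)))
    stop("curve file must have columns t and F: ", path)
  fu <- if (!is.null(meta$force_units)) meta$force_units else "nN"
  tu <- if (!is.null(meta$time_units)) meta$time_units else "s"
  if (!tu %in% c("s", "dimensionless"))
    stop("unsupported time units '", tu, "' in ", path)
  force_time_curve(
    dat$t, dat$F,
    R = if (!is.null(meta$probe_radius_um)) as.numeric(meta$probe_radius_um) else 27.5,
    h = if (!is.null(meta$depth_um)) as.numeric(meta$depth_um) else 3,
    force_units = fu, time_units = tu,
    normalized = identical(meta$normalized, "TRUE"),
    group = if (!is.null(meta$group)) meta$group else NA_character_)
}

#' Summarise a group of relaxation curves
#'
#' Full analysis of one curve group: preprocess each curve, average, and
#' extract the peak force, the time to 80% force and the energy
#' dissipation.
#'
#' @param curves list of raw [force_time_curve]s from one condition.
#' @param ed_method energy-dissipation definition (see
#'   [energy_dissipation_pct]).
#' @return A one-row data.frame (`relaxation_summary`): `F0` (nN, mean over
#'   curves), `t80` (s or NA), `t80_reached`, `energy_dissipation_pct`,
#'   `n_curves`; the averaged curve is in attribute `"avg_curve"`.
#' @export
summarise_relaxation <- function(curves, ed_method = "amplitude") {
  pre <- lapply(curves, preprocess_relaxation)
  avg <- average_curves(pre)
  f0 <- mean(vapply(pre, function(p) attr(p, "F0"), numeric(1)))
  t80 <- time_to_80pct(avg)
  ed <- energy_dissipation_pct(avg, method = ed_method)
  out <- data.frame(group = curves[[1]]$group, F0 = f0, t80 = t80$t80,
                    t80_reached = t80$reached, energy_dissipation_pct = ed,
                    n_curves = length(curves), stringsAsFactors = FALSE)
  attr(out, "avg_curve") <- avg
  class(out) <- c("relaxation_summary", class(out))
  out
}
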