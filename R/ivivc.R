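#' Matched in vitro / in vivo clearance pairs
#'
#' @param label Membrane + drug labels.
#' @param cl_in_vitro,cl_in_vivo Clearances, ml/min; both `> 0`.
#' @param sd_in_vitro,sd_in_vivo Optional standard deviations, ml/min
#'   (carried along; unused by the default unweighted fit).
#' @return A data.frame of class `clearance_pairs`.
#' @export
clearance_pairs <- function(label, cl_in_vitro, cl_in_vivo,
                            sd_in_vitro = NA_real_, sd_in_vivo = NA_real_) {
  if (any(cl_in_vitro <= 0) || any(cl_in_vivo <= 0))
    stop("clearances must be > 0", call. = FALSE)
  structure(data.frame(label = label, cl_in_vitro = cl_in_vitro,
                       cl_in_vivo = cl_in_vivo, sd_in_vitro = sd_in_vitro,
                       sd_in_vivo = sd_in_vivo, stringsAsFactors = FALSE),
            class = c("clearance_pairs", "data.frame"))
}

#' Straight-line correlation of in vitro and in vivo clearance
#'
#' Ordinary least-squares best-fit line between matched clearance values.
#' With the default orientation `"invitro_on_invivo"` the in vitro clearance
#' is regressed on the in vivo clearance; the Pearson correlation is
#' orientation-independent, the residual sum of squares is not.
#'
#' @param pairs A [clearance_pairs()] data.frame (or any data.frame with
#'   columns `cl_in_vitro` and `cl_in_vivo`); at least 3 rows.
#' @param orientation `"invitro_on_invivo"` (default) or
#'   `"invivo_on_invitro"`.
#' @return List of class `ivivc_correlation` with `n_points`, `df`
#'   (`n_points - 2`), `slope`, `intercept` (ml/min), `pearson_r`,
#'   `r_squared`, `adj_r_squared`, `rss` ((ml/min)^2), `orientation`.
#' @export
#' @examples
#' pairs <- clearance_pairs(letters[1:4], c(50, 80, 110, 140),
#'                          c(55, 78, 105, 150))
#' correlate_clearances(pairs)
correlate_clearances <- function(pairs,
                                 orientation = c("invitro_on_invivo",
                                                 "invivo_on_invitro")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(pairs),
            all(c("cl_in_vitro", "cl_in_vivo") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 clearance pairs", call. = FALSE)
  x <- if (orientation == "invitro_on_invivo") pairs$cl_in_vivo else pairs$cl_in_vitro
  y <- if (orientation == "invitro_on_invivo") pairs$cl_in_vitro else pairs$cl_in_vivo
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one axis; correlation undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(
    n_points = n, df = n - 2L,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = r, r_squared = r^2,
    adj_r_squared = adjusted_r_squared(r^2, n),
    rss = sum(stats::resid(fit)^2),
    orientation = orientation
  ), class = "ivivc_correlation")
}

#' @export
print.ivivc_correlation <- function(x, ...) {
  cat(sprintf(
    "<ivivc_correlation> n = %d (df %d), %s\n  slope %.4f, intercept %.2f ml/min\n  Pearson r %.5f, R^2 %.5f, adj R^2 %.5f, RSS %.2f\n",
    x$n_points, x$df, x$orientation, x$slope, x$intercept,
    x$pearson_r, x$r_squared, x$adj_r_squared, x$rss))
  invisible(x)
}

#' Adjusted R-squared for a straight-line fit
#'
#' `1 - (1 - R^2) (n - 1) / (n - p)` with `p = 2` parameters for a line.
#'
#' @param r_squared Coefficient of determination.
#' @param n_points Number of points; must exceed `n_params`.
#' @param n_params Number of fitted parameters (default 2).
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r_squared, n_points, n_params = 2L) {
  if (n_points <= n_params)
    stop("'n_points' must exceed 'n_params'", call. = FALSE)
  1 - (1 - r_squared) * (n_points - 1) / (n_points - n_params)
}

#' Time-scaling factor from distribution volumes
#'
#' The bench circuit holds far less drug-accessible volume than a patient, so
#' in vitro concentrations decline much faster. Aligning the curves requires
#' stretching in vitro time by the ratio of apparent distribution volumes,
#' `Vd_in_vivo / Vd_in_vitro`.
#'
#' @param vd_in_vivo,vd_in_vitro Apparent distribution volumes, ml; `> 0`.
#' @return Dimensionless time multiplication factor.
#' @export
#' @examples
#' time_scale_factor(vd_in_vivo = 14768, vd_in_vitro = 1300)  # 11.36
time_scale_factor <- function(vd_in_vivo, vd_in_vitro) {
  if (vd_in_vivo <= 0 || vd_in_vitro <= 0)
    stop("distribution volumes must be > 0", call. = FALSE)
  vd_in_vivo / vd_in_vitro
}

#' Apply a time-scaling factor
#'
#' @param times Sample times, min.
#' @param factor Positive multiplier.
#' @return Elementwise `times * factor` (order preserved).
#' @export
apply_time_scaling <- function(times, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("'factor' must be a single positive number", call. = FALSE)
  times * factor
}

#' Fit the time-scaling factor between two concentration curves
#'
#' Finds the factor `f` minimizing the sum of squared log-concentration
#' residuals \eqn{\sum_i [\ln C_{vivo}(t_i) - \ln C_{vitro}(t_i/f)]^2} over
#' the in vivo timepoints whose scaled image falls inside the in vitro
#' support, with linear interpolation in `(t, ln C)`. A log-spaced grid
#' search brackets the optimum, then golden-section search refines it.
#' Working in log concentration equalizes relative errors across the decline
#' and makes mono-exponential alignment exact.
#'
#' @param times_vitro,conc_vitro In vitro curve; at least 3 positive
#'   concentrations.
#' @param times_vivo,conc_vivo In vivo curve; at least 3 positive
#'   concentrations.
#' @param factor_range Search interval for the factor (default 0.05 to 500).
#' @return List of class `time_scaling_fit` with `factor`, `fit_loss` and the
#'   number of overlapping points used at the optimum.
#' @export
#' @examples
#' tt <- c(1, 5, 10, 15, 20, 30, 40, 60)
#' fit_time_factor(tt, exp(-0.1 * tt), tt * 11.36, exp(-0.1 * tt))
fit_time_factor <- function(times_vitro, conc_vitro, times_vivo, conc_vivo,
                            factor_range = c(0.05, 500)) {
  keep_a <- is.finite(conc_vitro) & conc_vitro > 0
  keep_b <- is.finite(conc_vivo) & conc_vivo > 0
  if (sum(keep_a) < 3L || sum(keep_b) < 3L)
    stop("each curve needs at least 3 positive concentrations", call. = FALSE)
  ta <- times_vitro[keep_a]; la <- log(conc_vitro[keep_a])
  tb <- times_vivo[keep_b]; lb <- log(conc_vivo[keep_b])
  loss <- function(f) {
    ts <- tb / f
    inside <- ts >= min(ta) & ts <= max(ta)
    if (sum(inside) < 3L) return(NA_real_)
    pred <- stats::approx(ta, la, xout = ts[inside])$y
    sum((lb[inside] - pred)^2)
  }
  grid <- exp(seq(log(factor_range[1]), log(factor_range[2]), length.out = 400L))
  lvals <- vapply(grid, loss, numeric(1))
  if (all(is.na(lvals)))
    stop("curves have no overlapping support for any factor in range",
         call. = FALSE)
  i <- which.min(lvals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  # golden-section refinement on log-factor
  phi <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  safe_loss <- function(lf) { v <- loss(exp(lf)); if (is.na(v)) Inf else v }
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- safe_loss(c1); f2 <- safe_loss(c2)
  for (k in seq_len(80L)) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- safe_loss(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- safe_loss(c2) }
    if (b - a < 1e-10) break
  }
  fbest <- exp((a + b) / 2)
  ts <- tb / fbest
  structure(list(factor = fbest, fit_loss = loss(fbest),
                 n_overlap = sum(ts >= min(ta) & ts <= max(ta))),
            class = "time_scaling_fit")
}

#' Clearance gain factor between two membrane areas
#'
#' Ratio of the larger-area membrane's clearance to the smaller one's, used
#' to extrapolate clearance to a structurally related membrane of a different
#' surface area.
#'
#' @param cl_small,cl_large Clearances of the smaller- and larger-area
#'   membranes, ml/min; both `> 0`.
#' @return Dimensionless scaling factor `cl_large / cl_small`.
#' @export
#' @examples
#' area_scaling_factor(160.75, 178.25)  # 1.109 for a 1.7 -> 2.1 m^2 step
area_scaling_factor <- function(cl_small, cl_large) {
  if (cl_small <= 0 || cl_large <= 0)
    stop("clearances must be > 0", call. = FALSE)
  cl_large / cl_small
}

#' Area-extrapolation specification
#'
#' The scaling factor is an explicit input, not derived from the areas: the
#' clearance gain of a real membrane family is an empirical quantity (it is
#' not proportional to area), so the factor measured on an analogous family
#' is supplied directly.
#'
#' @param area_from,area_to Membrane areas, m^2; `> 0`.
#' @param factor Clearance scaling factor; `> 0`.
#' @return An object of class `extrapolation_spec`.
#' @export
extrapolation_spec <- function(area_from, area_to, factor) {
  if (area_from <= 0 || area_to <= 0) stop("areas must be > 0", call. = FALSE)
  if (factor <= 0) stop("'factor' must be > 0", call. = FALSE)
  structure(list(area_from = area_from, area_to = area_to, factor = factor),
            class = "extrapolation_spec")
}

#' Extrapolate clearance to a different membrane area
#'
#' @param cl_ref Reference clearance, ml/min; `> 0`.
#' @param spec An [extrapolation_spec()].
#' @return `cl_ref * spec$factor`, ml/min.
#' @export
#' @examples
#' extrapolate_clearance(90.12, extrapolation_spec(1.7, 2.1, factor = 1.2))
extrapolate_clearance <- function(cl_ref, spec) {
  stopifnot(inherits(spec, "extrapolation_spec"))
  if (any(cl_ref <= 0)) stop("'cl_ref' must be > 0", call. = FALSE)
  cl_ref * spec$factor
}
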