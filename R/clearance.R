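#' Hematocrit-corrected hemofilter clearance
#'
#' Blood-side clearance corrected for the plasma fraction of blood flow:
#' \deqn{CL = (1 - Hc)\,\frac{BFR \cdot C_{pre} - C_{post}(BFR - UFR)}{C_{pre}},}
#' which for `UFR = 0` reduces to `(1 - Hc) * BFR * (C_pre - C_post) / C_pre`.
#' By default the denominator is `C_pre` (the standard dialysance convention,
#' consistent with dimensional analysis); `denominator = "c_post"` selects the
#' alternate reading.
#'
#' Negative values — which measurement noise can produce — are returned as-is,
#' never clamped; downstream summaries flag and exclude them explicitly.
#'
#' @param c_pre Pre-filter plasma concentration, mg/L; must be `> 0`.
#' @param c_post Post-filter plasma concentration, mg/L.
#' @param settings A [dialysis_settings()] supplying BFR, UFR and Hc.
#' @param denominator `"c_pre"` (default) or `"c_post"`.
#' @return Clearance in ml/min (vectorized over `c_pre`/`c_post`).
#' @export
#' @examples
#' s <- dialysis_settings(bfr = 300, hematocrit = 0.35)
#' hct_corrected_clearance(10, 4, s)  # 0.65 * 300 * 6 / 10 = 117 ml/min
hct_corrected_clearance <- function(c_pre, c_post, settings,
                                    denominator = c("c_pre", "c_post")) {
  (1 - settings$hematocrit) *
    uncorrected_clearance(c_pre, c_post, settings, denominator)
}

#' Non-hematocrit-corrected clearance
#'
#' As [hct_corrected_clearance()] without the `(1 - Hc)` factor:
#' `[BFR * C_pre - C_post * (BFR - UFR)] / C_pre`.
#'
#' @inheritParams hct_corrected_clearance
#' @return Clearance in ml/min.
#' @export
uncorrected_clearance <- function(c_pre, c_post, settings,
                                  denominator = c("c_pre", "c_post")) {
  stopifnot(inherits(settings, "dialysis_settings"))
  denominator <- match.arg(denominator)
  if (any(c_pre <= 0, na.rm = TRUE))
    stop("'c_pre' must be > 0 (flag/exclude zero samples upstream)", call. = FALSE)
  num <- settings$bfr * c_pre - c_post * (settings$bfr - settings$ufr)
  den <- if (denominator == "c_pre") c_pre else c_post
  num / den
}

#' Dialysate-side clearance
#'
#' Mass-balance cross-check on the effluent side:
#' `CL = DFR * C_dial / C_pre`. On a noiseless simulated run this equals the
#' hematocrit-corrected blood-side clearance by construction.
#'
#' @param c_pre Pre-filter plasma concentration, mg/L; `> 0`.
#' @param c_dial Dialysate concentration, mg/L, or `NA` when no dialysate
#'   sample exists (propagated as `NA`, never silently zero).
#' @param settings A [dialysis_settings()].
#' @return Clearance in ml/min; `NA` where `c_dial` is missing.
#' @export
dialysate_side_clearance <- function(c_pre, c_dial, settings) {
  stopifnot(inherits(settings, "dialysis_settings"))
  if (any(c_pre <= 0, na.rm = TRUE))
    stop("'c_pre' must be > 0", call. = FALSE)
  settings$dfr * c_dial / c_pre
}

#' Dialysate saturation coefficient
#'
#' How fully the dialysate equilibrates with plasma across the filter. The
#' default is the mean-plasma convention
#' `2 * C_dial / (C_pre + C_post)`; `convention = "c_pre"` selects the
#' single-sided `C_dial / C_pre`.
#'
#' @param c_pre,c_post,c_dial Concentrations, mg/L.
#' @param convention `"mean"` (default) or `"c_pre"`.
#' @return Dimensionless saturation coefficient.
#' @export
#' @examples
#' saturation_coefficient(10, 6, 4)  # 0.5
saturation_coefficient <- function(c_pre, c_post, c_dial,
                                   convention = c("mean", "c_pre")) {
  convention <- match.arg(convention)
  den <- if (convention == "mean") (c_pre + c_post) / 2 else c_pre
  if (any(den <= 0, na.rm = TRUE))
    stop("zero plasma-concentration denominator", call. = FALSE)
  c_dial / den
}

#' Per-timepoint clearance estimates for one run
#'
#' Computes corrected and uncorrected blood-side clearance, dialysate-side
#' clearance and the saturation coefficient at every sampled timepoint.
#' Timepoints with non-positive `c_pre` are flagged (`NA` estimates), as are
#' negative clearance estimates; nothing is clamped or dropped here.
#'
#' @param run A `dialysis_run`.
#' @param settings A [dialysis_settings()]; defaults to the run's own.
#' @param denominator Passed to [hct_corrected_clearance()].
#' @return A data.frame with columns `time`, `cl_corrected`,
#'   `cl_uncorrected`, `cl_dialysate_side`, `saturation_coefficient`,
#'   `flagged`.
#' @export
clearance_time_course <- function(run, settings = run$settings,
                                  denominator = c("c_pre", "c_post")) {
  stopifnot(inherits(run, "dialysis_run"))
  denominator <- match.arg(denominator)
  n <- length(run$times)
  if (n == 0L) stop("empty run", call. = FALSE)
  ok <- is.finite(run$c_pre) & run$c_pre > 0
  cl_c <- cl_u <- cl_d <- sat <- rep(NA_real_, n)
  if (any(ok)) {
    cl_c[ok] <- hct_corrected_clearance(run$c_pre[ok], run$c_post[ok],
                                        settings, denominator)
    cl_u[ok] <- uncorrected_clearance(run$c_pre[ok], run$c_post[ok],
                                      settings, denominator)
    cl_d[ok] <- dialysate_side_clearance(run$c_pre[ok], run$c_dial[ok], settings)
    den <- (run$c_pre[ok] + run$c_post[ok]) / 2
    sat[ok] <- ifelse(den > 0, run$c_dial[ok] / den, NA_real_)
  }
  flagged <- !ok | (!is.na(cl_c) & cl_c < 0)
  data.frame(time = run$times, cl_corrected = cl_c, cl_uncorrected = cl_u,
             cl_dialysate_side = cl_d, saturation_coefficient = sat,
             flagged = flagged)
}

#' Trapezoidal area under the concentration-time curve
#'
#' Linear trapezoid from the first to the last sample; no extrapolation
#' beyond the observed span.
#'
#' @param times Strictly increasing sample times, min; at least 2.
#' @param concentrations Concentrations, mg/L.
#' @return AUC in mg*min/L.
#' @export
#' @examples
#' auc_trapezoid(c(0, 10), c(10, 0))  # 50
auc_trapezoid <- function(times, concentrations) {
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(times) != length(concentrations))
    stop("'times' and 'concentrations' lengths differ", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  sum(diff(times) * (utils::head(concentrations, -1) +
                       utils::tail(concentrations, -1)) / 2)
}

#' Log-linear terminal elimination fit
#'
#' Ordinary least squares of `ln(C)` on time. Non-positive concentrations are
#' excluded before fitting; at least 3 positive points must remain.
#'
#' @param times Sample times, min.
#' @param concentrations Concentrations, mg/L.
#' @param dose Optional dose in mg; when given, the apparent distribution
#'   volume `vd = dose / C0_extrapolated` (ml, with dose in mg and C in mg/L
#'   giving L, converted to ml) is returned.
#' @return List with `k_el` (1/min), `half_life` (min, `ln 2 / k_el`;
#'   `Inf` for a flat series), `intercept` (ln mg/L) and `vd` (ml, or `NA`
#'   without a dose).
#' @export
#' @examples
#' tt <- c(1, 5, 10, 15, 20, 30, 40, 60)
#' elimination_fit(tt, 10 * exp(-0.05 * tt))  # k_el = 0.05, t1/2 = 13.86 min
elimination_fit <- function(times, concentrations, dose = NULL) {
  keep <- is.finite(concentrations) & concentrations > 0
  if (sum(keep) < 3L)
    stop("need at least 3 positive concentrations", call. = FALSE)
  fit <- stats::lm(log(concentrations[keep]) ~ times[keep])
  k_el <- -unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  vd <- if (is.null(dose)) NA_real_ else 1000 * dose / exp(intercept)
  list(k_el = k_el,
       half_life = if (k_el > 0) log(2) / k_el else Inf,
       intercept = intercept, vd = vd)
}

#' Summarize clearance estimates for one condition
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and count of
#' the retained per-timepoint estimates. Flagged estimates (non-positive
#' `c_pre`, negative clearance) are excluded, and the exclusion count is
#' reported; nothing is clamped.
#'
#' @param values Numeric clearance estimates, ml/min.
#' @param flagged Logical vector marking estimates to exclude (default: `NA`
#'   or negative values).
#' @return List with `mean`, `sd` (`NA` when `n < 2`), `n`, `n_excluded`.
#' @export
#' @examples
#' summarize_condition(c(100, 110, 120))  # mean 110, sd 10, n 3
summarize_condition <- function(values, flagged = is.na(values) | values < 0) {
  stopifnot(length(values) == length(flagged))
  kept <- values[!flagged]
  if (length(kept) == 0L) stop("no retained estimates in group", call. = FALSE)
  list(mean = mean(kept),
       sd = if (length(kept) >= 2L) stats::sd(kept) else NA_real_,
       n = length(kept),
       n_excluded = sum(flagged))
}

#' Per-condition clearance table for a study
#'
#' Pools per-timepoint clearance estimates across replicate runs of each
#' condition (membrane x drug x BFR x DFR) and summarizes them. By default N
#' counts every retained per-timepoint estimate across replicates;
#' `within_run_first = TRUE` averages each run's timepoints first so that N
#' counts runs.
#'
#' @param runs List of `dialysis_run` objects (e.g. from [generate_study()]).
#' @param within_run_first Average within runs before pooling.
#' @param denominator Passed to [hct_corrected_clearance()].
#' @return A data.frame with columns `membrane`, `drug`, `bfr_ml_min`,
#'   `dfr_ml_min`, `cl_ml_min`, `cl_uncorrected_ml_min`, `sd_ml_min`, `n`,
#'   `n_excluded`.
#' @export
estimate_study <- function(runs, within_run_first = FALSE,
                           denominator = c("c_pre", "c_post")) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(runs), length(runs) >= 1L)
  key <- vapply(runs, function(r)
    sprintf("%s\r%s\r%g\r%g", r$membrane$name, r$drug$name,
            r$settings$bfr, r$settings$dfr), character(1))
  out <- lapply(split(runs, key), function(grp) {
    per_run <- lapply(grp, clearance_time_course, denominator = denominator)
    pool <- function(col) {
      if (within_run_first)
        vapply(per_run, function(tc) mean(col(tc)[!tc$flagged]), numeric(1))
      else
        unlist(lapply(per_run, function(tc) col(tc)[!tc$flagged]))
    }
    vals <- pool(function(tc) tc$cl_corrected)
    vals_u <- pool(function(tc) tc$cl_uncorrected)
    n_flagged <- sum(vapply(per_run, function(tc) sum(tc$flagged), integer(1)))
    s <- summarize_condition(vals, flagged = is.na(vals))
    r1 <- grp[[1]]
    data.frame(membrane = r1$membrane$name, drug = r1$drug$name,
               bfr_ml_min = r1$settings$bfr, dfr_ml_min = r1$settings$dfr,
               cl_ml_min = s$mean,
               cl_uncorrected_ml_min = mean(vals_u, na.rm = TRUE),
               sd_ml_min = s$sd, n = s$n, n_excluded = n_flagged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Noncompartmental summary of one run
#'
#' Trapezoidal AUC over the sampled span, log-linear elimination fit and the
#' derived half-life and apparent distribution volume (from the run's known
#' initial reservoir drug mass).
#'
#' @param run A `dialysis_run`.
#' @return List with `auc` (mg*min/L), `k_el` (1/min), `half_life` (min),
#'   `vd` (ml).
#' @export
pk_summary <- function(run) {
  stopifnot(inherits(run, "dialysis_run"))
  fit <- elimination_fit(run$times, run$c_pre, dose = run$mass$initial)
  list(auc = auc_trapezoid(run$times, run$c_pre),
       k_el = fit$k_el, half_life = fit$half_life, vd = fit$vd)
}
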