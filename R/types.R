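#' Membrane specification
#'
#' Describes a hemofilter: its material, surface area and how its diffusive
#' clearance is modelled. Two models are supported: `"fixed_clearance"`, where
#' the intrinsic diffusive clearance `cl_membrane` (ml/min) is given directly
#' as an observed quantity, and `"k0a"`, where clearance is derived from the
#' mass-transfer-area coefficient K0A via the countercurrent dialyzer relation
#' (see [clearance_from_k0a()]), so that simulated clearance responds to blood
#' and dialysate flow the way real dialyzers do.
#'
#' @param name Text label, e.g. `"F80s"`.
#' @param material One of `"diacetate"`, `"triacetate"`, `"polysulfone"`.
#' @param area Membrane surface area in m^2; must be positive.
#' @param model `"fixed_clearance"` or `"k0a"`.
#' @param cl_membrane Intrinsic diffusive clearance, ml/min. Required when
#'   `model = "fixed_clearance"`.
#' @param k0a Mass-transfer-area coefficient, ml/min. Required when
#'   `model = "k0a"`.
#' @param adsorption Optional [adsorption_spec()] describing saturable drug
#'   binding to the membrane.
#' @return An object of class `membrane_spec`.
#' @export
#' @examples
#' membrane_spec("F80s", "polysulfone", area = 1.8,
#'               model = "fixed_clearance", cl_membrane = 122)
membrane_spec <- function(name, material, area,
                          model = c("fixed_clearance", "k0a"),
                          cl_membrane = NULL, k0a = NULL,
                          adsorption = NULL) {
  model <- match.arg(model)
  material <- match.arg(material, c("diacetate", "triacetate", "polysulfone"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("membrane 'area' must be a single positive number (m^2)", call. = FALSE)
  if (model == "fixed_clearance") {
    if (is.null(cl_membrane))
      stop("model 'fixed_clearance' requires 'cl_membrane'", call. = FALSE)
    if (!is.numeric(cl_membrane) || cl_membrane < 0)
      stop("'cl_membrane' must be >= 0 ml/min", call. = FALSE)
  } else {
    if (is.null(k0a))
      stop("model 'k0a' requires 'k0a'", call. = FALSE)
    if (!is.numeric(k0a) || k0a < 0)
      stop("'k0a' must be >= 0 ml/min", call. = FALSE)
  }
  if (!is.null(adsorption) && !inherits(adsorption, "adsorption_spec"))
    stop("'adsorption' must be an adsorption_spec or NULL", call. = FALSE)
  structure(list(name = name, material = material, area = area, model = model,
                 cl_membrane = cl_membrane, k0a = k0a, adsorption = adsorption),
            class = "membrane_spec")
}

#' Saturable membrane adsorption specification
#'
#' A finite pool of membrane binding sites taking up drug at a first-order
#' rate until exhausted. This mechanism reproduces the behaviour of drugs such
#' as teicoplanin, whose elimination is dominated by binding to the membrane
#' material rather than by diffusion into the dialysate.
#'
#' @param capacity Total binding-site capacity, mg; `>= 0`.
#' @param rate First-order adsorption rate constant, 1/min; `>= 0`. While the
#'   pool is unsaturated the uptake mass flux is `rate * C * Vp` (mg/min),
#'   equivalent to an adsorptive clearance of `rate * Vp` ml/min.
#' @return An object of class `adsorption_spec`.
#' @export
adsorption_spec <- function(capacity, rate) {
  if (!is.numeric(capacity) || length(capacity) != 1L || capacity < 0)
    stop("'capacity' must be >= 0 mg", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("'rate' must be >= 0 per min", call. = FALSE)
  structure(list(capacity = capacity, rate = rate), class = "adsorption_spec")
}

#' Dialysis machine operating point
#'
#' The flow settings and blood characteristics of one run. Defaults follow
#' standard intermittent hemodialysis bench conditions: blood flow 300 ml/min,
#' dialysate flow 500 ml/min, ultrafiltration 0 ml/min, a 2 L blood reservoir.
#' The bovine-blood hematocrit is configurable (it is never hard-coded
#' elsewhere); 0.35 is a typical value for both bovine blood and patients on
#' intermittent renal replacement therapy.
#'
#' @param bfr Blood flow rate (BFR), ml/min; `> 0`.
#' @param dfr Dialysate flow rate (DFR), ml/min; `> 0`.
#' @param ufr Ultrafiltration rate (UFR), ml/min; `>= 0` and `< bfr`.
#' @param hematocrit Hematocrit (Hc) as a fraction in `[0, 1)`.
#' @param blood_volume Reservoir blood volume, ml; `> 0`.
#' @return An object of class `dialysis_settings`.
#' @export
#' @examples
#' dialysis_settings()                      # standard 300/500, Hc 0.35, 2 L
#' dialysis_settings(bfr = 400, dfr = 800)
dialysis_settings <- function(bfr = 300, dfr = 500, ufr = 0,
                              hematocrit = 0.35, blood_volume = 2000) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  chk(bfr, "bfr"); chk(dfr, "dfr"); chk(ufr, "ufr")
  chk(hematocrit, "hematocrit"); chk(blood_volume, "blood_volume")
  if (bfr <= 0) stop("'bfr' must be > 0 ml/min", call. = FALSE)
  if (dfr <= 0) stop("'dfr' must be > 0 ml/min", call. = FALSE)
  if (ufr < 0) stop("'ufr' must be >= 0 ml/min", call. = FALSE)
  if (ufr >= bfr) stop("'ufr' must be < 'bfr'", call. = FALSE)
  if (hematocrit < 0 || hematocrit >= 1)
    stop("'hematocrit' must be a fraction in [0, 1)", call. = FALSE)
  if (blood_volume <= 0) stop("'blood_volume' must be > 0 ml", call. = FALSE)
  structure(list(bfr = bfr, dfr = dfr, ufr = ufr, hematocrit = hematocrit,
                 blood_volume = blood_volume),
            class = "dialysis_settings")
}

#' Drug specification
#'
#' @param name Drug name.
#' @param c0 Target initial plasma concentration, mg/L; `> 0`.
#' @param fraction_bound Plasma protein bound fraction in `[0, 1]`.
#' @return An object of class `drug_spec`.
#' @seealso [default_drugs()] for the four reference antimicrobials.
#' @export
drug_spec <- function(name, c0, fraction_bound = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop("'c0' must be > 0 mg/L", call. = FALSE)
  if (!is.numeric(fraction_bound) || fraction_bound < 0 || fraction_bound > 1)
    stop("'fraction_bound' must be in [0, 1]", call. = FALSE)
  structure(list(name = name, c0 = c0, fraction_bound = fraction_bound),
            class = "drug_spec")
}

#' Reference antimicrobial drug set
#'
#' The four antimicrobials commonly profiled on intermittent hemodialysis
#' benches, at their target starting concentrations: gentamicin 10 mg/L,
#' vancomycin 20 mg/L, teicoplanin 25 mg/L, doripenem 40 mg/L. Bound fractions
#' are bovine-plasma values (gentamicin binding is minimal and set to 0;
#' teicoplanin is > 99 % bound).
#'
#' @return Named list of [drug_spec()] objects.
#' @export
default_drugs <- function() {
  list(
    gentamicin  = drug_spec("gentamicin", c0 = 10, fraction_bound = 0),
    vancomycin  = drug_spec("vancomycin", c0 = 20, fraction_bound = 0.436),
    teicoplanin = drug_spec("teicoplanin", c0 = 25, fraction_bound = 0.99),
    doripenem   = drug_spec("doripenem", c0 = 40, fraction_bound = 0.097)
  )
}

#' Sampling grid
#'
#' Times at which pre-filter, post-filter and dialysate samples are drawn.
#' The default is the standard bench grid: end of minutes 1, 5, 10, 15, 20,
#' 30, 40 and 60.
#'
#' @param timepoints Strictly increasing sample times, min; all `> 0`.
#' @return An object of class `sampling_grid`.
#' @export
sampling_grid <- function(timepoints = c(1, 5, 10, 15, 20, 30, 40, 60)) {
  if (!is.numeric(timepoints) || length(timepoints) < 1L)
    stop("'timepoints' must be a non-empty numeric vector", call. = FALSE)
  if (any(timepoints <= 0)) stop("all timepoints must be > 0 min", call. = FALSE)
  if (any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing", call. = FALSE)
  structure(list(timepoints = as.numeric(timepoints)), class = "sampling_grid")
}

#' Multiplicative measurement-noise model
#'
#' Assay error is modelled as independent multiplicative lognormal deviates
#' with median 1 and the stated coefficient of variation, so concentrations
#' stay positive and errors scale with level.
#'
#' @param cv Coefficient of variation (fraction); `>= 0`.
#' @param seed Integer random seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv, seed = 1L) {
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0)
    stop("'cv' must be >= 0", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(list(cv = cv, seed = seed), class = "noise_model")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cl <- if (x$model == "fixed_clearance")
    sprintf("CL_m = %g ml/min", x$cl_membrane)
  else sprintf("K0A = %g ml/min", x$k0a)
  cat(sprintf("<membrane_spec> %s (%s, %.2g m^2), %s%s\n",
              x$name, x$material, x$area, cl,
              if (is.null(x$adsorption)) "" else ", adsorbing"))
  invisible(x)
}

#' @export
print.dialysis_settings <- function(x, ...) {
  cat(sprintf(
    "<dialysis_settings> BFR %g, DFR %g, UFR %g ml/min; Hc %.2f; V %g ml\n",
    x$bfr, x$dfr, x$ufr, x$hematocrit, x$blood_volume))
  invisible(x)
}
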