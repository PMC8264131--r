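#' Plasma-water flow through the dialyzer
#'
#' Drug transit through the hemofilter is too fast for equilibration out of
#' the erythrocyte compartment, so only the plasma fraction of blood carries
#' drug to the membrane: `Qp = BFR * (1 - Hc)`.
#'
#' @param settings A [dialysis_settings()] object.
#' @return Plasma flow Qp in ml/min.
#' @export
#' @examples
#' plasma_flow(dialysis_settings(bfr = 300, hematocrit = 0.35))  # 195
plasma_flow <- function(settings) {
  stopifnot(inherits(settings, "dialysis_settings"))
  settings$bfr * (1 - settings$hematocrit)
}

#' Diffusive clearance from the mass-transfer-area coefficient
#'
#' Countercurrent dialyzer solution
#' \deqn{CL = Q_p \frac{e^{N(1-R)} - 1}{e^{N(1-R)} - R}, \quad
#'       N = K_0A/Q_p, \; R = Q_p/Q_d,}
#' continuous at \eqn{R = 1} where it reduces to \eqn{Q_p N/(N+1)}. The result
#' never exceeds \eqn{\min(Q_p, Q_d)}, which is the perfect-exchange limit as
#' \eqn{K_0A \to \infty}.
#'
#' @param k0a Mass-transfer-area coefficient, ml/min; `>= 0`.
#' @param qp Plasma-water flow, ml/min; `> 0`.
#' @param qd Dialysate flow, ml/min; `> 0`.
#' @return Diffusive clearance, ml/min.
#' @export
#' @examples
#' clearance_from_k0a(600, qp = 195, qd = 500)
clearance_from_k0a <- function(k0a, qp, qd) {
  if (!is.numeric(k0a) || any(k0a < 0)) stop("'k0a' must be >= 0", call. = FALSE)
  if (!is.numeric(qp) || any(qp <= 0)) stop("'qp' must be > 0", call. = FALSE)
  if (!is.numeric(qd) || any(qd <= 0)) stop("'qd' must be > 0", call. = FALSE)
  n <- k0a / qp
  r <- qp / qd
  x <- n * (1 - r)
  cl <- ifelse(
    abs(x) < 1e-10,
    # R -> 1 limit (and k0a -> 0 where both branches agree)
    qp * n / (n + 1),
    ifelse(x > 700,
           qp,  # exp overflow guard: R < 1 perfect-exchange limit is Qp
           qp * expm1(x) / (exp(x) - r))
  )
  # x -> -Inf (R > 1, large N): ratio -> 1/R, CL -> Qd
  cl <- ifelse(is.finite(cl), cl, ifelse(r > 1, qd, qp))
  pmin(cl, pmin(qp, qd))
}

#' Effective membrane clearance for a run
#'
#' Resolves a [membrane_spec()] to its diffusive clearance at the given
#' operating point: either the fixed `cl_membrane` or the K0A-derived
#' countercurrent value.
#'
#' @inheritParams simulate_run
#' @return Diffusive membrane clearance CL_m, ml/min.
#' @export
membrane_clearance <- function(membrane, settings) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(settings, "dialysis_settings"))
  if (membrane$model == "fixed_clearance") membrane$cl_membrane
  else clearance_from_k0a(membrane$k0a, plasma_flow(settings), settings$dfr)
}

#' Simulate one noiseless closed-loop dialysis run
#'
#' Well-mixed reservoir model on plasma water. The effective distribution
#' volume is `Vp = blood_volume * (1 - Hc)`. Without membrane adsorption the
#' reservoir concentration follows the closed form
#' `C(t) = c0 * exp(-(CL_m + UFR) * t / Vp)`; with an [adsorption_spec()] the
#' system (concentration, cumulative dialysate mass, adsorbed mass) is
#' integrated with fixed-step fourth-order Runge-Kutta at 0.01 min until the
#' membrane site pool saturates. At each sample time:
#' \itemize{
#'   \item `c_pre = C(t)` (reservoir = pre-filter concentration),
#'   \item `c_post = c_pre * (Qp - CL_x - UFR) / (Qp - UFR)` where `CL_x` is
#'     the blood-side extraction clearance (diffusive CL_m plus, while the
#'     adsorption pool is unsaturated, the adsorptive clearance `rate * Vp`),
#'   \item `c_dial = (CL_m + UFR) * c_pre / (DFR + UFR)` (dialysate effluent;
#'     adsorbed drug stays on the membrane and never reaches the dialysate).
#' }
#' Mass is conserved exactly: reservoir + cumulative dialysate + adsorbed
#' equals the initial mass (to integrator accuracy in the adsorption case).
#' The mass accounting at the last sample time is attached as `$mass`.
#'
#' @param membrane A [membrane_spec()].
#' @param settings A [dialysis_settings()].
#' @param drug A [drug_spec()].
#' @param grid A [sampling_grid()].
#' @param run_id Text identifier for the run.
#' @return An object of class `dialysis_run`: list with `run_id`, `membrane`,
#'   `settings`, `drug`, `times`, `c_pre`, `c_post`, `c_dial` (all mg/L) and
#'   `mass` (list `initial`, `reservoir`, `dialysate`, `adsorbed`, mg, at the
#'   last sample time).
#' @export
#' @examples
#' run <- simulate_run(
#'   membrane_spec("F80s", "polysulfone", 1.8, "fixed_clearance",
#'                 cl_membrane = 117),
#'   dialysis_settings(bfr = 300, hematocrit = 0.35),
#'   drug_spec("gentamicin", 10),
#'   sampling_grid())
#' run$c_pre[3]  # 10 * exp(-117 * 10 / 1300) = 4.066 mg/L at 10 min
simulate_run <- function(membrane, settings, drug, grid = sampling_grid(),
                         run_id = paste0(membrane$name, "_", drug$name)) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(settings, "dialysis_settings"),
            inherits(drug, "drug_spec"),
            inherits(grid, "sampling_grid"))
  qp <- plasma_flow(settings)
  cl_m <- membrane_clearance(membrane, settings)
  ufr <- settings$ufr
  vp <- settings$blood_volume * (1 - settings$hematocrit)
  if (cl_m > qp)
    stop(sprintf(
      "membrane clearance (%.4g ml/min) exceeds plasma flow (%.4g ml/min): extraction ratio > 1 is impossible",
      cl_m, qp), call. = FALSE)
  ads <- membrane$adsorption
  cl_ads0 <- if (is.null(ads)) 0 else ads$rate * vp
  if (cl_m + cl_ads0 + ufr > qp)
    stop("combined extraction clearance (diffusive + adsorptive + UFR) exceeds plasma flow",
         call. = FALSE)
  times <- grid$timepoints
  m0 <- drug$c0 * vp / 1000  # mg (c0 mg/L, vp ml)

  if (is.null(ads) || ads$capacity == 0 || ads$rate == 0) {
    cl_tot <- cl_m + ufr
    c_pre <- drug$c0 * exp(-cl_tot * times / vp)
    ads_active <- rep(FALSE, length(times))
    m_ads <- 0
    m_dial <- m0 - drug$c0 * exp(-cl_tot * max(times) / vp) * vp / 1000
  } else {
    sol <- .integrate_adsorbing(drug$c0, vp, cl_m, ufr, ads, max(times), times)
    c_pre <- sol$c_pre
    ads_active <- sol$ads_active
    m_ads <- sol$m_ads
    m_dial <- sol$m_dial
  }
  cl_x <- cl_m + ifelse(ads_active, cl_ads0, 0)
  c_post <- c_pre * (qp - cl_x - ufr) / (qp - ufr)
  c_dial <- (cl_m + ufr) * c_pre / (settings$dfr + ufr)
  structure(list(
    run_id = run_id, membrane = membrane, settings = settings, drug = drug,
    times = times, c_pre = c_pre, c_post = c_post, c_dial = c_dial,
    mass = list(initial = m0,
                reservoir = c_pre[length(c_pre)] * vp / 1000,
                dialysate = m_dial, adsorbed = m_ads)
  ), class = "dialysis_run")
}

# RK4 at fixed 0.01-min steps for the adsorbing reservoir.
# State: y = (C [mg/L], m_dial [mg], m_ads [mg]). Uptake flux rate*C*Vp runs
# while m_ads < capacity; pool exhaustion ends uptake.
.integrate_adsorbing <- function(c0, vp, cl_m, ufr, ads, t_end, sample_times) {
  dt <- 0.01
  deriv <- function(y) {
    c <- y[1]
    u <- if (y[3] < ads$capacity) ads$rate * c * vp / 1000 else 0  # mg/min
    d_dial <- (cl_m + ufr) * c / 1000                              # mg/min
    c(-(d_dial + u) * 1000 / vp, d_dial, u)
  }
  knots <- sort(unique(c(sample_times, t_end)))
  y <- c(c0, 0, 0)
  t <- 0
  out <- matrix(NA_real_, nrow = length(sample_times), ncol = 3)
  active <- logical(length(sample_times))
  for (k in knots) {
    nstep <- max(1L, ceiling((k - t) / dt))
    h <- (k - t) / nstep
    for (i in seq_len(nstep)) {
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (y[3] > ads$capacity) y[3] <- ads$capacity
    }
    t <- k
    idx <- which(sample_times == k)
    if (length(idx)) {
      out[idx, ] <- rep(y, each = length(idx))
      active[idx] <- y[3] < ads$capacity
    }
  }
  list(c_pre = out[, 1], m_dial = out[nrow(out), 2], m_ads = out[nrow(out), 3],
       ads_active = active)
}

#' Apply multiplicative lognormal measurement noise to a run
#'
#' Each concentration is multiplied by an independent lognormal deviate with
#' median 1 and coefficient of variation `noise$cv` (i.e. `meanlog = 0`,
#' `sdlog = sqrt(log(1 + cv^2))`). The same `(run, seed)` pair always yields
#' identical output; `cv = 0` returns the input unchanged.
#'
#' @param run A `dialysis_run`.
#' @param noise A [noise_model()].
#' @return A `dialysis_run` with perturbed concentrations.
#' @export
add_noise <- function(run, noise) {
  stopifnot(inherits(run, "dialysis_run"), inherits(noise, "noise_model"))
  if (noise$cv == 0) return(run)
  sdlog <- sqrt(log1p(noise$cv^2))
  n <- length(run$times)
  dev <- local_seed(noise$seed, stats::rlnorm(3L * n, meanlog = 0, sdlog = sdlog))
  run$c_pre <- run$c_pre * dev[seq_len(n)]
  run$c_post <- run$c_post * dev[n + seq_len(n)]
  run$c_dial <- run$c_dial * dev[2L * n + seq_len(n)]
  run
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Define one study condition
#'
#' @param membrane A [membrane_spec()].
#' @param settings A [dialysis_settings()].
#' @param drug A [drug_spec()].
#' @param replicates Number of replicate runs; `>= 1`.
#' @return An object of class `study_condition`.
#' @export
study_condition <- function(membrane, settings, drug, replicates = 1L) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(settings, "dialysis_settings"),
            inherits(drug, "drug_spec"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(membrane = membrane, settings = settings, drug = drug,
                 replicates = replicates,
                 label = sprintf("%s_%s_%g_%g", membrane$name, drug$name,
                                 settings$bfr, settings$dfr)),
            class = "study_condition")
}

#' Generate a full synthetic study
#'
#' Simulates `replicates` runs for every condition, with per-run noise streams
#' derived deterministically from the master seed and the run index, so a
#' fixed master seed reproduces the whole study bit for bit.
#'
#' @param conditions List of [study_condition()] objects; condition labels
#'   (membrane, drug, BFR, DFR) must be distinct.
#' @param grid A [sampling_grid()] shared by all runs.
#' @param noise A [noise_model()]; its `seed` is the master seed.
#' @return List of `dialysis_run` objects with distinct `run_id`s.
#' @export
#' @examples
#' m <- membrane_spec("F80s", "polysulfone", 1.8, "fixed_clearance",
#'                    cl_membrane = 117)
#' cond <- study_condition(m, dialysis_settings(), drug_spec("gentamicin", 10),
#'                         replicates = 3)
#' runs <- generate_study(list(cond), noise = noise_model(cv = 0.05, seed = 7))
generate_study <- function(conditions, grid = sampling_grid(),
                           noise = noise_model(cv = 0, seed = 1L)) {
  stopifnot(is.list(conditions), length(conditions) >= 1L)
  if (!all(vapply(conditions, inherits, logical(1), "study_condition")))
    stop("'conditions' must be a list of study_condition objects", call. = FALSE)
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  runs <- list()
  run_index <- 0L
  for (cond in conditions) {
    base <- simulate_run(cond$membrane, cond$settings, cond$drug, grid,
                         run_id = cond$label)
    for (r in seq_len(cond$replicates)) {
      run_index <- run_index + 1L
      run <- base
      run$run_id <- sprintf("%s_r%02d", cond$label, r)
      if (noise$cv > 0) {
        run_seed <- (as.numeric(noise$seed) + 7919 * run_index) %% 2147483647
        run <- add_noise(run, noise_model(noise$cv, seed = as.integer(run_seed)))
      }
      runs[[run_index]] <- run
    }
  }
  runs
}

#' @export
print.dialysis_run <- function(x, ...) {
  cat(sprintf("<dialysis_run> %s: %s on %s, %d timepoints (%g-%g min)\n",
              x$run_id, x$drug$name, x$membrane$name, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}
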