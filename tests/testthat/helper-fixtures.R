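# Shared fixtures and independent oracles.

std_settings <- function(...) dialysis_settings(bfr = 300, dfr = 500,
                                                hematocrit = 0.35, ...)

fixed_membrane <- function(cl = 117, name = "F80s", ads = NULL)
  membrane_spec(name, "polysulfone", 1.8, "fixed_clearance",
                cl_membrane = cl, adsorption = ads)

# The six published in vitro / in vivo clearance pairs used for the
# correlation fixture (ml/min).
table2_pairs <- function() {
  clearance_pairs(
    label = c("CAHP-210 gentamicin", "F80s gentamicin", "F60s vancomycin",
              "F80s vancomycin", "F60s teicoplanin", "SF21UX doripenem"),
    cl_in_vitro = c(108.34, 137.62, 71.20, 93.61, 38.95, 155.76),
    cl_in_vivo = c(104.03, 116, 73.0, 85.2, 39.70, 148.61))
}

# Independent straight-line oracle: explicit sum-of-products / normal
# equations, no lm(), no cor().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, r = r, rss = rss)
}

# Discretized countercurrent dialyzer: march the blood/dialysate profiles
# along the fiber in n segments with a shooting method on the dialysate
# outlet concentration. Independent of the closed-form solution.
segmented_dialyzer_cl <- function(k0a, qp, qd, n = 10000L) {
  h <- 1 / n
  march <- function(cd0) {
    cb <- 1; cd <- cd0
    for (i in seq_len(n)) {
      j <- k0a * (cb - cd) * h
      cb <- cb - j / qp
      cd <- cd - j / qd
    }
    c(cb_out = cb, cd_end = cd)
  }
  cd0 <- stats::uniroot(function(cd0) march(cd0)[2], c(0, 1), tol = 1e-13)$root
  qp * (1 - march(cd0)[1])
}
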