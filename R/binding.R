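#' Fraction of drug unbound in plasma
#'
#' Ultrafiltration separates plasma water (carrying only free drug) from the
#' protein-bound pool, so `fu = C_ultrafiltrate / C_total`. Values above 1 are
#' physically impossible and indicate an assay anomaly; they are returned
#' as-is with a warning, never clamped.
#'
#' @param c_total Total (bound + unbound) plasma concentration, mg/L; `> 0`.
#' @param c_ultrafiltrate Plasma-water (ultrafiltrate) concentration, mg/L.
#' @param recovery Optional device recovery factor in `(0, 1]` dividing the
#'   ultrafiltrate concentration, for correcting nonspecific binding to the
#'   ultrafiltration device. Default 1 (no correction).
#' @return Fraction unbound (vectorized).
#' @export
#' @examples
#' fraction_unbound(50, 28.2)  # 0.564, i.e. 43.6 % bound
fraction_unbound <- function(c_total, c_ultrafiltrate, recovery = 1) {
  if (any(c_total <= 0)) stop("'c_total' must be > 0", call. = FALSE)
  if (recovery <= 0 || recovery > 1)
    stop("'recovery' must be in (0, 1]", call. = FALSE)
  fu <- (c_ultrafiltrate / recovery) / c_total
  if (any(fu > 1, na.rm = TRUE))
    warning("fraction unbound > 1 for ", sum(fu > 1, na.rm = TRUE),
            " sample(s): assay anomaly, value returned unclamped",
            call. = FALSE)
  fu
}

#' Percent of drug bound to plasma protein
#'
#' @param fu Fraction unbound (e.g. from [fraction_unbound()]).
#' @return `100 * (1 - fu)`, percent bound.
#' @export
#' @examples
#' percent_bound(0.585)  # 41.5 %
percent_bound <- function(fu) 100 * (1 - fu)

#' Summarize protein-binding replicates per drug and species
#'
#' Averages fraction unbound across replicates within each drug x species
#' group. When a limit of quantification (`loq`, mg/L) is supplied and all
#' ultrafiltrate samples of a group fall below it — as happens for very
#' highly bound drugs like teicoplanin — the group gets a one-sided bound:
#' `percent_bound` is the value implied by `c_ultrafiltrate = loq` and
#' `censored` is `TRUE`, read as "at least this much bound".
#'
#' @param samples A data.frame with columns `drug`, `species`,
#'   `c_total_mg_l`, `c_uf_mg_l` (one row per replicate).
#' @param loq Optional ultrafiltrate limit of quantification, mg/L.
#' @param recovery Passed to [fraction_unbound()].
#' @return A data.frame with columns `drug`, `species`, `fraction_unbound`,
#'   `percent_bound`, `n`, `censored`.
#' @export
analyze_binding <- function(samples, loq = NULL, recovery = 1) {
  need <- c("drug", "species", "c_total_mg_l", "c_uf_mg_l")
  if (!all(need %in% names(samples)))
    stop("'samples' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- interaction(samples$drug, samples$species, drop = TRUE)
  out <- lapply(split(samples, key), function(g) {
    censored <- FALSE
    uf <- g$c_uf_mg_l
    if (!is.null(loq) && all(uf < loq)) {
      uf <- rep(loq, nrow(g))
      censored <- TRUE
    }
    fu <- mean(fraction_unbound(g$c_total_mg_l, uf, recovery = recovery))
    data.frame(drug = g$drug[1], species = g$species[1],
               fraction_unbound = fu, percent_bound = percent_bound(fu),
               n = nrow(g), censored = censored, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare protein binding between species
#'
#' Absolute difference in percent bound between two species per drug; used
#' to judge whether an animal plasma is an adequate surrogate for human
#' plasma in binding terms.
#'
#' @param results A data.frame with columns `drug`, `species`,
#'   `percent_bound` (e.g. from [analyze_binding()], or assembled from
#'   literature values).
#' @param species Character vector of the two species to compare
#'   (default `c("human", "bovine")`).
#' @return A data.frame with columns `drug`, the two per-species percent
#'   bound columns, and `abs_difference_pct` (percentage points).
#' @export
#' @examples
#' tab <- data.frame(drug = rep(c("vancomycin", "doripenem"), each = 2),
#'                   species = rep(c("human", "bovine"), 2),
#'                   percent_bound = c(41.5, 43.6, 8.0, 9.7))
#' species_comparison(tab)
species_comparison <- function(results, species = c("human", "bovine")) {
  stopifnot(all(c("drug", "species", "percent_bound") %in% names(results)),
            length(species) == 2L)
  out <- lapply(split(results, results$drug), function(g) {
    a <- g$percent_bound[g$species == species[1]]
    b <- g$percent_bound[g$species == species[2]]
    if (length(a) != 1L || length(b) != 1L)
      stop("drug '", g$drug[1], "': need exactly one row per species (",
           paste(species, collapse = ", "), ")", call. = FALSE)
    d <- data.frame(drug = g$drug[1], a, b, abs(b - a),
                    stringsAsFactors = FALSE)
    names(d) <- c("drug", paste0("percent_bound_", species),
                  "abs_difference_pct")
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
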