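# File formats and configuration. Units are fixed package-wide (ml/min, mg/L,
# min, m^2) and encoded in the column names; no unit inference anywhere.

RUNS_CSV_COLS <- c("run_id", "membrane", "area_m2", "material", "bfr_ml_min",
                   "dfr_ml_min", "ufr_ml_min", "hematocrit", "drug",
                   "time_min", "c_pre_mg_l", "c_post_mg_l", "c_dial_mg_l")

CLEARANCE_CSV_COLS <- c("membrane", "drug", "bfr_ml_min", "dfr_ml_min",
                        "cl_ml_min", "cl_uncorrected_ml_min", "sd_ml_min", "n")

#' Flatten simulated runs into the runs table
#'
#' One row per run x timepoint, in the canonical runs-CSV column order.
#'
#' @param runs List of `dialysis_run` objects.
#' @return A data.frame with the runs-CSV columns.
#' @export
runs_to_table <- function(runs) {
  stopifnot(is.list(runs))
  if (length(runs) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(RUNS_CSV_COLS), numeric(0), simplify = FALSE),
      RUNS_CSV_COLS))
    return(df)
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(run_id = r$run_id, membrane = r$membrane$name,
               area_m2 = r$membrane$area, material = r$membrane$material,
               bfr_ml_min = r$settings$bfr, dfr_ml_min = r$settings$dfr,
               ufr_ml_min = r$settings$ufr, hematocrit = r$settings$hematocrit,
               drug = r$drug$name, time_min = r$times,
               c_pre_mg_l = r$c_pre, c_post_mg_l = r$c_post,
               c_dial_mg_l = r$c_dial, stringsAsFactors = FALSE)
  }))
}

#' Rebuild run objects from a runs table
#'
#' Inverse of [runs_to_table()] as far as estimation needs: membrane model
#' parameters and reservoir volume are not stored in the table, so the
#' reconstructed runs carry placeholder values for them (they play no role in
#' clearance estimation, which uses only flows, hematocrit and
#' concentrations).
#'
#' @param df A data.frame with the runs-CSV columns.
#' @return List of `dialysis_run` objects, one per distinct `run_id`.
#' @export
runs_from_table <- function(df) {
  miss <- setdiff(RUNS_CSV_COLS, names(df))
  if (length(miss))
    stop("runs table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$run_id), function(g) {
    g <- g[order(g$time_min), ]
    structure(list(
      run_id = g$run_id[1],
      membrane = membrane_spec(g$membrane[1], g$material[1], g$area_m2[1],
                               "fixed_clearance", cl_membrane = 0),
      settings = dialysis_settings(bfr = g$bfr_ml_min[1], dfr = g$dfr_ml_min[1],
                                   ufr = g$ufr_ml_min[1],
                                   hematocrit = g$hematocrit[1]),
      drug = drug_spec(g$drug[1], c0 = max(g$c_pre_mg_l, 1e-9)),
      times = g$time_min, c_pre = g$c_pre_mg_l, c_post = g$c_post_mg_l,
      c_dial = g$c_dial_mg_l, mass = NULL
    ), class = "dialysis_run")
  })
}

# Deterministic numeric formatting at 12 significant digits so write/read
# round-trips to full working precision and rewrites are byte-stable.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.12g", x)))
}

#' Write the runs CSV
#'
#' @param runs List of `dialysis_run` objects or a runs table data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_runs_csv <- function(runs, path) {
  df <- if (is.data.frame(runs)) runs else runs_to_table(runs)
  df <- df[, RUNS_CSV_COLS, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a runs CSV
#'
#' Column-name addressed: column order is free, but all documented columns
#' must be present under their exact names.
#'
#' @param path File written by [write_runs_csv()] (or compatible).
#' @return A data.frame in canonical column order.
#' @export
read_runs_csv <- function(path) {
  if (!file.exists(path)) stop("runs CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(RUNS_CSV_COLS, names(df))
  if (length(miss))
    stop("malformed runs CSV header; expected columns: ",
         paste(RUNS_CSV_COLS, collapse = ","), " (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  df[, RUNS_CSV_COLS, drop = FALSE]
}

#' Write the per-condition clearance CSV
#'
#' @param summary_df Output of [estimate_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clearance_csv <- function(summary_df, path) {
  miss <- setdiff(CLEARANCE_CSV_COLS, names(summary_df))
  if (length(miss))
    stop("clearance table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- summary_df[, CLEARANCE_CSV_COLS, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clearance CSV
#' @param path File written by [write_clearance_csv()] (or compatible).
#' @return A data.frame with the clearance-CSV columns.
#' @export
read_clearance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CLEARANCE_CSV_COLS, names(df))
  if (length(miss))
    stop("malformed clearance CSV; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df[, CLEARANCE_CSV_COLS, drop = FALSE]
}

#' Read an in vivo reference clearance CSV
#'
#' Expected columns: `membrane,drug,cl_invivo_ml_min,sd_ml_min,source`.
#' A reference table of published clearances ships with the package at
#' `system.file("extdata", "invivo_reference.csv", package = "dialysim")`.
#'
#' @param path Reference CSV path.
#' @return A data.frame.
#' @export
read_invivo_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("membrane", "drug", "cl_invivo_ml_min", "sd_ml_min", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed reference CSV; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Pair in vitro condition summaries with in vivo reference clearances
#'
#' Joins on membrane and drug.
#'
#' @param invitro A clearance table ([estimate_study()] /
#'   [read_clearance_csv()] shape).
#' @param invivo A reference table ([read_invivo_reference()] shape).
#' @return A [clearance_pairs()] data.frame.
#' @export
pair_clearances <- function(invitro, invivo) {
  m <- merge(invitro, invivo, by = c("membrane", "drug"),
             suffixes = c("_vitro", "_vivo"))
  if (nrow(m) == 0L) stop("no matching membrane/drug pairs", call. = FALSE)
  clearance_pairs(label = paste(m$membrane, m$drug),
                  cl_in_vitro = m$cl_ml_min,
                  cl_in_vivo = m$cl_invivo_ml_min,
                  sd_in_vitro = if ("sd_ml_min_vitro" %in% names(m))
                    m$sd_ml_min_vitro else m$sd_ml_min,
                  sd_in_vivo = if ("sd_ml_min_vivo" %in% names(m))
                    m$sd_ml_min_vivo else NA_real_)
}

#' Write an IVIVC correlation result as JSON
#'
#' Keys: `n_points, df, slope, intercept, pearson_r, r_squared,
#' adj_r_squared, rss, orientation`.
#'
#' @param corr An `ivivc_correlation` from [correlate_clearances()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ivivc_json <- function(corr, path) {
  stopifnot(inherits(corr, "ivivc_correlation"))
  jsonlite::write_json(corr[c("n_points", "df", "slope", "intercept",
                              "pearson_r", "r_squared", "adj_r_squared",
                              "rss", "orientation")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study configuration file
#'
#' A flat YAML mapping defining the study grid. Top-level keys: `seed`,
#' `noise` (`cv`), `grid` (sample times, min; defaults to the standard
#' 1/5/10/15/20/30/40/60 grid), `membranes`, `drugs`, `settings` (each a
#' list of mappings; settings entries may carry a `name`, defaulting to
#' `s1`, `s2`, ...), and `conditions` referencing membranes/drugs/settings
#' by name with a per-condition `replicates` count. Unknown keys anywhere
#' are rejected, and every nested invariant is enforced at load with the
#' offending field named.
#'
#' @param path Config file path.
#' @return A list of class `study_config` with elements `membranes`, `drugs`,
#'   `settings`, `grid`, `noise`, `conditions` (list of [study_condition()]),
#'   `seed`, and `path`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "noise", "grid", "membranes", "drugs", "settings",
             "conditions")
  .reject_unknown(cfg, known, "config")
  for (req in c("membranes", "drugs", "settings", "conditions"))
    if (is.null(cfg[[req]]))
      stop("config missing required section '", req, "'", call. = FALSE)

  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  noise <- if (is.null(cfg$noise)) noise_model(cv = 0, seed = seed) else {
    .reject_unknown(cfg$noise, c("cv"), "noise")
    noise_model(cv = cfg$noise$cv, seed = seed)
  }
  grid <- if (is.null(cfg$grid)) sampling_grid() else
    .with_path("grid", sampling_grid(as.numeric(unlist(cfg$grid))))

  membranes <- .load_named(cfg$membranes, "membranes", function(m, where) {
    .reject_unknown(m, c("name", "material", "area", "model", "cl_membrane",
                         "k0a", "adsorption"), where)
    ads <- if (!is.null(m$adsorption)) {
      .reject_unknown(m$adsorption, c("capacity", "rate"),
                      paste0(where, ".adsorption"))
      adsorption_spec(m$adsorption$capacity, m$adsorption$rate)
    }
    membrane_spec(m$name, m$material, m$area,
                  model = if (is.null(m$model)) "fixed_clearance" else m$model,
                  cl_membrane = m$cl_membrane, k0a = m$k0a, adsorption = ads)
  })
  drugs <- .load_named(cfg$drugs, "drugs", function(d, where) {
    .reject_unknown(d, c("name", "c0", "fraction_bound"), where)
    drug_spec(d$name, d$c0,
              fraction_bound = if (is.null(d$fraction_bound)) 0
              else d$fraction_bound)
  })
  settings <- list()
  for (i in seq_along(cfg$settings)) {
    s <- cfg$settings[[i]]
    where <- sprintf("settings[%d]", i)
    .reject_unknown(s, c("name", "bfr", "dfr", "ufr", "hematocrit",
                         "blood_volume"), where)
    nm <- if (is.null(s$name)) paste0("s", i) else s$name
    if (nm %in% names(settings))
      stop("duplicate settings name '", nm, "'", call. = FALSE)
    args <- s[setdiff(names(s), "name")]
    settings[[nm]] <- .with_path(where, do.call(dialysis_settings, args))
  }

  conditions <- lapply(seq_along(cfg$conditions), function(i) {
    co <- cfg$conditions[[i]]
    where <- sprintf("conditions[%d]", i)
    .reject_unknown(co, c("membrane", "drug", "settings", "replicates"), where)
    lookup <- function(pool, key, what) {
      if (is.null(co[[key]]) || !co[[key]] %in% names(pool))
        stop(where, ": unknown ", what, " '", co[[key]], "'", call. = FALSE)
      pool[[co[[key]]]]
    }
    study_condition(lookup(membranes, "membrane", "membrane"),
                    lookup(settings, "settings", "settings"),
                    lookup(drugs, "drug", "drug"),
                    replicates = if (is.null(co$replicates)) 1L
                    else co$replicates)
  })
  if (length(conditions) == 0L) stop("empty condition grid", call. = FALSE)
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate conditions: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  structure(list(membranes = membranes, drugs = drugs, settings = settings,
                 grid = grid, noise = noise, conditions = conditions,
                 seed = seed, path = normalizePath(path)),
            class = "study_config")
}

.reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(where, ": unknown key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
}

.load_named <- function(entries, section, loader) {
  out <- list()
  for (i in seq_along(entries)) {
    where <- sprintf("%s[%d]", section, i)
    obj <- .with_path(where, loader(entries[[i]], where))
    if (obj$name %in% names(out))
      stop("duplicate ", section, " name '", obj$name, "'", call. = FALSE)
    out[[obj$name]] <- obj
  }
  out
}

.with_path <- function(where, expr) {
  tryCatch(expr, error = function(e)
    stop(where, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline for a configured study
#'
#' Simulates every configured condition, estimates per-condition clearance,
#' and returns both with a provenance block (config file hash, master seed,
#' package version).
#'
#' @param config A `study_config` from [read_config()].
#' @return List with `runs`, `clearance` (data.frame), `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  runs <- generate_study(config$conditions, config$grid, config$noise)
  list(runs = runs,
       clearance = estimate_study(runs),
       provenance = provenance_block(config))
}

provenance_block <- function(config = NULL) {
  list(config_hash = if (!is.null(config))
    unname(tools::md5sum(config$path)) else NA_character_,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    package_version = as.character(utils::packageVersion("dialysim")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Assemble and write the study report bundle
#'
#' Aggregates the artifacts found in a study directory — `clearance.csv`
#' (required), `ivivc.json` and `binding_out.csv` (optional), `config.yaml`
#' (optional; hashed into provenance) — into one JSON report with a
#' provenance block.
#'
#' @param study_dir Directory holding the pipeline outputs.
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_report <- function(study_dir, path) {
  clr <- file.path(study_dir, "clearance.csv")
  if (!file.exists(clr))
    stop("study dir must contain clearance.csv", call. = FALSE)
  report <- list(condition_summaries = read_clearance_csv(clr))
  iv <- file.path(study_dir, "ivivc.json")
  if (file.exists(iv)) report$ivivc <- jsonlite::read_json(iv, simplifyVector = TRUE)
  bd <- file.path(study_dir, "binding_out.csv")
  if (file.exists(bd)) report$binding <- utils::read.csv(bd, stringsAsFactors = FALSE)
  cfgp <- file.path(study_dir, "config.yaml")
  prov <- provenance_block(NULL)
  if (file.exists(cfgp)) {
    prov$config_hash <- unname(tools::md5sum(cfgp))
    cfg <- tryCatch(read_config(cfgp), error = function(e) NULL)
    if (!is.null(cfg)) prov$seed <- cfg$seed
  }
  report$provenance <- prov
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
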