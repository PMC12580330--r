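# CSV profile tables, inversion-recovery tables, YAML run configuration and
# JSON reports.

.profile_cols <- c("sample_id", "b1_hz", "offset_ppm", "z")

#' Read MT profiles from a CSV profile table
#'
#' Expects columns `sample_id`, `b1_hz`, `offset_ppm` (or `offset_hz` with
#' `offset_unit = "hz"`), `z`, optionally `temperature_C`. Offsets in Hz
#' are measured from the water resonance and are converted to the ppm axis
#' internally (the canonical unit). Duplicate (sample, B1, offset) rows are
#' rejected with the offending line numbers.
#'
#' @param path CSV file path.
#' @param offset_unit `"ppm"` (default) or `"hz"`.
#' @param field A [field_settings()] object, used for Hz -> ppm conversion.
#' @return A named list of [mt_profile()] objects, one per `sample_id`.
#' @export
read_profiles <- function(path, offset_unit = c("ppm", "hz"),
                          field = field_settings()) {
  offset_unit <- match.arg(offset_unit)
  if (!file.exists(path)) {
    cmt_stop("missing_input", sprintf("profile table not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  off_col <- if (offset_unit == "hz" && "offset_hz" %in% names(df))
    "offset_hz" else "offset_ppm"
  need <- c("sample_id", "b1_hz", off_col, "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cmt_stop("parse_error", sprintf("missing column(s): %s",
                                    paste(miss, collapse = ", ")))
  }
  for (cc in c("b1_hz", off_col, "z")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad)) {
      cmt_stop("parse_error",
               sprintf("non-numeric '%s' at line(s) %s", cc,
                       paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if (offset_unit == "hz") {
    df$offset_ppm <- field$water_reference_ppm +
      df[[off_col]] / field$larmor_frequency_MHz
  }
  dup <- duplicated(df[, c("sample_id", "b1_hz", "offset_ppm")])
  if (any(dup)) {
    cmt_stop("parse_error",
             sprintf("duplicate (sample_id, b1_hz, offset) at line(s) %s",
                     paste(utils::head(which(dup) + 1L, 5), collapse = ", ")))
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    g <- saturation_grid(unique(d$b1_hz),
                         lapply(unique(d$b1_hz),
                                function(b) d$offset_ppm[d$b1_hz == b]))
    # reorder z to the canonical grid order
    key <- paste(g$points$b1_hz, format(g$points$offset_ppm, digits = 15))
    dkey <- paste(d$b1_hz, format(d$offset_ppm, digits = 15))
    tc <- if ("temperature_C" %in% names(d)) d$temperature_C[1] else NA_real_
    mt_profile(g, d$z[match(key, dkey)], sample_label = d$sample_id[1],
               temperature_C = tc)
  })
  out
}

#' Write MT profiles to a CSV profile table
#'
#' @param profiles An [mt_profile()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly. Values round-trip through [read_profiles()]
#'   at 15 significant digits.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "mt_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_label,
               b1_hz = p$grid$points$b1_hz,
               offset_ppm = p$grid$points$offset_ppm,
               z = p$z_values,
               temperature_C = p$temperature_C)
  }))
  for (cc in c("b1_hz", "offset_ppm", "z")) {
    df[[cc]] <- formatC(df[[cc]], digits = 15, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an inversion-recovery table
#'
#' CSV with columns `delay_s`, `intensity`, optional `sample_id`.
#'
#' @param path CSV path.
#' @return An [ir_curve()] (the first sample if several are present).
#' @export
read_ir <- function(path) {
  if (!file.exists(path)) {
    cmt_stop("missing_input", sprintf("inversion-recovery table not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("delay_s", "intensity")
  if (!all(need %in% names(df))) {
    cmt_stop("parse_error", "need columns delay_s, intensity")
  }
  lbl <- if ("sample_id" %in% names(df)) df$sample_id[1] else ""
  o <- order(df$delay_s)
  ir_curve(df$delay_s[o], df$intensity[o], label = lbl)
}

# ---- run configuration -----------------------------------------------------

.runconfig_keys <- c("field", "water", "pools", "fit", "preset", "seed",
                     "noise_sigma", "offset_unit")

#' Read and validate a YAML run configuration
#'
#' Recognized top-level keys: `field` (`larmor_frequency_MHz`,
#' `water_reference_ppm`), `water` (`R1_per_s`, `R2_per_s`), `pools` (list
#' of pool maps: `name`, `lineshape`, `center_ppm`, `k_pool_to_water_per_s`,
#' `k_water_to_pool_per_s`, `T2_us`), `fit` (passed to [fit_config()],
#' `free`, `offset_window_ppm`, `water_exclusion_ppm`), `preset`, `seed`,
#' `noise_sigma`, `offset_unit`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    cmt_stop("missing_input", sprintf("config not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runconfig_keys)
  if (length(unknown)) {
    cmt_stop("parse_error", sprintf("unknown config key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

# Build package objects from a run_config (with defaults filled in).
.config_field <- function(cfg) {
  f <- cfg$field
  field_settings(
    larmor_frequency_MHz = f$larmor_frequency_MHz %||% 700,
    water_reference_ppm = f$water_reference_ppm %||% 4.7
  )
}

.config_system <- function(cfg) {
  field <- .config_field(cfg)
  w <- cfg$water
  if (is.null(w$R1_per_s)) cmt_stop("parse_error", "config water.R1_per_s is required")
  water <- water_pool(w$R1_per_s, w$R2_per_s %||% (1.5 * w$R1_per_s))
  pools <- lapply(cfg$pools %||% list(), function(p) {
    semisolid_pool(
      name = p$name %||% "pool",
      k_pool_to_water_per_s = p$k_pool_to_water_per_s %||% 100,
      k_water_to_pool_per_s = p$k_water_to_pool_per_s %||% 0.1,
      T2_pool_s = (p$T2_us %||% 10) * 1e-6,
      center_ppm = p$center_ppm %||% NA_real_,
      lineshape = p$lineshape %||% "super_lorentzian"
    )
  })
  spin_system(field, water, pools)
}

.config_fitcfg <- function(cfg) {
  f <- cfg$fit %||% list()
  fit_config(
    free = f$free %||% .free_param_names,
    fixed = f$fixed %||% list(),
    offset_window_ppm = unlist(f$offset_window_ppm %||% c(-150, 4.7)),
    water_exclusion_ppm = f$water_exclusion_ppm %||% 0.3
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- JSON reports ----------------------------------------------------------

.fit_report <- function(fit) {
  list(
    estimates = as.list(fit$estimates),
    uncertainties = as.list(fit$uncertainties),
    covariance = unclass(fit$covariance),
    fit_deviation = list(sse = fit$sse, rms_per_point = fit$rms),
    n_points = fit$n_points,
    fixed = fit$fixed,
    derived = fit$derived,
    convergence = fit$convergence,
    diagnostics = fit$diagnostics
  )
}

write_report <- function(report, path) {
  report$software <- list(
    package = "condensemt",
    version = as.character(utils::packageVersion("condensemt"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

.fit_residuals <- function(fit, profiles) {
  sys <- fit$system    # estimates already applied
  pts <- .assemble_fit_data(profiles, sys, fit$config)
  zm <- .z_model(pts, sys$field, sys$water, sys$pools,
                 exclusion_ppm = fit$config$water_exclusion_ppm,
                 sl_normalization = fit$config$sl_normalization)$z
  data.frame(b1_hz = pts$b1_hz, offset_ppm = pts$offset_ppm,
             z = pts$z, z_model = zm, residual = pts$z - zm)
}
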