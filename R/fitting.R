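# Stepwise global multi-parameter estimation from multi-B1 MT profiles.
#
# The optimizer is Nelder-Mead simplex on log-transformed (positive)
# parameters; uncertainties come from the variance-covariance matrix
# sigma^2 (J'J)^-1 with J by central finite differences at the optimum.

.free_param_names <- c("k_pool_to_water", "k_water_to_pool", "T2_pool", "R2_water")

#' Fit configuration
#'
#' @param free Character vector naming the free parameters, a subset of
#'   `k_pool_to_water`, `k_water_to_pool`, `T2_pool`, `R2_water`. Pool
#'   parameters refer to the last (target) pool of the system; earlier
#'   pools are frozen.
#' @param fixed Named list of values held constant. `R1_water` (if given)
#'   overrides the water R1 of the system template (normally it comes from
#'   an inversion-recovery fit); `R1_pool` overrides the target pool's R1
#'   (1/s by convention).
#' @param offset_window_ppm Inclusive fit range on the ppm axis; the default
#'   `c(-150, 4.7)` restricts the fit to offsets upfield of water, avoiding
#'   downfield liquid-state CEST contamination.
#' @param water_exclusion_ppm Half-width (ppm) around the water resonance
#'   and around super-Lorentzian pool centers excluded from the residuals.
#' @param sse_tol Relative convergence tolerance on the sum of squared
#'   errors for the simplex.
#' @param max_eval Maximum simplex function evaluations.
#' @param jacobian_step_rel Relative step of the central finite differences
#'   used for the Jacobian (parameters at zero use an absolute 1e-8 step).
#' @param init Named list of initial values overriding the defaults
#'   (`k_pool_to_water` 100/s, `k_water_to_pool` 0.1/s, `T2_pool` 10 us,
#'   `R2_water` 1.5x R1_water).
#' @param sl_normalization Super-Lorentzian normalization constant, see
#'   [r_rf_superlorentzian()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = .free_param_names,
                       fixed = list(),
                       offset_window_ppm = c(-150, 4.7),
                       water_exclusion_ppm = 0.3,
                       sse_tol = 1e-10,
                       max_eval = 20000,
                       jacobian_step_rel = 1e-5,
                       init = list(),
                       sl_normalization = "printed") {
  free <- match.arg(free, .free_param_names, several.ok = TRUE)
  if (length(intersect(free, names(fixed))) > 0) {
    cmt_stop("invalid_argument", "a parameter cannot be both free and fixed")
  }
  if (offset_window_ppm[1] >= offset_window_ppm[2]) {
    cmt_stop("invalid_argument", "offset window lower bound must be < upper bound")
  }
  structure(
    list(free = free, fixed = fixed,
         offset_window_ppm = offset_window_ppm,
         water_exclusion_ppm = water_exclusion_ppm,
         sse_tol = sse_tol, max_eval = max_eval,
         jacobian_step_rel = jacobian_step_rel,
         init = init, sl_normalization = sl_normalization),
    class = "fit_config"
  )
}

# Pool the (b1, offset, z) points of one or more profiles, applying the fit
# window and exclusion rules.
.assemble_fit_data <- function(profiles, system, config) {
  if (inherits(profiles, "mt_profile")) profiles <- list(profiles)
  pts <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(inherits(p, "mt_profile"))
    cbind(p$grid$points, z = p$z_values)
  }))
  w <- config$offset_window_ppm
  keep <- pts$offset_ppm >= w[1] & pts$offset_ppm <= w[2] & !is.na(pts$z)
  keep <- keep & abs(pts$offset_ppm - system$field$water_reference_ppm) >=
    config$water_exclusion_ppm
  for (p in system$pools) {
    if (p$lineshape == "super_lorentzian") {
      keep <- keep & abs(pts$offset_ppm - p$center_ppm) >=
        config$water_exclusion_ppm
    }
  }
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) cmt_stop("invalid_argument", "no data points left after windowing")
  if (length(unique(pts$b1_hz)) < 2) {
    cmt_warn("single_b1",
             "fewer than 2 distinct B1 amplitudes: semi-solid parameters may be poorly constrained")
  }
  pts
}

# Apply a named natural-scale parameter vector to the system template.
.apply_params <- function(system, par) {
  if ("R2_water" %in% names(par)) {
    system$water$R2_per_s <- unname(par[["R2_water"]])
  }
  if (length(system$pools)) {
    i <- length(system$pools)           # target pool = last
    if ("k_pool_to_water" %in% names(par)) {
      system$pools[[i]]$k_pool_to_water_per_s <- unname(par[["k_pool_to_water"]])
    }
    if ("k_water_to_pool" %in% names(par)) {
      system$pools[[i]]$k_water_to_pool_per_s <- unname(par[["k_water_to_pool"]])
    }
    if ("T2_pool" %in% names(par)) {
      system$pools[[i]]$T2_pool_s <- unname(par[["T2_pool"]])
    }
  }
  system
}

.model_z_at <- function(pts, system, config, par) {
  sys2 <- .apply_params(system, par)
  .z_model(pts, sys2$field, sys2$water, sys2$pools,
           exclusion_ppm = config$water_exclusion_ppm,
           sl_normalization = config$sl_normalization)$z
}

#' Global multi-parameter fit of MT profiles
#'
#' Minimizes the unweighted sum of squared differences between the
#' steady-state Z model and all data points (across every B1 amplitude)
#' inside the fit window, over the configured free parameters. Positive
#' parameters are optimized in log space with a Nelder-Mead simplex. The
#' covariance of the estimates is `sigma^2 (J'J)^-1` with
#' `sigma^2 = SSE/(n - p)` and J the central-finite-difference Jacobian at
#' the optimum; parameter uncertainties are the square roots of its
#' diagonal. A singular `J'J` yields `NA` uncertainties plus a diagnostic
#' listing the unconstrained directions instead of an error.
#'
#' @param profiles An [mt_profile()] or list of them (e.g. one per B1).
#' @param system A [spin_system()] template supplying fixed parameters and
#'   initial structure; the last pool is the fit target.
#' @param config A [fit_config()].
#' @return An object of class `mt_fit` with elements `estimates`,
#'   `uncertainties`, `covariance`, `sse`, `rms` (per-point root mean
#'   square deviation), `n_points`, `fixed` (registry of held parameters),
#'   `derived` (pool population with propagated uncertainty), and
#'   `convergence` diagnostics.
#' @export
fit_system <- function(profiles, system, config = fit_config()) {
  stopifnot(inherits(system, "spin_system"), inherits(config, "fit_config"))
  if (!is.null(config$fixed$R1_water)) {
    system$water$R1_per_s <- config$fixed$R1_water
  }
  if (length(system$pools) && !is.null(config$fixed$R1_pool)) {
    system$pools[[length(system$pools)]]$R1_pool_per_s <- config$fixed$R1_pool
  }
  free <- config$free
  if (length(system$pools) == 0) {
    free <- intersect(free, "R2_water")
  }
  pts <- .assemble_fit_data(profiles, system, config)

  init <- list(
    k_pool_to_water = 100, k_water_to_pool = 0.1, T2_pool = 1e-5,
    R2_water = 1.5 * system$water$R1_per_s
  )
  init[names(config$init)] <- config$init
  p0 <- vapply(free, function(nm) init[[nm]], numeric(1))
  if (any(p0 <= 0)) cmt_stop("invalid_argument", "initial values must be > 0")

  obj <- function(theta) {
    par <- exp(theta); names(par) <- free
    zm <- .model_z_at(pts, system, config, par)
    r <- pts$z - zm
    if (anyNA(r) || any(!is.finite(r))) return(1e10)
    sum(r * r)
  }
  opt <- stats::optim(log(p0), obj, method = "Nelder-Mead",
                      control = list(maxit = config$max_eval,
                                     reltol = config$sse_tol))
  if (opt$convergence != 0) {
    cmt_warn("fit_nonconvergence",
             sprintf("simplex did not converge (code %d) after %d evaluations",
                     opt$convergence, config$max_eval))
  }
  est <- exp(opt$par); names(est) <- free
  n <- nrow(pts); p <- length(free)
  sse <- opt$value
  sigma2 <- sse / max(n - p, 1)

  # Jacobian d model / d parameter (natural scale), central differences
  J <- matrix(NA_real_, n, p, dimnames = list(NULL, free))
  for (j in seq_len(p)) {
    v <- est[j]
    h <- if (v == 0) 1e-8 else config$jacobian_step_rel * abs(v)
    up <- est; up[j] <- v + h
    dn <- est; dn[j] <- v - h
    J[, j] <- (.model_z_at(pts, system, config, up) -
               .model_z_at(pts, system, config, dn)) / (2 * h)
  }
  # solve in relative (per-parameter scaled) space for conditioning, then
  # map the covariance back to natural units
  Js <- sweep(J, 2, est, `*`)
  JtJ <- crossprod(Js)
  cov_rel <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
  diagnostics <- NULL
  if (is.null(cov_rel) || any(!is.finite(cov_rel))) {
    sv <- svd(JtJ)$d
    weak <- free[sv < max(sv) * 1e-12]
    diagnostics <- sprintf(
      "J'J is singular; unconstrained parameter direction(s): %s",
      paste(weak, collapse = ", "))
    covm <- matrix(NA_real_, p, p, dimnames = list(free, free))
  } else {
    covm <- cov_rel * outer(est, est)
    dimnames(covm) <- list(free, free)
  }
  unc <- sqrt(diag(covm)); names(unc) <- free

  # fixed-parameter registry
  tgt <- if (length(system$pools)) system$pools[[length(system$pools)]] else NULL
  fixed <- list(R1_water = system$water$R1_per_s)
  if (!is.null(tgt)) {
    fixed$R1_pool <- tgt$R1_pool_per_s
    fixed$center_ppm <- tgt$center_ppm
    fixed$lineshape <- tgt$lineshape
    for (nm in setdiff(.free_param_names, c(free, "R2_water"))) {
      fixed[[nm]] <- switch(nm,
        k_pool_to_water = tgt$k_pool_to_water_per_s,
        k_water_to_pool = tgt$k_water_to_pool_per_s,
        T2_pool = tgt$T2_pool_s)
    }
  }
  if (length(system$pools) > 1) {
    fixed$frozen_pools <- lapply(
      system$pools[-length(system$pools)],
      function(p) p[c("name", "k_pool_to_water_per_s", "k_water_to_pool_per_s",
                      "T2_pool_s", "R1_pool_per_s", "center_ppm", "lineshape")])
  }
  if (!"R2_water" %in% free) fixed$R2_water <- system$water$R2_per_s

  derived <- NULL
  if (!is.null(tgt)) {
    kf <- if ("k_water_to_pool" %in% free) est[["k_water_to_pool"]] else tgt$k_water_to_pool_per_s
    kb <- if ("k_pool_to_water" %in% free) est[["k_pool_to_water"]] else tgt$k_pool_to_water_per_s
    pop <- if (kf + kb > 0) kf / (kf + kb) else NA_real_
    g <- c(k_water_to_pool = kb / (kf + kb)^2,
           k_pool_to_water = -kf / (kf + kb)^2)
    use <- intersect(names(g), free)
    pop_se <- if (length(use) && all(is.finite(covm[use, use]))) {
      sqrt(drop(t(g[use]) %*% covm[use, use, drop = FALSE] %*% g[use]))
    } else NA_real_
    derived <- list(population = pop, population_se = pop_se,
                    k_ex_per_s = kf + kb)
  }

  structure(
    list(estimates = est, uncertainties = unc, covariance = covm,
         sse = sse, rms = sqrt(sse / n), n_points = n, df = n - p,
         fixed = fixed, derived = derived,
         convergence = list(code = opt$convergence, evaluations = opt$counts[["function"]]),
         diagnostics = diagnostics,
         system = .apply_params(system, est), config = config),
    class = "mt_fit"
  )
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("<mt_fit> n = %d points, SSE = %.4g, per-point RMS = %.4g\n",
              x$n_points, x$sse, x$rms))
  for (nm in names(x$estimates)) {
    v <- x$estimates[[nm]]; s <- x$uncertainties[[nm]]
    if (nm == "T2_pool") {
      cat(sprintf("  %-16s %.4g +/- %.2g us\n", nm, v * 1e6, s * 1e6))
    } else {
      cat(sprintf("  %-16s %.4g +/- %.2g 1/s\n", nm, v, s))
    }
  }
  if (!is.null(x$derived)) {
    cat(sprintf("  pool population  %.4g%% +/- %.2g%% (k_ex = %.4g 1/s)\n",
                100 * x$derived$population, 100 * x$derived$population_se,
                x$derived$k_ex_per_s))
  }
  if (!is.null(x$diagnostics)) cat("  !", x$diagnostics, "\n")
  invisible(x)
}

#' Stepwise reference-then-sample fit
#'
#' Implements the two-step workflow for a condensate embedded in a reference
#' meshwork: first the reference (e.g. agarose) profiles are fitted with a
#' one-pool system; the fitted reference pool is then frozen, a second
#' (condensate) pool is added, and only the second pool's parameters plus
#' the water R2 are fitted against the sample profiles.
#'
#' @param reference_profiles Profiles of the reference material alone.
#' @param sample_profiles Profiles of reference + condensate.
#' @param reference_system One-pool [spin_system()] template for step 1.
#' @param condensate_pool [semisolid_pool()] template added in step 2 (its
#'   rate/T2 values seed nothing; they are replaced by the fit initials).
#' @param config_ref,config_sample [fit_config()] objects for the two steps.
#'   `config_sample$fixed$R1_water` should carry the sample's own
#'   inversion-recovery R1 when it differs from the reference.
#' @return A list of class `mt_stepwise_fit` with elements `reference` and
#'   `sample`, both [fit_system()] results.
#' @export
stepwise_fit <- function(reference_profiles, sample_profiles,
                         reference_system, condensate_pool,
                         config_ref = fit_config(),
                         config_sample = fit_config()) {
  stopifnot(inherits(reference_system, "spin_system"),
            inherits(condensate_pool, "mt_pool"))
  if (length(reference_system$pools) != 1) {
    cmt_stop("invalid_argument", "reference system must have exactly one pool")
  }
  ref_fit <- fit_system(reference_profiles, reference_system, config_ref)
  frozen <- ref_fit$system$pools[[1]]
  sample_water <- water_pool(
    R1_per_s = if (!is.null(config_sample$fixed$R1_water))
      config_sample$fixed$R1_water else reference_system$water$R1_per_s,
    R2_per_s = ref_fit$system$water$R2_per_s
  )
  sample_system <- spin_system(reference_system$field, sample_water,
                               pools = list(frozen, condensate_pool))
  sample_fit <- fit_system(sample_profiles, sample_system, config_sample)
  structure(list(reference = ref_fit, sample = sample_fit),
            class = "mt_stepwise_fit")
}

#' @export
print.mt_stepwise_fit <- function(x, ...) {
  cat("== step 1: reference pool ==\n"); print(x$reference)
  cat("== step 2: sample (reference frozen) ==\n"); print(x$sample)
  invisible(x)
}

#' Lineshape model selection for the target pool
#'
#' Fits the same data twice, once with a Gaussian and once with a
#' super-Lorentzian lineshape on the target pool, and compares the
#' per-point RMS deviations. Differences below 1% relative are reported as
#' indistinguishable.
#'
#' @inheritParams fit_system
#' @return A list of class `mt_lineshape_comparison` with both fits, their
#'   RMS values, the flagged `best` model and a `tie` indicator.
#' @export
select_lineshape <- function(profiles, system, config = fit_config()) {
  if (length(system$pools) == 0) {
    cmt_stop("invalid_argument", "system must contain a target pool")
  }
  fits <- lapply(c(gaussian = "gaussian", super_lorentzian = "super_lorentzian"),
                 function(ls) {
    sys2 <- system
    sys2$pools[[length(sys2$pools)]]$lineshape <- ls
    fit_system(profiles, sys2, config)
  })
  rms <- vapply(fits, `[[`, 0, "rms")
  tie <- abs(diff(rms)) < 0.01 * mean(rms)
  structure(
    list(fits = fits, rms = rms,
         best = if (tie) NA_character_ else names(which.min(rms)),
         tie = tie),
    class = "mt_lineshape_comparison"
  )
}

#' @export
print.mt_lineshape_comparison <- function(x, ...) {
  cat("<mt_lineshape_comparison>\n")
  for (nm in names(x$rms)) cat(sprintf("  %-18s RMS %.5g\n", nm, x$rms[[nm]]))
  cat(if (x$tie) "  models indistinguishable (<1% RMS difference)\n"
      else sprintf("  preferred: %s\n", x$best))
  invisible(x)
}
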