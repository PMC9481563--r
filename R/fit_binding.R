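# Nonlinear Kd fitting for direct (quadratic) and competitive (cubic)
# fluorescence-polarization titrations. Replicates are fitted as pooled
# observations so standard errors reflect replicate scatter.

.new_binding_fit <- function(kd, p_free, p_bound, std_errors, covariance,
                             residual_norm, converged, n_obs, mode,
                             message = NA_character_) {
  structure(
    list(kd = kd, p_free = p_free, p_bound = p_bound,
         std_errors = std_errors, covariance = covariance,
         residual_norm = residual_norm, converged = converged,
         n_obs = n_obs, mode = mode, message = message),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s titration)%s\n", x$mode,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  Kd      = %.4g +/- %.3g nM\n", x$kd, x$std_errors[["kd"]]))
  cat(sprintf("  p_free  = %.4g +/- %.3g mP\n", x$p_free,
              x$std_errors[["p_free"]]))
  cat(sprintf("  p_bound = %.4g +/- %.3g mP\n", x$p_bound,
              x$std_errors[["p_bound"]]))
  cat(sprintf("  n = %d, residual norm = %.4g mP^2\n", x$n_obs,
              x$residual_norm))
  if (!is.na(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

# Pool replicate readings into long (x, y) vectors.
.pool_series <- function(series) {
  k <- ncol(series$readings)
  list(x = rep(series$varied_conc, times = k),
       y = as.numeric(series$readings))
}

# Shared nlsLM wrapper: model_fun(x, kd, p_free, p_bound) -> predicted mP.
# `start` overrides the sigmoid heuristic (used by the competitive fitter,
# whose endpoints are not both observed along the curve).
.fit_three_parameter <- function(series, model_fun, kd_lower = 1e-6,
                                 start = NULL) {
  obs <- .pool_series(series)
  if (stats::sd(obs$y) < .Machine$double.eps^0.5 * max(1, abs(mean(obs$y))))
    return(.new_binding_fit(NA_real_, mean(obs$y), mean(obs$y),
                            c(kd = NA_real_, p_free = NA_real_,
                              p_bound = NA_real_),
                            NULL, 0, FALSE, length(obs$y), series$mode,
                            "constant readings: parameters not identifiable"))
  if (is.null(start)) {
    mean_by_conc <- tapply(obs$y, obs$x, mean)
    concs <- as.numeric(names(mean_by_conc))
    half <- (max(mean_by_conc) + min(mean_by_conc)) / 2
    kd0 <- concs[which.min(abs(mean_by_conc - half))]
    if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(concs[concs > 0])
    # endpoint starts follow the observed direction of the signal
    rising <- unname(mean_by_conc[length(mean_by_conc)] >= mean_by_conc[1])
    p_free0 <- if (rising) min(obs$y) else max(obs$y)
    p_bound0 <- if (rising) max(obs$y) else min(obs$y)
    start <- list(kd = kd0, p_free = p_free0, p_bound = p_bound0)
  }
  # raw Levenberg-Marquardt on the residual vector, with Kd fitted on the
  # log scale: positivity without an active box constraint, comparable
  # parameter scales across Kd magnitudes, and none of the rank-check
  # fragility of nls-model construction on borderline Jacobians
  resid_fun <- function(par)
    obs$y - model_fun(obs$x, exp(par[[1]]), par[[2]], par[[3]])
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = c(log_kd = log(max(start$kd, kd_lower)),
              p_free = start$p_free, p_bound = start$p_bound),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-10)
    ),
    error = function(e) e
  )
  if (inherits(out, "error"))
    return(.new_binding_fit(NA_real_, NA_real_, NA_real_,
                            c(kd = NA_real_, p_free = NA_real_,
                              p_bound = NA_real_),
                            NULL, NA_real_, FALSE, length(obs$y), series$mode,
                            paste("fit failed:", conditionMessage(out))))
  kd_hat <- exp(out$par[["log_kd"]])
  est <- c(kd = kd_hat, p_free = out$par[["p_free"]],
           p_bound = out$par[["p_bound"]])
  n <- length(obs$y)
  dof <- n - 3L
  sigma2 <- out$deviance / dof
  vcv <- tryCatch({
    v <- sigma2 * solve(out$hessian)
    jac <- diag(c(kd_hat, 1, 1))  # delta method: log Kd -> Kd
    v <- jac %*% v %*% jac
    dimnames(v) <- list(c("kd", "p_free", "p_bound"),
                        c("kd", "p_free", "p_bound"))
    v
  }, error = function(e) NULL)
  se <- if (is.null(vcv) || any(diag(vcv) < 0))
    c(kd = NA_real_, p_free = NA_real_, p_bound = NA_real_) else
    sqrt(diag(vcv))
  converged <- out$info %in% 1:3  # ftol/ptol/both criteria met
  identifiable <- is.finite(se[["kd"]]) &&
    abs(est[["p_bound"]] - est[["p_free"]]) >
      .Machine$double.eps^0.25 * max(1, abs(est[["p_free"]]))
  .new_binding_fit(
    kd = unname(est[["kd"]]),
    p_free = unname(est[["p_free"]]),
    p_bound = unname(est[["p_bound"]]),
    std_errors = se,
    covariance = vcv,
    residual_norm = out$deviance,
    converged = converged && identifiable,
    n_obs = n,
    mode = series$mode,
    message = if (!identifiable) "parameters not identifiable"
              else NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a direct titration (quadratic equilibrium model)
#'
#' Least-squares fit of `(kd, p_free, p_bound)` to pooled replicate readings
#' through the ligand-depletion quadratic [fraction_bound_direct()] and the
#' linear [polarization_signal()] model.
#'
#' @param series A `titration_series` with `mode = "direct"` and at least 6
#'   distinct concentrations; `fixed_components$probe_total` gives the
#'   constant labelled-probe concentration (nM).
#' @return A `binding_fit` with estimates, standard errors (from the
#'   covariance at the optimum), residual norm and an honest `converged` flag.
#' @export
fit_direct_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (series$mode != "direct") stop("series mode must be 'direct'")
  if (length(unique(series$varied_conc)) < 6L)
    stop("need at least 6 distinct concentrations")
  l_total <- series$fixed_components$probe_total
  model_fun <- function(x, kd, p_free, p_bound)
    polarization_signal(fraction_bound_direct(x, l_total, kd), p_free, p_bound)
  .fit_three_parameter(series, model_fun)
}

#' Fit a competitive titration (cubic equilibrium model)
#'
#' Least-squares fit of the competitor dissociation constant (plus signal
#' endpoints) through the exact three-component equilibrium
#' [solve_competitive_analytic()]: the labelled probe and receptor are fixed
#' and the unlabelled competitor is varied. The probe Kd must come from a
#' prior direct fit and is supplied in `fixed_components$probe_kd`.
#'
#' @param series A `titration_series` with `mode = "competitive"`;
#'   `fixed_components` must contain `receptor_total`, `probe_total` and
#'   `probe_kd` (all nM).
#' @return A `binding_fit` whose `kd` is the competitor dissociation constant.
#' @export
fit_competitive_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (series$mode != "competitive") stop("series mode must be 'competitive'")
  fc <- series$fixed_components
  if (is.null(fc$probe_kd) || !is.finite(fc$probe_kd) || fc$probe_kd <= 0)
    stop("competitive fit requires a positive probe_kd from a prior direct fit")
  if (all(series$varied_conc == 0))
    stop("competitor concentrations are all zero: Kd not identifiable")
  r_total <- fc$receptor_total
  l_total <- fc$probe_total
  kd_probe <- fc$probe_kd
  model_fun <- function(x, kd, p_free, p_bound) {
    bound <- .bound_probe_competitive(x, r_total, l_total, kd_probe, kd)
    polarization_signal(bound / l_total, p_free, p_bound)
  }
  # model-aware starts: along a displacement curve the signal runs from
  # p_free + f0 * (p_bound - p_free) at zero competitor down towards p_free,
  # so p_bound itself is never observed and must be extrapolated through the
  # zero-competitor bound fraction f0 (known from the fixed components).
  obs <- .pool_series(series)
  mean_by_conc <- tapply(obs$y, obs$x, mean)
  concs <- as.numeric(names(mean_by_conc))
  f0 <- .bound_probe_competitive(0, r_total, l_total, kd_probe,
                                 kd_probe) / l_total
  y0 <- mean_by_conc[[1]]                      # lowest (usually zero) competitor
  y_end <- mean_by_conc[[length(mean_by_conc)]] # full displacement end
  p_free0 <- y_end
  p_bound0 <- if (f0 > 1e-6) p_free0 + (y0 - p_free0) / f0 else max(obs$y)
  half <- (y0 + y_end) / 2
  kd0 <- concs[which.min(abs(mean_by_conc - half))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(concs[concs > 0])
  .fit_three_parameter(series, model_fun,
                       start = list(kd = kd0, p_free = p_free0,
                                    p_bound = p_bound0))
}

#' Kd fold change between two binding fits
#'
#' Ratio of the weaker (larger) to the tighter (smaller) dissociation
#' constant, e.g. Kd(pTyr-only peptide) / Kd(pTyr+pSer peptide). Uncertainty
#' propagation is delegated to [mc_ratio()] / [delta_method_ratio()].
#'
#' @param fit_weak,fit_tight Converged `binding_fit` objects (numerator and
#'   denominator respectively).
#' @param mc If `TRUE`, attach a Monte-Carlo `ratio_summary` (see
#'   [mc_ratio()]).
#' @param n_samples,seed Passed to [mc_ratio()] when `mc = TRUE`.
#' @return A list with `ratio` and, when requested, `mc` (a `ratio_summary`).
#' @export
kd_fold_change <- function(fit_weak, fit_tight, mc = FALSE,
                           n_samples = 5000L, seed = 1L) {
  stopifnot(inherits(fit_weak, "binding_fit"), inherits(fit_tight, "binding_fit"))
  if (!isTRUE(fit_weak$converged) || !isTRUE(fit_tight$converged))
    stop("both fits must have converged")
  if (fit_weak$kd <= 0 || fit_tight$kd <= 0) stop("Kd estimates must be > 0")
  out <- list(ratio = fit_weak$kd / fit_tight$kd)
  if (mc) {
    out$mc <- mc_ratio(
      estimate(fit_weak$kd, fit_weak$std_errors[["kd"]]),
      estimate(fit_tight$kd, fit_tight$std_errors[["kd"]]),
      n_samples = n_samples, seed = seed
    )
  }
  out
}

#' Export a binding fit as a JSON report
#'
#' @param fit A `binding_fit`.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "binding_fit"))
  rep <- list(
    mode = fit$mode,
    parameters = list(kd_nM = fit$kd, p_free_mP = fit$p_free,
                      p_bound_mP = fit$p_bound),
    std_errors = as.list(fit$std_errors),
    covariance = if (is.null(fit$covariance)) NULL else
      unclass(as.data.frame(fit$covariance)),
    residual_norm_mP2 = fit$residual_norm,
    converged = fit$converged,
    n_obs = fit$n_obs,
    note = if (is.na(fit$message)) NULL else fit$message
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
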