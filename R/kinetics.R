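# Michaelis-Menten analysis: initial rates from fluorogenic (DIFMUP-style)
# time courses, nonlinear MM fits, exact integrated progress curves for
# peptide dephosphorylation assays, and the enzyme-equalization multiplier.
#
# Unit conventions (centralised here): enzyme nM, substrate uM, time s.
# A rate kcat[1/s] * E[nM] is kcat * E / 1000 in uM/s.

.enzyme_uM <- function(enzyme_nM) enzyme_nM / 1000

#' Construct a kinetic trace
#'
#' One time-course signal from a kinetic assay: fluorescence units for
#' plate-reader assays, or product as percent of initial substrate for
#' capillary-electrophoresis peak tables.
#'
#' @param time Time, s; strictly increasing, `time[1] >= 0`.
#' @param signal Signal, same length as `time`. If `unit = "percent"`, values
#'   must lie in `[0, 100]`.
#' @param substrate0 Initial substrate, uM (optional metadata).
#' @param enzyme_total Total enzyme, nM (optional metadata).
#' @param unit `"au"` (arbitrary units) or `"percent"` (product %).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, signal, substrate0 = NA_real_,
                          enzyme_total = NA_real_,
                          unit = c("au", "percent")) {
  unit <- match.arg(unit)
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal)) stop("time and signal lengths differ")
  if (length(time) < 2L) stop("need at least two samples")
  if (time[1] < 0 || any(diff(time) <= 0))
    stop("time must be non-negative and strictly increasing")
  if (unit == "percent" && any(signal < -1e-9 | signal > 100 + 1e-9))
    stop("percent signals must lie in [0, 100]")
  structure(list(time = time, signal = signal, substrate0 = substrate0,
                 enzyme_total = enzyme_total, unit = unit),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace: %d points, t = %.4g - %.4g s (%s)\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$unit))
  if (is.finite(x$substrate0)) cat(sprintf("  S0 = %.4g uM\n", x$substrate0))
  if (is.finite(x$enzyme_total)) cat(sprintf("  E = %.4g nM\n", x$enzyme_total))
  invisible(x)
}

#' Read a kinetic trace from CSV
#'
#' Expects columns `time_s` and `signal`; assay metadata is supplied as
#' arguments.
#'
#' @param path CSV path.
#' @inheritParams kinetic_trace
#' @return A `kinetic_trace`.
#' @export
read_trace_csv <- function(path, substrate0 = NA_real_,
                           enzyme_total = NA_real_, unit = "au") {
  tab <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(c("time_s", "signal"), names(tab))
  if (length(missing_cols))
    stop("trace CSV ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("time_s", "signal")) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(num) & nzchar(tab[[col]]))
    if (length(bad))
      stop("trace CSV ", path, ": non-numeric '", tab[[col]][bad[1]],
           "' in column ", col, " at data line ", bad[1])
    tab[[col]] <- num
  }
  kinetic_trace(tab$time_s, tab$signal, substrate0, enzyme_total, unit)
}

#' Initial rate by linear regression over the first points of a trace
#'
#' Ordinary least-squares slope over the first `n_points` samples, the
#' standard estimator for initial velocities of fluorogenic substrate assays
#' (at least 30 initial points by default).
#'
#' @param trace A `kinetic_trace`.
#' @param n_points Number of leading points to regress over (>= 30 by
#'   default; >= 3 always).
#' @return List with `rate` (slope, signal units/s), `std_error`, and
#'   `r_squared` as a linearity diagnostic.
#' @export
initial_rate <- function(trace, n_points = 30L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be at least 3")
  if (length(trace$time) < n_points)
    stop(sprintf("trace has %d points, need %d", length(trace$time), n_points))
  idx <- seq_len(n_points)
  fit <- stats::lm(y ~ x, data = data.frame(x = trace$time[idx],
                                            y = trace$signal[idx]))
  # summary.lm warns on exact data ("essentially perfect fit"); the slope SE
  # is legitimately ~0 there, so the warning is noise for this use
  sm <- suppressWarnings(summary(fit))
  list(rate = unname(stats::coef(fit)[["x"]]),
       std_error = unname(sm$coefficients["x", "Std. Error"]),
       r_squared = sm$r.squared)
}

#' Michaelis-Menten velocity
#'
#' `v = kcat * E * S / (Km + S)` in uM/s, with enzyme in nM and substrate and
#' Km in uM.
#'
#' @param s Substrate, uM (vectorised).
#' @param kcat Turnover number, 1/s.
#' @param km Michaelis constant, uM.
#' @param enzyme_total Enzyme, nM.
#' @return Velocity, uM/s.
#' @export
mm_velocity <- function(s, kcat, km, enzyme_total) {
  kcat * .enzyme_uM(enzyme_total) * s / (km + s)
}

#' Fit Michaelis-Menten parameters to substrate/rate data
#'
#' Nonlinear least-squares fit of `v = kcat * E * S / (Km + S)` with rates in
#' uM/s; standard errors come from the covariance at the optimum. The fit is
#' flagged non-identifiable when the substrate range never approaches Km
#' (linear regime, only kcat/Km determined).
#'
#' @param substrate Substrate concentrations, uM (>= 5 levels).
#' @param rates Initial rates, uM/s, same length.
#' @param enzyme_total Enzyme, nM.
#' @return An `mm_fit` with `kcat` (1/s), `km` (uM), `vmax` (uM/s),
#'   `std_errors`, `converged` and `identifiable` flags.
#' @export
fit_michaelis_menten <- function(substrate, rates, enzyme_total) {
  substrate <- as.numeric(substrate); rates <- as.numeric(rates)
  if (length(substrate) != length(rates)) stop("lengths differ")
  if (length(unique(substrate)) < 5L) stop("need at least 5 substrate levels")
  if (enzyme_total <= 0) stop("enzyme_total must be positive")
  e_uM <- .enzyme_uM(enzyme_total)
  vmax0 <- max(rates)
  km0 <- substrate[which.min(abs(rates - vmax0 / 2))]
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(substrate)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ kcat * e_uM * s / (km + s),
      data = data.frame(s = substrate, v = rates),
      start = list(kcat = vmax0 / e_uM, km = km0),
      lower = c(kcat = 1e-12, km = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(structure(list(kcat = NA_real_, km = NA_real_, vmax = NA_real_,
                          enzyme_total = enzyme_total,
                          std_errors = c(kcat = NA_real_, km = NA_real_),
                          converged = FALSE, identifiable = FALSE,
                          message = conditionMessage(fit)),
                     class = "mm_fit"))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  identifiable <- est[["km"]] <= 3 * max(substrate) &&
    is.finite(se[["km"]]) && se[["km"]] < est[["km"]]
  structure(
    list(kcat = unname(est[["kcat"]]), km = unname(est[["km"]]),
         vmax = unname(est[["kcat"]]) * e_uM, enzyme_total = enzyme_total,
         std_errors = c(kcat = unname(se[["kcat"]]), km = unname(se[["km"]])),
         converged = isTRUE(fit$convInfo$isConv %||% TRUE),
         identifiable = identifiable,
         message = if (identifiable) NA_character_ else
           "substrate range well below Km: only kcat/Km is determined"),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit%s\n",
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  kcat = %.4g +/- %.3g 1/s\n", x$kcat, x$std_errors[["kcat"]]))
  cat(sprintf("  Km   = %.4g +/- %.3g uM\n", x$km, x$std_errors[["km"]]))
  cat(sprintf("  Vmax = %.4g uM/s (E = %.4g nM)\n", x$vmax, x$enzyme_total))
  if (!is.na(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

# W(e^x) on the principal branch for real x, safe against overflow of exp(x).
.lambert_w_exp <- function(x) {
  vapply(x, function(xi) {
    # pracma's iteration is only reliable for moderate arguments; above
    # that, solve w + log(w) = x directly on the log scale
    if (xi < 30) return(pracma::lambertWp(exp(xi)))
    # asymptotic start then Newton on w + log(w) = x (xi >= 30 > e)
    w <- xi - log(xi)
    for (i in 1:100) {
      delta <- (w + log(w) - xi) / (1 + 1 / w)
      w <- w - delta
      if (abs(delta) < 1e-14 * w) break
    }
    w
  }, numeric(1))
}

#' Simulate an enzymatic progress curve (integrated Michaelis-Menten)
#'
#' Substrate depletion under `dS/dt = -kcat * E * S / (Km + S)` from the
#' closed-form integrated solution
#' \deqn{S(t) = K_m W\!\left(\frac{S_0}{K_m}
#'   e^{(S_0 - V_{max} t)/K_m}\right)}
#' with `W` the Lambert function (evaluated through an overflow-safe
#' log-argument form). Product is reported as percent of initial substrate,
#' matching electrophoretic peak-percent readouts.
#'
#' @param kcat Turnover number, 1/s.
#' @param km Michaelis constant, uM.
#' @param enzyme_total Enzyme, nM.
#' @param substrate0 Initial substrate, uM.
#' @param times Sampling times, s.
#' @return A `kinetic_trace` with `unit = "percent"` (product %).
#' @export
simulate_progress_curve <- function(kcat, km, enzyme_total, substrate0,
                                    times) {
  if (kcat <= 0 || km <= 0 || enzyme_total <= 0 || substrate0 <= 0)
    stop("kcat, km, enzyme_total and substrate0 must be positive")
  times <- as.numeric(times)
  vmax <- kcat * .enzyme_uM(enzyme_total)  # uM/s
  logarg <- log(substrate0 / km) + (substrate0 - vmax * times) / km
  s_t <- km * .lambert_w_exp(logarg)
  s_t <- pmin(pmax(s_t, 0), substrate0)
  product_pct <- 100 * (1 - s_t / substrate0)
  kinetic_trace(times, product_pct, substrate0 = substrate0,
                enzyme_total = enzyme_total, unit = "percent")
}

#' Fit an origin-anchored exponential to a progress curve
#'
#' Least squares for `A * (1 - exp(-k_obs * t))`, the standard empirical
#' summary of dephosphorylation progress curves; in the first-order regime
#' (`S0 << Km`) `k_obs` approximates `kcat * E / Km`. An additive offset is
#' available behind `offset = TRUE` for curves that do not start at zero.
#'
#' @param trace A `kinetic_trace` with at least 6 time points.
#' @param offset Include an additive baseline term (default `FALSE`).
#' @return List with `amplitude`, `k_obs` (1/s), `std_errors`, `converged`,
#'   and `identifiable` (`FALSE` for flat traces, where `k_obs` is
#'   meaningless).
#' @export
fit_exponential_progress <- function(trace, offset = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$time) < 6L) stop("need at least 6 time points")
  y <- trace$signal; t <- trace$time
  if (stats::sd(y) < 1e-10 * max(1, abs(mean(y))))
    return(list(amplitude = 0, k_obs = NA_real_,
                std_errors = c(amplitude = NA_real_, k_obs = NA_real_),
                converged = TRUE, identifiable = FALSE))
  a0 <- max(y)
  t_half <- t[which.min(abs(y - a0 / 2))]
  k0 <- if (t_half > 0) log(2) / t_half else 1 / max(t)
  form <- if (offset) y ~ c0 + a * (1 - exp(-k * t)) else
    y ~ a * (1 - exp(-k * t))
  start <- if (offset) list(a = a0, k = k0, c0 = min(y)) else
    list(a = a0, k = k0)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t = t, y = y), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-12)),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(list(amplitude = NA_real_, k_obs = NA_real_,
                std_errors = c(amplitude = NA_real_, k_obs = NA_real_),
                converged = FALSE, identifiable = FALSE))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(amplitude = unname(est[["a"]]), k_obs = unname(est[["k"]]),
       std_errors = c(amplitude = unname(se[["a"]]),
                      k_obs = unname(se[["k"]])),
       converged = isTRUE(fit$convInfo$isConv %||% TRUE),
       identifiable = TRUE)
}

#' Enzyme multiplier that equalises mutant and wild-type progress curves
#'
#' Finds the scalar `m` minimising the L2 distance between the wild-type
#' progress curve and the mutant curve simulated at `m x` the wild-type
#' enzyme concentration. Because rate scales as `kcat * E`, when only kcat
#' differs the minimiser is exactly `kcat_wt / kcat_mut` — the logic behind
#' equalising impaired mutants by dosing them at 4x or 40x enzyme.
#'
#' @param wt,mutant Lists (or `mm_fit`s) with elements `kcat` (1/s) and `km`
#'   (uM).
#' @param enzyme_total Wild-type enzyme concentration, nM.
#' @param substrate0 Initial substrate, uM.
#' @param times Comparison time grid, s.
#' @return The multiplier `m` (dimensionless).
#' @export
match_enzyme_concentration <- function(wt, mutant, enzyme_total, substrate0,
                                       times) {
  for (p in list(wt, mutant))
    if (!is.finite(p$kcat) || p$kcat <= 0 || !is.finite(p$km) || p$km <= 0)
      stop("wt and mutant must carry positive kcat and km")
  ref <- simulate_progress_curve(wt$kcat, wt$km, enzyme_total, substrate0,
                                 times)$signal
  obj <- function(log10_m) {
    m <- 10^log10_m
    cur <- simulate_progress_curve(mutant$kcat, mutant$km,
                                   m * enzyme_total, substrate0, times)$signal
    sum((cur - ref)^2)
  }
  guess <- log10(wt$kcat / mutant$kcat)
  opt <- stats::optimize(obj, interval = guess + c(-2, 2),
                         tol = .Machine$double.eps^0.5)
  if (!is.finite(opt$objective))
    stop("enzyme-matching optimisation failed")
  # polish with a narrow second pass around the optimum
  opt2 <- stats::optimize(obj, interval = opt$minimum + c(-0.05, 0.05),
                          tol = .Machine$double.eps^0.6)
  10^opt2$minimum
}
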