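#' Point estimate with standard error
#'
#' Minimal container for a fitted positive quantity (e.g. a Kd in nM) quoted
#' as value +/- standard error.
#'
#' @param value Positive point estimate.
#' @param std_error Standard error, >= 0 and finite.
#' @return An object of class `estimate`.
#' @export
estimate <- function(value, std_error) {
  if (!is.finite(value) || value <= 0) stop("value must be finite and > 0")
  if (!is.finite(std_error) || std_error < 0)
    stop("std_error must be finite and >= 0")
  structure(list(value = value, std_error = std_error), class = "estimate")
}

#' Monte-Carlo uncertainty of a ratio of two estimates
#'
#' Propagates the standard errors of two independently fitted quantities into
#' their ratio by simulation: draws `n_samples` pairs, forms the ratio for
#' each, and summarises with mean and standard deviation. This is the
#' procedure behind Kd-ratio bar plots with error bars (5000 samples per
#' ratio by default).
#'
#' @param numerator,denominator `estimate` objects (or plain
#'   `list(value, std_error)`).
#' @param n_samples Number of Monte-Carlo draws (default 5000).
#' @param seed Integer seed; the summary is fully reproducible given the seed.
#' @param sampling_model `"normal-truncated"` (default): Gaussian draws with
#'   non-positive values rejected and redrawn; requires CV < 1. `"lognormal"`:
#'   moment-matched lognormal (same mean and sd), valid for any CV.
#' @return A `ratio_summary` with `mean`, `sd`, `n_samples`, `seed`,
#'   `sampling_model`.
#' @seealso [delta_method_ratio()] for the analytic cross-check.
#' @export
mc_ratio <- function(numerator, denominator, n_samples = 5000L, seed = 1L,
                     sampling_model = c("normal-truncated", "lognormal")) {
  sampling_model <- match.arg(sampling_model)
  num <- unclass(numerator)
  den <- unclass(denominator)
  for (e in list(num, den)) {
    if (!is.finite(e$value) || e$value <= 0) stop("estimate values must be > 0")
    if (!is.finite(e$std_error) || e$std_error < 0)
      stop("std errors must be finite and >= 0")
  }
  if (sampling_model == "normal-truncated") {
    cvs <- c(num$std_error / num$value, den$std_error / den$value)
    if (any(cvs >= 1))
      stop("CV >= 1 under the truncated-normal model; ",
           "use sampling_model = 'lognormal'")
  }
  n_samples <- as.integer(n_samples)
  if (n_samples <= 0L) stop("n_samples must be positive")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  draw <- function(e) {
    if (e$std_error == 0) return(rep(e$value, n_samples))
    if (sampling_model == "normal-truncated") {
      x <- stats::rnorm(n_samples, e$value, e$std_error)
      bad <- which(x <= 0)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), e$value, e$std_error)
        bad <- bad[x[bad] <= 0]
      }
      x
    } else {
      sdlog <- sqrt(log1p((e$std_error / e$value)^2))
      meanlog <- log(e$value) - sdlog^2 / 2
      stats::rlnorm(n_samples, meanlog, sdlog)
    }
  }
  xn <- draw(num)
  xd <- draw(den)
  r <- xn / xd
  structure(
    list(mean = mean(r),
         sd = if (n_samples > 1L) stats::sd(r) else 0,
         n_samples = n_samples,
         seed = as.integer(seed),
         sampling_model = sampling_model),
    class = "ratio_summary"
  )
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("Ratio: %.4g +/- %.4g  (n = %d, %s, seed %d)\n",
              x$mean, x$sd, x$n_samples, x$sampling_model, x$seed))
  invisible(x)
}

#' Delta-method mean and sd of a ratio
#'
#' Analytic Taylor approximation for the ratio N/D of two independent
#' estimates: second-order mean \eqn{R (1 + cv_D^2)} and first-order sd
#' \eqn{R \sqrt{cv_N^2 + cv_D^2}}, with \eqn{R = N/D}. Serves as the
#' closed-form oracle for [mc_ratio()]; quoted as valid for CVs below 0.5.
#'
#' @inheritParams mc_ratio
#' @return Named numeric vector `c(mean, sd)`.
#' @export
delta_method_ratio <- function(numerator, denominator) {
  num <- unclass(numerator)
  den <- unclass(denominator)
  r <- num$value / den$value
  cvn <- num$std_error / num$value
  cvd <- den$std_error / den$value
  if (max(cvn, cvd) >= 0.5)
    warning("delta-method approximation is unreliable for CV >= 0.5")
  c(mean = r * (1 + cvd^2), sd = r * sqrt(cvn^2 + cvd^2))
}

#' Summarise several labelled Kd ratios into a table
#'
#' Convenience wrapper producing the bar-plot-shaped table (scenario, ratio
#' mean, ratio sd) from named numerator/denominator estimate pairs.
#'
#' @param pairs Named list; each element is `list(numerator =, denominator =)`
#'   of `estimate`s.
#' @param n_samples,seed,sampling_model Passed to [mc_ratio()]. Each pair gets
#'   a distinct sub-seed derived from `seed`.
#' @return A data.frame with columns `scenario`, `ratio_mean`, `ratio_sd`,
#'   `n_samples`.
#' @export
ratio_table <- function(pairs, n_samples = 5000L, seed = 1L,
                        sampling_model = "normal-truncated") {
  stopifnot(length(pairs) > 0, !is.null(names(pairs)))
  rows <- lapply(seq_along(pairs), function(i) {
    rs <- mc_ratio(pairs[[i]]$numerator, pairs[[i]]$denominator,
                   n_samples = n_samples, seed = seed + i - 1L,
                   sampling_model = sampling_model)
    data.frame(scenario = names(pairs)[i], ratio_mean = rs$mean,
               ratio_sd = rs$sd, n_samples = rs$n_samples,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
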