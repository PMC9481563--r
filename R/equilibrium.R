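#' Bound-probe fraction for a two-component binding equilibrium
#'
#' Exact solution of the single-site equilibrium R + L <-> RL with ligand
#' depletion: the quadratic model used to fit direct fluorescence-polarization
#' titrations, where receptor (protein) is varied against a fixed labelled
#' probe.
#'
#' @param r_total Total receptor concentration(s), nM. Vectorised.
#' @param l_total Total probe (labelled ligand) concentration, nM. Must be > 0.
#' @param kd Dissociation constant, nM. Must be > 0.
#'
#' @return Fraction of probe bound, in `[0, 1]`, same length as `r_total`.
#'
#' @details The bound complex is
#' \deqn{[RL] = \frac{(R+L+K_d) - \sqrt{(R+L+K_d)^2 - 4RL}}{2}}
#' evaluated in the numerically stable form \eqn{2RL/(S + \sqrt{S^2 - 4RL})}
#' with \eqn{S = R+L+K_d}, which avoids catastrophic cancellation when
#' \eqn{4RL \ll S^2} (e.g. trace probe).
#'
#' @examples
#' fraction_bound_direct(r_total = 100, l_total = 100, kd = 100)
#' # half-saturation at R = Kd in the no-depletion limit:
#' fraction_bound_direct(r_total = 50, l_total = 1e-6, kd = 50)
#' @export
fraction_bound_direct <- function(r_total, l_total, kd) {
  if (length(l_total) != 1L || length(kd) != 1L)
    stop("l_total and kd must be scalars")
  if (any(r_total < 0)) stop("r_total must be non-negative")
  if (l_total <= 0) stop("l_total must be strictly positive")
  if (kd <= 0) stop("kd must be strictly positive")
  s <- r_total + l_total + kd
  disc <- s^2 - 4 * r_total * l_total
  disc[disc < 0] <- 0  # guard against rounding; true discriminant is >= kd^2 > 0
  bound <- 2 * r_total * l_total / (s + sqrt(disc))
  pmin(pmax(bound / l_total, 0), 1)
}

#' Linear polarization signal model
#'
#' Maps a bound-probe fraction to a millipolarization reading assuming the
#' observed polarization is linear in fraction bound (no intensity change on
#' binding).
#'
#' @param fraction_bound Fraction(s) in `[0, 1]`.
#' @param p_free Polarization of the free probe, mP.
#' @param p_bound Polarization of the fully bound probe, mP.
#' @return Polarization, mP.
#' @export
polarization_signal <- function(fraction_bound, p_free, p_bound) {
  if (any(fraction_bound < -1e-12 | fraction_bound > 1 + 1e-12))
    stop("fraction_bound must lie in [0, 1]")
  p_free + (p_bound - p_free) * fraction_bound
}

# Physically valid free-receptor root of the three-component cubic, by the
# trigonometric real-root formula, then polished to machine precision with
# Newton steps on the receptor mass balance. Scalar in all arguments except
# c_total is allowed to vectorise at the caller.
.free_receptor_cubic <- function(r_total, l_total, c_total, kd_probe, kd_comp) {
  if (r_total == 0) return(0)
  # cubic in free receptor Rf: Rf^3 + a Rf^2 + b Rf + c = 0
  a <- kd_probe + kd_comp + l_total + c_total - r_total
  b <- kd_comp * (l_total - r_total) + kd_probe * (c_total - r_total) +
    kd_probe * kd_comp
  cc <- -kd_probe * kd_comp * r_total
  p <- a^2 - 3 * b
  if (p <= 0) {
    rf <- r_total / 2  # degenerate start; Newton below converges on [0, r_total]
  } else {
    arg <- (-2 * a^3 + 9 * a * b - 27 * cc) / (2 * sqrt(p^3))
    arg <- min(1, max(-1, arg))
    theta <- acos(arg)
    rf <- (2 * sqrt(p) * cos(theta / 3) - a) / 3
  }
  rf <- min(max(rf, 0), r_total)
  .newton_polish(rf, r_total, l_total, c_total, kd_probe, kd_comp)
}

# Newton refinement on f(Rf) = Rf (1 + L/(K1+Rf) + C/(K2+Rf)) - R0, keeping
# the iterate inside [0, r_total]; converges to machine precision from any
# reasonable start within the bracket.
.newton_polish <- function(rf, r_total, l_total, c_total, kd_probe, kd_comp) {
  for (i in 1:50) {
    f <- rf + rf * l_total / (kd_probe + rf) + rf * c_total / (kd_comp + rf) -
      r_total
    fp <- 1 + l_total * kd_probe / (kd_probe + rf)^2 +
      c_total * kd_comp / (kd_comp + rf)^2
    rf_new <- rf - f / fp
    if (rf_new < 0) rf_new <- rf / 2
    if (rf_new > r_total) rf_new <- (rf + r_total) / 2
    if (abs(rf_new - rf) <= 1e-15 * max(rf_new, 1e-300)) return(rf_new)
    rf <- rf_new
  }
  rf
}

.species_from_free_receptor <- function(rf, r_total, l_total, c_total,
                                        kd_probe, kd_comp) {
  rl <- rf * l_total / (kd_probe + rf)
  rc <- rf * c_total / (kd_comp + rf)
  structure(
    list(
      free_receptor = rf,
      free_probe = l_total - rl,
      free_competitor = c_total - rc,
      receptor_probe = rl,
      receptor_competitor = rc
    ),
    class = "species_state"
  )
}

.check_species <- function(st, r_total, l_total, c_total, tol = 1e-9) {
  scale_r <- max(r_total, 1)
  ok <- abs(st$free_receptor + st$receptor_probe + st$receptor_competitor -
              r_total) <= tol * scale_r &&
    abs(st$free_probe + st$receptor_probe - l_total) <= tol * max(l_total, 1) &&
    abs(st$free_competitor + st$receptor_competitor - c_total) <=
      tol * max(c_total, 1) &&
    all(unlist(st) >= -tol * scale_r)
  ok
}

#' Exact species concentrations for the competitive (three-component) equilibrium
#'
#' Solves R + L <-> RL and R + C <-> RC simultaneously for the free-receptor
#' concentration via the physically valid root of the resulting cubic
#' (trigonometric form, polished by Newton iteration on the mass balance), as
#' used to fit competitive fluorescence-polarization titrations in which an
#' unlabelled competitor displaces a fixed labelled probe.
#'
#' @param r_total,l_total,c_total Total receptor, probe and competitor, nM
#'   (all >= 0).
#' @param kd_probe,kd_comp Dissociation constants of the probe and competitor
#'   complexes, nM (> 0).
#' @return A `species_state` list with elements `free_receptor`, `free_probe`,
#'   `free_competitor`, `receptor_probe`, `receptor_competitor` (all nM).
#' @seealso [solve_equilibrium_numeric()] for the independent bracketed solver.
#' @examples
#' st <- solve_competitive_analytic(100, 100, 100, 100, 100)
#' st$receptor_probe / 100  # bound-probe fraction
#' @export
solve_competitive_analytic <- function(r_total, l_total, c_total,
                                       kd_probe, kd_comp) {
  stopifnot(length(r_total) == 1L, length(l_total) == 1L, length(c_total) == 1L)
  if (r_total < 0 || l_total < 0 || c_total < 0)
    stop("total concentrations must be non-negative")
  if (kd_probe <= 0 || kd_comp <= 0)
    stop("dissociation constants must be strictly positive")
  rf <- .free_receptor_cubic(r_total, l_total, c_total, kd_probe, kd_comp)
  st <- .species_from_free_receptor(rf, r_total, l_total, c_total,
                                    kd_probe, kd_comp)
  if (!.check_species(st, r_total, l_total, c_total))
    stop(sprintf(
      paste0("no physically valid equilibrium root found ",
             "(R0=%g, L0=%g, C0=%g, Kd1=%g, Kd2=%g, Rf=%g)"),
      r_total, l_total, c_total, kd_probe, kd_comp, rf))
  st
}

#' Numerical competitive equilibrium by bracketed root finding
#'
#' Independent check of [solve_competitive_analytic()]: solves the
#' free-receptor mass balance on the bracket `[0, r_total]` with
#' [stats::uniroot()]. Intended for tests and cross-validation.
#'
#' @inheritParams solve_competitive_analytic
#' @return A `species_state` list, as for [solve_competitive_analytic()].
#' @export
solve_equilibrium_numeric <- function(r_total, l_total, c_total,
                                      kd_probe, kd_comp) {
  if (r_total < 0 || l_total < 0 || c_total < 0)
    stop("total concentrations must be non-negative")
  if (kd_probe <= 0 || kd_comp <= 0)
    stop("dissociation constants must be strictly positive")
  if (r_total == 0)
    return(.species_from_free_receptor(0, r_total, l_total, c_total,
                                       kd_probe, kd_comp))
  f <- function(rf) {
    rf + rf * l_total / (kd_probe + rf) + rf * c_total / (kd_comp + rf) -
      r_total
  }
  root <- tryCatch(
    stats::uniroot(f, lower = 0, upper = r_total,
                   tol = 1e-14 * max(1, r_total), maxiter = 2000L),
    error = function(e) stop("bracketing failure in equilibrium solve: ",
                             conditionMessage(e))
  )
  rf <- .newton_polish(root$root, r_total, l_total, c_total,
                       kd_probe, kd_comp)
  .species_from_free_receptor(rf, r_total, l_total, c_total,
                              kd_probe, kd_comp)
}

# Vectorised bound-probe concentration over a competitor series (fixed R, L).
.bound_probe_competitive <- function(c_total, r_total, l_total,
                                     kd_probe, kd_comp) {
  vapply(c_total, function(ci) {
    solve_competitive_analytic(r_total, l_total, ci, kd_probe, kd_comp)$receptor_probe
  }, numeric(1))
}

#' @export
print.species_state <- function(x, ...) {
  cat("Equilibrium species (nM):\n")
  for (nm in names(x)) cat(sprintf("  %-20s %.6g\n", nm, x[[nm]]))
  invisible(x)
}
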