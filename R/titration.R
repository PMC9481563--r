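#' Construct a titration series
#'
#' Container for one fluorescence-polarization binding experiment: a varied
#' concentration grid with one or more replicate polarization readings, plus
#' the fixed assay components.
#'
#' @param varied_conc Varied total concentration, nM (receptor in `direct`
#'   mode, unlabelled competitor in `competitive` mode). Non-negative.
#' @param readings Numeric matrix (or vector for a single replicate) of
#'   polarization readings, mP; one column per replicate, rows matching
#'   `varied_conc`.
#' @param mode `"direct"` or `"competitive"`.
#' @param fixed_components Named list of fixed totals, nM. `direct` mode needs
#'   `probe_total`; `competitive` mode needs `receptor_total`, `probe_total`
#'   and `probe_kd` (from a prior direct fit).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(varied_conc, readings,
                             mode = c("direct", "competitive"),
                             fixed_components = list()) {
  mode <- match.arg(mode)
  varied_conc <- as.numeric(varied_conc)
  if (any(!is.finite(varied_conc)) || any(varied_conc < 0))
    stop("varied_conc must be finite and non-negative")
  if (is.null(dim(readings))) readings <- matrix(readings, ncol = 1L)
  readings <- as.matrix(readings)
  if (nrow(readings) != length(varied_conc))
    stop("readings must have one row per concentration")
  if (ncol(readings) < 1L) stop("at least one replicate required")
  req <- switch(mode,
                direct = "probe_total",
                competitive = c("receptor_total", "probe_total", "probe_kd"))
  missing_comp <- setdiff(req, names(fixed_components))
  if (length(missing_comp))
    stop("fixed_components missing: ", paste(missing_comp, collapse = ", "))
  ord <- order(varied_conc)
  structure(
    list(varied_conc = varied_conc[ord],
         readings = readings[ord, , drop = FALSE],
         mode = mode,
         fixed_components = fixed_components),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series (%s): %d concentrations x %d replicate(s)\n",
              x$mode, length(x$varied_conc), ncol(x$readings)))
  cat(sprintf("  varied: %.4g - %.4g nM\n",
              min(x$varied_conc), max(x$varied_conc)))
  fc <- x$fixed_components
  if (length(fc))
    cat("  fixed:", paste(sprintf("%s=%.4g", names(fc), unlist(fc)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Read a titration series from CSV
#'
#' Expects columns `conc_nM`, `rep1_mP`, `rep2_mP`, ... with a header row.
#' Assay metadata (mode and fixed components) is not stored in the CSV and is
#' supplied here.
#'
#' @param path CSV file path.
#' @inheritParams titration_series
#' @return A `titration_series`.
#' @export
read_titration_csv <- function(path, mode = c("direct", "competitive"),
                               fixed_components = list()) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"conc_nM" %in% names(tab))
    stop("titration CSV must have a 'conc_nM' column")
  rep_cols <- grep("^rep[0-9]+_mP$", names(tab), value = TRUE)
  if (!length(rep_cols))
    stop("titration CSV must have at least one 'rep<i>_mP' column")
  titration_series(tab$conc_nM, as.matrix(tab[rep_cols]),
                   mode = mode, fixed_components = fixed_components)
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()]; fixed components and mode are metadata
#' and are not written.
#'
#' @param series A `titration_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  tab <- data.frame(conc_nM = series$varied_conc)
  for (j in seq_len(ncol(series$readings)))
    tab[[sprintf("rep%d_mP", j)]] <- series$readings[, j]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
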