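# Ensemble distance statistics for docking restraints: a centre with
# asymmetric lower/upper offsets covering every distance observed across a
# set of homologous structures, written as "dist(PAIR) = C (-M + P)".

# Round half-up on a decimal grid (round-half-even would contradict the
# convention used for the printed restraints, e.g. 2.85 -> 2.9).
.round_grid <- function(x, grid) {
  d <- 1 / grid
  floor(x * d + 0.5 + 1e-9) / d
}

#' Construct a distance ensemble
#'
#' @param pair_label Atom-pair label, e.g. `"TyrO2P-Ala461N"`.
#' @param distances Positive distances in Angstrom, one per structure.
#' @return An object of class `distance_ensemble`.
#' @export
distance_ensemble <- function(pair_label, distances) {
  distances <- as.numeric(distances)
  if (!length(distances)) stop("empty distance ensemble")
  if (any(!is.finite(distances) | distances <= 0))
    stop("all distances must be finite and > 0")
  structure(list(pair_label = as.character(pair_label),
                 distances = distances,
                 n_structures = length(distances)),
            class = "distance_ensemble")
}

#' Ensemble distance statistics for one atom pair
#'
#' Reduces an ensemble of observed distances to a centre with asymmetric
#' bounds: `center` per `center_rule` (median by default), rounded to the
#' given grid; `minus = center - min` and `plus = max - center` with the
#' extremes rounded to the same grid, so the interval
#' `[center - minus, center + plus]` covers every input distance after
#' rounding. Negative offsets arising from rounding ties are clipped to zero
#' with a warning.
#'
#' @param ensemble A `distance_ensemble`.
#' @param rounding Grid in Angstrom (default 0.1).
#' @param center_rule `"median"` (default), `"mean"`, or `"reference"` (use
#'   `reference`).
#' @param reference Centre value when `center_rule = "reference"`.
#' @return A `restraint_stat` list: `pair_label`, `center`, `minus`, `plus`
#'   (Angstrom).
#' @export
ensemble_distance_stats <- function(ensemble, rounding = 0.1,
                                    center_rule = c("median", "mean",
                                                    "reference"),
                                    reference = NULL) {
  stopifnot(inherits(ensemble, "distance_ensemble"))
  center_rule <- match.arg(center_rule)
  if (rounding <= 0) stop("rounding grid must be positive")
  d <- ensemble$distances
  center_raw <- switch(center_rule,
                       median = stats::median(d),
                       mean = mean(d),
                       reference = {
                         if (is.null(reference))
                           stop("center_rule 'reference' needs a reference value")
                         reference
                       })
  center <- .round_grid(center_raw, rounding)
  minus <- center - .round_grid(min(d), rounding)
  plus <- .round_grid(max(d), rounding) - center
  if (minus < 0 || plus < 0) {
    warning(sprintf("offset(s) clipped to zero for %s (rounding ties)",
                    ensemble$pair_label))
    minus <- max(minus, 0)
    plus <- max(plus, 0)
  }
  structure(list(pair_label = ensemble$pair_label,
                 center = center, minus = .round_grid(minus, rounding),
                 plus = .round_grid(plus, rounding)),
            class = "restraint_stat")
}

.format_restraint <- function(s, digits = 1L) {
  fmt <- sprintf("dist(%%s) = %%.%df (-%%.%df + %%.%df)",
                 digits, digits, digits)
  sprintf(fmt, s$pair_label, s$center, s$minus, s$plus)
}

#' @export
print.restraint_stat <- function(x, ...) {
  cat(.format_restraint(x), "\n")
  invisible(x)
}

#' Write a docking restraint table
#'
#' Writes one line per restraint in the form
#' `dist(PAIR) = C (-M + P)`, in input order, byte-stable across runs.
#'
#' @param stats A list of `restraint_stat` objects (non-empty).
#' @param path Output file path.
#' @param digits Decimal places (default 1, matching a 0.1 Angstrom grid).
#' @return `path`, invisibly.
#' @seealso [read_restraint_table()] for the inverse.
#' @export
write_restraint_table <- function(stats, path, digits = 1L) {
  if (inherits(stats, "restraint_stat")) stats <- list(stats)
  if (!length(stats)) stop("empty restraint list")
  lines <- vapply(stats, .format_restraint, "", digits = digits)
  con <- file(path, open = "wb")  # byte-stable: LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Parse a docking restraint table
#'
#' Inverse of [write_restraint_table()]: reads `dist(PAIR) = C (-M + P)`
#' lines into `restraint_stat` objects.
#'
#' @param path File path.
#' @return List of `restraint_stat` objects, in file order.
#' @export
read_restraint_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no restraints in ", path)
  rx <- "^dist\\((.+)\\) = ([0-9.]+) \\(-([0-9.]+) \\+ ([0-9.]+)\\)$"
  bad <- !grepl(rx, lines)
  if (any(bad))
    stop("unparseable restraint line: '", lines[which(bad)[1]], "'")
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(rx, ln))[[1]]
    structure(list(pair_label = m[2], center = as.numeric(m[3]),
                   minus = as.numeric(m[4]), plus = as.numeric(m[5])),
              class = "restraint_stat")
  })
}

#' Read an atom-pair distance table (TSV)
#'
#' Consumes a pre-computed long-format table with columns `pair_label`,
#' `structure_id`, `distance_A` and groups it into one
#' [distance_ensemble()] per pair (in order of first appearance).
#'
#' @param path TSV path.
#' @return Named list of `distance_ensemble` objects.
#' @export
read_distance_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_label", "structure_id", "distance_A")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("distance TSV missing column(s): ", paste(miss, collapse = ", "))
  labels <- unique(tab$pair_label)
  out <- lapply(labels, function(lb)
    distance_ensemble(lb, tab$distance_A[tab$pair_label == lb]))
  stats::setNames(out, labels)
}

#' Path to the packaged tyrosine-phosphatase restraint table
#'
#' Seven unambiguous atom-pair restraints for the phosphotyrosine and the -2
#' glycine of a phosphatase-bound substrate peptide, derived from an ensemble
#' of published tyrosine phosphatase structures (SHP2 numbering, UniProt
#' Q06124-2).
#'
#' @return File path inside the installed package.
#' @export
ptp_restraints_path <- function() {
  system.file("extdata", "ptp_ensemble_restraints.txt", package = "ptpkit",
              mustWork = TRUE)
}
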