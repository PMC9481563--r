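# Position frequency matrix of Y-centred substrate windows and the
# charge-enrichment summary used for substrate-site logos.

#' Build a position frequency matrix from Y-centred windows
#'
#' Counts residues per relative position (-5..+5) over a set of aligned,
#' ungapped 11-mer windows whose central residue is the phospho-acceptor Y.
#'
#' @param windows Character vector of 11-mer sequences (any case), each with
#'   `Y` at position 6.
#' @return A `pfm`: an integer matrix (20 residues x 11 positions, columns
#'   named `-5`..`+5`) with attribute `n_sequences`; every column sums to the
#'   number of windows.
#' @export
build_pfm <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  windows <- toupper(windows)
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L || wlen != 11L)
    stop("all windows must be ungapped 11-mers")
  center <- substr(windows, 6, 6)
  if (any(center != "Y"))
    stop("window(s) not centred on Y: ",
         paste(utils::head(which(center != "Y"), 3), collapse = ", "))
  mat <- matrix(0L, nrow = length(.AA20), ncol = 11L,
                dimnames = list(.AA20, as.character(-5:5)))
  for (w in windows) {
    chars <- strsplit(w, "")[[1]]
    bad <- setdiff(chars, .AA20)
    if (length(bad))
      stop("non-canonical residue(s) in window '", w, "': ",
           paste(bad, collapse = ","))
    for (j in 1:11) mat[chars[j], j] <- mat[chars[j], j] + 1L
  }
  structure(mat, n_sequences = length(windows), class = c("pfm", "matrix"))
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d sequences, positions -5..+5\n",
              attr(x, "n_sequences")))
  print(unclass(x))
  invisible(x)
}

#' Write a position frequency matrix as TSV
#'
#' @param pfm A `pfm`.
#' @param path Output path (residues as rows, relative positions as columns).
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  tab <- data.frame(residue = rownames(pfm), unclass(pfm),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-position charge fractions and enrichment
#'
#' Summarises a substrate-site frequency matrix by the fraction of negatively
#' charged (D, E) and positively charged (K, R) residues at each relative
#' position, with enrichment over a background composition. Used to quantify
#' acidic-residue enrichment flanking the phosphotyrosine (e.g. at +4/+5 and
#' -4..-1, where pSer/pThr or Asp/Glu supply the negative charge).
#'
#' @param pfm A `pfm` from [build_pfm()].
#' @param background Named per-residue background frequencies summing to 1;
#'   default uniform (0.05 per residue, so 0.10 for the D+E class).
#' @return A data.frame with columns `position`, `frac_negative`,
#'   `frac_positive`, `enrich_negative`, `enrich_positive`.
#' @export
charge_enrichment <- function(pfm,
                              background = stats::setNames(rep(0.05, 20),
                                                           .AA20)) {
  n <- attr(pfm, "n_sequences")
  if (is.null(n) || n <= 0) stop("pfm must carry a positive n_sequences")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  neg_bg <- sum(background[c("D", "E")])
  pos_bg <- sum(background[c("K", "R")])
  frac_neg <- colSums(pfm[c("D", "E"), , drop = FALSE]) / n
  frac_pos <- colSums(pfm[c("K", "R"), , drop = FALSE]) / n
  data.frame(
    position = as.integer(colnames(pfm)),
    frac_negative = unname(frac_neg),
    frac_positive = unname(frac_pos),
    enrich_negative = unname(frac_neg / neg_bg),
    enrich_positive = unname(frac_pos / pos_bg)
  )
}
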