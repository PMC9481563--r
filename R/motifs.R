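# Consensus-motif scanning for pSer/pThr-flanked phosphotyrosine sites.
# Patterns are short linear motifs over fixed residues, "." wildcards and
# residue classes "[...]", anchored on a phospho-acceptor Y at relative
# position 0 (e.g. "Y..M[ST]P").

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Compile a consensus pattern into a matcher
#'
#' Parses a fixed-width short-linear-motif pattern built from fixed one-letter
#' residue codes, the wildcard `"."`, and residue classes like `"[ST]"`. The
#' pattern must contain exactly one fixed `Y`, which anchors the motif at
#' relative position 0. Matching is case-insensitive; terminal padding
#' characters (`"-"`) never match any element.
#'
#' @param pattern Pattern string, e.g. `"Y[ILV].[ILV][ST]P"`.
#' @param effectors Character vector of effector labels associated with the
#'   pattern (optional).
#' @return An object of class `consensus_pattern` with elements `pattern`,
#'   `elements` (list of allowed-residue character vectors, `NULL` for
#'   wildcard), `anchor` (1-based index of the Y element), `width`, and
#'   `effectors`.
#' @examples
#' p <- compile_consensus("Y..M[ST]P", effectors = "PI3K")
#' pattern_matches(p, "YMPMSP")
#' @export
compile_consensus <- function(pattern, effectors = character()) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string")
  chars <- strsplit(pattern, "")[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == ".") {
      elements[length(elements) + 1L] <- list(NULL)  # wildcard
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        cls <- c(cls, toupper(chars[j]))
        j <- j + 1L
      }
      if (j > length(chars))
        stop(sprintf("unterminated residue class at position %d of '%s'",
                     i, pattern))
      if (!length(cls))
        stop(sprintf("empty residue class at position %d of '%s'", i, pattern))
      bad <- setdiff(cls, .AA20)
      if (length(bad))
        stop(sprintf("non-canonical residue(s) %s in class at position %d of '%s'",
                     paste(bad, collapse = ","), i, pattern))
      elements[[length(elements) + 1L]] <- cls
      i <- j + 1L
    } else if (toupper(ch) %in% .AA20) {
      elements[[length(elements) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at position %d of '%s'",
                   ch, i, pattern))
    }
  }
  fixed_y <- which(vapply(elements, function(e)
    length(e) == 1L && identical(e, "Y"), logical(1)))
  if (length(fixed_y) != 1L)
    stop(sprintf("pattern '%s' must contain exactly one anchor Y", pattern))
  structure(
    list(pattern = pattern, elements = elements, anchor = fixed_y,
         width = length(elements), effectors = as.character(effectors)),
    class = "consensus_pattern"
  )
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("Consensus pattern %s (width %d, anchor Y at element %d)",
              x$pattern, x$width, x$anchor))
  if (length(x$effectors))
    cat("  ->", paste(x$effectors, collapse = "; "))
  cat("\n")
  invisible(x)
}

#' Test a compiled pattern against a sequence segment
#'
#' Matches the pattern with its anchor Y aligned on position `at` of `seq`
#' (1-based). With the default `at`, the segment itself must start with the
#' anchor.
#'
#' @param cp A `consensus_pattern`.
#' @param seq Amino-acid sequence (any case).
#' @param at Position of the anchor Y in `seq`.
#' @return `TRUE` or `FALSE`.
#' @export
pattern_matches <- function(cp, seq, at = cp$anchor) {
  stopifnot(inherits(cp, "consensus_pattern"))
  chars <- toupper(strsplit(seq, "")[[1]])
  start <- at - cp$anchor + 1L
  end <- start + cp$width - 1L
  if (start < 1L || end > length(chars)) return(FALSE)
  for (k in seq_len(cp$width)) {
    ch <- chars[start + k - 1L]
    if (!ch %in% .AA20) return(FALSE)  # padding / non-canonical never match
    el <- cp$elements[[k]]
    if (is.null(el)) next
    if (!ch %in% el) return(FALSE)
  }
  TRUE
}

#' Default consensus pattern set
#'
#' The six pSer/pThr-flanked phosphotyrosine consensus motifs used for
#' proteome scanning, each with its predicted effector label(s): two PI3K
#' motifs (`Y..M[ST]P`, `Y..M.[ST]P`), two GRB2 motifs (`Y.N.[ST]P`,
#' `Y.N..[ST]P`), a PLCg/SRC motif pair (`Y[ILV].[ILV][ST]P`, `Y.[DE].[ST]P`).
#'
#' @return Named list of `consensus_pattern` objects.
#' @export
default_consensus_patterns <- function() {
  spec <- list(
    "Y..M[ST]P"        = "PI3K",
    "Y.N.[ST]P"        = "GRB2",
    "Y[ILV].[ILV][ST]P" = "PLCg",
    "Y.[DE].[ST]P"     = "SRC",
    "Y.N..[ST]P"       = "GRB2",
    "Y..M.[ST]P"       = "PI3K"
  )
  out <- lapply(names(spec), function(p) compile_consensus(p, spec[[p]]))
  names(out) <- names(spec)
  out
}

.window_around <- function(chars, center, left = 5L, right = 9L) {
  idx <- (center - left):(center + right)
  w <- rep("-", length(idx))
  ok <- idx >= 1L & idx <= length(chars)
  w[ok] <- chars[idx[ok]]
  paste(w, collapse = "")
}

.as_named_sequences <- function(x) {
  if (inherits(x, "AAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x)))
      names(x) <- sprintf("seq%d", seq_along(x))
    return(x)
  }
  stop("sequences must be a FASTA path, a named character vector, ",
       "or an AAStringSet")
}

#' Scan protein sequences for consensus motif hits
#'
#' Tests every tyrosine of every sequence against every pattern and returns
#' one hit per (protein, Y) position that matches at least one pattern,
#' aggregating all matching patterns and the union of their effector labels.
#'
#' @param sequences FASTA file path, named character vector of amino-acid
#'   sequences, or a `Biostrings::AAStringSet`.
#' @param patterns List of `consensus_pattern` objects (default:
#'   [default_consensus_patterns()]).
#' @return A data.frame of class `motif_hits` with columns `protein_id`,
#'   `tyr_position` (1-based), `window` (15-mer, positions -5..+9 around the
#'   Y, `"-"`-padded), `matched_patterns` and `effectors` (both
#'   `"; "`-separated), and filter flag columns (`NA` until [filter_hits()]
#'   is applied).
#' @export
scan_sequences <- function(sequences, patterns = default_consensus_patterns()) {
  if (!length(patterns)) stop("empty pattern list")
  patterns <- lapply(patterns, function(p)
    if (inherits(p, "consensus_pattern")) p else compile_consensus(p))
  seqs <- .as_named_sequences(sequences)
  rows <- list()
  for (si in seq_along(seqs)) {  # positional: names may be duplicated
    id <- names(seqs)[si]
    chars <- toupper(strsplit(seqs[[si]], "")[[1]])
    noncanon <- setdiff(unique(chars), .AA20)
    if (length(noncanon))
      warning(sprintf("sequence %s contains non-canonical residue(s) %s; %s",
                      id, paste(noncanon, collapse = ","),
                      "they will never match"))
    y_pos <- which(chars == "Y")
    for (p in y_pos) {
      matched <- vapply(patterns, function(cp)
        pattern_matches(cp, seqs[[si]], at = p), logical(1))
      if (!any(matched)) next
      mp <- vapply(patterns[matched], `[[`, "", "pattern")
      eff <- unique(unlist(lapply(patterns[matched], `[[`, "effectors")))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, tyr_position = p,
        window = .window_around(chars, p),
        matched_patterns = paste(mp, collapse = "; "),
        effectors = paste(eff, collapse = "; "),
        phospho_evidence_ok = NA, conserved_ok = NA, outside_domain_ok = NA,
        retained = NA, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), tyr_position = integer(),
               window = character(), matched_patterns = character(),
               effectors = character(), phospho_evidence_ok = logical(),
               conserved_ok = logical(), outside_domain_ok = logical(),
               retained = logical(), stringsAsFactors = FALSE)
  class(out) <- c("motif_hits", "data.frame")
  out
}

# Relative offsets (to the anchor Y) of the phospho-acceptor [ST] element of
# a compiled pattern: the first class after the anchor containing only S/T,
# or a fixed S/T.
.st_offset <- function(cp) {
  for (k in seq_len(cp$width)) {
    if (k == cp$anchor) next
    el <- cp$elements[[k]]
    if (!is.null(el) && all(el %in% c("S", "T")))
      return(k - cp$anchor)
  }
  NA_integer_
}

.lookup_detections <- function(evidence, protein, site) {
  hit <- evidence$n_detections[evidence$protein == protein &
                                 evidence$site == site]
  if (!length(hit)) 0L else max(hit)
}

#' Apply phosphosite, conservation and folded-domain filters to motif hits
#'
#' Reproduces a proteome-scan filter chain: a hit is retained only if (i) the
#' phosphosites are detected more than once (`n_detections > 1`) — by default
#' required of both the anchor Y and the flanking S/T of at least one matched
#' pattern — (ii) the Y site is conserved at least in mammals, and (iii) the
#' Y lies outside all folded-domain intervals. Rejected hits are kept in the
#' returned table with their flags.
#'
#' @param hits A `motif_hits` table from [scan_sequences()].
#' @param phospho_evidence data.frame with columns `protein`, `site`
#'   (1-based), `n_detections`; or `NULL` (flag unknown).
#' @param conservation data.frame with columns `protein`, `site`,
#'   `conserved_in_mammals` (logical); or `NULL`.
#' @param domain_mask data.frame with columns `protein`, `start`, `end`
#'   (1-based, inclusive folded-domain intervals); or `NULL`.
#' @param patterns Pattern set used for the scan (needed to locate each
#'   pattern's phospho-acceptor S/T).
#' @param require_both Require `n > 1` on both the Y and the S/T (default);
#'   `FALSE` requires it only on the Y.
#' @param permissive Retain hits whose flags are unknown because an
#'   annotation table is missing (default `FALSE`).
#' @return The `hits` table with flag columns and `retained` filled in.
#' @export
filter_hits <- function(hits, phospho_evidence = NULL, conservation = NULL,
                        domain_mask = NULL,
                        patterns = default_consensus_patterns(),
                        require_both = TRUE, permissive = FALSE) {
  stopifnot(inherits(hits, "data.frame"))
  if (!nrow(hits)) return(hits)
  patterns <- lapply(patterns, function(p)
    if (inherits(p, "consensus_pattern")) p else compile_consensus(p))
  pat_index <- stats::setNames(patterns,
                               vapply(patterns, `[[`, "", "pattern"))
  for (i in seq_len(nrow(hits))) {
    prot <- hits$protein_id[i]
    ypos <- hits$tyr_position[i]
    mp <- strsplit(hits$matched_patterns[i], "; ", fixed = TRUE)[[1]]

    if (is.null(phospho_evidence)) {
      ev_ok <- NA
    } else {
      y_ok <- .lookup_detections(phospho_evidence, prot, ypos) > 1L
      st_ok <- any(vapply(mp, function(pat) {
        off <- .st_offset(pat_index[[pat]])
        if (is.na(off)) return(FALSE)
        .lookup_detections(phospho_evidence, prot, ypos + off) > 1L
      }, logical(1)))
      ev_ok <- if (require_both) y_ok && st_ok else y_ok
    }

    if (is.null(conservation)) {
      cons_ok <- NA
    } else {
      fl <- conservation$conserved_in_mammals[conservation$protein == prot &
                                                conservation$site == ypos]
      cons_ok <- length(fl) > 0 && isTRUE(fl[1])
    }

    if (is.null(domain_mask)) {
      dom_ok <- NA
    } else {
      masked <- any(domain_mask$protein == prot &
                      domain_mask$start <= ypos & ypos <= domain_mask$end)
      dom_ok <- !masked
    }

    hits$phospho_evidence_ok[i] <- ev_ok
    hits$conserved_ok[i] <- cons_ok
    hits$outside_domain_ok[i] <- dom_ok
    flags <- c(ev_ok, cons_ok, dom_ok)
    hits$retained[i] <- if (permissive) all(flags %in% c(TRUE, NA)) else
      isTRUE(all(flags))
  }
  hits
}

#' Write a motif hits table to TSV
#'
#' @param hits A `motif_hits` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
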