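# Independent oracles used across the suite.

# Bisection on the free-receptor mass balance of the two-component system;
# deliberately avoids the package's closed forms.
bisect_fraction_bound <- function(r_total, l_total, kd, tol = 1e-12) {
  f <- function(rf) rf + rf * l_total / (kd + rf) - r_total
  lo <- 0; hi <- r_total
  if (r_total == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, r_total)) break
  }
  rf <- (lo + hi) / 2
  (rf * l_total / (kd + rf)) / l_total
}

# Regex-based brute-force motif matcher, independent of the package's
# element-wise matcher: translates the pattern to a PCRE lookahead and
# enumerates all (overlapping) anchor-Y positions.
brute_force_hits <- function(sequences, pattern_strings) {
  out <- list()
  for (id in names(sequences)) {
    s <- toupper(sequences[[id]])
    for (pat in pattern_strings) {
      anchor_off <- {
        # index of the fixed Y among pattern elements
        stripped <- gsub("\\[[A-Z]+\\]", "x", pat)
        which(strsplit(stripped, "")[[1]] == "Y") - 1L
      }
      rx <- paste0("(?=", gsub(".", "[A-Z]", pat, fixed = TRUE), ")")
      m <- gregexpr(rx, s, perl = TRUE)[[1]]
      starts <- m[m > 0]
      for (st in starts)
        out[[length(out) + 1L]] <- data.frame(
          protein_id = id, tyr_position = st + anchor_off,
          pattern = pat, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), tyr_position = integer(),
                      pattern = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Scenario with noise switched off, for exact-recovery tests.
noiseless <- function(scenario) {
  scenario$assay_design$noise_sd <- 0
  scenario$assay_design$noise_cv <- 0
  scenario
}
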