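test_that("consensus patterns compile and match their defining examples", {
  p1 <- compile_consensus("Y..M[ST]P")
  expect_true(pattern_matches(p1, "YMPMSP"))
  expect_false(pattern_matches(p1, "YMPMAP"))
  p3 <- compile_consensus("Y[ILV].[ILV][ST]P")
  expect_true(pattern_matches(p3, "YLDLTP"))
  expect_false(pattern_matches(p3, "YADLTP"))
  # matching is case-insensitive and padding never matches
  expect_true(pattern_matches(p1, "ympmsp"))
  expect_false(pattern_matches(p1, "YMPMS-"))
})

test_that("malformed patterns are rejected with positions", {
  expect_error(compile_consensus(""), "non-empty")
  expect_error(compile_consensus("Y..M[STP"), "unterminated.*position 5")
  expect_error(compile_consensus("Y..M[]P"), "empty residue class")
  expect_error(compile_consensus("A..M[ST]P"), "exactly one anchor Y")
  expect_error(compile_consensus("Y..Y[ST]P"), "exactly one anchor Y")
  expect_error(compile_consensus("Y..M[SZ]P"), "non-canonical")
})

test_that("scanning aggregates all matching patterns per tyrosine", {
  hits <- scan_sequences(c(CD28 = "RSRLLHSDYMNMTPRRPGP"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$tyr_position, 9L)
  expect_setequal(strsplit(hits$matched_patterns, "; ")[[1]],
                  c("Y..M[ST]P", "Y.N.[ST]P"))
  expect_setequal(strsplit(hits$effectors, "; ")[[1]], c("PI3K", "GRB2"))
  expect_equal(nrow(scan_sequences(c(noy = "ASDFGHKLMNPQRST"))), 0L)
  expect_error(scan_sequences(c(a = "AYA"), patterns = list()), "empty")
})

test_that("hit windows are the -5..+9 15-mers with terminal padding", {
  hits <- scan_sequences(c(x = "YMPMSPKSVSA"))  # anchor at position 1
  expect_equal(nchar(hits$window), 15L)
  expect_equal(hits$window, "-----YMPMSPKSVS")
  expect_equal(substr(hits$window, 6, 6), "Y")
})

test_that("scanner agrees exactly with a regex brute-force matcher", {
  pats <- names(default_consensus_patterns())
  set.seed(21)
  prot <- gen_proteome_with_motifs(60, c(150, 300),
                                   planted = c("Y..M[ST]P" = 10,
                                               "Y.[DE].[ST]P" = 8),
                                   seed = 99)
  hits <- scan_sequences(prot$sequences)
  bf <- brute_force_hits(prot$sequences, pats)
  key_scan <- sort(paste(hits$protein_id, hits$tyr_position))
  key_bf <- sort(unique(paste(bf$protein_id, bf$tyr_position)))
  expect_identical(key_scan, key_bf)
  # per-site pattern sets agree too
  for (i in seq_len(nrow(hits))) {
    got <- strsplit(hits$matched_patterns[i], "; ")[[1]]
    want <- bf$pattern[bf$protein_id == hits$protein_id[i] &
                         bf$tyr_position == hits$tyr_position[i]]
    expect_setequal(got, want)
  }
})

test_that("planted motifs are all recovered (sensitivity 1)", {
  prot <- gen_proteome_with_motifs(20, c(120, 200),
                                   planted = c("Y..M[ST]P" = 5), seed = 5)
  hits <- scan_sequences(prot$sequences)
  for (i in seq_len(nrow(prot$truth))) {
    found <- hits$protein_id == prot$truth$protein_id[i] &
      hits$tyr_position == prot$truth$tyr_position[i]
    expect_true(any(found))
  }
  # and any extra hits are genuine chance matches per the brute force
  bf <- brute_force_hits(prot$sequences, names(default_consensus_patterns()))
  expect_true(all(paste(hits$protein_id, hits$tyr_position) %in%
                    paste(bf$protein_id, bf$tyr_position)))
})

test_that("the packaged motif table rows all yield hits at their anchors", {
  tab <- shp2_motif_table()
  expect_equal(nrow(tab), 21L)
  expect_equal(sum(tab$confirmed), 3L)  # CD28 plus two IRS1 windows
  hits <- scan_sequences(stats::setNames(tab$sequence,
                                         sprintf("row%02d", seq_len(nrow(tab)))))
  expect_equal(nrow(hits), 21L)
  expect_true(all(hits$tyr_position == 6L))
  # printed consensus assignments are always a subset of what the patterns
  # match (one printed row omits a second matching pattern)
  for (i in seq_len(nrow(tab))) {
    printed <- strsplit(tab$matched_consensus[i], "; ")[[1]]
    got <- strsplit(hits$matched_patterns[hits$protein_id ==
                                            sprintf("row%02d", i)], "; ")[[1]]
    expect_true(all(printed %in% got))
  }
})

test_that("filter chain enforces evidence, conservation and domain rules", {
  seqs <- c(p1 = "AAAAAYMPMSPAAAAAAA")
  hits <- scan_sequences(seqs)
  ev <- data.frame(protein = "p1", site = c(6L, 10L), n_detections = c(3L, 2L))
  cons <- data.frame(protein = "p1", site = 6L, conserved_in_mammals = TRUE)
  dom <- data.frame(protein = "p1", start = 100L, end = 200L)
  out <- filter_hits(hits, ev, cons, dom)
  expect_true(out$phospho_evidence_ok & out$conserved_ok &
                out$outside_domain_ok & out$retained)

  # singly detected flanking Ser fails the evidence rule
  ev1 <- ev; ev1$n_detections[2] <- 1L
  expect_false(filter_hits(hits, ev1, cons, dom)$retained)
  expect_false(filter_hits(hits, ev1, cons, dom)$phospho_evidence_ok)
  # ...unless the rule is relaxed to the tyrosine only
  expect_true(filter_hits(hits, ev1, cons, dom,
                          require_both = FALSE)$retained)

  # a tyrosine inside a masked folded domain is dropped
  dom2 <- data.frame(protein = "p1", start = 1L, end = 50L)
  out2 <- filter_hits(hits, ev, cons, dom2)
  expect_false(out2$outside_domain_ok)
  expect_false(out2$retained)

  # missing annotation: flag unknown; retained only in permissive mode
  out3 <- filter_hits(hits, ev, NULL, dom)
  expect_true(is.na(out3$conserved_ok))
  expect_false(out3$retained)
  expect_true(filter_hits(hits, ev, NULL, dom, permissive = TRUE)$retained)
})

test_that("PFM counts are exact tallies with conserved column sums", {
  one <- build_pfm("AAAAAYAAAAA")
  expect_equal(attr(one, "n_sequences"), 1L)
  expect_true(all(colSums(one) == 1L))
  expect_equal(unname(one["Y", "0"]), 1L)
  two <- build_pfm(rep("AAAAAYAAAAA", 2))
  expect_equal(unname(two["A", "-5"]), 2L)
  expect_error(build_pfm("AAAAAAAAAAA"), "centred on Y")
  expect_error(build_pfm(c("AAAAAYAAAAA", "SHORT")), "11-mers")

  # 30 windows, 18 of them with D or E at +4: tally must be exactly 18
  set.seed(2)
  base <- "AAAAAYAAAAA"
  wins <- vapply(1:30, function(i) {
    w <- strsplit(base, "")[[1]]
    w[10] <- if (i <= 18) sample(c("D", "E"), 1) else
      sample(c("A", "K", "S", "G"), 1)
    paste(w, collapse = "")
  }, "")
  pfm <- build_pfm(wins)
  expect_equal(unname(pfm["D", "4"] + pfm["E", "4"]), 18L)
  expect_true(all(colSums(pfm) == 30L))
})

test_that("charge enrichment fractions behave at the anchors and extremes", {
  wins <- vapply(1:10, function(i) "AAAAAYAAADA", "")  # D at +4 everywhere
  ce <- charge_enrichment(build_pfm(wins))
  expect_equal(ce$frac_negative[ce$position == 4], 1.0)
  expect_equal(ce$frac_negative[ce$position == 0], 0)  # anchor is Y
  expect_equal(ce$enrich_negative[ce$position == 4], 10)  # vs 0.10 background
  # uniform random windows sit near the 0.10 background
  set.seed(10)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVW", "")[[1]]
  rwins <- vapply(1:4000, function(i) {
    w <- sample(aa, 11, replace = TRUE); w[6] <- "Y"
    paste(w, collapse = "")
  }, "")
  cer <- charge_enrichment(build_pfm(rwins))
  off_anchor <- cer$frac_negative[cer$position != 0]
  p <- 2 / 19  # D,E among the 19 non-Y residues used above
  expect_true(all(abs(off_anchor - p) < 4 * sqrt(p * (1 - p) / 4000)))
})
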