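# Seeded generators emulating every experimental input the pipeline
# consumes: FP titrations (direct and competitive), fluorogenic-substrate
# rate tables, dephosphorylation progress curves, and proteomes with planted
# consensus motifs. Each generator is a deterministic function of
# (scenario, seed); the process RNG state is saved and restored.

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Construct a synthetic-assay scenario
#'
#' Bundles the ground-truth parameters and assay design of one simulated
#' experiment. Defaults mirror the packaged study conditions: 100 nM labelled
#' probe, 2/3 (direct) or 1/2 (competitive) dilution series, triplicate
#' readings with 2 mP Gaussian noise, competitive titrations at 65% probe
#' saturation.
#'
#' @param name Scenario name.
#' @param ground_truth Named list of true parameters (e.g. `probe_kd`,
#'   `kd_tight`, `kd_weak` in nM; `kcat` 1/s, `km` uM, ...).
#' @param assay_design Named list overriding design defaults
#'   (`dilution_factor`, `n_points`, `n_replicates`, `probe_conc` nM,
#'   `noise_sd` mP, `p_free`/`p_bound` mP, `top_direct` nM, `saturation`,
#'   `comp_top_factor`, `comp_dilution`).
#' @param seed Default integer seed (mandatory).
#' @return An object of class `assay_scenario`.
#' @export
assay_scenario <- function(name, ground_truth, assay_design = list(),
                           seed = 1L) {
  if (is.null(seed)) stop("a seed is mandatory")
  design <- utils::modifyList(list(
    dilution_factor = 2 / 3, n_points = 12L, n_replicates = 3L,
    probe_conc = 100, noise_sd = 2, p_free = 60, p_bound = 260,
    top_direct = 10000, saturation = 0.65, comp_top_factor = 100,
    comp_dilution = 1 / 2
  ), assay_design)
  conc <- c(design$probe_conc, design$top_direct,
            unlist(ground_truth[grepl("kd|km", names(ground_truth))]))
  if (any(unlist(conc) <= 0)) stop("all concentrations must be positive")
  if (design$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name, ground_truth = ground_truth,
                 assay_design = design, seed = as.integer(seed)),
            class = "assay_scenario")
}

#' Built-in binding scenarios
#'
#' Scenario fixtures for the phosphatase / IRS1- and CD28-peptide binding
#' experiments. Ground-truth competitor Kd pairs encode the fold enhancements
#' by +4 Ser/Thr phosphorylation: 49x (SHP2-IRS1), 19x (PTP1B-IRS1), 2x
#' (PTPRe-IRS1) and 7x (SHP2-CD28); the labelled-probe Kd equals the
#' doubly-phosphorylated IRS1 peptide Kd of the matching phosphatase.
#'
#' @return Named list of `assay_scenario` objects with ground-truth fields
#'   `probe_kd`, `kd_tight` (doubly phosphorylated peptide), `kd_weak`
#'   (pTyr-only peptide) and `fold`.
#' @export
binding_scenarios <- function() {
  mk <- function(name, probe_kd, kd_tight, fold)
    assay_scenario(name,
                   ground_truth = list(probe_kd = probe_kd,
                                       kd_tight = kd_tight,
                                       kd_weak = kd_tight * fold,
                                       fold = fold),
                   seed = 1L)
  list(
    shp2_irs1 = mk("shp2_irs1", probe_kd = 100, kd_tight = 100, fold = 49),
    ptp1b_irs1 = mk("ptp1b_irs1", probe_kd = 150, kd_tight = 150, fold = 19),
    ptpre_irs1 = mk("ptpre_irs1", probe_kd = 500, kd_tight = 500, fold = 2),
    shp2_cd28 = mk("shp2_cd28", probe_kd = 100, kd_tight = 300, fold = 7)
  )
}

#' Built-in kinetics scenarios
#'
#' Fixtures for phosphatase catalytic-apparatus mutants. `shp2_ce`: peptide
#' dephosphorylation progress curves (50 uM substrate, 25 nM wild-type
#' enzyme) with mutant turnover reduced 4-fold (H426A-like) and 40-fold
#' (D425A-like), so equal-looking curves require enzyme at 1:4:40.
#' `shp2_difmup`: fluorogenic small-molecule substrate rate assays (serial
#' 1/2 dilutions from 100 uM; enzyme 2.5 nM, or 12.5 nM for the most
#' impaired mutant) with turnover reduced 4-fold and 10-fold.
#'
#' @return Named list of `assay_scenario` objects.
#' @export
kinetics_scenarios <- function() {
  list(
    shp2_ce = assay_scenario(
      "shp2_ce",
      ground_truth = list(
        kcat_wt = 1.0, km = 200, enzyme_total = 25, substrate0 = 50,
        kcat_h426a = 1.0 / 4, kcat_d425a = 1.0 / 40
      ),
      assay_design = list(noise_sd = 2),  # additive, product-% units
      seed = 1L
    ),
    shp2_difmup = assay_scenario(
      "shp2_difmup",
      ground_truth = list(
        kcat_wt = 5, km = 30, enzyme_wt = 2.5,
        kcat_h426a = 5 / 4, enzyme_h426a = 2.5,
        kcat_d425a = 5 / 10, enzyme_d425a = 12.5,
        substrate_top = 100
      ),
      assay_design = list(noise_cv = 0.05),
      seed = 1L
    )
  )
}

#' Simulate a direct FP titration
#'
#' Receptor is varied along a serial dilution from `top_direct` against the
#' fixed labelled probe; readings are the quadratic-model polarization plus
#' additive Gaussian noise, one column per replicate.
#'
#' @param scenario An `assay_scenario` with ground truth `probe_kd`.
#' @param seed Seed (defaults to the scenario's).
#' @return A `titration_series` with `mode = "direct"`.
#' @export
gen_direct_titration <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "assay_scenario"))
  d <- scenario$assay_design
  g <- scenario$ground_truth
  if (is.null(g$probe_kd)) stop("scenario lacks ground-truth probe_kd")
  conc <- d$top_direct * d$dilution_factor^(seq_len(d$n_points) - 1L)
  frac <- fraction_bound_direct(conc, d$probe_conc, g$probe_kd)
  mu <- polarization_signal(frac, d$p_free, d$p_bound)
  readings <- .with_seed(seed, {
    mu + matrix(stats::rnorm(length(mu) * d$n_replicates, 0, d$noise_sd),
                nrow = length(mu))
  })
  titration_series(conc, readings, mode = "direct",
                   fixed_components = list(probe_total = d$probe_conc))
}

# Receptor total achieving a target bound-probe fraction at zero competitor.
.receptor_for_saturation <- function(target, probe_conc, probe_kd) {
  if (target <= 0 || target >= 1) stop("saturation must be in (0, 1)")
  f <- function(r) fraction_bound_direct(r, probe_conc, probe_kd) - target
  upper <- probe_kd * target / (1 - target) + probe_conc  # exact, no depletion cap
  upper <- upper * 2
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-12 * upper)$root
}

#' Simulate a competitive FP titration
#'
#' Receptor and labelled probe are fixed — receptor chosen numerically to hit
#' the design's probe saturation (50-80%) at zero competitor — and the
#' unlabelled competitor is varied along a serial dilution (plus a
#' zero-competitor point). Readings are the cubic-model polarization plus
#' Gaussian noise.
#'
#' @param scenario An `assay_scenario` with ground truth `probe_kd` and the
#'   chosen competitor Kd.
#' @param which Which competitor to titrate: `"weak"` (`kd_weak`) or
#'   `"tight"` (`kd_tight`).
#' @param seed Seed (defaults to the scenario's).
#' @return A `titration_series` with `mode = "competitive"`;
#'   `fixed_components` carries `receptor_total`, `probe_total` and the true
#'   `probe_kd` (replace the latter with a fitted value when exercising the
#'   full analysis chain).
#' @export
gen_competitive_titration <- function(scenario, which = c("weak", "tight"),
                                      seed = scenario$seed) {
  stopifnot(inherits(scenario, "assay_scenario"))
  which <- match.arg(which)
  d <- scenario$assay_design
  g <- scenario$ground_truth
  kd_comp <- switch(which, weak = g$kd_weak, tight = g$kd_tight)
  if (is.null(kd_comp) || is.null(g$probe_kd))
    stop("scenario lacks the required ground-truth Kd values")
  if (d$saturation < 0.5 || d$saturation > 0.8)
    stop("target probe saturation must lie in [0.5, 0.8]")
  r_total <- .receptor_for_saturation(d$saturation, d$probe_conc, g$probe_kd)
  top <- d$comp_top_factor * kd_comp
  conc <- c(0, rev(top * d$comp_dilution^(seq_len(d$n_points - 1L) - 1L)))
  bound <- .bound_probe_competitive(conc, r_total, d$probe_conc,
                                    g$probe_kd, kd_comp)
  mu <- polarization_signal(bound / d$probe_conc, d$p_free, d$p_bound)
  readings <- .with_seed(seed, {
    mu + matrix(stats::rnorm(length(mu) * d$n_replicates, 0, d$noise_sd),
                nrow = length(mu))
  })
  titration_series(conc, readings, mode = "competitive",
                   fixed_components = list(receptor_total = r_total,
                                           probe_total = d$probe_conc,
                                           probe_kd = g$probe_kd))
}

#' Simulate dephosphorylation progress curves for a mutant panel
#'
#' Noiseless curves come from [simulate_progress_curve()]; Gaussian noise is
#' added on the product-% scale and clipped to `[0, 100]`.
#'
#' @param scenario An `assay_scenario` from [kinetics_scenarios()]
#'   (`shp2_ce`-like ground truth).
#' @param times Sampling times, s.
#' @param enzyme_multipliers Named multipliers applied to the wild-type
#'   enzyme concentration per variant (e.g. `c(wt = 1, h426a = 4,
#'   d425a = 40)` for the equalized experiment). Default: all 1.
#' @param seed Seed (defaults to the scenario's).
#' @return Named list of `kinetic_trace` objects (product %).
#' @export
gen_progress_curves <- function(scenario, times = seq(0, 7200, by = 60),
                                enzyme_multipliers = NULL,
                                seed = scenario$seed) {
  stopifnot(inherits(scenario, "assay_scenario"))
  g <- scenario$ground_truth
  kcats <- c(wt = g$kcat_wt, h426a = g$kcat_h426a, d425a = g$kcat_d425a)
  kcats <- kcats[!vapply(kcats, is.null, logical(1))]
  if (is.null(enzyme_multipliers))
    enzyme_multipliers <- stats::setNames(rep(1, length(kcats)), names(kcats))
  noise_sd <- scenario$assay_design$noise_sd %||% 0
  .with_seed(seed, {
    out <- lapply(names(kcats), function(v) {
      tr <- simulate_progress_curve(kcats[[v]], g$km,
                                    enzyme_multipliers[[v]] * g$enzyme_total,
                                    g$substrate0, times)
      if (noise_sd > 0)
        tr$signal <- pmin(pmax(tr$signal +
                                 stats::rnorm(length(tr$signal), 0, noise_sd),
                               0), 100)
      tr
    })
    stats::setNames(out, names(kcats))
  })
}

#' Simulate a fluorogenic-substrate initial-rate table
#'
#' Substrate serial dilutions (1/2 from the scenario's top concentration);
#' rates from the Michaelis-Menten model with proportional Gaussian noise.
#'
#' @param scenario An `assay_scenario` from [kinetics_scenarios()]
#'   (`shp2_difmup`-like ground truth).
#' @param variant `"wt"`, `"h426a"` or `"d425a"`.
#' @param n_dilutions Number of substrate levels (default 8).
#' @param seed Seed (defaults to the scenario's).
#' @return data.frame with columns `substrate_uM`, `rate` (uM/s) and the
#'   enzyme concentration as attribute `enzyme_total`.
#' @export
gen_difmup_rates <- function(scenario, variant = c("wt", "h426a", "d425a"),
                             n_dilutions = 8L, seed = scenario$seed) {
  stopifnot(inherits(scenario, "assay_scenario"))
  variant <- match.arg(variant)
  g <- scenario$ground_truth
  kcat <- g[[paste0("kcat_", variant)]]
  enzyme <- g[[paste0("enzyme_", variant)]]
  if (is.null(kcat) || is.null(enzyme))
    stop("scenario lacks parameters for variant ", variant)
  s <- g$substrate_top * (1 / 2)^(seq_len(n_dilutions) - 1L)
  v <- mm_velocity(s, kcat, g$km, enzyme)
  cv <- scenario$assay_design$noise_cv %||% 0
  v_obs <- .with_seed(seed, v * (1 + stats::rnorm(length(v), 0, cv)))
  out <- data.frame(substrate_uM = s, rate = v_obs)
  attr(out, "enzyme_total") <- enzyme
  out
}

#' Generate a synthetic proteome with planted consensus motifs
#'
#' Background sequences are drawn i.i.d. from a stated residue composition;
#' planted motif instances (a random realisation of each pattern) overwrite
#' the background at recorded, non-overlapping positions. A truth table of
#' planted sites is returned alongside for scanner benchmarking.
#'
#' @param n_proteins Number of sequences.
#' @param length_range Integer range of sequence lengths (sampled uniformly).
#' @param planted Named integer vector: pattern string -> number of planted
#'   instances (spread round-robin across proteins).
#' @param seed Integer seed.
#' @param background Named residue frequencies (default uniform over the 20
#'   canonical residues).
#' @return List with `sequences` (named character vector) and `truth`
#'   (data.frame `protein_id`, `tyr_position`, `pattern`).
#' @export
gen_proteome_with_motifs <- function(n_proteins, length_range = c(200L, 400L),
                                     planted = integer(), seed = 1L,
                                     background = stats::setNames(
                                       rep(1 / 20, 20), .AA20)) {
  if (n_proteins < 1L) stop("need at least one protein")
  .with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    seqs <- lapply(lens, function(L)
      sample(names(background), L, replace = TRUE, prob = background))
    names(seqs) <- sprintf("synth%03d", seq_len(n_proteins))
    truth <- list()
    if (length(planted)) {
      cps <- lapply(names(planted), compile_consensus)
      names(cps) <- names(planted)
      slots <- rep(seq_len(n_proteins),
                   length.out = sum(planted))  # round-robin assignment
      k <- 0L
      for (pat in names(planted)) {
        for (i in seq_len(planted[[pat]])) {
          k <- k + 1L
          target <- slots[k]
          cp <- cps[[pat]]
          L <- lens[target]
          if (L < cp$width + 2L)
            stop("sequence too short to plant pattern ", pat)
          # realise the pattern: fixed residues kept, wildcards from
          # background, classes sampled within the class
          realiz <- vapply(cp$elements, function(el) {
            if (is.null(el)) sample(names(background), 1, prob = background)
            else if (length(el) == 1L) el
            else sample(el, 1)
          }, "")
          start <- sample(seq_len(L - cp$width + 1L), 1)
          s <- seqs[[target]]
          s[start:(start + cp$width - 1L)] <- realiz
          seqs[[target]] <- s
          truth[[k]] <- data.frame(
            protein_id = names(seqs)[target],
            tyr_position = start + cp$anchor - 1L,
            pattern = pat, stringsAsFactors = FALSE)
        }
      }
    }
    list(
      sequences = vapply(seqs, paste, "", collapse = ""),
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(protein_id = character(), tyr_position = integer(),
                   pattern = character(), stringsAsFactors = FALSE)
    )
  })
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' The packaged predicted-motif table
#'
#' Twenty-one pSer/pThr-flanked phosphotyrosine motif windows from human
#' signalling proteins with their matched consensus patterns, predicted
#' effectors and an experimental-confirmation flag, as used for validating
#' the scanner.
#'
#' @return data.frame with columns `protein`, `category`, `sequence`,
#'   `matched_consensus`, `effectors`, `confirmed`.
#' @export
shp2_motif_table <- function() {
  path <- system.file("extdata", "predicted_shp2_motifs.tsv",
                      package = "ptpkit", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$confirmed <- as.logical(tab$confirmed)
  tab
}
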