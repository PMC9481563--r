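# Workflow layer: validated run configurations, the full binding analysis
# chain (direct fit -> competitive fits -> fold change with Monte-Carlo
# uncertainty), kinetics and motif workflows, and report bundles.

.known_keys <- list(
  binding = c("scenario", "seed", "n_seeds", "mc_samples", "out_dir",
              "permissive", "log_level"),
  kinetics = c("scenario", "seed", "times", "out_dir", "log_level"),
  motif = c("fasta", "sequences", "patterns", "phospho_evidence",
            "conservation", "domain_mask", "out_dir", "permissive",
            "log_level")
)

#' Validate a run configuration
#'
#' Checks a configuration list (or YAML file) against the known keys of a
#' workflow before any computation; unknown keys are rejected.
#'
#' @param config Named list, or path to a YAML file.
#' @param workflow `"binding"`, `"kinetics"` or `"motif"`.
#' @return The validated config list, invisibly on error-free return.
#' @export
validate_config <- function(config, workflow = c("binding", "kinetics",
                                                 "motif")) {
  workflow <- match.arg(workflow)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML file")
  unknown <- setdiff(names(config), .known_keys[[workflow]])
  if (length(unknown))
    stop("unknown config key(s) for ", workflow, " workflow: ",
         paste(unknown, collapse = ", "))
  if (!is.null(config$seed) && (!is.numeric(config$seed) ||
                                config$seed != as.integer(config$seed)))
    stop("seed must be an integer")
  config
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.report_meta <- function(config, seed) {
  list(package_version = as.character(utils::packageVersion("ptpkit")),
       seed = seed, config_hash = .config_hash(config))
}

.resolve_scenario <- function(name, pool) {
  if (inherits(name, "assay_scenario")) return(name)
  sc <- pool[[name]]
  if (is.null(sc))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(pool), collapse = ", "))
  sc
}

#' Recover a Kd fold change through the full fitting chain
#'
#' Runs the complete analysis pipeline on synthetic data for one binding
#' scenario and seed: simulate and fit the direct titration of the labelled
#' probe (quadratic model), feed the fitted probe Kd into the two competitive
#' titrations (cubic model) of the weak (pTyr-only) and tight (pTyr+pSer)
#' competitors, and return the recovered Kd ratio.
#'
#' @param scenario An `assay_scenario` or a name from [binding_scenarios()].
#' @param seed Integer seed controlling all three simulated titrations.
#' @return List with `fold` (recovered kd_weak/kd_tight), `probe_fit`,
#'   `weak_fit`, `tight_fit`.
#' @export
recover_fold_change <- function(scenario, seed = 1L) {
  scenario <- .resolve_scenario(scenario, binding_scenarios())
  direct <- gen_direct_titration(scenario, seed = seed)
  probe_fit <- fit_direct_titration(direct)
  if (!isTRUE(probe_fit$converged))
    stop("direct titration fit did not converge (seed ", seed, ")")
  offsets <- c(weak = 1000L, tight = 2000L)
  fits <- lapply(stats::setNames(nm = names(offsets)), function(which) {
    series <- gen_competitive_titration(scenario, which = which,
                                        seed = seed + offsets[[which]])
    series$fixed_components$probe_kd <- probe_fit$kd  # chain, not truth
    fit <- fit_competitive_titration(series)
    if (!isTRUE(fit$converged))
      stop("competitive fit (", which, ") did not converge (seed ", seed, ")")
    fit
  })
  list(fold = fits$weak$kd / fits$tight$kd,
       probe_fit = probe_fit, weak_fit = fits$weak, tight_fit = fits$tight)
}

#' Median recovered fold change over seeds
#'
#' @inheritParams recover_fold_change
#' @param seeds Integer vector of seeds (e.g. 50 replicate simulations).
#' @return List with `median_fold` and the per-seed `folds`.
#' @export
recover_fold_median <- function(scenario, seeds = 1:50) {
  folds <- vapply(seeds, function(s) recover_fold_change(scenario, s)$fold,
                  numeric(1))
  list(median_fold = stats::median(folds), folds = folds)
}

.write_bundle <- function(report, tables, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (nm in names(tables))
    utils::write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

.fit_summary <- function(fit) {
  list(kd_nM = fit$kd, kd_se = unname(fit$std_errors[["kd"]]),
       p_free_mP = fit$p_free, p_bound_mP = fit$p_bound,
       converged = fit$converged)
}

#' Run the binding analysis workflow
#'
#' Simulates one binding scenario and runs the full direct + competitive
#' fitting chain, reporting the Kd table and the fold change with
#' Monte-Carlo uncertainty.
#'
#' @param config Named list (or YAML path) with keys `scenario` (name from
#'   [binding_scenarios()]), `seed`, optional `mc_samples` (default 5000),
#'   `out_dir` and `permissive`.
#' @return Report list with `kd_table`, `fold` (ratio + MC summary) and
#'   metadata (seed, config hash, package version).
#' @export
run_binding_workflow <- function(config) {
  config <- validate_config(config, "binding")
  if (is.null(config$scenario)) stop("config must name a scenario")
  seed <- as.integer(config$seed %||% 1L)
  mc_samples <- as.integer(config$mc_samples %||% 5000L)
  chain <- recover_fold_change(config$scenario, seed = seed)
  fold <- kd_fold_change(chain$weak_fit, chain$tight_fit, mc = TRUE,
                         n_samples = mc_samples, seed = seed)
  kd_table <- data.frame(
    curve = c("probe_direct", "competitor_weak", "competitor_tight"),
    kd_nM = c(chain$probe_fit$kd, chain$weak_fit$kd, chain$tight_fit$kd),
    kd_se = c(chain$probe_fit$std_errors[["kd"]],
              chain$weak_fit$std_errors[["kd"]],
              chain$tight_fit$std_errors[["kd"]])
  )
  report <- c(.report_meta(config, seed), list(
    scenario = if (is.character(config$scenario)) config$scenario else
      config$scenario$name,
    fits = lapply(list(probe = chain$probe_fit, weak = chain$weak_fit,
                       tight = chain$tight_fit), .fit_summary),
    fold_change = list(ratio = fold$ratio, mc_mean = fold$mc$mean,
                       mc_sd = fold$mc$sd, mc_n = fold$mc$n_samples)
  ))
  .write_bundle(report, list(kd_table = kd_table), config$out_dir)
  c(report, list(kd_table = kd_table))
}

#' Run the kinetics analysis workflow
#'
#' Simulates the fluorogenic-substrate rate tables for a mutant panel, fits
#' Michaelis-Menten parameters for each variant, and computes the
#' enzyme-equalization multiplier of each mutant against the wild type from
#' noiseless progress curves.
#'
#' @param config Named list (or YAML path) with keys `scenario` (name from
#'   [kinetics_scenarios()], default `"shp2_difmup"` for rates plus
#'   `"shp2_ce"` for equalization), `seed`, optional `out_dir`.
#' @return Report list with `mm_fits` and `equalization` multipliers.
#' @export
run_kinetics_workflow <- function(config) {
  config <- validate_config(config, "kinetics")
  seed <- as.integer(config$seed %||% 1L)
  pool <- kinetics_scenarios()
  difmup <- pool$shp2_difmup
  ce <- pool$shp2_ce
  variants <- c("wt", "h426a", "d425a")
  mm_fits <- lapply(seq_along(variants), function(i) {
    tab <- gen_difmup_rates(difmup, variants[i], seed = seed + i)
    fit_michaelis_menten(tab$substrate_uM, tab$rate,
                         attr(tab, "enzyme_total"))
  })
  names(mm_fits) <- variants
  g <- ce$ground_truth
  times <- config$times %||% seq(0, 7200, by = 60)
  wt_pars <- list(kcat = g$kcat_wt, km = g$km)
  equalization <- vapply(c("h426a", "d425a"), function(v)
    match_enzyme_concentration(wt_pars,
                               list(kcat = g[[paste0("kcat_", v)]], km = g$km),
                               g$enzyme_total, g$substrate0, times),
    numeric(1))
  mm_table <- data.frame(
    variant = variants,
    kcat = vapply(mm_fits, `[[`, 0, "kcat"),
    kcat_se = vapply(mm_fits, function(f) f$std_errors[["kcat"]], 0),
    km = vapply(mm_fits, `[[`, 0, "km"),
    km_se = vapply(mm_fits, function(f) f$std_errors[["km"]], 0)
  )
  report <- c(.report_meta(config, seed), list(
    mm_fits = lapply(mm_fits, function(f)
      list(kcat = f$kcat, km = f$km, converged = f$converged)),
    equalization = as.list(equalization)
  ))
  .write_bundle(report, list(mm_table = mm_table), config$out_dir)
  c(report, list(mm_table = mm_table, mm_fit_objects = mm_fits))
}

#' Run the motif-scanning workflow
#'
#' Scans sequences for the consensus pattern set, applies the phosphosite /
#' conservation / folded-domain filter chain when annotation tables are
#' given, and summarises retained 11-mer windows as a position frequency
#' matrix with charge enrichment.
#'
#' @param config Named list (or YAML path) with `fasta` (path) or
#'   `sequences` (named character vector); optional `patterns` (character
#'   vector of pattern strings), `phospho_evidence`, `conservation`,
#'   `domain_mask` (TSV paths or data.frames), `permissive`, `out_dir`.
#' @return Report list with `hits`, `pfm` (or NULL if no retained hits) and
#'   `enrichment`.
#' @export
run_motif_workflow <- function(config) {
  config <- validate_config(config, "motif")
  seqs <- config$sequences %||% config$fasta
  if (is.null(seqs)) stop("config must provide 'fasta' or 'sequences'")
  patterns <- if (is.null(config$patterns)) default_consensus_patterns() else
    lapply(config$patterns, compile_consensus)
  hits <- scan_sequences(seqs, patterns)
  load_tab <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    utils::read.delim(x, stringsAsFactors = FALSE)
  }
  any_annot <- !is.null(config$phospho_evidence) ||
    !is.null(config$conservation) || !is.null(config$domain_mask)
  if (any_annot || isTRUE(config$permissive))
    hits <- filter_hits(hits,
                        phospho_evidence = load_tab(config$phospho_evidence),
                        conservation = load_tab(config$conservation),
                        domain_mask = load_tab(config$domain_mask),
                        patterns = patterns,
                        permissive = isTRUE(config$permissive))
  use <- if (any_annot) hits[hits$retained %in% TRUE, , drop = FALSE] else hits
  windows <- substr(use$window, 1, 11)
  windows <- windows[!grepl("-", windows, fixed = TRUE)]
  pfm <- if (length(windows)) build_pfm(windows) else NULL
  enrichment <- if (!is.null(pfm)) charge_enrichment(pfm) else NULL
  report <- c(.report_meta(config, 0L), list(
    n_sequences = length(.as_named_sequences(seqs)),
    n_hits = nrow(hits),
    n_retained = if (any_annot) sum(hits$retained %in% TRUE) else NA
  ))
  tables <- list(hits = hits)
  if (!is.null(enrichment)) tables$charge_enrichment <- enrichment
  .write_bundle(report, tables, config$out_dir)
  if (!is.null(config$out_dir) && !is.null(pfm))
    write_pfm_tsv(pfm, file.path(config$out_dir, "pfm.tsv"))
  c(report, list(hits = hits, pfm = pfm, enrichment = enrichment))
}
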