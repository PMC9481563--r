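# ptpkit

Quantitative analysis of pSer/pThr-modulated substrate recognition by
protein tyrosine phosphatases (SHP2, PTP1B, PTPRε and relatives).

Tyrosine phosphatases select their substrates partly through residues
flanking the phosphotyrosine. For SHP2 in particular, a second
phosphorylation on a Ser/Thr at the +4/+5 position (as in the IRS1
Y632/S636 and CD28 Y191/T195 tandem sites) dramatically tightens
binding. Quantifying that effect takes a specific analysis stack —
exact binding equilibria for fluorescence-polarization (FP) titrations,
Monte-Carlo error propagation for Kd ratios, enzyme kinetics for
catalytic-apparatus mutants, and proteome-wide motif scanning for
candidate sites. `ptpkit` implements that stack as a tested, reusable R
package, together with seeded synthetic-data generators so every stage
can be exercised and validated without instrument data.

## What it computes

* **Direct FP titrations** — the ligand-depletion quadratic
  `f = ((R+L+K_d) − sqrt((R+L+K_d)² − 4RL)) / (2L)` fitted for
  `(K_d, P_free, P_bound)` by Levenberg–Marquardt
  (`fit_direct_titration()`).
* **Competitive FP titrations** — the exact three-component cubic
  equilibrium (labelled probe + unlabelled competitor for a fixed
  receptor), solved by the trigonometric real root with Newton polish
  (`solve_competitive_analytic()`) and fitted for the competitor Kd
  (`fit_competitive_titration()`), cross-checked against an independent
  bracketed mass-balance solver.
* **Kd fold changes with uncertainty** — `kd_fold_change()` plus
  Monte-Carlo propagation (`mc_ratio()`, 5000 samples per ratio by
  default) with a delta-method analytic check.
* **Enzyme kinetics** — initial rates, Michaelis–Menten fits
  (`v = k_cat·E·S/(K_m+S)`), exact integrated progress curves via
  Lambert W, exponential progress-curve summaries, and the enzyme
  multiplier that superimposes an impaired mutant's curve on the wild
  type's (`match_enzyme_concentration()` — the 1:4:40 experiment).
* **Motif discovery** — consensus scanning (`Y..M[ST]P` and friends)
  for pSer/pThr-flanked phosphotyrosines with effector labels, the
  phosphosite-evidence / conservation / folded-domain filter chain, and
  position-frequency + charge-enrichment statistics for substrate-site
  logos.
* **Docking restraints** — ensemble distance statistics
  (`center (−minus +plus)`) and a byte-stable writer/parser for
  `dist(PAIR) = C (−M + P)` tables.

## Worked example

The packaged `shp2_irs1` scenario encodes a 49-fold binding enhancement
of the doubly phosphorylated IRS1 peptide (ground-truth Kds 100 nM vs
4900 nM, probe Kd 100 nM). Simulate the assays and run the full
analysis chain:

```r
library(ptpkit)

sc <- binding_scenarios()$shp2_irs1

# direct titration of the labelled probe (quadratic model)
direct    <- gen_direct_titration(sc, seed = 101)
probe_fit <- fit_direct_titration(direct)
probe_fit
#> Binding fit (direct titration)
#>   Kd      = 95.22 +/- 4.42 nM
#>   p_free  = 54.55 +/- 4.09 mP
#>   p_bound = 259.8 +/- 0.531 mP
#>   n = 36, residual norm = 107.1 mP^2

# full chain: the fitted probe Kd feeds both competitive fits
chain <- recover_fold_change("shp2_irs1", seed = 101)
fold  <- kd_fold_change(chain$weak_fit, chain$tight_fit, mc = TRUE,
                        seed = 101)
sprintf("fold = %.2f", fold$ratio)
#> [1] "fold = 48.33"
fold$mc
#> Ratio: 48.41 +/- 2.287  (n = 5000, normal-truncated, seed 101)
```

The direct fit recovers the probe Kd (95 ± 4 nM vs the generating
100 nM); the chained competitive fits recover the 49-fold Kd ratio
(48.3 from this seed), and the Monte-Carlo summary attaches the
uncertainty an experimenter would put on the bar plot.

A thin CLI over the same functions lives at `inst/cli/ptpkit.R`:

```sh
Rscript inst/cli/ptpkit.R binding --scenario shp2_cd28 --seed 3
# [ptpkit] fold change 6.683 (MC sd 0.341)
```

## Documentation

The methods vignette (`vignettes/ptpkit-methods.Rmd`) documents the
models, their assumptions, the numerical choices (stable quadratic
form, cubic root selection, log-scale Kd fitting, overflow-safe Lambert
W), the synthetic-data designs, and known limitations.
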