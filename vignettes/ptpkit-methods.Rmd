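---
title: "Models and methods behind ptpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ptpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptpkit)
```

`ptpkit` bundles the quantitative machinery needed to study how
Ser/Thr phosphorylation next to a phosphotyrosine modulates substrate
recognition by protein tyrosine phosphatases such as SHP2: equilibrium
models for fluorescence-polarization (FP) titrations, Monte-Carlo
uncertainty for Kd ratios, Michaelis–Menten and progress-curve kinetics
for catalytic mutants, consensus-motif scanning of protein sequences,
and ensemble statistics for docking distance restraints. This vignette
explains each model, its assumptions, and the numerical and design
choices made.

## Equilibrium binding models

### Direct titrations (two components)

A direct FP titration varies the receptor (phosphatase domain) `R`
against a fixed, fluorescently labelled probe peptide `L` (100 nM by
default). With ligand depletion the bound complex is the root of a
quadratic, and the bound-probe fraction is

$$ f = \frac{(R_0+L_0+K_d) - \sqrt{(R_0+L_0+K_d)^2 - 4R_0L_0}}{2L_0}. $$

`fraction_bound_direct()` evaluates this in the algebraically
equivalent form $2R_0L_0/(S+\sqrt{S^2-4R_0L_0})$ with
$S=R_0+L_0+K_d$, which is stable when $4R_0L_0 \ll S^2$ (trace-probe
conditions), where the textbook form loses all significant digits to
cancellation.

### Competitive titrations (three components)

In a competitive titration the receptor and labelled probe are fixed —
the receptor is chosen so the probe starts 50–80% saturated — and an
unlabelled competitor peptide `C` displaces the probe. The simultaneous
equilibria

$$ R + L \rightleftharpoons RL \;(K_1), \qquad
   R + C \rightleftharpoons RC \;(K_2) $$

reduce to a cubic in the free receptor concentration.
`solve_competitive_analytic()` takes the physically valid root via the
trigonometric real-root formula (numerically safer than Cardano's
formula, which suffers catastrophic cancellation for well-separated
roots) and then polishes it with Newton steps on the receptor mass
balance to machine precision. `solve_equilibrium_numeric()` solves the
same mass balance by bracketed root finding on `[0, R_total]`; it exists
purely as an independent cross-check and the two agree to better than
1e-8 relative across twelve orders of magnitude of inputs.

### Signal model and fitting

Polarization is assumed linear in the bound-probe fraction,
`P = P_free + (P_bound - P_free) f` — the minimal model when binding
does not change fluorescence intensity. An intensity-weighted variant is
deliberately out of scope. Fits run through Levenberg–Marquardt
(`minpack.lm::nls.lm`, at most 500 iterations, `ftol` 1e-12) with three
free parameters; `Kd` is fitted on the log scale, which guarantees
positivity without an active box constraint, keeps the Jacobian columns
comparably scaled whether the Kd is 100 nM or 5 µM, and removes a
failure mode in which the optimizer could collapse the Kd onto a hard
lower bound. Standard errors come from the Hessian-based covariance at
the optimum, with the Kd column transformed back from the log scale by
the delta method. Replicates are pooled rather than averaged so the
reported standard errors reflect replicate scatter.
Starting values: for direct curves, `Kd` at the concentration of
half-maximal mean signal and the endpoints at the observed extremes; for
competitive curves the upper endpoint `P_bound` is never observed along
the displacement curve, so it is extrapolated through the known
zero-competitor bound fraction, and the Kd start is the half-displacement
concentration. Degenerate inputs (constant readings, coinciding
endpoints, all-zero competitor) are reported as non-identifiable with an
honest `converged = FALSE` rather than a spurious fit.

The probe Kd used by a competitive fit must come from a prior direct
fit; `recover_fold_change()` wires the full chain (direct fit →
competitive fits for the weak and tight peptide → Kd ratio) exactly the
way the assays are analysed in practice.

## Monte-Carlo Kd ratios

Relative binding strengths are reported as ratios of two fitted Kds.
`mc_ratio()` propagates the fit standard errors by simulation: 5000
draws per ratio by default, Gaussian with rejection of non-positive
values (fitted Kd errors are quoted as symmetric ±, so a truncated
normal is the natural default; a moment-matched lognormal is available
via `sampling_model` for coefficients of variation approaching 1, where
the truncated normal becomes untenable). Numerator and denominator are
assumed independent, as they come from separate titrations.
`delta_method_ratio()` provides the analytic cross-check: second-order
Taylor mean $R(1+cv_d^2)$ and first-order sd
$R\sqrt{cv_n^2+cv_d^2}$. The delta sd is a first-order quantity: it
undershoots the simulated sd by $O(cv^2)$ relative terms (about 3% at
cv = 0.1), which matters when comparing the two at large sample sizes.
Note also that under truncation at zero the ratio's second moment is
formally divergent, so the MC sd becomes a heavy-tailed estimator as the
denominator CV approaches ~0.2; the lognormal model has closed-form
moments at every CV and is the better choice there.

## Enzyme kinetics

Units are fixed package-wide: enzyme nM, substrate µM, time s.

* `initial_rate()` is an OLS slope over the first `n_points` samples
  (30 by default, matching standard practice for fluorogenic substrate
  assays) with `R^2` reported as a linearity diagnostic.
* `fit_michaelis_menten()` fits `v = k_cat E S/(K_m+S)` and flags the
  unidentifiable linear regime (all `S` well below `K_m`), where only
  `k_cat/K_m` is determined.
* `simulate_progress_curve()` integrates `dS/dt = -k_cat E S/(K_m+S)`
  exactly via the Lambert-W closed form
  $S(t) = K_m W\!\big(\tfrac{S_0}{K_m}e^{(S_0-V_{max}t)/K_m}\big)$.
  The W argument overflows `exp()` when `S_0/K_m` is large, so the
  implementation evaluates `W(e^x)` from the log-scale argument with a
  Newton iteration on `w + log w = x` in that regime. Product is
  expressed as % of initial substrate, matching electrophoretic
  peak-percent readouts.
* `fit_exponential_progress()` fits the empirical
  `A(1 - e^{-k_{obs}t})` summary, anchored at the origin because the
  reaction starts at zero product (an offset term is available behind a
  flag). In the first-order limit `S_0 << K_m` it recovers
  `k_obs = k_cat E/K_m`, which is why exponential fits summarise
  integrated Michaelis–Menten curves well on typical assay windows.
* `match_enzyme_concentration()` finds the enzyme multiplier that
  superimposes a mutant's progress curve on the wild type's by scalar
  minimisation over the log-multiplier. Because rate enters only through
  the product `k_cat E`, when only `k_cat` differs the minimiser is
  exactly `k_cat(wt)/k_cat(mut)` — the logic behind running impaired
  mutants at 4x and 40x enzyme to equalise their substrate-consumption
  curves (progress curves are exactly invariant under
  `(k_cat/a, aE)`, a property the test suite checks to machine
  precision).

## Motif discovery

Patterns are fixed-width short linear motifs over one-letter residue
codes, `.` wildcards and residue classes (`Y..M[ST]P`), anchored on a
phospho-acceptor tyrosine at relative position 0. The default set is the
six pSer/pThr-flanked phosphotyrosine consensus motifs with effector
labels (PI3K, GRB2, PLCg, SRC). `scan_sequences()` tests every tyrosine
of every sequence against every pattern and aggregates matches per site;
coordinates are 1-based (UniProt convention), reported windows span
-5..+9 with `-` padding that never matches. The matcher is validated
against an independent regex-based brute force on seeded random
proteomes.

`filter_hits()` applies the three-stage curation used for proteome
scans: phosphosite evidence (`n > 1` detections required, by default on
both the tyrosine and the flanking Ser/Thr of at least one matched
pattern — the stricter of the two plausible readings, adjustable via
`require_both`), conservation at least in mammals, and exclusion of
folded-domain blocks. Conservation and domain masks are consumed as
annotation tables, never computed: orthology inference and domain
prediction are delegated to external resources by design. One caveat
worth knowing: in the packaged 21-row motif table, one window
(`pctgdYMNMSPvgdsn`) matches both `Y..M[ST]P` and `Y.N.[ST]P` by the
pattern definitions, although its curated "matched consensus" entry
lists only the former; the scanner reports what the patterns match.

`build_pfm()` tallies aligned 11-mer windows (-5..+5, centre Y) into a
position frequency matrix whose columns each sum to the number of
sequences, and `charge_enrichment()` reduces it to per-position D+E and
K+R fractions with enrichment over a configurable background (uniform
0.05 per residue by default, i.e. 0.10 for a two-residue class). The
curated identities of literature substrate sites are not redistributed
with the package; the PFM operations are exercised on synthetic
stand-ins and accept any user-supplied window table.

## Distance-restraint statistics

`ensemble_distance_stats()` reduces the distances observed for one atom
pair across an ensemble of homologous structures to `center (-minus
+plus)`. The centre rule is the median (mean and reference-structure
rules are selectable) rounded half-up on a 0.1 Å grid; half-up rather
than banker's rounding so a single distance of 2.85 Å reports as 2.9.
The offsets are computed from the grid-rounded minimum and maximum so
that `center - minus` and `center + plus` equal the rounded extremes
exactly and the interval covers every (rounded) input distance; negative
offsets arising from rounding ties are clipped to zero with a warning.
`write_restraint_table()` emits `dist(PAIR) = C (-M + P)` lines in input
order with LF endings, byte-stable across platforms, and
`read_restraint_table()` inverts it exactly. Distance extraction from
structure files is out of scope: the module consumes a long-format TSV
(`pair_label`, `structure_id`, `distance_A`).

## Synthetic data: what it emulates, and what it does not

The generators reproduce the designs of the real assays: direct FP
titrations as 12-point 2/3 dilution series from 10 µM receptor against
100 nM probe, in triplicate with additive Gaussian noise (sd 2 mP);
competitive titrations with the receptor solved numerically to 65% probe
saturation and a 12-point 1/2 competitor dilution (top at 100x the
competitor Kd) plus a zero-competitor point; progress curves with
additive noise on the product-% scale clipped to [0, 100]; rate tables
with 5% proportional noise on 1/2 serial dilutions from 100 µM
substrate. Noise magnitudes are not reported quantities; these defaults
were chosen once to resemble the visual spread of triplicate FP curves
and are configuration-exposed.

The built-in binding scenarios encode the studied fold enhancements —
49x, 19x and 2x for the IRS1 Y632/S636 peptide pair against SHP2, PTP1B
and PTPRε, and 7x for the CD28 Y191/T195 pair against SHP2 — with round
ground-truth Kds (100/4900, 150/2850, 500/1000, 300/2100 nM) on the
scale of the real assays, the probe Kd set equal to the
doubly-phosphorylated peptide's Kd for the matching receptor (it is the
same peptide, carboxyfluorescein-labelled). The kinetics scenarios use a
wild-type turnover of 1 s⁻¹ with K_m 200 µM on the peptide substrate
(25 nM enzyme, 50 µM substrate) with 4-fold and 40-fold impaired
mutants, and a fluorogenic-substrate panel (k_cat 5 s⁻¹, K_m 30 µM,
2.5 nM enzyme; the severely impaired mutant at 12.5 nM and one order of
magnitude lower k_cat).

What passing round-trip tests on these data does **not** show: real FP
plates drift, show inner-filter and intensity effects, and have
correlated replicate errors; real kinetic traces have bursts, product
inhibition and instrument lag; real proteomes are not i.i.d. residue
strings. The generators make the pipeline testable end to end, not a
simulator of instrument physics.

## Problem sizes and determinism

Every stochastic component takes an explicit integer seed and restores
the caller's RNG state; reports embed the seed, a config hash and the
package version. The regression suite runs the fold-recovery chain at 50
seeds per scenario (12 concentrations x 3 replicates per curve), the
solver cross-check on 1000 random parameter sets spanning 1e-3 to 1e6
nM, confidence-interval coverage on 200 simulated titrations, and
scanner equivalence on dozens of simulated proteins — sizes chosen so
the whole suite completes in a few minutes on a laptop while keeping the
Monte-Carlo margins meaningful.

## Known limitations

* No global multi-curve fitting with shared endpoints; each titration is
  fitted independently, and the probe Kd is propagated as a point value
  (not resampled) into competitive fits.
* No anisotropy/polarization conversion or plate-reader file parsing;
  inputs are plain CSV/TSV.
* The delta-method sd is first-order and should not be used as a
  precision reference for the MC sd beyond cv ≈ 0.1 (see above).
* Restraint statistics assume a single representative per structure; no
  superposition or outlier rejection is performed.
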