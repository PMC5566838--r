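---
title: "Measuring methane metabolism with monodeuterated methane: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring methane metabolism with monodeuterated methane: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch3drates)
```

## The measurement principle

Methanotrophic metabolisms begin by breaking a C–H bond of methane.
When the headspace methane is partly monodeuterated (CH₃D), some of the
mobilised hydrogen atoms that end up in water-exchangeable intermediates
are deuterium, and the aqueous D/H ratio rises in proportion to the
amount of methane activated. Because water is an enormous, well-mixed
hydrogen reservoir (111 mol of H atoms per liter), tiny molar amounts of
released deuterium produce measurable ratio changes, and abiotic
methane–water hydrogen exchange is negligible on experimental
timescales — killed controls hold a constant D/H over months. The
aqueous D/H ratio is therefore a proxy for *methane activation*,
complementary to ¹⁴CH₄ radiotracing, which quantifies *complete
oxidation* of methane carbon to inorganic carbon.

`ch3drates` implements both calculations and the statistics that link
them, in five analysis modules (instrument processing, CH₃D rates,
radiotracer rates, interpretation, solubility) plus a forward simulator
and a thin pipeline/CLI layer.

## From raw injections to calibrated D/H

A liquid water isotope analyzer measures each water sample as four
rounds of ten 700-nl injections. Two instrument artifacts must be
handled before the numbers are usable:

* **Memory carry-over.** Early injections of a round partially re-read
  the previous analyte. The remedy is positional: only the last five
  injections of each round are used (`qc_filter()`, `keep_last = 5`).
  Rounds shorter than the window keep all their injections — the rule
  discards a fixed-length contaminated head, it is not proportional.
* **Instrument excursions.** Injections acquired while the internal
  temperature changed faster than 0.3 °C h⁻¹, or while cell pressure
  was rising, are excluded outright. Records lacking these diagnostic
  columns are treated as passing, with a warning, because not all
  instrument exports carry them. An analyte losing *every* injection
  raises an error rather than vanishing silently.

Scale normalisation uses two water standards of known δD (the defaults
bracket typical samples at +0.5 ‰ and −73.4 ‰ VSMOW) measured
alongside the samples. To absorb drift, the run is partitioned into
consecutive 40-injection segments and a fresh two-point linear map from
measured to known δD is fitted in each
(`build_calibration_segments()`). Segment boundaries count *all*
injections (standards included), matching the operational rule of
re-standardising after every 40 injections. Within a segment a
standard's value is the mean of its retained injections, so the
calibration reproduces each standard's segment mean exactly (the test
suite asserts this to 1e-12). Calibration is applied to δ values rather
than raw ratios; at these enrichments the two differ negligibly, and δ
is what the instrument reports.

Conversion between δD and absolute ratio uses the VSMOW reference
ratio, R_VSMOW = 155.76 × 10⁻⁶, the standard reference value; it is an
argument everywhere it appears. Per-analyte summaries report the mean
and standard error (n−1 variance, sd/√n) of the calibrated per-injection
ratios; a single-injection analyte gets SE 0 by convention plus a
warning, since no dispersion estimate exists.

## The CH₃D rate calculus

For an incubation with water volume $V_w$ (L), inoculum volume $V_i$
(cm³) and CH₃D headspace fraction $f$:

$$H = 111 \, V_w, \qquad
D_{new} = \left[(D/H)_{T2} - (D/H)_{T1}\right] H, \qquad
C = 4\, D_{new}, \qquad
C_{corr} = C / f,$$

$$R_{CH_3D} = C_{corr} \times 10^9 / (t \, V_i)
\quad \text{(nmol cm}^{-3}\text{ d}^{-1}).$$

Choices worth stating explicitly:

* **The stoichiometric factor 4** assumes exactly one of the four
  methane hydrogen positions reaches water per activated molecule, the
  end-member that maximises the consumption estimate (the deuterium sits
  at one of four positions, so observed D undercounts activation by 4).
  If $n$ hydrogens exchange, the correct factor is $4/n$; the factor is
  a parameter of `methane_activated()` and `chd_rate_series()` because
  the end-member is not appropriate for every metabolism.
* **Fractionation factors are not applied** — isotope effects for the
  relevant enzymatic steps are not well constrained. A pass-through
  multiplier `alpha` (default 1) exists purely for sensitivity analysis.
* **The constant-inventory approximation** $H_{T2} \approx H_{T1}$ is
  the default. Removed-and-replaced sampling aliquots can optionally be
  book-kept exactly (`sampling_replacement_adjust(mode = "exact")`),
  crediting the deuterium carried away by each aliquot
  ($V_{aliquot} \times 111 \times (D/H - baseline)$ mol) back to the
  cumulative series; replacement medium is assumed to carry background
  D/H because it is pre-equilibrated with gas, which does not abiotically
  alter water D/H. For ml-scale aliquots from tens of ml the correction
  is a ~10⁻³ relative effect.
* **Time units.** Series are in hours (sampling resolution); the rate
  conversion divides by days only inside `rate_chd()` /
  `chd_rate_series()`, since rates are conventionally reported per day.
* **Interval convention.** Rates default to cumulative-from-T₀
  (consistent with "maximum moles consumed"); consecutive-interval rates
  are available via `intervals = "consecutive"`.
* **Negative rates are never clamped.** After killed-control
  subtraction, sub-zero scatter is real information about the noise
  floor; suppressing it would bias replicate means upward.

Killed-control subtraction takes the mean over control replicates and
combines its SE with the sample SE in quadrature; replicate aggregation
uses mean and sd/√n with n−1 variance throughout.

## Radiotracer rates

The ¹⁴CH₄ route partitions recovered label between combusted residual
methane and acidified oxidation product:

$$R_{^{14}C} = \frac{^{14}CO_2}{^{14}CH_4 + {}^{14}CO_2}
  \times \frac{CH_4^{initial}}{V_i \, t}.$$

Only the activity *ratio* enters, so the rate is independent of the
dosed specific activity, and using the initial methane inventory keeps
methanogenesis during the incubation from contaminating the estimate.
The denominator volume is the inoculum (initial sediment, rock or
culture) volume, the same denominator the CH₃D rate uses. The two
combustion vials are summed on input; an optional recovery correction
(98% CO₂ recovery) exists but defaults to off, since the rate equation
is conventionally applied to raw activities. Initial methane comes
either from GC quantification — a two-point response-to-ppm line through
the 10/100 ppm standards, not forced through the origin, with a warning
on extrapolation — plus ideal-gas conversion (`headspace_moles()`), or
as a declared value.

## Interpreting the D/¹⁴C tracer ratio

`tracer_ratio()` divides the CH₃D-derived rate by the ¹⁴C-derived rate
(amounts are converted to rates first when observation times differ).
Its SE uses first-order delta-method propagation assuming independent
errors — the two tracers are measured on different instruments, and no
joint error model is available. Ratios are stored at full precision and
conventionally reported at two decimals.

Two hydrogen-exchange readings are implemented verbatim as separate
models, because the two metabolisms motivate different mappings:

* *activation-stoichiometric* (reverse methanogenesis): ratio $r$ ⇒
  $n = r$ hydrogens enter water-exchangeable intermediates per fully
  oxidized methane.
* *full-oxidation-complement* (aerobic methanotrophy): all four
  hydrogens of a catabolised methane are exchangeable, so a ratio below
  4 reflects assimilatory carbon diversion and $n = 4/r$.

The models coincide only at $r = 2$ (e.g. at $r = 1.5$ they give 1.5
and 2.67 respectively); the package makes no attempt to reconcile
them — the discrepancy is a genuine open question of the underlying
biochemistry, and the test suite documents it. Implied $n > 4$ is
capped at 4 with a warning rather than an error: such values diagnose
model violation, which the `capped` flag preserves.

Back-flux bounds: with pure CH₃D headspace, a rise $\Delta$ in the CH₄
headspace fraction over the incubation indicates back-reaction. If only
the methane-activating enzyme (Mcr) reversed, the re-formed methane is
$4\Delta$ (the returned hydrogen is deuterium only 1 time in 4); if the
whole pathway reversed, it is $\Delta$. Both are scaled by the fraction
of methane not yet fully oxidized, giving
$[\Delta(1-\phi_{ox}),\ 4\Delta(1-\phi_{ox})]$, an envelope whose
upper/lower ratio is exactly 4. Isotope effects and methanogenic CH₄
production are deliberately neglected, consistent with the measurement's
own conventions.

## Solubility accounting

Dissolved tracer concentrations come from Henry's law in the
concentration/pressure convention (mol m⁻³ Pa⁻¹, so k × Pa is directly
mM). The adjustment for temperature and salinity uses the standard
forms — van 't Hoff for temperature,
$k = k_{ref}\exp[B(1/T - 1/T_{ref})]$, and Setchenow salting-out,
$10^{-k_s S}$ — with every parameter user-configurable
(`henry_params()`); a pre-adjusted constant can also be passed straight
to `dissolved_concentration()`. The bundled CH₄ defaults
(k_ref = 1.4 × 10⁻⁵ mol m⁻³ Pa⁻¹ at 298.15 K, B = 1750 K,
k_s = 0.13 L mol⁻¹) are standard-compilation values. These units were
adopted because they make a seep-conditions constant of 5.7 × 10⁻⁶
reproduce 1.1 mM under a 2 × 10⁵ Pa methane headspace.

## The forward simulator

`simulate_experiment()` generates every input stream the pipeline
consumes, from a known ground truth:

1. **Consumption**: linear (constant volumetric rate) or logistic
   (growth-curve-like) cumulative activation, deterministic.
2. **Deuterium release**: each activated methane is CH₃D with
   probability $f$, and an activated CH₃D releases its deuterium with
   probability $n_{true}/4$ (times `alpha`). The generator uses the
   expectation directly — at ~10¹⁹ molecules the binomial noise is
   irrelevant — while an independent per-molecule Bernoulli sampler
   lives in the test suite as the oracle, and the two agree within
   Monte-Carlo error at 10⁶ molecules.
3. **Instrument acquisition**: rounds of ten injections; injection $i$
   reads $(1-m_i)\,\delta_{analyte} + m_i\,\delta_{previous}$ with
   geometrically decaying carry-over
   $m_i = m_0\, d^{\,i-1}$ (defaults $m_0 = 0.3$, $d = 0.5$ — the
   functional form is a modeling choice; only the last-five remedy is
   operationally specified), plus linear drift per injection and
   Gaussian noise. Runs are laid out in 40-injection blocks of four
   rounds (both standards, then two sample rounds), so every
   calibration segment contains both standards.
4. **Radiotracer counting**: expected oxidized fraction
   $\phi \times consumed(t)/CH_4^{initial}$, multiplicative counting
   noise, residual activity split across two combustion vials.

Every stochastic stage derives from the config seed, so truth is
recoverable from config + seed alone, and a killed-control twin (zero
consumption, same noise model) accompanies every experiment.

Under this generative model the factor-4 analysis recovers
$n_{true} \times$ the true rate (exactly, in the noise-free limit — the
suite asserts 1e-9 relative), and the simulated tracer ratio converges
to $n_{true}/\phi$. Exact rate recovery requires the matched analysis
factor $4/n_{true}$; this is the quantitative content of calling
factor 4 a maximum-consumption end-member.

**Default study conditions.** The default config is an anoxic
seep-style incubation: 10 cm³ consolidated inoculum, 20 ml water,
30 ml headspace at 2 × 10⁵ Pa methane (50:50 CH₃D:CH₄), 4 °C, five
samplings over 8 days, label dose 52 kBq, baseline D/H 1.40 × 10⁻⁴ (a
typical killed-control reading, deliberately not VSMOW). The
per-injection noise default of 0.9 ‰ is back-calculated from
killed-control replicate precision of ~3.1 × 10⁻⁸ SE on the mean ratio
over 20 retained injections; counting CV defaults to 2%, ordinary for
10-minute scintillation counts.

**Parameter recovery.** The recovery study uses culture-style geometry
(9.44 ml medium and inoculum volume — the small water volume
concentrates released deuterium), pure-CH₃D headspace, seven samplings
over 480 h (a slow-growing-culture schedule), $n_{true} = 2$ analysed
with the matched factor, and true rates drawn log-uniformly over
10–1000 nmol cm⁻³ d⁻¹ across 20 seeds. Median relative error is ~1%,
comfortably within the 5% the suite demands, and the whole study runs
in a few seconds.

**What the simulator does not emulate** — and hence what passing tests
do *not* establish about real data: gas–liquid equilibration kinetics
(slow dissolution would depress early-time rates), methane depletion and
product inhibition, spatial heterogeneity of sediments, pressure effects
(different pressures enter only as different true rates), NMR spectral
acquisition (isotopologue fractions are taken as input), and any
coupling between the D/H noise and sample enrichment. Recovery results
certify the calculus and the QC/calibration chain, not the field
accuracy of the method.

## Numerical and degenerate-input conventions

* Two-point fits (VSMOW calibration, GC) are exact interpolations;
  with more than two standards/anchors they fall back to ordinary least
  squares.
* A calibration segment missing a standard, an analyte with zero
  retained injections, zero total ¹⁴C activity, a zero ¹⁴C rate in a
  ratio denominator, and nonpositive volumes/times/fractions all raise
  errors naming the offending object; they are never silently patched.
* Single-replicate aggregation and single-injection summaries return
  SE 0 with a warning.
* δD ≤ −1000 ‰ is rejected as nonphysical; D/H round-trips through δD
  are exact to 1e-10 ‰.
* The pipeline (`run_pipeline()`) is deterministic given inputs and
  config; QC exclusions are logged exactly once each with the rule that
  fired.

## Known limitations

* The two exchange models disagree away from ratio 2 by construction;
  the package reports both rather than adjudicating.
* Observed tracer ratios spanning 1.5–2.1 cannot all be generated by a
  single $(n, \phi)$ pair under the simulator's generative model; the
  simulator exposes that tension for exploration instead of resolving
  it.
* Tracer-ratio SEs assume independent errors between methods.
* Back-flux bounds neglect isotope effects and methanogenesis, as the
  underlying calculation prescribes.
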