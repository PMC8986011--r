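---
title: "Habitat use, preference and niche breadth from seasonal tick surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat use, preference and niche breadth from seasonal tick surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickhab)
```

## The design and its assumptions

`tickhab` analyses a *paired used/available* habitat design: a study area
is partitioned into `k ≥ 2` discrete habitats with known areas `A_i`, and
free-living tick stages are captured within each habitat by CO₂ traps and
cloth-drag transects over one or more seasons. The inference compares
observed **use** — the proportion of captures per habitat,
`r_i = O_i / N` — against **availability**, the proportion of area,
`p_i = A_i / ΣA`. Preference is a disproportion of use over availability;
avoidance is the reverse; equality is plain use.

The assumptions this entails, and which the synthetic generator makes
explicit, are:

- captures within a group-season are a multinomial sample of size `N`
  over habitats (individuals are exchangeable; no spatial structure
  within a habitat);
- sampling effort is comparable across habitats, so capture proportions
  estimate use; collection methods are pooled for inference (method
  efficiency differences are treated as composition-level descriptives,
  not selection);
- availability is the mapped area, identical across seasons unless an
  explicit per-season override is supplied.

## Statistics implemented

**Adequacy.** The G statistic `2 Σ O_i ln(O_i/E_i)` and Pearson
`X² = Σ (O_i−E_i)²/E_i` against `E_i = N p_i`, both on `k−1` degrees of
freedom, plus the Cherry rule (`min N p_i > 5` and `min N(1−p_i) > 5`)
as a yes/no adequacy gate. Cells with `O_i = 0` contribute zero to G (the
`x ln x → 0` limit); an expectation of zero alongside a positive count is
an error, since availability is strictly positive by construction.

**Preference indices.** Ivlev electivity `(r−p)/(r+p)` (preference iff
positive); Jacobs' D `(r−p)/(r+p−2rp)` binned into strong/moderate
avoidance, indifference, neutral and strong selection; Manly's alpha
under constant resources, `(r_i/p_i)/Σ_j(r_j/p_j)` (preference iff
`α > 1/k`); Bailey simultaneous confidence intervals; and Duncan's index
with the published decision threshold of 0.3.

**Consensus.** A habitat is *preferred* when at least 3 of the 5 indices
signal preference (neutral or strong selection counts as a signal for
Jacobs' D), *avoided* when Jacobs' D falls in an avoidance bin and no
index signals preference, else *used*. A habitat with zero captures in a
season gets the per-index label `absent` (rendered "—"), and the
consensus call *avoided*: zero use against strictly positive availability
is the strongest possible disproportion, and Jacobs' D is −1 there. The
published label set has no separate "absent" consensus level, so this is
a deliberate design choice rather than an interpolation of the source
tables.

**Niche breadth.** Shannon `H = −Σ r ln r` in nats with `H_std = H/ln k`;
Levins `B = 1/Σ r²` with `B_std = (B−1)/(k−1)` and `B_mod = B/k`; the
Ivlev amplitude `Σ|E_i|` with inverted orientation (0 = broadest).
Natural logarithms are used throughout: the bundled survey's printed
breadth cells are reproduced with `ln` and not with log₂ or log₁₀.
Zero-use habitats stay in `k` for normalisation — a stage found in 2 of
4 habitats is narrow relative to what was available, which is exactly
what the bundled wet-season larvae cell (0.32, not 0.64) encodes.

**Growth chain.** `growth_chain()` chains the wet/dry decline ratio with
the females→larvae rebound ratio into a net annual balance, with the
stationarity assumption (next year's larvae = this year's observed
larvae) exposed as an explicit argument rather than baked in.

## Numerical and display conventions

- **Rounding** for table reproduction is *half away from zero* (base R's
  `round()` is banker's): preference indices to 1 dp, breadth indices to
  2 dp, shares to 1 dp, sex ratio to 3 dp.
- **The growth chain truncates.** The source arithmetic for the seasonal
  chain truncates rather than rounds its ratios (266/6733 = 0.0395…
  is reported as 0.039, and 2533/77 = 32.896… as 32.89). In
  `rounding = "table"` mode the chain therefore truncates the decline to
  3 dp and the rebound to 2 dp before multiplying, and truncates the
  product to 2 dp, reproducing 0.039 × 32.89 = 1.28 and the 28% net
  gain; `rounding = "full"` keeps exact ratios, for which
  `R_net = R_decline × R_rebound` holds to machine precision.
- **Jacobs bins.** The published bin edges leave the gaps (−0.26, −0.25)
  and (0.25, 0.26) uncovered; values in a gap are assigned to the
  adjacent, *stronger* bin (moderate avoidance / neutral selection), and
  the strong bins are closed at ±0.5.
- **Bailey intervals.** The source prints only the expected counts, not
  interval bounds, so the interval construction follows the conventional
  use-availability form: Bonferroni-adjusted simultaneous binomial
  intervals on each use proportion, normal approximation with z at
  `α/(2k)` and a ±1/(2N) continuity correction, scaled to counts. It is
  validated at the decision level (preference / use / no preference)
  against the published bold/plain marking, which it reproduces for
  every dry-season cell tested.
- **Duncan's formula is a configuration point.** No candidate formula
  (forage ratio, `r/(r+p)`, area- or effort-normalised variants)
  reproduces every published Duncan magnitude, and the source does not
  state one. The default, `r_i/(k p_i)` (forage ratio with parity at
  `1/k`), reproduces the published *decisions* at the 0.3 threshold;
  magnitudes are not asserted anywhere, and `duncan_index(formula=)`
  accepts a replacement.
- **Wet-season availability override.** The bundled survey's wet-season
  preference columns were evidently computed against an availability
  vector that differs from the area-derived one; its provenance is not
  stated in the source. The package ships it as
  `amblyomma_wet_availability`, back-derived from the printed expected
  counts (41.1, 175.0, 36.4, 13.5)/266, and treats it strictly as an
  explicit override: nothing in the package guesses where it came from,
  and area-derived availability remains the default for both seasons.
- The adequacy table's unexplained "estimation error" column and the
  power output of the original point-and-click tool are not implemented;
  neither has a recoverable definition.

## The synthetic generator: what a green test establishes

`simulate_survey()` draws, for each group-season, a multinomial
allocation of the configured total `N` over habitats with probabilities
`π_i ∝ w_i p_i`, where `w_i > 0` is a per-unit-area selection weight
(`w ≡ 1` is no selection), then splits each habitat count binomially
into trap vs transect with a selection-neutral trap fraction `q`
(default 0.7; the bundled scenario uses the observed dry-season fraction
4981/6733 ≈ 0.74). Under this model Manly's alpha estimates `w/Σw`, so
`recovery_experiment()` — repeated simulation, re-estimation, and
comparison against the generating truth — is a meaningful consistency
check of the full pipeline, not a tautology.

The bundled scenario (`amblyomma_sim_config()`) is the stated world of
the case study: the four habitats with their areas, the observed
per-stage totals (dry 6,733 → wet 266, an order-of-magnitude crash),
selection weights equal to the observed per-stage selectivity ratios
`r/p` — strong selection for the small king-grass crop, avoidance of the
large riparian forest — and a floor weight of 10⁻³ for habitats a stage
never used, so wet-season immature zeros arise with high probability
rather than by construction.

What the generator does **not** emulate: spatial clustering within
habitats, trap-level overdispersion, tick development and diapause,
host-mediated movement between habitats, and weather-driven activity.
A green recovery test therefore establishes that the estimators are
consistent *under the multinomial selection model* — it says nothing
about robustness to spatial or temporal structure the model omits.

## Known limitations

- Inference is at the pooled-profile level; there is no per-trap or
  spatially explicit selection model, mirroring the design the package
  implements.
- The Bailey decision rule inherits the normal approximation; for very
  small `N p_i` its bounds are crude (the Cherry flags exist precisely
  to mark that regime).
- The consensus rule weights all five indices equally; indices are
  correlated (Ivlev and Jacobs' D share a numerator), so "3 of 5" is a
  convention, not a calibrated error rate.
- The growth chain is a two-ratio accounting identity under a
  stationarity assumption, not a stage-structured demographic model; it
  quantifies the source's persistence argument, nothing more.
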