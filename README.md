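# tickhab

Use/availability analysis for seasonal field surveys of free-living
(off-host) tick stages across discrete habitats.

Vector ticks such as *Amblyomma mixtum* quest for hosts in pastures, crops
and forest fragments; knowing which habitats a population *prefers* (uses
disproportionately to their area), merely *uses*, or *avoids* is what turns
a capture table into a control strategy. `tickhab` implements the standard
resource-selection toolkit for the paired used/available design at the
population level:

- **Availability vs use.** Each habitat's availability is its share of the
  study area, `p_i = A_i / ΣA`; observed use is the share of captures,
  `r_i = O_i / N`. Expected use under no selection is `E_i = N p_i`.
- **Sample adequacy and goodness of fit.** Log-likelihood-ratio
  `G = 2 Σ O_i ln(O_i/E_i)`, Pearson `X² = Σ (O_i−E_i)²/E_i` (both
  `df = k−1`), and the Cherry criterion (`min N p_i > 5`,
  `min N(1−p_i) > 5`).
- **Five preference indices with decision rules and a consensus call.**
  Ivlev electivity `(r−p)/(r+p)`; Jacobs' D `(r−p)/(r+p−2rp)` with its
  avoidance/indifference/selection bins; Manly's alpha (constant
  resources) `(r/p)/Σ(r/p)` with parity at `1/k`; Bonferroni-simultaneous
  Bailey confidence intervals; Duncan's index (configurable formula,
  threshold 0.3). A habitat is *preferred* when ≥ 3 indices signal
  preference, *avoided* when Jacobs' D signals avoidance and nothing
  signals preference, otherwise *used*.
- **Five niche-breadth statistics.** Shannon `H = −Σ r ln r` (nats) and
  `H/ln k`; Levins `B = 1/Σ r²`, standardized `(B−1)/(k−1)` and modified
  `B/k`; the Ivlev amplitude `Σ|E_i|` (inverted orientation: 0 is
  broadest).
- **Seasonal growth chain.** Decline `R = n_wet/n_dry`, rebound
  `R = larvae_next_dry / females_wet`, and their product as the net annual
  balance.
- **Synthetic surveys.** A multinomial generator with per-unit-area
  selection weights (`π ∝ w·p`), a selection-neutral trap/transect split,
  and a parameter-recovery harness: under this model Manly's alpha
  estimates the normalised weights, so recovery of `α` is an end-to-end
  consistency check of the whole pipeline.

The package bundles the survey it was built around (a four-habitat
tropical agroecosystem: cocoa crop, riparian forest, star grass paddock,
king grass crop; 6,733 dry-season and 266 wet-season captures) as
plain-CSV fixtures, so every number below is reproducible offline.

## Worked example

```r
library(tickhab)

sv   <- amblyomma_survey()          # bundled areas + counts
p    <- availability(sv$habitats)   # 0.10358 0.77855 0.09498 0.02289
prof <- use_profile(sv$counts, "all", "dry")

g_test(prof$O, expected_use(prof, p))$G
#> [1] 14838.43        # >> chi-square(3): use is far from availability

round(manly_alpha(prof$r, p), 3)
#>         Cocoa Crop    Riparian Forest Star Grass Paddock    King Grass Crop
#>              0.099              0.014              0.064              0.822

consensus(preference_report(prof, p))
#>   group season            habitat votes     label
#> 1   all    dry         Cocoa Crop     4 preferred
#> 2   all    dry    Riparian Forest     0   avoided
#> 3   all    dry Star Grass Paddock     3 preferred
#> 4   all    dry    King Grass Crop     5 preferred

growth_chain(6733, 266, 77, 2533)
#> Seasonal decline R = 0.039 (loss 96.1%); rebound R = 32.89;
#> net R = 1.28 (+28%)
```

The tiny King Grass crop (2.3% of the area but 41% of the captures) drives
`α = 0.822` — strong selection; the large riparian forest is used far
below its availability and is called avoided. Despite a 96.1% wet-season
crash, the chained seasonal ratios imply a 28% net annual gain, consistent
with the population persisting year over year.

The full pipeline, report files included:

```r
cfg <- analysis_config(areas = amblyomma_files()$areas,
                       counts = amblyomma_files()$counts,
                       rounding = "table", out_dir = "reports")
run_analysis(cfg)   # use_availability/adequacy/preference/consensus/
                    # breadth/growth .csv + summary.txt
```

or from the shell via `exec/tickhab`:

```sh
Rscript exec/tickhab analyze --areas areas.csv --counts counts.csv \
    --rounding table --out reports
Rscript exec/tickhab simulate --config sim.cfg --seed 42 --out counts.csv
```

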