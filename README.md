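# mangrovehm

Gap-model growth of mangrove stands under heavy-metal stress.

Planted *Rhizophora apiculata* forests — the Can Gio mangrove in southern
Vietnam is the motivating case — retain heavy metals from contaminated
sediment in their roots, and are damaged by the same pollution once tissue
burdens pass tolerance thresholds. Because such plantations are
monospecific and of known age, an ordinary plot inventory doubles as a
long-term growth experiment. `mangrovehm` is for ecologists and
ecotoxicologists who want to quantify that trade-off: it estimates how
salinity, tree density, ground elevation and root metal burden jointly
reduce growth, and projects stand trunk biomass under alternative
pollution loads.

## The model

Diameter at breast height evolves by the Botkin (JABOWA) growth equation

    d(dbh)/dt = Gopt · dbh (1 − dbh·H / (Dmax·Hmax))
                / (2b1 + 3b2·dbh − 4b3·dbh²) · MUL

with height coupled as `H = b1 + b2·dbh − b3·dbh²` and trunk biomass
`Biom = a1·dbh^c1`. The multiplier `MUL ∈ [0, 1]` is a product of

* decreasing sigmoids in salinity and tree density,
  `g(x) = (1−a0)/(1+e^{d(x−tr)}) + a0`,
* a rise–plateau–fall elevation response (zero below a minimum viable
  elevation), and
* a hormetic two-threshold dose–response in root metal concentration,
  `P(x) = (1 − e^{−(x/th1)^α1}) · e^{−(x/th2)^α2}` — growth is stimulated
  by dose below `th1` and suppressed beyond `th2`.

Because the equation is separable under a constant multiplier, the
lifetime growth rate `G = Gopt·MUL` implied by a plot record
`(dbh0, dbh_age, age)` is recovered exactly by one quadrature
(`extract_G()`); response-function parameters are then estimated from the
extracted rates by bounded multi-start nonlinear least squares
(`fit_multipliers()`). A cohort-based raster simulator (`run_scenario()`)
projects the plantation period 1978–2020 under scenarios SC0 / SC0P1 /
SC0P2 (no, observed, doubled chromium load).

## Worked example

The 11-site field survey ships with the package (iron, unpublished for
these sites, is provided as a clearly labelled synthetic column so
enrichment factors can be computed end to end):

```r
library(mangrovehm)
sv <- cangio_survey(with_synthetic_fe = TRUE)
soil <- sv$hm[sv$hm$compartment == "soil" & sv$hm$metal != "Fe", ]
hm_summarize(soil, by = "region")
#>   region metal n      mean         sd   min    max
#> 1 CanGio    Cr 6  4.380000  0.3866264  3.76   4.96
#> 3 CanGio    Cu 6 72.233333  6.2866833 64.51  80.04
#> 5 CanGio    Ni 6  3.008333  0.2769416  2.63   3.31
#> 2 ThiVai    Cr 5 16.348000  3.8993166 12.39  21.14
#> 4 ThiVai    Cu 5 83.762000 29.7852207 60.40 134.03
#> 6 ThiVai    Ni 5  9.298000  2.4770688  5.82  12.01
```

Soil metal loads are higher in the industrially impacted Thi Vai region
(Cr 16.3 vs 4.4 mg/kg). Against the continental-shale background, copper
is anthropogenically enriched at every site but one:

```r
subset(enrichment_factor(sv$hm), metal == "Cu" & class != "natural")$site_id
#> "NP1" "DK4" "DK6" "DK7" "DK8" "NP2" "DN2" "M5" "M3" "M1"   # 10 of 11
```

Growth-rate extraction inverts the growth equation per plot; at site NP1
(mean dbh 18.62 cm at age 26) the lifetime rate is

```r
sp <- species_params()
extract_G(0.5, 18.62, 26, sp)
#> [1] 268.4
pl <- extract_G_plots(cangio_survey()$plots, sp)
cor(pl$G, pl$salinity)
#> [1] -0.8
```

i.e. growth declines strongly along the salinity gradient. The combined
multiplier at the most stressed surveyed site (salinity 17.1 ppt, 17
trees/100 m², root Cr 5.24 mg/kg) is

```r
mp <- default_multiplier_params()
combined_mul(env_conditions(salinity = 17.1, density = 17,
                            elevation = 0.1, pollutant = c(Cr = 5.24)), mp)
#> [1] 0.1652084
```

— that stand grows at ~17% of the optimal rate. The full pipeline
(synthetic survey → G extraction → stratified 76/132 split → fit →
hold-out validation) and the three-scenario raster projection are
demonstrated in the vignette; a thin command-line wrapper for the
simulator is in `inst/scripts/simulate.R`:

```sh
Rscript inst/scripts/simulate.R --scenario SC0P1 --seed 42 --out runs/p1
```

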