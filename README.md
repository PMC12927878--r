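# rivermacro

Quantitative macroecology of bacterioplankton along large rivers.

A litre of river water spends days to weeks travelling from headwater to
mouth. During that journey its bacterial community produces biomass,
divides, and is progressively replaced. `rivermacro` turns routine survey
measurements — total cell counts (*TCC*), bulk bacterial secondary
production (*BSP*, µgC l⁻¹ h⁻¹), mean cell volumes, and 16S rRNA ASV
tables — into the quantities that describe those dynamics on a common
axis, cumulative **water travel time** (WTT):

- **Production calculus.** Per-cell production
  *BSP*_c = *BSP*·10⁹/*TCC*; biomass from cell volume; division rates
  *CD* = *BSP*_c/*mBM*_c and doubling times 1/*CD*_d; cumulative doubling
  events *CD*_d·*tt*_cum; segment-wise cell production
  *aCP*_h = mean(*BSP*)·10⁹/*mBM*_c,up and its whole-river sum *CP*_tot;
  the standing-stock ratio *CP*_tot/median(*TCC*); and the conversion of
  per-cell production slopes into carbon atoms cell⁻¹ h⁻¹ per travel-hour
  (× *N*_A/*M*_C).
- **Diversity engine.** Multinomial rarefaction (50 repetitions, averaged,
  rounded half away from zero), observed-ASV richness, Bray–Curtis
  dissimilarity, and the partition of Sørensen beta diversity into Simpson
  **turnover** (replacement) and **nestedness** (loss):
  β_sim = min(b,c)/(a+min(b,c)), β_sor = (b+c)/(2a+b+c),
  β_nes = β_sor − β_sim — pairwise, between consecutive sites, and
  whole-river (endpoint or Baselga multiple-site), plus persistence of
  headwater phylotypes downstream.
- **Trend models.** OLS slopes ± SE with adjusted R², backward-selection
  multiple regression (AIC or α removal), PCoA/NMDS ordination with
  permutation-tested environmental vector fitting, and the
  discharge-ratio richness model (slope per discharge doubling via
  log₂ ratios).
- **Phylotype growth.** Selection filters (100-fold ratio, 1% maximum,
  20-sample prevalence), absolute abundances (relative × *TCC*),
  penalized-spline trajectories over travel time with derivative series,
  extreme net change rates, and sitewise per-capita rates compared to the
  bulk division rate.
- **Synthetic generator.** River transects and ASV tables with fully known
  ground truth (planted trends, a persistent core, Bernoulli phylotype
  replacement, logistic bloomers), so every stage is testable without
  survey data. Presets `jds3like` (54 sites, 49.7 travel days) and
  `jds2like` (75 sites, 33.7 days).

The methods vignette
(`vignettes/river-bacterial-macroecology.Rmd`) documents the models,
parameter choices and limitations.

## Worked example

```r
library(rivermacro)

tru  <- synthetic_truth("jds3like", seed = 1)   # planted ground truth
tr   <- generate_transect(tru)
prof <- production_profile(tr)
print(tr)
print(prof)

tab <- generate_asv_table(tru, tr)
fit_linear(tr$tt_cum, observed_asvs(tab),
           xname = "tt_cum_h", yname = "observed_asvs")
```

```
River transect: 54 sites, 53 segments
  rkm 2600.0 -> 18.0, total travel time 1192.8 h (49.7 days)
Production profile
  median CD_d: 0.133 1/d (doubling time 7.49 d)
  cumulative divisions over 49.7 d: 6.63
  CP_tot: 7.01e+10 cells/l (7.11 x median standing stock)
Linear model for observed_asvs (n = 54, adj R^2 = 0.965)
  tt_cum_h: -0.1329 +/- 0.00346 (p = 7.45e-40)
```

Reading this: over the ~50-day journey a median cell divides every 7.5
days, i.e. ~6.6 doublings end to end; one travelling litre produces
7.0 × 10¹⁰ cells — about 7× the ambient standing stock, so most produced
cells must be lost to grazing, die-off or sedimentation; and richness
erodes at 0.133 ± 0.003 ASVs per travel-hour, recovering the planted
slope of 0.13. `whole_river_turnover()` and `headwater_persistence()` on
the same table give a turnover of 0.751 (92.3% of total beta diversity)
and 10.0% of the 599-member headwater pool persisting downstream.

## Analysis workflow

Numbered drivers under `analysis/` run the full study sequence on the
synthetic datasets and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # transects + ASV tables + ground truth
Rscript analysis/02_production.R   # production calculus + published chains
Rscript analysis/03_diversity.R    # rarefaction, partition, persistence
Rscript analysis/04_trends.R       # trend models, ordination, discharge model
Rscript analysis/05_growth.R       # phylotype spline growth analysis
```

Each script prints a one-paragraph narrative of what it found. The same
computations are available programmatically through `run_pipeline()`.

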