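# phenoseg

Change-point and trend analysis of short annual phenological and temperature
series.

Long series of fruit-tree flowering dates (25–56 years, one day-of-year value
per year) are the main observational record of how floral phenology responds
to warming, and the central question they pose is *qualitative*: did
flowering shift abruptly around a given year, drift as a linear trend, or
stay stationary? The same question applies to the series of mean temperatures
over the chill-accumulation (CA) and heat-accumulation (HA) periods that
drive dormancy release. phenoseg answers it with homoscedastic Gaussian
multiple change-point models and quantifies how sure the answer is —
something a fitted line or a bare change year cannot do on series this
short. It is aimed at researchers in phenology and applied biostatistics
working with annual observational series and nearby weather-station records.

## The model in brief

For a series $x_1,\dots,x_T$ there exist instants
$\tau_1 < \dots < \tau_{J-1}$ such that, within segment $j$,

$$E(X_t) = \alpha_j + \beta_j t, \qquad \operatorname{Var}(X_t) = \sigma^2,$$

with $\beta_j \equiv 0$ for the piecewise *constant* family and free slopes
for the piecewise *linear* family; the variance is common to all segments.
The package computes, per family:

* the exact RSS-optimal segmentation for each $J$ (dynamic programming);
* a modified BIC (mBIC) for Gaussian homoscedastic change-point models to
  select $J$, with Jeffreys' rule — a difference of $2\log 100 = 9.2$ —
  deciding when one model is *substantially* better, and model posterior
  probabilities $P(M_J \mid x) \propto e^{\mathrm{mBIC}_J/2}$;
* the posterior probability of the optimal segmentation
  $P(s^\* \mid x; J) = L_J(s^\*,x;\hat\theta)\big/\sum_s L_J(s,x;\hat\theta)$
  and, for a single change point, the full change-point posterior
  distribution over the $T-1$ candidate instants, by exhaustive enumeration;
* the residual-series procedure that disambiguates the classic stalemate
  between a 2-segment constant model and a plain linear trend.

Around the core: CA/HA aggregation of daily temperature records,
flowering-duration analysis (Kruskal–Wallis pooling across cultivars, ECDF
comparison), flowering–temperature correlations with the `**`/`*`/`n.s.`
star convention, and seeded synthetic-data generators for three contrasting
phenoclimatic scenarios (`european`, `brazilian`, `mediterranean`). See the
methods vignette (`vignettes/phenoseg-methods.Rmd`) for assumptions,
parameter defaults and design choices.

## Worked example

```r
library(phenoseg)

# a synthetic temperate-European pseudo-location: flowering with an abrupt
# advance, heat-period warming step, daily temperature record
bundle <- generate_scenario_bundle("european", seed = 42)

report <- analyze_series(bundle$flowering)
print(report)
#> <series_report> european stage 61 (1974-2013, n = 40)
#>   selected: constant, J = 2 (mBIC -279.90) [families indiscernible]
#>   retained change point(s): 1996 (amplitude -7.20), sd 6.47
#>   2-segment summary: change 1996, amplitude -7.20, P(s*|x;2) = 0.40, P(M2|x) = 0.54
#>   change point detected: TRUE

ha <- aggregate_period_mean(bundle$daily, bundle$periods$ha)
ct <- correlate_flowering_temperature(bundle$flowering, ha)
cat(sprintf("flowering~HA: r = %.2f (n = %d) %s\n", ct$r, ct$n, ct$class))
#> flowering~HA: r = -0.80 (n = 40) **

d <- changepoint_posterior_distribution(bundle$flowering)
head(d[order(-d$prob), ], 3)
#>    tau year       prob
#> 22  22 1996 0.39776663
#> 23  23 1997 0.11967390
#> 24  24 1998 0.09289549
```

Reading the output: the mBIC selects a 2-segment piecewise constant model —
flowering advanced abruptly by 7.2 days, with the first year of the new
regime estimated as 1996 (the generating truth for this seed is an 8-day
advance entering at 1994) against interannual noise of 6.5 days. The
`[families indiscernible]` flag records that a plain linear trend fits almost
as well, the situation the residual procedure exists for; the change-point
posterior shows the instant is localised but not sharp (40% of the mass on
1996, the rest spread over neighbouring years). Flowering correlates strongly
and negatively with the heat-accumulation temperature (earlier flowering in
warm springs), significant at the 1% level.

A thin command-line front end over the same functions ships in
`inst/cli/phenoseg` (subcommands `analyze`, `temps`, `correlate`,
`durations`, `simulate`).

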