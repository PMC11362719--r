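# awaredose

Antibiotic drug-utilization metrics from pack-level sales and procurement
records: WHO defined daily doses (DDD), DDDs per 1000 population per day
(DID), and spending metrics (total cost, cost per DDD, per-capita cost)
under selectable price bases, stratified by route, public/private sector,
AWaRe group and ATC level.

## Who this is for

Pharmacoepidemiologists and health-policy analysts who receive antibiotic
market data as pack-level extracts — private-sector sales with MRP/wholesale
prices, public-sector tender procurement — and need comparable consumption
and cost summaries. The package ships the whole chain: a molecule registry
(ATC codes, route-specific DDD values, AWaRe classes), validating ingest
with an explicit rejects report, the DDD/DID conversion, costing under MRP,
wholesale or procurement bases with a price-basis sensitivity analysis,
stratified share tables, and a seeded synthetic-data generator with exact
ground truth so every stage is testable without proprietary data.

## The metrics

For a record with strength *s*, pack size *k*, annual packs *q* and
registry DDD *d* (common units after normalization):

```
DDDs = s · k / d · q
DID  = DDDs / (population_thousands × 365)
cost = price_per_pack · q            (MRP | wholesale | procurement)
cost per DDD = cost / DDDs,   per-capita cost = cost / population
```

Wholesale prices, when absent, derive from a configured margin *m* as
`MRP / (1 + m)`. Shares are always computed on unrounded totals and rounded
only for display.

## Worked example

Recompute the AWaRe share table from the bundled national injectable
summary (values in DDDs and INR):

```r
library(awaredose)
aware <- load_reference_table("national_aware")
format_share_table(share_table(aware, "aware"))
#>        group total_ddds ddd_share_pct total_cost cost_share_pct cost_per_ddd
#> 1      Watch  133700000          50.9  3.960e+10           52.4        296.2
#> 2     Access   69500000          26.5  1.160e+10           15.3        166.9
#> 3 Discouraged  57700000          22.0  1.990e+10           26.3        344.9
#> 4    Reserve    1600000           0.6  4.500e+09            5.9       2812.5
#> 5  NotListed      18520           0.0  3.610e+07            0.0       1949.2
#> 6      Total  262518520         100.0  7.564e+10          100.0        288.1
```

Watch-group injectables dominate: half the volume at ₹296.2 per DDD,
while Reserve antibiotics are under 1% of volume at ~17× the Access price
per dose. Public-private splits come from `sector_share()`:

```r
kerala <- load_reference_table("kerala_route_sector")
format_share_table(sector_share(kerala, "route"))
#>        group public_ddd_share_pct private_ddd_share_pct public_cost_share_pct
#> 1       oral                 39.8                  60.2                   9.3
#> 2 injectable                 32.1                  67.9                   6.3
#> 3      Total                 39.6                  60.4                   8.3
```

The public sector supplies roughly a third of injectable DDDs for about 6%
of injectable spending — the cost-efficiency gap the per-DDD metric is
designed to expose.

A full synthetic run, end to end:

```r
ds  <- cmd_generate("demo", seed = 1)          # sales/procurement/population CSVs
m   <- cmd_compute(sales_path = "demo/sales.csv",
                   procurement_path = "demo/procurement.csv",
                   population_path = "demo/population.csv",
                   region = "KL", years = 2016:2019)
cmd_report(m, out_dir = "demo/reports")        # share tables as CSVs
```

A thin shell wrapper with the same subcommands is at
`inst/scripts/awaredose.R`. The methods vignette
(`vignettes/consumption-metrics.Rmd`) documents the model, the registry
conventions (route-specific DDDs, FDC handling, MU units), the rounding
policy, and what the synthetic generator does and does not emulate.

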