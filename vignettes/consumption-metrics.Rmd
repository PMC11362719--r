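---
title: "Measuring antibiotic consumption and cost with ATC/DDD and AWaRe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring antibiotic consumption and cost with ATC/DDD and AWaRe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awaredose)
```

## The measurement problem

Pharmaceutical sales and procurement data arrive as *packs*: a product line
is a molecule in a route-specific presentation (a 500 mg vial, a strip of ten
250 mg tablets), and what is recorded per year is how many packs moved and at
what price. Packs are not comparable across products, so drug-utilization
research converts them to WHO **defined daily doses** (DDD) — the assumed
average adult maintenance dose per day for a drug's main indication. For a
record with strength $s$, pack size $k$, annual pack volume $q$ and a
registry DDD $d$ (all in a common unit),

$$\mathrm{DDDs} = \frac{s \cdot k}{d} \cdot q ,$$

and population-adjusted consumption is expressed as DDDs per 1000
inhabitants per day,

$$\mathrm{DID} = \frac{\mathrm{DDDs}}{P_{\text{thousands}} \times 365},$$

with $P_{\text{thousands}}$ the mid-year population in thousands. Spending
is summarized as total cost, cost per DDD (the per-dose efficiency metric
used to compare sectors and antibiotic groups) and per-capita cost.

Two classifications stratify everything: the **ATC hierarchy** (level 3 =
pharmacological subgroup such as J01D, level 4 = chemical subgroup such as
J01DD, level 5 = substance) and the WHO **AWaRe** stewardship classes
(Access, Watch, Reserve, plus the "not recommended" fixed-dose combinations,
here labelled Discouraged, and NotListed as the fallback for molecules the
registry does not know).

The package implements this conversion chain for a two-sector market:
private-sector sales priced at MRP (the Indian maximum retail price) with an
optional wholesale price, and public-sector procurement priced at tender
cost. The intended users are pharmacoepidemiologists and health-policy
analysts working with pack-level sales or procurement extracts.

## The reference registry

`load_registry()` reads a TSV binding each (molecule, route) pair to a DDD
value and unit, an ATC level-5 code, and an AWaRe class. Design choices that
matter:

* **Route-specific DDDs.** Oral and parenteral DDDs differ (cefuroxime:
  0.5 g oral vs 3 g parenteral), so a lookup never substitutes the other
  route's value; a missing pair is a typed miss, not a fallback.
* **Fixed-dose combinations.** FDC names are canonicalized to
  `component+component` form; any `-`, `+` or `/` separator spelling maps to
  the same key, and the transformation is idempotent. FDCs with a WHO
  combination DDD carry it (`ddd_source = who_combined`); combinations the
  index does not list carry the principal antibacterial component's DDD and
  are flagged `ddd_source = principal_component` so the assumption is
  auditable. Hyphenated shorthand names ("co-trimoxazole") must arrive
  pre-expanded, as the bundled registry does for
  sulfamethoxazole+trimethoprim.
* **Unit families.** Biological-unit molecules (benzylpenicillin, colistin)
  are kept in million units (MU) end to end; converting MU to milligrams is
  a hard error rather than a silent approximation, because the mass
  equivalence is molecule-specific and a wrong factor corrupts every
  downstream total.
* **Vintage is data, not code.** The bundled registry transcribes the WHO
  ATC/DDD index (2022 vintage, including the 2019 DDD revisions such as
  amoxicillin 1.5 g oral / 3 g parenteral and meropenem 3 g) and the 2021
  AWaRe list; swapping in another vintage is a data edit, not a code change.

## Ingest and exclusion policy

`read_sales()` / `read_procurement()` are lossless: every input row is
accepted or appears in a rejects report (row, column, reason); a missing
mandatory column aborts. Records whose molecule has no registry DDD are
excluded from DDD totals but summed into a coverage report with their pack
volume and spend, so the excluded mass is visible — in the data this package
emulates that mass is of the order of 0.01% of volume, but the policy
guards against silently dropping a registry gap of any size. Multi-strength
product lines are kept as separate records; nothing is pooled before the
DDD conversion. Annual volumes are taken as given (moving annual totals);
no within-year seasonality is modeled.

## Price bases and the sensitivity analysis

Private records can be costed at MRP (what patients face at the point of
sale) or at the wholesale price (MRP minus the retail margin); public
records are always costed at procurement price, the only price that channel
has. Because published sales extracts often omit wholesale prices, the
wholesale basis accepts a configured margin $m$ and derives
$\text{wholesale} = \text{MRP}/(1+m)$ (default $m = 0.20$); the margin is
explicitly an assumption of the analysis, not an estimate, and
`sensitivity_compare()` reports cost shares under both bases side by side
with their difference in percentage points. For any $m \ge 0$ the wholesale
basis can only lower private costs, so public cost shares can only rise
under the sensitivity basis — a monotonicity the tests enforce per stratum.

Cost per DDD for a stratum with zero DDDs but non-zero cost (possible for
excluded molecules) is reported as `NA` ("undefined"), never infinity.

## Aggregation and rounding

`share_table()` and `sector_share()` compute percent shares **on unrounded
totals** and round only at display time (`format_share_table()`, one decimal
for shares and cost per DDD). This matters when checking published tables:
printed shares are derived from unrounded source data, so recomputing them
from printed (rounded) numerators and denominators can differ in the last
digit — e.g. a printed 31.4% public share of injectables recomputes to
32.1% from the printed one-decimal volumes. The bundled fixture tables
reproduce printed ratios exactly after one-decimal rounding except for such
rounded-input cases, where agreement is within 0.2% relative.

`top_n_share()` orders by DDDs or cost, breaking ties alphabetically by
label for deterministic output, and folds everything below rank $n$ into a
remainder row recomputed from unrounded totals, so top-$n$ plus remainder
always reproduce the grand total. Multi-year results are computed per year
and then averaged (`multi_year_average()`), never pooled, and the year is
fixed at 365 days (leap years ignored — the convention of the DID formula).
The population table accepts year-specific denominators; a constant
population across years (as in the bundled national table) is a special
case, and both conventions give DID values within half a percent of each
other for the bundled data.

## The synthetic-data generator

Real pack-level sales data are proprietary, so `generate_dataset()` emulates
their structure: four annual cross-sections (2016–2019), a two-sector split,
route-specific presentations (single vials for injectables, strips for
orals), heterogeneous strengths and pack sizes, and a multiplicative price
chain procurement $\le$ wholesale $\le$ MRP. Pack volumes per product line
are lognormal around each line's expected volume ($\sigma = 1.0$), giving
the heavy-tailed, blockbuster-dominated volume distribution that makes
top-$n$ tables non-degenerate; product lines are allocated to molecules in
proportion to expected volume, as brands accumulate on high-volume
molecules in real markets. All randomness flows from one seed; a config
draws byte-identical datasets, and ground-truth aggregates are computed at
generation time by an independent per-record arithmetic pass so the full
pipeline can be checked against them exactly.

`paper_like_profile()` is the calibrated default: its expectations are the
published Kerala/national consumption profile — injectable AWaRe volume mix
26.5/50.9/0.61/21.9% (Access/Watch/Reserve/Discouraged), class-specific
public shares of injectable volume (34.0/33.3/25.8/20.8%, overall about
31%), molecule weights following the published molecule shares (ceftriaxone
about a third of injectable DDDs), class-level prices per DDD (Access 167.5
to Reserve 2798.8 INR), a retail margin of 0.20 and a public procurement
discount of 0.86 chosen so the public share of injectable spending (about
6%) sits far below its volume share, reproducing the cost-efficiency gap
between sectors. A deliberate 0.01% sliver of volume belongs to a molecule
absent from the registry, exercising the coverage report.

What the generator does **not** emulate: brand names and product-name
matching (records arrive pre-annotated with molecule names), within-year
dynamics, regional heterogeneity beyond a single region label, demand
correlation across years, and price regulation effects. Passing tests
therefore demonstrate the correctness of the conversion and aggregation
arithmetic under realistic volume/price structure — not the epidemiological
realism of any particular market.

## Problem sizes and numerical tolerances

The test suite checks conservation (stratum sums equal grand totals, shares
sum to 100%) at relative tolerance $10^{-9}$, ATC level-5 → 4 → 3 roll-up
consistency, price-basis monotonicity, and equality with a per-record
brute-force oracle, all on a 10,000-record draw; parameter recovery
(empirical AWaRe mix and sector split within three bootstrap standard
errors of the configured values) uses a 50,000-record draw. These sizes
make the sampling error of group shares small (about one percentage point
at the 10k scale) while keeping the whole suite inside a few seconds.

## Known limitations

* Cost results are nominal INR; no deflation, exchange conversion or
  purchasing-power adjustment.
* Procurement prices are treated as directly comparable to wholesale
  prices, although tender prices may or may not include comparable
  distribution overheads; the comparison inherits that caveat.
* Hospital-level denominators (DDD per 100 bed-days) and prescribed-daily-
  dose adjustments are out of scope; DID is the only rate produced.
* The wholesale margin is a single configured scalar applied to all private
  records; molecule- or class-specific margins are not modeled, and no
  tax/margin decomposition is attempted.
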