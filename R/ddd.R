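#' DDDs contributed by a single record
#'
#' Implements the pack-to-DDD conversion: the number of defined daily doses in
#' one pack is `strength * pack_size / DDD`, computed after normalizing both
#' strength and DDD value to a common unit (mg, or MU for biological-unit
#' molecules); the record's annual DDD volume is the per-pack value times the
#' packs sold in the year.
#'
#' @param record A one-row record tibble (see [read_sales()]).
#' @param assignment The matching registry row (see [lookup_ddd()]); its route
#'   must equal the record's route and its unit family (mass vs MU) must match
#'   the record's strength unit.
#' @return Tibble with `ddd_per_pack` and `total_ddds`.
#' @examples
#' reg <- load_registry(awaredose_example("ddd_registry.tsv"))
#' rec <- tibble::tibble(molecule = "ceftriaxone", route = "injectable",
#'                       strength_value = 500, strength_unit = "mg",
#'                       pack_size = 10L, packs_per_year = 1)
#' ddds_for_record(rec, lookup_ddd(reg, "ceftriaxone", "injectable"))
#' @export
ddds_for_record <- function(record, assignment) {
  stopifnot(nrow(record) == 1, nrow(assignment) == 1)
  if (record$route != assignment$route) {
    abort(paste0("route mismatch for '", assignment$molecule, "': record is ",
                 record$route, ", assignment is ", assignment$route))
  }
  s <- normalize_strength(record$strength_value, record$strength_unit)
  d <- normalize_strength(assignment$ddd_value, assignment$ddd_unit)
  if (s$unit != d$unit) {
    abort(paste0("incompatible units for '", assignment$molecule, "': strength in ",
                 s$unit, " but DDD in ", d$unit))
  }
  ddd_per_pack <- s$value * record$pack_size / d$value
  tibble::tibble(ddd_per_pack = ddd_per_pack,
                 total_ddds = ddd_per_pack * record$packs_per_year)
}

#' Annotate records with DDD volumes and registry attributes
#'
#' Vectorized pack-to-DDD conversion over a record set.  Each record is joined
#' to its (molecule, route) registry entry; covered records gain `atc5`,
#' `aware`, `ddd_per_pack` and `total_ddds` columns.  Records whose molecule
#' lacks a registry DDD are excluded from the returned set but accounted for
#' in the coverage report (retrievable with [coverage_report()]) — exclusion
#' is visible, never silent.
#'
#' @param records Record tibble (any mix of sectors).
#' @param registry A `ddd_registry`.
#' @return The covered records with DDD annotations; attribute `coverage`
#'   holds a tibble (`molecule`, `route`, `reason`, `packs`, `spend`) of
#'   excluded volume and MRP/procurement spend.
#' @export
compute_ddds <- function(records, registry) {
  stopifnot(inherits(registry, "ddd_registry"))
  entries <- registry$entries[c("molecule", "route", "atc5", "ddd_value",
                                "ddd_unit", "aware", "is_fdc")]
  # re-annotation is safe: stale registry/DDD columns are recomputed
  stale <- setdiff(names(entries), c("molecule", "route"))
  records <- records[setdiff(names(records),
                             c(stale, "ddd_per_pack", "total_ddds"))]
  out <- dplyr::left_join(records, entries, by = c("molecule", "route"))

  uncovered <- out[is.na(out$ddd_value), , drop = FALSE]
  covered <- out[!is.na(out$ddd_value), , drop = FALSE]

  col_or_na <- function(df, col) {
    if (col %in% names(df)) df[[col]] else rep(NA_real_, nrow(df))
  }
  uncovered$spend_basis <- dplyr::coalesce(
    col_or_na(uncovered, "mrp_per_pack"),
    col_or_na(uncovered, "procurement_cost_per_pack"),
    0
  )
  coverage <- uncovered |>
    dplyr::summarise(
      reason = "no registry DDD",
      packs = sum(.data$packs_per_year),
      spend = sum(.data$spend_basis * .data$packs_per_year),
      .by = c("molecule", "route")
    )

  s <- normalize_strength(covered$strength_value, covered$strength_unit)
  d <- normalize_strength(covered$ddd_value, covered$ddd_unit)
  incompatible <- s$unit != d$unit
  if (any(incompatible)) {
    abort(paste0("incompatible units for '", covered$molecule[incompatible][1],
                 "': strength in ", s$unit[incompatible][1], " but DDD in ",
                 d$unit[incompatible][1]))
  }
  covered$ddd_per_pack <- s$value * covered$pack_size / d$value
  covered$total_ddds <- covered$ddd_per_pack * covered$packs_per_year
  attr(covered, "coverage") <- coverage
  covered
}

#' Coverage report of DDD-excluded records
#'
#' @param x A tibble returned by [compute_ddds()].
#' @return Tibble of molecules excluded from DDD totals, with packed volume
#'   and spend so the exclusion's weight is auditable.
#' @export
coverage_report <- function(x) {
  attr(x, "coverage") %||%
    tibble::tibble(molecule = character(), route = character(),
                   reason = character(), packs = double(), spend = double())
}

#' Total DDDs over a stratum
#'
#' Sums annotated records, optionally restricted by dplyr-style filter
#' expressions; an empty selection totals to 0.
#'
#' @param x Tibble from [compute_ddds()].
#' @param ... Optional filter expressions (e.g. `route == "injectable"`).
#' @return A single number.
#' @examples
#' # total_ddds(annotated, sector == "public", route == "injectable")
#' @export
total_ddds <- function(x, ...) {
  x <- dplyr::filter(x, ...)
  sum(x$total_ddds)
}

#' DDDs per 1000 population per day (DID)
#'
#' The standard population-normalized consumption rate:
#' `total_ddds / (population_thousands * days)`, with a 365-day year.
#'
#' @param total_ddds Annual DDD volume (numeric, vectorized).
#' @param population_thousands Mid-year population in thousands (> 0).
#' @param days Days per year; fixed default 365.
#' @return DID value(s).
#' @examples
#' did(5123.5e6, 1.31e6)
#' @export
did <- function(total_ddds, population_thousands, days = 365L) {
  if (any(is.na(population_thousands) | population_thousands <= 0)) {
    abort("population_thousands must be present and strictly positive")
  }
  total_ddds / (population_thousands * days)
}

#' Population lookup for one region-year
#'
#' @param pop Population tibble from [read_population()].
#' @param region Region label.
#' @param year Year.
#' @return Population in thousands; error when the pair is absent.
#' @export
population_for <- function(pop, region, year) {
  hit <- pop$population_thousands[pop$region == region & pop$year == year]
  if (length(hit) != 1) {
    abort(paste0("no population for (", region, ", ", year, ")"))
  }
  hit
}

#' Average a yearly metric over a year window
#'
#' Multi-year results are computed per year and then averaged (arithmetic
#' mean), never pooled; every requested year must be present.
#'
#' @param values Named numeric vector (names are years) or a two-column
#'   tibble/data.frame `(year, value)`.
#' @param years Years to average over; default all years in `values`.
#' @return The mean over `years`.
#' @examples
#' multi_year_average(c("2016" = 8, "2017" = 12))
#' @export
multi_year_average <- function(values, years = NULL) {
  if (is.data.frame(values)) {
    values <- setNames(values[[2]], values[[1]])
  }
  years <- as.character(years %||% names(values))
  missing_years <- setdiff(years, names(values))
  if (length(missing_years) > 0) {
    abort(paste0("missing year(s): ", paste(missing_years, collapse = ", ")))
  }
  mean(values[years])
}
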