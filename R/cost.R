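#' Select a price basis for cost computations
#'
#' Which price column values a record's spend.  Private-sector records can be
#' costed at MRP (the consumer ceiling price, the headline basis) or at the
#' wholesale price (MRP minus the retail margin, the sensitivity basis);
#' public-sector records are always costed at their procurement price, which
#' is the only price the public channel has.  Requesting the procurement
#' basis for private records is an error.
#'
#' @param basis `"mrp"`, `"wholesale"` or `"procurement"`.
#' @param margin_fallback Optional margin fraction (>= 0) used to derive a
#'   missing wholesale price as `mrp / (1 + margin)`; for any margin >= 0 the
#'   derived wholesale price cannot exceed MRP.
#' @return A `price_basis` object.
#' @examples
#' price_basis("wholesale", margin_fallback = 0.20)
#' @export
price_basis <- function(basis = c("mrp", "wholesale", "procurement"),
                        margin_fallback = NULL) {
  basis <- match.arg(basis)
  if (!is.null(margin_fallback) &&
      (!is.numeric(margin_fallback) || margin_fallback < 0)) {
    abort("margin_fallback must be a non-negative fraction")
  }
  structure(list(basis = basis, margin_fallback = margin_fallback),
            class = "price_basis")
}

as_price_basis <- function(basis) {
  if (inherits(basis, "price_basis")) basis else price_basis(basis)
}

#' Per-record annual cost under a price basis
#'
#' `cost = price_per_pack * packs_per_year`, with the price column selected by
#' the basis (see [price_basis()]).  Public records are always valued at
#' procurement cost.
#'
#' @param records Record tibble (mixed sectors allowed).
#' @param basis A `price_basis` or a basis name.
#' @return Numeric vector of record costs (INR).
#' @export
record_cost <- function(records, basis = price_basis("mrp")) {
  basis <- as_price_basis(basis)
  is_private <- records$sector == "private"
  if (basis$basis == "procurement" && any(is_private)) {
    abort("procurement basis is only valid for public-sector records")
  }
  price <- rep(NA_real_, nrow(records))
  if (any(!is_private)) {
    price[!is_private] <- records$procurement_cost_per_pack[!is_private]
  }
  if (any(is_private)) {
    price[is_private] <- switch(
      basis$basis,
      mrp = records$mrp_per_pack[is_private],
      wholesale = {
        w <- records$wholesale_per_pack[is_private]
        if (anyNA(w)) {
          if (is.null(basis$margin_fallback)) {
            abort("wholesale price absent and no margin_fallback configured")
          }
          m <- records$mrp_per_pack[is_private]
          w[is.na(w)] <- m[is.na(w)] / (1 + basis$margin_fallback)
        }
        w
      }
    )
  }
  if (anyNA(price)) abort("price missing for some records under this basis")
  price * records$packs_per_year
}

#' Annotate records with their cost under a basis
#'
#' Adds a `total_cost` column (per-record annual cost) so the record set can
#' feed the aggregation functions directly.
#'
#' @inheritParams record_cost
#' @return `records` with a `total_cost` column; other columns and attributes
#'   (including the DDD coverage report) are preserved.
#' @export
annotate_cost <- function(records, basis = price_basis("mrp")) {
  records$total_cost <- record_cost(records, basis)
  records
}

#' Cost per defined daily dose
#'
#' Total spend on a stratum divided by its DDD volume — the per-dose
#' efficiency metric.  A stratum with zero DDDs but non-zero cost has no
#' defined per-dose cost and is reported as `NA`, never infinity.
#'
#' @param total_cost,total_ddds Numeric (vectorized).
#' @return Cost per DDD (INR/DDD).
#' @examples
#' cost_per_ddd(39.6e9, 133.7e6)
#' @export
cost_per_ddd <- function(total_cost, total_ddds) {
  out <- ifelse(total_ddds > 0, total_cost / total_ddds, NA_real_)
  ifelse(total_cost == 0 & total_ddds == 0, NA_real_, out)
}

#' Per-capita cost
#'
#' @param total_cost Total spend (INR).
#' @param population_thousands Population in thousands (> 0).
#' @return INR per person: `total_cost / (population_thousands * 1000)`.
#' @examples
#' per_capita_cost(75.7e9, 1.31e6)
#' @export
per_capita_cost <- function(total_cost, population_thousands) {
  if (any(is.na(population_thousands) | population_thousands <= 0)) {
    abort("population_thousands must be present and strictly positive")
  }
  total_cost / (population_thousands * 1000)
}

#' Price-basis sensitivity comparison of cost shares
#'
#' Recomputes each stratum's cost share under two price bases (typically MRP
#' vs wholesale for the private sector, with public records at procurement
#' cost under both) and reports the shift in percentage points.  This is the
#' sensitivity analysis that checks whether public-private cost shares are an
#' artifact of the retail mark-up.
#'
#' @param records Record tibble; must contain the grouping column(s).
#' @param bases List of two `price_basis` objects (or basis names).
#' @param group Column name(s) to stratify by (e.g. `"sector"`).
#' @return Tibble with one row per stratum: total cost and percent share under
#'   each basis, and `share_diff_pp` (basis 2 minus basis 1).
#' @export
sensitivity_compare <- function(records, bases = list("mrp", "wholesale"),
                                group = "sector") {
  stopifnot(length(bases) == 2)
  one <- function(basis) {
    basis <- as_price_basis(basis)
    records |>
      dplyr::mutate(.cost = record_cost(records, basis)) |>
      dplyr::summarise(total_cost = sum(.data$.cost),
                       .by = dplyr::all_of(group)) |>
      dplyr::mutate(cost_share_pct = 100 * .data$total_cost /
                      sum(.data$total_cost))
  }
  b1 <- as_price_basis(bases[[1]])$basis
  b2 <- as_price_basis(bases[[2]])$basis
  out <- dplyr::full_join(one(bases[[1]]), one(bases[[2]]),
                          by = group, suffix = paste0("_", c(b1, b2)))
  out$share_diff_pp <- out[[paste0("cost_share_pct_", b2)]] -
    out[[paste0("cost_share_pct_", b1)]]
  out
}
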