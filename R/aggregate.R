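#' Attach ATC level-3/4 grouping columns
#'
#' Adds `atc3`, `atc3_label`, `atc4`, `atc4_label` to a DDD-annotated record
#' set so share tables can stratify at any ATC level.
#'
#' @param x Tibble from [compute_ddds()] (must carry `atc5`).
#' @param registry The `ddd_registry` supplying prefix labels.
#' @return `x` with the four grouping columns added.
#' @export
add_atc_groups <- function(x, registry) {
  stopifnot(inherits(registry, "ddd_registry"))
  g3 <- atc_group(x, 3L, registry)
  g4 <- atc_group(x, 4L, registry)
  x$atc3 <- g3$code
  x$atc3_label <- g3$label
  x$atc4 <- g4$code
  x$atc4_label <- g4$label
  x
}

#' Volume and cost share table for one stratification
#'
#' Aggregates DDD volume and cost by a grouping column and derives each
#' group's percent share of volume and of cost, its cost per DDD, and
#' (when a population is given) its DID.  Shares are computed on unrounded
#' totals; rounding is applied only when a table is formatted for display.
#' A totals row closes the table.
#'
#' @param data Tibble with the grouping column(s) plus `total_ddds` and
#'   `total_cost` (per-record annotated data from
#'   [compute_ddds()] + [annotate_cost()], or an already-aggregated table).
#' @param group Grouping column name (e.g. `"aware"`, `"atc3_label"`,
#'   `"molecule"`, `"route"`, `"sector"`).
#' @param population_thousands Optional population (thousands) for a DID
#'   column.
#' @param total_label Label of the totals row.
#' @return A `share_table` tibble: `group`, `total_ddds`, `ddd_share_pct`,
#'   `total_cost`, `cost_share_pct`, `cost_per_ddd` (+ `did`), ordered by
#'   descending DDDs then label, totals row last.
#' @export
share_table <- function(data, group, population_thousands = NULL,
                        total_label = "Total") {
  empty <- nrow(data) == 0
  tbl <- data |>
    dplyr::summarise(total_ddds = sum(.data$total_ddds),
                     total_cost = sum(.data$total_cost),
                     .by = dplyr::all_of(group)) |>
    dplyr::rename(group = dplyr::all_of(group)) |>
    dplyr::arrange(dplyr::desc(.data$total_ddds), .data$group)
  grand_d <- sum(tbl$total_ddds)
  grand_c <- sum(tbl$total_cost)
  tbl$ddd_share_pct <- if (grand_d > 0) 100 * tbl$total_ddds / grand_d else 0
  tbl$cost_share_pct <- if (grand_c > 0) 100 * tbl$total_cost / grand_c else 0
  totals <- tibble::tibble(
    group = total_label, total_ddds = grand_d, total_cost = grand_c,
    ddd_share_pct = if (empty) 0 else 100,
    cost_share_pct = if (empty) 0 else 100
  )
  out <- dplyr::bind_rows(tbl, totals)
  out$cost_per_ddd <- cost_per_ddd(out$total_cost, out$total_ddds)
  if (!is.null(population_thousands)) {
    out$did <- did(out$total_ddds, population_thousands)
  }
  out <- out[c("group", "total_ddds", "ddd_share_pct", "total_cost",
               "cost_share_pct", "cost_per_ddd",
               if (!is.null(population_thousands)) "did")]
  class(out) <- c("share_table", class(out))
  attr(out, "total_label") <- total_label
  out
}

#' Public-private sector shares of volume and cost
#'
#' For each group, the public and private DDD totals and cost totals with
#' within-group percent shares (public + private = 100 for volume and for
#' cost).  Either sector may be absent from the data; its totals are then 0.
#'
#' @param data Tibble with a `sector` column plus the grouping column,
#'   `total_ddds` and `total_cost`.
#' @param group Grouping column name (e.g. `"route"`, `"aware"`,
#'   `"molecule"`).
#' @param total_label Label of the totals row.
#' @return Tibble with one row per group: `public_ddds`, `private_ddds`,
#'   `public_ddd_share_pct`, `private_ddd_share_pct`, and the cost
#'   equivalents, plus a totals row.
#' @export
sector_share <- function(data, group, total_label = "Total") {
  agg <- data |>
    dplyr::summarise(total_ddds = sum(.data$total_ddds),
                     total_cost = sum(.data$total_cost),
                     .by = dplyr::all_of(c(group, "sector"))) |>
    dplyr::rename(group = dplyr::all_of(group))
  wide <- agg |>
    tidyr::pivot_wider(
      names_from = "sector",
      values_from = c("total_ddds", "total_cost"),
      values_fill = 0
    )
  for (col in c("total_ddds_public", "total_ddds_private",
                "total_cost_public", "total_cost_private")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide <- wide |>
    dplyr::transmute(
      group = .data$group,
      public_ddds = .data$total_ddds_public,
      private_ddds = .data$total_ddds_private,
      public_cost = .data$total_cost_public,
      private_cost = .data$total_cost_private
    ) |>
    dplyr::arrange(dplyr::desc(.data$public_ddds + .data$private_ddds),
                   .data$group)
  totals <- tibble::tibble(
    group = total_label,
    public_ddds = sum(wide$public_ddds),
    private_ddds = sum(wide$private_ddds),
    public_cost = sum(wide$public_cost),
    private_cost = sum(wide$private_cost)
  )
  out <- dplyr::bind_rows(wide, totals)
  ddd_tot <- out$public_ddds + out$private_ddds
  cost_tot <- out$public_cost + out$private_cost
  out$public_ddd_share_pct <- ifelse(ddd_tot > 0, 100 * out$public_ddds / ddd_tot, 0)
  out$private_ddd_share_pct <- ifelse(ddd_tot > 0, 100 * out$private_ddds / ddd_tot, 0)
  out$public_cost_share_pct <- ifelse(cost_tot > 0, 100 * out$public_cost / cost_tot, 0)
  out$private_cost_share_pct <- ifelse(cost_tot > 0, 100 * out$private_cost / cost_tot, 0)
  out
}

#' Count distinct formulations with non-zero consumption
#'
#' Number of distinct (canonical) molecules with positive DDD volume under
#' the given filters — e.g. how many injectable antibiotic formulations a
#' sector actually used.
#'
#' @param data DDD-annotated record tibble.
#' @param sector Optional sector filter (`"public"`/`"private"`).
#' @param route Optional route filter (`"oral"`/`"injectable"`).
#' @return Integer count.
#' @export
formulation_count <- function(data, sector = NULL, route = NULL) {
  if (!is.null(sector)) data <- data[data$sector == sector, , drop = FALSE]
  if (!is.null(route)) data <- data[data$route == route, , drop = FALSE]
  used <- data |>
    dplyr::summarise(total_ddds = sum(.data$total_ddds), .by = "molecule") |>
    dplyr::filter(.data$total_ddds > 0)
  nrow(used)
}

#' Keep the top-n groups and fold the rest into a remainder row
#'
#' Orders a [share_table()] by DDDs or cost (descending, ties broken
#' alphabetically by label), keeps the first `n` groups, and folds all
#' remaining groups into an `"All the other"` row whose totals are the grand
#' totals minus the top-n sums; shares are recomputed from unrounded totals,
#' so remainder + top-n always reproduce the grand total exactly.
#'
#' @param table A `share_table`.
#' @param n Number of groups to keep (>= 1).
#' @param by `"ddds"` or `"cost"`.
#' @param other_label Label for the remainder row.
#' @return A `share_table` with at most `n` + 2 rows (top n, remainder,
#'   totals); when `n` covers every group the table is returned unchanged
#'   (no empty remainder row).
#' @export
top_n_share <- function(table, n, by = c("ddds", "cost"),
                        other_label = "All the other") {
  by <- match.arg(by)
  stopifnot(n >= 1)
  total_label <- attr(table, "total_label") %||% "Total"
  body <- table[table$group != total_label, , drop = FALSE]
  totals <- table[table$group == total_label, , drop = FALSE]
  metric <- if (by == "ddds") body$total_ddds else body$total_cost
  body <- body[order(-metric, body$group), , drop = FALSE]
  if (n >= nrow(body)) {
    out <- dplyr::bind_rows(body, totals)
    class(out) <- class(table)
    attr(out, "total_label") <- total_label
    return(out)
  }
  top <- body[seq_len(n), , drop = FALSE]
  rest_d <- totals$total_ddds - sum(top$total_ddds)
  rest_c <- totals$total_cost - sum(top$total_cost)
  rest <- tibble::tibble(
    group = other_label,
    total_ddds = rest_d,
    ddd_share_pct = if (totals$total_ddds > 0) 100 * rest_d / totals$total_ddds else 0,
    total_cost = rest_c,
    cost_share_pct = if (totals$total_cost > 0) 100 * rest_c / totals$total_cost else 0,
    cost_per_ddd = cost_per_ddd(rest_c, rest_d)
  )
  out <- dplyr::bind_rows(top, rest, totals)
  class(out) <- class(table)
  attr(out, "total_label") <- total_label
  out
}

#' Round a share table for display
#'
#' Applies the display rounding policy (shares and cost per DDD to one
#' decimal) without touching the stored unrounded totals the shares were
#' computed from.
#'
#' @param table A `share_table` (or any tibble with share columns).
#' @param digits Decimal places for percentage and per-DDD columns.
#' @return The table with display columns rounded.
#' @export
format_share_table <- function(table, digits = 1) {
  for (col in intersect(
    c("ddd_share_pct", "cost_share_pct", "cost_per_ddd",
      "public_ddd_share_pct", "private_ddd_share_pct",
      "public_cost_share_pct", "private_cost_share_pct", "share_diff_pp"),
    names(table)
  )) {
    table[[col]] <- round(table[[col]], digits)
  }
  table
}
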