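#' Load a bundled published summary table
#'
#' Reads one of the transcribed published consumption/cost tables shipped
#' under `inst/extdata` (file names `ref_*.csv`), rescales columns stored in
#' printed units (`*_thousand`, `*_million`, `*_billion`) to absolute DDDs
#' and INR, renames volume/cost columns to the `total_ddds` / `total_cost`
#' names the aggregation functions expect, and — for sector-wide tables —
#' pivots `public_*` / `private_*` column pairs into a long `sector` column.
#' Printed share columns are kept verbatim for comparison against recomputed
#' shares.
#'
#' @param name Bare table name (e.g. `"national_aware"`,
#'   `"kerala_molecule_sector"`) or a path to a CSV in the same layout.
#' @param long For sector tables: pivot to one row per (group, sector)?
#'   Default `TRUE`.
#' @return A tibble in absolute units.
#' @examples
#' load_reference_table("national_aware")
#' @export
load_reference_table <- function(name, long = TRUE) {
  path <- if (file.exists(name)) name else {
    awaredose_example(paste0("ref_", name, ".csv"))
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  scales <- c(thousand = 1e3, million = 1e6, billion = 1e9)
  for (suffix in names(scales)) {
    hit <- grep(paste0("_", suffix, "$"), names(tbl), value = TRUE)
    for (col in hit) {
      tbl[[col]] <- tbl[[col]] * scales[[suffix]]
      names(tbl)[names(tbl) == col] <- sub(paste0("_", suffix, "$"), "", col)
    }
  }
  # harmonize with the aggregation interface
  ren <- c(total_ddds = "ddds", total_ddds = "ddd", total_cost = "cost")
  for (i in seq_along(ren)) {
    if (ren[[i]] %in% names(tbl)) {
      names(tbl)[names(tbl) == ren[[i]]] <- names(ren)[i]
    }
  }
  sector_cols <- grep("^(public|private)_(ddds|ddd|cost|did)$", names(tbl),
                      value = TRUE)
  if (long && length(sector_cols) > 0) {
    tbl <- tidyr::pivot_longer(
      tbl, dplyr::all_of(sector_cols),
      names_pattern = "^(public|private)_(.*)$",
      names_to = c("sector", ".value")
    )
    for (i in seq_along(ren)) {
      if (ren[[i]] %in% names(tbl)) {
        names(tbl)[names(tbl) == ren[[i]]] <- names(ren)[i]
      }
    }
  }
  if ("molecule" %in% names(tbl)) {
    tbl$molecule <- normalize_molecule(tbl$molecule)
  }
  tbl
}

#' Generate a synthetic dataset on disk
#'
#' Thin wrapper: builds the calibrated profile (or takes a ready
#' `generator_config`), draws the dataset and writes it with
#' [write_dataset()].
#'
#' @param out_dir Output directory.
#' @param seed Generator seed (ignored when `config` is given).
#' @param config Optional `generator_config` overriding the default profile.
#' @return The `synthetic_dataset`, invisibly.
#' @export
cmd_generate <- function(out_dir, seed = 1L, config = NULL) {
  config <- config %||% paper_like_profile(seed = seed)
  ds <- generate_dataset(config)
  write_dataset(ds, out_dir)
  message("wrote ", nrow(ds$sales), " sales and ", nrow(ds$procurement),
          " procurement records to ", out_dir)
  invisible(ds)
}

#' Run the full consumption/cost computation
#'
#' Wires ingest, DDD conversion, costing and stratified aggregation into a
#' metrics store: ingest both sectors, restrict to the requested region and
#' years, convert packs to DDDs against the registry (excluded molecules go
#' to the coverage report), cost every record under the chosen basis, and
#' build the standard share tables.
#'
#' @param sales_path Private-sector sales CSV (or `NULL`).
#' @param procurement_path Public-sector procurement CSV (or `NULL`).
#' @param population_path Population CSV.
#' @param region Region label to analyse.
#' @param years Year window (every year must be in the population table).
#' @param registry_path Registry TSV; default the bundled registry.
#' @param basis Price basis for private records (see [price_basis()]).
#' @param verbose Log record counts and coverage to stderr?
#' @return A `metrics_store`: list with `records` (annotated), `tables`
#'   (named list of share/sector tables), `did_by_route`, `coverage`,
#'   `formulations`, and the run parameters.
#' @export
cmd_compute <- function(sales_path = NULL, procurement_path = NULL,
                        population_path, region, years,
                        registry_path = awaredose_example("ddd_registry.tsv"),
                        basis = price_basis("mrp"), verbose = TRUE) {
  if (is.null(sales_path) && is.null(procurement_path)) {
    abort("at least one of sales_path / procurement_path is required")
  }
  basis <- as_price_basis(basis)
  registry <- load_registry(registry_path)
  pop <- read_population(population_path)
  say <- function(...) if (verbose) message(...)

  parts <- list()
  if (!is.null(sales_path)) {
    ing <- read_sales(sales_path)
    say("sales: ", nrow(ing$records), " accepted, ", nrow(ing$rejects),
        " rejected")
    parts$private <- ing$records
  }
  if (!is.null(procurement_path)) {
    ing <- read_procurement(procurement_path)
    say("procurement: ", nrow(ing$records), " accepted, ", nrow(ing$rejects),
        " rejected")
    parts$public <- ing$records
  }
  records <- dplyr::bind_rows(parts)
  records <- records[records$region == region & records$year %in% years, ,
                     drop = FALSE]
  if (nrow(records) == 0) abort("no records for the requested region/years")

  ann <- compute_ddds(records, registry)
  cov <- coverage_report(ann)
  if (nrow(cov) > 0) {
    say("excluded from DDD totals (no registry DDD): ",
        paste(cov$molecule, collapse = ", "))
  }
  ann <- annotate_cost(ann, basis)
  ann <- add_atc_groups(ann, registry)

  pop_years <- vapply(years, function(y) population_for(pop, region, y),
                      numeric(1))
  mean_pop <- mean(pop_years)

  did_by_route <- ann |>
    dplyr::summarise(total_ddds = sum(.data$total_ddds),
                     .by = c("route", "year")) |>
    dplyr::mutate(did = did(.data$total_ddds,
                            pop_years[match(.data$year, years)])) |>
    dplyr::summarise(did = mean(.data$did), .by = "route")

  tables <- list(
    route_share = share_table(ann, "route", mean_pop),
    aware_share = share_table(ann, "aware", mean_pop),
    atc3_share = share_table(ann, "atc3_label"),
    atc4_share = share_table(ann, "atc4_label"),
    molecule_share = share_table(ann, "molecule"),
    sector_route = sector_share(ann, "route"),
    sector_aware = sector_share(ann, "aware"),
    sector_molecule = sector_share(ann, "molecule"),
    coverage = cov
  )
  if (!is.null(sales_path) && basis$basis != "procurement") {
    wb <- price_basis("wholesale", margin_fallback = basis$margin_fallback %||% 0.20)
    tables$sensitivity_sector <-
      sensitivity_compare(ann, list(price_basis("mrp"), wb), "sector")
  }

  structure(
    list(records = ann, tables = tables, did_by_route = did_by_route,
         coverage = cov,
         formulations = list(
           public_injectable = formulation_count(ann, "public", "injectable"),
           private_injectable = formulation_count(ann, "private", "injectable")
         ),
         region = region, years = years, basis = basis,
         population_thousands = mean_pop),
    class = "metrics_store"
  )
}

#' @export
print.metrics_store <- function(x, ...) {
  cat("<metrics_store> region ", x$region, ", years ",
      paste(range(x$years), collapse = "-"), ", basis ", x$basis$basis,
      ", ", nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Write report tables from a metrics store
#'
#' Writes each selected table as `<id>.csv` under `out_dir`, with the display
#' rounding policy applied (shares and cost per DDD to one decimal; totals
#' unrounded).  Reruns with identical inputs are byte-identical.
#'
#' @param metrics A `metrics_store` from [cmd_compute()].
#' @param selection Table ids (see `names(metrics$tables)`); default all.
#' @param out_dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
cmd_report <- function(metrics, selection = NULL, out_dir = ".") {
  stopifnot(inherits(metrics, "metrics_store"))
  selection <- selection %||% names(metrics$tables)
  unknown <- setdiff(selection, names(metrics$tables))
  if (length(unknown) > 0) {
    abort(paste0("unknown table id(s): ", paste(unknown, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(selection, function(id) {
    path <- file.path(out_dir, paste0(id, ".csv"))
    readr::write_csv(format_share_table(metrics$tables[[id]]), path,
                     na = "", progress = FALSE)
    path
  }, character(1))
  invisible(paths)
}
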