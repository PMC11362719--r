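sales_columns <- function() {
  c("product_id", "molecule", "route", "strength_value", "strength_unit",
    "pack_size", "packs_per_year", "mrp_per_pack", "wholesale_per_pack",
    "year", "region")
}

procurement_columns <- function() {
  c("molecule", "route", "strength_value", "strength_unit", "pack_size",
    "packs_per_year", "procurement_cost_per_pack", "year", "region")
}

#' Normalize a dose strength to its canonical unit
#'
#' Grams are converted to milligrams; milligrams and million units (MU) pass
#' through.  MU quantities (biological-unit penicillins, polymyxins) are never
#' converted to mass.
#'
#' @param value Numeric vector of strengths.
#' @param unit Character vector of units, each one of `"mg"`, `"g"`, `"MU"`.
#' @return Tibble with columns `value` and `unit` (`"mg"` or `"MU"`).
#' @examples
#' normalize_strength(c(1, 500, 1), c("g", "mg", "MU"))
#' @export
normalize_strength <- function(value, unit) {
  if (any(!unit %in% ddd_units())) {
    abort(paste0("unknown strength unit(s): ",
                 paste(setdiff(unique(unit), ddd_units()), collapse = ", ")))
  }
  out_value <- ifelse(unit == "g", value * 1000, value)
  out_unit <- ifelse(unit == "MU", "MU", "mg")
  tibble::tibble(value = out_value, unit = out_unit)
}

# Parse one character column to double, recording failures as rejects.
parse_num <- function(x) suppressWarnings(as.numeric(x))

validate_rows <- function(raw, sector) {
  n <- nrow(raw)
  reject <- tibble::tibble(row = integer(), column = character(),
                           reason = character())
  flag <- function(bad, column, reason) {
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      reject <<- dplyr::bind_rows(
        reject,
        tibble::tibble(row = which(bad), column = column, reason = reason)
      )
    }
  }

  num_cols <- c("strength_value", "pack_size", "packs_per_year", "year",
                if (sector == "private") c("mrp_per_pack", "wholesale_per_pack"),
                if (sector == "public") "procurement_cost_per_pack")
  parsed <- raw
  for (col in num_cols) {
    blank <- !nzchar(trimws(raw[[col]] %||% character(n)))
    val <- parse_num(raw[[col]])
    optional <- col == "wholesale_per_pack"
    flag(!blank & is.na(val), col, "malformed numeric")
    if (optional) {
      val[blank] <- NA_real_
    } else {
      flag(blank, col, "missing value")
    }
    parsed[[col]] <- val
  }

  flag(!parsed$strength_value > 0, "strength_value", "must be positive")
  flag(!(parsed$pack_size >= 1 & parsed$pack_size == round(parsed$pack_size)),
       "pack_size", "must be a positive integer")
  flag(parsed$packs_per_year < 0, "packs_per_year", "must be non-negative")
  flag(parsed$year != round(parsed$year), "year", "must be an integer")
  flag(!raw$route %in% routes(), "route", "unknown route")
  flag(!raw$strength_unit %in% ddd_units(), "strength_unit", "unknown unit")
  if (sector == "private") {
    flag(parsed$mrp_per_pack < 0, "mrp_per_pack", "must be non-negative")
    flag(!is.na(parsed$wholesale_per_pack) &
           parsed$wholesale_per_pack > parsed$mrp_per_pack,
         "wholesale_per_pack", "exceeds MRP")
    flag(!is.na(parsed$wholesale_per_pack) & parsed$wholesale_per_pack < 0,
         "wholesale_per_pack", "must be non-negative")
  } else {
    flag(parsed$procurement_cost_per_pack < 0, "procurement_cost_per_pack",
         "must be non-negative")
  }

  reject <- dplyr::arrange(reject, .data$row)
  keep <- setdiff(seq_len(n), reject$row)
  records <- parsed[keep, , drop = FALSE]
  records$molecule <- normalize_molecule(records$molecule)
  records$year <- as.integer(records$year)
  records$pack_size <- as.integer(records$pack_size)
  records$sector <- rep(sector, nrow(records))
  list(records = tibble::as_tibble(records), rejects = reject)
}

read_records <- function(path, columns, sector) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("input is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- validate_rows(raw[columns], sector)
  structure(c(out, list(n_input = nrow(raw))), class = "ingest_result")
}

#' Read private-sector pack-level sales records
#'
#' Parses a sales CSV into the internal record shape tagged `sector =
#' "private"`.  Ingest is lossless: every input row is either accepted or
#' listed in the rejects report with its row number, offending column and
#' reason; nothing is silently dropped.  A missing mandatory column is a hard
#' error.
#'
#' @param path CSV with columns `product_id`, `molecule`, `route`,
#'   `strength_value`, `strength_unit`, `pack_size`, `packs_per_year`,
#'   `mrp_per_pack`, `wholesale_per_pack` (may be blank), `year`, `region`.
#' @return An `ingest_result`: list with `records` (tibble of accepted
#'   records, molecule names canonicalized), `rejects` (tibble `row`,
#'   `column`, `reason`) and `n_input`.
#' @export
read_sales <- function(path) {
  read_records(path, sales_columns(), "private")
}

#' Read public-sector procurement records
#'
#' Same contract as [read_sales()] for the public procurement CSV (columns as
#' the sales file minus `product_id`/`mrp_per_pack`/`wholesale_per_pack`,
#' plus `procurement_cost_per_pack`); records are tagged `sector = "public"`.
#'
#' @param path Procurement CSV path.
#' @return An `ingest_result`; see [read_sales()].
#' @export
read_procurement <- function(path) {
  read_records(path, procurement_columns(), "public")
}

#' @export
print.ingest_result <- function(x, ...) {
  cat("<ingest_result> ", nrow(x$records), " accepted, ", nrow(x$rejects),
      " rejected of ", x$n_input, " rows (", x$records$sector[1] %||% "?",
      " sector)\n", sep = "")
  invisible(x)
}

#' Read a mid-year population table
#'
#' @param path CSV with columns `region`, `year`, `population_thousands`.
#' @return Tibble; errors on duplicate (region, year) or non-positive
#'   populations.
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(
    path,
    col_types = readr::cols(
      region = readr::col_character(),
      year = readr::col_integer(),
      population_thousands = readr::col_double()
    ),
    progress = FALSE
  )
  if (anyDuplicated(pop[c("region", "year")]) > 0) {
    abort("duplicate (region, year) in population table")
  }
  if (any(!is.finite(pop$population_thousands) | pop$population_thousands <= 0)) {
    abort("populations must be strictly positive")
  }
  pop
}

#' Write records back to their CSV dialect
#'
#' Inverse of [read_sales()] / [read_procurement()]: writes the accepted
#' records of one sector so that re-reading yields identical records
#' (round-trip property used by the ingest tests).
#'
#' @param records Tibble of records from a single sector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  sector <- unique(records$sector)
  if (length(sector) != 1) abort("records must come from a single sector")
  cols <- if (sector == "private") sales_columns() else procurement_columns()
  readr::write_csv(records[cols], path, na = "", progress = FALSE)
  invisible(path)
}
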