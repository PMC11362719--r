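#' Configure the synthetic sales/procurement generator
#'
#' Builds and validates the configuration that fully determines a synthetic
#' dataset: the molecule catalogue with route-specific DDDs and expected
#' volume weights, a two-sector split per molecule, a lognormal volume model
#' for pack counts, and a multiplicative price chain (procurement <=
#' wholesale <= MRP).  A given seed always reproduces the same dataset.
#'
#' @param catalogue Tibble with one row per molecule-route: `molecule`,
#'   `route`, `ddd_value`, `ddd_unit`, `aware`, `volume_weight` (expected
#'   share of the route's annual DDDs), `public_share` (expected public share
#'   of the molecule's DDDs, in `[0, 1]`), `price_per_ddd` (expected private
#'   MRP per DDD, INR).
#' @param seed Integer seed; the only source of randomness.
#' @param years Years to simulate (annual cross-sections).
#' @param region Region label stamped on every record.
#' @param population Tibble (`region`, `year`, `population_thousands`)
#'   covering every simulated region-year.
#' @param annual_route_ddds Named vector: expected total DDDs per year for
#'   `oral` and `injectable`.
#' @param n_lines Named vector: product lines per route (per sector); lines
#'   are allocated to molecules proportionally to volume weight, so
#'   high-volume molecules get many product lines (as in real sales data).
#' @param volume_sigma Lognormal sigma of pack counts around each line's
#'   expected volume (heavy-tailed volume heterogeneity).
#' @param price_sigma Lognormal sigma of pack prices around the molecule's
#'   expected price per DDD.
#' @param margin Retail margin: wholesale = MRP / (1 + margin).
#' @param procurement_discount Fraction `delta` in `[0, 1)`: public
#'   procurement price per DDD = (1 - delta) * private price per DDD.
#' @param not_listed_share Fraction of each route's volume given to a
#'   molecule deliberately absent from the registry (exercises the coverage
#'   report).
#' @return A validated `generator_config`.
#' @seealso [paper_like_profile()] for the calibrated default, and
#'   [generate_dataset()] to draw a dataset.
#' @export
generator_config <- function(catalogue,
                             seed = 1L,
                             years = 2016:2019,
                             region = "KL",
                             population = NULL,
                             annual_route_ddds = c(oral = 277.6e6,
                                                   injectable = 8.1e6),
                             n_lines = c(oral = 60L, injectable = 120L),
                             volume_sigma = 1.0,
                             price_sigma = 0.2,
                             margin = 0.20,
                             procurement_discount = 0.86,
                             not_listed_share = 1e-4) {
  if (is.null(population)) {
    population <- tibble::tibble(region = region, year = as.integer(years),
                                 population_thousands = 34900)
  }
  cfg <- structure(
    list(catalogue = tibble::as_tibble(catalogue), seed = as.integer(seed),
         years = as.integer(years), region = region, population = population,
         annual_route_ddds = annual_route_ddds, n_lines = n_lines,
         volume_sigma = volume_sigma, price_sigma = price_sigma,
         margin = margin, procurement_discount = procurement_discount,
         not_listed_share = not_listed_share),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  cat_cols <- c("molecule", "route", "ddd_value", "ddd_unit", "aware",
                "volume_weight", "public_share", "price_per_ddd")
  missing_cols <- setdiff(cat_cols, names(cfg$catalogue))
  if (length(missing_cols) > 0) {
    abort(paste0("catalogue is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cfg$catalogue) == 0) abort("catalogue is empty")
  if (length(cfg$years) == 0) abort("years must be non-empty")
  with(cfg$catalogue, {
    if (any(volume_weight < 0) || any(ddd_value <= 0) || any(price_per_ddd < 0)) {
      abort("catalogue weights and DDDs must be non-negative (DDD positive)")
    }
    if (any(public_share < 0 | public_share > 1)) {
      abort("public_share must lie in [0, 1]")
    }
  })
  if (cfg$margin < 0) abort("margin must be >= 0")
  if (cfg$procurement_discount < 0 || cfg$procurement_discount >= 1) {
    abort("procurement_discount must lie in [0, 1)")
  }
  if (cfg$not_listed_share < 0 || cfg$not_listed_share > 1) {
    abort("not_listed_share must lie in [0, 1]")
  }
  pairs <- expand.grid(region = cfg$region, year = cfg$years)
  have <- paste(cfg$population$region, cfg$population$year)
  need <- paste(pairs$region, pairs$year)
  if (!all(need %in% have)) abort("population table does not cover all region-years")
  invisible(cfg)
}

# Normalized DDD value in mg (or MU for biological-unit molecules).
ddd_norm_value <- function(ddd_value, ddd_unit) {
  ifelse(ddd_unit == "g", ddd_value * 1000, ddd_value)
}

#' Calibrated generator profile
#'
#' A [generator_config()] whose expectations match the published Kerala /
#' national consumption profile this package's fixtures describe: injectable
#' AWaRe DDD mix of roughly 26.5 / 50.9 / 0.6 / 21.9 percent
#' (Access/Watch/Reserve/Discouraged), an expected public share of about 31%
#' of injectable DDDs (with class-specific public shares of 34.0 / 33.3 /
#' 25.8 / 20.8 percent), and a deep public procurement discount so the public
#' share of injectable cost (about 6%) sits far below its volume share.
#' Molecule-level weights follow the published molecule shares where printed
#' (ceftriaxone 33 percent of injectable DDDs, amikacin 13.5, gentamicin 8.7,
#' cefotaxime 5.3, ...).
#'
#' @param seed Seed forwarded to [generator_config()].
#' @param ... Overrides forwarded to [generator_config()] (e.g. `n_lines` to
#'   scale the dataset).
#' @return A `generator_config`.
#' @export
paper_like_profile <- function(seed = 1L, ...) {
  inj <- tibble::tribble(
    ~molecule, ~volume_weight, ~price_per_ddd,
    # Access (sums to 26.5)
    "gentamicin", 8.7, 29.0,
    "amikacin", 13.5, 207.3,
    "ampicillin", 1.5, 167.5,
    "amoxicillin", 0.8, 167.5,
    "amoxicillin+clavulanic acid", 1.0, 167.5,
    "benzylpenicillin", 0.3, 167.5,
    "cloxacillin", 0.2, 167.5,
    "clindamycin", 0.3, 167.5,
    "doxycycline", 0.2, 167.5,
    # Watch (sums to 50.9)
    "ceftriaxone", 33.2, 131.3,
    "cefotaxime", 5.3, 177.6,
    "cefuroxime", 1.5, 296.2,
    "ceftazidime", 0.5, 296.2,
    "cefoperazone", 0.3, 296.2,
    "cefoperazone+sulbactam", 2.0, 296.2,
    "cefepime", 0.4, 296.2,
    "meropenem", 1.8, 1500.0,
    "imipenem+cilastatin", 0.4, 1500.0,
    "piperacillin+tazobactam", 2.2, 400.0,
    "vancomycin", 0.5, 500.0,
    "teicoplanin", 0.4, 800.0,
    "azithromycin", 0.6, 296.2,
    "levofloxacin", 0.6, 213.6,
    "ofloxacin", 0.4, 213.6,
    "ciprofloxacin", 0.5, 213.6,
    "streptomycin", 0.2, 141.7,
    "netilmicin", 0.1, 296.2,
    # Reserve (sums to 0.61)
    "linezolid", 0.3, 2798.8,
    "tigecycline", 0.05, 2798.8,
    "colistin", 0.15, 2798.8,
    "polymyxin b", 0.05, 2798.8,
    "aztreonam", 0.06, 2798.8,
    # Discouraged (sums to 21.9)
    "ceftriaxone+sulbactam", 6.6, 330.7,
    "ampicillin+cloxacillin", 7.0, 345.0,
    "ceftriaxone+tazobactam", 8.3, 345.0
  )
  oral <- tibble::tribble(
    ~molecule, ~volume_weight, ~price_per_ddd,
    "amoxicillin", 25, 20,
    "amoxicillin+clavulanic acid", 20, 35,
    "azithromycin", 15, 35,
    "cefixime", 8, 35,
    "ciprofloxacin", 6, 25,
    "doxycycline", 5, 15,
    "cefalexin", 4, 25,
    "cefpodoxime", 3, 35,
    "cefuroxime", 3, 40,
    "levofloxacin", 3, 30,
    "ofloxacin", 3, 30,
    "norfloxacin", 2, 25,
    "sulfamethoxazole+trimethoprim", 2, 10,
    "nitrofurantoin", 0.5, 20,
    "ampicillin+cloxacillin", 0.5, 30
  )
  inj$route <- "injectable"
  oral$route <- "oral"
  reg <- load_registry(awaredose_example("ddd_registry.tsv"))
  catalogue <- dplyr::bind_rows(inj, oral) |>
    dplyr::inner_join(
      reg$entries[c("molecule", "route", "ddd_value", "ddd_unit", "aware")],
      by = c("molecule", "route")
    )
  stopifnot(nrow(catalogue) == nrow(inj) + nrow(oral))
  # published class-specific public shares of injectable volume; oral uniform
  pub_inj <- c(Access = 0.340, Watch = 0.333, Reserve = 0.258,
               Discouraged = 0.208)
  catalogue$public_share <- ifelse(
    catalogue$route == "injectable",
    pub_inj[catalogue$aware],
    0.398
  )
  generator_config(catalogue, seed = seed, ...)
}

#' Draw a synthetic dataset with exact ground-truth aggregates
#'
#' Emits a private-sector sales table and a public-sector procurement table
#' in the exact CSV dialects the ingest module reads, the population table,
#' and a `ground_truth` list of per-stratum aggregates computed at generation
#' time by an independent per-record arithmetic pass (no pipeline code), so
#' every pipeline stage can be verified against it.
#'
#' @param config A `generator_config`.
#' @return A `synthetic_dataset`: list with tibbles `sales`, `procurement`,
#'   `population`, the `ground_truth` list, and the `config`.
#' @examples
#' ds <- generate_dataset(paper_like_profile(seed = 7))
#' names(ds$ground_truth)
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  cat0 <- config$catalogue
  cat0$ddd_norm <- ddd_norm_value(cat0$ddd_value, cat0$ddd_unit)

  lines <- list()
  for (rt in names(config$n_lines)) {
    cr <- cat0[cat0$route == rt, , drop = FALSE]
    if (nrow(cr) == 0) next
    w <- cr$volume_weight / sum(cr$volume_weight)
    n_m <- pmax(1L, as.integer(round(config$n_lines[[rt]] * w)))
    cr$expect_route_ddds <- w * config$annual_route_ddds[[rt]]
    cr$n_lines <- n_m
    lines[[rt]] <- cr[rep(seq_len(nrow(cr)), n_m), , drop = FALSE]
  }
  lines <- dplyr::bind_rows(lines)

  # both sectors share the product-line grid; volumes split by public_share
  grid <- dplyr::bind_rows(
    dplyr::mutate(lines, sector = "private"),
    dplyr::mutate(lines, sector = "public")
  )
  grid <- grid[rep(seq_len(nrow(grid)), each = length(config$years)), ,
               drop = FALSE]
  grid$year <- rep(config$years, length.out = nrow(grid))

  out <- withr::with_seed(config$seed, {
    n <- nrow(grid)
    # per-line dose presentation: strength as a fraction of the DDD, route-
    # typical pack sizes (single vials for injectables, strips for orals)
    frac <- ifelse(grid$route == "injectable",
                   sample(c(0.25, 0.5, 1), n, replace = TRUE),
                   sample(c(0.25, 0.5), n, replace = TRUE))
    pack <- ifelse(grid$route == "injectable",
                   1L, sample(c(6L, 10L, 15L), n, replace = TRUE))
    strength_norm <- grid$ddd_norm * frac
    unit <- ifelse(grid$ddd_unit == "MU", "MU", "mg")
    to_g <- unit == "mg" & strength_norm >= 1000 & strength_norm %% 1000 == 0
    strength_value <- ifelse(to_g, strength_norm / 1000, strength_norm)
    strength_unit <- ifelse(to_g, "g", unit)

    ddd_per_pack <- strength_norm * pack / grid$ddd_norm
    sector_frac <- ifelse(grid$sector == "public",
                          grid$public_share, 1 - grid$public_share)
    target_packs <- grid$expect_route_ddds * sector_frac /
      (grid$n_lines * ddd_per_pack)
    packs <- rlnorm(n,
                    meanlog = log(pmax(target_packs, 1e-12)) -
                      config$volume_sigma^2 / 2,
                    sdlog = config$volume_sigma)
    packs[target_packs == 0] <- 0
    keep <- target_packs > 0

    price_noise <- rlnorm(n, -config$price_sigma^2 / 2, config$price_sigma)
    mrp <- grid$price_per_ddd * ddd_per_pack * price_noise
    wholesale <- mrp / (1 + config$margin)
    proc_noise <- rlnorm(n, -config$price_sigma^2 / 2, config$price_sigma)
    procurement <- grid$price_per_ddd * (1 - config$procurement_discount) *
      ddd_per_pack * proc_noise

    rec <- tibble::tibble(
      molecule = grid$molecule, route = grid$route, sector = grid$sector,
      year = grid$year, region = config$region,
      strength_value = strength_value, strength_unit = strength_unit,
      pack_size = as.integer(pack), packs_per_year = packs,
      mrp_per_pack = mrp, wholesale_per_pack = wholesale,
      procurement_cost_per_pack = procurement,
      ddd_norm = grid$ddd_norm, aware = grid$aware, registered = TRUE
    )
    rec <- rec[keep, , drop = FALSE]  # a sector with share 0 emits no lines

    # a sliver of volume for a molecule the registry does not know
    if (config$not_listed_share > 0) {
      nl <- rec[rec$sector == "private" & rec$route == "injectable", ,
                drop = FALSE]
      nl <- nl[seq_len(min(length(config$years), nrow(nl))), , drop = FALSE]
      if (nrow(nl) > 0) {
        nl$molecule <- "cefpirome+sulbactam"
        nl$year <- config$years[seq_len(nrow(nl))]
        nl$packs_per_year <- nl$packs_per_year * config$not_listed_share
        nl$aware <- "NotListed"
        nl$registered <- FALSE
        rec <- dplyr::bind_rows(rec, nl)
      }
    }
    rec
  })

  out$product_id <- sprintf("SKU%05d", seq_len(nrow(out)))
  sales <- out[out$sector == "private", , drop = FALSE]
  sales <- sales[c("product_id", "molecule", "route", "strength_value",
                   "strength_unit", "pack_size", "packs_per_year",
                   "mrp_per_pack", "wholesale_per_pack", "year", "region")]
  procurement <- out[out$sector == "public", , drop = FALSE]
  procurement <- procurement[c("molecule", "route", "strength_value",
                               "strength_unit", "pack_size", "packs_per_year",
                               "procurement_cost_per_pack", "year", "region")]

  structure(
    list(sales = sales, procurement = procurement,
         population = config$population,
         ground_truth = ground_truth_pass(out, config),
         config = config),
    class = "synthetic_dataset"
  )
}

# Independent ground-truth aggregation: plain arithmetic + rowsum(), no
# pipeline code.  Unregistered molecules contribute no DDDs (the pipeline
# excludes them into its coverage report) but their packs/spend are recorded.
ground_truth_pass <- function(rec, config) {
  reg <- rec[rec$registered, , drop = FALSE]
  snorm <- ifelse(reg$strength_unit == "g",
                  reg$strength_value * 1000, reg$strength_value)
  ddd_per_pack <- snorm * reg$pack_size / reg$ddd_norm
  ddds <- ddd_per_pack * reg$packs_per_year
  cost_natural <- ifelse(reg$sector == "public",
                         reg$procurement_cost_per_pack,
                         reg$mrp_per_pack) * reg$packs_per_year
  cost_wholesale <- ifelse(reg$sector == "public",
                           reg$procurement_cost_per_pack,
                           reg$wholesale_per_pack) * reg$packs_per_year

  by_key <- function(key) {
    m <- rowsum(cbind(ddds, cost_natural, cost_wholesale), key)
    tibble::tibble(key = rownames(m), total_ddds = unname(m[, 1]),
                   total_cost = unname(m[, 2]),
                   total_cost_wholesale = unname(m[, 3]))
  }
  pop <- config$population$population_thousands[
    match(paste(config$region, config$years),
          paste(config$population$region, config$population$year))
  ]
  yearly <- rowsum(ddds, reg$year)
  did_by_year <- yearly[, 1] / (pop[match(rownames(yearly),
                                          as.character(config$years))] * 365)
  nl <- rec[!rec$registered, , drop = FALSE]
  list(
    total_ddds = sum(ddds),
    by_route = by_key(reg$route),
    by_sector = by_key(reg$sector),
    by_sector_route = by_key(paste(reg$sector, reg$route, sep = ".")),
    by_aware_route = by_key(paste(reg$aware, reg$route, sep = ".")),
    by_molecule_route = by_key(paste(reg$molecule, reg$route, sep = ".")),
    by_year = tibble::tibble(year = as.integer(rownames(yearly)),
                             total_ddds = unname(yearly[, 1]),
                             did = unname(did_by_year)),
    did_mean = mean(did_by_year),
    not_listed = tibble::tibble(
      molecule = unique(nl$molecule),
      packs = sum(nl$packs_per_year),
      spend = sum(nl$mrp_per_pack * nl$packs_per_year)
    )
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$sales), " sales + ",
      nrow(x$procurement), " procurement records, years ",
      paste(range(x$config$years), collapse = "-"),
      ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `sales.csv`, `procurement.csv` and `population.csv` in the ingest
#' CSV dialects, plus `ground_truth.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$sales, file.path(dir, "sales.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(dataset$procurement, file.path(dir, "procurement.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(dataset$population, file.path(dir, "population.csv"),
                   progress = FALSE)
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
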