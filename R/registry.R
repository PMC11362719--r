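#' Canonicalize a molecule name
#'
#' Folds case and whitespace and rewrites fixed-dose-combination (FDC)
#' separators so that spellings such as `"Ceftriaxone - sulbactam"`,
#' `"ceftriaxone/sulbactam"` and `"ceftriaxone+Sulbactam"` all map to the
#' canonical `"ceftriaxone+sulbactam"`.  Any `-`, `+` or `/` (with or without
#' surrounding spaces) is treated as a component separator, so hyphenated
#' shorthand names (e.g. "co-trimoxazole") must arrive pre-expanded into
#' component form.  The transformation is idempotent.
#'
#' @param x Character vector of molecule names.
#' @return Character vector of canonical names (lower case, components joined
#'   with `"+"`).
#' @examples
#' normalize_molecule(c("CEFTRIAXONE ", "Piperacillin -tazobactam"))
#' @export
normalize_molecule <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s*[-+/]\\s*", "+", x)
  x <- gsub("\\s+", " ", x)
  x
}

routes <- function() c("oral", "injectable")
aware_classes <- function() c("Access", "Watch", "Reserve", "Discouraged", "NotListed")
ddd_units <- function() c("mg", "g", "MU")

#' Load the ATC/DDD/AWaRe molecule registry
#'
#' Reads the tab-separated registry that binds every molecule-route pair to a
#' defined daily dose (DDD), an ATC level-5 code and an AWaRe class, together
#' with the display labels for ATC level-3/4 prefixes.  Molecule names are
#' canonicalized with [normalize_molecule()] on load.
#'
#' @param path Registry TSV with columns `molecule`, `atc5`, `route`,
#'   `ddd_value`, `ddd_unit`, `aware`, `is_fdc`, `components`
#'   (semicolon-separated), `ddd_source`.
#' @param labels_path Label TSV with columns `prefix`, `level`, `label`.
#'   Defaults to the bundled ATC label table.
#' @return An object of class `ddd_registry`: a list with `entries` (tibble of
#'   DDD assignments) and `labels` (tibble of ATC prefix labels).
#' @details Loading fails with an informative error on a duplicated
#'   (molecule, route) pair, a non-positive DDD value, an unknown dose unit or
#'   route, an unknown AWaRe class, a malformed ATC code, or an FDC entry with
#'   fewer than two components.
#' @examples
#' reg <- load_registry(awaredose_example("ddd_registry.tsv"))
#' reg
#' @export
load_registry <- function(path,
                          labels_path = awaredose_example("atc_labels.tsv")) {
  entries <- readr::read_tsv(
    path,
    col_types = readr::cols(
      molecule = readr::col_character(),
      atc5 = readr::col_character(),
      route = readr::col_character(),
      ddd_value = readr::col_double(),
      ddd_unit = readr::col_character(),
      aware = readr::col_character(),
      is_fdc = readr::col_logical(),
      components = readr::col_character(),
      ddd_source = readr::col_character()
    ),
    na = character(),
    progress = FALSE
  )
  required <- c("molecule", "atc5", "route", "ddd_value", "ddd_unit",
                "aware", "is_fdc", "components", "ddd_source")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  entries$molecule <- normalize_molecule(entries$molecule)
  entries$aware <- gsub("\\s+", "", entries$aware)

  dup <- entries[duplicated(entries[c("molecule", "route")]), , drop = FALSE]
  if (nrow(dup) > 0) {
    abort(paste0("duplicate registry entry for (",
                 dup$molecule[1], ", ", dup$route[1], ")"))
  }
  if (any(!is.finite(entries$ddd_value) | entries$ddd_value <= 0)) {
    bad <- entries$molecule[!is.finite(entries$ddd_value) | entries$ddd_value <= 0][1]
    abort(paste0("non-positive DDD value for '", bad, "'"))
  }
  if (any(!entries$ddd_unit %in% ddd_units())) {
    bad <- setdiff(unique(entries$ddd_unit), ddd_units())
    abort(paste0("unknown DDD unit(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!entries$route %in% routes())) {
    bad <- setdiff(unique(entries$route), routes())
    abort(paste0("unknown route(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!entries$aware %in% aware_classes())) {
    bad <- setdiff(unique(entries$aware), aware_classes())
    abort(paste0("unknown AWaRe class(es): ", paste(bad, collapse = ", ")))
  }
  if (any(!grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", entries$atc5))) {
    bad <- entries$atc5[!grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", entries$atc5)][1]
    abort(paste0("malformed ATC level-5 code: '", bad, "'"))
  }
  n_comp <- vapply(
    strsplit(entries$components, ";", fixed = TRUE),
    function(x) sum(nzchar(trimws(x))), integer(1)
  )
  if (any(entries$is_fdc & n_comp < 2)) {
    bad <- entries$molecule[entries$is_fdc & n_comp < 2][1]
    abort(paste0("FDC entry '", bad, "' lists fewer than two components"))
  }
  # one molecule must not mix MU and mass units across routes
  mixed <- entries |>
    dplyr::summarise(
      mu = any(.data$ddd_unit == "MU"),
      mass = any(.data$ddd_unit != "MU"),
      .by = "molecule"
    ) |>
    dplyr::filter(.data$mu & .data$mass)
  if (nrow(mixed) > 0) {
    abort(paste0("molecule '", mixed$molecule[1],
                 "' mixes MU and mass DDD units"))
  }

  labels <- readr::read_tsv(
    labels_path,
    col_types = readr::cols(
      prefix = readr::col_character(),
      level = readr::col_integer(),
      label = readr::col_character()
    ),
    progress = FALSE
  )
  reachable <- unique(c(substr(entries$atc5, 1, 4), substr(entries$atc5, 1, 5)))
  uncovered <- setdiff(reachable, labels$prefix)
  if (length(uncovered) > 0) {
    abort(paste0("no ATC label for prefix(es): ",
                 paste(uncovered, collapse = ", ")))
  }

  structure(list(entries = entries, labels = labels), class = "ddd_registry")
}

#' @export
print.ddd_registry <- function(x, ...) {
  cat("<ddd_registry> ", nrow(x$entries), " molecule-route entries (",
      sum(x$entries$route == "injectable"), " injectable, ",
      sum(x$entries$route == "oral"), " oral), ",
      nrow(x$labels), " ATC labels\n", sep = "")
  invisible(x)
}

#' Look up the DDD assignment for a molecule-route pair
#'
#' @param registry A `ddd_registry`.
#' @param molecule Molecule name (canonicalized internally).
#' @param route `"oral"` or `"injectable"`.  The lookup never substitutes the
#'   other route's DDD.
#' @return A one-row tibble (the assignment), or `NULL` when the pair is not
#'   in the registry.
#' @examples
#' reg <- load_registry(awaredose_example("ddd_registry.tsv"))
#' lookup_ddd(reg, "Ceftriaxone - sulbactam", "injectable")
#' @export
lookup_ddd <- function(registry, molecule, route) {
  stopifnot(inherits(registry, "ddd_registry"))
  if (!route %in% routes()) abort(paste0("unknown route '", route, "'"))
  key <- normalize_molecule(molecule)
  hit <- registry$entries[registry$entries$molecule == key &
                            registry$entries$route == route, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit
}

#' Classify a molecule into its AWaRe group
#'
#' Registry hits return the entry's class; misses fall back to `"NotListed"`.
#' Vectorized over `molecule` and `route`.
#'
#' @inheritParams lookup_ddd
#' @return Character vector of AWaRe classes.
#' @examples
#' reg <- load_registry(awaredose_example("ddd_registry.tsv"))
#' classify_aware(reg, c("gentamicin", "no-such-drug"), "injectable")
#' @export
classify_aware <- function(registry, molecule, route) {
  stopifnot(inherits(registry, "ddd_registry"))
  key <- paste(normalize_molecule(molecule), route, sep = "\r")
  ref <- paste(registry$entries$molecule, registry$entries$route, sep = "\r")
  out <- registry$entries$aware[match(key, ref)]
  out[is.na(out)] <- "NotListed"
  out
}

#' ATC group of a DDD assignment at a chosen level
#'
#' Truncates the level-5 ATC code to the level-3 (4 characters) or level-4
#' (5 characters) prefix and attaches its display label; at level 5 the label
#' is the molecule name itself.
#'
#' @param assignment One or more registry entry rows (as returned by
#'   [lookup_ddd()] or taken from `registry$entries`).
#' @param level 3, 4 or 5.
#' @param registry The `ddd_registry` supplying prefix labels.
#' @return Tibble with columns `code` and `label`, one row per assignment row.
#' @examples
#' reg <- load_registry(awaredose_example("ddd_registry.tsv"))
#' atc_group(lookup_ddd(reg, "ceftriaxone", "injectable"), 3, reg)
#' @export
atc_group <- function(assignment, level, registry) {
  stopifnot(inherits(registry, "ddd_registry"), level %in% c(3L, 4L, 5L))
  if (level == 5) {
    return(tibble::tibble(code = assignment$atc5, label = assignment$molecule))
  }
  width <- if (level == 3) 4L else 5L
  code <- substr(assignment$atc5, 1, width)
  lab <- registry$labels$label[match(code, registry$labels$prefix)]
  if (anyNA(lab)) {
    abort(paste0("no ATC label for prefix '", code[is.na(lab)][1], "'"))
  }
  tibble::tibble(code = code, label = lab)
}
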