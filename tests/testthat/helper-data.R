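# Shared fixtures built in code: registry loaded once, small record builders.

test_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) {
      reg <<- load_registry(awaredose_example("ddd_registry.tsv"))
    }
    reg
  }
})

# One private record with sensible defaults, overridable per test.
make_record <- function(molecule = "ceftriaxone", route = "injectable",
                        strength_value = 1, strength_unit = "g",
                        pack_size = 1L, packs_per_year = 1,
                        mrp_per_pack = 100, wholesale_per_pack = NA_real_,
                        procurement_cost_per_pack = NA_real_,
                        year = 2016L, region = "KL", sector = "private",
                        product_id = "SKU00001") {
  tibble::tibble(
    product_id = product_id, molecule = normalize_molecule(molecule),
    route = route, strength_value = strength_value,
    strength_unit = strength_unit, pack_size = pack_size,
    packs_per_year = packs_per_year, mrp_per_pack = mrp_per_pack,
    wholesale_per_pack = wholesale_per_pack,
    procurement_cost_per_pack = procurement_cost_per_pack,
    year = year, region = region, sector = sector
  )
}

# A written-to-disk synthetic dataset reread through ingest, memoized per
# size so several tests can share one draw.
synthetic_roundtrip <- local({
  cache <- list()
  function(seed = 42L, n_lines = c(oral = 60L, injectable = 120L)) {
    key <- paste(seed, paste(n_lines, collapse = "x"))
    if (is.null(cache[[key]])) {
      ds <- generate_dataset(paper_like_profile(seed = seed, n_lines = n_lines))
      dir <- tempfile("synthetic")
      write_dataset(ds, dir)
      sales <- read_sales(file.path(dir, "sales.csv"))
      proc <- read_procurement(file.path(dir, "procurement.csv"))
      cache[[key]] <<- list(
        ds = ds, dir = dir,
        records = dplyr::bind_rows(sales$records, proc$records),
        rejects = dplyr::bind_rows(sales$rejects, proc$rejects)
      )
    }
    cache[[key]]
  }
})
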