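test_that("the generator is byte-identical under a fixed seed", {
  cfg <- paper_like_profile(seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("sales.csv", "procurement.csv", "population.csv",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed changes the data
  write_dataset(generate_dataset(paper_like_profile(seed = 100)), d2)
  expect_false(identical(readLines(file.path(d1, "sales.csv")),
                         readLines(file.path(d2, "sales.csv"))))
})

test_that("invalid generator configs fail before any output", {
  cat_ok <- paper_like_profile()$catalogue
  expect_error(generator_config(cat_ok, margin = -0.1), "margin")
  expect_error(generator_config(cat_ok, procurement_discount = 1), "discount")
  expect_error(generator_config(cat_ok[0, ]), "empty")
  bad <- cat_ok; bad$public_share[1] <- 1.5
  expect_error(generator_config(bad), "public_share")
  expect_error(generator_config(cat_ok, years = integer(0)), "years")
})

test_that("an all-private split leaves the procurement file empty", {
  cfg <- paper_like_profile(seed = 3)
  cfg$catalogue$public_share <- 0
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$procurement), 0)
  expect_gt(nrow(ds$sales), 0)
})

test_that("the price chain is ordered: procurement < wholesale < MRP", {
  ds <- synthetic_roundtrip()$ds
  expect_true(all(ds$sales$wholesale_per_pack < ds$sales$mrp_per_pack))
  # per molecule, mean public procurement price per pack sits far below the
  # private wholesale price of the same presentations
  expect_equal(ds$sales$mrp_per_pack / ds$sales$wholesale_per_pack,
               rep(1.20, nrow(ds$sales)), tolerance = 1e-12)
  m <- ds$config$margin
  expect_equal(m, 0.20)
  delta <- ds$config$procurement_discount
  expect_true(delta > 0 && (1 - delta) < 1 / (1 + m))
})

test_that("the full pipeline reproduces the generator's ground truth", {
  rt <- synthetic_roundtrip()
  gt <- rt$ds$ground_truth
  reg <- test_registry()
  ann <- annotate_cost(compute_ddds(rt$records, reg), "mrp")

  expect_equal(total_ddds(ann), gt$total_ddds, tolerance = 1e-9)

  by_sr <- dplyr::summarise(ann, d = sum(total_ddds), c = sum(total_cost),
                            .by = c("sector", "route"))
  for (i in seq_len(nrow(by_sr))) {
    key <- paste(by_sr$sector[i], by_sr$route[i], sep = ".")
    expect_equal(by_sr$d[i],
                 gt$by_sector_route$total_ddds[gt$by_sector_route$key == key],
                 tolerance = 1e-9)
    expect_equal(by_sr$c[i],
                 gt$by_sector_route$total_cost[gt$by_sector_route$key == key],
                 tolerance = 1e-9)
  }
  by_ar <- dplyr::summarise(ann, d = sum(total_ddds),
                            .by = c("aware", "route"))
  for (i in seq_len(nrow(by_ar))) {
    key <- paste(by_ar$aware[i], by_ar$route[i], sep = ".")
    expect_equal(by_ar$d[i],
                 gt$by_aware_route$total_ddds[gt$by_aware_route$key == key],
                 tolerance = 1e-9)
  }
  # wholesale-basis cost reproduces the wholesale ground truth
  annw <- annotate_cost(ann[setdiff(names(ann), "total_cost")],
                        price_basis("wholesale"))
  expect_equal(sum(annw$total_cost),
               sum(gt$by_sector_route$total_cost_wholesale),
               tolerance = 1e-9)
  # the deliberately unregistered molecule surfaces in the coverage report
  cov <- coverage_report(ann)
  expect_equal(cov$molecule, gt$not_listed$molecule)
  expect_equal(sum(cov$packs), gt$not_listed$packs, tolerance = 1e-9)
})

test_that("configured AWaRe mix, sector split and mark-up are recovered", {
  # one large draw; empirical shares vs configured expectations at 3 SE,
  # with SE from a nonparametric bootstrap over product-line records
  cfg <- paper_like_profile(seed = 11,
                            n_lines = c(oral = 2700L, injectable = 3500L))
  ds <- generate_dataset(cfg)
  gt <- ds$ground_truth
  n_rec <- nrow(ds$sales) + nrow(ds$procurement)
  expect_gt(n_rec, 49000)

  inj <- gt$by_aware_route[grepl("\\.injectable$", gt$by_aware_route$key), ]
  watch_hat <- inj$total_ddds[inj$key == "Watch.injectable"] /
    sum(inj$total_ddds)
  sr <- gt$by_sector_route
  inj_keys <- grepl("\\.injectable$", sr$key)
  pub_hat <- sr$total_ddds[sr$key == "public.injectable"] /
    sum(sr$total_ddds[inj_keys])

  # per-record DDD volumes for the bootstrap (plain arithmetic)
  recs <- dplyr::bind_rows(
    dplyr::mutate(ds$sales, sector = "private"),
    dplyr::mutate(ds$procurement, sector = "public")
  )
  recs <- recs[recs$route == "injectable", ]
  catal <- cfg$catalogue[cfg$catalogue$route == "injectable", ]
  idx <- match(recs$molecule, catal$molecule)
  ddd_norm <- ifelse(catal$ddd_unit[idx] == "g", catal$ddd_value[idx] * 1000,
                     catal$ddd_value[idx])
  snorm <- ifelse(recs$strength_unit == "g", recs$strength_value * 1000,
                  recs$strength_value)
  vol <- snorm * recs$pack_size / ddd_norm * recs$packs_per_year
  vol[is.na(vol)] <- 0  # the unregistered molecule carries no DDDs
  is_watch <- !is.na(idx) & catal$aware[idx] == "Watch"
  is_pub <- recs$sector == "public"

  boot <- withr::with_seed(1234, {
    n <- length(vol)
    t(vapply(seq_len(200), function(b) {
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      v <- vol * w
      c(sum(v[is_watch]) / sum(v), sum(v[is_pub]) / sum(v))
    }, numeric(2)))
  })
  se_watch <- sd(boot[, 1]); se_pub <- sd(boot[, 2])

  watch_cfg <- sum(catal$volume_weight[catal$aware == "Watch"]) /
    sum(catal$volume_weight)
  pub_cfg <- sum(catal$volume_weight * catal$public_share) /
    sum(catal$volume_weight)
  expect_lt(abs(watch_hat - watch_cfg), 3 * se_watch)
  expect_lt(abs(pub_hat - pub_cfg), 3 * se_pub)

  # mark-up recovery is exact by construction of the price chain
  markup <- ds$sales$mrp_per_pack / ds$sales$wholesale_per_pack - 1
  expect_equal(mean(markup), cfg$margin, tolerance = 1e-9)
})

test_that("the calibrated profile reproduces the published mix in a 10k draw", {
  cfg <- paper_like_profile(seed = 7,
                            n_lines = c(oral = 550L, injectable = 700L))
  ds <- generate_dataset(cfg)
  expect_gt(nrow(ds$sales) + nrow(ds$procurement), 9999)
  gt <- ds$ground_truth

  inj <- gt$by_aware_route[grepl("\\.injectable$", gt$by_aware_route$key), ]
  watch_share <- 100 * inj$total_ddds[inj$key == "Watch.injectable"] /
    sum(inj$total_ddds)
  expect_lt(abs(watch_share - 50.9), 3)

  sr <- gt$by_sector_route
  inj_keys <- grepl("\\.injectable$", sr$key)
  pub_ddd <- 100 * sr$total_ddds[sr$key == "public.injectable"] /
    sum(sr$total_ddds[inj_keys])
  pub_cost <- 100 * sr$total_cost[sr$key == "public.injectable"] /
    sum(sr$total_cost[inj_keys])
  expect_lt(abs(pub_ddd - 31.4), 3)
  expect_lt(pub_cost, pub_ddd)
})
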