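test_that("share tables reproduce the published national AWaRe arithmetic", {
  aware <- load_reference_table("national_aware")
  st <- share_table(aware, "aware")
  stf <- format_share_table(st)
  watch <- stf[stf$group == "Watch", ]
  expect_equal(watch$cost_per_ddd, 296.2)
  expect_equal(watch$ddd_share_pct, 50.9)
  # the published 52.3% derives from unrounded totals; from printed inputs
  # the recomputed share agrees within 0.2% relative
  expect_equal(st$cost_share_pct[st$group == "Watch"], 52.3,
               tolerance = 0.002)
  reserve <- st[st$group == "Reserve", ]
  expect_equal(round(reserve$ddd_share_pct, 2), 0.61)
  # shares are computed pre-rounding and sum to 100
  body <- st[st$group != "Total", ]
  expect_equal(sum(body$ddd_share_pct), 100, tolerance = 1e-9)
  expect_equal(sum(body$cost_share_pct), 100, tolerance = 1e-9)
  expect_equal(st$total_ddds[st$group == "Total"], sum(body$total_ddds))
})

test_that("molecule share table matches the published top-five rows", {
  mol <- load_reference_table("national_molecule")
  st <- format_share_table(share_table(mol, "molecule"))
  expect_equal(st$ddd_share_pct[st$group == "cefotaxime"], 5.3)
  expect_equal(st$cost_per_ddd[st$group == "gentamicin"], 29.0)
  # remainder row recomputed from unrounded totals: printed as 32.4
  other <- share_table(mol, "molecule")
  other <- other[other$group == "all the other antibiotics", ]
  expect_equal(other$ddd_share_pct, 32.4, tolerance = 0.005)
  # single-group input covers everything
  one <- share_table(mol[mol$molecule == "ceftriaxone", ], "molecule")
  expect_equal(one$ddd_share_pct, c(100, 100))
})

test_that("sector shares reproduce the published Kerala arithmetic", {
  route <- load_reference_table("kerala_route_sector")
  ss <- format_share_table(sector_share(route, "route"))
  expect_equal(ss$public_ddd_share_pct[ss$group == "oral"], 39.8)
  expect_equal(ss$private_cost_share_pct[ss$group == "injectable"], 93.7)
  expect_equal(ss$public_cost_share_pct[ss$group == "Total"], 8.3)

  mol <- load_reference_table("kerala_molecule_sector")
  ms <- format_share_table(sector_share(mol, "molecule"))
  expect_equal(ms$private_ddd_share_pct[ms$group == "ceftriaxone"], 78.7)
  expect_equal(ms$private_cost_share_pct[ms$group == "meropenem"], 99.2)
  # within every group, public + private = 100 for volume and cost
  raw <- sector_share(mol, "molecule")
  expect_equal(raw$public_ddd_share_pct + raw$private_ddd_share_pct,
               rep(100, nrow(raw)), tolerance = 1e-9)
  expect_equal(raw$public_cost_share_pct + raw$private_cost_share_pct,
               rep(100, nrow(raw)), tolerance = 1e-9)
})

test_that("all-public input yields a 100/0 sector split", {
  mol <- load_reference_table("kerala_molecule_sector")
  pub <- mol[mol$sector == "public", ]
  ss <- sector_share(pub, "molecule")
  expect_true(all(ss$public_ddd_share_pct == 100))
  expect_true(all(ss$private_ddds == 0))
})

test_that("formulation counting is distinct over molecules with volume", {
  mol <- load_reference_table("kerala_molecule_sector")
  mol$route <- "injectable"
  expect_equal(formulation_count(mol, sector = "public",
                                 route = "injectable"), 21)
  # benzylpenicillin and cloxacillin have zero private volume in this table
  expect_equal(formulation_count(mol, sector = "private"), 19)
  expect_equal(formulation_count(mol[0, ]), 0)
  dup <- dplyr::bind_rows(mol, mol)
  expect_equal(formulation_count(dup, sector = "public"), 21)
})

test_that("top-n folds the remainder so totals are conserved", {
  mol <- load_reference_table("kerala_molecule_sector") |>
    dplyr::summarise(total_ddds = sum(total_ddds),
                     total_cost = sum(total_cost), .by = "molecule")
  st <- share_table(mol, "molecule")
  top5 <- top_n_share(st, 5, by = "ddds")
  expect_equal(nrow(top5), 7)  # 5 + remainder + totals
  body <- top5[!top5$group %in% "Total", ]
  expect_equal(sum(body$total_ddds), st$total_ddds[st$group == "Total"])
  expect_equal(sum(body$ddd_share_pct), 100, tolerance = 1e-9)
  # n covering all groups: unchanged, no empty remainder
  all_n <- top_n_share(st, nrow(st), by = "cost")
  expect_equal(nrow(all_n), nrow(st))
  expect_false("All the other" %in% all_n$group)
  # deterministic tie-break: descending metric then alphabetical
  tie <- tibble::tibble(molecule = c("b", "a", "c"),
                        total_ddds = c(5, 5, 1), total_cost = c(1, 1, 1))
  tt <- top_n_share(share_table(tie, "molecule"), 2)
  expect_equal(tt$group[1:2], c("a", "b"))
})

test_that("ATC level-5 totals roll up exactly through level 4 to level 3", {
  rt <- synthetic_roundtrip()
  reg <- test_registry()
  ann <- add_atc_groups(compute_ddds(rt$records, reg), reg)
  ann$total_cost <- record_cost(ann, "mrp")
  t5 <- dplyr::summarise(ann, d = sum(total_ddds), c = sum(total_cost),
                         .by = c("atc3", "atc4", "atc5"))
  t4 <- dplyr::summarise(ann, d = sum(total_ddds), .by = "atc4")
  t3 <- dplyr::summarise(ann, d = sum(total_ddds), .by = "atc3")
  roll4 <- dplyr::summarise(t5, d = sum(d), .by = "atc4")
  expect_equal(dplyr::arrange(roll4, atc4), dplyr::arrange(t4, atc4),
               tolerance = 1e-9)
  roll3 <- dplyr::summarise(t5, d = sum(d), .by = "atc3")
  expect_equal(dplyr::arrange(roll3, atc3), dplyr::arrange(t3, atc3),
               tolerance = 1e-9)
  expect_true(all(startsWith(t5$atc4, t5$atc3)))
  expect_true(all(startsWith(t5$atc5, t5$atc4)))
})
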