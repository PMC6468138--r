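# Domain types, readers/writers and the bundled dataset.

test_that("macronutrient_profile enforces non-negativity and sum-to-100", {
  p <- macronutrient_profile(25, 0, 75)
  expect_s3_class(p, "macronutrient_profile")
  expect_equal(unname(sum(p)), 100)
  expect_error(macronutrient_profile(25, 0, 74), "sum to 100")
  expect_error(macronutrient_profile(-1, 26, 75), ">= 0")
  # rounded literature triplets are rescued by normalize
  q <- macronutrient_profile(37.7, 45.8, 16.4, normalize = TRUE)
  expect_equal(unname(sum(q)), 100, tolerance = 1e-12)
})

test_that("diet_composition validates RF totals and duplicates", {
  items <- data.frame(food_id = c("a", "b"), rf_pct = c(60, 30))
  d <- diet_composition(items, unidentified_rf_pct = 10)
  expect_equal(sum(d$items$rf_pct) + d$unidentified_rf_pct, 100)
  expect_error(diet_composition(items, unidentified_rf_pct = 0), "total 100")
  expect_error(
    diet_composition(data.frame(food_id = c("a", "a"), rf_pct = c(50, 50))),
    "duplicate")
})

test_that("bundled proximate fixtures match the printed composition tables", {
  dhr_s <- bear_proximate("dhr_summer")
  expect_equal(nrow(dhr_s), 8)
  expect_equal(dhr_s$food_id[1], "Rubus ellipticus")
  expect_equal(dhr_s$crude_fiber_pct[1], 22.58)
  # golden spot checks, one row per table, all six components
  expect_equal(
    unlist(dhr_s[dhr_s$food_id == "Zea mays",
                 c("ash_pct", "crude_protein_pct", "ether_extract_pct",
                   "moisture_pct", "crude_fiber_pct",
                   "available_carbohydrate_pct")], use.names = FALSE),
    c(3.65, 8.05, 2.82, 7.58, 2.44, 75.46))
  dhr_a <- bear_proximate("dhr_autumn")
  expect_equal(nrow(dhr_a), 6)
  expect_equal(dhr_a$crude_protein_pct[dhr_a$food_id == "Rhododendron spp."], 7.82)
  ksl_s <- bear_proximate("ksl_summer")
  expect_equal(nrow(ksl_s), 11)
  expect_equal(
    unlist(ksl_s[ksl_s$food_id == "Arundinaria spp.",
                 c("crude_protein_pct", "ether_extract_pct",
                   "available_carbohydrate_pct")], use.names = FALSE),
    c(8.24, 1.40, 24.87))
  ksl_a <- bear_proximate("ksl_autumn")
  expect_equal(nrow(ksl_a), 9)
  expect_equal(ksl_a$ether_extract_pct[ksl_a$food_id == "Ficus semicordata"], 0.15)
  # every bundled row satisfies the 100 +/- 0.1 component-sum invariant
  for (nm in c("dhr_summer", "dhr_autumn", "ksl_summer", "ksl_autumn")) {
    x <- bear_proximate(nm)
    tots <- rowSums(x[, c("ash_pct", "crude_protein_pct", "ether_extract_pct",
                          "moisture_pct", "crude_fiber_pct",
                          "available_carbohydrate_pct")])
    expect_true(all(abs(tots - 100) <= 0.1), info = nm)
  }
})

test_that("bundled diet fixtures match the printed RF tables digit for digit", {
  d <- bear_diet("dhr_summer")
  expect_equal(nrow(d$items), 10)
  expect_equal(d$unidentified_rf_pct, 1.6)
  expect_equal(d$n_scats, 41L)
  expect_equal(
    setNames(d$items$rf_pct, d$items$food_id),
    c("Rubus ellipticus" = 3.2, "Arundinaria spp." = 34.6,
      "Berberis aristata" = 7.9, "Lichen" = 5.6, "Ants" = 3.3,
      "Paskate (unknown)" = 3.1, "Quercus semicarpifolia (seed)" = 5.6,
      "Arisaema tortuosum" = 11.8, "Zea mays" = 12.8,
      "Matteuccia struthiopteris" = 10.5))
  da <- bear_diet("dhr_autumn")
  expect_equal(
    setNames(da$items$rf_pct, da$items$food_id),
    c("Rubus ellipticus" = 7.5, "Arundinaria spp." = 30.2,
      "Berberis aristata" = 12.5, "Lichen" = 13.3,
      "Quercus semicarpifolia (leaf)" = 6.7, "Rhododendron spp." = 17.0,
      "Ants" = 4.3, "Termites" = 3.1))
  ks <- bear_diet("ksl_summer")
  expect_equal(
    setNames(ks$items$rf_pct, ks$items$food_id),
    c("Berberis aristata" = 2.3, "Arundinaria spp." = 24.2,
      "Ficus semicordata" = 3.4, "Ghamari (unknown sp.)" = 5.2,
      "Quercus incana" = 7.1, "Matteuccia struthiopteris" = 9.2,
      "Rubus ellipticus" = 3.4, "Arisaema tortuosum" = 9.5,
      "Paspalum scrobiculatum" = 9.8, "Pyrus pyraster" = 13.2,
      "Zea mays" = 10.2))
  ka <- bear_diet("ksl_autumn")
  expect_equal(
    setNames(ka$items$rf_pct, ka$items$food_id),
    c("Berberis aristata" = 3.3, "Arundinaria spp." = 21.5,
      "Ficus semicordata" = 7.2, "Ghamari (unknown sp.)" = 7.9,
      "Quercus incana" = 8.6, "Matteuccia struthiopteris" = 15.9,
      "Rubus ellipticus" = 7.8, "Rhododendron spp." = 13,
      "Lichen" = 9.4))
  expect_equal(ka$unidentified_rf_pct, 5.4)
})

test_that("proximate reader flags missing AC, rejects bad schema and values", {
  # empty file with header only -> empty table
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("food_id,ash_pct,crude_protein_pct,ether_extract_pct,",
                   "moisture_pct,crude_fiber_pct", sep = ""), f)
  expect_equal(nrow(read_proximate_table(f)), 0)
  # AC column absent entirely -> flagged, filled with NA
  writeLines(c("food_id,ash_pct,crude_protein_pct,ether_extract_pct,moisture_pct,crude_fiber_pct",
               "x,5,10,2,10,20"), f)
  x <- read_proximate_table(f)
  expect_true(all(attr(x, "ac_missing")))
  expect_true(is.na(x$available_carbohydrate_pct[1]))
  # missing mandatory column named in the error
  writeLines(c("food_id,ash_pct,crude_protein_pct,ether_extract_pct,moisture_pct",
               "x,5,10,2,10"), f)
  expect_error(read_proximate_table(f), "crude_fiber_pct")
  # negative value -> validation error naming the row
  writeLines(c("food_id,ash_pct,crude_protein_pct,ether_extract_pct,moisture_pct,crude_fiber_pct,available_carbohydrate_pct",
               "x,5,-1,2,10,20,64"), f)
  expect_error(read_proximate_table(f), "crude_protein_pct")
})

test_that("diet reader requires an Unidentified row and a valid total", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_id,rf_pct", "a,60", "b,30"), f)
  expect_error(read_diet_table(f), "Unidentified")
  writeLines(c("food_id,rf_pct", "a,60", "b,20", "Unidentified,10"), f)
  expect_error(read_diet_table(f), "total 100")
})

test_that("diet tables round-trip through write/read to 1 dp", {
  for (nm in c("dhr_summer", "ksl_autumn")) {
    d <- bear_diet(nm)
    f <- withr::local_tempfile(fileext = ".csv")
    write_diet_table(d, f)
    d2 <- read_diet_table(f)
    expect_equal(d2$items$rf_pct, d$items$rf_pct)
    expect_equal(d2$items$food_id, d$items$food_id)
    expect_equal(d2$unidentified_rf_pct, d$unidentified_rf_pct)
    expect_equal(d2$study_area, d$study_area)
    expect_equal(d2$n_scats, d$n_scats)
  }
})

test_that("proximate tables round-trip through write/read", {
  x <- bear_proximate("ksl_summer")
  f <- withr::local_tempfile(fileext = ".csv")
  write_proximate_table(x, f)
  y <- read_proximate_table(f)
  expect_equal(y$available_carbohydrate_pct, x$available_carbohydrate_pct)
  expect_equal(y$food_id, x$food_id)
})

test_that("insect profiles carry the literature constants, renormalized", {
  ins <- bundled_insect_profiles()
  expect_named(ins, c("Ants", "Termites"))
  expect_equal(ins$Ants[["protein"]], 37.7, tolerance = 0.002)
  expect_equal(ins$Termites[["lipid"]], 55.9, tolerance = 0.002)
  expect_equal(unname(sum(ins$Ants)), 100, tolerance = 1e-12)
  expect_equal(unname(sum(ins$Termites)), 100, tolerance = 1e-12)
})

test_that("bear_profiles covers each diet and records the fern substitution", {
  for (nm in c("dhr_summer", "dhr_autumn", "ksl_summer", "ksl_autumn")) {
    d <- bear_diet(nm)
    pr <- bear_profiles(nm)
    expect_setequal(pr$food_id, d$items$food_id)
  }
  expect_equal(attr(bear_profiles("dhr_summer"), "substituted"),
               "Matteuccia struthiopteris")
  expect_length(attr(bear_profiles("ksl_summer"), "substituted"), 0)
})
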