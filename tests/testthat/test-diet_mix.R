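# RF%-weighted mixing, pooling and group summaries.

test_that("weights renormalize RF% over identified items", {
  w <- renormalized_weights(bear_diet("dhr_summer"))
  expect_equal(unname(sum(w)), 1, tolerance = 1e-12)
  expect_equal(w[["Arundinaria spp."]], 34.6 / 98.4, tolerance = 1e-12)
  # no unidentified material -> weights are rf/100
  d <- diet_composition(data.frame(food_id = c("a", "b"), rf_pct = c(70, 30)))
  expect_equal(unname(renormalized_weights(d)), c(0.7, 0.3))
  # a single identified food takes all the weight
  d1 <- diet_composition(data.frame(food_id = "a", rf_pct = 50),
                         unidentified_rf_pct = 50)
  expect_equal(unname(renormalized_weights(d1)), 1)
  # all-unidentified diet is undefined
  d0 <- diet_composition(data.frame(food_id = "a", rf_pct = 0),
                         unidentified_rf_pct = 100)
  expect_error(renormalized_weights(d0), "undefined")
})

test_that("mixing reproduces the four realized-niche diet points", {
  expected <- list(
    dhr_summer = c(24.1, 8.7, 67.2), dhr_autumn = c(21.1, 10.5, 68.4),
    ksl_summer = c(16.7, 8.2, 75.1), ksl_autumn = c(19.0, 11.0, 70.0))
  for (nm in names(expected)) {
    pt <- mix_diet(bear_diet(nm), bear_profiles(nm))
    expect_equal(unname(round(as.numeric(pt), 1)), expected[[nm]], info = nm)
  }
})

test_that("a single-food diet returns that food's profile; missing foods are named", {
  p <- macronutrient_profile(30, 20, 50)
  d <- diet_composition(data.frame(food_id = "only", rf_pct = 95),
                        unidentified_rf_pct = 5)
  expect_equal(as.numeric(mix_diet(d, list(only = p))), as.numeric(p))
  expect_error(mix_diet(d, list(other = p)), "only")
})

test_that("mixing is linear in the weight vector", {
  set.seed(21)
  profs <- rand_profile_list(5)
  m <- t(sapply(profs, as.numeric))
  for (i in 1:20) {
    w1 <- as.numeric(rmtniche:::.rdirichlet(1, rep(1, 5)))
    w2 <- as.numeric(rmtniche:::.rdirichlet(1, rep(1, 5)))
    a <- runif(1)
    mixw <- function(w) colSums(m * w)
    expect_equal(mixw(a * w1 + (1 - a) * w2),
                 a * mixw(w1) + (1 - a) * mixw(w2), tolerance = 1e-9)
  }
  # and the package's mixture is that same convex combination
  d <- diet_composition(data.frame(food_id = names(profs),
                                   rf_pct = c(30, 25, 20, 15, 10)))
  expect_equal(as.numeric(mix_diet(d, profs)),
               unname(colSums(m * c(30, 25, 20, 15, 10) / 100)),
               tolerance = 1e-9)
})

test_that("pooling is the unweighted mean and reproduces the overall diet", {
  pts <- lapply(c("dhr_summer", "dhr_autumn", "ksl_summer", "ksl_autumn"),
                function(nm) mix_diet(bear_diet(nm), bear_profiles(nm)))
  pool <- pooled_diet(pts)
  expect_equal(unname(round(as.numeric(pool), 1)), c(20.2, 9.6, 70.2))
  # idempotence and permutation invariance
  expect_equal(as.numeric(pooled_diet(pts[c(3, 1, 4, 2)])), as.numeric(pool))
  one <- pts[[1]]
  expect_equal(as.numeric(pooled_diet(list(one))), as.numeric(one))
  expect_equal(as.numeric(pooled_diet(list(one, one))), as.numeric(one))
  expect_error(pooled_diet(list()), "empty")
})

test_that("group summaries reproduce the seasonal/study-area table", {
  pts <- sapply(c("dhr_summer", "dhr_autumn", "ksl_summer", "ksl_autumn"),
                function(nm) mix_diet(bear_diet(nm), bear_profiles(nm)),
                simplify = FALSE)
  summer <- summarize_group(pts[c("dhr_summer", "ksl_summer")], "Summer", 118)
  expect_equal(round(summer$mean[summer$macronutrient == "protein"], 1), 20.4)
  expect_equal(round(summer$sd[summer$macronutrient == "protein"], 1), 5.3)
  expect_equal(round(summer$cv[summer$macronutrient == "protein"], 2), 0.26)
  dhr <- summarize_group(pts[c("dhr_summer", "dhr_autumn")], "DHR", 73)
  expect_lt(abs(dhr$sd[dhr$macronutrient == "protein"] - 2.14), 0.02)
  expect_lt(abs(dhr$sd[dhr$macronutrient == "lipid"] - 1.31), 0.02)
  # sample (n-1) denominator: two points a, b give |a-b|/sqrt(2)
  a <- pts$dhr_summer[["protein"]]; b <- pts$ksl_summer[["protein"]]
  expect_equal(summer$sd[summer$macronutrient == "protein"],
               abs(a - b) / sqrt(2), tolerance = 1e-12)
  # identical diets -> SD and CV are zero
  same <- summarize_group(list(pts[[1]], pts[[1]]), "same")
  expect_equal(same$sd, rep(0, 3))
  expect_equal(same$cv, rep(0, 3))
  # a single diet leaves SD/CV undefined
  single <- summarize_group(list(pts[[1]]), "one")
  expect_true(all(is.na(single$sd)))
  # permutation invariance
  swapped <- summarize_group(pts[c("ksl_summer", "dhr_summer")], "Summer")
  expect_equal(swapped$sd, summer$sd)
  expect_equal(swapped$mean, summer$mean)
})

test_that("category RF sums reproduce the crop comparison", {
  expect_equal(category_rf_sum(bear_diet("ksl_summer"), "Crop"), 20.0)
  expect_equal(category_rf_sum(bear_diet("dhr_summer"), "Crop"), 12.8)
  # explicit map: a known category with no members in the diet sums to 0
  d <- bear_diet("dhr_autumn")
  map <- c(setNames(rep("Other", nrow(d$items)), d$items$food_id),
           "Zea mays" = "Crop")
  expect_equal(category_rf_sum(d, "Crop", category_map = map), 0)
  expect_error(category_rf_sum(d, "Nonsense"), "unknown category")
})

test_that("diet points lie inside their food hulls", {
  for (nm in c("dhr_summer", "dhr_autumn", "ksl_summer", "ksl_autumn")) {
    profs <- bear_profiles(nm)
    hull <- niche_hull(to_rmt(profs), nm)
    dp <- to_rmt(mix_diet(bear_diet(nm), profs))
    expect_true(in_hull(dp$x, dp$y, hull$vertices$x, hull$vertices$y),
                info = nm)
    # adding the diet point to the cloud changes neither vertices nor area
    aug <- rbind(to_rmt(profs)[, c("x", "y")], dp[, c("x", "y")])
    expect_equal(niche_hull(aug)$area, hull$area, tolerance = 1e-9)
  }
})
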