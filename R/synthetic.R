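# Synthetic proximate/diet generator with known ground truth, so every
# pipeline stage is testable end to end.

# run code with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dirichlet sampler via normalized gammas
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate random food macronutrient profiles
#'
#' Samples `n` compositions from a Dirichlet law with the given
#' concentration triple (protein, lipid, carbohydrate) and scales them to
#' sum to 100. Large equal concentrations shrink profiles toward
#' (33.3, 33.3, 33.3); small ones spread them toward the simplex corners.
#'
#' @param n Number of profiles (>= 1).
#' @param concentration Positive Dirichlet concentration triple.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Named list of `n` [macronutrient_profile()] objects
#'   (`food_1` ... `food_n`).
#' @export
gen_food_profiles <- function(n, concentration = c(2, 2, 2), seed = NULL) {
  stopifnot(n >= 1)
  if (length(concentration) != 3 || any(!is.finite(concentration)) ||
      any(concentration <= 0))
    stop("concentration must be three positive numbers")
  m <- .with_seed(seed, .rdirichlet(n, concentration)) * 100
  out <- lapply(seq_len(n), function(i)
    macronutrient_profile(m[i, 1], m[i, 2], m[i, 3], normalize = TRUE))
  names(out) <- paste0("food_", seq_len(n))
  out
}

# largest-remainder rounding: round values to `digits` dp so they sum
# exactly to `total` (itself a multiple of 10^-digits)
largest_remainder_round <- function(values, total = 100, digits = 1) {
  m <- 10^digits
  scaled <- values * m
  fl <- floor(scaled)
  short <- round(total * m) - sum(fl)
  if (short > 0) {
    give <- order(scaled - fl, decreasing = TRUE)[seq_len(short)]
    fl[give] <- fl[give] + 1
  }
  fl / m
}

#' Generate a diet table with known truth point
#'
#' Draws Dirichlet mixing weights over the given food profiles, assigns a
#' fixed unidentified fraction, and emits a [diet_composition()] whose RF%
#' values are rounded to 1 dp with largest-remainder repair so the table
#' totals exactly 100 — the same invariant printed scat tables satisfy. The
#' truth diet point uses the unrounded weights, so [mix_diet()] on the
#' rounded table recovers it only up to the rounding bound (about 0.15 per
#' component for realistic tables).
#'
#' @param profiles Named list of [macronutrient_profile()] objects.
#' @param weight_concentration Positive scalar (or length-n vector)
#'   Dirichlet concentration for the weights.
#' @param unidentified_frac Fraction of RF in the unidentified row, in
#'   `[0, 0.2]`.
#' @param seed Optional integer seed.
#' @param study_area,season Labels for the generated group.
#' @return List with `diet` (a [diet_composition()]) and `truth`
#'   (a [macronutrient_profile()]).
#' @export
gen_diet_table <- function(profiles, weight_concentration = 1,
                           unidentified_frac = 0.05, seed = NULL,
                           study_area = "SYN", season = "any") {
  n <- length(profiles)
  stopifnot(n >= 1)
  if (unidentified_frac < 0 || unidentified_frac > 0.2)
    stop("unidentified_frac must be in [0, 0.2]")
  alpha <- rep_len(weight_concentration, n)
  if (any(alpha <= 0)) stop("weight_concentration must be positive")
  w <- as.numeric(.with_seed(seed, .rdirichlet(1, alpha)))
  truth <- colSums(.profile_matrix(profiles) * w)
  rf <- c(w * (100 - 100 * unidentified_frac), 100 * unidentified_frac)
  rf <- largest_remainder_round(rf, total = 100, digits = 1)
  diet <- diet_composition(
    items = data.frame(food_id = names(profiles), rf_pct = rf[seq_len(n)],
                       stringsAsFactors = FALSE),
    unidentified_rf_pct = rf[n + 1],
    study_area = study_area, season = season)
  list(diet = diet,
       truth = macronutrient_profile(truth[["protein"]], truth[["lipid"]],
                                     truth[["carbohydrate"]],
                                     normalize = TRUE))
}

#' Back-compute a proximate record from a target energy profile
#'
#' Inverse of [energy_profile()]: given a target energy-proportion profile
#' and a mass budget for the non-macronutrient components, solves for crude
#' protein, ether extract and available carbohydrate masses so that
#' converting the record recovers the profile exactly. The macronutrient
#' masses are proportional to (P/f_P, L/f_L, C/f_C) under the conversion
#' factors f and are scaled to fill `100 - moisture - ash - crude_fiber`.
#' The map is exact, so no randomness is involved.
#'
#' @param profile A [macronutrient_profile()].
#' @param moisture,ash,crude_fiber Mass percentages of the
#'   non-macronutrient components; must sum below 100.
#' @param food_id Label for the generated record.
#' @param conversion An [energy_conversion()] object.
#' @return One-row proximate table (data frame).
#' @export
gen_proximate_from_profile <- function(profile, moisture = 10, ash = 8,
                                       crude_fiber = 20, food_id = "synthetic",
                                       conversion = energy_conversion()) {
  stopifnot(inherits(profile, "macronutrient_profile"))
  budget <- 100 - moisture - ash - crude_fiber
  if (budget <= 0)
    stop("infeasible mass budget: moisture + ash + crude fiber >= 100")
  raw <- c(profile[["protein"]] / conversion$protein,
           profile[["lipid"]] / conversion$lipid,
           profile[["carbohydrate"]] / conversion$carbohydrate)
  mass <- budget * raw / sum(raw)
  validate_proximate(data.frame(
    food_id = food_id, ash_pct = ash, crude_protein_pct = mass[1],
    ether_extract_pct = mass[2], moisture_pct = moisture,
    crude_fiber_pct = crude_fiber, available_carbohydrate_pct = mass[3],
    stringsAsFactors = FALSE))
}

#' Generate a full synthetic scenario with ground truth
#'
#' One seeded draw of the whole pipeline's input: food profiles, a diet
#' table, and the derived truth (diet point and food-hull area). Regenerated
#' bit-identically from the same seed.
#'
#' @param seed Integer seed (required: scenarios are meant to be
#'   reproducible by construction).
#' @param n_foods Number of foods.
#' @param profile_concentration Dirichlet concentration triple for food
#'   profiles.
#' @param weight_concentration Dirichlet concentration for RF weights.
#' @param unidentified_frac Unidentified fraction in `[0, 0.2]`.
#' @param axes Axis pair for the truth hull (see [to_rmt()]).
#' @return Object of class `"rmt_scenario"`: list with `seed`, `profiles`,
#'   `diet`, `truth` (list: `point`, `hull_area`, `weights`).
#' @export
simulate_scenario <- function(seed, n_foods = 8,
                              profile_concentration = c(2, 2, 2),
                              weight_concentration = 1,
                              unidentified_frac = 0.05,
                              axes = c("carbohydrate", "protein")) {
  profiles <- gen_food_profiles(n_foods, profile_concentration, seed = seed)
  dt <- gen_diet_table(profiles, weight_concentration, unidentified_frac,
                       seed = seed + 1L)
  hull <- niche_hull(to_rmt(profiles, axes = axes), label = "synthetic")
  structure(list(seed = seed, profiles = profiles, diet = dt$diet,
                 truth = list(point = dt$truth, hull_area = hull$area,
                              weights = renormalized_weights(dt$diet))),
            class = "rmt_scenario")
}
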