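# RF%-weighted diet mixing: realized macronutrient niche points and group
# summaries.

#' Renormalized diet weights
#'
#' Mixing weights for the identified food items: each item's RF% divided by
#' the total identified RF%, so that weights sum to 1 after correcting for
#' unidentified material.
#'
#' @param diet A [diet_composition()] object.
#' @return Named numeric vector of weights summing to 1.
#' @examples
#' w <- renormalized_weights(bear_diet("dhr_summer"))
#' w[["Arundinaria spp."]]  # 34.6 / 98.4
#' @export
renormalized_weights <- function(diet) {
  stopifnot(inherits(diet, "diet_composition"))
  s <- sum(diet$items$rf_pct)
  if (s <= 0) stop("diet has no identified material; weights are undefined")
  stats::setNames(diet$items$rf_pct / s, diet$items$food_id)
}

#' Mix food profiles into a realized diet point
#'
#' The realized macronutrient niche of a group: the component-wise weighted
#' mean of its food profiles, weighted by RF% renormalized over identified
#' items ([renormalized_weights()]). Being a convex combination, the diet
#' point always lies inside the convex hull of its food profiles.
#'
#' @param diet A [diet_composition()] object.
#' @param profiles Profile table (data frame from [profile_table()]) or
#'   named list of [macronutrient_profile()] objects covering every
#'   identified food in `diet`.
#' @return A [macronutrient_profile()]: the diet point.
#' @examples
#' mix_diet(bear_diet("dhr_summer"), bear_profiles("dhr_summer"))  # 24.1P:8.7L:67.2C
#' @export
mix_diet <- function(diet, profiles) {
  w <- renormalized_weights(diet)
  m <- .profile_matrix(profiles)
  missing <- setdiff(names(w), rownames(m))
  if (length(missing))
    stop("no macronutrient profile for food(s): ",
         paste(missing, collapse = ", "))
  mixed <- colSums(m[names(w), , drop = FALSE] * w)
  macronutrient_profile(mixed[["protein"]], mixed[["lipid"]],
                        mixed[["carbohydrate"]], normalize = TRUE)
}

#' Pooled diet across groups
#'
#' Unweighted component-wise mean of several diet points, used to estimate
#' an overall diet across study areas and seasons. Scat counts are not used
#' as weights: each group's diet point counts equally.
#'
#' @param diets List of [macronutrient_profile()] objects (at least one).
#' @return A [macronutrient_profile()].
#' @export
pooled_diet <- function(diets) {
  if (!length(diets)) stop("cannot pool an empty list of diets")
  m <- .profile_matrix(diets)
  avg <- colMeans(m)
  macronutrient_profile(avg[["protein"]], avg[["lipid"]],
                        avg[["carbohydrate"]], normalize = TRUE)
}

#' Summarize a group of diet points
#'
#' Per-macronutrient mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation (CV = SD / mean) over a set of diet points,
#' computed from the unrounded profiles. With fewer than two diets the SD
#' and CV are undefined and reported as `NA`.
#'
#' @param diets List of [macronutrient_profile()] objects.
#' @param label Group label (e.g. `"Summer"`).
#' @param n_scats Total scat count behind the group (metadata only).
#' @return Data frame of class `"diet_summary"` with one row per
#'   macronutrient and columns `mean`, `sd`, `cv`.
#' @export
summarize_group <- function(diets, label = "", n_scats = NA_integer_) {
  if (!length(diets)) stop("cannot summarize an empty list of diets")
  m <- .profile_matrix(diets)
  mu <- colMeans(m)
  if (nrow(m) >= 2) {
    s <- apply(m, 2, stats::sd)
  } else {
    s <- rep(NA_real_, 3)
  }
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  out <- data.frame(macronutrient = c("protein", "lipid", "carbohydrate"),
                    mean = as.numeric(mu), sd = as.numeric(s),
                    cv = as.numeric(cv), stringsAsFactors = FALSE)
  attr(out, "label") <- label
  attr(out, "n_scats") <- n_scats
  class(out) <- c("diet_summary", class(out))
  out
}

#' @export
print.diet_summary <- function(x, ...) {
  cat(sprintf("Diet summary: %s (n = %s scats)\n", attr(x, "label"),
              ifelse(is.na(attr(x, "n_scats")), "?", attr(x, "n_scats"))))
  y <- as.data.frame(x)
  y$mean <- round_half_up(y$mean, 1)
  y$sd <- round_half_up(y$sd, 2)
  y$cv <- round_half_up(y$cv, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Sum of RF% over a food category
#'
#' Total uncorrected RF% of the diet items assigned to a category (e.g.
#' `"Crop"`, `"Hard mast"`). By default categories come from the diet
#' table's own `category` column; an explicit `category_map`
#' (food_id -> category) overrides it.
#'
#' @param diet A [diet_composition()] object.
#' @param category Category label to sum.
#' @param category_map Optional named character vector mapping `food_id` to
#'   category.
#' @return Numeric: summed RF% (0 if the category exists but no diet item
#'   belongs to it).
#' @examples
#' category_rf_sum(bear_diet("ksl_summer"), "Crop")  # 20.0
#' @export
category_rf_sum <- function(diet, category, category_map = NULL) {
  stopifnot(inherits(diet, "diet_composition"))
  if (is.null(category_map)) {
    if (!"category" %in% names(diet$items))
      stop("diet has no 'category' column and no category_map was given")
    cats <- diet$items$category
    known <- unique(cats)
  } else {
    cats <- unname(category_map[diet$items$food_id])
    known <- unique(category_map)
  }
  if (!category %in% known)
    stop("unknown category: '", category, "'")
  sum(diet$items$rf_pct[!is.na(cats) & cats == category])
}
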