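# Core domain objects: macronutrient profiles, energy conversion factors,
# diet compositions, and proximate-table validation.

#' Macronutrient profile
#'
#' A three-part composition giving protein, lipid and carbohydrate as
#' percentages of total macronutrient-derived metabolizable energy (ME).
#' This is the coordinate object of the right-angled mixture triangle:
#' components are non-negative and sum to 100.
#'
#' @param protein,lipid,carbohydrate Percent of macronutrient ME; each >= 0.
#' @param normalize If `TRUE`, rescale the triple to sum exactly 100 (useful
#'   for literature values printed with rounding, whose sum may be 99.9 or
#'   100.1). If `FALSE` (default), a sum differing from 100 by more than
#'   `1e-9` is an error.
#' @return A named numeric vector of class `"macronutrient_profile"` with
#'   components `protein`, `lipid`, `carbohydrate`.
#' @examples
#' macronutrient_profile(25, 0, 75)
#' macronutrient_profile(37.7, 45.8, 16.4, normalize = TRUE)  # sums to 99.9
#' @export
macronutrient_profile <- function(protein, lipid, carbohydrate,
                                  normalize = FALSE) {
  p <- c(protein = as.numeric(protein), lipid = as.numeric(lipid),
         carbohydrate = as.numeric(carbohydrate))
  if (anyNA(p)) stop("profile components must be non-missing numbers")
  if (any(p < 0)) stop("profile components must be >= 0")
  s <- sum(p)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero profile")
    p <- 100 * p / s
  } else if (abs(s - 100) > 1e-9) {
    stop(sprintf("profile components must sum to 100 (got %.6f); use normalize = TRUE for rounded inputs", s))
  }
  structure(p, class = "macronutrient_profile")
}

#' @export
print.macronutrient_profile <- function(x, digits = 1, ...) {
  cat(sprintf("%sP:%sL:%sC (%% of macronutrient ME)\n",
              format(round_half_up(x[["protein"]], digits)),
              format(round_half_up(x[["lipid"]], digits)),
              format(round_half_up(x[["carbohydrate"]], digits))))
  invisible(x)
}

#' Metabolizable-energy conversion factors
#'
#' Standard factors used to put the three macronutrients on a common energy
#' scale: 4 kcal/g for protein and carbohydrate, 9 kcal/g for lipid. Other
#' factor sets (e.g. digestibility-corrected) can be supplied.
#'
#' @param protein,lipid,carbohydrate kcal per gram; each > 0.
#' @return A list of class `"energy_conversion"`.
#' @examples
#' energy_conversion()            # 4/9/4
#' energy_conversion(lipid = 4)   # deliberately wrong factors, for sanity checks
#' @export
energy_conversion <- function(protein = 4, lipid = 9, carbohydrate = 4) {
  conv <- list(protein = as.numeric(protein), lipid = as.numeric(lipid),
               carbohydrate = as.numeric(carbohydrate))
  if (any(unlist(conv) <= 0) || anyNA(unlist(conv)))
    stop("energy conversion factors must be positive numbers")
  structure(conv, class = "energy_conversion")
}

#' Diet composition from scat relative frequencies
#'
#' One study-area/season diet: identified food items with their percent
#' relative frequency (RF%) in pooled scat analysis, plus the RF% of
#' unidentified material held separately. Identified plus unidentified RF%
#' must total 100 within 0.1 (printed tables are rounded to 1 dp).
#'
#' @param items Data frame with columns `food_id` and `rf_pct` (an optional
#'   `category` column is kept and used by [category_rf_sum()]).
#' @param unidentified_rf_pct RF% of unidentified material.
#' @param study_area,season Group labels.
#' @param n_scats Number of scats pooled into the table (metadata only; the
#'   RF% values are already pooled).
#' @return An object of class `"diet_composition"`.
#' @export
diet_composition <- function(items, unidentified_rf_pct = 0,
                             study_area = NA_character_,
                             season = NA_character_, n_scats = NA_integer_) {
  items <- as.data.frame(items)
  if (!all(c("food_id", "rf_pct") %in% names(items)))
    stop("items must have columns 'food_id' and 'rf_pct'")
  items$rf_pct <- as.numeric(items$rf_pct)
  if (anyNA(items$rf_pct) || any(items$rf_pct < 0))
    stop("rf_pct must be non-negative and non-missing")
  if (anyDuplicated(items$food_id))
    stop("duplicate food_id in diet items: ",
         paste(unique(items$food_id[duplicated(items$food_id)]), collapse = ", "))
  total <- sum(items$rf_pct) + unidentified_rf_pct
  if (abs(total - 100) > 0.1)
    stop(sprintf("identified + unidentified RF%% must total 100 +/- 0.1 (got %.2f)", total))
  structure(list(items = items, unidentified_rf_pct = unidentified_rf_pct,
                 study_area = study_area, season = season,
                 n_scats = n_scats),
            class = "diet_composition")
}

#' @export
print.diet_composition <- function(x, ...) {
  cat(sprintf("Diet composition: %s %s (%d identified foods, %.1f%% unidentified, n = %s scats)\n",
              x$study_area, x$season, nrow(x$items), x$unidentified_rf_pct,
              ifelse(is.na(x$n_scats), "?", x$n_scats)))
  print(x$items[, intersect(c("food_id", "category", "rf_pct"), names(x$items))],
        row.names = FALSE)
  invisible(x)
}

# columns every proximate table must carry
.proximate_components <- c("ash_pct", "crude_protein_pct", "ether_extract_pct",
                           "moisture_pct", "crude_fiber_pct")

#' Validate a proximate composition table
#'
#' Checks the schema and value ranges of a proximate table: one row per food
#' with ash, crude protein (CP), ether extract (EE), moisture and crude
#' fiber (CF) as percent of sample mass, plus available carbohydrate (AC),
#' which may be missing (`NA`) and later computed by difference. When AC is
#' present, the six components must sum to 100 within 0.1 (tables are
#' printed to 2 dp).
#'
#' @param x Data frame of proximate records.
#' @return `x` invisibly, with class `"proximate_table"` prepended.
#' @export
validate_proximate <- function(x) {
  x <- as.data.frame(x)
  required <- c("food_id", .proximate_components)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("proximate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"available_carbohydrate_pct" %in% names(x))
    x$available_carbohydrate_pct <- rep(NA_real_, nrow(x))
  num_cols <- c(.proximate_components, "available_carbohydrate_pct")
  for (col in num_cols) {
    v <- as.numeric(x[[col]])
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad))
      stop(sprintf("invalid value in column '%s', row %d (food '%s'): %g",
                   col, bad[1], x$food_id[bad[1]], v[bad[1]]))
    x[[col]] <- v
  }
  has_ac <- !is.na(x$available_carbohydrate_pct)
  if (any(has_ac)) {
    tot <- rowSums(x[has_ac, num_cols, drop = FALSE])
    off <- which(abs(tot - 100) > 0.1)
    if (length(off)) {
      i <- which(has_ac)[off[1]]
      stop(sprintf("proximate components of food '%s' sum to %.2f, outside 100 +/- 0.1",
                   x$food_id[i], tot[off[1]]))
    }
  }
  if (!inherits(x, "proximate_table")) class(x) <- c("proximate_table", class(x))
  invisible(x)
}

# round half away from zero, the convention of the printed tables
# (base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
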