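# Proximate composition -> metabolizable-energy macronutrient profiles.

#' Available carbohydrate by difference
#'
#' The standard proximate-analysis estimate of digestible carbohydrate:
#' 100% minus ash, crude protein, ether extract, moisture and crude fiber,
#' floored at zero. Values within rounding slack of zero (components summing
#' to at most 100.1) are tolerated; components summing beyond that indicate
#' an inconsistent record and raise an error.
#'
#' @param x A proximate table (data frame with the five non-AC component
#'   columns); all rows are processed.
#' @return Numeric vector of available carbohydrate, percent of sample mass.
#' @examples
#' rec <- data.frame(food_id = "m", ash_pct = 3.65, crude_protein_pct = 8.05,
#'                   ether_extract_pct = 2.82, moisture_pct = 7.58,
#'                   crude_fiber_pct = 2.44)
#' available_carbohydrate(rec)  # 75.46
#' @export
available_carbohydrate <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(.proximate_components, names(x))
  if (length(missing_cols))
    stop("missing component column(s): ", paste(missing_cols, collapse = ", "))
  comp <- rowSums(x[, .proximate_components, drop = FALSE])
  over <- which(comp > 100.1)
  if (length(over))
    stop(sprintf("non-AC components of row %d ('%s') sum to %.2f > 100.1",
                 over[1], x$food_id[over[1]], comp[over[1]]))
  pmax(100 - comp, 0)
}

# energy shares for vectors of CP/EE/AC mass percentages; rows sum to 100
.energy_shares <- function(cp, ee, ac, conversion) {
  kcal <- cbind(protein = conversion$protein * cp,
                lipid = conversion$lipid * ee,
                carbohydrate = conversion$carbohydrate * ac)
  total <- rowSums(kcal)
  if (any(total <= 0))
    stop("undefined profile: total macronutrient energy is zero")
  100 * kcal / total
}

#' Convert a proximate record to an energy-proportion profile
#'
#' Expresses crude protein, ether extract (lipid) and available carbohydrate
#' as percentages of total macronutrient-derived metabolizable energy, using
#' the conversion factors in `conversion` (default 4/9/4 kcal/g). Crude
#' fiber, ash and moisture contribute no macronutrient energy. The result is
#' invariant to rescaling all three masses by a common factor.
#'
#' @param crude_protein,ether_extract,carbohydrate Mass percentages (each
#'   >= 0, at least one > 0). `crude_protein` may instead be a one-row
#'   proximate table, in which case the other two arguments are taken from
#'   its columns (AC computed by difference if missing).
#' @param conversion An [energy_conversion()] object.
#' @return A [macronutrient_profile()].
#' @examples
#' energy_profile(20.31, 1.66, 25.48)   # DHR summer bamboo: 41.0P
#' energy_profile(8.24, 1.40, 24.87)    # KSL summer bamboo: 22.7P
#' @export
energy_profile <- function(crude_protein, ether_extract, carbohydrate,
                           conversion = energy_conversion()) {
  if (is.data.frame(crude_protein)) {
    rec <- crude_protein
    if (nrow(rec) != 1) stop("expected a single proximate record")
    ac <- rec$available_carbohydrate_pct
    if (is.null(ac) || is.na(ac)) ac <- available_carbohydrate(rec)
    crude_protein <- rec$crude_protein_pct
    ether_extract <- rec$ether_extract_pct
    carbohydrate <- ac
  }
  if (any(c(crude_protein, ether_extract, carbohydrate) < 0))
    stop("macronutrient masses must be >= 0")
  sh <- .energy_shares(crude_protein, ether_extract, carbohydrate, conversion)
  macronutrient_profile(sh[1, "protein"], sh[1, "lipid"],
                        sh[1, "carbohydrate"], normalize = TRUE)
}

#' Profile table: convert many foods, merge insect constants
#'
#' Converts every row of a proximate table with [energy_profile()] and
#' appends pass-through energy-proportion profiles (typically the literature
#' insect constants) that have no proximate record. Rows with missing
#' available carbohydrate get it filled by difference first.
#'
#' @param proximate A proximate table (data frame); may have zero rows.
#' @param insects Named list of [macronutrient_profile()] objects to append,
#'   keyed by `food_id`.
#' @param conversion An [energy_conversion()] object.
#' @return Data frame with columns `food_id`, `protein_pct`, `lipid_pct`,
#'   `carbohydrate_pct`; one row per food; profiles unrounded.
#' @export
profile_table <- function(proximate, insects = NULL,
                          conversion = energy_conversion()) {
  out_list <- list()
  if (!is.null(proximate) && nrow(as.data.frame(proximate)) > 0) {
    x <- validate_proximate(proximate)
    na_ac <- is.na(x$available_carbohydrate_pct)
    if (any(na_ac))
      x$available_carbohydrate_pct[na_ac] <-
        available_carbohydrate(x[na_ac, , drop = FALSE])
    sh <- .energy_shares(x$crude_protein_pct, x$ether_extract_pct,
                         x$available_carbohydrate_pct, conversion)
    out_list$plants <- data.frame(food_id = x$food_id,
                                  protein_pct = sh[, "protein"],
                                  lipid_pct = sh[, "lipid"],
                                  carbohydrate_pct = sh[, "carbohydrate"],
                                  stringsAsFactors = FALSE)
  }
  if (length(insects)) {
    out_list$insects <- data.frame(
      food_id = names(insects),
      protein_pct = vapply(insects, `[[`, numeric(1), "protein"),
      lipid_pct = vapply(insects, `[[`, numeric(1), "lipid"),
      carbohydrate_pct = vapply(insects, `[[`, numeric(1), "carbohydrate"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out_list)
  if (is.null(out))
    out <- data.frame(food_id = character(0), protein_pct = numeric(0),
                      lipid_pct = numeric(0), carbohydrate_pct = numeric(0))
  rownames(out) <- NULL
  dup <- out$food_id[duplicated(out$food_id)]
  if (length(dup))
    stop("duplicate food_id in profile table: ",
         paste(unique(dup), collapse = ", "))
  out
}

# pull one food's profile object out of a profile table or named list
.lookup_profile <- function(profiles, food_id) {
  if (is.data.frame(profiles)) {
    i <- match(food_id, profiles$food_id)
    if (is.na(i)) return(NULL)
    macronutrient_profile(profiles$protein_pct[i], profiles$lipid_pct[i],
                          profiles$carbohydrate_pct[i], normalize = TRUE)
  } else {
    profiles[[food_id]]
  }
}

# profile table / named list -> matrix with rownames = food_id,
# columns protein/lipid/carbohydrate
.profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    m <- as.matrix(profiles[, c("protein_pct", "lipid_pct", "carbohydrate_pct")])
    colnames(m) <- c("protein", "lipid", "carbohydrate")
    rownames(m) <- profiles$food_id
  } else {
    m <- do.call(rbind, lapply(profiles, function(p)
      c(protein = p[["protein"]], lipid = p[["lipid"]],
        carbohydrate = p[["carbohydrate"]])))
    rownames(m) <- names(profiles)
  }
  m
}
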