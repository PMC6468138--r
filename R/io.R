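# Delimited-table readers/writers and the bundled Nepal black-bear dataset.

#' Read a proximate composition table
#'
#' Reads a comma-separated table with one row per food and the six proximate
#' columns (`ash_pct`, `crude_protein_pct`, `ether_extract_pct`,
#' `moisture_pct`, `crude_fiber_pct`, `available_carbohydrate_pct`) plus a
#' `food_id` key. `available_carbohydrate_pct` may be absent or `NA`; such
#' rows are flagged in the `ac_missing` attribute and AC can be filled by
#' [available_carbohydrate()].
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of class `"proximate_table"`.
#' @seealso [bear_proximate()] for the bundled tables.
#' @export
read_proximate_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  x <- validate_proximate(x)
  attr(x, "ac_missing") <- is.na(x$available_carbohydrate_pct)
  x
}

#' Write a proximate composition table
#'
#' @param x A proximate table (validated data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_proximate_table <- function(x, path) {
  x <- validate_proximate(x)
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a diet (RF%) table
#'
#' Reads a comma-separated diet table with columns `food_id` and `rf_pct`
#' (optionally `category`, `study_area`, `season`, `n_scats`). The table
#' must contain a row whose `food_id` is `"Unidentified"`; its RF% is stored
#' separately from the identified items, and the grand total is validated
#' against 100 +/- 0.1.
#'
#' @param path Path to a CSV file.
#' @return A [diet_composition()] object.
#' @seealso [bear_diet()] for the bundled tables.
#' @export
read_diet_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("food_id", "rf_pct") %in% names(x)))
    stop("diet table is missing column(s): ",
         paste(setdiff(c("food_id", "rf_pct"), names(x)), collapse = ", "))
  unid <- x$food_id == "Unidentified"
  if (!any(unid))
    stop("diet table must contain an 'Unidentified' row (use rf_pct 0 if none)")
  meta <- function(col, default) if (col %in% names(x)) x[[col]][1] else default
  diet_composition(
    items = x[!unid, setdiff(names(x), c("study_area", "season", "n_scats")),
              drop = FALSE],
    unidentified_rf_pct = sum(as.numeric(x$rf_pct[unid])),
    study_area = meta("study_area", NA_character_),
    season = meta("season", NA_character_),
    n_scats = as.integer(meta("n_scats", NA))
  )
}

#' Write a diet (RF%) table
#'
#' Inverse of [read_diet_table()]: emits the identified items plus an
#' `Unidentified` row so that the file round-trips.
#'
#' @param diet A [diet_composition()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diet_table <- function(diet, path) {
  stopifnot(inherits(diet, "diet_composition"))
  items <- diet$items
  unid <- items[0, , drop = FALSE]
  unid[1, "food_id"] <- "Unidentified"
  unid[1, "rf_pct"] <- diet$unidentified_rf_pct
  out <- rbind(items, unid)
  out$study_area <- diet$study_area
  out$season <- diet$season
  out$n_scats <- diet$n_scats
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.fixture_names <- c("dhr_summer", "dhr_autumn", "ksl_summer", "ksl_autumn")

.fixture_path <- function(name, kind = c("diet", "proximate")) {
  kind <- match.arg(kind)
  name <- match.arg(tolower(name), .fixture_names)
  system.file("extdata", paste0(name, "_", kind, ".csv"),
              package = "rmtniche", mustWork = TRUE)
}

#' Bundled Asiatic black bear diet tables (Nepal)
#'
#' Scat-based percent relative frequency (RF%) diet tables for Asiatic black
#' bear in two Nepalese study areas — the Dhorpatan Hunting Reserve (DHR)
#' and the Kailash Sacred Landscape (KSL) — in summer and autumn.
#'
#' @param name One of `"dhr_summer"`, `"dhr_autumn"`, `"ksl_summer"`,
#'   `"ksl_autumn"`.
#' @return A [diet_composition()] object.
#' @examples
#' bear_diet("dhr_summer")
#' @export
bear_diet <- function(name) read_diet_table(.fixture_path(name, "diet"))

#' Bundled proximate composition tables (Nepal bear foods)
#'
#' Proximate analyses (ash, crude protein, ether extract, moisture, crude
#' fiber, available carbohydrate by difference; percent of sample mass) of
#' the plant foods in the bundled bear diets, one composite record per food
#' and study-area/season. The `source` column marks values taken from the
#' literature rather than assayed composites. Insects (ants, termites) were
#' not assayed; see [bundled_insect_profiles()].
#'
#' @inheritParams bear_diet
#' @return A data frame of class `"proximate_table"`.
#' @examples
#' bear_proximate("ksl_autumn")
#' @export
bear_proximate <- function(name) read_proximate_table(.fixture_path(name, "proximate"))

#' Literature macronutrient profiles for insect foods
#'
#' Energy-proportion macronutrient profiles for the two insect foods (ants,
#' Formicidae; termites, Blattodea) found in the DHR diets, taken from
#' published averages rather than proximate assay. The printed triplets
#' (37.7P:45.8L:16.4C and 26.8P:55.9L:17.3C) are renormalized to sum exactly
#' 100.
#'
#' @return Named list of two [macronutrient_profile()] objects, `Ants` and
#'   `Termites`.
#' @export
bundled_insect_profiles <- function() {
  list(
    Ants     = macronutrient_profile(37.7, 45.8, 16.4, normalize = TRUE),
    Termites = macronutrient_profile(26.8, 55.9, 17.3, normalize = TRUE)
  )
}

#' Macronutrient profile table for a bundled diet
#'
#' Assembles the energy-proportion profile of every identified food in a
#' bundled diet: plant foods are converted from their proximate records via
#' [profile_table()], and insect foods take the literature constants of
#' [bundled_insect_profiles()]. The DHR-summer fern (*Matteuccia
#' struthiopteris*) has no DHR proximate record and is substituted with the
#' KSL-summer record of the same species; the substitution is recorded in
#' the `substituted` attribute.
#'
#' @inheritParams bear_diet
#' @param conversion An [energy_conversion()] object.
#' @return Data frame with columns `food_id`, `protein_pct`, `lipid_pct`,
#'   `carbohydrate_pct`, covering exactly the identified foods of the diet.
#' @examples
#' bear_profiles("dhr_summer")
#' @export
bear_profiles <- function(name, conversion = energy_conversion()) {
  name <- match.arg(tolower(name), .fixture_names)
  diet <- bear_diet(name)
  prox <- bear_proximate(name)
  substituted <- character(0)
  if (name == "dhr_summer") {
    fern <- bear_proximate("ksl_summer")
    fern <- fern[fern$food_id == "Matteuccia struthiopteris", , drop = FALSE]
    prox <- validate_proximate(rbind(as.data.frame(unclass(prox)),
                                     as.data.frame(unclass(fern))))
    substituted <- "Matteuccia struthiopteris"
  }
  profs <- profile_table(prox, insects = bundled_insect_profiles(),
                         conversion = conversion)
  profs <- profs[profs$food_id %in% diet$items$food_id, , drop = FALSE]
  missing <- setdiff(diet$items$food_id, profs$food_id)
  if (length(missing))
    stop("no profile for diet food(s): ", paste(missing, collapse = ", "))
  rownames(profs) <- NULL
  attr(profs, "substituted") <- substituted
  profs
}

#' Write a flat key-value results file
#'
#' Emits `key<TAB>value` lines, one per result, for machine consumption.
#'
#' @param values Named list or vector of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(values, path) {
  stopifnot(length(names(values)) == length(values))
  lines <- vapply(seq_along(values), function(i)
    paste(names(values)[i], format(values[[i]], digits = 15), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value results file written by [write_results()]
#'
#' @param path Path to the file.
#' @return Named list of values (numeric where possible).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) p[2] else v
  })
  names(vals) <- vapply(parts, `[`, character(1), 1)
  vals
}
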