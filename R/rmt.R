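# Right-angled mixture triangle geometry: projection, convex hulls,
# polygon areas, niche-breadth ratios.

.macros <- c("protein", "lipid", "carbohydrate")

# accept full names or single-letter P/L/C axis labels
.match_axis <- function(a) {
  a <- tolower(a)
  full <- c(p = "protein", l = "lipid", c = "carbohydrate")
  if (a %in% names(full)) return(unname(full[a]))
  match.arg(a, .macros)
}

#' Project profiles into the right-angled mixture triangle
#'
#' A three-part composition (P + L + C = 100) is plotted in 2D by taking two
#' components as explicit x and y axes; the third is implicit as
#' 100 - x - y. Convex-hull areas, and therefore breadth ratios, do not
#' depend on which pair is explicit (each axis choice projects the simplex
#' plane with the same area scaling), so the choice is cosmetic.
#'
#' @param profiles A single [macronutrient_profile()], a named list of them,
#'   or a profile table data frame from [profile_table()].
#' @param axes Character vector of two distinct macronutrients for the
#'   (x, y) axes; full names or single letters `"P"`, `"L"`, `"C"`. Default
#'   x = carbohydrate, y = protein (lipid implicit).
#' @return Data frame with columns `food_id`, `x`, `y`, `implicit` and an
#'   `axes` attribute.
#' @examples
#' to_rmt(macronutrient_profile(41, 7.5, 51.5), axes = c("C", "P"))
#' @export
to_rmt <- function(profiles, axes = c("carbohydrate", "protein")) {
  if (length(axes) != 2) stop("axes must name exactly two macronutrients")
  axes <- vapply(axes, .match_axis, character(1), USE.NAMES = FALSE)
  if (axes[1] == axes[2]) stop("axes must be two distinct macronutrients")
  implicit <- setdiff(.macros, axes)
  if (inherits(profiles, "macronutrient_profile")) profiles <- list(profiles)
  m <- .profile_matrix(profiles)
  out <- data.frame(
    food_id = if (is.null(rownames(m))) paste0("p", seq_len(nrow(m))) else rownames(m),
    x = m[, axes[1]], y = m[, axes[2]], implicit = m[, implicit],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "axes") <- c(x = axes[1], y = axes[2], implicit = implicit)
  out
}

# 2D cross product of (b - a) x (c - a); > 0 means a counter-clockwise turn
.cross2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Andrew's monotone chain on point matrix; returns indices of hull vertices
# in counter-clockwise order starting at the lexicographic minimum.
# Collinear points interior to an edge are dropped (minimal vertex set).
.monotone_chain <- function(x, y) {
  ord <- order(x, y)
  ux <- x[ord]; uy <- y[ord]
  keep <- !duplicated(cbind(ux, uy))
  ord <- ord[keep]; ux <- ux[keep]; uy <- uy[keep]
  n <- length(ord)
  if (n <= 2) return(ord)
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        if (.cross2(x[a], y[a], x[b], y[b], x[i], y[i]) <= 0)
          h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(ord)
  upper <- build(rev(ord))
  c(lower[-length(lower)], upper[-length(upper)])
}

#' Shoelace polygon area
#'
#' Area of a simple polygon from its ordered vertices via the shoelace
#' (surveyor's) formula. Units are the squared units of the coordinates
#' (percent-squared for RMT points).
#'
#' @param x,y Vertex coordinates in boundary order.
#' @return Non-negative area; 0 for fewer than three vertices.
#' @export
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex hull of RMT points (macronutrient niche hull)
#'
#' Builds the convex hull of a set of food points in the right-angled
#' mixture triangle using Andrew's monotone chain. The vertex list is the
#' minimal set (points interior to an edge are excluded), ordered
#' counter-clockwise starting at the lexicographically smallest vertex, so
#' output is deterministic. Fewer than three distinct points, or all points
#' collinear, give a degenerate hull with area 0 and `degenerate = TRUE`.
#'
#' @param points Data frame with columns `x` and `y` (as from [to_rmt()]).
#' @param label Hull label (e.g. `"DHR summer"`).
#' @return Object of class `"niche_hull"`: list with `label`, `vertices`
#'   (data frame), `area`, `n_points`, `degenerate`.
#' @examples
#' pts <- to_rmt(bear_profiles("dhr_summer"))
#' niche_hull(pts, "DHR summer")
#' @export
niche_hull <- function(points, label = "") {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  if (anyNA(x) || anyNA(y)) stop("hull points must be non-missing")
  idx <- .monotone_chain(x, y)
  verts <- points[idx, , drop = FALSE]
  rownames(verts) <- NULL
  area <- shoelace_area(x[idx], y[idx])
  structure(list(label = label, vertices = verts, area = area,
                 n_points = nrow(points),
                 degenerate = length(idx) < 3 || area <= 0),
            class = "niche_hull")
}

#' @export
print.niche_hull <- function(x, ...) {
  cat(sprintf("Niche hull '%s': %d vertices from %d points, area %.2f%s\n",
              x$label, nrow(x$vertices), x$n_points, x$area,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Area of a niche hull
#'
#' Recomputes the shoelace area over the hull's ordered vertices
#' (0 for degenerate hulls).
#'
#' @param hull A [niche_hull()] object.
#' @return Non-negative area in percent-squared units.
#' @export
hull_area <- function(hull) {
  stopifnot(inherits(hull, "niche_hull"))
  if (hull$degenerate) return(0)
  shoelace_area(hull$vertices$x, hull$vertices$y)
}

#' Niche-breadth ratio between two hulls
#'
#' Relative effect size of macronutrient niche breadth: the larger hull area
#' divided by the smaller, together with which group is larger.
#'
#' @param hull_a,hull_b [niche_hull()] objects with positive area.
#' @return List with `ratio` (>= 1) and `larger` (label of the larger hull).
#' @examples
#' h1 <- niche_hull(to_rmt(bear_profiles("dhr_summer")), "DHR summer")
#' h2 <- niche_hull(to_rmt(bear_profiles("ksl_summer")), "KSL summer")
#' breadth_ratio(h1, h2)  # ~3.1, larger DHR
#' @export
breadth_ratio <- function(hull_a, hull_b) {
  stopifnot(inherits(hull_a, "niche_hull"), inherits(hull_b, "niche_hull"))
  a <- hull_area(hull_a); b <- hull_area(hull_b)
  if (a <= 0 || b <= 0)
    stop("breadth ratio undefined for zero-area (degenerate) hulls")
  if (a >= b) list(ratio = a / b, larger = hull_a$label)
  else list(ratio = b / a, larger = hull_b$label)
}
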