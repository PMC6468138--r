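# Independent oracles and small generators shared across tests.

# random valid macronutrient profiles (rows sum to 100)
rand_profile_matrix <- function(n, alpha = c(1, 1, 1)) {
  g <- matrix(rgamma(n * 3, shape = alpha), nrow = n, byrow = TRUE)
  m <- 100 * g / rowSums(g)
  colnames(m) <- c("protein", "lipid", "carbohydrate")
  m
}

rand_profile_list <- function(n, alpha = c(1, 1, 1)) {
  m <- rand_profile_matrix(n, alpha)
  out <- lapply(seq_len(n), function(i)
    macronutrient_profile(m[i, 1], m[i, 2], m[i, 3], normalize = TRUE))
  names(out) <- paste0("food_", seq_len(n))
  out
}

# non-strict point-in-triangle test via sign of cross products
in_triangle <- function(px, py, ax, ay, bx, by, cx, cy) {
  s1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  s2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
  s3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
  (s1 >= -1e-12 & s2 >= -1e-12 & s3 >= -1e-12) |
    (s1 <= 1e-12 & s2 <= 1e-12 & s3 <= 1e-12)
}

# brute-force extremality: a point is a hull vertex iff it lies in no
# triangle formed by three other points (Caratheodory in 2D); O(n^4),
# for small point sets only
brute_hull_vertices <- function(x, y) {
  n <- length(x)
  extreme <- logical(n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    inside <- FALSE
    if (length(others) >= 3) {
      combs <- combn(others, 3)
      for (k in seq_len(ncol(combs))) {
        i <- combs[1, k]; j <- combs[2, k]; l <- combs[3, k]
        if (in_triangle(x[p], y[p], x[i], y[i], x[j], y[j], x[l], y[l])) {
          inside <- TRUE; break
        }
      }
    }
    extreme[p] <- !inside
  }
  which(extreme)
}

# fan-triangulation area of a convex polygon given ordered vertices
fan_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  tri <- function(i, j) abs((x[i] - x[1]) * (y[j] - y[1]) -
                            (y[i] - y[1]) * (x[j] - x[1])) / 2
  sum(vapply(2:(n - 1), function(i) tri(i, i + 1), numeric(1)))
}

# point-in-convex-polygon (non-strict), vertices in CCW order
in_hull <- function(px, py, hx, hy) {
  n <- length(hx)
  j <- c(2:n, 1)
  all((hx[j] - hx) * (py - hy) - (hy[j] - hy) * (px - hx) >= -1e-9)
}
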