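# Independent oracles used across tests. These deliberately avoid the
# package's own geometry code paths: hulls via gift wrapping (not chull),
# hull rasterization via triangle-area decomposition (not half-plane signs),
# and pixel sets as explicit (row, col) coordinate tables.

# pixel coordinate table of a filled disk, by exhaustive enumeration
oracle_disk_coords <- function(cr, cc, rad) {
  rows <- floor(cr - rad):ceiling(cr + rad)
  cols <- floor(cc - rad):ceiling(cc + rad)
  out <- expand.grid(row = rows, col = cols)
  out[(out$row - cr)^2 + (out$col - cc)^2 <= rad^2, ]
}

coords_to_idx <- function(coords, dm) (coords$col - 1L) * dm[1L] + coords$row

mask_from_coords <- function(coords, dm, label = 1L) {
  m <- matrix(0L, dm[1L], dm[2L])
  m[coords_to_idx(coords, dm)] <- label
  m
}

# gift-wrapping (Jarvis march) convex hull of points given as a 2-col matrix
oracle_jarvis_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  start <- which.min(pts[, 1L] + pts[, 2L] * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (p == start && length(hull) > 1L) integer(0) else seq_len(n)
    best <- NA_integer_
    for (q in setdiff(seq_len(n), p)) {
      if (is.na(best)) { best <- q; next }
      cr <- (pts[q, 1L] - pts[p, 1L]) * (pts[best, 2L] - pts[p, 2L]) -
            (pts[q, 2L] - pts[p, 2L]) * (pts[best, 1L] - pts[p, 1L])
      if (cr > 0 ||
          (cr == 0 && sum((pts[q, ] - pts[p, ])^2) > sum((pts[best, ] - pts[p, ])^2)))
        best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("hull did not close")
  }
  pts[hull, , drop = FALSE]
}

# point-in-convex-polygon by triangle-area decomposition: p is inside (or on
# the boundary) iff the triangle fan areas from p sum to the polygon area
oracle_in_hull <- function(p, hull) {
  nv <- nrow(hull)
  jj <- c(2:nv, 1L)
  poly2 <- abs(sum(hull[, 1L] * hull[jj, 2L] - hull[jj, 1L] * hull[, 2L]))
  fan2 <- 0
  for (i in seq_len(nv)) {
    j <- jj[i]
    fan2 <- fan2 + abs((hull[i, 1L] - p[1L]) * (hull[j, 2L] - p[2L]) -
                       (hull[j, 1L] - p[1L]) * (hull[i, 2L] - p[2L]))
  }
  abs(fan2 - poly2) < 1e-6
}

# brute-force solidity deficit of a pixel set given as coordinates
oracle_solidity_deficit <- function(coords) {
  pts <- as.matrix(coords)
  hull <- oracle_jarvis_hull(pts)
  if (nrow(hull) < 3L) return(0)
  grid <- expand.grid(row = min(pts[, 1L]):max(pts[, 1L]),
                      col = min(pts[, 2L]):max(pts[, 2L]))
  n_hull <- sum(apply(as.matrix(grid), 1L, oracle_in_hull, hull = hull))
  1 - nrow(pts) / n_hull
}

# brute-force containment: shared coordinate rows over dead rows
oracle_containment <- function(dead_coords, host_coords) {
  key <- function(df) paste(df$row, df$col)
  mean(key(dead_coords) %in% key(host_coords))
}

# build cell_object-like fixtures straight from a label mask
objects_from_mask <- function(mask, class = "dead") {
  extract_objects(mask, class)
}

# textbook Pearson r and two-sided t-based p from explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# deterministic mixed scene specs used by the recovery suites
recovery_spec <- function(seed, noise_sigma) {
  scene_spec(seed = seed, noise_sigma = noise_sigma,
             n_viable_free = 2L + seed %% 4L,
             n_dead_free = 1L + seed %% 3L,
             n_cic = 1L + seed %% 3L)
}
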