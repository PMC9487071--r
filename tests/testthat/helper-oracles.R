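# Independent oracles and small fixtures. These deliberately re-derive
# quantities through different formulations than the package code paths.

# --- closest point: plane-projection + edge-clamp formulation -------------

cross_o <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

closest_on_segment_o <- function(q, p0, p1) {
  d <- p1 - p0
  t <- sum((q - p0) * d) / sum(d * d)
  t <- min(1, max(0, t))
  p0 + t * d
}

# closest point on one triangle: interior plane projection (checked via
# barycentric coordinates) against the three clamped edges
closest_on_triangle_o <- function(q, a, b, c) {
  n <- cross_o(b - a, c - a)
  n <- n / sqrt(sum(n^2))
  qp <- q - sum((q - a) * n) * n
  # barycentric coordinates of the projection
  v0 <- b - a; v1 <- c - a; v2 <- qp - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  cands <- list(closest_on_segment_o(q, a, b),
                closest_on_segment_o(q, b, c),
                closest_on_segment_o(q, c, a))
  if (v >= 0 && w >= 0 && v + w <= 1) cands <- c(cands, list(qp))
  d2 <- vapply(cands, function(p) sum((q - p)^2), numeric(1))
  cands[[which.min(d2)]]
}

# exhaustive all-triangles closest point on a mesh
brute_closest_o <- function(q, mesh) {
  best <- Inf
  bp <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[f, ]
    p <- closest_on_triangle_o(q, mesh$vertices[tri[1], ],
                               mesh$vertices[tri[2], ],
                               mesh$vertices[tri[3], ])
    d2 <- sum((q - p)^2)
    if (d2 < best) { best <- d2; bp <- p }
  }
  list(point = bp, dist = sqrt(best))
}

# --- rigid alignment: brute-force axis-angle minimization -----------------

rodrigues_o <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-14) return(diag(3))
  k <- rv / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# residual sum of squares for the best translation at a given rotation
rss_at_rotation_o <- function(rv, src, dst) {
  R <- rodrigues_o(rv)
  moved <- src %*% t(R)
  t <- colMeans(dst) - colMeans(moved)
  sum((sweep(moved, 2, -t) - dst)^2)
}

# grid of axis-angle starts + Nelder-Mead refinement
brute_kabsch_rss_o <- function(src, dst) {
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1),
                c(-1, 1, 0), c(1, -1, 1), c(-1, -1, 1))
  axes <- axes / sqrt(rowSums(axes^2))
  angles <- seq(0, pi, length.out = 13)[-1]
  best <- rss_at_rotation_o(c(0, 0, 0), src, dst)
  starts <- list(c(0, 0, 0))
  for (i in seq_len(nrow(axes)))
    for (th in angles) starts <- c(starts, list(axes[i, ] * th))
  for (s in starts) {
    o <- stats::optim(s, rss_at_rotation_o, src = src, dst = dst,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# --- ICC: independent explicit two-way ANOVA ------------------------------

icc_a_k_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(m[i, ]) / k - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(m[, j]) / n - gm)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - sum(m[i, ]) / k - sum(m[, j]) / n + gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# --- fixtures -------------------------------------------------------------

# small non-axis-aligned test mesh: a coarse synthetic face
small_face <- function(resolution = 24, ...) {
  generate_face(synthetic_face_spec(resolution = resolution, ...))
}

# drop faces (keeping every stride-th) and compact the vertex set; yields an
# irregular open mesh small enough for exhaustive oracles
decimate_faces <- function(mesh, stride = 3L) {
  keep <- mesh$faces[seq(1, nrow(mesh$faces), by = stride), , drop = FALSE]
  used <- sort(unique(as.integer(keep)))
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(match(keep, used), ncol = 3))
}

# a canonical landmark set on which all 12 measurements are defined
toy_landmarks <- function() {
  f <- generate_face(synthetic_face_spec(resolution = 40))
  f$landmarks
}

random_rigid <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rotation_axis_angle(ax, stats::runif(1, -180, 180)),
                  stats::rnorm(3, sd = 20))
}
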