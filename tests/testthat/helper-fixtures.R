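# Geometric fixtures built in code.

ring_poly <- function(r, n = 64, cx = 0, cy = 0, rx = r, ry = r) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

# stack of circular slices (a cylinder), endo radius r, wall w
cylinder_stack <- function(r = 20, wall = 8, n_slices = 5, height = 40,
                           n_vert = 80, es_scale = 1) {
  z <- seq(0, -height, length.out = n_slices)
  slices <- lapply(z, function(zi) {
    list(z = zi,
         endo_ed = ring_poly(r, n_vert),
         epi_ed = ring_poly(r + wall, n_vert),
         endo_es = ring_poly(r * es_scale, n_vert),
         epi_es = ring_poly((r + wall) * es_scale, n_vert),
         scar = list())
  })
  contour_stack(slices, pixel_spacing = 0.25)
}

# single-slice annulus with a scar wedge occupying area fraction `frac` of the
# wall between angles th1..th2 (radians)
wedge_stack <- function(r_in = 20, r_out = 30, frac = 0.6,
                        th1 = pi / 4, th2 = 3 * pi / 4, n_vert = 256,
                        pixel_spacing = 0.25, n_slices = 1) {
  r_sc <- sqrt(r_in^2 + frac * (r_out^2 - r_in^2))
  th <- seq(th1, th2, length.out = 96)
  scar <- rbind(cbind(r_sc * cos(th), r_sc * sin(th)),
                cbind(r_in * cos(rev(th)), r_in * sin(rev(th))))
  slices <- lapply(seq_len(n_slices), function(i) {
    list(z = -(i - 1) * 5,
         endo_ed = ring_poly(r_in, n_vert),
         epi_ed = ring_poly(r_out, n_vert),
         scar = list(scar))
  })
  contour_stack(slices, pixel_spacing = pixel_spacing)
}

# independent R oracle: exact point-to-triangle distance, vectorized over
# triangles (different code path from the compiled kernel)
oracle_point_tri_dist <- function(p, V, F) {
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  seg_dist2 <- function(p, a, b) {
    ab <- b - a
    t <- rowSums(sweep(a, 2, p, "-") * -ab) / pmax(rowSums(ab^2), 1e-300)
    t <- pmin(pmax(t, 0), 1)
    q <- a + ab * t
    rowSums(sweep(q, 2, p, "-")^2)
  }
  e1 <- B - A; e2 <- C - A
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- rowSums(n^2)
  ap <- sweep(-A, 2, p, "+")          # p - A per triangle
  tparam <- rowSums(ap * n) / pmax(nn, 1e-300)
  proj <- matrix(p, nrow(A), 3, byrow = TRUE) - n * tparam
  # barycentric test of the projected point
  v0 <- e1; v1 <- e2; v2 <- proj - A
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- pmax(d00 * d11 - d01 * d01, 1e-300)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  inside <- v >= 0 & w >= 0 & v + w <= 1
  d2 <- ifelse(inside, tparam^2 * nn,
               pmin(seg_dist2(p, A, B), seg_dist2(p, B, C), seg_dist2(p, C, A)))
  sqrt(min(d2))
}

# independent R oracle: ray-parity inside test against the capped mesh
oracle_inside <- function(p, V, F, dir = c(0.213, 0.587, 0.781)) {
  dir <- dir / sqrt(sum(dir^2))
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(-A, 2, p, "+")
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
  t <- rowSums(e2 * q) / a
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 1e-9
  sum(hit) %% 2 == 1
}

# closed capped copy of a mesh for the inside oracle
capped_for_test <- function(mesh) {
  ring <- which(mesh$slice_of_vertex == 1)
  v <- rbind(mesh$vertices, mesh$basal_plane$point)
  m <- length(ring)
  cap <- t(vapply(seq_len(m), function(j) {
    c(ring[j], ring[j %% m + 1], nrow(v))
  }, integer(3)))
  list(vertices = v, triangles = rbind(mesh$triangles, cap))
}

random_rigid <- function(max_deg = 30, max_mm = 20, pivot = c(0, 0, 0)) {
  rigid_transform(runif(3, -max_deg, max_deg), runif(3, -max_mm, max_mm), pivot)
}

expect_transform_equal <- function(t1, t2, tol = 1e-9) {
  expect_lt(max(abs(t1$rotation - t2$rotation)), tol)
  p <- matrix(rnorm(30), ncol = 3) * 20
  expect_lt(max(abs(transform_points(t1, p) - transform_points(t2, p))), tol * 100)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Mann-Whitney pairwise-concordance AUC oracle: P(pred_pos < pred_neg) + ties/2
# for the "low predictor = positive" direction
concordance_auc <- function(pred, ref, cutoff) {
  pos <- pred[ref >= cutoff]; neg <- pred[ref < cutoff]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, "<") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

simulate_hierarchical <- function(seed, n_groups = 17, n_per = 90,
                                  tau00 = 4, sigma2 = 16, beta = 0.5,
                                  cov_sd = sqrt(20)) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  u <- rnorm(n_groups, 0, sqrt(tau00))[g]
  x <- rnorm(n_groups * n_per, 0, cov_sd)   # var(beta * x) = beta^2 * 20 = 5
  y <- 10 + beta * x + u + rnorm(n_groups * n_per, 0, sqrt(sigma2))
  tibble::tibble(animal = g, it = y, uv = x)
}

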