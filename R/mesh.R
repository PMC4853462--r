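#' Triangulated LV endocardial surface mesh
#'
#' An open triangulated surface (single boundary loop at the base) with
#' optional per-vertex scalar channels (infarct transmurality `it` in percent,
#' wall thickening `wt` in mm). Built from stacked contours by
#' [build_endocardial_mesh()].
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles k x 3 integer matrix of 1-based vertex indices.
#' @param channels named list of length-n numeric vectors.
#' @param basal_plane list with `point` and `normal` (length-3); the normal
#'   points away from the apex (toward the atria).
#' @param apex_vertex index of the apex vertex.
#' @param slice_of_vertex integer slice index (1 = most basal) per vertex.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, channels = list(),
                         basal_plane = NULL, apex_vertex = NA_integer_,
                         slice_of_vertex = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3) {
    abort("vertices must be n x 3 and triangles k x 3", class = "emmfuse_format_error")
  }
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices))) {
    abort("triangle indices out of range", class = "emmfuse_validation_error")
  }
  for (nm in names(channels)) {
    if (length(channels[[nm]]) != nrow(vertices)) {
      abort(sprintf("channel '%s' length != vertex count", nm),
            class = "emmfuse_validation_error")
    }
  }
  structure(
    list(vertices = unname(vertices), triangles = unname(triangles),
         channels = channels, basal_plane = basal_plane,
         apex_vertex = as.integer(apex_vertex),
         slice_of_vertex = slice_of_vertex),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, channels: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (length(x$channels)) paste(names(x$channels), collapse = ", ") else "none"))
  invisible(x)
}

# resample a closed polygon (open repr.) to m equal-arclength points,
# starting at the original first vertex
resample_ring <- function(p, m) {
  pc <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  total <- sum(seg)
  if (total <= 0 || abs(polygon_area(p)) < 1e-9) {
    abort("degenerate (zero-area) ring", class = "emmfuse_validation_error")
  }
  s <- c(0, cumsum(seg))
  target <- total * (0:(m - 1)) / m
  x <- stats::approx(s, pc[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(s, pc[, 2], xout = target, ties = "ordered")$y
  cbind(x, y)
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

polygon_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(p))
  cx <- sum((p[, 1] + p[j, 1]) * cr) / (6 * a)
  cy <- sum((p[, 2] + p[j, 2]) * cr) / (6 * a)
  c(cx, cy)
}

#' Build the end-diastolic endocardial surface mesh from stacked contours
#'
#' Each end-diastolic endocardial polygon is resampled to `points_per_ring`
#' equal-arclength points; rings are oriented consistently and their angular
#' origins aligned by minimizing summed inter-ring vertex distance over
#' discrete circular offsets (this prevents twisted stitching). Adjacent rings
#' are stitched with `2 * points_per_ring` triangles; the apex is closed with
#' a triangle fan to the centroid of the most apical ring, which becomes the
#' apex vertex. The basal plane is the plane of the most basal ring. Triangle
#' normals are oriented consistently outward from the cavity.
#'
#' @param stack a `contour_stack` with at least 3 slices.
#' @param points_per_ring ring resolution (default 80, matching the number of
#'   circumferential segments); minimum 16.
#' @return A `surface_mesh` with `slice_of_vertex`, `apex_vertex` and
#'   `basal_plane` set. Vertex count is
#'   `points_per_ring * n_slices + 1`.
#' @export
build_endocardial_mesh <- function(stack, points_per_ring = 80) {
  stopifnot(inherits(stack, "contour_stack"))
  if (points_per_ring < 16) {
    abort("points_per_ring must be >= 16", class = "emmfuse_error")
  }
  L <- n_slices(stack)
  if (L < 3) {
    abort("need at least 3 slices to build a mesh", class = "emmfuse_validation_error")
  }
  m <- as.integer(points_per_ring)
  rings <- vector("list", L)
  for (i in seq_len(L)) {
    p <- stack$slices[[i]]$endo_ed
    if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    rings[[i]] <- resample_ring(p, m)
  }
  # align angular origin of each ring to the ring above it
  for (i in 2:L) {
    a <- rings[[i - 1]]; b <- rings[[i]]
    cost <- vapply(0:(m - 1), function(off) {
      idx <- ((seq_len(m) - 1 + off) %% m) + 1
      sum((a - b[idx, , drop = FALSE])^2)
    }, numeric(1))
    off <- which.min(cost) - 1
    idx <- ((seq_len(m) - 1 + off) %% m) + 1
    rings[[i]] <- b[idx, , drop = FALSE]
  }
  z <- vapply(stack$slices, function(s) s$z, numeric(1))
  vertices <- do.call(rbind, lapply(seq_len(L), function(i) {
    cbind(rings[[i]], z[i])
  }))
  apex_ring <- rings[[L]]
  apex <- c(polygon_centroid(apex_ring), z[L])
  vertices <- rbind(vertices, apex)
  apex_vertex <- nrow(vertices)
  slice_of_vertex <- c(rep(seq_len(L), each = m), L)

  tri <- matrix(0L, nrow = 2 * m * (L - 1) + m, ncol = 3)
  r <- 1L
  for (i in seq_len(L - 1)) {
    for (j in seq_len(m)) {
      jn <- j %% m + 1
      v1 <- (i - 1) * m + j
      v2 <- (i - 1) * m + jn
      v3 <- i * m + j
      v4 <- i * m + jn
      tri[r, ] <- c(v1, v3, v2); r <- r + 1L
      tri[r, ] <- c(v2, v3, v4); r <- r + 1L
    }
  }
  for (j in seq_len(m)) {
    jn <- j %% m + 1
    tri[r, ] <- c((L - 1) * m + j, apex_vertex, (L - 1) * m + jn)
    r <- r + 1L
  }

  base_centroid <- c(polygon_centroid(rings[[1]]), z[1])
  long_axis <- base_centroid - apex
  normal <- long_axis / sqrt(sum(long_axis^2))
  mesh <- surface_mesh(vertices, tri,
                       basal_plane = list(point = base_centroid, normal = normal),
                       apex_vertex = apex_vertex,
                       slice_of_vertex = slice_of_vertex)
  # orient triangles outward from the cavity (signed volume of capped mesh > 0)
  if (capped_signed_volume(mesh) < 0) {
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  }
  mesh
}

# close the basal boundary with a fan to the basal ring centroid; the cap
# traverses each boundary edge opposite to the surface's single traversal so
# the closed mesh stays consistently oriented
capped_mesh <- function(mesh) {
  bp <- mesh$basal_plane
  ring <- which(mesh$slice_of_vertex == 1)
  v <- rbind(mesh$vertices, bp$point)
  c_idx <- nrow(v)
  m <- length(ring)
  tri <- mesh$triangles
  # direction in which the surface traverses boundary edge ring[1] -> ring[2]
  dirs <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  fwd <- any(dirs[, 1] == ring[1] & dirs[, 2] == ring[2])
  cap <- t(vapply(seq_len(m), function(j) {
    jn <- j %% m + 1
    if (fwd) c(ring[jn], ring[j], c_idx) else c(ring[j], ring[jn], c_idx)
  }, integer(3)))
  list(vertices = v, triangles = rbind(tri, cap))
}

signed_volume <- function(v, tri) {
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

capped_signed_volume <- function(mesh) {
  cm <- capped_mesh(mesh)
  signed_volume(cm$vertices, cm$triangles)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return scalar area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

triangle_areas <- function(mesh) {
  a <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Exact closest distance from points to the mesh surface
#'
#' Minimum point-to-triangle distance over all triangles (exhaustive exact
#' scan in compiled code). Returns, per point, the distance, the foot point on
#' the surface, and the index of the closest triangle.
#'
#' @param points n x 3 matrix, length-3 vector, or data frame with `x,y,z`.
#' @param mesh a `surface_mesh`.
#' @return A tibble with columns `distance`, `foot_x`, `foot_y`, `foot_z`,
#'   `triangle` (one row per query point).
#' @export
closest_surface_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$triangles) == 0) {
    abort("mesh has no triangles", class = "emmfuse_validation_error")
  }
  m <- as_point_matrix(points)
  res <- cpp_closest_surface(m, mesh$vertices, mesh$triangles)
  tibble::tibble(
    distance = as.numeric(res$distance),
    foot_x = res$foot[, 1], foot_y = res$foot[, 2], foot_z = res$foot[, 3],
    triangle = as.integer(res$triangle)
  )
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    as.matrix(points[, c("x", "y", "z")])
  } else if (is.null(dim(points))) {
    matrix(as.numeric(points), ncol = 3)
  } else {
    m <- as.matrix(points)
    stopifnot(ncol(m) == 3)
    m
  }
}

#' Test whether points lie inside the LV cavity
#'
#' The open endocardial surface is closed by capping the basal boundary loop
#' with a triangle fan to the basal ring centroid; a point is inside iff it is
#' inside this closed volume (generalized winding number > 1/2). Points on the
#' atrial side of the basal plane are outside by construction — this is what
#' excludes outflow-tract mapping points.
#'
#' @param points n x 3 matrix, length-3 vector, or data frame with `x,y,z`.
#' @param mesh a `surface_mesh` built by [build_endocardial_mesh()].
#' @return logical vector, one per point.
#' @export
is_inside_lv <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$triangles) == 0) {
    abort("mesh has no triangles", class = "emmfuse_validation_error")
  }
  m <- as_point_matrix(points)
  cm <- capped_mesh(mesh)
  w <- cpp_winding_number(m, cm$vertices, cm$triangles)
  abs(w) > 0.5
}

#' Project a scattered scalar field onto mesh vertices
#'
#' Values sampled at arbitrary 3D positions are interpolated to every mesh
#' vertex by a distance-weighted local linear least-squares fit over the `k`
#' nearest samples, clamped to the global range of the sample values. The
#' estimator reproduces constants and, inside the samples' convex hull, any
#' affine field exactly (the clamp cannot bind there); a vertex coinciding
#' with a sample takes that sample's value; far outside the sample cloud the
#' prediction tends to the nearest sample's value. It never produces values
#' outside `[min(values), max(values)]`.
#'
#' @param mesh a `surface_mesh`.
#' @param samples n x 3 matrix (or data frame with `x,y,z`) of sample
#'   positions, n >= 4.
#' @param values length-n numeric sample values.
#' @param channel channel name to store (e.g. `"it"`, `"wt"`).
#' @param k neighborhood size (default 12, capped at n).
#' @return The mesh with the new vertex channel.
#' @export
project_scalar_field <- function(mesh, samples, values, channel, k = 12) {
  stopifnot(inherits(mesh, "surface_mesh"))
  s <- as_point_matrix(samples)
  values <- as.numeric(values)
  keep <- is.finite(values)
  s <- s[keep, , drop = FALSE]; values <- values[keep]
  if (nrow(s) < 4) {
    abort("need at least 4 samples to project a field", class = "emmfuse_validation_error")
  }
  k <- min(k, nrow(s))
  lo <- min(values); hi <- max(values)
  V <- mesh$vertices
  out <- numeric(nrow(V))
  for (i in seq_len(nrow(V))) {
    d2 <- (s[, 1] - V[i, 1])^2 + (s[, 2] - V[i, 2])^2 + (s[, 3] - V[i, 3])^2
    nn <- order(d2)[seq_len(k)]
    if (d2[nn[1]] < 1e-18) {
      out[i] <- values[nn[1]]
      next
    }
    dx <- sweep(s[nn, , drop = FALSE], 2, V[i, ])
    h <- sqrt(stats::median(d2[nn]))
    w <- 1 / (d2[nn] + (0.1 * h)^2)
    X <- cbind(1, dx) * sqrt(w)
    y <- values[nn] * sqrt(w)
    sv <- svd(X)
    tol <- max(sv$d) * 1e-8
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    out[i] <- min(hi, max(lo, beta[1]))
  }
  mesh$channels[[channel]] <- out
  mesh
}

# vertex adjacency list from triangles
vertex_adjacency <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$vertices))))
}
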