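#' Area-based infarct transmurality per circumferential segment
#'
#' Rasterizes the myocardium (epicardial minus endocardial polygon) and the
#' scar polygons at the stack's `pixel_spacing`, partitions myocardial pixels
#' into `n_segments` equal angular sectors about the end-diastolic endocardial
#' centroid, and returns per segment
#' \deqn{IT_k = 100 \cdot \mathrm{area}(scar \cap myo)_k / \mathrm{area}(myo)_k.}
#' Segments with no myocardial pixels are `NA`. The angular origin is the +x
#' direction, proceeding counterclockwise (the package's declared bullseye
#' convention).
#'
#' @param stack a `contour_stack`.
#' @param slice_index slice number (1 = most basal).
#' @param n_segments number of circumferential segments (default 80).
#' @param detail if `TRUE`, return a tibble with per-segment myocardial and
#'   scar pixel counts instead of the bare IT vector.
#' @return numeric length-`n_segments` vector of IT percentages (or a detail
#'   tibble).
#' @export
segment_transmurality <- function(stack, slice_index, n_segments = 80,
                                  detail = FALSE) {
  stopifnot(inherits(stack, "contour_stack"))
  s <- stack$slices[[slice_index]]
  if (is.null(s$epi_ed)) {
    abort(sprintf("slice %d lacks an epicardial contour", slice_index),
          class = "emmfuse_validation_error")
  }
  px <- stack$pixel_spacing
  rng_x <- range(s$epi_ed[, 1]); rng_y <- range(s$epi_ed[, 2])
  gx <- seq(rng_x[1] + px / 2, rng_x[2], by = px)
  gy <- seq(rng_y[1] + px / 2, rng_y[2], by = px)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))

  in_epi <- cpp_points_in_polygon(grid[, 1], grid[, 2], s$epi_ed[, 1], s$epi_ed[, 2])
  in_endo <- cpp_points_in_polygon(grid[, 1], grid[, 2], s$endo_ed[, 1], s$endo_ed[, 2])
  myo <- in_epi & !in_endo

  scar <- rep(FALSE, nrow(grid))
  for (j in seq_along(s$scar)) {
    sc <- cpp_points_in_polygon(grid[, 1], grid[, 2], s$scar[[j]][, 1], s$scar[[j]][, 2])
    if (!any(sc & myo)) {
      warn(sprintf("slice %d scar polygon %d lies entirely outside the myocardium",
                   slice_index, j))
    }
    scar <- scar | sc
  }
  scar <- scar & myo

  ctr <- polygon_centroid(s$endo_ed)
  theta <- atan2(grid[, 2] - ctr[2], grid[, 1] - ctr[1]) %% (2 * pi)
  seg <- pmin(floor(theta / (2 * pi / n_segments)), n_segments - 1)
  myo_n <- tabulate(seg[myo] + 1L, nbins = n_segments)
  scar_n <- tabulate(seg[scar] + 1L, nbins = n_segments)
  it <- ifelse(myo_n > 0, 100 * scar_n / myo_n, NA_real_)
  if (detail) {
    return(tibble::tibble(segment = 0:(n_segments - 1), myo_pixels = myo_n,
                          scar_pixels = scar_n, it = it))
  }
  it
}

#' Transmurality bullseye for a whole stack
#'
#' @inheritParams segment_transmurality
#' @return matrix `n_slices x n_segments` of IT percentages, rows base to
#'   apex.
#' @export
transmurality_bullseye <- function(stack, n_segments = 80) {
  do.call(rbind, lapply(seq_len(n_slices(stack)), function(i) {
    segment_transmurality(stack, i, n_segments = n_segments)
  }))
}

.it_class_labels <- c("0%", "0-25%", "25-50%", "50-75%", "75-100%")

#' Classify infarct transmurality into the five standard areas
#'
#' Partition of \eqn{[0, 100]}: exactly 0 maps to `"0%"`; thereafter
#' half-open intervals that exclude the lower and include the upper bound:
#' (0, 25] -> `"0-25%"`, (25, 50] -> `"25-50%"`, (50, 75] -> `"50-75%"`,
#' (75, 100] -> `"75-100%"`.
#'
#' @param it numeric vector of IT percentages in `[0, 100]` (`NA` allowed).
#' @return factor with the five class labels.
#' @export
classify_it <- function(it) {
  bad <- which(!is.na(it) & (it < 0 | it > 100))
  if (length(bad)) {
    abort(sprintf("IT value %g outside [0, 100]", it[bad[1]]),
          class = "emmfuse_validation_error")
  }
  cut(it, breaks = c(-Inf, 0, 25, 50, 75, 100), labels = .it_class_labels,
      right = TRUE)
}

# outermost positive ray-polygon crossing distance from center along angle;
# NA if the ray misses
ray_crossing <- function(poly, center, angle) {
  d <- c(cos(angle), sin(angle))
  n <- nrow(poly)
  a <- sweep(poly, 2, center)
  b <- a[c(2:n, 1), , drop = FALSE]
  e <- b - a
  denom <- d[1] * e[, 2] - d[2] * e[, 1]
  t_num <- a[, 1] * e[, 2] - a[, 2] * e[, 1]
  u_num <- a[, 1] * d[2] - a[, 2] * d[1]
  ok <- abs(denom) > 1e-14
  t <- ifelse(ok, t_num / denom, NA)
  u <- ifelse(ok, -u_num / denom, NA)
  hit <- ok & t > 0 & u >= 0 & u < 1
  if (!any(hit, na.rm = TRUE)) return(NA_real_)
  max(t[hit], na.rm = TRUE)
}

#' Wall thickening per circumferential segment
#'
#' Wall thickness is the mean radial epicardial-minus-endocardial distance
#' along rays cast from the end-diastolic endocardial centroid within each
#' sector (the same polar frame as [segment_transmurality()]); wall
#' thickening is the end-systolic minus end-diastolic thickness in mm and may
#' be negative in dyskinetic regions.
#'
#' @param stack a `contour_stack` whose slices carry `endo_es` and `epi_es`.
#' @param slice_index slice number.
#' @param n_segments number of segments (default 80).
#' @param rays_per_segment rays averaged per sector (default 3).
#' @return numeric length-`n_segments` vector of WT in mm (`NA` where a ray
#'   misses a contour).
#' @export
wall_thickening <- function(stack, slice_index, n_segments = 80,
                            rays_per_segment = 3) {
  s <- stack$slices[[slice_index]]
  for (nm in c("endo_ed", "epi_ed", "endo_es", "epi_es")) {
    if (is.null(s[[nm]])) {
      abort(sprintf("slice %d lacks contour '%s' needed for wall thickening",
                    slice_index, nm), class = "emmfuse_validation_error")
    }
  }
  ctr <- polygon_centroid(s$endo_ed)
  width <- 2 * pi / n_segments
  vapply(seq_len(n_segments) - 1L, function(k) {
    angles <- k * width + width * (seq_len(rays_per_segment) - 0.5) / rays_per_segment
    th <- vapply(angles, function(a) {
      r_endo_ed <- ray_crossing(s$endo_ed, ctr, a)
      r_epi_ed <- ray_crossing(s$epi_ed, ctr, a)
      r_endo_es <- ray_crossing(s$endo_es, ctr, a)
      r_epi_es <- ray_crossing(s$epi_es, ctr, a)
      if (anyNA(c(r_endo_ed, r_epi_ed, r_endo_es, r_epi_es))) return(NA_real_)
      (r_epi_es - r_endo_es) - (r_epi_ed - r_endo_ed)
    }, numeric(1))
    if (anyNA(th)) NA_real_ else mean(th)
  }, numeric(1))
}

#' Wall-thickening bullseye for a whole stack
#' @inheritParams wall_thickening
#' @return matrix `n_slices x n_segments` of WT in mm.
#' @export
wall_thickening_bullseye <- function(stack, n_segments = 80,
                                     rays_per_segment = 3) {
  do.call(rbind, lapply(seq_len(n_slices(stack)), function(i) {
    wall_thickening(stack, i, n_segments = n_segments,
                    rays_per_segment = rays_per_segment)
  }))
}

#' Infarct border-zone vertex mask
#'
#' Minimal declared definition of the border zone on a mesh with an `it`
#' channel: vertices with `lo < it <= hi` (infarcted but non-transmural),
#' restricted to the connected components of that band that are edge-adjacent
#' to the transmural core (`it > hi`) when a core exists, otherwise to
#' components adjacent to territory with `it <= lo`. Uniform fields (all 0 or
#' all 100) yield an empty mask.
#'
#' @param mesh `surface_mesh` with an `it` channel.
#' @param lo,hi band bounds in percent, `0 <= lo < hi <= 100` (defaults 0 and
#'   75).
#' @return logical vertex mask.
#' @export
border_zone <- function(mesh, lo = 0, hi = 75) {
  it <- mesh$channels$it
  if (is.null(it)) {
    abort("mesh has no 'it' channel", class = "emmfuse_validation_error")
  }
  stopifnot(lo >= 0, hi <= 100, lo < hi)
  band <- !is.na(it) & it > lo & it <= hi
  if (!any(band)) return(band)
  adj <- vertex_adjacency(mesh)
  core <- !is.na(it) & it > hi
  anchor <- if (any(core)) core else (!is.na(it) & it <= lo)
  comp <- band_components(band, adj)
  keep <- logical(max(comp, na.rm = TRUE))
  for (v in which(band)) {
    if (any(anchor[adj[[v]]])) keep[comp[v]] <- TRUE
  }
  res <- band
  res[band] <- keep[comp[band]]
  res
}

# connected-component labels of the TRUE vertices of mask
band_components <- function(mask, adj) {
  comp <- rep(NA_integer_, length(mask))
  label <- 0L
  for (start in which(mask)) {
    if (!is.na(comp[start])) next
    label <- label + 1L
    queue <- start
    comp[start] <- label
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[mask[nb] & is.na(comp[nb])]
      comp[nb] <- label
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Endocardial surface area per bullseye segment
#'
#' Assigns each mesh triangle to a (slice, segment) cell by its centroid —
#' slice by the mean slice index of its vertices, segment by the centroid's
#' angle about the slice ring center — and sums triangle areas. The total over
#' all cells equals the mesh surface area.
#'
#' @param mesh a `surface_mesh` with `slice_of_vertex`.
#' @param n_segments number of segments (default 80).
#' @return matrix `n_slices x n_segments` of areas in cm^2.
#' @export
segment_areas <- function(mesh, n_segments = 80) {
  if (is.null(mesh$slice_of_vertex)) {
    abort("mesh lacks slice_of_vertex", class = "emmfuse_validation_error")
  }
  L <- max(mesh$slice_of_vertex)
  areas <- triangle_areas(mesh)
  tri <- mesh$triangles
  tri_slice <- round(rowMeans(matrix(mesh$slice_of_vertex[tri], ncol = 3)))
  tri_slice <- pmin(pmax(tri_slice, 1), L)
  centroids <- (mesh$vertices[tri[, 1], , drop = FALSE] +
                mesh$vertices[tri[, 2], , drop = FALSE] +
                mesh$vertices[tri[, 3], , drop = FALSE]) / 3
  # ring centers per slice
  centers <- t(vapply(seq_len(L), function(i) {
    colMeans(mesh$vertices[mesh$slice_of_vertex == i, , drop = FALSE])
  }, numeric(3)))
  cx <- centers[tri_slice, 1]; cy <- centers[tri_slice, 2]
  theta <- atan2(centroids[, 2] - cy, centroids[, 1] - cx) %% (2 * pi)
  seg <- pmin(floor(theta / (2 * pi / n_segments)), n_segments - 1) + 1L
  out <- matrix(0, nrow = L, ncol = n_segments)
  for (t in seq_along(areas)) {
    out[tri_slice[t], seg[t]] <- out[tri_slice[t], seg[t]] + areas[t]
  }
  out / 100  # mm^2 -> cm^2
}
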