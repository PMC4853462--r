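#' Linear local shortening from point trajectories
#'
#' For each index point \eqn{i}, LLS is the weighted relative change of the
#' distances to all other recorded points from end diastole to maximal
#' systole:
#' \deqn{LLS_i = 100 \cdot \frac{\sum_{j \ne i} w_{ij}\,(d^{ED}_{ij} - d^{ES}_{ij})}
#'   {\sum_{j \ne i} w_{ij}\, d^{ED}_{ij}}}
#' Positive values mean shortening. The weight emphasizes neighbor pairs
#' whose end-diastolic distance lies in the `band_mm` window: a tent window
#' equal to 1 on `[band_mm[1], band_mm[2]]`, ramping linearly to 0 at
#' `ramp_mm[1]` below and `ramp_mm[2]` above. (The mapping system's exact
#' weighting is proprietary; this declared surrogate reproduces the stated
#' 8-15 mm emphasis band, and the scale-invariance properties of LLS do not
#' depend on the window shape.)
#'
#' @param traj tibble with columns `id, phase, x, y, z`; phases `"ED"` and
#'   `"ES"` (one row per point per phase).
#' @param band_mm full-weight distance band in mm (default `c(8, 15)`).
#' @param ramp_mm distances at which the weight reaches zero (default
#'   `c(4, 25)`).
#' @return tibble `id, lls` (percent; `NA` where all weights vanish).
#' @export
compute_lls <- function(traj, band_mm = c(8, 15), ramp_mm = c(4, 25)) {
  stopifnot(all(c("id", "phase", "x", "y", "z") %in% names(traj)))
  ed <- traj[traj$phase == "ED", ]
  es <- traj[traj$phase == "ES", ]
  if (nrow(ed) < 2) {
    abort("need at least 2 points with ED positions", class = "emmfuse_validation_error")
  }
  es <- es[match(ed$id, es$id), ]
  if (anyNA(es$id)) {
    abort("every point needs both ED and ES positions", class = "emmfuse_validation_error")
  }
  ped <- as.matrix(ed[, c("x", "y", "z")])
  pes <- as.matrix(es[, c("x", "y", "z")])
  n <- nrow(ped)
  ded <- as.matrix(stats::dist(ped))
  des <- as.matrix(stats::dist(pes))
  w <- lls_weight(ded, band_mm, ramp_mm)
  diag(w) <- 0
  num <- rowSums(w * (ded - des))
  den <- rowSums(w * ded)
  lls <- unname(ifelse(den > 0, 100 * num / den, NA_real_))
  tibble::tibble(id = ed$id, lls = lls)
}

# tent window on ED distance: 0 below ramp[1] and above ramp[2], 1 in band
lls_weight <- function(d, band = c(8, 15), ramp = c(4, 25)) {
  w <- matrix(0, nrow(d), ncol(d))
  up <- d > ramp[1] & d < band[1]
  w[up] <- (d[up] - ramp[1]) / (band[1] - ramp[1])
  w[d >= band[1] & d <= band[2]] <- 1
  down <- d > band[2] & d < ramp[2]
  w[down] <- (ramp[2] - d[down]) / (ramp[2] - band[2])
  w
}

#' EMM point density per infarct-transmurality class
#'
#' Each included analysis point is assigned the IT class of its closest mesh
#' vertex; the endocardial area of each class is the sum of the bullseye
#' segment areas whose IT falls in that class. Density is points per cm^2.
#'
#' @param emm registered, analysis-filtered EMM tibble.
#' @param mesh `surface_mesh` with an `it` channel.
#' @param area_grid `n_slices x n_segments` matrix of segment areas in cm^2
#'   (from [segment_areas()]).
#' @param it_grid matching matrix of segment IT percentages used to classify
#'   segments (e.g. the measured or ground-truth bullseye).
#' @return tibble with one row per IT class: `it_class, n_points, area_cm2,
#'   density_pts_per_cm2`.
#' @export
point_density <- function(emm, mesh, area_grid, it_grid) {
  it <- mesh$channels$it
  if (is.null(it)) {
    abort("mesh has no 'it' channel", class = "emmfuse_validation_error")
  }
  stopifnot(all(dim(area_grid) == dim(it_grid)))
  inc <- if ("included" %in% names(emm)) emm$included else rep(TRUE, nrow(emm))
  pts <- as_point_matrix(emm)[inc, , drop = FALSE]
  nn <- nearest_vertex(pts, mesh)
  pt_class <- classify_it(pmin(pmax(it[nn], 0), 100))
  seg_class <- classify_it(pmin(pmax(as.vector(it_grid), 0), 100))
  area_by_class <- vapply(.it_class_labels, function(cl) {
    sum(as.vector(area_grid)[!is.na(seg_class) & seg_class == cl])
  }, numeric(1))
  n_by_class <- vapply(.it_class_labels, function(cl) {
    sum(pt_class == cl, na.rm = TRUE)
  }, numeric(1))
  bad <- n_by_class > 0 & area_by_class <= 0
  if (any(bad)) {
    abort(sprintf("class %s has points but zero area: inconsistent inputs",
                  .it_class_labels[which(bad)[1]]),
          class = "emmfuse_validation_error")
  }
  tibble::tibble(
    it_class = factor(.it_class_labels, levels = .it_class_labels),
    n_points = as.integer(unname(n_by_class)),
    area_cm2 = unname(area_by_class),
    density_pts_per_cm2 = unname(
      ifelse(area_by_class > 0, n_by_class / area_by_class, NA_real_))
  )
}
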