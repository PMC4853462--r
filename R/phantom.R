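#' Parameter set for the synthetic infarcted-LV phantom
#'
#' The phantom is a truncated-ellipsoid left ventricle: the endocardium is
#' the surface \eqn{(x/a)^2 + (y/b)^2 + (z/c)^2 = 1} for z from the apex
#' (z = -c) up to the basal truncation plane, the epicardium the same with
#' all semi-axes enlarged by the wall thickness. A spatially smooth infarct
#' transmurality field (0-100 %) is centered on a chosen circumferential
#' angle near the apex; scar polygons realize it slice by slice as a radial
#' band occupying the IT fraction of the wall's cross-sectional area. EMM
#' points are surface samples with IT-dependent unipolar/bipolar voltage plus
#' noise, inhomogeneous density (oversampling of dense-scar territory, as
#' catheter maps show), and motion-derived linear local shortening.
#'
#' Voltage defaults (healthy 12/3 mV, scar 4/0.5 mV for UV/BV) bracket the
#' clinically reported low-voltage thresholds so that threshold-recovery
#' analyses operate mid-grid; they are simulation knobs, not physiological
#' claims.
#'
#' @param endo_axes endocardial semi-axes `c(a, b, c)` in mm.
#' @param wall_mm end-diastolic wall thickness in mm.
#' @param n_slices number of short-axis slices (apex to base).
#' @param base_truncation fraction of `c` above the equator where the stack
#'   is truncated (0 = truncate at the equator, giving a half ellipsoid).
#' @param infarct list: `center_deg` (circumferential center), `width_deg`
#'   (full angular width), `extent_frac` (apex-to-base longitudinal extent as
#'   a fraction of the long axis), `peak_it` (peak transmurality, %).
#' @param emm list: `n_points`, `contact_noise_mm`, `uv_healthy`, `uv_scar`,
#'   `bv_healthy`, `bv_scar`, `uv_noise`, `bv_noise`, `oversample_factor`.
#' @param motion list: `contraction` (radial contraction fraction of healthy
#'   wall at end systole), `it_coupling` (1 = fully akinetic scar).
#' @param seed RNG seed for all stochastic parts.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(endo_axes = c(25, 25, 60), wall_mm = 10,
                         n_slices = 20, base_truncation = 0,
                         infarct = list(), emm = list(), motion = list(),
                         seed = 1) {
  infarct <- utils::modifyList(
    list(center_deg = 60, width_deg = 120, extent_frac = 0.65, peak_it = 95),
    infarct)
  emm <- utils::modifyList(
    list(n_points = 150, contact_noise_mm = 1,
         uv_healthy = 12, uv_scar = 4, bv_healthy = 3, bv_scar = 0.5,
         uv_noise = 1, bv_noise = 0.3, oversample_factor = 2),
    emm)
  motion <- utils::modifyList(list(contraction = 0.15, it_coupling = 0.9), motion)
  stopifnot(all(endo_axes > 0), wall_mm > 0, n_slices >= 3,
            base_truncation >= 0, base_truncation < 0.5)
  if (infarct$peak_it > 100 || infarct$peak_it < 0) {
    abort("peak IT must lie in [0, 100]", class = "emmfuse_validation_error")
  }
  if (infarct$extent_frac > 1) {
    abort("infarct extent exceeds the base", class = "emmfuse_validation_error")
  }
  structure(
    list(endo_axes = endo_axes, wall_mm = wall_mm, n_slices = n_slices,
         base_truncation = base_truncation, infarct = infarct, emm = emm,
         motion = motion, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# smooth IT field: cosine-tapered in angle (width_deg full width) and in the
# normalized apex->base coordinate u in [0, 1] (zero beyond extent_frac)
phantom_it_field <- function(spec) {
  inf <- spec$infarct
  c_ax <- spec$endo_axes[3]
  z_apex <- -c_ax
  z_base <- spec$base_truncation * c_ax
  force(inf); force(z_apex); force(z_base)
  function(theta, z) {
    dth <- (theta - inf$center_deg * pi / 180 + pi) %% (2 * pi) - pi
    g_th <- 0.5 + 0.5 * cos(pi * pmin(abs(dth) / (inf$width_deg * pi / 360), 1))
    u <- (z - z_apex) / (z_base - z_apex)
    g_u <- 0.5 + 0.5 * cos(pi * pmin(pmax(u, 0) / max(inf$extent_frac, 1e-9), 1))
    pmin(inf$peak_it * g_th * g_u, 100)
  }
}

# ellipse radius of the level-z cross-section of an ellipsoid (a, b, c), per
# angle theta; 0 if the plane misses the ellipsoid
ellipsoid_radius <- function(axes, z, theta) {
  f <- 1 - (z / axes[3])^2
  if (f <= 0) return(rep(0, length(theta)))
  rx <- axes[1] * sqrt(f); ry <- axes[2] * sqrt(f)
  # polar radius of an axis-aligned ellipse
  1 / sqrt((cos(theta) / rx)^2 + (sin(theta) / ry)^2)
}

#' Generate a synthetic infarcted-LV contour stack with ground truth
#'
#' Builds the short-axis contour stack (end-diastolic and end-systolic
#' endocardial/epicardial contours plus scar polygons), the analytic
#' ground-truth IT bullseye (quadrature over the same field the scar polygons
#' realize, independent of any rasterization), and the endocardial surface
#' mesh. End-systolic contours contract radially by
#' `contraction * (1 - it_coupling * IT/100)`, so scar is hypokinetic.
#'
#' @param spec a [phantom_spec()].
#' @param points_per_contour vertices per generated polygon.
#' @return list with `stack` (`contour_stack`), `it_bullseye`
#'   (`n_slices x 80` analytic IT), `mesh` (`surface_mesh`), `it_fun`
#'   (vectorized `function(theta, z)`), and `spec`.
#' @export
generate_phantom <- function(spec, points_per_contour = 96) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$endo_axes
  ep <- a + spec$wall_mm
  c_ax <- a[3]
  z_base <- spec$base_truncation * c_ax
  z_apex_margin <- -c_ax * 0.97
  z <- seq(z_base, z_apex_margin, length.out = spec$n_slices)
  itf <- phantom_it_field(spec)
  m <- points_per_contour
  th <- 2 * pi * (0:(m - 1)) / m

  slices <- lapply(z, function(zi) {
    r_en <- ellipsoid_radius(a, zi, th)
    r_ep <- ellipsoid_radius(ep, zi, th)
    it <- itf(th, zi)
    cf <- spec$motion$contraction * (1 - spec$motion$it_coupling * it / 100)
    s <- list(
      z = zi,
      endo_ed = cbind(r_en * cos(th), r_en * sin(th)),
      epi_ed = cbind(r_ep * cos(th), r_ep * sin(th)),
      endo_es = cbind(r_en * (1 - cf) * cos(th), r_en * (1 - cf) * sin(th)),
      epi_es = cbind(r_ep * (1 - cf) * cos(th), r_ep * (1 - cf) * sin(th)),
      scar = list()
    )
    # scar outer radius: area fraction it/100 of the wall cross-section
    r_sc <- sqrt(r_en^2 + (it / 100) * (r_ep^2 - r_en^2))
    active <- it > 0.5
    if (any(active)) {
      runs <- split(seq_len(m), cumsum(c(1, diff(active)) != 0))
      runs <- runs[vapply(runs, function(ix) active[ix[1]], logical(1))]
      # merge a wrap-around pair of runs
      if (length(runs) > 1 && active[1] && active[m]) {
        runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
        runs[[length(runs)]] <- NULL
      }
      for (ix in runs) {
        if (length(ix) < 2) next
        outer <- cbind(r_sc[ix] * cos(th[ix]), r_sc[ix] * sin(th[ix]))
        inner <- cbind(r_en[ix] * cos(th[ix]), r_en[ix] * sin(th[ix]))
        s$scar <- c(s$scar, list(rbind(outer, inner[rev(seq_len(nrow(inner))), ])))
      }
    }
    s
  })
  stack <- contour_stack(slices, pixel_spacing = 0.25)

  # analytic IT per 80 segments by angular quadrature of the same field
  nseg <- 80
  qn <- 16
  it_bullseye <- t(vapply(z, function(zi) {
    r_en2 <- function(t_) ellipsoid_radius(a, zi, t_)^2
    r_ep2 <- function(t_) ellipsoid_radius(ep, zi, t_)^2
    vapply(seq_len(nseg) - 1L, function(k) {
      tq <- (k + (seq_len(qn) - 0.5) / qn) * 2 * pi / nseg
      scar <- sum((itf(tq, zi) / 100) * (r_ep2(tq) - r_en2(tq)))
      myo <- sum(r_ep2(tq) - r_en2(tq))
      100 * scar / myo
    }, numeric(1))
  }, numeric(nseg)))
  # stack is ordered base->apex (z descending); z here is already descending
  mesh <- build_endocardial_mesh(stack, points_per_ring = 80)
  list(stack = stack, it_bullseye = it_bullseye, mesh = mesh,
       it_fun = itf, spec = spec)
}

#' Sample synthetic EMM points on a phantom mesh
#'
#' Surface positions are drawn triangle-area weighted, with territory whose
#' IT exceeds 75 % oversampled by `oversample_factor` (mimicking the targeted
#' catheter search of the infarct). Voltages follow a linear IT link with
#' Gaussian noise, truncated at 0: `uv = uv_healthy - (uv_healthy -
#' uv_scar) * IT/100 + e`. End-systolic trajectory positions apply the same
#' radial contraction as the phantom contours; LLS is computed from the
#' noise-free trajectories with [compute_lls()]. Measured point positions are
#' jittered by the contact noise.
#'
#' @param phantom result of [generate_phantom()].
#' @param n_points number of points (default from the spec).
#' @param seed RNG seed for the draw (default: the spec's seed).
#' @return list with `emm` (tibble `id, x, y, z, uv, bv, lls, included,
#'   it_true`) and `traj` (tibble `id, phase, x, y, z`).
#' @export
sample_emm <- function(phantom, n_points = NULL, seed = NULL) {
  spec <- phantom$spec
  if (is.null(n_points)) n_points <- spec$emm$n_points
  if (n_points < 10) {
    abort("need at least 10 EMM points", class = "emmfuse_validation_error")
  }
  set.seed(if (is.null(seed)) spec$seed else seed)
  mesh <- phantom$mesh
  itf <- phantom$it_fun
  areas <- triangle_areas(mesh)
  cent <- (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
           mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
           mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
  it_c <- itf(atan2(cent[, 2], cent[, 1]) %% (2 * pi), cent[, 3])
  w <- areas * ifelse(it_c > 75, spec$emm$oversample_factor, 1)
  tri_idx <- sample.int(length(areas), n_points, replace = TRUE, prob = w)
  u1 <- runif(n_points); u2 <- runif(n_points)
  flip <- u1 + u2 > 1
  u1[flip] <- 1 - u1[flip]; u2[flip] <- 1 - u2[flip]
  A <- mesh$vertices[mesh$triangles[tri_idx, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$triangles[tri_idx, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$triangles[tri_idx, 3], , drop = FALSE]
  pos <- A + u1 * (B - A) + u2 * (C - A)

  theta <- atan2(pos[, 2], pos[, 1]) %% (2 * pi)
  it <- itf(theta, pos[, 3])
  uv <- pmax(0, spec$emm$uv_healthy -
               (spec$emm$uv_healthy - spec$emm$uv_scar) * it / 100 +
               rnorm(n_points, 0, spec$emm$uv_noise))
  bv <- pmax(0, spec$emm$bv_healthy -
               (spec$emm$bv_healthy - spec$emm$bv_scar) * it / 100 +
               rnorm(n_points, 0, spec$emm$bv_noise))

  cf <- spec$motion$contraction * (1 - spec$motion$it_coupling * it / 100)
  pos_es <- cbind(pos[, 1] * (1 - cf), pos[, 2] * (1 - cf), pos[, 3])
  traj <- tibble::tibble(
    id = rep(seq_len(n_points), 2),
    phase = rep(c("ED", "ES"), each = n_points),
    x = c(pos[, 1], pos_es[, 1]),
    y = c(pos[, 2], pos_es[, 2]),
    z = c(pos[, 3], pos_es[, 3])
  )
  lls <- compute_lls(traj)$lls

  jitter <- matrix(rnorm(3 * n_points, 0, spec$emm$contact_noise_mm), ncol = 3)
  meas <- pos + jitter
  emm <- tibble::tibble(
    id = seq_len(n_points),
    x = meas[, 1], y = meas[, 2], z = meas[, 3],
    uv = uv, bv = bv, lls = lls, included = TRUE, it_true = it
  )
  list(emm = emm, traj = traj)
}

#' Apply a known rigid mis-registration to an EMM dataset
#'
#' Maps all point positions (and trajectory positions, if given) by the
#' transform and stores it in the `true_transform` attribute for recovery
#' scoring.
#'
#' @param emm EMM tibble.
#' @param transform a `rigid_transform`.
#' @param traj optional trajectory tibble, transformed alongside.
#' @return The transformed EMM tibble (with `traj` attached as the `traj`
#'   attribute when supplied).
#' @export
perturb_rigid <- function(emm, transform, traj = NULL) {
  out <- transform_points(transform, emm)
  attr(out, "true_transform") <- transform
  if (!is.null(traj)) {
    attr(out, "traj") <- transform_points(transform, traj)
  }
  out
}
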