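#' Apex-based rigid initialization of an EMM point cloud onto a mesh
#'
#' Estimates the mapping catheter cloud's long axis and apex, then returns the
#' rigid transform (pivot at the mesh apex) that maps the EMM apex onto the
#' mesh apex and rotates the EMM long axis onto the mesh long axis (apex to
#' basal-ring centroid) by the minimal rotation — residual roll about the long
#' axis is left at zero and is the job of the subsequent constrained ICP.
#'
#' The long axis of the cloud is estimated geometrically rather than by plain
#' PCA (a truncated-LV shell is roughly as wide as it is long, and catheter
#' maps oversample the infarct, which biases moment-based axes): the basal
#' opening is located as the largest empty spherical cap in the directions
#' from the cloud centroid to the points, and the axis is then refined by
#' fitting circle centers to projection slabs and passing a line through them
#' (a density-robust estimate of the chamber center line). The apex end is
#' the end opposite the opening; the EMM apex is the point extremal along it.
#'
#' @param emm EMM tibble (`x,y,z` mm, plus `id`).
#' @param mesh a `surface_mesh` with an apex vertex and basal plane.
#' @param emm_apex `"auto"` or the `id` of the point to treat as the apex.
#' @return A `rigid_transform`.
#' @export
apex_align <- function(emm, mesh, emm_apex = "auto") {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(emm) < 10) {
    abort("need at least 10 EMM points for a stable axis estimate",
          class = "emmfuse_validation_error")
  }
  pts <- as_point_matrix(emm)
  ax <- estimate_long_axis(pts)
  apex_dir <- -ax$axis  # axis points apex -> base

  if (identical(emm_apex, "auto")) {
    proj <- drop(sweep(pts, 2, ax$center) %*% apex_dir)
    # among points near the apical extreme, take the one closest to the axis
    # line (robust to small axis-estimate tilt at a near-flat apex)
    near <- which(proj >= max(proj) - 3)
    off <- sweep(pts[near, , drop = FALSE], 2, ax$center)
    radial2 <- rowSums(off^2) - (off %*% apex_dir)^2
    apex_idx <- near[which.min(radial2)]
  } else {
    apex_idx <- match(emm_apex, emm$id)
    if (is.na(apex_idx)) {
      abort(sprintf("emm_apex id %s not found", emm_apex), class = "emmfuse_error")
    }
  }
  emm_apex_pos <- pts[apex_idx, ]
  emm_long <- ax$axis  # apex -> base direction of the cloud

  mesh_apex <- mesh$vertices[mesh$apex_vertex, ]
  mesh_long <- mesh$basal_plane$point - mesh_apex
  mesh_long <- mesh_long / sqrt(sum(mesh_long^2))

  R <- minimal_rotation(emm_long, mesh_long)
  # p' = R (p - pivot) + pivot + t with pivot = mesh apex; choose t so the
  # EMM apex lands exactly on the mesh apex
  t <- mesh_apex - drop(R %*% (emm_apex_pos - mesh_apex)) - mesh_apex
  rigid_transform_from_matrix(R, t, mesh_apex)
}

# geometric long-axis estimate of a cup-shaped point shell.
# Returns axis (unit, apex -> base) and a center point on the axis.
estimate_long_axis <- function(pts, n_slabs = 5, reps = 6, damp = 0.5) {
  ctr <- colMeans(pts)
  u <- sweep(pts, 2, ctr)
  u <- u / sqrt(rowSums(u^2))
  # basal opening = largest empty spherical cap of point directions
  n <- 400
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  g <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  nearest <- apply(g %*% t(u), 1, max)
  axis <- g[which.min(nearest), ]  # apex -> base (toward the opening)
  # refine: circle-fit the slab rings, pass a line through their centers
  for (rep in seq_len(reps)) {
    proj <- drop(sweep(pts, 2, ctr) %*% axis)
    qs <- stats::quantile(proj, seq(0, 1, length.out = n_slabs + 1))
    centers <- NULL
    for (s in seq_len(n_slabs)) {
      sel <- proj >= qs[s] & proj <= qs[s + 1]
      if (sum(sel) < 6) next
      b1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      b1 <- b1 - sum(b1 * axis) * axis
      b1 <- b1 / sqrt(sum(b1^2))
      b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
              axis[3] * b1[1] - axis[1] * b1[3],
              axis[1] * b1[2] - axis[2] * b1[1])
      P <- sweep(pts[sel, , drop = FALSE], 2, ctr) %*% cbind(b1, b2)
      # algebraic (Coope) circle fit, density-robust for partial rings
      A <- cbind(2 * P, 1)
      sol <- tryCatch(qr.solve(A, rowSums(P^2)), error = function(e) NULL)
      if (is.null(sol)) next
      centers <- rbind(centers,
                       ctr + sol[1] * b1 + sol[2] * b2 + mean(proj[sel]) * axis)
    }
    if (is.null(centers) || nrow(centers) < 3) break
    cc <- colMeans(centers)
    ax2 <- svd(sweep(centers, 2, cc))$v[, 1]
    if (sum(ax2 * axis) < 0) ax2 <- -ax2
    axis <- (1 - damp) * axis + damp * ax2
    axis <- axis / sqrt(sum(axis^2))
    ctr <- cc
  }
  list(axis = axis, center = ctr)
}

# minimal rotation (no roll) taking unit vector u onto unit vector v
minimal_rotation <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate 180 deg about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u
    w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Rotation-constrained iterative closest point registration
#'
#' Alternates (a) matching each included EMM point to its closest foot point
#' on the mesh surface and (b) solving the least-squares rigid update by SVD
#' (Kabsch) about the mesh apex pivot, then clamping the *cumulative* Euler
#' rotation since the ICP start to the componentwise limits — by default 10,
#' 20 and 20 degrees about the sagittal, coronal and transverse axes, the
#' bounds used to prevent excess rotation when the two acquisitions disagree.
#' Translation is unconstrained. Iteration stops when the mean closest
#' distance improves by less than `tol_mm` or after `max_iter` iterations;
#' the accepted-iteration error trace is non-increasing.
#'
#' @param emm EMM tibble, already frame-swapped and apex-aligned; only rows
#'   with `included == TRUE` participate.
#' @param mesh a `surface_mesh`.
#' @param limits_deg cumulative Euler-angle bounds (sagittal, coronal,
#'   transverse) in degrees.
#' @param tol_mm convergence tolerance on the mean distance (mm).
#' @param max_iter maximum iterations.
#' @return A list with `transform` (the cumulative `rigid_transform`, pivot at
#'   the mesh apex), `trace` (tibble of `iteration`, `mean_mm`, `sd_mm`), and
#'   `error` (the final [registration_error()] stats).
#' @export
constrained_icp <- function(emm, mesh, limits_deg = c(10, 20, 20),
                            tol_mm = 0.01, max_iter = 100) {
  stopifnot(inherits(mesh, "surface_mesh"))
  inc <- if ("included" %in% names(emm)) emm$included else rep(TRUE, nrow(emm))
  p0 <- as_point_matrix(emm)[inc, , drop = FALSE]
  if (nrow(p0) == 0) {
    abort("no included points for ICP", class = "emmfuse_validation_error")
  }
  pivot <- mesh$vertices[mesh$apex_vertex, ]
  limits_deg <- abs(as.numeric(limits_deg))
  cur <- rigid_transform(pivot = pivot)

  d0 <- closest_surface_distance(p0, mesh)$distance
  trace <- list(c(0, mean(d0), stats::sd(d0)))
  best_rms <- sqrt(mean(d0^2))
  last_traced_mean <- mean(d0)

  long_axis <- if (!is.null(mesh$basal_plane)) mesh$basal_plane$normal else c(0, 0, 1)

  # clamp a candidate's TOTAL Euler rotation (since the ICP start) to the
  # limits, re-solving the optimal translation for the clamped rotation, and
  # evaluate its distances
  finish_cand <- function(cand, q, iter) {
    eul <- matrix_to_euler(cand$rotation)
    eul_c <- pmin(pmax(eul, -limits_deg), limits_deg)
    if (!all(eul_c == eul)) {
      Rc <- euler_to_matrix(eul_c)
      p_bar <- colMeans(p0); q_bar <- colMeans(q)
      tc <- q_bar - drop(Rc %*% (p_bar - pivot)) - pivot
      cand <- rigid_transform_from_matrix(Rc, tc, pivot)
      cand$euler_deg <- eul_c  # exact clamped angles, not re-derived
    }
    if (!all(is.finite(cand$translation)) || !all(is.finite(cand$rotation))) {
      abort(sprintf("non-finite ICP update at iteration %d", iter),
            class = "emmfuse_error")
    }
    dnew <- closest_surface_distance(transform_points(cand, p0), mesh)$distance
    list(transform = cand, rms = sqrt(mean(dnew^2)),
         mean = mean(dnew), sd = stats::sd(dnew))
  }

  for (iter in seq_len(max_iter)) {
    x <- transform_points(cur, p0)
    cs <- closest_surface_distance(x, mesh)
    q <- cbind(cs$foot_x, cs$foot_y, cs$foot_z)
    # monotone ICP step: incremental rigid fit of the CURRENT positions onto
    # their foot points, with step extrapolation (tangential sliding along
    # the surface converges slowly otherwise); the scaled step with the
    # lowest RMS distance is taken, plain step (scale 1) included
    fit <- kabsch_about_pivot(x, q, pivot)
    best_cand <- NULL
    for (lambda in c(8, 4, 2, 1)) {
      step_tf <- scale_rigid_step(fit$R, fit$t, lambda, pivot)
      cand <- finish_cand(compose_transforms(step_tf, cur), q, iter)
      if (is.null(best_cand) || cand$rms < best_cand$rms) best_cand <- cand
    }
    if (best_cand$rms >= best_rms - tol_mm) {
      # stalled: probe rotations about the long axis (where point-to-foot
      # steps carry almost no torque) before giving up
      for (roll in c(-10, -7.5, -5, -2.5, 2.5, 5, 7.5, 10)) {
        Rr <- rotation_about_axis(long_axis, roll * pi / 180)
        roll_tf <- rigid_transform_from_matrix(Rr, c(0, 0, 0), pivot)
        cand <- finish_cand(compose_transforms(roll_tf, cur), q, iter)
        if (cand$rms < best_cand$rms) best_cand <- cand
      }
    }
    # the SVD step minimizes the sum of squared residuals, so acceptance and
    # convergence are judged on the RMS distance; the reported trace keeps
    # the (monotone) mean
    if (best_cand$rms < best_rms - 1e-15) {
      cur <- best_cand$transform
      improvement <- best_rms - best_cand$rms
      best_rms <- best_cand$rms
      if (best_cand$mean <= last_traced_mean) {
        trace[[length(trace) + 1]] <- c(iter, best_cand$mean, best_cand$sd)
        last_traced_mean <- best_cand$mean
      }
      if (improvement < tol_mm) break
    } else {
      break
    }
  }
  tr <- do.call(rbind, trace)
  trace_tbl <- tibble::tibble(iteration = tr[, 1], mean_mm = tr[, 2], sd_mm = tr[, 3])
  emm_out <- emm
  emm_out[c("x", "y", "z")] <- as.data.frame(transform_points(cur, as_point_matrix(emm)))
  err <- registration_error(emm_out, mesh)
  list(transform = cur, trace = trace_tbl, error = err)
}

# Rodrigues rotation about a unit axis
rotation_about_axis <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * K %*% K
}

# scale a rigid step (R, t about pivot) by lambda: rotation angle scaled via
# axis-angle, translation scaled linearly
scale_rigid_step <- function(R, t, lambda, pivot) {
  if (lambda == 1) return(rigid_transform_from_matrix(R, t, pivot))
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-12) {
    return(rigid_transform_from_matrix(diag(3), lambda * t, pivot))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  a2 <- lambda * ang
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R2 <- diag(3) + sin(a2) * K + (1 - cos(a2)) * K %*% K
  rigid_transform_from_matrix(R2, lambda * t, pivot)
}

# least-squares rigid fit q ~= R (p - pivot) + pivot + t
kabsch_about_pivot <- function(p, q, pivot) {
  P <- sweep(p, 2, pivot)
  Q <- sweep(q, 2, pivot)
  p_bar <- colMeans(p); q_bar <- colMeans(q)
  H <- crossprod(sweep(P, 2, colMeans(P)), sweep(Q, 2, colMeans(Q)))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- q_bar - drop(R %*% (p_bar - pivot)) - pivot
  list(R = R, t = t, p_bar = p_bar, q_bar = q_bar)
}

#' Bounded manual refinement of a registration
#'
#' Composes a six-degree-of-freedom adjustment (three rotations in degrees,
#' three translations in mm) onto an existing transform. Each rotation
#' component is bounded (default 5 degrees) — adjustments beyond the bound
#' are refused with an error naming the axis, mirroring the rule that manual
#' optimization must not introduce large rotations.
#'
#' @param transform the current `rigid_transform`.
#' @param delta numeric length 6: (sagittal, coronal, transverse) degrees then
#'   (x, y, z) mm.
#' @param rot_bound_deg per-axis rotation bound in degrees; `Inf` disables it.
#' @return The composed `rigid_transform`.
#' @export
manual_adjust <- function(transform, delta, rot_bound_deg = 5) {
  stopifnot(inherits(transform, "rigid_transform"), length(delta) == 6)
  axes <- c("sagittal", "coronal", "transverse")
  over <- which(abs(delta[1:3]) > rot_bound_deg)
  if (length(over)) {
    abort(sprintf("%s rotation exceeds %g degrees", axes[over[1]], rot_bound_deg),
          class = "emmfuse_bound_error")
  }
  adj <- rigid_transform(delta[1:3], delta[4:6], pivot = transform$pivot)
  compose_transforms(adj, transform)
}

#' Registration error statistics
#'
#' Mean and sample standard deviation (n-1) of the closest distance between
#' the included EMM points and the mesh surface — the registration error
#' statistic of surface-based EMM/MRI fusion.
#'
#' @param emm EMM tibble (positions already registered); only rows with
#'   `included == TRUE` are counted.
#' @param mesh a `surface_mesh`.
#' @return An `error_stats` list: `mean_mm`, `sd_mm`, `per_point_mm`,
#'   `n_points`, `n_excluded`.
#' @export
registration_error <- function(emm, mesh) {
  inc <- if ("included" %in% names(emm)) emm$included else rep(TRUE, nrow(emm))
  if (!any(inc)) {
    abort("no included points", class = "emmfuse_validation_error")
  }
  d <- closest_surface_distance(as_point_matrix(emm)[inc, , drop = FALSE], mesh)$distance
  structure(
    list(mean_mm = mean(d), sd_mm = if (length(d) > 1) stats::sd(d) else 0,
         per_point_mm = d, n_points = sum(inc), n_excluded = sum(!inc)),
    class = "error_stats"
  )
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> %.2f +/- %.2f mm (n = %d, excluded = %d)\n",
              x$mean_mm, x$sd_mm, x$n_points, x$n_excluded))
  invisible(x)
}

#' Flag EMM points excluded from registration or analysis
#'
#' Registration mode excludes points lying outside the capped LV volume (e.g.
#' in the outflow tract) *and* farther than `contact_tol` mm from the surface;
#' points just off the wall from catheter contact noise are kept. Analysis
#' mode additionally excludes points whose closest vertex lies in the most
#' basal `exclude_basal_slices` slices — the valvular-plane region where low
#' voltage does not indicate infarct. The input is not modified; a copy with
#' updated `included` flags is returned.
#'
#' @param emm EMM tibble.
#' @param mesh a `surface_mesh` with `slice_of_vertex`.
#' @param mode `"registration"` or `"analysis"`.
#' @param contact_tol outward distance tolerance in mm (default 5).
#' @param exclude_basal_slices number of basal slices dropped in analysis
#'   mode (default 2).
#' @return The EMM tibble with `included` updated.
#' @export
filter_points <- function(emm, mesh, mode = c("registration", "analysis"),
                          contact_tol = 5, exclude_basal_slices = 2) {
  mode <- match.arg(mode)
  pts <- as_point_matrix(emm)
  inside <- is_inside_lv(pts, mesh)
  cs <- closest_surface_distance(pts, mesh)
  included <- inside | cs$distance <= contact_tol
  if (mode == "analysis" && exclude_basal_slices > 0) {
    vert_slice <- mesh$slice_of_vertex
    if (is.null(vert_slice)) {
      abort("mesh lacks slice_of_vertex; cannot exclude basal slices",
            class = "emmfuse_validation_error")
    }
    nn <- nearest_vertex(pts, mesh)
    included <- included & vert_slice[nn] > exclude_basal_slices
  }
  out <- emm
  out$included <- (if ("included" %in% names(emm)) emm$included else TRUE) & included
  out
}

# index of the nearest mesh vertex per point
nearest_vertex <- function(points, mesh) {
  V <- mesh$vertices
  vapply(seq_len(nrow(points)), function(i) {
    which.min((V[, 1] - points[i, 1])^2 + (V[, 2] - points[i, 2])^2 +
              (V[, 3] - points[i, 3])^2)
  }, integer(1))
}

#' Full registration chain: frame swap, apex alignment, constrained ICP
#'
#' Runs the complete rigid chain: the constant frame-swap rotation between the
#' mapping and MRI coordinate systems, apex-based rigid initialization, point
#' filtering, and rotation-constrained ICP. Returns the composed net transform
#' along with the stage transforms and error statistics.
#'
#' @param emm EMM tibble in the mapping frame.
#' @param mesh target `surface_mesh`.
#' @param convention axis convention name for [standard_axes_transform()].
#' @param limits_deg,tol_mm,max_iter passed to [constrained_icp()].
#' @param contact_tol passed to [filter_points()].
#' @return A list: `emm` (registered, with `included` flags), `transform`
#'   (net `rigid_transform`, pivot at the mesh apex), `stages` (list of the
#'   three stage transforms), `error` (`error_stats`), `trace` (ICP trace).
#' @export
register_emm <- function(emm, mesh, convention = "identity",
                         limits_deg = c(10, 20, 20), tol_mm = 0.01,
                         max_iter = 100, contact_tol = 5) {
  t_std <- standard_axes_transform(convention)
  emm1 <- emm
  emm1[c("x", "y", "z")] <- as.data.frame(transform_points(t_std, as_point_matrix(emm)))
  t_apex <- apex_align(emm1, mesh)
  emm2 <- emm1
  emm2[c("x", "y", "z")] <- as.data.frame(transform_points(t_apex, as_point_matrix(emm1)))
  emm2 <- filter_points(emm2, mesh, mode = "registration", contact_tol = contact_tol)
  icp <- constrained_icp(emm2, mesh, limits_deg = limits_deg,
                         tol_mm = tol_mm, max_iter = max_iter)
  emm3 <- emm2
  emm3[c("x", "y", "z")] <- as.data.frame(transform_points(icp$transform, as_point_matrix(emm2)))
  err <- registration_error(emm3, mesh)
  net <- compose_transforms(icp$transform, t_apex, t_std)
  net <- repivot_transform(net, mesh$vertices[mesh$apex_vertex, ])
  list(emm = emm3, transform = net,
       stages = list(standard_axes = t_std, apex = t_apex, icp = icp$transform),
       error = err, trace = icp$trace)
}
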