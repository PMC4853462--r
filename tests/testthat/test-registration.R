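# shared phantom fixture for registration tests (elliptical cross-section so
# rotation about the long axis is geometrically identifiable)
reg_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(
        phantom_spec(endo_axes = c(25, 18, 60),
                     emm = list(contact_noise_mm = 0.5), seed = 42))
    }
    cache
  }
})

surface_emm <- function(mesh, n = 200, seed = 1, noise = 0) {
  set.seed(seed)
  areas_ <- emmfuse:::triangle_areas(mesh)
  tri <- sample.int(length(areas_), n, replace = TRUE, prob = areas_)
  u1 <- runif(n); u2 <- runif(n)
  flip <- u1 + u2 > 1
  u1[flip] <- 1 - u1[flip]; u2[flip] <- 1 - u2[flip]
  A <- mesh$vertices[mesh$triangles[tri, 1], ]
  B <- mesh$vertices[mesh$triangles[tri, 2], ]
  C <- mesh$vertices[mesh$triangles[tri, 3], ]
  pos <- A + u1 * (B - A) + u2 * (C - A) + matrix(rnorm(3 * n, 0, noise), ncol = 3)
  tibble::tibble(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 uv = 10, bv = 2, lls = 5, included = TRUE)
}

test_that("apex alignment recovers a pure translation", {
  mesh <- reg_phantom()$mesh
  emm <- tibble::tibble(id = seq_len(nrow(mesh$vertices)),
                        x = mesh$vertices[, 1] + 10,
                        y = mesh$vertices[, 2] - 5,
                        z = mesh$vertices[, 3] + 3)
  tf <- apex_align(emm, mesh)
  # the estimated transform puts the EMM apex exactly on the mesh apex
  apex_after <- transform_points(tf, as.matrix(emm[mesh$apex_vertex, c("x", "y", "z")]))
  expect_lt(sqrt(sum((apex_after - mesh$vertices[mesh$apex_vertex, ])^2)), 1e-6)
  # rotation is (near) zero and the translation is the planted inverse
  expect_lt(max(abs(tf$euler_deg)), 0.5)
  expect_equal(tf$translation, c(-10, 5, -3), tolerance = 0.25)
})

test_that("apex alignment recovers a planted coronal rotation about the apex", {
  mesh <- reg_phantom()$mesh
  piv <- mesh$vertices[mesh$apex_vertex, ]
  tf_true <- rigid_transform(c(0, 15, 0), c(0, 0, 0), pivot = piv)
  emm <- tibble::tibble(id = seq_len(nrow(mesh$vertices)))
  emm[c("x", "y", "z")] <- as.data.frame(transform_points(tf_true, mesh$vertices))
  tf <- apex_align(emm, mesh)
  expect_equal(tf$euler_deg[2], -15, tolerance = 0.5)
  expect_error(apex_align(emm[1:5, ], mesh), class = "emmfuse_validation_error")
})

test_that("constrained ICP recovers a noise-free planted perturbation", {
  mesh <- reg_phantom()$mesh
  piv <- mesh$vertices[mesh$apex_vertex, ]
  emm <- surface_emm(mesh, n = 200, seed = 11)
  tf_true <- rigid_transform(c(5, -8, 4), c(2, 2, 2), pivot = piv)
  emm_p <- perturb_rigid(emm, tf_true)
  res <- constrained_icp(emm_p, mesh, tol_mm = 1e-5, max_iter = 300)
  D <- compose_transforms(res$transform, tf_true)
  expect_lt(max(abs(matrix_to_euler(D$rotation))), 1)
  expect_lt(max(abs(D$translation)), 0.5)
  expect_lt(res$error$mean_mm, 0.1)
})

test_that("ICP on already-registered points returns the identity immediately", {
  mesh <- reg_phantom()$mesh
  emm <- surface_emm(mesh, n = 150, seed = 12)
  res <- constrained_icp(emm, mesh)
  expect_lt(max(abs(res$transform$euler_deg)), 1e-6)
  expect_lt(max(abs(res$transform$translation)), 1e-6)
  expect_equal(nrow(res$trace), 1)  # no iteration accepted past the check
})

test_that("a 30-degree sagittal perturbation is clamped to exactly 10 degrees", {
  mesh <- reg_phantom()$mesh
  piv <- mesh$vertices[mesh$apex_vertex, ]
  emm <- surface_emm(mesh, n = 200, seed = 13)
  emm_p <- perturb_rigid(emm, rigid_transform(c(30, 0, 0), c(0, 0, 0), pivot = piv))
  res <- constrained_icp(emm_p, mesh, tol_mm = 1e-4, max_iter = 200)
  expect_identical(abs(res$transform$euler_deg[1]), 10)
})

test_that("accepted ICP iterations have a non-increasing mean error trace", {
  ph <- reg_phantom()
  samp <- sample_emm(ph)
  piv <- ph$mesh$vertices[ph$mesh$apex_vertex, ]
  emm_p <- perturb_rigid(samp$emm, rigid_transform(c(4, -6, 8), c(3, -2, 5), pivot = piv))
  reg <- register_emm(emm_p, ph$mesh, tol_mm = 1e-4, max_iter = 300)
  expect_true(all(diff(reg$trace$mean_mm) <= 0))
})

test_that("registration error statistics match hand arithmetic and oracles", {
  mesh <- reg_phantom()$mesh
  tri <- mesh$triangles[500, ]
  A <- mesh$vertices[tri[1], ]; B <- mesh$vertices[tri[2], ]; C <- mesh$vertices[tri[3], ]
  n <- c((B - A)[2] * (C - A)[3] - (B - A)[3] * (C - A)[2],
         (B - A)[3] * (C - A)[1] - (B - A)[1] * (C - A)[3],
         (B - A)[1] * (C - A)[2] - (B - A)[2] * (C - A)[1])
  n <- n / sqrt(sum(n^2))
  ctr <- (A + B + C) / 3
  emm <- tibble::tibble(id = 1:2,
                        x = c(ctr[1] + n[1], ctr[1] + 3 * n[1]),
                        y = c(ctr[2] + n[2], ctr[2] + 3 * n[2]),
                        z = c(ctr[3] + n[3], ctr[3] + 3 * n[3]),
                        uv = 0, bv = 0, lls = 0, included = TRUE)
  err <- registration_error(emm, mesh)
  expect_equal(err$mean_mm, 2, tolerance = 1e-9)
  expect_equal(err$sd_mm, sqrt(2), tolerance = 1e-9)

  # surface points give zero error
  emm0 <- surface_emm(mesh, n = 50, seed = 14)
  err0 <- registration_error(emm0, mesh)
  expect_lt(err0$mean_mm, 1e-9)
  expect_equal(err0$sd_mm, 0, tolerance = 1e-9)

  # brute-force oracle agreement on random points
  set.seed(15)
  pts <- cbind(runif(100, -30, 30), runif(100, -20, 20), runif(100, -60, 5))
  emm1 <- tibble::tibble(id = seq_len(100), x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         uv = 0, bv = 0, lls = 0, included = TRUE)
  err1 <- registration_error(emm1, mesh)
  slow <- vapply(seq_len(100), function(i) {
    oracle_point_tri_dist(pts[i, ], mesh$vertices, mesh$triangles)
  }, numeric(1))
  expect_lt(max(abs(err1$per_point_mm - slow)), 1e-9)
})

test_that("error statistics are invariant to point order and joint rigid motion", {
  mesh <- reg_phantom()$mesh
  emm <- surface_emm(mesh, n = 80, seed = 16, noise = 1)
  err <- registration_error(emm, mesh)
  err_perm <- registration_error(emm[sample(nrow(emm)), ], mesh)
  expect_equal(err$mean_mm, err_perm$mean_mm, tolerance = 1e-12)
  expect_equal(err$sd_mm, err_perm$sd_mm, tolerance = 1e-12)

  tf <- random_rigid(pivot = c(0, 5, -20))
  mesh2 <- mesh
  mesh2$vertices <- transform_points(tf, mesh$vertices)
  emm2 <- transform_points(tf, emm)
  err2 <- registration_error(emm2, mesh2)
  expect_equal(err2$mean_mm, err$mean_mm, tolerance = 1e-9)
})

test_that("filtering excludes outflow-tract points but keeps contact points", {
  mesh <- reg_phantom()$mesh
  emm <- surface_emm(mesh, n = 60, seed = 17)
  # plant 10 points above the basal plane on the long axis (outflow tract)
  lvot <- tibble::tibble(id = 1000 + 1:10,
                         x = runif(10, -5, 5), y = runif(10, -5, 5),
                         z = 10 + runif(10, 0, 15),
                         uv = 10, bv = 2, lls = 5, included = TRUE)
  far <- tibble::tibble(id = 2000, x = 60, y = 0, z = -30,
                        uv = 10, bv = 2, lls = 5, included = TRUE)
  all_pts <- dplyr::bind_rows(emm, lvot, far)
  filt <- filter_points(all_pts, mesh, mode = "registration")
  expect_true(all(filt$included[filt$id <= 60]))       # surface points kept
  expect_false(any(filt$included[filt$id >= 1000]))    # LVOT + far excluded
  expect_identical(sum(!filt$included), 11L)
  # input untouched
  expect_true(all(all_pts$included))

  # analysis mode additionally drops points nearest to the 2 basal slices
  basal_pt <- mesh$vertices[which(mesh$slice_of_vertex == 1)[3], ]
  apex_pt <- mesh$vertices[which(mesh$slice_of_vertex == max(mesh$slice_of_vertex))[3], ]
  two <- tibble::tibble(id = 1:2,
                        x = c(basal_pt[1], apex_pt[1]),
                        y = c(basal_pt[2], apex_pt[2]),
                        z = c(basal_pt[3], apex_pt[3]),
                        uv = 0, bv = 0, lls = 0, included = TRUE)
  fa <- filter_points(two, mesh, mode = "analysis", exclude_basal_slices = 2)
  expect_identical(fa$included, c(FALSE, TRUE))
})

test_that("excluded points never influence the ICP update", {
  mesh <- reg_phantom()$mesh
  piv <- mesh$vertices[mesh$apex_vertex, ]
  emm <- surface_emm(mesh, n = 120, seed = 18)
  tf_true <- rigid_transform(c(3, -4, 6), c(1, -2, 1), pivot = piv)
  emm_p <- perturb_rigid(emm, tf_true)
  outliers <- tibble::tibble(id = 9000 + 1:5,
                             x = runif(5, 100, 200), y = runif(5, 100, 200),
                             z = runif(5, 50, 100),
                             uv = 0, bv = 0, lls = 0, included = FALSE)
  res_clean <- constrained_icp(emm_p, mesh, tol_mm = 1e-4)
  res_out <- constrained_icp(dplyr::bind_rows(emm_p, outliers), mesh, tol_mm = 1e-4)
  expect_lt(max(abs(res_clean$transform$rotation - res_out$transform$rotation)), 1e-9)
  expect_lt(max(abs(res_clean$transform$translation - res_out$transform$translation)), 1e-9)
})

test_that("the full chain recovers random perturbations end to end", {
  # condensed Monte-Carlo (5 seeds here; the acceptance suite runs 20)
  worst_rot <- 0; worst_trans <- 0
  for (seed in 1:5) {
    set.seed(seed + 300)
    ang <- runif(3, -1, 1) * c(8, 15, 15)
    tr <- runif(3, -10, 10)
    spec <- phantom_spec(endo_axes = c(25, 18, 60),
                         emm = list(contact_noise_mm = 0.5), seed = seed)
    ph <- generate_phantom(spec)
    samp <- sample_emm(ph)
    piv <- ph$mesh$vertices[ph$mesh$apex_vertex, ]
    tf_true <- rigid_transform(ang, tr, pivot = piv)
    emm_p <- perturb_rigid(samp$emm, tf_true)
    reg <- register_emm(emm_p, ph$mesh, tol_mm = 1e-4, max_iter = 500)
    D <- compose_transforms(reg$transform, tf_true)
    worst_rot <- max(worst_rot, max(abs(matrix_to_euler(D$rotation))))
    worst_trans <- max(worst_trans, max(abs(D$translation)))
  }
  expect_lt(worst_rot, 2)
  expect_lt(worst_trans, 1)
})
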