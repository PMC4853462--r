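test_that("transmurality is zero without scar and 100 for a full-thickness scar", {
  st <- cylinder_stack(r = 20, wall = 10, n_slices = 3)
  it <- segment_transmurality(st, 1)
  expect_length(it, 80)
  expect_true(all(it == 0))

  # scar polygon equal to the epicardial contour: the entire wall is scar
  full <- st
  full$slices[[1]]$scar <- list(full$slices[[1]]$epi_ed)
  it_full <- segment_transmurality(full, 1)
  expect_true(all(it_full == 100))
})

test_that("the analytic wedge phantom reads its planted area fraction", {
  st <- wedge_stack(r_in = 20, r_out = 30, frac = 0.6, th1 = pi / 4, th2 = 3 * pi / 4)
  it <- segment_transmurality(st, 1)
  seg_lo <- ceiling(45 / 4.5) + 1   # first segment fully inside the arc (1-based)
  seg_hi <- floor(135 / 4.5)        # last segment fully inside
  inside <- seg_lo:seg_hi
  outside <- setdiff(1:80, (floor(45 / 4.5) + 1):(ceiling(135 / 4.5)))
  expect_true(all(abs(it[inside] - 60) <= 2))
  expect_true(all(it[outside] == 0))
})

test_that("scar pixel areas are conserved across segments", {
  st <- wedge_stack()
  det <- segment_transmurality(st, 1, detail = TRUE)
  # independent total: rasterize once more over the union masks
  s <- st$slices[[1]]
  px <- st$pixel_spacing
  gx <- seq(min(s$epi_ed[, 1]) + px / 2, max(s$epi_ed[, 1]), by = px)
  gy <- seq(min(s$epi_ed[, 2]) + px / 2, max(s$epi_ed[, 2]), by = px)
  gr <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  in_epi <- emmfuse:::cpp_points_in_polygon(gr[, 1], gr[, 2], s$epi_ed[, 1], s$epi_ed[, 2])
  in_endo <- emmfuse:::cpp_points_in_polygon(gr[, 1], gr[, 2], s$endo_ed[, 1], s$endo_ed[, 2])
  in_scar <- emmfuse:::cpp_points_in_polygon(gr[, 1], gr[, 2],
                                             s$scar[[1]][, 1], s$scar[[1]][, 2])
  expect_identical(sum(det$myo_pixels), sum(in_epi & !in_endo))
  expect_identical(sum(det$scar_pixels), sum(in_scar & in_epi & !in_endo))
  # pixel myocardial area matches the analytic annulus to < 0.5 %
  analytic <- pi * (30^2 - 20^2)
  expect_lt(abs(sum(det$myo_pixels) * px^2 - analytic) / analytic, 0.005)
})

test_that("transmurality is equivariant under rotation by one segment", {
  st <- wedge_stack(n_vert = 256)
  it0 <- segment_transmurality(st, 1)
  rot <- 2 * pi / 80
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  st_rot <- st
  for (nm in c("endo_ed", "epi_ed")) {
    st_rot$slices[[1]][[nm]] <- st$slices[[1]][[nm]] %*% t(R)
  }
  st_rot$slices[[1]]$scar <- lapply(st$slices[[1]]$scar, function(p) p %*% t(R))
  it1 <- segment_transmurality(st_rot, 1)
  shifted <- c(it0[80], it0[1:79])
  expect_lt(max(abs(it1 - shifted), na.rm = TRUE), 2)
})

test_that("halving the pixel spacing moves wedge transmurality by < 1 %", {
  it_coarse <- segment_transmurality(wedge_stack(pixel_spacing = 0.25), 1)
  it_fine <- segment_transmurality(wedge_stack(pixel_spacing = 0.125), 1)
  inside <- 12:29
  expect_lt(max(abs(it_coarse[inside] - it_fine[inside])), 1)
})

test_that("scar outside the myocardium warns and contributes nothing", {
  st <- cylinder_stack(r = 20, wall = 10, n_slices = 3)
  st$slices[[1]]$scar <- list(ring_poly(3, cx = 0, cy = 0))  # inside the cavity
  expect_warning(it <- segment_transmurality(st, 1), "outside the myocardium")
  expect_true(all(it == 0))
})

test_that("IT classification matches the published partition boundaries", {
  expect_equal(as.character(classify_it(c(0, 25, 25.0001, 50, 75, 100))),
               c("0%", "0-25%", "25-50%", "25-50%", "50-75%", "75-100%"))
  expect_equal(as.character(classify_it(50.0001)), "50-75%")
  expect_equal(as.character(classify_it(75.0001)), "75-100%")
  expect_error(classify_it(-1), class = "emmfuse_validation_error")
  expect_error(classify_it(100.5), class = "emmfuse_validation_error")

  # partition property: every value maps to exactly one class
  grid <- seq(0, 100, by = 0.05)
  cls <- classify_it(grid)
  expect_false(anyNA(cls))
  expect_identical(levels(cls), c("0%", "0-25%", "25-50%", "50-75%", "75-100%"))
})

test_that("wall thickening is zero without motion and exact for uniform growth", {
  st0 <- cylinder_stack(r = 20, wall = 10, n_slices = 3, es_scale = 1)
  expect_true(all(abs(wall_thickening(st0, 1)) < 1e-9))

  # ED wall 10 mm; ES endo contracts to r=18 with epi fixed -> wall 12, WT 2
  st <- cylinder_stack(r = 20, wall = 10, n_slices = 3)
  st$slices[[1]]$endo_es <- ring_poly(17, 80)
  st$slices[[1]]$epi_es <- ring_poly(30, 80)
  wt <- wall_thickening(st, 1)
  expect_true(all(abs(wt - 3) < 0.01))
})

test_that("wall thickening recovers a planted linear coupling to transmurality", {
  set.seed(13)
  n_vert <- 128
  th <- 2 * pi * (0:(n_vert - 1)) / n_vert
  it_profile <- function(t) 90 * exp(-((t - pi) / 0.8)^2)  # smooth IT field
  slices <- lapply(c(0, -8, -16), function(z) {
    wall_es <- 10 + 6 * (1 - it_profile(th) / 100)  # WT = 6 * (1 - IT/100)
    list(z = z,
         endo_ed = ring_poly(20, n_vert),
         epi_ed = ring_poly(30, n_vert),
         endo_es = ring_poly(20, n_vert),
         epi_es = cbind((20 + wall_es) * cos(th), (20 + wall_es) * sin(th)),
         scar = list())
  })
  st <- contour_stack(slices, pixel_spacing = 0.25)
  wt <- wall_thickening(st, 1)
  seg_centers <- (seq_len(80) - 0.5) * 2 * pi / 80
  x <- 1 - it_profile(seg_centers) / 100
  fit <- lm(wt ~ x)
  expect_equal(unname(coef(fit)[2]), 6, tolerance = 0.5)
})

test_that("border zone masks form a closed ring around the transmural core", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  mesh <- ph$mesh
  theta <- atan2(mesh$vertices[, 2], mesh$vertices[, 1]) %% (2 * pi)
  mesh$channels$it <- ph$it_fun(theta, mesh$vertices[, 3])

  mask <- border_zone(mesh, lo = 0, hi = 75)
  expect_true(any(mask))
  # single connected component (independent BFS over the mask subgraph)
  adj <- emmfuse:::vertex_adjacency(mesh)
  seen <- rep(FALSE, length(mask))
  start <- which(mask)[1]
  queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]; nb <- nb[mask[nb] & !seen[nb]]
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  expect_identical(sum(seen), sum(mask))
  # the mask is non-transmural territory only
  expect_true(all(mesh$channels$it[mask] > 0 & mesh$channels$it[mask] <= 75))

  # degenerate fields give empty masks
  m0 <- mesh; m0$channels$it <- rep(0, nrow(mesh$vertices))
  expect_false(any(border_zone(m0)))
  m100 <- mesh; m100$channels$it <- rep(100, nrow(mesh$vertices))
  expect_false(any(border_zone(m100)))
  m_none <- mesh; m_none$channels$it <- NULL
  expect_error(border_zone(m_none), class = "emmfuse_validation_error")
})

test_that("segment areas tile the mesh surface exactly", {
  ph <- generate_phantom(phantom_spec(n_slices = 8, seed = 6))
  areas <- segment_areas(ph$mesh)
  expect_equal(dim(areas), c(8, 80))
  expect_equal(sum(areas) * 100, mesh_area(ph$mesh), tolerance = 1e-9)
})
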