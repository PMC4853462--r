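#' Run the full fusion pipeline on one dataset and report summary JSON
#'
#' Executes the complete analysis on a single animal/dataset: read contours
#' and EMM points, build the endocardial mesh, compute the IT bullseye from
#' the scar contours, project IT onto the mesh, register the EMM cloud
#' (frame swap, apex alignment, rotation-constrained ICP), filter points for
#' analysis, and summarize: point counts, registration error mean/SD, point
#' densities per IT class, and the best ROC operating points of UV, BV and
#' LLS against IT. The output is deterministic given the inputs and seed and
#' embeds a hash of the configuration for provenance.
#'
#' @param config named list (or path to a JSON file) with elements:
#'   `emm` (EMM CSV path), `contours` (contour JSON path), optional
#'   `trajectories` (trajectory CSV path, recomputes LLS), `out` (output JSON
#'   path), `seed` (default 1), `convention` (default `"identity"`),
#'   `limits_deg` (default `c(10, 20, 20)`), `tol_mm` (default 0.01),
#'   `basal_exclusion` (default 2), `points_per_ring` (default 80).
#' @return The report as a named list, invisibly if written to file.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("emm", "contours", "trajectories", "out", "seed", "convention",
             "limits_deg", "tol_mm", "basal_exclusion", "points_per_ring")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
          class = "emmfuse_format_error")
  }
  defaults <- list(seed = 1, convention = "identity", limits_deg = c(10, 20, 20),
                   tol_mm = 0.01, basal_exclusion = 2, points_per_ring = 80)
  config <- utils::modifyList(defaults, config)
  for (req in c("emm", "contours")) {
    if (is.null(config[[req]])) {
      abort(sprintf("config lacks required key '%s'", req),
            class = "emmfuse_format_error")
    }
  }
  set.seed(config$seed)

  emm <- read_emm_table(config$emm)
  stack <- read_contour_stack(config$contours)
  mesh <- build_endocardial_mesh(stack, points_per_ring = config$points_per_ring)
  it_grid <- transmurality_bullseye(stack)
  mesh <- project_it_bullseye(mesh, stack, it_grid)

  if (!is.null(config$trajectories)) {
    traj <- read_trajectories(config$trajectories)
    lls <- compute_lls(traj)
    emm$lls <- lls$lls[match(emm$id, lls$id)]
  }

  reg <- register_emm(emm, mesh, convention = config$convention,
                      limits_deg = config$limits_deg, tol_mm = config$tol_mm)
  analysis <- filter_points(reg$emm, mesh, mode = "analysis",
                            exclude_basal_slices = config$basal_exclusion)
  areas <- segment_areas(mesh)
  dens <- point_density(analysis, mesh, areas, it_grid)
  pairs <- pair_points_with_reference(analysis, mesh, "it")

  ranges <- emm_roc_ranges()
  roc_of <- function(col) {
    tryCatch({
      g <- roc_grid(tibble::tibble(pred = pairs[[col]], ref = pairs$ref),
                    pred_range = ranges[[col]], ref_range = ranges$it)
      as.list(g$best)
    }, error = function(e) NULL)
  }

  report <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out")]),
    n_points_total = nrow(emm),
    n_points_registration = reg$error$n_points,
    n_points_analysis = sum(analysis$included),
    registration_error_mean_mm = reg$error$mean_mm,
    registration_error_sd_mm = reg$error$sd_mm,
    transform = list(euler_deg = reg$transform$euler_deg,
                     translation_mm = reg$transform$translation,
                     pivot_mm = reg$transform$pivot),
    density_per_it_class = as.list(setNames(dens$density_pts_per_cm2,
                                            as.character(dens$it_class))),
    points_per_it_class = as.list(setNames(dens$n_points,
                                           as.character(dens$it_class))),
    area_per_it_class_cm2 = as.list(setNames(dens$area_cm2,
                                             as.character(dens$it_class))),
    roc_best = list(uv = roc_of("uv"), bv = roc_of("bv"), lls = roc_of("lls"))
  )
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = I(10),
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}

#' Project a per-slice/segment IT bullseye onto mesh vertices
#'
#' Builds 3D sample positions at the segment centers on each slice's
#' endocardial ring and projects the bullseye values onto the mesh with
#' [project_scalar_field()].
#'
#' @param mesh `surface_mesh` built from `stack`.
#' @param stack the source `contour_stack`.
#' @param it_grid `n_slices x n_segments` IT matrix.
#' @return mesh with an `it` channel.
#' @export
project_it_bullseye <- function(mesh, stack, it_grid) {
  nseg <- ncol(it_grid)
  samples <- list(); values <- numeric(0)
  for (i in seq_len(n_slices(stack))) {
    s <- stack$slices[[i]]
    ctr <- polygon_centroid(s$endo_ed)
    ang <- (seq_len(nseg) - 0.5) * 2 * pi / nseg
    r <- vapply(ang, function(a) ray_crossing(s$endo_ed, ctr, a), numeric(1))
    ok <- !is.na(r) & !is.na(it_grid[i, ])
    samples[[i]] <- cbind(ctr[1] + r[ok] * cos(ang[ok]),
                          ctr[2] + r[ok] * sin(ang[ok]),
                          s$z)
    values <- c(values, it_grid[i, ok])
  }
  project_scalar_field(mesh, do.call(rbind, samples), values, "it")
}

#' Polar bullseye plot of a slice-by-segment grid
#'
#' @param grid `n_slices x n_segments` matrix (slices base to apex).
#' @param name fill legend label.
#' @return a ggplot object (polar heatmap, base at the rim, apex at the
#'   center).
#' @export
plot_bullseye <- function(grid, name = "IT (%)") {
  L <- nrow(grid); S <- ncol(grid)
  df <- tidyr::expand_grid(slice = seq_len(L), segment = seq_len(S))
  df$value <- as.vector(t(grid))[(df$slice - 1) * S + df$segment]
  df$ring <- L - df$slice + 1  # apex innermost
  ggplot(df, aes(x = .data$segment, y = .data$ring, fill = .data$value)) +
    geom_tile() +
    coord_polar(theta = "x") +
    scale_fill_viridis_c(name = name, na.value = "grey90") +
    theme_void()
}
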