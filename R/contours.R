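#' Stacked short-axis LV contours
#'
#' A `contour_stack` holds ordered short-axis slices of the left ventricle,
#' base to apex, each with closed endocardial and epicardial polygons at end
#' diastole (and optionally end systole) plus zero or more scar polygons from
#' late-gadolinium-enhancement segmentation. Coordinates are millimetres in a
#' right-handed patient-like frame (x = left, y = posterior, z = toward head);
#' each slice carries its absolute z position.
#'
#' Polygons are stored "open" (first vertex not repeated); a trailing vertex
#' equal to the first is stripped on construction. Validation enforces: at
#' least 3 vertices per polygon, simple (non-self-intersecting) polygons,
#' strictly monotone slice z, and every end-diastolic endocardial vertex inside
#' the epicardial polygon of its slice.
#'
#' @param slices list of slices; each slice is a list with elements `z`
#'   (scalar mm), `endo_ed`, `epi_ed` (n x 2 matrices), optionally `endo_es`,
#'   `epi_es`, and `scar` (list of n x 2 matrices, possibly empty).
#' @param pixel_spacing rasterization pixel size in mm (used by the
#'   transmurality computations).
#' @return A validated `contour_stack`, slices ordered base (largest z) to
#'   apex.
#' @export
contour_stack <- function(slices, pixel_spacing = 0.25) {
  if (!is.list(slices) || length(slices) < 1) {
    abort("slices must be a non-empty list", class = "emmfuse_format_error")
  }
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0) {
    abort("pixel_spacing must be a positive number", class = "emmfuse_format_error")
  }
  slices <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    if (is.null(s$z) || !is.finite(s$z)) {
      abort(sprintf("slice %d: missing or non-finite z", i),
            class = "emmfuse_format_error")
    }
    for (nm in c("endo_ed", "epi_ed")) {
      if (is.null(s[[nm]])) {
        abort(sprintf("slice %d: missing polygon '%s'", i, nm),
              class = "emmfuse_format_error")
      }
    }
    for (nm in c("endo_ed", "epi_ed", "endo_es", "epi_es")) {
      if (!is.null(s[[nm]])) s[[nm]] <- canonicalize_polygon(s[[nm]], sprintf("slice %d %s", i, nm))
    }
    s$scar <- lapply(seq_along(s$scar %||% list()), function(j) {
      canonicalize_polygon(s$scar[[j]], sprintf("slice %d scar %d", i, j))
    })
    s
  })
  z <- vapply(slices, function(s) s$z, numeric(1))
  if (anyDuplicated(z)) {
    abort("slice z positions are not strictly monotone (duplicates present)",
          class = "emmfuse_format_error")
  }
  ord <- order(z, decreasing = TRUE)  # base (toward head) first
  slices <- slices[ord]
  # endo inside epi (end diastole), every vertex
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    inside <- cpp_points_in_polygon(s$endo_ed[, 1], s$endo_ed[, 2],
                                    s$epi_ed[, 1], s$epi_ed[, 2])
    if (!all(inside)) {
      abort(sprintf("slice %d: endocardial contour not inside epicardial contour", i),
            class = "emmfuse_validation_error")
    }
  }
  structure(list(slices = slices, pixel_spacing = as.numeric(pixel_spacing)),
            class = "contour_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# open representation + implicit closure; checks >=3 vertices and simplicity
canonicalize_polygon <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || !is.numeric(p) || !all(is.finite(p))) {
    abort(sprintf("%s: polygon must be a finite n x 2 matrix", what),
          class = "emmfuse_format_error")
  }
  n <- nrow(p)
  if (n >= 2 && all(p[n, ] == p[1, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3) {
    abort(sprintf("%s: polygon needs at least 3 distinct vertices", what),
          class = "emmfuse_format_error")
  }
  if (!is_simple_polygon(p)) {
    abort(sprintf("%s: polygon is self-intersecting", what),
          class = "emmfuse_validation_error")
  }
  unname(p)
}

# vectorized test that no two non-adjacent edges properly intersect
is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adjacent <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (length(i) == 0) return(TRUE)
  p1 <- a[i, , drop = FALSE]; p2 <- b[i, , drop = FALSE]
  p3 <- a[j, , drop = FALSE]; p4 <- b[j, , drop = FALSE]
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(u, v) u[, 1] * v[, 2] - u[, 2] * v[, 1]

#' @export
print.contour_stack <- function(x, ...) {
  z <- vapply(x$slices, function(s) s$z, numeric(1))
  n_scar <- sum(vapply(x$slices, function(s) length(s$scar), integer(1)))
  cat(sprintf("<contour_stack> %d slices, z %.1f .. %.1f mm (base -> apex), %d scar polygons, pixel %.3g mm\n",
              length(x$slices), z[1], z[length(z)], n_scar, x$pixel_spacing))
  invisible(x)
}

#' Number of slices in a contour stack
#' @param stack a `contour_stack`.
#' @return integer count.
#' @export
n_slices <- function(stack) length(stack$slices)

#' Read a contour stack from its JSON dialect
#'
#' Schema: `{"slices": [{"z": ..., "endo_ed": [[x,y],...], "epi_ed": [...],`
#' `"endo_es": [...], "epi_es": [...], "scar": [[[x,y],...],...]}, ...],`
#' `"pixel_spacing": ...}`. Polygons may repeat the first vertex as the last;
#' the reader canonicalizes to the open representation. All
#' `contour_stack` invariants are enforced; violations raise typed errors
#' rather than silently coercing.
#'
#' @param path file path.
#' @return A `contour_stack`.
#' @export
read_contour_stack <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("contour file not found: %s", path), class = "emmfuse_io_error")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(j$slices)) {
    abort("contour JSON lacks 'slices'", class = "emmfuse_format_error")
  }
  slices <- j$slices
  # jsonlite may simplify to a data frame of list-columns or keep a list
  if (is.data.frame(slices)) {
    slices <- lapply(seq_len(nrow(slices)), function(i) {
      s <- lapply(slices, function(col) if (is.list(col)) col[[i]] else col[i])
      s
    })
  }
  slices <- lapply(slices, function(s) {
    out <- list(z = as.numeric(s$z))
    for (nm in c("endo_ed", "epi_ed", "endo_es", "epi_es")) {
      if (!is.null(s[[nm]]) && length(s[[nm]])) out[[nm]] <- as.matrix(s[[nm]])
    }
    sc <- s$scar
    if (is.null(sc) || length(sc) == 0) {
      out$scar <- list()
    } else if (is.array(sc) && length(dim(sc)) == 3) {
      # jsonlite simplifies equal-sized polygons to a 3-D array
      out$scar <- lapply(seq_len(dim(sc)[1]), function(k) sc[k, , ])
    } else if (is.matrix(sc)) {
      out$scar <- list(sc)
    } else {
      out$scar <- lapply(sc, as.matrix)
    }
    out
  })
  contour_stack(slices, pixel_spacing = j$pixel_spacing %||% 0.25)
}

#' Write a contour stack to its JSON dialect
#'
#' Numeric values are written with `%.6g` precision (sub-micrometre at LV
#' scale). `read_contour_stack(write_contour_stack(x))` is the identity at
#' that precision.
#'
#' @param stack a `contour_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  slices <- lapply(stack$slices, function(s) {
    out <- list(z = s$z)
    for (nm in c("endo_ed", "epi_ed", "endo_es", "epi_es")) {
      if (!is.null(s[[nm]])) out[[nm]] <- s[[nm]]
    }
    out$scar <- s$scar
    out
  })
  jsonlite::write_json(
    list(slices = slices, pixel_spacing = stack$pixel_spacing),
    path, digits = I(6), auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}
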