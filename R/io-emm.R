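#' Read an electromechanical-mapping point table
#'
#' The CSV dialect stands in for the mapping system's database export: a
#' header line `id,x,y,z,uv,bv,lls` followed by one row per measurement point.
#' Positions are mm, unipolar (`uv`) and bipolar (`bv`) voltages are mV, and
#' linear local shortening (`lls`) is percent. No `uv >= bv` constraint is
#' imposed. The returned tibble gains a logical `included` column initialized
#' `TRUE`; row order is preserved.
#'
#' @param path CSV file path.
#' @return A tibble with columns `id, x, y, z, uv, bv, lls, included`.
#' @export
read_emm_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("EMM file not found: %s", path), class = "emmfuse_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("id", "x", "y", "z", "uv", "bv", "lls")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("missing column %s", paste(missing, collapse = ", ")),
          class = "emmfuse_format_error")
  }
  out <- tibble::as_tibble(raw[required])
  for (col in required) {
    suppressWarnings(num <- as.numeric(out[[col]]))
    bad <- which(is.na(num) & !out[[col]] %in% c("", "NA"))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                    out[[col]][bad[1]], col, bad[1]),
            class = "emmfuse_format_error")
    }
    out[[col]] <- num
  }
  if (anyDuplicated(out$id)) {
    abort(sprintf("duplicate point id: %s",
                  out$id[anyDuplicated(out$id)][1]),
          class = "emmfuse_format_error")
  }
  if (!all(is.finite(as.matrix(out[, c("x", "y", "z")])))) {
    abort("non-finite point positions", class = "emmfuse_validation_error")
  }
  out$included <- TRUE
  out
}

#' Write an electromechanical-mapping point table
#'
#' Numeric values are written at `%.6g` precision; reading the file back
#' reproduces the table at that precision. The `included` column is not
#' serialized (it is session state, not acquisition data).
#'
#' @param emm tibble with columns `id, x, y, z, uv, bv, lls`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_emm_table <- function(emm, path) {
  required <- c("id", "x", "y", "z", "uv", "bv", "lls")
  stopifnot(all(required %in% names(emm)))
  fmt <- emm[required]
  fmt$id <- format(fmt$id, trim = TRUE, scientific = FALSE)
  for (col in required[-1]) fmt[[col]] <- sprintf("%.6g", emm[[col]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read point trajectories over the cardiac cycle
#'
#' Dialect: CSV `id,phase,x,y,z`; `phase` is a label such as `"ED"` or
#' `"ES"` (or an integer phase index). Positions are mm.
#'
#' @param path CSV file path.
#' @return A tibble `id, phase, x, y, z`.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("trajectory file not found: %s", path), class = "emmfuse_io_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE)
  required <- c("id", "phase", "x", "y", "z")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("missing column %s", paste(missing, collapse = ", ")),
          class = "emmfuse_format_error")
  }
  tibble::as_tibble(raw[required])
}

#' Write point trajectories
#' @param traj tibble `id, phase, x, y, z`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(all(c("id", "phase", "x", "y", "z") %in% names(traj)))
  fmt <- traj[c("id", "phase", "x", "y", "z")]
  for (col in c("x", "y", "z")) fmt[[col]] <- sprintf("%.6g", traj[[col]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bullseye grid as CSV
#'
#' Rows are slices ordered base to apex; columns are the 80 circumferential
#' segments, starting at the anterior-septal junction and proceeding
#' counterclockwise when viewed from the apex (this package's declared
#' convention; the angular origin of polar-map segments is not standardized).
#' Missing segments are written as empty cells. Values are written at
#' `%.12g` so the read-back reproduces the grid to 1e-9.
#'
#' @param grid numeric matrix, one row per slice, exactly 80 columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bullseye <- function(grid, path) {
  grid <- as.matrix(grid)
  if (ncol(grid) != 80) {
    abort(sprintf("bullseye rows must have exactly 80 values, got %d", ncol(grid)),
          class = "emmfuse_format_error")
  }
  txt <- apply(grid, 1, function(row) {
    cells <- ifelse(is.na(row), "", sprintf("%.12g", row))
    paste(cells, collapse = ",")
  })
  header <- paste(sprintf("seg%02d", 0:79), collapse = ",")
  writeLines(c(header, txt), path)
  invisible(path)
}

#' Read a bullseye CSV written by [write_bullseye()]
#' @param path CSV file path.
#' @return numeric matrix, slices x 80, `NA` for empty cells.
#' @export
read_bullseye <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("bullseye file not found: %s", path), class = "emmfuse_io_error")
  }
  lines <- readLines(path)
  if (length(lines) < 2) {
    abort("bullseye file has no data rows", class = "emmfuse_format_error")
  }
  body <- lines[-1]
  rows <- lapply(body, function(l) {
    cells <- strsplit(l, ",", fixed = TRUE)[[1]]
    # trailing empty cells are dropped by strsplit; pad back out
    cells <- c(cells, rep("", 80 - length(cells)))
    if (length(cells) != 80) {
      abort(sprintf("bullseye row has %d cells, expected 80", length(cells)),
            class = "emmfuse_format_error")
    }
    suppressWarnings(as.numeric(ifelse(cells == "", NA, cells)))
  })
  do.call(rbind, rows)
}
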