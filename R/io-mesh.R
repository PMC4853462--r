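#' Write a surface mesh as ASCII PLY
#'
#' Vertex properties `x y z` plus any scalar channels present (e.g. `it`,
#' `wt`) and the per-vertex `slice` index. The apex vertex index and basal
#' plane are stored in `comment` lines so the mesh round-trips through
#' [read_mesh_ply()]. Numeric precision is `%.6g`.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  ch <- names(mesh$channels)
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("comment apex_vertex %d", mesh$apex_vertex),
    if (!is.null(mesh$basal_plane)) {
      sprintf("comment basal_plane %s",
              paste(sprintf("%.6g", c(mesh$basal_plane$point,
                                      mesh$basal_plane$normal)), collapse = " "))
    },
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    if (!is.null(mesh$slice_of_vertex)) "property int slice",
    sprintf("property float %s", ch),
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vmat <- cbind(mesh$vertices)
  vcols <- apply(vmat, 2, function(col) sprintf("%.6g", col))
  if (!is.null(mesh$slice_of_vertex)) {
    vcols <- cbind(vcols, as.character(mesh$slice_of_vertex))
  }
  for (nm in ch) {
    vcols <- cbind(vcols, ifelse(is.na(mesh$channels[[nm]]), "nan",
                                 sprintf("%.6g", mesh$channels[[nm]])))
  }
  vlines <- apply(vcols, 1, paste, collapse = " ")
  flines <- sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                    mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY surface mesh written by [write_mesh_ply()]
#'
#' @param path file path.
#' @return A `surface_mesh`.
#' @export
read_mesh_ply <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("mesh file not found: %s", path), class = "emmfuse_io_error")
  }
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply" || lines[2] != "format ascii 1.0") {
    abort("not an ASCII PLY file", class = "emmfuse_format_error")
  }
  end <- match("end_header", lines)
  if (is.na(end)) abort("PLY header not terminated", class = "emmfuse_format_error")
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  if (!length(nv) || !length(nf)) {
    abort("PLY header lacks vertex/face counts", class = "emmfuse_format_error")
  }
  # vertex property names in declaration order (between vertex and face elems)
  vstart <- grep("^element vertex ", header)
  fstart <- grep("^element face ", header)
  props <- header[(vstart + 1):(fstart - 1)]
  props <- sub("^property (float|int|double) ", "", props[grepl("^property ", props)])
  vlines <- lines[(end + 1):(end + nv)]
  vmat <- matrix(as.numeric(unlist(strsplit(vlines, " ", fixed = TRUE))),
                 nrow = nv, byrow = TRUE)
  if (ncol(vmat) != length(props)) {
    abort("vertex rows do not match declared properties", class = "emmfuse_format_error")
  }
  colnames(vmat) <- props
  flines <- lines[(end + nv + 1):(end + nv + nf)]
  fmat <- matrix(as.integer(unlist(strsplit(flines, " ", fixed = TRUE))),
                 nrow = nf, byrow = TRUE)
  if (any(fmat[, 1] != 3)) {
    abort("only triangular faces are supported", class = "emmfuse_format_error")
  }
  tri <- fmat[, 2:4, drop = FALSE] + 1L

  apex_line <- grep("^comment apex_vertex ", header, value = TRUE)
  apex <- if (length(apex_line)) as.integer(sub("comment apex_vertex ", "", apex_line[1])) else NA_integer_
  bp_line <- grep("^comment basal_plane ", header, value = TRUE)
  bp <- NULL
  if (length(bp_line)) {
    nums <- as.numeric(strsplit(sub("comment basal_plane ", "", bp_line[1]), " ")[[1]])
    bp <- list(point = nums[1:3], normal = nums[4:6])
  }
  channels <- list()
  for (nm in setdiff(props, c("x", "y", "z", "slice"))) {
    channels[[nm]] <- vmat[, nm]
  }
  surface_mesh(
    vmat[, c("x", "y", "z")], tri, channels = channels, basal_plane = bp,
    apex_vertex = apex,
    slice_of_vertex = if ("slice" %in% props) as.integer(vmat[, "slice"]) else NULL
  )
}
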