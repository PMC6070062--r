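#' Read a triangle mesh from a Wavefront OBJ file
#'
#' Supports `v` and `f` records; face entries may use the `v/vt/vn` syntax
#' (only the vertex index is used). Faces with other than three vertices are
#' rejected: canopies are triangle meshes.
#'
#' @param path path to the OBJ file.
#' @param ... passed on to [canopy_mesh()] (e.g. `ground_cell`).
#' @return a [canopy_mesh()].
#' @export
read_obj <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ file has no vertices or no faces: ", path)
  verts <- t(vapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- lapply(strsplit(sub("^f\\s+", "", flines), "\\s+"), function(toks) {
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1L))
    if (length(idx) != 3L)
      stop("non-triangular face in OBJ (", length(idx),
           " vertices); only triangles are supported")
    if (any(is.na(idx)) || any(idx < 0L))
      stop("unsupported face indexing in OBJ")
    idx
  })
  canopy_mesh(verts, do.call(rbind, faces), ...)
}

#' Write a canopy mesh to a Wavefront OBJ file
#'
#' @param canopy a [canopy_mesh()].
#' @param path output path.
#' @export
write_obj <- function(canopy, path) {
  stopifnot(inherits(canopy, "canopy_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", canopy$vertices[, 1L],
                     canopy$vertices[, 2L], canopy$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", canopy$faces[, 1L], canopy$faces[, 2L],
                     canopy$faces[, 3L]), con)
  invisible(path)
}

#' Write per-patch canopy summaries as CSV
#'
#' Columns: `patch_id, centroid_x, centroid_y, centroid_z, area, h`.
#'
#' @param canopy a [canopy_mesh()].
#' @param path output path.
#' @param provenance optional named character vector written as `#` comment
#'   header lines.
#' @export
write_canopy_csv <- function(canopy, path, provenance = NULL) {
  stopifnot(inherits(canopy, "canopy_mesh"))
  p <- canopy$patches
  df <- data.frame(patch_id = p$patch_id, centroid_x = p$cx,
                   centroid_y = p$cy, centroid_z = p$cz,
                   area = p$area, h = p$h)
  .write_csv_prov(df, path, provenance)
  invisible(path)
}

#' Read a per-patch canopy summary CSV
#' @param path path written by [write_canopy_csv()].
#' @return data frame.
#' @export
read_canopy_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

.write_csv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}
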