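#' Construct a triangle-mesh canopy
#'
#' A canopy is a set of triangular surface patches (leaves and stems) over a
#' rectangular ground cell. Coordinates are in mm with z vertical (upwards).
#' Per-patch centroids, unit normals (oriented to have a non-negative upward
#' component), one-sided areas and normalized heights are computed on
#' construction; the leaf area index (LAI) is the total one-sided patch area
#' divided by the ground-cell area unless an explicit value is supplied (as is
#' needed for periodic lattice tilings, where the mesh holds nine plant copies
#' but the periodic unit cell holds one).
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices;
#'   every face must be a triangle.
#' @param ground_cell numeric length-4 vector `c(xmin, xmax, ymin, ymax)` of
#'   the periodic footprint; defaults to the bounding footprint of the mesh.
#' @param lai optional LAI override (dimensionless).
#' @param centre_patches optional integer vector of patch ids belonging to the
#'   centre plant of a lattice tiling; these are the analysis patches.
#' @return an object of class `canopy_mesh` with elements `vertices`, `faces`,
#'   `patches` (data frame with `patch_id`, centroid, normal, `area`, `h`),
#'   `z_min`, `z_max`, `ground_cell`, `lai`, `centre_patches`.
#' @export
canopy_mesh <- function(vertices, faces, ground_cell = NULL, lai = NULL,
                        centre_patches = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must be triangles (3 vertex indices)")
  if (nrow(faces) < 1L) stop("empty canopy: no patches")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range")

  v1 <- vertices[faces[, 1L], , drop = FALSE]
  v2 <- vertices[faces[, 2L], , drop = FALSE]
  v3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- sqrt(rowSums(cr^2))
  if (any(nrm <= 0)) stop("degenerate (zero-area) triangle in mesh")
  area <- nrm / 2
  normal <- cr / nrm
  flip <- normal[, 3L] < 0
  normal[flip, ] <- -normal[flip, ]
  centroid <- (v1 + v2 + v3) / 3

  z_min <- min(vertices[unique(as.vector(faces)), 3L])
  z_max <- max(vertices[unique(as.vector(faces)), 3L])
  h <- normalized_height(centroid[, 3L], z_min, z_max)

  if (is.null(ground_cell)) {
    used <- unique(as.vector(faces))
    ground_cell <- c(range(vertices[used, 1L]), range(vertices[used, 2L]))
  }
  cell_area <- (ground_cell[2L] - ground_cell[1L]) *
    (ground_cell[4L] - ground_cell[3L])
  if (!is.finite(cell_area) || cell_area <= 0)
    stop("ground cell must have positive area")
  if (is.null(lai)) lai <- sum(area) / cell_area
  if (lai <= 0) stop("lai must be positive")

  patches <- data.frame(
    patch_id = seq_len(nrow(faces)),
    cx = centroid[, 1L], cy = centroid[, 2L], cz = centroid[, 3L],
    nx = normal[, 1L], ny = normal[, 2L], nz = normal[, 3L],
    area = area, h = h)

  structure(list(vertices = vertices, faces = faces, patches = patches,
                 z_min = z_min, z_max = z_max, ground_cell = ground_cell,
                 lai = lai, centre_patches = centre_patches),
            class = "canopy_mesh")
}

#' @export
print.canopy_mesh <- function(x, ...) {
  cat("canopy_mesh:", nrow(x$faces), "patches,",
      sprintf("z in [%.1f, %.1f] mm,", x$z_min, x$z_max),
      sprintf("LAI = %.3f", x$lai), "\n")
  invisible(x)
}

#' Normalized height of a point within a canopy
#'
#' Rescales a height (typically a patch centroid's z coordinate) to \[0, 1\]
#' between the lowest and highest vertices of the whole canopy:
#' `h = (z - z_min) / (z_max - z_min)`.
#'
#' @param z height(s), mm.
#' @param z_min,z_max minimum and maximum vertex heights of the canopy, mm.
#' @return normalized height(s) in \[0, 1\].
#' @export
normalized_height <- function(z, z_min, z_max) {
  if (z_max <= z_min)
    stop("degenerate canopy: zero height range (z_min >= z_max)")
  if (any(z < z_min - 1e-9) || any(z > z_max + 1e-9))
    stop("height outside [z_min, z_max]")
  pmin(1, pmax(0, (z - z_min) / (z_max - z_min)))
}

#' Cumulative leaf area index profile
#'
#' Accumulates one-sided leaf area from the top of the canopy downwards, as a
#' function of depth `d = 1 - h` (normalized). The profile is non-decreasing,
#' starts at 0 at the canopy top and ends exactly at the canopy LAI.
#'
#' @param canopy a [canopy_mesh()].
#' @param n_bins number of depth bins (>= 1).
#' @return data frame with columns `depth` (length `n_bins + 1`, from 0 to 1)
#'   and `clai`.
#' @export
cumulative_lai_profile <- function(canopy, n_bins = 50L) {
  stopifnot(inherits(canopy, "canopy_mesh"))
  if (n_bins < 1L) stop("n_bins must be >= 1")
  p <- canopy$patches
  if (nrow(p) == 0L) stop("empty canopy")
  depth <- seq(0, 1, length.out = n_bins + 1L)
  total <- sum(p$area)
  # strict inequality so the profile starts at 0 even when a flat top leaf
  # sits exactly at h = 1; the final bin takes everything
  clai <- vapply(depth, function(d)
    if (d >= 1) total else sum(p$area[p$h > 1 - d]), numeric(1))
  # scale so the profile ends at the lai field even when lai is an override
  # (periodic lattice: mesh area and per-cell area differ by a known factor)
  data.frame(depth = depth, clai = clai / total * canopy$lai)
}

# rotate points about the vertical axis through `centre` by `angle` radians
.rotate_z <- function(pts, angle, centre) {
  ca <- cos(angle); sa <- sin(angle)
  x <- pts[, 1L] - centre[1L]
  y <- pts[, 2L] - centre[2L]
  cbind(centre[1L] + ca * x - sa * y, centre[2L] + sa * x + ca * y, pts[, 3L])
}

#' Assemble a single plant into a canopy
#'
#' Two layouts mirror the two ways an individual plant reconstruction is
#' turned into an (effectively infinite, periodic) canopy: `single_box` places
#' the periodic ground cell just outside the plant's footprint, so the canopy
#' is an infinite square lattice of identical copies; `lattice_3x3` places
#' nine copies on a square lattice a distance `spacing_d` apart, each rotated
#' about its own vertical axis, with the ground cell passing through the
#' centres of the boundary plants. For the lattice layout the patches of the
#' centre plant are flagged as the analysis patches and the LAI is the
#' one-plant leaf area per periodic cell `spacing_d^2`.
#'
#' @param plant a [canopy_mesh()] holding a single plant.
#' @param layout `"single_box"` or `"lattice_3x3"`.
#' @param spacing_d lattice spacing, mm (> 0; required for the lattice).
#' @param orientations optional numeric vector of 9 rotation angles (radians)
#'   about the vertical axis, one per copy (centre copy last); random when
#'   omitted.
#' @param seed integer seed used when `orientations` is omitted.
#' @return a [canopy_mesh()].
#' @export
tile_canopy <- function(plant, layout = c("single_box", "lattice_3x3"),
                        spacing_d = NULL, orientations = NULL, seed = 1L) {
  stopifnot(inherits(plant, "canopy_mesh"))
  layout <- match.arg(layout)
  if (layout == "single_box") {
    out <- canopy_mesh(plant$vertices, plant$faces)
    out$centre_patches <- out$patches$patch_id
    return(out)
  }
  if (is.null(spacing_d) || spacing_d <= 0)
    stop("lattice layout needs positive spacing_d")
  if (is.null(orientations)) {
    set.seed(seed)
    orientations <- runif(9L, 0, 2 * pi)
  }
  if (length(orientations) != 9L) stop("need 9 orientations")

  used <- unique(as.vector(plant$faces))
  c0 <- c(mean(range(plant$vertices[used, 1L])),
          mean(range(plant$vertices[used, 2L])))
  grid <- expand.grid(ix = -1:1, iy = -1:1)
  # put the centre copy first so its patch ids are 1..k
  ord <- order(grid$ix != 0 | grid$iy != 0)
  grid <- grid[ord, ]

  nv <- nrow(plant$vertices)
  nf <- nrow(plant$faces)
  verts <- vector("list", 9L)
  faces <- vector("list", 9L)
  for (i in seq_len(9L)) {
    v <- .rotate_z(plant$vertices, orientations[i], c(c0, 0))
    v[, 1L] <- v[, 1L] + grid$ix[i] * spacing_d
    v[, 2L] <- v[, 2L] + grid$iy[i] * spacing_d
    verts[[i]] <- v
    faces[[i]] <- plant$faces + (i - 1L) * nv
  }
  plant_area <- sum(plant$patches$area)
  cell <- c(c0[1L] - spacing_d, c0[1L] + spacing_d,
            c0[2L] - spacing_d, c0[2L] + spacing_d)
  canopy_mesh(do.call(rbind, verts), do.call(rbind, faces),
              ground_cell = cell, lai = plant_area / spacing_d^2,
              centre_patches = seq_len(nf))
}
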