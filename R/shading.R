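# triangle soup matrix (nf x 9) for the occlusion kernel
.tri_matrix <- function(canopy) {
  v <- canopy$vertices
  f <- canopy$faces
  cbind(v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
        v[f[, 3L], , drop = FALSE])
}

# periodic image offsets a sun ray can traverse before leaving the canopy:
# a ray climbing from z0 to z_max travels a bounded horizontal distance, so
# only finitely many wrapped cells can occlude it. Rather than the full
# rectangle of candidate cells, sample the projected ray and keep a band of
# cells (+/- 1 cell margin covers all origins within the base cell), ordered
# outward along the ray so early-exit hits are found quickly.
.periodic_offsets <- function(canopy, sun_dir, z0, cap = 40L) {
  gc <- canopy$ground_cell
  Lx <- gc[2L] - gc[1L]
  Ly <- gc[4L] - gc[3L]
  dz <- sun_dir[3L]
  if (dz <= 0) return(matrix(0, 1L, 2L))
  tmax <- (canopy$z_max - z0) / dz
  kx <- min(cap, ceiling(abs(sun_dir[1L]) * tmax / Lx) + 1L)
  ky <- min(cap, ceiling(abs(sun_dir[2L]) * tmax / Ly) + 1L)
  ns <- 8L * (kx + ky + 2L)
  s <- seq(0, tmax, length.out = ns)
  ix0 <- round(s * sun_dir[1L] / Lx)
  iy0 <- round(s * sun_dir[2L] / Ly)
  cells <- unique(data.frame(
    ix = rep(ix0, each = 9L) + rep(-1:1, times = 3L),
    iy = rep(iy0, each = 9L) + rep(-1:1, each = 3L)))
  cells <- cells[abs(cells$ix) <= kx & abs(cells$iy) <= ky, ]
  zero <- cells$ix == 0L & cells$iy == 0L
  cells <- rbind(cells[zero, ], cells[!zero, ])
  cbind(cells$ix * Lx, cells$iy * Ly)
}

#' Is the line of sight from a patch to the sun occluded?
#'
#' Casts a ray from the patch centroid toward the sun and tests intersection
#' with every other patch (Moller-Trumbore, tolerance 1e-9 mm). Under
#' `periodic = TRUE` the ray wraps at the vertical walls of the ground cell,
#' emulating the periodic boundary conditions of a canopy ray-tracer; only
#' the finitely many periodic images reachable below the canopy top are
#' tested.
#'
#' @param canopy a [canopy_mesh()].
#' @param patch patch id (row of `canopy$patches`).
#' @param sun_dir unit 3-vector toward the sun; must point upwards.
#' @param periodic wrap rays at the ground-cell walls?
#' @return logical.
#' @export
line_of_sight_occluded <- function(canopy, patch, sun_dir, periodic = TRUE) {
  stopifnot(inherits(canopy, "canopy_mesh"))
  if (sun_dir[3L] <= 0) stop("sun is below the horizon")
  sun_dir <- sun_dir / sqrt(sum(sun_dir^2))
  p <- canopy$patches[patch, ]
  origin <- matrix(c(p$cx, p$cy, p$cz), 1L, 3L)
  off <- if (periodic) .periodic_offsets(canopy, sun_dir, p$cz)
         else matrix(0, 1L, 2L)
  as.logical(cpp_occluded(.tri_matrix(canopy), origin, sun_dir,
                          as.integer(patch), off, 1e-9))
}

#' Per-patch direct-light traces over a day (ray-tracer stand-in)
#'
#' For every analysis patch and every grid time with the sun above the
#' horizon, the direct flux is the clear-sky envelope on that patch if the
#' line of sight to the sun is clear, and 0 if it is occluded. This is the
#' binary-occlusion emulation of a forward ray-tracer (no scattered or
#' transmitted light; leaves are opaque).
#'
#' @param canopy a [canopy_mesh()].
#' @param config a [solar_config()].
#' @param patch_ids patches to trace; defaults to `canopy$centre_patches`
#'   (the analysis patches) or all patches.
#' @param periodic wrap rays at the ground-cell walls?
#' @return object of class `light_trace_set`: list with `patch_id`, `t_min`,
#'   `flux` (patches x times), `envelope` (same shape) and `h` (normalized
#'   heights).
#' @export
trace_canopy <- function(canopy, config, patch_ids = NULL, periodic = TRUE) {
  stopifnot(inherits(canopy, "canopy_mesh"), inherits(config, "solar_config"))
  if (is.null(patch_ids))
    patch_ids <- canopy$centre_patches %||% canopy$patches$patch_id
  p <- canopy$patches[patch_ids, ]
  t_h <- config$t_grid_min / 60
  bd <- .beam_and_dirs(config, t_h)
  normals <- as.matrix(p[, c("nx", "ny", "nz")])
  # envelope: S0 tau^m |N . dir|
  env <- abs(normals %*% t(bd$dirs)) * rep(bd$beam, each = nrow(p))
  flux <- env
  tri <- .tri_matrix(canopy)
  origins <- as.matrix(p[, c("cx", "cy", "cz")])
  zmin <- min(origins[, 3L])
  for (k in which(bd$up)) {
    dir <- bd$dirs[k, ]
    off <- if (periodic) .periodic_offsets(canopy, dir, zmin)
           else matrix(0, 1L, 2L)
    occ <- cpp_occluded(tri, origins, dir, as.integer(patch_ids), off, 1e-9)
    flux[occ, k] <- 0
  }
  structure(list(patch_id = patch_ids, t_min = config$t_grid_min,
                 flux = flux, envelope = env, h = p$h),
            class = "light_trace_set")
}

#' Extract one patch's trace from a trace set
#' @param traces a `light_trace_set` from [trace_canopy()].
#' @param patch_id a patch id present in the set.
#' @return list of class `light_trace` with `patch_id`, `t_min`, `flux`, and
#'   the matching `envelope_trace` as attribute-free element `envelope`.
#' @export
light_trace <- function(traces, patch_id) {
  i <- match(patch_id, traces$patch_id)
  if (is.na(i)) stop("patch ", patch_id, " not in trace set")
  structure(list(patch_id = patch_id, t_min = traces$t_min,
                 flux = traces$flux[i, ],
                 envelope = traces$envelope[i, ], h = traces$h[i]),
            class = "light_trace")
}

#' Generate a synthetic canopy
#'
#' Reproducible fixture canopies for testing the shading oracle and the
#' downstream model pipeline without an external ray-tracer or plant
#' reconstructions.
#'
#' Styles: `stacked_leaves` stacks horizontal square leaves (two triangles
#' each) directly above one another - a worst-case occlusion column;
#' `random_rosette` places elongated triangular leaves radiating from a
#' central stem at random heights and azimuths, a crude rosette/cereal plant;
#' `scattered_leaves` scatters triangular leaves uniformly over the footprint
#' at random heights and azimuths - a homogeneous closed canopy whose LAI is
#' directly controlled by leaf count and size;
#' `lattice` builds a rosette and tiles it 3 x 3 via [tile_canopy()].
#'
#' @param style canopy style.
#' @param n_leaves number of leaves (>= 1).
#' @param seed RNG seed; the mesh is identical for identical seeds.
#' @param leaf_length leaf length, mm.
#' @param leaf_width leaf width (rosette) or side (stacked), mm.
#' @param height_range heights of leaf attachment, mm, `c(min, max)`.
#' @param footprint half-width of the ground cell, mm (stacked/rosette).
#' @param spacing_d lattice spacing, mm (lattice style).
#' @param droop downward tilt of rosette leaf tips, fraction of length.
#' @return a [canopy_mesh()].
#' @export
make_synthetic_canopy <- function(style = c("random_rosette",
                                            "stacked_leaves",
                                            "scattered_leaves", "lattice"),
                                  n_leaves = 50L, seed = 1L,
                                  leaf_length = 120, leaf_width = 40,
                                  height_range = c(50, 600),
                                  footprint = 150, spacing_d = 200,
                                  droop = 0.35) {
  style <- match.arg(style)
  if (n_leaves < 1L) stop("n_leaves must be >= 1")
  set.seed(seed)

  if (style == "stacked_leaves") {
    s <- leaf_width / 2
    z <- seq(height_range[1L], height_range[2L], length.out = n_leaves)
    verts <- do.call(rbind, lapply(z, function(zi)
      rbind(c(-s, -s, zi), c(s, -s, zi), c(s, s, zi), c(-s, s, zi))))
    faces <- do.call(rbind, lapply(seq_len(n_leaves) - 1L, function(i)
      rbind(4L * i + c(1L, 2L, 3L), 4L * i + c(1L, 3L, 4L))))
    cell <- c(-footprint, footprint, -footprint, footprint)
    return(canopy_mesh(verts, faces, ground_cell = cell))
  }

  rosette <- function(n) {
    az <- runif(n, 0, 2 * pi)
    z <- runif(n, height_range[1L], height_range[2L])
    r0 <- 10  # stem radius, mm
    verts <- vector("list", n)
    for (i in seq_len(n)) {
      u <- c(cos(az[i]), sin(az[i]))        # outward
      w <- c(-sin(az[i]), cos(az[i]))       # sideways
      base1 <- c(r0 * u + leaf_width / 2 * w, z[i])
      base2 <- c(r0 * u - leaf_width / 2 * w, z[i])
      tip <- c((r0 + leaf_length) * u, z[i] - droop * leaf_length)
      verts[[i]] <- rbind(base1, base2, tip)
    }
    faces <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
    list(verts = do.call(rbind, verts), faces = faces)
  }

  if (style == "random_rosette") {
    m <- rosette(n_leaves)
    cell <- c(-footprint, footprint, -footprint, footprint)
    return(canopy_mesh(m$verts, m$faces, ground_cell = cell))
  }

  if (style == "scattered_leaves") {
    x <- runif(n_leaves, -footprint, footprint)
    y <- runif(n_leaves, -footprint, footprint)
    az <- runif(n_leaves, 0, 2 * pi)
    z <- runif(n_leaves, height_range[1L], height_range[2L])
    verts <- vector("list", n_leaves)
    for (i in seq_len(n_leaves)) {
      u <- c(cos(az[i]), sin(az[i]))
      w <- c(-sin(az[i]), cos(az[i]))
      base1 <- c(x[i] + leaf_width / 2 * w[1L], y[i] + leaf_width / 2 * w[2L],
                 z[i])
      base2 <- c(x[i] - leaf_width / 2 * w[1L], y[i] - leaf_width / 2 * w[2L],
                 z[i])
      tip <- c(x[i] + leaf_length * u[1L], y[i] + leaf_length * u[2L],
               z[i] - droop * leaf_length)
      verts[[i]] <- rbind(base1, base2, tip)
    }
    faces <- matrix(seq_len(3L * n_leaves), ncol = 3L, byrow = TRUE)
    cell <- c(-footprint, footprint, -footprint, footprint)
    return(canopy_mesh(do.call(rbind, verts), faces, ground_cell = cell))
  }

  # lattice: tile a rosette plant
  m <- rosette(n_leaves)
  plant <- canopy_mesh(m$verts, m$faces)
  tile_canopy(plant, "lattice_3x3", spacing_d = spacing_d, seed = seed)
}

#' Write light traces as CSV
#'
#' Long format, columns `patch_id, t_min, flux`.
#' @param traces a `light_trace_set`.
#' @param path output path.
#' @param provenance optional named character vector of `#` header lines.
#' @export
write_traces_csv <- function(traces, path, provenance = NULL) {
  df <- data.frame(
    patch_id = rep(traces$patch_id, times = length(traces$t_min)),
    t_min = rep(traces$t_min, each = length(traces$patch_id)),
    flux = as.vector(traces$flux))
  .write_csv_prov(df, path, provenance)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
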