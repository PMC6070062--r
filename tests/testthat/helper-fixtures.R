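# Tiny meshes and records built in code.

# one horizontal triangle of given centroid height and size
flat_tri <- function(z, cx = 0, cy = 0, s = 10) {
  rbind(c(cx - s, cy - s, z), c(cx + s, cy - s, z), c(cx, cy + s, z))
}

# canopy of n horizontal triangles at the given heights (same footprint)
stacked_tri_canopy <- function(z, s = 10, cell = c(-50, 50, -50, 50)) {
  verts <- do.call(rbind, lapply(z, flat_tri, s = s))
  faces <- matrix(seq_len(3 * length(z)), ncol = 3, byrow = TRUE)
  canopy_mesh(verts, faces, ground_cell = cell)
}

# all-sunlit / all-shaded / mixed records for the four boundary cases
rec_sun_all <- function(h = 0.5, T_h = 12)
  switch_record(-1, T_h + 1, T_h = T_h, h = h, patch_id = 1L)
rec_shade_all <- function(h = 0.5, T_h = 12)
  switch_record(numeric(0), numeric(0), T_h = T_h, h = h, patch_id = 2L)
# sunlit at 0, shaded at T (off at y1, maybe more switches)
rec_sun_shade <- function(h = 0.5, T_h = 12)
  switch_record(c(-1, 5), c(3, 9), T_h = T_h, h = h, patch_id = 3L)
# shaded at 0, sunlit at T
rec_shade_sun <- function(h = 0.5, T_h = 12)
  switch_record(c(2, 8), c(4, T_h + 1), T_h = T_h, h = h, patch_id = 4L)

fig2_records <- function(h = 0.5, T_h = 12)
  list(rec_sun_all(h, T_h), rec_shade_all(h, T_h),
       rec_sun_shade(h, T_h), rec_shade_sun(h, T_h))
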