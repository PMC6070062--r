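test_that("line of sight: covered patches are occluded, top patches are not", {
  can <- stacked_tri_canopy(c(0, 100))
  zenith <- c(0, 0, 1)
  expect_true(line_of_sight_occluded(can, 1, zenith, periodic = FALSE))
  expect_false(line_of_sight_occluded(can, 2, zenith, periodic = FALSE))
  expect_error(line_of_sight_occluded(can, 1, c(0, 0, -1)), "horizon")
})

test_that("compiled occlusion agrees with the plain-R oracle", {
  set.seed(23)
  for (rep in 1:3) {
    can <- make_synthetic_canopy("random_rosette", n_leaves = 15,
                                 seed = 100 + rep)
    for (k in 1:4) {
      d <- c(rnorm(2), runif(1, 0.2, 1))
      d <- d / sqrt(sum(d^2))
      got <- vapply(seq_len(nrow(can$faces)), function(j)
        line_of_sight_occluded(can, j, d, periodic = FALSE), logical(1))
      want <- vapply(seq_len(nrow(can$faces)), function(j)
        oracle_occluded(can, j, d), logical(1))
      expect_identical(got, want)
    }
  }
})

test_that("occlusion flips exactly once as the sun crosses a half-plane edge", {
  # target patch at the origin under a large leaf covering x > 50
  target <- flat_tri(0, s = 5)
  cover <- rbind(c(50, -4000, 100), c(8000, -4000, 100), c(50, 4000, 100),
                 c(8000, -4000, 100), c(8000, 4000, 100), c(50, 4000, 100))
  can <- canopy_mesh(rbind(target, cover),
                     matrix(1:9, ncol = 3, byrow = TRUE),
                     ground_cell = c(-100, 100, -100, 100))
  # at 45 deg elevation the ray reaches z = 100 at horizontal distance 100,
  # crossing the x = 50 edge when cos(azimuth) = 0.5 (azimuth -60 deg)
  az <- seq(-pi / 2 + 0.01, 0, length.out = 301)
  elev <- pi / 4
  occ <- vapply(az, function(a) {
    d <- c(cos(elev) * cos(a), cos(elev) * sin(a), sin(elev))
    line_of_sight_occluded(can, 1, d, periodic = FALSE)
  }, logical(1))
  expect_equal(sum(diff(occ) != 0), 1)
  expect_false(occ[1])   # sun nearly along -y: ray misses the cover
  expect_true(occ[301])  # sun over the covered side
})

test_that("periodic wrapping finds occluders in neighbouring images", {
  # cell of width 100; occluder centred at x = 150 (next image over)
  target <- flat_tri(0, s = 5)
  occl <- rbind(c(130, -40, 50), c(170, -40, 50), c(150, 40, 50))
  can <- canopy_mesh(rbind(target, occl),
                     matrix(1:6, ncol = 3, byrow = TRUE),
                     ground_cell = c(-50, 50, -50, 50))
  d <- c(1, 0, 1) / sqrt(2)  # 45 deg east: hits z=50 at x=50 -> image x=150
  expect_true(line_of_sight_occluded(can, 1, d, periodic = TRUE))
  expect_false(line_of_sight_occluded(can, 1, d, periodic = FALSE))
})

test_that("trace_canopy: unshaded patches follow the envelope, covered ones go dark", {
  cfg <- solar_config(dt_min = 10)
  # single isolated (tilted) leaf: trace equals envelope everywhere
  one <- canopy_mesh(rbind(c(-10, -10, 0), c(10, -10, 2), c(0, 10, 5)),
                     matrix(1:3, 1), ground_cell = c(-50, 50, -50, 50))
  tr1 <- trace_canopy(one, cfg, periodic = FALSE)
  expect_equal(tr1$flux, tr1$envelope)

  # small leaf 10 mm under a much larger one: dark whenever the sun is up
  lower <- flat_tri(0, s = 10)
  upper <- flat_tri(10, s = 300)
  can <- canopy_mesh(rbind(lower, upper), matrix(1:6, ncol = 3, byrow = TRUE),
                     ground_cell = c(-400, 400, -400, 400))
  tr <- trace_canopy(can, cfg, patch_ids = 1L, periodic = FALSE)
  expect_true(all(tr$flux[1, ] == 0))
  expect_true(any(tr$envelope[1, ] > 0))
  # invariant: flux never exceeds the envelope
  expect_true(all(tr$flux <= tr$envelope + 1e-9))
})

test_that("adding occluders never decreases a patch's daily shaded time", {
  cfg <- solar_config(dt_min = 15)
  set.seed(77)
  zs <- runif(12, 50, 400)
  xs <- runif(12, -120, 120)
  ys <- runif(12, -120, 120)
  shaded_time <- vapply(c(2, 5, 8, 12), function(k) {
    verts <- rbind(flat_tri(0, s = 15),
                   do.call(rbind, lapply(seq_len(k), function(i)
                     flat_tri(zs[i], cx = xs[i], cy = ys[i], s = 40))))
    can <- canopy_mesh(verts,
                       matrix(seq_len(3 * (k + 1)), ncol = 3, byrow = TRUE),
                       ground_cell = c(-200, 200, -200, 200))
    tr <- trace_canopy(can, cfg, patch_ids = 1L, periodic = FALSE)
    sum(tr$flux[1, ] == 0 & tr$envelope[1, ] > 0)
  }, numeric(1))
  expect_true(all(diff(shaded_time) >= 0))
})

test_that("synthetic canopies are reproducible and scale as expected", {
  a <- make_synthetic_canopy("random_rosette", n_leaves = 30, seed = 42)
  b <- make_synthetic_canopy("random_rosette", n_leaves = 30, seed = 42)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)

  s1 <- make_synthetic_canopy("stacked_leaves", n_leaves = 10, seed = 1)
  s2 <- make_synthetic_canopy("stacked_leaves", n_leaves = 20, seed = 1)
  expect_equal(s2$lai / s1$lai, 2)

  r <- make_synthetic_canopy("random_rosette", n_leaves = 50, seed = 9)
  expect_true(all(r$patches$h > 0 & r$patches$h < 1))

  lat <- make_synthetic_canopy("lattice", n_leaves = 10, seed = 4,
                               spacing_d = 250)
  expect_equal(length(lat$centre_patches), 10)
})
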