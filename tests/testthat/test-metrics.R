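test_that("buffer clipping matches circle geometry and nests", {
  r <- land_cover_raster(matrix(1L, 100, 100), 10)
  ctr <- c(500, 500)
  v <- clip_buffer(r, ctr, 300)
  n_cells <- sum(!is.na(v$m))
  expect_lt(abs(n_cells - pi * 30^2) / (pi * 30^2), 0.01)
  ## nested radii give strictly nested member sets
  prev <- 0
  for (rad in c(100, 200, 300, 400)) {
    n <- sum(!is.na(clip_buffer(r, ctr, rad)$m))
    expect_gt(n, prev)
    prev <- n
  }
  ## radius below half a cell centred on a cell centre -> exactly that cell
  v1 <- clip_buffer(r, c(505, 505), 4)
  expect_equal(sum(!is.na(v1$m)), 1)
  expect_error(clip_buffer(r, c(50, 50), 300), "exceeds")
})

test_that("percent cover counts cells and classes partition the view", {
  g <- matrix(5L, 3, 4)
  g[1, 1:3] <- 1L
  v <- full_view(land_cover_raster(g, 10))
  expect_equal(percent_cover(v, 1), 25)
  expect_equal(percent_cover(v, 2), 0)
  total <- sum(vapply(1:7, function(k) percent_cover(v, k), numeric(1)))
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("patch labelling uses 8-connectivity", {
  g <- matrix(5L, 4, 4)
  g[1, 1] <- 1L; g[2, 2] <- 1L          # diagonal touch
  expect_equal(max(label_patches(full_view(land_cover_raster(g, 10)), 1)), 1)
  chk <- matrix(5L, 4, 4)
  chk[cbind(rep(1:4, each = 2), c(1, 3, 2, 4, 1, 3, 2, 4))] <- 1L
  expect_equal(max(label_patches(full_view(land_cover_raster(chk, 10)), 1)), 1)
  solid <- matrix(5L, 5, 5); solid[2:3, 2:3] <- 1L
  expect_equal(max(label_patches(full_view(land_cover_raster(solid, 10)), 1)), 1)
})

test_that("patch density reflects component count per hectare", {
  g <- matrix(5L, 10, 10)              # 100 cells x 100 m2 = 1 ha at 10 m
  v0 <- full_view(land_cover_raster(g, 10))
  expect_equal(patch_density(v0, 1), 0)
  g[1, 1:2] <- 1L
  joined <- patch_density(full_view(land_cover_raster(g, 10)), 1)
  g2 <- matrix(5L, 10, 10); g2[1, 1] <- 1L; g2[5, 5] <- 1L
  split <- patch_density(full_view(land_cover_raster(g2, 10)), 1)
  expect_equal(joined, 1)              # one patch in 1 ha
  expect_equal(split, 2)
  expect_gt(split, joined)             # splitting at fixed area raises PD
})

test_that("aggregation index reproduces analytic cases", {
  block22 <- matrix(5L, 4, 4); block22[2:3, 2:3] <- 1L
  expect_equal(aggregation_index(full_view(land_cover_raster(block22, 10)), 1), 100)
  iso <- matrix(5L, 5, 5); iso[cbind(c(1, 1, 5, 5), c(1, 5, 1, 5))] <- 1L
  expect_equal(aggregation_index(full_view(land_cover_raster(iso, 10)), 1), 0)
  strip <- matrix(5L, 3, 6); strip[2, 2:5] <- 1L
  expect_equal(aggregation_index(full_view(land_cover_raster(strip, 10)), 1), 75)
  single <- matrix(5L, 3, 3); single[2, 2] <- 1L
  expect_equal(aggregation_index(full_view(land_cover_raster(single, 10)), 1), 0)
  absent <- matrix(5L, 3, 3)
  expect_true(is.na(aggregation_index(full_view(land_cover_raster(absent, 10)), 1)))
})

test_that("patch isolation is a mean nearest-neighbour distance", {
  g <- matrix(5L, 3, 9)
  g[2, 2] <- 1L; g[2, 7] <- 1L          # 5 cells apart on a row, 10 m cells
  v <- full_view(land_cover_raster(g, 10))
  expect_equal(patch_isolation(v, 1), 50)
  one <- matrix(5L, 3, 3); one[2, 2] <- 1L
  expect_true(is.na(patch_isolation(full_view(land_cover_raster(one, 10)), 1)))
  ## rigid translation leaves PI unchanged
  g2 <- matrix(5L, 3, 9); g2[3, 3] <- 1L; g2[3, 8] <- 1L
  expect_equal(patch_isolation(full_view(land_cover_raster(g2, 10)), 1), 50)
})

test_that("edge contrast weights boundaries by habitat-quality rank", {
  ## forest cell surrounded by water: d = (7 - 1)/6 = 1
  g <- matrix(7L, 3, 3); g[2, 2] <- 1L
  expect_equal(edge_contrast(full_view(land_cover_raster(g, 10)), 1), 100)
  ## interior-only patch: the whole view is forest, no boundary -> 0
  expect_equal(edge_contrast(full_view(land_cover_raster(matrix(1L, 3, 3), 10)), 1), 0)
  ## half cattle pasture (d = 4/6), half secondary forest (d = 1/6)
  g2 <- matrix(0L, 3, 3)
  g2[] <- 2L; g2[2, 2] <- 1L
  g2[1, 2] <- 5L; g2[3, 2] <- 5L        # N and S pasture; E and W secondary
  expect_equal(edge_contrast(full_view(land_cover_raster(g2, 10)), 1),
               100 * (0.5 * 4 / 6 + 0.5 * 1 / 6))
  ## raising a neighbour's rank strictly lowers the contrast
  g3 <- g2; g3[1, 2] <- 3L              # pasture -> floodplain (rank 3 -> 5)
  expect_lt(edge_contrast(full_view(land_cover_raster(g3, 10)), 1),
            edge_contrast(full_view(land_cover_raster(g2, 10)), 1))
})

test_that("metric table enumerates patch x radius x metric and composes", {
  set.seed(31)
  g <- matrix(sample(1:7, 60 * 60, replace = TRUE, prob = c(.4, .2, .1, .1, .1, .05, .05)),
              60, 60)
  r <- land_cover_raster(g, 10)
  ctr <- data.frame(patch_id = c("A", "B"), x = c(300, 310), y = c(300, 290))
  mt <- metric_table(r, ctr, radii = c(100, 200))
  expect_equal(nrow(mt), 2 * 2 * 6)
  fc <- mt$value[mt$patch_id == "A" & mt$radius_m == 200 & mt$metric == "FC"]
  expect_equal(fc, percent_cover(clip_buffer(r, c(300, 300), 200), 1))
  ## all-forest landscape degenerates as expected
  rf <- land_cover_raster(matrix(1L, 60, 60), 10)
  m1 <- metric_table(rf, ctr[1, ], radii = 200)
  val <- function(m) m1$value[m1$metric == m]
  expect_equal(val("FC"), 100)
  expect_equal(val("SF"), 0)
  area_ha <- sum(!is.na(clip_buffer(rf, c(300, 300), 200)$m)) * 100 / 1e4
  expect_equal(val("PD"), 1 / area_ha)
  expect_gt(val("AI"), 95)
  expect_equal(val("EC"), 0)
  expect_true(is.na(val("PI")))
})

test_that("metrics agree with brute-force enumeration on small grids", {
  set.seed(17)
  for (i in 1:40) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    g <- random_grid(nr, nc)
    v <- full_view(land_cover_raster(g, 10))
    expect_equal(patch_density(v, 1), oracle_pd(g, 1, 10), tolerance = 1e-12)
    expect_equal(aggregation_index(v, 1), oracle_ai(g, 1), tolerance = 1e-12)
    expect_equal(patch_isolation(v, 1), oracle_pi(g, 1, 10), tolerance = 1e-12)
    expect_equal(edge_contrast(v, 1), oracle_ec(g, 1), tolerance = 1e-12)
  }
})
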