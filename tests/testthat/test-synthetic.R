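test_that("landscape generator honours proportions and determinism", {
  ## degenerate proportions: everything one class
  r <- generate_landscape(1000, 1000, 10, c(1, 0, 0, 0, 0, 0, 0), 0.4, 1)
  expect_true(all(r$grid == 1L))
  ## iid limit: uniform proportions realized within 1% on a 500x500 grid
  p <- rep(1 / 7, 7)
  r2 <- generate_landscape(5000, 5000, 10, p, 0, 2)
  prop <- tabulate(r2$grid, 7) / length(r2$grid)
  expect_true(all(abs(prop - 1 / 7) < 0.01))
  ## tolerance shrinks with grid area
  r3 <- generate_landscape(1000, 1000, 10, p, 0, 2)
  prop3 <- tabulate(r3$grid, 7) / length(r3$grid)
  expect_lte(max(abs(prop - 1 / 7)), max(abs(prop3 - 1 / 7)) + 1e-9)
  ## identical seeds give bit-identical rasters
  a <- generate_landscape(2000, 1500, 50, p, 0.3, 7)
  b <- generate_landscape(2000, 1500, 50, p, 0.3, 7)
  expect_identical(a$grid, b$grid)
  expect_equal(dim(a$grid), c(30, 40))
  ## clustered mosaics keep roughly the requested composition
  pc <- c(0.19, 0.15, 0.10, 0.08, 0.38, 0.05, 0.05)
  r4 <- generate_landscape(8000, 8000, 50, pc, 0.3, 3)
  prop4 <- tabulate(r4$grid, 7) / length(r4$grid)
  expect_true(all(abs(prop4 - pc) < 0.05))
  expect_error(generate_landscape(1000, 1000, 10, rep(0.2, 7), 0.3, 1),
               "summing to 1")
  expect_error(generate_landscape(-5, 1000, 10, p, 0.3, 1), "positive")
  expect_error(generate_landscape(1000, 1000, 10, p, 1, 1), "clustering")
})

test_that("positive clustering aggregates classes spatially", {
  p <- rep(1 / 7, 7)
  like_adj <- function(r) {
    g <- r$grid
    same_e <- g[, -ncol(g)] == g[, -1]
    same_s <- g[-nrow(g), ] == g[-1, ]
    mean(c(same_e, same_s))
  }
  iid <- generate_landscape(3000, 3000, 10, p, 0, 5)
  agg <- generate_landscape(3000, 3000, 10, p, 0.45, 5)
  expect_gt(like_adj(agg), like_adj(iid) + 0.2)
})

test_that("patch centres respect class, margin and separation constraints", {
  r <- forest_raster(400, 400, 50)     # 20 x 20 km, all old-growth
  ctr <- place_patch_centres(r, 16, 1000, seed = 3)
  expect_equal(nrow(ctr), 16)
  D <- as.matrix(dist(cbind(ctr$x, ctr$y)))
  expect_true(all(D[upper.tri(D)] >= 1000))
  expect_true(all(ctr$x >= 1500 & ctr$x <= 20000 - 1500))
  expect_true(all(ctr$y >= 1500 & ctr$y <= 20000 - 1500))
  ## single centre on a small all-forest raster
  one <- place_patch_centres(forest_raster(80, 80, 50), 1, 0, seed = 1)
  expect_equal(nrow(one), 1)
  ## infeasible separation errors out
  expect_error(place_patch_centres(forest_raster(80, 80, 50), 2, 1e6,
                                   seed = 1, max_attempts = 5),
               "could not place")
})

test_that("community generator hits planted targets deterministically", {
  cfg <- simulation_config(seed = 9, noise_sd = 0)
  b1 <- generate_community(cfg, 0.5, "P01", c(0, 0))
  b2 <- generate_community(cfg, 0.5, "P01", c(0, 0))
  expect_identical(b1$abundance, b2$abundance)
  expect_identical(b1$dispersal, b2$dispersal)
  ## null effect, no noise: every patch shares the same planted target
  cfg0 <- simulation_config(seed = 9, effect_size = 0, noise_sd = 0)
  t1 <- attr(generate_community(cfg0, -2, "A"), "target_d1")
  t2 <- attr(generate_community(cfg0, 2, "B"), "target_d1")
  expect_equal(t1, t2)
  expect_error(generate_community(cfg, NaN, "C"), "finite")
})

test_that("plot concentration controls within-patch turnover", {
  lo <- simulation_config(seed = 4, plot_concentration = 0.5,
                          individuals_mean = 4000)
  hi <- simulation_config(seed = 4, plot_concentration = 1e6,
                          individuals_mean = 4000)
  beta_lo <- hill_beta(generate_community(lo, 0, "P"), 1)
  beta_hi <- hill_beta(generate_community(hi, 0, "P"), 1)
  expect_lt(beta_hi, 1.35)             # plots converge to one composition
  expect_gt(beta_lo, beta_hi + 0.5)
})

test_that("diversity responds monotonically to the metric without noise", {
  cfg <- simulation_config(seed = 21, noise_sd = 0, effect_size = 1.5,
                           individuals_mean = 2000)
  zs <- seq(-1.5, 1.5, length.out = 8)
  blocks <- lapply(seq_along(zs), function(i)
    generate_community(cfg, zs[i], paste0("P", i)))
  targets <- vapply(blocks, attr, numeric(1), "target_d1")
  expect_true(all(diff(targets) > 0))  # strictly monotone planted response
  realized <- vapply(blocks, hill_gamma, numeric(1), q = 1)
  expect_gte(cor(zs, log(realized), method = "spearman"), 0.9)
})

test_that("a full study assembles blocks driven by the focal metric", {
  cfg <- simulation_config(seed = 6)
  st <- make_study(cfg)
  expect_s3_class(st, "seedscape_study")
  expect_length(st$blocks, 16)
  expect_true(all(vapply(st$blocks, function(b) nrow(b$abundance),
                         integer(1)) == 10))
  expect_identical(names(st$blocks), st$centres$patch_id)
  ## reproducibility of the whole study
  st2 <- make_study(cfg)
  expect_identical(st$raster$grid, st2$raster$grid)
  expect_identical(lapply(st$blocks, `[[`, "abundance"),
                   lapply(st2$blocks, `[[`, "abundance"))
  ## distinct patch ids at other sizes
  st3 <- make_study(simulation_config(seed = 6, n_patches = 3))
  expect_length(unique(vapply(st3$blocks, `[[`, character(1), "patch_id")), 3)
  ## strong planted effect shows up as a metric-diversity correlation
  d1 <- vapply(st$blocks, hill_gamma, numeric(1), q = 1)
  expect_gt(cor(st$focal$z, log(d1)), 0.7)
})

test_that("null studies show no metric-diversity association", {
  ## with effect_size = 0 the planted driver must not predict diversity
  reps <- 40
  pvals <- vapply(seq_len(reps), function(s) {
    cfg <- simulation_config(seed = 3000 + s, effect_size = 0,
                             n_patches = 8, width_m = 6000, height_m = 6000,
                             min_separation_m = 800)
    st <- make_study(cfg)
    d1 <- log(vapply(st$blocks, hill_gamma, numeric(1), q = 1))
    stats::cor.test(st$focal$z, d1)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("study percentages match the emulated design", {
  st <- make_study(simulation_config(seed = 12))
  tot <- sum(vapply(st$blocks, function(b) sum(b$abundance), numeric(1)))
  anim <- sum(vapply(st$blocks, function(b) sum(b$abundance[, b$dispersal]),
                     numeric(1)))
  expect_gt(anim / tot, 0.90)          # ~94% animal-dispersed individuals
  ## many species restricted to a single patch (rare-species tail)
  pooled <- lapply(st$blocks, function(b) colnames(b$abundance))
  all_sp <- unique(unlist(pooled))
  n_patches_of <- vapply(all_sp, function(s)
    sum(vapply(pooled, function(x) s %in% x, logical(1))), numeric(1))
  expect_gt(mean(n_patches_of == 1), 0.15)
  ## coverage in the empirically observed band
  cov <- coverage_table(st$blocks)
  expect_gt(mean(cov$coverage), 0.75)
  expect_lt(mean(cov$coverage), 1)
})
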