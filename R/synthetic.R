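#' Configuration for a synthetic multi-scale diversity study
#'
#' Bundles every parameter of the synthetic study generator: the landscape
#' mosaic, the patch sampling design, the regional species pool, and the
#' planted diversity-landscape relationship. The defaults emulate the study
#' design the package targets: 16 forest patches sampled with ten 1-m^2
#' plots each, ~19% old-growth cover in the surrounding mosaic, ~94% of
#' species animal-dispersed, and a single focal landscape metric at one
#' radius (the planted scale of effect) driving patch-level diversity.
#'
#' @param n_patches Number of forest patches (default 16).
#' @param n_plots Plots per patch (default 10; must be >= 2).
#' @param n_species Regional species-pool size (default 150; the pool is
#'   deliberately larger than the number of species a ~1300-individual
#'   sample detects under a lognormal abundance distribution).
#' @param sad_shape List with `meanlog` and `sdlog`: the lognormal shape of
#'   the regional species-abundance distribution; `sdlog` sets the reference
#'   unevenness that the per-patch diversity tuning rescales.
#' @param focal_metric Landscape metric driving diversity, one of
#'   "FC","SF","PD","AI","PI","EC" (default "FC").
#' @param true_radius Planted scale of effect in metres, one of the 13 radii
#'   300-1500 m (default 800).
#' @param effect_size Slope of log effective-number response per unit of the
#'   standardized focal metric (default 1).
#' @param noise_sd Residual SD of the log-diversity response (default 0.25).
#' @param prop_animal_dispersed Fraction of pool species labelled
#'   animal-dispersed (default 0.94).
#' @param intercept Baseline log effective number of typical species at the
#'   mean metric value (default `log(8)`).
#' @param plot_concentration Dirichlet concentration controlling how evenly
#'   each species spreads over a patch's plots; small values concentrate
#'   species in few plots (high within-patch turnover), large values
#'   homogenise plots (beta -> 1). Default 2.
#' @param individuals_mean,individuals_size Negative-binomial mean and size
#'   of the number of individuals per patch (defaults 79 and 6, i.e. a
#'   79 +/- ~34 individuals / 10 m^2 seedling density).
#' @param width_m,height_m,cell_size Raster extent and resolution in metres
#'   (defaults 8000 x 8000 m at 50 m cells).
#' @param class_proportions Target cover proportions of the seven classes
#'   (codes 1..7), summing to 1. Default: 19% old-growth, 15% secondary,
#'   10% floodplain, 8% arboreal crop, 38% pasture, 5% anthropogenic,
#'   5% water.
#' @param clustering Spatial aggregation of the mosaic in [0, 1): the
#'   occupancy of the modified-random-clusters percolation stage. Default
#'   0.3, giving forest patches of roughly 0.25-5 ha so that the landscape
#'   decorrelates between adjacent buffer radii.
#' @param min_separation_m Minimum pairwise distance between patch centres
#'   (default 1000 m).
#' @param seed RNG seed; every stochastic stage of the generator is a pure
#'   function of it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patches = 16, n_plots = 10, n_species = 150,
                              sad_shape = list(meanlog = 0, sdlog = 1),
                              focal_metric = "FC", true_radius = 800,
                              effect_size = 1, noise_sd = 0.25,
                              prop_animal_dispersed = 0.94,
                              intercept = log(8), plot_concentration = 2,
                              individuals_mean = 79, individuals_size = 6,
                              width_m = 8000, height_m = 8000, cell_size = 50,
                              class_proportions = c(0.19, 0.15, 0.10, 0.08,
                                                    0.38, 0.05, 0.05),
                              clustering = 0.3, min_separation_m = 1000,
                              seed = 1) {
  cfg <- list(
    n_patches = as.integer(n_patches), n_plots = as.integer(n_plots),
    n_species = as.integer(n_species), sad_shape = sad_shape,
    focal_metric = focal_metric, true_radius = true_radius,
    effect_size = effect_size, noise_sd = noise_sd,
    prop_animal_dispersed = prop_animal_dispersed, intercept = intercept,
    plot_concentration = plot_concentration,
    individuals_mean = individuals_mean,
    individuals_size = individuals_size,
    width_m = width_m, height_m = height_m, cell_size = cell_size,
    class_proportions = as.numeric(class_proportions),
    clustering = clustering, min_separation_m = min_separation_m,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (!cfg$true_radius %in% seq(300, 1500, by = 100))
    stop("true_radius must be one of the 13 radii 300, 400, ..., 1500 m")
  if (cfg$n_plots < 2) stop("n_plots must be >= 2")
  if (cfg$n_patches < 1) stop("n_patches must be >= 1")
  if (cfg$prop_animal_dispersed < 0 || cfg$prop_animal_dispersed > 1)
    stop("prop_animal_dispersed must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_species < 3) stop("n_species must be >= 3")
  if (!cfg$focal_metric %in% c("FC", "SF", "PD", "AI", "PI", "EC"))
    stop("unknown focal_metric")
  if (length(cfg$class_proportions) != 7 ||
      abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class_proportions must be 7 values summing to 1")
  if (cfg$sad_shape$sdlog <= 0) stop("sad_shape$sdlog must be > 0")
  invisible(cfg)
}

## Sub-2^31 deterministic seed from a base seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Generate a neutral land-cover mosaic
#'
#' Modified-random-clusters neutral landscape: a Bernoulli percolation map
#' at occupancy `clustering` is labelled into 4-connected clusters, clusters
#' are assigned to the seven classes by greedy largest-deficit filling of
#' the target proportions, and unoccupied cells take the modal class of
#' their already-assigned 8-neighbours (iterated; isolated remainders are
#' drawn independently from the target proportions). `clustering = 0`
#' reduces to an independent multinomial draw per cell.
#'
#' @param width_m,height_m Extent in metres.
#' @param cell_size Cell edge in metres.
#' @param class_proportions Seven target proportions summing to 1 (codes
#'   1..7).
#' @param clustering Aggregation parameter in [0, 1); values well below the
#'   percolation threshold (~0.59) keep cluster sizes finite.
#' @param seed RNG seed; identical seeds give bit-identical rasters.
#' @return A `land_cover_raster`.
#' @export
generate_landscape <- function(width_m, height_m, cell_size,
                               class_proportions, clustering, seed) {
  if (width_m <= 0 || height_m <= 0 || cell_size <= 0)
    stop("dimensions must be positive")
  if (length(class_proportions) != 7 ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be 7 values summing to 1")
  if (clustering < 0 || clustering >= 1) stop("clustering must be in [0, 1)")
  nr <- as.integer(round(height_m / cell_size))
  nc <- as.integer(round(width_m / cell_size))
  if (nr < 1 || nc < 1) stop("raster dimensions collapse to zero cells")
  prop <- as.numeric(class_proportions)
  set.seed(as.integer(seed))
  grid <- matrix(0L, nr, nc)
  if (clustering > 0) {
    mask <- matrix(stats::runif(nr * nc) < clustering, nr, nc)
    labels <- label_mask_conn(mask, diagonals = FALSE)
    k <- max(labels)
    if (k > 0L) {
      sizes <- tabulate(labels[labels > 0L], nbins = k)
      total <- nr * nc
      assigned <- numeric(7)
      cls_of <- integer(k)
      ## fill classes by largest relative shortfall so the assigned shares
      ## track the target proportions at any percolation occupancy
      for (cl in sample.int(k)) {
        ratio <- ifelse(prop > 0, assigned / (prop * total), Inf)
        pick <- which.min(ratio)
        cls_of[cl] <- pick
        assigned[pick] <- assigned[pick] + sizes[cl]
      }
      grid[labels > 0L] <- as.integer(cls_of[labels[labels > 0L]])
    }
  }
  grid <- fill_modal_neighbours(grid, prop)
  land_cover_raster(grid, cell_size)
}

## 4- or 8-connected labelling of a logical matrix (shared with metrics).
label_mask_conn <- function(mask, diagonals = TRUE) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  cells <- which(mask)
  if (length(cells) == 0L) return(labels)
  vid <- integer(length(mask)); vid[cells] <- seq_along(cells)
  pr <- adjacent_pairs(mask, diagonals = diagonals)
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (!is.null(pr) && nrow(pr) > 0L)
    g <- igraph::add_edges(g, rbind(vid[pr[, 1]], vid[pr[, 2]]))
  labels[cells] <- as.integer(igraph::components(g)$membership)
  labels
}

## Iteratively assign unclassified cells (code 0) the modal class of their
## assigned 8-neighbours; random (seeded) tie-breaks; cells never reached
## are drawn iid from the target proportions.
fill_modal_neighbours <- function(grid, prop) {
  nr <- nrow(grid); nc <- ncol(grid)
  shift_sum <- function(B) {
    out <- matrix(0, nr, nc)
    for (dr in -1:1) for (dcol in -1:1) {
      if (dr == 0 && dcol == 0) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dcol):min(nc, nc + dcol)
      out[rs - dr, cs - dcol] <- out[rs - dr, cs - dcol] + B[rs, cs]
    }
    out
  }
  while (any(grid == 0L)) {
    counts <- array(0, c(nr, nc, 7))
    for (cl in 1:7) counts[, , cl] <- shift_sum(grid == cl)
    tot <- apply(counts, c(1, 2), sum)
    todo <- which(grid == 0L & tot > 0)
    if (length(todo) == 0L) {
      rest <- which(grid == 0L)
      grid[rest] <- sample.int(7, length(rest), replace = TRUE, prob = prop)
      break
    }
    flat <- matrix(counts, nr * nc, 7)[todo, , drop = FALSE]
    flat <- flat + matrix(stats::runif(length(flat)) * 1e-3,
                          nrow(flat), 7)  # seeded random tie-break
    grid[todo] <- max.col(flat)
  }
  grid
}

#' Place patch centres on old-growth cells
#'
#' Draws `n_patches` cell centres of class 1 (old-growth forest), pairwise
#' at least `min_separation_m` apart and at least `margin_m` from every
#' raster edge so the largest analysis buffer fits around each centre.
#' Placement is greedy over a random permutation of eligible cells and
#' restarts on failure; an infeasible constraint set raises an error.
#'
#' @param raster A `land_cover_raster`.
#' @param n_patches Number of centres (>= 1).
#' @param min_separation_m Minimum pairwise centre distance, metres.
#' @param seed RNG seed.
#' @param margin_m Margin to the raster boundary (default 1500 m, the
#'   largest buffer radius).
#' @param max_attempts Number of greedy restarts before giving up.
#' @return data.frame with columns patch_id, x, y.
#' @export
place_patch_centres <- function(raster, n_patches, min_separation_m,
                                seed = 1, margin_m = 1500,
                                max_attempts = 200) {
  stopifnot(inherits(raster, "land_cover_raster"))
  if (n_patches < 1) stop("n_patches must be >= 1")
  nr <- nrow(raster$grid); nc <- ncol(raster$grid); cs <- raster$cell_size
  forest <- which(raster$grid == 1L)
  if (length(forest) == 0L) stop("raster holds no old-growth cells")
  rows <- (forest - 1L) %% nr + 1L
  cols <- (forest - 1L) %/% nr + 1L
  xy <- cell_centres(raster, rows, cols)
  ok <- xy[, 1] >= raster$origin[1] + margin_m &
    xy[, 1] <= raster$origin[1] + nc * cs - margin_m &
    xy[, 2] >= raster$origin[2] + margin_m &
    xy[, 2] <= raster$origin[2] + nr * cs - margin_m
  xy <- xy[ok, , drop = FALSE]
  if (nrow(xy) == 0L)
    stop("no old-growth cells at least ", margin_m, " m from the boundary")
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(nrow(xy))
    chosen <- integer(0)
    for (i in ord) {
      if (length(chosen) == 0L) {
        chosen <- i
      } else {
        d2 <- (xy[chosen, 1] - xy[i, 1])^2 + (xy[chosen, 2] - xy[i, 2])^2
        if (all(d2 >= min_separation_m^2)) chosen <- c(chosen, i)
      }
      if (length(chosen) == n_patches) break
    }
    if (length(chosen) == n_patches) {
      return(data.frame(
        patch_id = sprintf("P%02d", seq_len(n_patches)),
        x = xy[chosen, 1], y = xy[chosen, 2], stringsAsFactors = FALSE))
    }
  }
  stop("could not place ", n_patches, " centres ", min_separation_m,
       " m apart within the eligible area")
}

## Saturating link keeping the target log-diversity inside (log lo, log hi):
## logistic in eta with unit slope at the interval midpoint, so the planted
## log-linear response is preserved in the interior and strictly monotone
## everywhere.
saturate_log_target <- function(eta, n_species) {
  lo <- log(1.05); hi <- log(0.98 * n_species)
  mid <- (lo + hi) / 2; sc <- (hi - lo) / 4
  lo + (hi - lo) * stats::plogis((eta - mid) / sc)
}

## Effective number of typical species of the pool distribution at
## unevenness t (relative abundances softmax(t * z)).
pool_d1 <- function(t, z) {
  w <- t * z
  p <- exp(w - max(w))
  p <- p / sum(p)
  pos <- p > 0
  exp(-sum(p[pos] * log(p[pos])))
}

## Regional structure shared by all patches of a study: lognormal dominance
## ranks over the pool and dispersal labels. Abiotically dispersed species
## are drawn from outside the top decile of regional dominance: in the
## emulated system the dominant species are animal-dispersed and abiotic
## species hold few individuals.
regional_structure <- function(config) {
  S <- config$n_species
  set.seed(derive_seed(config$seed, "regional"))
  z_regional <- stats::rnorm(S)
  n_anim <- ceiling(config$prop_animal_dispersed * S)
  animal <- logical(S)
  if (n_anim > 0) {
    n_abiotic <- S - n_anim
    eligible <- order(z_regional, decreasing = TRUE)[-seq_len(ceiling(S / 10))]
    animal[] <- TRUE
    if (n_abiotic > 0)
      animal[sample(eligible, min(n_abiotic, length(eligible)))] <- FALSE
  }
  list(z_regional = z_regional, animal = animal)
}

## Pool relative abundances with unevenness tuned so the pool's
## typical-species number equals `target`.
tune_pool <- function(z, target) {
  f <- function(t) pool_d1(t, z) - target
  t_hi <- 1
  while (f(t_hi) > 0 && t_hi < 1e6) t_hi <- t_hi * 2
  t_star <- stats::uniroot(f, c(0, t_hi), tol = 1e-10)$root
  w <- t_star * z
  p <- exp(w - max(w))
  p / sum(p)
}

## Sampling chain of one patch: negative-binomial total, multinomial species
## counts, Dirichlet-multinomial allocation over plots. Consumes the current
## RNG stream. Every plot ends up with at least one animal-dispersed
## individual (the analysed community is the filtered one), enforced by
## redraws and, as a last resort, deterministic transfers.
draw_alloc <- function(config, p, animal) {
  S <- config$n_species; N <- config$n_plots
  n_tot <- max(N, stats::rnbinom(1, mu = config$individuals_mean,
                                 size = config$individuals_size))
  counts <- as.integer(stats::rmultinom(1, n_tot, p))
  if (any(animal) && any(!animal)) {
    while (sum(counts[animal]) < N && sum(counts[!animal]) > 0) {
      from <- which(!animal)[which.max(counts[!animal])]
      to <- which(animal)[which.max(counts[animal] + p[animal])]
      counts[from] <- counts[from] - 1L
      counts[to] <- counts[to] + 1L
    }
  }
  guard_cols <- if (any(animal & counts > 0)) which(animal) else seq_len(S)
  plot_ok <- function(A) all(rowSums(A[, guard_cols, drop = FALSE]) > 0)
  alloc <- NULL
  for (try in 1:100) {
    A <- matrix(0L, N, S)
    for (i in which(counts > 0)) {
      gshape <- stats::rgamma(N, shape = config$plot_concentration / N)
      if (sum(gshape) == 0) gshape <- rep(1, N)
      A[, i] <- as.integer(stats::rmultinom(1, counts[i], gshape / sum(gshape)))
    }
    if (plot_ok(A)) { alloc <- A; break }
  }
  if (is.null(alloc)) {       # deterministic repair of stubborn empty plots
    G <- A[, guard_cols, drop = FALSE]
    for (j in which(rowSums(G) == 0)) {
      gsum <- rowSums(A[, guard_cols, drop = FALSE])
      donor <- which.max(gsum)
      if (gsum[donor] < 2) break
      sp <- guard_cols[which.max(A[donor, guard_cols])]
      A[donor, sp] <- A[donor, sp] - 1L
      A[j, sp] <- A[j, sp] + 1L
    }
    alloc <- A
  }
  alloc
}

## log typical-species gamma of the animal-dispersed fraction of an
## allocation matrix (the quantity the downstream analysis regresses).
alloc_log_gamma1 <- function(alloc, animal) {
  cols <- which(animal & colSums(alloc) > 0)
  if (length(cols) == 0L) cols <- which(colSums(alloc) > 0)
  A <- alloc[, cols, drop = FALSE]
  tot <- rowSums(A)
  if (any(tot == 0)) return(NA_real_)
  pbar <- colMeans(A / tot)
  pbar <- pbar[pbar > 0]
  -sum(pbar * log(pbar))
}

## Finite sampling (n ~ 79 individuals in 10 plots) both attenuates and
## biases the realized diversity relative to the latent pool target. The
## planted effect size is defined on the realized response, so the latent ->
## realized map is estimated by a seeded Monte Carlo over the latent range
## and inverted when setting each patch's pool target.
calibrate_sampling <- function(config, reg = regional_structure(config)) {
  S <- config$n_species
  set.seed(derive_seed(config$seed, "calibration"))
  us <- seq(log(2), log(0.9 * S), length.out = 7)
  K <- 24
  means <- vapply(us, function(u) {
    r <- vapply(seq_len(K), function(k) {
      z <- sqrt(0.5) * reg$z_regional + sqrt(0.5) * stats::rnorm(S)
      p <- tune_pool(z * config$sad_shape$sdlog, exp(u))
      alloc_log_gamma1(draw_alloc(config, p, reg$animal), reg$animal)
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  cf <- stats::coef(stats::lm(means ~ us))
  if (!all(is.finite(cf)) || cf[2] < 0.2 || cf[2] > 1.5)
    cf <- c(0, 1)                       # degenerate fit: fall back to identity
  list(a = unname(cf[1]), b = unname(cf[2]))
}

#' Generate one patch's seedling community
#'
#' Draws a patch-level target effective number of typical species from the
#' planted response `intercept + effect_size * metric + Normal(0, noise_sd)`
#' on the log scale (passed through a saturating link that keeps the target
#' inside the feasible range `(1, S)`), tunes the unevenness of a lognormal
#' species-abundance distribution over the regional pool, draws the patch's
#' individuals multinomially from it, and spreads each species over the
#' `n_plots` plots with a Dirichlet-multinomial whose concentration
#' (`plot_concentration`) controls within-patch turnover. Because finite
#' sampling attenuates the realized diversity relative to the latent pool,
#' the latent target is first passed through the inverse of a
#' Monte-Carlo-estimated latent-to-realized calibration, so the planted
#' slope refers to the realized diversity response. Allocations leaving a
#' plot without an animal-dispersed individual are redrawn. The fraction
#' `prop_animal_dispersed` of the pool is labelled animal-dispersed (a
#' regional property shared by all patches of a study).
#'
#' @param config A `simulation_config`.
#' @param metric_value Standardized focal landscape metric at the planted
#'   scale of effect for this patch (finite).
#' @param patch_id Identifier for the block.
#' @param centre Numeric (x, y) patch centre, metres.
#' @param calibration Optional precomputed sampling calibration (as stored
#'   by [make_study()]); computed from the config when missing.
#' @return A `community_block` with attribute `target_d1` (the planted
#'   target effective number before sampling noise).
#' @export
generate_community <- function(config, metric_value, patch_id,
                               centre = c(NA_real_, NA_real_),
                               calibration = NULL) {
  validate_config(config)
  if (!is.finite(metric_value)) stop("metric_value must be finite")
  S <- config$n_species
  reg <- regional_structure(config)
  if (is.null(calibration)) calibration <- calibrate_sampling(config, reg)
  ## patch-level randomness
  set.seed(derive_seed(config$seed, paste0("patch:", patch_id)))
  z <- sqrt(0.5) * reg$z_regional + sqrt(0.5) * stats::rnorm(S)
  z <- z * config$sad_shape$sdlog
  eta <- config$intercept + config$effect_size * metric_value +
    stats::rnorm(1, 0, config$noise_sd)
  target_log <- saturate_log_target(eta, S)
  pool_log <- (target_log - calibration$a) / calibration$b
  pool_log <- min(max(pool_log, log(1.2)), log(0.95 * S))
  p <- tune_pool(z, exp(pool_log))
  alloc <- draw_alloc(config, p, reg$animal)
  observed <- which(colSums(alloc) > 0)
  block <- community_block(
    patch_id, alloc[, observed, drop = FALSE],
    species_labels = sprintf("sp%03d", observed),
    dispersal = reg$animal[observed], centre = centre)
  attr(block, "target_d1") <- exp(target_log)
  block
}

#' Generate a complete synthetic study
#'
#' End-to-end dataset with known ground truth: a neutral land-cover mosaic,
#' `n_patches` patch centres on old-growth cells, and one plot-by-species
#' community per patch whose diversity responds to the focal landscape
#' metric measured at `true_radius` (standardized across patches). All
#' randomness flows from `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return A list of class `seedscape_study`: `raster`, `centres`
#'   (data.frame patch_id/x/y), `blocks` (list of `community_block`),
#'   `focal` (data.frame patch_id, value, z of the focal metric at the true
#'   radius), and `config`.
#' @export
make_study <- function(config) {
  validate_config(config)
  raster <- generate_landscape(config$width_m, config$height_m,
                               config$cell_size, config$class_proportions,
                               config$clustering, config$seed)
  centres <- place_patch_centres(raster, config$n_patches,
                                 config$min_separation_m,
                                 seed = derive_seed(config$seed, "centres"))
  mt <- metric_table(raster, centres, radii = config$true_radius,
                     metrics = config$focal_metric)
  vals <- mt$value[match(centres$patch_id, mt$patch_id)]
  if (anyNA(vals))
    stop("focal metric ", config$focal_metric,
         " is undefined for some patches at the planted radius")
  z <- if (stats::sd(vals) > 0) (vals - mean(vals)) / stats::sd(vals)
       else rep(0, length(vals))
  calibration <- calibrate_sampling(config)
  blocks <- lapply(seq_len(nrow(centres)), function(i)
    generate_community(config, z[i], centres$patch_id[i],
                       centre = c(centres$x[i], centres$y[i]),
                       calibration = calibration))
  names(blocks) <- centres$patch_id
  structure(
    list(raster = raster, centres = centres, blocks = blocks,
         focal = data.frame(patch_id = centres$patch_id, value = vals, z = z,
                            stringsAsFactors = FALSE),
         config = config),
    class = "seedscape_study"
  )
}

#' @export
print.seedscape_study <- function(x, ...) {
  cat(sprintf(
    "seedscape_study: %d patches, %d plots each; focal %s at %d m (effect %.2f, noise %.2f), seed %d\n",
    length(x$blocks), x$config$n_plots, x$config$focal_metric,
    x$config$true_radius, x$config$effect_size, x$config$noise_sd,
    x$config$seed))
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#'
#' @param config A `simulation_config`.
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   `simulation_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(simulation_config, lst)
}
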