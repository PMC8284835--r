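## Independent oracles and fixture builders used across the suite. The
## oracles deliberately avoid the package's own code paths: diversity goes
## through vegan and explicit loops, landscape metrics through exhaustive
## flood-fill enumeration, cross-validation through per-split lm() fits.

## random community block with every plot non-empty
random_block <- function(n_species, n_plots, max_count = 9,
                         patch_id = "X") {
  repeat {
    A <- matrix(rpois(n_plots * n_species, 1.2), n_plots, n_species)
    A[A > max_count] <- max_count
    if (all(rowSums(A) > 0) && any(colSums(A) > 0)) break
  }
  community_block(patch_id, A)
}

## ---- diversity oracle (vegan + scalar loops) ---------------------------

oracle_diversity <- function(A, q) {
  P <- A / rowSums(A)
  N <- nrow(P)
  pbar <- colMeans(P)
  gamma <- if (q == 0) {
    sum(pbar > 0)
  } else if (q == 1) {
    exp(vegan::diversity(pbar, index = "shannon"))
  } else {
    vegan::diversity(pbar, index = "invsimpson")
  }
  alpha <- if (q == 0) {
    mean(vegan::specnumber(A))
  } else if (q == 1) {
    exp(mean(vegan::diversity(A, index = "shannon")))
  } else {
    1 / mean(1 - vegan::diversity(A, index = "simpson"))
  }
  list(gamma = gamma, alpha = alpha, beta = gamma / alpha)
}

## ---- landscape-metric oracles (exhaustive enumeration) -----------------

## flood-fill 8-connected components over a full rectangular grid
oracle_components <- function(grid, class_code) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (grid[r, cc] != class_code || lab[r, cc] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1] + dr; c2 <- p[2] + dc
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
            grid[rr, c2] == class_code && lab[rr, c2] == 0L) {
          lab[rr, c2] <- cur
          stack[[length(stack) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

oracle_pd <- function(grid, class_code, cell_size) {
  k <- max(oracle_components(grid, class_code))
  k / (length(grid) * cell_size^2 / 1e4)
}

oracle_ai <- function(grid, class_code) {
  A <- sum(grid == class_code)
  if (A == 0) return(NA_real_)
  g <- 0
  nr <- nrow(grid); nc <- ncol(grid)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (grid[r, cc] != class_code) next
    if (cc < nc && grid[r, cc + 1] == class_code) g <- g + 1
    if (r < nr && grid[r + 1, cc] == class_code) g <- g + 1
  }
  n <- floor(sqrt(A)); m <- A - n^2
  gmax <- if (m == 0) 2 * n * (n - 1)
          else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
          else 2 * n * (n - 1) + 2 * m - 2
  if (gmax == 0) return(0)
  100 * g / gmax
}

oracle_pi <- function(grid, class_code, cell_size) {
  lab <- oracle_components(grid, class_code)
  k <- max(lab)
  if (k < 2) return(NA_real_)
  cells <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  nn <- numeric(k)
  for (comp in seq_len(k)) {
    best <- Inf
    for (i in which(ids == comp)) for (j in which(ids != comp)) {
      d <- cell_size * sqrt(sum((cells[i, ] - cells[j, ])^2))
      if (d < best) best <- d
    }
    nn[comp] <- best
  }
  mean(nn)
}

oracle_ec <- function(grid, class_code, ranking = quality_ranking()) {
  lab <- oracle_components(grid, class_code)
  k <- max(lab)
  if (k < 1) return(NA_real_)
  r_focal <- ranking[[as.character(class_code)]]
  nr <- nrow(grid); nc <- ncol(grid)
  wsum <- numeric(k); cnt <- numeric(k)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (grid[r, cc] != class_code) next
    comp <- lab[r, cc]
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
      if (grid[rr, c2] == class_code) next
      cnt[comp] <- cnt[comp] + 1
      wsum[comp] <- wsum[comp] +
        (r_focal - ranking[[as.character(grid[rr, c2])]]) / 6
    }
  }
  ec <- ifelse(cnt > 0, 100 * wsum / cnt, 0)
  area <- tabulate(lab[lab > 0], nbins = k)
  sum(ec * area) / sum(area)
}

## random small land-cover grid guaranteed to contain the focal class
random_grid <- function(nr, nc, p_forest = 0.4) {
  repeat {
    g <- matrix(ifelse(runif(nr * nc) < p_forest, 1L,
                       sample(2:7, nr * nc, replace = TRUE)), nr, nc)
    if (any(g == 1L)) return(g)
  }
}

## ---- cross-validation oracle (per-split lm fits) -----------------------

oracle_r2cv <- function(y, x) {
  n <- length(y)
  pairs <- utils::combn(n, 2)
  sse <- 0
  for (s in seq_len(ncol(pairs))) {
    hold <- pairs[, s]
    fit <- stats::lm(y ~ x, data = data.frame(y = y[-hold], x = x[-hold]))
    pred <- predict(fit, newdata = data.frame(x = x[hold]))
    sse <- sse + sum((y[hold] - pred)^2)
  }
  ss_cv <- sse / (2 * ncol(pairs))
  1 - ss_cv / (mean((y - mean(y))^2))
}

## ---- hand-constructed model sets for averaging algebra -----------------

fake_model_set <- function(terms_list, coefs, ses, weights,
                           n = 16, response = "y") {
  stopifnot(length(terms_list) == length(weights))
  models <- lapply(seq_along(terms_list), function(i) {
    list(terms = terms_list[[i]], label = paste(terms_list[[i]],
                                                collapse = " + "),
         k = length(terms_list[[i]]) + 2L, loglik = NA_real_,
         aicc = NA_real_, coef = coefs[[i]], se = ses[[i]],
         weight = weights[i])
  })
  tab <- data.frame(
    model = vapply(models, `[[`, character(1), "label"),
    k = vapply(models, `[[`, integer(1), "k"),
    loglik = NA_real_, aicc = NA_real_,
    delta = NA_real_, weight = weights, stringsAsFactors = FALSE)
  structure(list(response = response, n = n, table = tab, models = models,
                 skipped = data.frame()),
            class = "model_set")
}

## small all-forest raster for placement tests
forest_raster <- function(nr, nc, cell_size = 50) {
  land_cover_raster(matrix(1L, nr, nc), cell_size)
}
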