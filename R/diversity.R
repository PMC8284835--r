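#' Hill number of a relative-abundance vector
#'
#' Effective number of species of order `q` for a probability vector:
#' `(sum(p^q))^(1/(1-q))`, with the `q = 1` limit `exp(-sum(p*log(p)))`
#' (exponential Shannon entropy) and the convention `0 * log(0) = 0`.
#'
#' This is the low-level kernel shared by the gamma and alpha estimators;
#' it accepts any real order `q >= 0`, which the continuity checks around
#' `q = 1` rely on.
#'
#' @param p Numeric vector of non-negative relative abundances; it is
#'   renormalised to sum to one.
#' @param q Diversity order (single non-negative number).
#' @return Effective number of species (>= 1 for a non-degenerate `p`).
#' @export
#' @examples
#' hill_number(c(0.5, 0.3, 0.2), 2)  # inverse Simpson = 1 / 0.38
hill_number <- function(p, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
    stop("q must be a single non-negative number")
  p <- p[p > 0]
  if (length(p) == 0L) stop("no positive abundances")
  p <- p / sum(p)
  if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

## Plot-wise relative abundances; errors on empty plots, whose p_ij are
## undefined and would silently change N (and hence beta's upper bound).
plot_probs <- function(block) {
  A <- block$abundance
  tot <- rowSums(A)
  if (any(tot == 0))
    stop("empty plot(s) ", paste(which(tot == 0), collapse = ", "),
         " in block ", block$patch_id, ": plot-level diversity undefined")
  A / tot
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !(q %in% c(0, 1, 2)))
    stop("q must be 0, 1 or 2")
  q
}

#' Patch-level (gamma) diversity of order q
#'
#' Gamma diversity of a patch in effective numbers of species, computed from
#' the mean relative abundance of each species over the `N` plots (equal plot
#' weights): `(sum(pbar_i^q))^(1/(1-q))`, with the exponential-Shannon form
#' at `q = 1`. `q = 0` is species richness ("all" species), `q = 1` the
#' number of equally-common ("typical") species, `q = 2` the effective number
#' of "dominant" species.
#'
#' @param block A `community_block` in which every plot holds at least one
#'   individual.
#' @param q Diversity order, one of 0, 1, 2.
#' @return Effective number of species at the patch level.
#' @seealso [hill_alpha()], [hill_beta()], [hill_number()]
#' @export
hill_gamma <- function(block, q) {
  check_q(q)
  P <- plot_probs(block)
  pbar <- colMeans(P)
  hill_number(pbar, q)
}

#' Plot-level (alpha) diversity of order q
#'
#' Alpha diversity across the `N` plots of a patch with equal plot weights:
#' for `q != 1`, `((1/N) * sum_j sum_i p_ij^q)^(1/(1-q))` with `p_ij` the
#' relative abundance of species `i` within plot `j`; for `q = 1`,
#' `exp(-(1/N) * sum_j sum_i p_ij * log(p_ij))`. At `q = 0` this is the mean
#' plot richness.
#'
#' @inheritParams hill_gamma
#' @return Effective number of species at the plot level.
#' @export
hill_alpha <- function(block, q) {
  check_q(q)
  P <- plot_probs(block)
  N <- nrow(P)
  pl <- P[P > 0]                      # 0^q must not count absent species
  if (q == 1) {
    exp(-sum(pl * log(pl)) / N)
  } else {
    (sum(pl^q) / N)^(1 / (1 - q))
  }
}

#' Beta diversity: effective number of distinct plot assemblages
#'
#' Multiplicative decomposition `beta = gamma / alpha`. Ranges from 1 (all
#' plot assemblages identical) to `N` (the `N` plots completely distinct).
#'
#' @inheritParams hill_gamma
#' @return Effective number of completely distinct assemblages.
#' @export
hill_beta <- function(block, q) {
  hill_gamma(block, q) / hill_alpha(block, q)
}

#' Sample coverage of a pooled community sample
#'
#' Estimated proportion of individuals in the community belonging to species
#' detected in the sample, from the abundance counts pooled over a patch's
#' plots: `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`, with `f1`/`f2`
#' the singleton and doubleton species counts and `n` the pooled number of
#' individuals. `f1 = 0` gives complete estimated coverage (`C = 1`); when
#' the correction factor is 0/0 (only possible at `n = 1`) the uncorrected
#' limit `1 - f1/n` is used.
#'
#' @param pooled_counts Non-negative integer vector of per-species pooled
#'   abundances.
#' @param patch_id Optional identifier stored in the result.
#' @return A list of class `coverage_record`: patch_id, coverage, n, f1, f2.
#' @export
#' @examples
#' sample_coverage(c(5, 3, 1, 1))$coverage  # 0.8
sample_coverage <- function(pooled_counts, patch_id = NA_character_) {
  x <- pooled_counts[pooled_counts > 0]
  if (length(x) == 0L) stop("all-zero counts: empty community")
  n <- sum(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) {
    cov <- 1
  } else {
    den <- (n - 1) * f1 + 2 * f2
    cov <- if (den == 0) 1 - f1 / n else 1 - (f1 / n) * ((n - 1) * f1 / den)
  }
  structure(
    list(patch_id = as.character(patch_id), coverage = cov,
         n = as.integer(n), f1 = as.integer(f1), f2 = as.integer(f2)),
    class = "coverage_record"
  )
}

#' Alpha/beta/gamma diversity table for a set of patches
#'
#' Computes the full effective-number decomposition for every block and
#' order.
#'
#' @param blocks List of `community_block`s (or a single block).
#' @param orders Diversity orders, a subset of `c(0, 1, 2)`.
#' @return data.frame with columns patch_id, q, alpha, beta, gamma, n_plots;
#'   one row per patch and order, and `gamma = alpha * beta` exactly.
#' @export
diversity_table <- function(blocks, orders = c(0, 1, 2)) {
  if (inherits(blocks, "community_block")) blocks <- list(blocks)
  if (length(blocks) == 0L) stop("need at least one community block")
  rows <- lapply(blocks, function(b) {
    do.call(rbind, lapply(orders, function(q) {
      g <- hill_gamma(b, q)
      a <- hill_alpha(b, q)
      data.frame(patch_id = b$patch_id, q = q, alpha = a, beta = g / a,
                 gamma = g, n_plots = nrow(b$abundance),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage table for a set of patches
#'
#' @inheritParams diversity_table
#' @return data.frame with columns patch_id, coverage, n, f1, f2.
#' @export
coverage_table <- function(blocks) {
  if (inherits(blocks, "community_block")) blocks <- list(blocks)
  rows <- lapply(blocks, function(b) {
    as.data.frame(unclass(sample_coverage(colSums(b$abundance), b$patch_id)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wide table of the six diversity responses
#'
#' Pivots a [diversity_table()] into one row per patch with the six response
#' variables used in scale-of-effect and multimodel analyses: alpha and beta
#' at q = 0 ("all"), 1 ("typical") and 2 ("dominant"), plus the gamma values.
#'
#' @param div A data.frame from [diversity_table()].
#' @return data.frame with columns patch_id, alpha_q0, alpha_q1, alpha_q2,
#'   beta_q0, beta_q1, beta_q2, gamma_q0, gamma_q1, gamma_q2.
#' @export
diversity_responses <- function(div) {
  patches <- unique(div$patch_id)
  out <- data.frame(patch_id = patches, stringsAsFactors = FALSE)
  for (comp in c("alpha", "beta", "gamma")) {
    for (q in sort(unique(div$q))) {
      sel <- div[div$q == q, ]
      out[[sprintf("%s_q%g", comp, q)]] <-
        sel[[comp]][match(patches, sel$patch_id)]
    }
  }
  out
}
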