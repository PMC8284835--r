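#' Clark-Evans aggregation statistic
#'
#' Ratio of the observed mean nearest-neighbour distance among points to its
#' expectation `0.5 / sqrt(lambda)` under complete spatial randomness at
#' intensity `lambda = n / area`. `R = 1` indicates randomness, `R < 1`
#' aggregation, `R -> 2.149` a perfectly regular pattern (2 for a square
#' lattice). The p-value uses the standard normal approximation for the
#' mean nearest-neighbour distance (SE `0.26136 / sqrt(n * lambda)`),
#' two-sided, without edge correction.
#'
#' @param centres data.frame with columns x, y (metres) or a two-column
#'   matrix; >= 2 points, duplicates allowed.
#' @param study_area Area of the observation window in square metres.
#' @return List with `R`, `p_value`, `n`, `mean_nn`, `expected_nn`.
#' @export
clark_evans <- function(centres, study_area) {
  if (is.data.frame(centres)) centres <- cbind(centres$x, centres$y)
  centres <- as.matrix(centres)
  n <- nrow(centres)
  if (n < 2) stop("need at least 2 points")
  if (study_area <= 0) stop("study_area must be positive")
  D <- as.matrix(stats::dist(centres))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  lambda <- n / study_area
  expected <- 0.5 / sqrt(lambda)
  R <- mean(nn) / expected
  se <- 0.26136 / sqrt(n * lambda)
  z <- (mean(nn) - expected) / se
  list(R = R, p_value = 2 * stats::pnorm(-abs(z)), n = n,
       mean_nn = mean(nn), expected_nn = expected)
}

#' Mantel-style spatial screen of a site-level variable
#'
#' Pearson correlation between the inter-site distance matrix and the
#' pairwise absolute-difference matrix of a site variable (a diversity
#' metric, a landscape metric, or model residuals), with a permutation
#' p-value. A positive significant correlation indicates spatial
#' autocorrelation of the variable.
#'
#' @param site_distances Square symmetric matrix of inter-site distances
#'   (or a `dist`).
#' @param values Numeric vector aligned with the distance matrix rows; must
#'   not be constant.
#' @param permutations Number of permutations (default 999).
#' @param seed RNG seed for the permutation draw.
#' @return List with `r` (Mantel correlation), `p_value`, `permutations`.
#' @export
distance_screen <- function(site_distances, values, permutations = 999,
                            seed = 1) {
  D <- as.matrix(site_distances)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("site_distances must be square and symmetric")
  if (length(values) != nrow(D)) stop("values length mismatch")
  if (stats::sd(values) == 0)
    stop("undefined correlation: values are constant across sites")
  V <- abs(outer(values, values, "-"))
  set.seed(as.integer(seed))
  mt <- vegan::mantel(stats::as.dist(D), stats::as.dist(V),
                      method = "pearson", permutations = permutations)
  list(r = unname(mt$statistic), p_value = mt$signif,
       permutations = permutations)
}

#' Shapiro-Wilk normality screen
#'
#' Reports the Shapiro-Wilk statistic for a variable; purely diagnostic,
#' the data are never transformed.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return List with `W`, `p_value`, `pass` (TRUE when normality is not
#'   rejected at `alpha`).
#' @export
shapiro_screen <- function(values, alpha = 0.05) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("degenerate sample: values are constant")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p_value = st$p.value,
       pass = st$p.value >= alpha)
}
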