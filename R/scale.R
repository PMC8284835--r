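#' Ordinary least squares on a single predictor
#'
#' @param y Response vector (length >= 3).
#' @param x Predictor vector, non-constant, same length as `y`.
#' @return List with `intercept`, `slope`, `residuals`.
#' @export
fit_simple_lm <- function(y, x) {
  if (length(y) != length(x)) stop("y and x lengths differ")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant")
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc * xc)
  intercept <- mean(y) - slope * mean(x)
  list(intercept = intercept, slope = slope,
       residuals = y - intercept - slope * x)
}

## Core leave-two-out R2_CV. Enumerates all C(n,2) held-out pairs; each
## calibration fit is obtained by downdating the centred sufficient
## statistics (exact OLS, O(1) per split). Returns NA instead of erroring
## when strict = FALSE (used by profile/bootstrap sweeps, where a degenerate
## resample marks the radius missing rather than aborting).
r2cv_core <- function(y, x, strict = TRUE) {
  n <- length(y)
  fail <- function(msg) if (strict) stop(msg) else return(NA_real_)
  if (n < 4) return(fail("need n >= 4 for leave-two-out cross-validation"))
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) return(fail("undefined R2: response has zero variance"))
  xc <- x - mean(x); yc <- y - mean(y)
  Sx <- 0; Sy <- 0                       # centred sums are zero by design
  Sxx <- sum(xc^2); Sxy <- sum(xc * yc)
  pr <- utils::combn(n, 2)
  i <- pr[1, ]; j <- pr[2, ]
  m <- n - 2
  sx <- Sx - xc[i] - xc[j]
  sy <- Sy - yc[i] - yc[j]
  sxx <- Sxx - xc[i]^2 - xc[j]^2
  sxy <- Sxy - xc[i] * yc[i] - xc[j] * yc[j]
  den <- sxx - sx^2 / m
  if (any(den <= 1e-12 * max(Sxx, 1)))
    return(fail("degenerate predictor: x constant in a calibration split"))
  slope <- (sxy - sx * sy / m) / den
  icpt <- sy / m - slope * sx / m
  e1 <- yc[i] - (icpt + slope * xc[i])
  e2 <- yc[j] - (icpt + slope * xc[j])
  ss_cv <- sum(e1^2 + e2^2) / (2 * ncol(pr))
  1 - ss_cv / (ssy / n)
}

#' Leave-two-out cross-validated R-squared
#'
#' Enumerates every split holding out a pair of observations, fits the
#' single-predictor OLS model on the remaining `n - 2`, and accumulates the
#' squared prediction errors on the held-out pair. With `SScv` the mean
#' squared held-out error over all `2 * choose(n, 2)` predictions,
#' `R2_CV = 1 - SScv / ((1/n) * sum((y - mean(y))^2))`. Ranges from `-Inf`
#' (worse than the mean-only model) to 1 (perfect out-of-sample prediction).
#'
#' @param y Response vector, non-constant, length >= 4.
#' @param x Predictor vector; must be non-constant in every calibration
#'   split.
#' @return R2_CV, a single number `<= 1`.
#' @export
r2_cv_leave_two_out <- function(y, x) {
  if (length(y) != length(x)) stop("y and x lengths differ")
  r2cv_core(as.numeric(y), as.numeric(x), strict = TRUE)
}

#' Scale-of-effect profile of one response/predictor pair
#'
#' Fits the 13 (or however many radii are present) single-predictor linear
#' models of a diversity response against one landscape metric measured at
#' each buffer radius, scores each with leave-two-out `R2_CV`, and selects
#' the radius with the strongest cross-validated response as the scale of
#' effect (ties broken toward the smallest radius). Patches with a missing
#' metric value at a radius (e.g. patch isolation with a single forest
#' patch) are dropped for that radius; radii with fewer than four complete
#' pairs, a constant predictor or a constant response are marked missing and
#' excluded from the argmax.
#'
#' @param response_values data.frame with columns `patch_id` and `value`
#'   (one diversity metric per patch), or a named numeric vector.
#' @param metric_table data.frame as from [metric_table()] (columns
#'   patch_id, radius_m, metric, value).
#' @param predictor Landscape-metric name to profile.
#' @param response Optional response name stored in the result.
#' @return Object of class `scale_profile`: `response`, `predictor`,
#'   `r2cv` (named vector over radii), `n` (complete pairs per radius), and
#'   `selected_radius`.
#' @export
scale_profile <- function(response_values, metric_table, predictor,
                          response = "response") {
  rv <- as_response_df(response_values)
  sub <- metric_table[metric_table$metric == predictor, , drop = FALSE]
  if (nrow(sub) == 0L) stop("predictor ", predictor, " absent from metric table")
  radii <- sort(unique(sub$radius_m))
  r2 <- setNames(rep(NA_real_, length(radii)), radii)
  nn <- setNames(integer(length(radii)), radii)
  for (k in seq_along(radii)) {
    s <- sub[sub$radius_m == radii[k], ]
    x <- s$value[match(rv$patch_id, s$patch_id)]
    ok <- !is.na(x) & !is.na(rv$value)
    nn[k] <- sum(ok)
    if (nn[k] >= 4)
      r2[k] <- r2cv_core(rv$value[ok], x[ok], strict = FALSE)
  }
  sel <- if (all(is.na(r2))) NA_real_ else radii[which.max(r2)]
  structure(
    list(response = response, predictor = predictor, r2cv = r2, n = nn,
         selected_radius = sel),
    class = "scale_profile"
  )
}

#' @export
print.scale_profile <- function(x, ...) {
  cat(sprintf("scale_profile %s ~ %s: scale of effect %s m (R2_CV = %.3f)\n",
              x$response, x$predictor, format(x$selected_radius),
              suppressWarnings(max(x$r2cv, na.rm = TRUE))))
  invisible(x)
}

as_response_df <- function(response_values) {
  if (is.data.frame(response_values)) {
    stopifnot(all(c("patch_id", "value") %in% names(response_values)))
    response_values
  } else {
    if (is.null(names(response_values)))
      stop("response_values must be a data.frame or a named vector")
    data.frame(patch_id = names(response_values),
               value = as.numeric(response_values), stringsAsFactors = FALSE)
  }
}

#' Bootstrap uncertainty of the selected scale of effect
#'
#' Resamples the patches with replacement `B` times, recomputes the
#' scale-of-effect profile on each resample, and tallies how often each
#' radius is selected. Resamples on which no radius can be scored (e.g.
#' zero response variance after resampling) are redrawn, so the counts sum
#' to `B` exactly.
#'
#' @inheritParams scale_profile
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return Object of class `bootstrap_scale`: `counts` (named vector over
#'   radii), `B`, `mean_radius`, `sd_radius`, `modal_radius`, `seed`.
#' @export
bootstrap_scale <- function(response_values, metric_table, predictor,
                            B = 1000, seed = 1, response = "response") {
  if (B < 1) stop("B must be >= 1")
  rv <- as_response_df(response_values)
  sub <- metric_table[metric_table$metric == predictor, , drop = FALSE]
  if (nrow(sub) == 0L) stop("predictor ", predictor, " absent from metric table")
  radii <- sort(unique(sub$radius_m))
  X <- sapply(radii, function(r) {
    s <- sub[sub$radius_m == r, ]
    s$value[match(rv$patch_id, s$patch_id)]
  })
  X <- matrix(X, nrow = nrow(rv))
  y <- rv$value
  n <- length(y)
  set.seed(as.integer(seed))
  picks <- numeric(B)
  b <- 1L
  guard <- 0L
  while (b <= B) {
    guard <- guard + 1L
    if (guard > 50L * B) stop("bootstrap could not draw valid resamples")
    idx <- sample.int(n, n, replace = TRUE)
    r2 <- vapply(seq_along(radii), function(k) {
      x <- X[idx, k]; yy <- y[idx]
      ok <- !is.na(x)
      if (sum(ok) < 4) return(NA_real_)
      r2cv_core(yy[ok], x[ok], strict = FALSE)
    }, numeric(1))
    if (all(is.na(r2))) next          # invalid resample: redraw
    picks[b] <- radii[which.max(r2)]
    b <- b + 1L
  }
  counts <- table(factor(picks, levels = radii))
  structure(
    list(counts = setNames(as.integer(counts), radii), B = as.integer(B),
         mean_radius = mean(picks), sd_radius = stats::sd(picks),
         modal_radius = radii[which.max(counts)], seed = as.integer(seed)),
    class = "bootstrap_scale"
  )
}

#' @export
print.bootstrap_scale <- function(x, ...) {
  cat(sprintf(
    "bootstrap_scale: B = %d, modal radius %d m, mean %.2f +/- %.2f m\n",
    x$B, x$modal_radius, x$mean_radius, x$sd_radius))
  invisible(x)
}

#' Full single-predictor sweep over responses and predictors
#'
#' Builds a [scale_profile()] for every response/predictor combination,
#' mirroring the full multi-scale screen (6 responses x 6 predictors x 13
#' radii = 468 single-predictor models for the default study design).
#'
#' @param responses data.frame with `patch_id` and one column per response
#'   (e.g. from [diversity_responses()]).
#' @param metric_table data.frame from [metric_table()].
#' @param response_names,predictor_names Columns / metrics to sweep
#'   (defaults: all non-id response columns; all metrics present).
#' @return Named list of `scale_profile`s (`response.predictor`), with
#'   attribute `n_models` = total fitted single-predictor models.
#' @export
scale_sweep <- function(responses, metric_table,
                        response_names = setdiff(names(responses), "patch_id"),
                        predictor_names = unique(metric_table$metric)) {
  out <- list()
  n_models <- 0L
  for (resp in response_names) {
    rv <- data.frame(patch_id = responses$patch_id,
                     value = responses[[resp]], stringsAsFactors = FALSE)
    for (pred in predictor_names) {
      prof <- scale_profile(rv, metric_table, pred, response = resp)
      n_models <- n_models + length(prof$r2cv)
      out[[paste(resp, pred, sep = ".")]] <- prof
    }
  }
  attr(out, "n_models") <- n_models
  out
}
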