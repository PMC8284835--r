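#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc Numeric vector of AICc (or delta) values.
#' @return Named list with `delta` and `weight`, both aligned with `aicc`.
#' @export
akaike_weights <- function(aicc) {
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Variance-inflation-factor screen
#'
#' Regresses each predictor on all the others; `VIF_j = 1 / (1 - R2_j)`.
#' Predictors with `VIF >= threshold` are flagged (perfect collinearity is
#' reported as infinite VIF, flagged, rather than an error).
#'
#' @param design Numeric matrix or data.frame of predictors (>= 2 columns,
#'   each non-constant).
#' @param threshold Flagging threshold (default 4).
#' @return data.frame with columns term, vif, flagged.
#' @export
vif_screen <- function(design, threshold = 4) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("need at least 2 predictors for a VIF screen")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant predictor in design")
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = terms, vif = vif, flagged = vif >= threshold,
             stringsAsFactors = FALSE)
}

#' Enumerate all additive candidate models
#'
#' All subsets of the global model's terms, including the empty set (the
#' intercept-only null model), in deterministic order (by size, then
#' lexicographic combination order).
#'
#' @param terms Character vector of 0-6 predictor names.
#' @return List of character vectors; `2^length(terms)` candidates.
#' @export
enumerate_models <- function(terms) {
  terms <- as.character(terms)
  if (length(terms) > 6) stop("at most 6 terms supported")
  out <- list(character(0))
  for (size in seq_along(terms)) {
    cmb <- utils::combn(terms, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

model_label <- function(terms) {
  if (length(terms) == 0L) "(null)" else paste(terms, collapse = " + ")
}

#' Fit candidate models and rank them by AICc
#'
#' Fits each candidate as a Gaussian OLS model of `response` on its terms,
#' computes `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with
#' `k = length(terms) + 2` (intercept, slopes, residual variance), and ranks
#' the candidates by AICc. Akaike weights are computed over the full
#' candidate set; models with `delta < 2` are flagged as best-supported.
#' Candidates for which `n <= k + 1` are skipped with a recorded reason.
#' The candidate list is treated as a set: duplicated term subsets are
#' collapsed before weighting, so repeating a candidate cannot inflate its
#' Akaike mass.
#'
#' @param candidates List of character vectors (from [enumerate_models()]).
#' @param response Name of the response column in `data`.
#' @param data data.frame holding the response and every term.
#' @return Object of class `model_set`: `table` (model, k, loglik, aicc,
#'   delta, weight, best_supported; sorted by AICc), `models` (per-candidate
#'   terms, coefficients, standard errors, weight, in table order),
#'   `skipped`, `n`, `response`.
#' @export
fit_and_rank <- function(candidates, response, data) {
  data <- data[stats::complete.cases(
    data[, c(response, unique(unlist(candidates))), drop = FALSE]), ,
    drop = FALSE]
  n <- nrow(data)
  candidates <- unique(lapply(candidates, function(tm) sort(as.character(tm))))
  fits <- list(); skipped <- list()
  for (cand in candidates) {
    k <- length(cand) + 2L
    lab <- model_label(cand)
    if (n <= k + 1L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(model = lab, reason = sprintf("n = %d <= k + 1 = %d",
                                                 n, k + 1L),
                   stringsAsFactors = FALSE)
      next
    }
    fml <- if (length(cand) == 0L) stats::as.formula(paste(response, "~ 1"))
           else stats::as.formula(paste(response, "~",
                                        paste(cand, collapse = " + ")))
    fit <- stats::lm(fml, data = data)
    ll <- as.numeric(stats::logLik(fit))
    aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    fits[[length(fits) + 1L]] <- list(terms = cand, label = lab, k = k,
                                      loglik = ll, aicc = aicc,
                                      coef = cf, se = se)
  }
  if (length(fits) == 0L) stop("no candidate model could be fitted")
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  aw <- akaike_weights(aicc)
  ord <- order(aicc)
  fits <- fits[ord]
  for (i in seq_along(fits)) fits[[i]]$weight <- aw$weight[ord][i]
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "label"),
    k = vapply(fits, `[[`, integer(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    delta = aw$delta[ord],
    weight = aw$weight[ord],
    stringsAsFactors = FALSE
  )
  tab$best_supported <- tab$delta < 2
  structure(
    list(response = response, n = n, table = tab, models = fits,
         skipped = if (length(skipped)) do.call(rbind, skipped)
                   else data.frame(model = character(0),
                                   reason = character(0))),
    class = "model_set"
  )
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model_set for %s (n = %d): %d candidates\n",
              x$response, x$n, nrow(x$table)))
  print(x$table, digits = 4)
  invisible(x)
}

#' 95% confidence set of models
#'
#' Smallest prefix of the AICc ranking whose cumulative Akaike weight
#' reaches `level`; the model crossing the threshold is included, so the
#' set's summed weight is always `>= level` (and the set is never empty).
#' Weights renormalized within the set (`weight_cs`) are attached for model
#' averaging.
#'
#' @param ranked A `model_set` from [fit_and_rank()].
#' @param level Cumulative-weight threshold (default 0.95).
#' @return A `model_set` restricted to the confidence set, with extra table
#'   columns `cumweight` and `weight_cs`.
#' @export
confidence_set <- function(ranked, level = 0.95) {
  stopifnot(inherits(ranked, "model_set"))
  cw <- cumsum(ranked$table$weight)
  m <- which(cw >= level)[1]
  if (is.na(m)) m <- nrow(ranked$table)
  out <- ranked
  out$table <- ranked$table[seq_len(m), , drop = FALSE]
  out$table$cumweight <- cw[seq_len(m)]
  out$table$weight_cs <- out$table$weight / sum(out$table$weight)
  out$models <- ranked$models[seq_len(m)]
  for (i in seq_len(m)) out$models[[i]]$weight_cs <- out$table$weight_cs[i]
  out
}

#' Model-averaged coefficients, unconditional SEs and importances
#'
#' Full (zero-substitution) model averaging over a confidence set: a term
#' absent from a model contributes a coefficient of 0 with zero variance.
#' With weights `w_i` renormalized within the set,
#' `beta_j = sum_i w_i * beta_ij` and the unconditional standard error is
#' `USE_j = sum_i w_i * sqrt(var(beta_ij) + (beta_ij - beta_j)^2)`
#' (Burnham-Anderson). A term's importance is the summed weight of the
#' models containing it, and it is flagged influential when the interval
#' `beta_j +/- USE_j` excludes zero.
#'
#' @param cset A `model_set`, normally from [confidence_set()]; plain
#'   ranked sets are renormalized over all their models.
#' @param terms Terms to report (default: the union of terms over the set's
#'   models). A requested term contained in no model of the set gets
#'   coefficient 0, importance 0 and is not influential.
#' @return data.frame of class `averaged_estimates` with columns term,
#'   coefficient, use, importance, influential.
#' @export
model_average <- function(cset, terms = NULL) {
  stopifnot(inherits(cset, "model_set"))
  if (length(cset$models) == 0L) stop("empty model set")
  w <- vapply(cset$models, function(m)
    if (!is.null(m$weight_cs)) m$weight_cs else m$weight, numeric(1))
  w <- w / sum(w)
  if (is.null(terms))
    terms <- unique(unlist(lapply(cset$models, `[[`, "terms")))
  if (length(terms) == 0L)
    return(structure(
      data.frame(term = character(0), coefficient = numeric(0),
                 use = numeric(0), importance = numeric(0),
                 influential = logical(0)),
      class = c("averaged_estimates", "data.frame")))
  rows <- lapply(terms, function(tm) {
    beta <- vapply(cset$models, function(m)
      if (tm %in% m$terms) unname(m$coef[tm]) else 0, numeric(1))
    v <- vapply(cset$models, function(m)
      if (tm %in% m$terms) unname(m$se[tm])^2 else 0, numeric(1))
    bbar <- sum(w * beta)
    use <- sum(w * sqrt(v + (beta - bbar)^2))
    imp <- sum(w[vapply(cset$models, function(m) tm %in% m$terms,
                        logical(1))])
    data.frame(term = tm, coefficient = bbar, use = use, importance = imp,
               influential = (bbar - use > 0) | (bbar + use < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("averaged_estimates", "data.frame")
  out
}

#' Multimodel inference for a set of global models
#'
#' For each response: screens the global model's design matrix for
#' collinearity (VIF), enumerates all term subsets plus the null model,
#' ranks them by AICc, extracts the 95% confidence set, and model-averages
#' the coefficients. A response whose global model fails the VIF screen is
#' aborted with a diagnostic (the caller must drop a term).
#'
#' @param global_specs Named list: response name -> named numeric vector of
#'   term radii, e.g. `list(alpha_q1 = c(AI = 600, PI = 1200, SF = 600))`.
#'   Term columns are named `<metric>_<radius>`.
#' @param responses data.frame with `patch_id` and the response columns
#'   (e.g. from [diversity_responses()]).
#' @param metrics data.frame from [metric_table()] holding every
#'   (metric, radius) the specs reference.
#' @param vif_threshold Collinearity threshold (default 4).
#' @return Named list of class `inference_report`; per response either
#'   `status = "ok"` with `vif`, `ranking` (`model_set`), `confidence_set`
#'   and `averaged` components, or `status = "vif_failure"` with the
#'   offending VIF table.
#' @export
run_inference <- function(global_specs, responses, metrics,
                          vif_threshold = 4) {
  out <- list()
  for (resp in names(global_specs)) {
    spec <- global_specs[[resp]]
    if (!resp %in% names(responses))
      stop("response ", resp, " absent from responses table")
    term_names <- sprintf("%s_%d", names(spec), as.integer(spec))
    data <- data.frame(patch_id = responses$patch_id,
                       stringsAsFactors = FALSE)
    data[[resp]] <- responses[[resp]]
    for (i in seq_along(spec)) {
      s <- metrics[metrics$metric == names(spec)[i] &
                     metrics$radius_m == spec[i], ]
      if (nrow(s) == 0L)
        stop("metric ", names(spec)[i], " at ", spec[i],
             " m absent from metric table")
      data[[term_names[i]]] <- s$value[match(data$patch_id, s$patch_id)]
    }
    data <- data[stats::complete.cases(data), , drop = FALSE]
    if (length(term_names) >= 2) {
      vif <- vif_screen(data[, term_names, drop = FALSE], vif_threshold)
      if (any(vif$flagged)) {
        out[[resp]] <- list(status = "vif_failure", vif = vif,
                            dropped = vif$term[vif$flagged])
        next
      }
    } else {
      vif <- data.frame(term = term_names, vif = 1, flagged = FALSE)
    }
    ranked <- fit_and_rank(enumerate_models(term_names), resp, data)
    cset <- confidence_set(ranked)
    out[[resp]] <- list(status = "ok", vif = vif, ranking = ranked,
                        confidence_set = cset,
                        averaged = model_average(cset, terms = term_names))
  }
  class(out) <- "inference_report"
  out
}

#' @export
print.inference_report <- function(x, ...) {
  for (resp in names(x)) {
    cat("==", resp, "==\n")
    if (x[[resp]]$status != "ok") {
      cat("  aborted:", x[[resp]]$status, "\n")
      next
    }
    print(x[[resp]]$averaged, digits = 3)
  }
  invisible(x)
}
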