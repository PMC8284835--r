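#' Run the full multi-scale diversity analysis pipeline
#'
#' Orchestrates the whole analysis: (1) obtain a study — either simulate one
#' from a [simulation_config()] or load raster/community/centre inputs from
#' files; (2) restrict communities to animal-dispersed species and compute
#' the Hill-number diversity table and sample coverage; (3) compute the six
#' class-level landscape metrics in the 13 nested buffers; (4) run the
#' spatial and normality diagnostics (Clark-Evans, Mantel screens,
#' Shapiro-Wilk) as gate-free reports; (5) sweep every response/predictor
#' pair for its scale of effect with leave-two-out cross-validation and
#' bootstrap the selection; (6) build per-response global models at the
#' selected scales (collinearity-pruned), rank all subsets by AICc and
#' model-average the confidence set. Every intermediate table is written as
#' CSV under `out_dir`; rerunning with the same config reproduces the files.
#'
#' @param config A `simulation_config` (used when no input paths are given;
#'   its seed drives every stochastic stage).
#' @param out_dir Output directory (created if missing).
#' @param inputs Optional named list of file paths (`raster` ASCII grid,
#'   `communities` long CSV, `centres` CSV) to analyse field data instead of
#'   simulating; all three must be given together.
#' @param radii Buffer radii (default 300-1500 m at 100 m steps).
#' @param B Bootstrap replicates for scale-selection uncertainty (default
#'   1000).
#' @param bootstrap Which pairs to bootstrap: the best predictor per
#'   response (`"best"`, default), `"all"`, or `"none"`.
#' @param permutations Permutations for the Mantel screens (default 999).
#' @return Invisibly, a list with the study, tables, profiles, bootstrap
#'   results, inference report, diagnostics and written file paths.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         inputs = NULL, radii = seq(300, 1500, by = 100),
                         B = 1000, bootstrap = c("best", "all", "none"),
                         permutations = 999) {
  bootstrap <- match.arg(bootstrap)
  if (missing(out_dir)) stop("out_dir is required")
  if (!is.null(inputs)) {
    need <- c("raster", "communities", "centres")
    if (!all(need %in% names(inputs)))
      stop("inputs must name raster, communities and centres paths")
    missing_files <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(missing_files))
      stop("missing input file(s): ", paste(missing_files, collapse = ", "))
  }
  validate_config(config)
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  log_lines <- c(
    sprintf("seedscape %s | R %s.%s", as.character(utils::packageVersion("seedscape")),
            R.version$major, R.version$minor),
    sprintf("seed: %d | bootstrap B: %d | permutations: %d",
            config$seed, B, permutations))

  ## -- stage 1: study ------------------------------------------------------
  if (is.null(inputs)) {
    study <- make_study(config)
    raster <- study$raster; centres <- study$centres; blocks <- study$blocks
    log_lines <- c(log_lines, sprintf(
      "simulated study: %d patches, planted %s @ %d m", length(blocks),
      config$focal_metric, config$true_radius))
  } else {
    raster <- read_ascii_grid(inputs$raster)
    centres <- utils::read.csv(inputs$centres, stringsAsFactors = FALSE)
    blocks <- read_community_csv(inputs$communities, centres = centres)
    study <- list(raster = raster, centres = centres, blocks = blocks,
                  config = config)
    log_lines <- c(log_lines, sprintf("loaded study: %d patches",
                                      length(blocks)))
  }
  write_ascii_grid(raster, fp("raster.asc"))
  utils::write.csv(centres, fp("centres.csv"), row.names = FALSE)
  write_community_csv(blocks, fp("communities.csv"))
  write_config(config, fp("config.yaml"))

  ## -- stage 2: diversity --------------------------------------------------
  animal <- lapply(blocks, filter_animal_dispersed)
  div <- diversity_table(animal)
  cov <- coverage_table(animal)
  responses <- diversity_responses(div)
  utils::write.csv(div, fp("diversity.csv"), row.names = FALSE)
  utils::write.csv(cov, fp("coverage.csv"), row.names = FALSE)
  log_lines <- c(log_lines, sprintf(
    "diversity: %d records; mean sample coverage %.2f%%",
    nrow(div), 100 * mean(cov$coverage)))

  ## -- stage 3: landscape metrics ------------------------------------------
  metrics <- metric_table(raster, centres, radii = radii)
  utils::write.csv(metrics, fp("metrics.csv"), row.names = FALSE)
  log_lines <- c(log_lines, sprintf("metrics: %d records", nrow(metrics)))

  ## -- stage 4: diagnostics ------------------------------------------------
  area <- nrow(raster$grid) * ncol(raster$grid) * raster$cell_size^2
  ce <- clark_evans(centres, area)
  D <- as.matrix(stats::dist(cbind(centres$x, centres$y)))
  resp_names <- grep("^(alpha|beta)_q", names(responses), value = TRUE)
  diag_rows <- list(data.frame(
    check = "clark_evans", variable = "centres", statistic = ce$R,
    p_value = ce$p_value, pass = NA, stringsAsFactors = FALSE))
  for (rn in resp_names) {
    v <- responses[[rn]]
    sw <- shapiro_screen(v)
    ds <- distance_screen(D, v, permutations = permutations,
                          seed = derive_seed(config$seed, paste0("mantel:", rn)))
    diag_rows <- c(diag_rows, list(
      data.frame(check = "shapiro", variable = rn, statistic = sw$W,
                 p_value = sw$p_value, pass = sw$pass,
                 stringsAsFactors = FALSE),
      data.frame(check = "mantel_response", variable = rn, statistic = ds$r,
                 p_value = ds$p_value, pass = ds$p_value >= 0.05,
                 stringsAsFactors = FALSE)))
  }
  diagnostics <- do.call(rbind, diag_rows)

  ## -- stage 5: scale of effect --------------------------------------------
  predictors <- c("FC", "SF", "PD", "AI", "PI", "EC")
  profiles <- scale_sweep(responses, metrics, response_names = resp_names,
                          predictor_names = predictors)
  prof_df <- do.call(rbind, lapply(profiles, function(p) data.frame(
    response = p$response, predictor = p$predictor,
    radius_m = as.numeric(names(p$r2cv)), r2cv = unname(p$r2cv),
    n = unname(p$n),
    selected = as.numeric(names(p$r2cv)) == p$selected_radius,
    stringsAsFactors = FALSE)))
  rownames(prof_df) <- NULL
  utils::write.csv(prof_df, fp("scale_profiles.csv"), row.names = FALSE)
  log_lines <- c(log_lines, sprintf(
    "scale sweep: %d single-predictor models over %d response x predictor pairs",
    attr(profiles, "n_models"), length(profiles)))

  boots <- list()
  if (bootstrap != "none") {
    for (rn in resp_names) {
      pair_names <- paste(rn, predictors, sep = ".")
      best <- vapply(profiles[pair_names], function(p)
        suppressWarnings(max(p$r2cv, na.rm = TRUE)), numeric(1))
      todo <- if (bootstrap == "all") predictors
              else predictors[which.max(best)]
      for (pred in todo) {
        rv <- data.frame(patch_id = responses$patch_id,
                         value = responses[[rn]], stringsAsFactors = FALSE)
        boots[[paste(rn, pred, sep = ".")]] <-
          bootstrap_scale(rv, metrics, pred, B = B,
                          seed = derive_seed(config$seed,
                                             paste0("boot:", rn, ":", pred)),
                          response = rn)
      }
    }
    boot_df <- do.call(rbind, lapply(names(boots), function(nm) {
      b <- boots[[nm]]
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      data.frame(response = parts[1], predictor = parts[2],
                 radius_m = as.numeric(names(b$counts)),
                 count = unname(b$counts), stringsAsFactors = FALSE)
    }))
    utils::write.csv(boot_df, fp("bootstrap_counts.csv"), row.names = FALSE)
  }

  ## -- stage 6: global models and multimodel inference ---------------------
  specs <- list()
  for (rn in resp_names) {
    sel <- vapply(predictors, function(pred)
      profiles[[paste(rn, pred, sep = ".")]]$selected_radius, numeric(1))
    terms <- sel[!is.na(sel)]
    ## collinearity pruning: drop the worst-VIF term until none is flagged
    repeat {
      if (length(terms) < 2) break
      dat <- metrics[metrics$metric %in% names(terms), ]
      X <- sapply(names(terms), function(pred) {
        s <- dat[dat$metric == pred & dat$radius_m == terms[pred], ]
        s$value[match(responses$patch_id, s$patch_id)]
      })
      X <- X[stats::complete.cases(X), , drop = FALSE]
      vf <- vif_screen(X)
      if (!any(vf$flagged)) break
      worst <- vf$term[which.max(vf$vif)]
      log_lines <- c(log_lines, sprintf(
        "global model %s: dropped %s (VIF %.1f)", rn, worst,
        max(vf$vif)))
      terms <- terms[names(terms) != worst]
    }
    specs[[rn]] <- terms
  }
  inference <- run_inference(specs, responses, metrics)
  rank_df <- do.call(rbind, lapply(names(inference), function(rn) {
    res <- inference[[rn]]
    if (res$status != "ok") return(NULL)
    cbind(response = rn, res$ranking$table, stringsAsFactors = FALSE)
  }))
  avg_df <- do.call(rbind, lapply(names(inference), function(rn) {
    res <- inference[[rn]]
    if (res$status != "ok") return(NULL)
    cbind(response = rn, as.data.frame(res$averaged),
          stringsAsFactors = FALSE)
  }))
  utils::write.csv(rank_df, fp("model_rankings.csv"), row.names = FALSE)
  utils::write.csv(avg_df, fp("averaged_estimates.csv"), row.names = FALSE)

  ## residual spatial screen of each response's global model
  for (rn in names(inference)) {
    res <- inference[[rn]]
    if (res$status != "ok") next
    full <- res$ranking$models[[which.max(vapply(res$ranking$models,
                                                 function(m) m$k,
                                                 integer(1)))]]
    if (length(full$terms) == 0L) next
    dat <- data.frame(y = responses[[rn]])
    for (tm in full$terms) {
      parts <- strsplit(tm, "_")[[1]]
      s <- metrics[metrics$metric == parts[1] &
                     metrics$radius_m == as.numeric(parts[2]), ]
      dat[[tm]] <- s$value[match(responses$patch_id, s$patch_id)]
    }
    keep <- stats::complete.cases(dat)
    if (sum(keep) < 4 || length(unique(dat$y[keep])) < 2) next
    fit <- stats::lm(y ~ ., data = dat[keep, , drop = FALSE])
    ds <- distance_screen(D[keep, keep], stats::residuals(fit),
                          permutations = permutations,
                          seed = derive_seed(config$seed,
                                             paste0("mantel_res:", rn)))
    diagnostics <- rbind(diagnostics, data.frame(
      check = "mantel_residuals", variable = rn, statistic = ds$r,
      p_value = ds$p_value, pass = ds$p_value >= 0.05,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(diagnostics, fp("diagnostics.csv"), row.names = FALSE)
  writeLines(log_lines, fp("log.txt"))

  invisible(list(study = study, diversity = div, coverage = cov,
                 responses = responses, metrics = metrics,
                 profiles = profiles, bootstraps = boots,
                 global_specs = specs, inference = inference,
                 diagnostics = diagnostics, out_dir = out_dir))
}
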