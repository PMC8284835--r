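test_that("VIF screen matches auxiliary-regression arithmetic", {
  set.seed(19)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)                 # orthogonal in expectation
  v <- vif_screen(cbind(a = x1, b = x2))
  expect_true(all(v$vif < 2))
  expect_false(any(v$flagged))
  ## duplicated predictor: infinite VIF, flagged but no error
  vdup <- vif_screen(cbind(a = x1, b = x1))
  expect_true(all(is.infinite(vdup$vif)))
  expect_true(all(vdup$flagged))
  ## three predictors with built-in correlation: oracle via lm()
  x3 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3)
  v3 <- vif_screen(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(v3$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_error(vif_screen(cbind(a = x1)), "at least 2")
  expect_error(vif_screen(cbind(a = x1, b = rep(1, n))), "constant")
})

test_that("candidate enumeration covers all subsets plus the null", {
  expect_length(enumerate_models(c("a", "b", "c")), 8)
  two <- enumerate_models(c("a", "b"))
  expect_length(two, 4)
  expect_identical(two[[1]], character(0))       # the null model
  expect_length(enumerate_models(character(0)), 1)
  expect_error(enumerate_models(letters[1:7]), "at most 6")
})

test_that("AICc ranking and Akaike weights follow the definitions", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(round(w$weight, 4), c(0.7311, 0.2689))

  set.seed(37)
  n <- 16
  dat <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n))
  dat$y <- dat$y + dat$a
  ms <- fit_and_rank(enumerate_models(c("a", "b")), "y", dat)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(ms$table$delta, ms$table$aicc - min(ms$table$aicc))
  expect_true(all(diff(ms$table$aicc) >= 0))
  expect_equal(ms$table$delta[1], 0)
  ## AICc recomputed independently from logLik for every candidate
  for (m in ms$models) {
    fml <- if (length(m$terms)) reformulate(m$terms, "y") else y ~ 1
    fit <- lm(fml, data = dat)
    k <- length(m$terms) + 2
    expect_equal(m$aicc,
                 -2 * as.numeric(logLik(fit)) + 2 * k +
                   2 * k * (k + 1) / (n - k - 1), tolerance = 1e-10)
  }
  ## small-sample correction vanishes for large n
  kk <- 3; nn <- 1e6
  expect_lt(2 * kk * (kk + 1) / (nn - kk - 1), 1e-3)
  ## candidates too rich for the sample size are skipped with a reason
  small <- data.frame(y = rnorm(5), a = rnorm(5), b = rnorm(5), c = rnorm(5))
  ms2 <- fit_and_rank(enumerate_models(c("a", "b", "c")), "y", small)
  expect_true("a + b + c" %in% ms2$skipped$model)
  expect_false("a + b + c" %in% ms2$table$model)
})

test_that("confidence sets take the smallest prefix reaching 95%", {
  mk <- function(w) {
    k <- length(w)
    fake_model_set(lapply(seq_len(k), function(i) paste0("t", i)),
                   replicate(k, c(t = 1), simplify = FALSE),
                   replicate(k, c(t = 0.1), simplify = FALSE), w)
  }
  expect_equal(nrow(confidence_set(mk(c(0.5, 0.3, 0.15, 0.05)))$table), 3)
  expect_equal(nrow(confidence_set(mk(rep(1 / 8, 8)))$table), 8)
  expect_equal(nrow(confidence_set(mk(c(0.97, 0.03)))$table), 1)
  cs <- confidence_set(mk(c(0.5, 0.3, 0.15, 0.05)))
  expect_equal(sum(cs$table$weight_cs), 1, tolerance = 1e-12)
})

test_that("model averaging follows the full-averaging identities", {
  ## single-model set: estimates pass through
  one <- fake_model_set(list("a"), list(c(`(Intercept)` = 0, a = 1.5)),
                        list(c(`(Intercept)` = 0.2, a = 0.3)), 1)
  avg1 <- model_average(one)
  expect_equal(avg1$coefficient[avg1$term == "a"], 1.5)
  expect_equal(avg1$use[avg1$term == "a"], 0.3)
  expect_equal(avg1$importance[avg1$term == "a"], 1)
  expect_true(avg1$influential[avg1$term == "a"])

  ## two equal-weight models, term only in the first: full average halves it
  two <- fake_model_set(list("a", character(0)),
                        list(c(`(Intercept)` = 0, a = 1),
                             c(`(Intercept)` = 0)),
                        list(c(`(Intercept)` = 0.1, a = 0.2),
                             c(`(Intercept)` = 0.1)),
                        c(0.5, 0.5))
  avg2 <- model_average(two)
  expect_equal(avg2$coefficient[avg2$term == "a"], 0.5)
  expect_equal(avg2$importance[avg2$term == "a"], 0.5)
  ## USE = 0.5*sqrt(0.04 + 0.25) + 0.5*sqrt(0 + 0.25)
  expect_equal(avg2$use[avg2$term == "a"],
               0.5 * sqrt(0.04 + 0.25) + 0.5 * 0.5, tolerance = 1e-12)

  ## a requested term in no model: zero everywhere, not influential
  avg3 <- model_average(one, terms = c("a", "ghost"))
  g <- avg3[avg3$term == "ghost", ]
  expect_equal(g$coefficient, 0)
  expect_equal(g$importance, 0)
  expect_false(g$influential)

  ## averaged magnitude never exceeds the largest within-set magnitude
  set.seed(50)
  for (i in 1:20) {
    w <- runif(3); w <- w / sum(w)
    betas <- rnorm(3)
    ms <- fake_model_set(list("a", "a", "a"),
                         lapply(betas, function(b) c(`(Intercept)` = 0, a = b)),
                         replicate(3, c(`(Intercept)` = 0.1, a = 0.1),
                                   simplify = FALSE), w)
    avg <- model_average(ms)
    expect_lte(abs(avg$coefficient[1]), max(abs(betas)) + 1e-12)
  }
})

test_that("duplicating a candidate changes no averaged estimate", {
  set.seed(73)
  n <- 16
  dat <- data.frame(a = rnorm(n), b = rnorm(n))
  dat$y <- 1 + 0.8 * dat$a + rnorm(n, sd = 0.3)
  base <- fit_and_rank(enumerate_models(c("a", "b")), "y", dat)
  dup <- fit_and_rank(c(enumerate_models(c("a", "b")), list("a")), "y", dat)
  expect_equal(dup$table, base$table)   # the candidate list is a set
  avg_base <- model_average(confidence_set(base, level = 1))
  avg_dup <- model_average(confidence_set(dup, level = 1))
  avg_dup <- avg_dup[match(avg_base$term, avg_dup$term), ]
  expect_equal(avg_base$coefficient, avg_dup$coefficient, tolerance = 1e-10)
  expect_equal(avg_base$use, avg_dup$use, tolerance = 1e-10)
  ## hand-constructed duplicates with explicitly equal weights also cancel
  m1 <- c(`(Intercept)` = 0, a = 1); s1 <- c(`(Intercept)` = 0.1, a = 0.2)
  single <- fake_model_set(list("a"), list(m1), list(s1), 1)
  twice <- fake_model_set(list("a", "a"), list(m1, m1), list(s1, s1),
                          c(0.5, 0.5))
  expect_equal(model_average(twice), model_average(single))
})

test_that("run_inference builds, screens and averages per response", {
  set.seed(29)
  ids <- paste0("P", 1:16)
  x1 <- rnorm(16); x2 <- rnorm(16); x3 <- rnorm(16)
  mt <- rbind(
    data.frame(patch_id = ids, radius_m = 600, metric = "AI", value = x1),
    data.frame(patch_id = ids, radius_m = 1200, metric = "PI", value = x2),
    data.frame(patch_id = ids, radius_m = 600, metric = "SF", value = x3),
    data.frame(patch_id = ids, radius_m = 500, metric = "PD", value = x2),
    data.frame(patch_id = ids, radius_m = 500, metric = "AI", value = x1))
  responses <- data.frame(patch_id = ids,
                          alpha_q0 = 2 + x1 + rnorm(16, sd = 0.2),
                          beta_q2 = 1 + 0.5 * x2 + rnorm(16, sd = 0.2))
  specs <- list(alpha_q0 = c(AI = 600, PI = 1200, SF = 600),
                beta_q2 = c(AI = 500, PD = 500))
  rep <- run_inference(specs, responses, mt)
  ## three-term global model -> 8 candidates; two-term -> 4
  expect_equal(nrow(rep$alpha_q0$ranking$table), 8)
  expect_equal(nrow(rep$beta_q2$ranking$table), 4)
  expect_equal(sum(rep$alpha_q0$ranking$table$weight), 1, tolerance = 1e-12)
  expect_setequal(rep$alpha_q0$averaged$term,
                  c("AI_600", "PI_1200", "SF_600"))
  expect_true(rep$alpha_q0$averaged$influential[
    rep$alpha_q0$averaged$term == "AI_600"])
  ## perfectly collinear global model aborts with a diagnostic
  mt2 <- rbind(mt, data.frame(patch_id = ids, radius_m = 700, metric = "FC",
                              value = x1))
  rep2 <- run_inference(list(alpha_q0 = c(AI = 600, FC = 700)), responses, mt2)
  expect_equal(rep2$alpha_q0$status, "vif_failure")
  expect_true(any(is.infinite(rep2$alpha_q0$vif$vif)))
})
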