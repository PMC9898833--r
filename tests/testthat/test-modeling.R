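cohort_from_codes <- function(x, outcome, kinds = NULL) {
  x <- as.matrix(x)
  if (is.null(kinds)) kinds <- rep("ordinal", ncol(x))
  toy_cohort(x, outcome, kinds = kinds)
}

test_that("chi-square filter matches the brute-force statistic and rules", {
  # independent 2x2 table -> chi2 = 0, P = 1, excluded
  x <- c(rep(0, 50), rep(1, 50))
  y <- rep(c(0, 1), 50)
  co <- cohort_from_codes(cbind(v = x), y, "diagnosis")
  tr <- chi_square_filter(co, alpha = 0.10)
  tests <- attr(tr, "tests")
  expect_equal(tests$statistic, 0)
  expect_equal(tests$p, 1)
  expect_equal(tr$chi_square_excluded$variable, "v")
  # association table [[30,10],[10,30]]: all expected counts 20, chi2 = 20
  x2 <- c(rep(0, 40), rep(1, 40))
  y2 <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  co2 <- cohort_from_codes(cbind(v = x2), y2, "diagnosis")
  tr2 <- chi_square_filter(co2)
  t2 <- attr(tr2, "tests")
  expect_equal(t2$statistic, 20.0)
  expect_equal(t2$df, 1)
  expect_lt(t2$p, 0.10)
  expect_equal(tr2$candidates, "v")
  # three-level variable reports df = 2
  set.seed(1)
  x3 <- sample(0:2, 120, replace = TRUE)
  y3 <- rbinom(120, 1, 0.5)
  co3 <- cohort_from_codes(cbind(v = x3), y3)
  expect_equal(attr(chi_square_filter(co3), "tests")$df, 2)
  # brute-force equivalence on random tables
  for (trial in 1:10) {
    xx <- sample(0:2, 90, replace = TRUE)
    yy <- rbinom(90, 1, 0.4 + 0.2 * (xx == 2))
    if (length(unique(yy)) < 2) next
    coi <- cohort_from_codes(cbind(v = xx), yy)
    got <- attr(chi_square_filter(coi), "tests")$statistic
    expect_equal(got, chisq_bruteforce(table(xx, yy)), tolerance = 1e-10)
  }
})

test_that("zero-margin levels are dropped and noted", {
  x <- c(rep(0, 30), rep(2, 30))   # level 1 never occurs
  y <- c(rbinom(30, 1, 0.2), rbinom(30, 1, 0.8))
  co <- cohort_from_codes(cbind(v = x), y)
  tests <- attr(chi_square_filter(co), "tests")
  expect_equal(tests$df, 1)
})

test_that("univariate logistic filter: Wald OR/CI geometry and null exclusion", {
  set.seed(2)
  n <- 600
  signal <- sample(0:2, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-1 + 1 * signal))
  noise <- sample(0:2, n, replace = TRUE)
  co <- cohort_from_codes(cbind(sig = signal, noise = noise), y)
  tr <- univariate_lr_filter(co, variables = c("sig", "noise"))
  tests <- attr(tr, "tests")
  expect_true("sig" %in% tr$candidates)
  expect_true("noise" %in% tr$univariate_excluded$variable)
  # CI endpoints are exp(beta +- 1.96 se): symmetric on the log scale
  row <- tests[tests$variable == "sig", ]
  expect_equal(log(row$ci_high) - log(row$or), log(row$or) - log(row$ci_low),
               tolerance = 1e-9)
  expect_gt(row$or, 1)
})

test_that("a perfectly separated univariate fit is flagged, not P-judged", {
  y <- rep(c(0, 1), each = 5)
  co <- cohort_from_codes(cbind(v = y), y, "diagnosis")
  tr <- univariate_lr_filter(co, variables = "v")
  expect_equal(tr$separation_flagged, "v")
  expect_false("v" %in% tr$univariate_excluded$variable)
  expect_true("v" %in% tr$candidates)
})

test_that("expert reintroduction respects the exclusion history", {
  set.seed(3)
  x <- matrix(sample(0:2, 300 * 9, replace = TRUE), 300, 9,
              dimnames = list(NULL, paste0("v", 1:9)))
  y <- rbinom(300, 1, 0.5)
  co <- cohort_from_codes(x, y)
  tr <- chi_square_filter(co)
  tr <- univariate_lr_filter(co, trace = tr)
  excluded <- c(tr$chi_square_excluded$variable, tr$univariate_excluded$variable)
  expect_gte(length(excluded), 2)  # null variables: most fail both filters
  expect_identical(reintroduce(tr, character()), tr)
  back <- excluded[1:2]
  tr2 <- reintroduce(tr, back)
  expect_setequal(tr2$reintroduced, back)
  expect_true(all(back %in% tr2$candidates))
  expect_equal(length(tr2$candidates), length(tr$candidates) + 2)
  kept <- setdiff(colnames(x), excluded)[1]
  expect_error(reintroduce(tr, kept), "never excluded")
})

test_that("multivariate logistic fit reports ORs, CIs and diagnostics", {
  set.seed(4)
  n <- 2000
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_multivariate_lr(x = x, outcome = y)
  expect_s3_class(fit, "lr_fit")
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
  expect_equal(fit$odds_ratios, c(1, 1), tolerance = 0.15)
  expect_equal(fit$intercept, 0, tolerance = 0.15)
  expect_true(all(fit$ci_low <= fit$odds_ratios))
  expect_true(all(fit$ci_high >= fit$odds_ratios))
  expect_equal(exp(fit$coefficients), fit$odds_ratios)
  expect_error(fit_multivariate_lr(x = data.frame(a = rep(1, 10)),
                                   outcome = rep(c(0, 1), 5)),
               "zero variance")
  # coef/summary/predict methods
  expect_length(coef(fit), 3)
  expect_equal(nrow(summary(fit)), 2)
  expect_true(all(predict(fit, x[1:5, ]) >= 0 & predict(fit, x[1:5, ]) <= 1))
})

test_that("bootstrap CIs are percentile intervals across refits", {
  set.seed(5)
  n <- 300
  x <- data.frame(a = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * x$a))
  fit <- fit_multivariate_lr(x = x, outcome = y, ci_method = "bootstrap",
                             B = 30, seed = 1)
  expect_true(fit$ci_low < fit$odds_ratios && fit$odds_ratios < fit$ci_high)
})

test_that("separation detection trips on separable data and respects thresholds", {
  y <- rep(c(0, 1), each = 5)
  sep_fit <- fit_multivariate_lr(x = data.frame(v = y), outcome = y)
  expect_true(sep_fit$separation_flag)
  expect_gt(abs(sep_fit$coefficients[1]), 10)
  null_fit <- fit_multivariate_lr(x = data.frame(v = rnorm(200)),
                                  outcome = rbinom(200, 1, 0.5))
  expect_false(detect_separation(null_fit))
  expect_warning(flag <- detect_separation(sep_fit, threshold = Inf),
                 "never")
  expect_false(flag)
})

test_that("forward group selection keeps signal and rejects noise", {
  set.seed(6)
  n <- 400
  a1 <- rnorm(n); a2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * a1 + 1.5 * a2 - 0.5))
  noise <- matrix(rnorm(n * 2), n, 2)
  x <- cbind(a1 = a1, a2 = a2, n1 = noise[, 1], n2 = noise[, 2])
  co <- toy_cohort(x, y, kinds = rep("continuous", 4))
  groups <- list(signal = c("a1", "a2"), noise = c("n1", "n2"))
  tr <- forward_group_selection(co, groups, B = 20, seed = 1)
  expect_setequal(tr$final_variables, c("a1", "a2"))
  path <- tr$forward_path
  expect_equal(path$group[1], "signal")
  expect_false(path$accepted[path$group == "noise"])
  # accepted steps never decrease the recorded best AUROC
  accepted <- path[path$accepted, ]
  expect_true(all(diff(accepted$auroc_after) >= 0 | nrow(accepted) < 2))
})

test_that("degenerate group configurations behave per contract", {
  set.seed(7)
  n <- 200
  a <- rnorm(n)
  y <- rbinom(n, 1, plogis(a))
  co <- toy_cohort(cbind(a = a), y, kinds = "continuous")
  tr <- forward_group_selection(co, list(only = "a"), B = 10, seed = 1)
  expect_equal(tr$final_variables, "a")
  # duplicated group adds nothing: rejected under strict improvement
  tr2 <- forward_group_selection(co, list(g1 = "a", g2 = "a"), B = 10, seed = 1)
  expect_equal(tr2$final_variables, "a")
  expect_false(tr2$forward_path$accepted[2])
})

test_that("pc regression converges where the raw sparse fit separates", {
  # rare arrest-style diagnoses occur only in positives (quasi-complete
  # separation); the bulk of the variance sits in common diagnoses, so the
  # cumulative-variance rule truncates the separating directions
  spec <- cohort_spec(n_pos = 150, n_neg = 850, n_continuous = 0,
                      n_discrete = 0, n_diagnosis = 20,
                      diagnosis_prevalence = c(0.2, 0.2, rep(0.4, 18)),
                      diagnosis_effect = c(0, 0, rep(0.5, 18)),
                      separating_vars = c("dx_01", "dx_02"), seed = 61)
  co <- generate_cohort(spec)
  xd <- co$observed
  raw <- fit_multivariate_lr(x = as.data.frame(xd), outcome = co$outcome)
  expect_true(raw$separation_flag)
  model <- pca_fit(xd)
  model$k <- select_k(model, 0.982)
  scores <- pc_transform(model, xd)
  pr <- pc_regression(scores, co$outcome, model)
  expect_false(pr$fit$separation_flag)
  expect_true(pr$fit$converged)
  expect_true(all(abs(log(pr$fit$odds_ratios)) < 10))
  expect_true(all(is.finite(pr$fit$odds_ratios)))
})

test_that("pc regression interprets significant components via loadings", {
  set.seed(8)
  n <- 800
  # single discriminating direction: dx_a and dx_b rise together in positives
  y <- rbinom(n, 1, 0.4)
  latent <- rbinom(n, 1, 0.15 + 0.5 * y)
  x <- cbind(dx_a = latent, dx_b = latent * rbinom(n, 1, 0.9),
             dx_c = rbinom(n, 1, 0.3))
  model <- pca_fit(x)
  model$k <- ncol(x)
  scores <- pc_transform(model, x)
  pr <- pc_regression(scores, y, model, top_m = 2)
  expect_true(length(pr$significant_components) >= 1)
  top <- pr$interpretation[[paste0("PC", pr$significant_components[1])]]
  expect_true(all(c("dx_a", "dx_b") %in% top$variable))
  # outcome independent of features -> ORs near 1
  y0 <- rbinom(n, 1, 0.5)
  pr0 <- pc_regression(scores, y0, model)
  expect_equal(pr0$pc_table$or, rep(1, 3), tolerance = 0.25)
})

test_that("model zoo tunes by CV, is seeded, and nails separable data", {
  co <- generate_cohort(cohort_spec(n_pos = 120, n_neg = 180,
                                    n_continuous = 4, n_discrete = 0,
                                    n_diagnosis = 0, effect_sizes = 3,
                                    seed = 62))
  zoo <- train_model_zoo(co, B = 5, seed = 1)
  for (m in names(zoo)) {
    expect_gt(zoo[[m]]$eval$metrics["mean", "auroc"], 0.95)
  }
  zoo2 <- train_model_zoo(co, models = c("lasso", "rf"), B = 5, seed = 1)
  expect_identical(zoo$lasso$best_params, zoo2$lasso$best_params)
  expect_identical(zoo$rf$best_params, zoo2$rf$best_params)
  # grid of size 1 equals the direct fit under the same evaluation
  grid1 <- list(lasso = list(list(lambda = 0.01)))
  z1 <- train_model_zoo(co, models = "lasso", grids = grid1, B = 5, seed = 3)
  expect_equal(z1$lasso$best_params$lambda, 0.01)
})
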