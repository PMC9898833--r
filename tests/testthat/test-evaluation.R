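test_that("auroc equals exhaustive pairwise concordance, ties count half", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.6, 0.6), c(1, 0)), 0.5)
  # 3 pos / 3 neg with one inversion: 8 of 9 concordant pairs
  expect_equal(auroc(c(0.9, 0.8, 0.35, 0.4, 0.3, 0.2), c(1, 1, 1, 0, 0, 0)),
               8 / 9)
  set.seed(1)
  for (trial in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)   # rounding forces frequent ties
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auroc agrees with an independent ROC implementation", {
  set.seed(11)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, plogis(scores))
  labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-10)
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(2)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(qlogis(plogis(scores)), labels), a, tolerance = 1e-12)
  expect_equal(auroc(rank(scores, ties.method = "average"), labels), a)
})

test_that("auprc integrates the precision envelope", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # single positive ranked second among 3: recall jumps 0 -> 1 at precision 1/2
  expect_equal(auprc(c(0.9, 0.5, 0.1), c(0, 1, 0)), 0.5)
  # random-ish sanity: AUPRC of a perfect inverse ranking equals prevalence-ish
  set.seed(3)
  p <- runif(200)
  y <- rbinom(200, 1, p)
  if (length(unique(y)) == 2) expect_gt(auprc(p, y), mean(y))
})

test_that("recall, precision and F1 follow their definitions", {
  pred <- c(1, 1, 0, 0, 1)
  y <- c(1, 0, 1, 0, 1)
  expect_equal(recall_score(pred, y), 2 / 3)
  expect_equal(precision_score(pred, y), 2 / 3)
  expect_equal(f1_score(pred, y), 2 / 3)
  expect_equal(f1_score(rep(0, 5), y), 0)
})

test_that("brier score: exact closed forms and input validation", {
  expect_equal(brier(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(brier(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  expect_equal(brier(c(0.8, 0.3), c(1, 0)), 0.065)
  # constant predictor p on prevalence pi: pi (1-p)^2 + (1-pi) p^2
  set.seed(4)
  y <- rbinom(400, 1, 0.3)
  pi_ <- mean(y)
  p <- 0.4
  expect_equal(brier(rep(p, 400), y), pi_ * (1 - p)^2 + (1 - pi_) * p^2,
               tolerance = 1e-12)
  expect_error(brier(c(1.2, 0.5), c(1, 0)), "probabilities")
})

test_that("reliability curves bin predictions against observed fractions", {
  set.seed(5)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)   # perfectly calibrated by construction
  curve <- reliability_curve(p, y, n_bins = 10)
  expect_equal(sum(curve$n), 5000)
  expect_true(all(curve$observed_fraction >= 0 & curve$observed_fraction <= 1))
  expect_lt(max(abs(curve$mean_predicted - curve$observed_fraction)), 0.08)
  # all probabilities in one bin
  one <- reliability_curve(rep(0.55, 20), rbinom(20, 1, 0.5), n_bins = 10)
  expect_equal(nrow(one), 1)
  expect_equal(length(attr(one, "omitted_bins")), 9)
  # n_bins = 1 recovers the prevalence
  single <- reliability_curve(p, y, n_bins = 1)
  expect_equal(single$observed_fraction, mean(y))
})

test_that("subsample evaluation: perfect scorer, degenerate B, stratification", {
  set.seed(6)
  y <- c(rep(1, 30), rep(0, 70))
  x <- data.frame(z = y + rnorm(100, sd = 1e-4))
  perfect_spec <- function(x_train, y_train) function(x_new) plogis(50 * x_new$z - 25)
  s <- subsample_evaluate(perfect_spec, x, y, B = 10, seed = 1)
  expect_equal(unname(s$metrics["mean", "auroc"]), 1.0)
  expect_equal(unname(s$metrics["ci_low", "auroc"]), 1.0)
  expect_equal(unname(s$metrics["ci_high", "auroc"]), 1.0)
  s1 <- subsample_evaluate(perfect_spec, x, y, B = 1, seed = 2)
  expect_equal(unname(s1$metrics["mean", "f1"]),
               unname(s1$metrics["ci_low", "f1"]))
  expect_equal(unname(s1$metrics["mean", "f1"]),
               unname(s1$metrics["ci_high", "f1"]))
  expect_error(subsample_evaluate(perfect_spec, x, rep(1, 100), B = 2),
               "both classes")
})

test_that("random scores give chance-level AUROC over repeats", {
  set.seed(7)
  y <- rbinom(400, 1, 0.3); y[1:2] <- c(0, 1)
  x <- data.frame(noise = rnorm(400))
  rand_spec <- function(x_train, y_train) function(x_new) runif(nrow(x_new))
  s <- subsample_evaluate(rand_spec, x, y, B = 40, seed = 3)
  expect_equal(unname(s$metrics["mean", "auroc"]), 0.5, tolerance = 0.05)
})

test_that("stratified splits preserve class counts within rounding", {
  y <- c(rep(1, 25), rep(0, 75))
  x <- data.frame(a = rnorm(100))
  spec <- function(x_train, y_train) {
    expect_equal(sum(y_train == 1), round(0.7 * 25))
    expect_equal(sum(y_train == 0), round(0.7 * 75))
    function(x_new) runif(nrow(x_new))
  }
  invisible(subsample_evaluate(spec, x, y, B = 3, seed = 4))
})

test_that("ratio experiment: balanced cohorts collapse across ratios", {
  co <- generate_cohort(cohort_spec(n_pos = 150, n_neg = 150,
                                    n_continuous = 3, n_discrete = 0,
                                    n_diagnosis = 0, effect_sizes = 1,
                                    seed = 51))
  ex <- ratio_experiment(co, ratios = list(c(1, 1)), seed = 1, B = 0)
  # at 1:1 on already-balanced data the sampled and original datasets have
  # the same size, so metrics agree closely
  expect_equal(ex$table["1:1", "n_train"], ex$table["original", "n_train"])
  expect_equal(ex$table["1:1", "auroc"], ex$table["original", "auroc"],
               tolerance = 0.05)
})

test_that("undersampled training raises recall but hurts calibration", {
  co <- generate_cohort(cohort_spec(n_pos = 150, n_neg = 2850,
                                    n_continuous = 4, n_discrete = 0,
                                    n_diagnosis = 0, effect_sizes = 1.2,
                                    seed = 52))
  ex <- ratio_experiment(co, ratios = list(c(1, 1)), seed = 2, B = 0)
  t11 <- ex$table["1:1", ]
  tor <- ex$table["original", ]
  expect_gte(t11$recall, tor$recall)
  expect_gt(t11$brier, tor$brier)
  # the test set is untouched by the rebalancing: original-ratio prevalence
  expect_equal(length(ex$test_rows), round(0.3 * 150) + round(0.3 * 2850))
})
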