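make_diag_cohort <- function(mat, outcome) {
  toy_cohort(mat, outcome, kinds = rep("diagnosis", ncol(mat)))
}

test_that("synonym merging ORs indicator sets and logs every rename", {
  n <- 10
  m <- matrix(0, n, 3, dimnames = list(NULL, c("mi_a", "mi_b", "other")))
  m[c(1, 3), "mi_a"] <- 1
  m[c(3, 7), "mi_b"] <- 1
  m[2, "other"] <- 1
  co <- make_diag_cohort(m, rep(c(0, 1), 5))
  merged <- merge_synonyms(co, data.frame(original = c("mi_a", "mi_b"),
                                          unified = "mi"))
  expect_equal(colnames(merged$observed), c("mi", "other"))
  expect_equal(which(merged$observed[, "mi"] == 1), c(1L, 3L, 7L))
  log <- attr(merged, "merge_log")
  expect_equal(nrow(log), 2)
  expect_setequal(log$original, c("mi_a", "mi_b"))
})

test_that("empty mapping is the identity and unknown names error", {
  co <- make_diag_cohort(matrix(0, 4, 2, dimnames = list(NULL, c("a", "b"))),
                         c(0, 1, 0, 1))
  out <- merge_synonyms(co, data.frame(original = character(),
                                       unified = character()))
  expect_identical(out$observed, co$observed)
  expect_error(merge_synonyms(co, data.frame(original = "zzz", unified = "u")),
               "zzz")
})

test_that("many-to-few mapping produces the unified column count", {
  m <- matrix(rbinom(60, 1, 0.3), 10, 6,
              dimnames = list(NULL, paste0("d", 1:6)))
  co <- make_diag_cohort(m, rep(c(0, 1), 5))
  mapping <- data.frame(original = paste0("d", 1:6),
                        unified = rep(c("u1", "u2"), each = 3))
  merged <- merge_synonyms(co, mapping)
  expect_equal(ncol(merged$observed), 2)
  expect_setequal(colnames(merged$observed), c("u1", "u2"))
  # OR semantics: unified column set wherever any synonym was set
  expect_equal(merged$observed[, "u1"],
               as.numeric(rowSums(m[, 1:3]) > 0), ignore_attr = TRUE)
})

test_that("missingness filter drops at the threshold boundary (>=)", {
  n <- 100
  fracs <- c(0.0, 0.5, 0.79, 0.80, 1.0)
  m <- sapply(fracs, function(f) {
    x <- rnorm(n)
    if (f > 0) x[seq_len(round(f * n))] <- NA
    x
  })
  colnames(m) <- paste0("v", 1:5)
  co <- toy_cohort(m, rep(c(0, 1), n / 2), kinds = rep("continuous", 5))
  rep <- filter_missingness(co, threshold = 0.8)
  expect_equal(rep$kept, c("v1", "v2", "v3"))
  expect_setequal(rep$dropped$variable, c("v4", "v5"))
  expect_equal(rep$dropped$value[rep$dropped$variable == "v4"], 0.80)
  # boundary in the small: 8 of 10 missing at threshold 0.8 -> dropped
  m10 <- cbind(v = c(rep(NA, 8), 1, 2))
  co10 <- toy_cohort(m10, rep(c(0, 1), 5), kinds = "continuous")
  expect_equal(filter_missingness(co10, 0.8)$dropped$variable, "v")
  expect_equal(nrow(filter_missingness(co10, 0.81)$dropped), 0)
})

test_that("prevalence filter is strict and supports per-class denominators", {
  n <- 100
  m <- cbind(p02 = c(rep(1, 2), rep(0, 98)),
             p05 = c(rep(1, 5), rep(0, 95)),
             p06 = c(rep(1, 6), rep(0, 94)),
             p50 = rep(c(1, 0), 50),
             zero = rep(0, 100))
  co <- make_diag_cohort(m, rep(c(0, 1), 50))
  rep <- filter_prevalence(co, threshold = 0.05, per_class = FALSE)
  expect_setequal(rep$kept, c("p06", "p50"))
  expect_true(all(c("p02", "p05", "zero") %in% rep$dropped$variable))
  # exactly 5% is dropped: the rule is strictly more than 5% of the population
  expect_true("p05" %in% rep$dropped$variable)
})

test_that("per-class prevalence keeps diagnoses concentrated in the rare class", {
  set.seed(1)
  outcome <- c(rep(1, 50), rep(0, 950))
  # 20% of positives, none of negatives: 1% overall but clearly positive-linked
  rare_dx <- c(rbinom(50, 1, 0.2), rep(0, 950))
  common <- rbinom(1000, 1, 0.3)
  co <- make_diag_cohort(cbind(rare_dx = rare_dx, common = common), outcome)
  overall <- filter_prevalence(co, 0.05, per_class = FALSE)
  per_class <- filter_prevalence(co, 0.05, per_class = TRUE)
  expect_false("rare_dx" %in% overall$kept)
  expect_true("rare_dx" %in% per_class$kept)
  expect_true("common" %in% per_class$kept)
})

test_that("prevalence filter rejects non-binary variables and keeps labs", {
  co <- toy_cohort(cbind(lab = rnorm(10), dx = rbinom(10, 1, 0.5)),
                   rep(c(0, 1), 5), kinds = c("continuous", "diagnosis"))
  rep <- filter_prevalence(co, 0.05)
  expect_true("lab" %in% rep$kept)
  bad <- toy_cohort(cbind(dx = c(0, 1, 2, rep(0, 7))), rep(c(0, 1), 5),
                    kinds = "diagnosis")
  expect_error(filter_prevalence(bad), "non-binary")
})

test_that("filters never modify cell values, only column membership", {
  co <- generate_cohort(cohort_spec(n_pos = 30, n_neg = 70, n_continuous = 3,
                                    n_discrete = 1, n_diagnosis = 3,
                                    missing_rate = 0.3, seed = 21))
  rep <- filter_missingness(co, 0.5)
  out <- apply_screen(co, rep)
  expect_equal(out$observed, co$observed[, rep$kept, drop = FALSE])
  rep2 <- filter_prevalence(co, 0.05)
  out2 <- apply_screen(co, rep2)
  expect_equal(out2$observed, co$observed[, rep2$kept, drop = FALSE])
})

test_that("L/N/H discretization follows the reference range with inclusive bounds", {
  # potassium reference range 3.5-5.1, serum albumin 35-51
  m <- cbind(potassium = c(3.0, 3.5, 5.1, 5.2, NA),
             albumin = c(60, 34.9, 40, 51, 35))
  co <- emr_cohort(m, c(1, 0, 1, 0, 1),
                   data.frame(name = c("potassium", "albumin"),
                              kind = "continuous",
                              ref_low = c(3.5, 35), ref_high = c(5.1, 51),
                              synonym_group = c("potassium", "albumin"),
                              impute_exclude = FALSE))
  out <- discretize_lnh(co)
  expect_equal(out$observed[, "potassium"], c(0, 1, 1, 2, NA),
               ignore_attr = TRUE)
  expect_equal(out$observed[, "albumin"], c(2, 0, 1, 1, 1), ignore_attr = TRUE)
  expect_true(all(out$meta$kind == "ordinal"))
  # mask unchanged; missing stays missing
  expect_identical(out$mask, co$mask)
  # re-applying is a no-op because the kind check skips ordinal columns
  again <- discretize_lnh(out)
  expect_identical(again$observed, out$observed)
})

test_that("discretization demands a reference range and caps codes at 3 levels", {
  co <- toy_cohort(cbind(x = rnorm(50)), rep(c(0, 1), 25), kinds = "continuous")
  expect_error(discretize_lnh(co), "x")
  co2 <- toy_cohort(cbind(x = rnorm(50)), rep(c(0, 1), 25),
                    kinds = "continuous", ref_low = -0.5, ref_high = 0.5)
  out <- discretize_lnh(co2)
  expect_lte(length(unique(out$observed[, 1])), 3)
  expect_true(all(out$observed[, 1] %in% 0:2))
})

test_that("merging before filtering equals filtering the merged matrix", {
  set.seed(3)
  m <- matrix(rbinom(300, 1, 0.2), 50, 6, dimnames = list(NULL, paste0("d", 1:6)))
  co <- make_diag_cohort(m, rep(c(0, 1), 25))
  mapping <- data.frame(original = c("d1", "d2"), unified = "u")
  a <- filter_prevalence(merge_synonyms(co, mapping), 0.05)
  merged <- merge_synonyms(co, mapping)
  b <- filter_prevalence(merged, 0.05)
  expect_identical(a$kept, b$kept)
})
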