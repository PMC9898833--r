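#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counting one half — computed from mean
#' ranks (Mann-Whitney form), which is exactly the pairwise concordance.
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  check_binary_labels(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)  # mean ranks give ties weight 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_binary_labels <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  invisible(TRUE)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration using the precision envelope (the running maximum
#' of precision from high recall down), which avoids the optimistic bias
#' of linear interpolation in precision-recall space.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_binary_labels(labels, scores)
  # group tied scores so a threshold never splits equal scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(labels == 1)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # envelope: best precision achievable at or beyond each recall level
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Classification metrics at a probability threshold
#'
#' @param predictions 0/1 predicted classes.
#' @param labels 0/1 true classes.
#' @return `recall_score`: TP / (TP + FN); `precision_score`:
#'   TP / (TP + FP); `f1_score`: harmonic mean of the two (0 when both
#'   are 0).
#' @export
recall_score <- function(predictions, labels) {
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == 0 & labels == 1)
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' @rdname recall_score
#' @export
precision_score <- function(predictions, labels) {
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  if (tp + fp == 0) return(0)
  tp / (tp + fp)
}

#' @rdname recall_score
#' @export
f1_score <- function(predictions, labels) {
  p <- precision_score(predictions, labels)
  r <- recall_score(predictions, labels)
  if (is.na(r) || p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the 0/1
#' outcome; lower is better calibrated.
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param labels 0/1 outcomes.
#' @return the Brier score.
#' @export
brier <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels differ in length")
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  mean((probabilities - labels)^2)
}

#' Reliability (calibration) curve
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on \[0, 1\]
#' and reports, per non-empty bin, the mean predicted probability and the
#' observed event fraction. Empty bins are omitted and listed in the
#' `"omitted_bins"` attribute.
#'
#' @inheritParams brier
#' @param n_bins number of equal-width bins.
#' @return data frame with `bin_midpoint`, `mean_predicted`,
#'   `observed_fraction`, `n`.
#' @export
reliability_curve <- function(probabilities, labels, n_bins = 10) {
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(probabilities, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- lapply(seq_len(n_bins), function(b) {
    in_bin <- bin == b
    if (!any(in_bin)) return(NULL)
    data.frame(bin_midpoint = mids[b],
               mean_predicted = mean(probabilities[in_bin]),
               observed_fraction = mean(labels[in_bin]),
               n = sum(in_bin))
  })
  empty <- which(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "omitted_bins") <- mids[empty]
  out
}

#' Logistic-regression model specification for evaluators
#'
#' Returns a fitter closure of the signature the evaluation protocol
#' expects: `function(x_train, y_train)` returning a prediction function
#' `function(x_new) -> probabilities`.
#'
#' @param variables optional column subset used by the fit.
#' @return a model-spec function.
#' @export
model_logistic <- function(variables = NULL) {
  function(x_train, y_train) {
    x_train <- as.data.frame(x_train)
    if (!is.null(variables)) x_train <- x_train[, variables, drop = FALSE]
    dat <- cbind(x_train, .y = y_train)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    function(x_new) {
      x_new <- as.data.frame(x_new)
      if (!is.null(variables)) x_new <- x_new[, variables, drop = FALSE]
      suppressWarnings(
        as.numeric(stats::predict(fit, newdata = x_new, type = "response")))
    }
  }
}

stratified_split <- function(labels, train_fraction, seed) {
  set.seed(seed)
  train <- integer(0)
  for (cl in c(0, 1)) {
    rows <- which(labels == cl)
    n_tr <- round(train_fraction * length(rows))
    n_tr <- min(max(n_tr, 1L), length(rows) - 1L)
    train <- c(train, sample(rows, n_tr))
  }
  sort(train)
}

#' Repeated stratified subsampling evaluation
#'
#' The internal-validation protocol: `B` independent stratified splits
#' place `train_fraction` of each class into a training part and the rest
#' into a test part; the model is refit on every training part and the
#' discrimination metrics (AUROC, AUPRC, recall, F1 at the 0.5
#' probability threshold) are computed on the corresponding test part.
#' Per-metric means and 2.5/97.5 percentile intervals over the `B`
#' repeats are reported. Despite the common "bootstrapping" label this is
#' subsampling without replacement, exactly as the splits are described.
#'
#' @param model_spec a fitter closure such as [model_logistic()].
#' @param x feature matrix or data frame.
#' @param labels 0/1 outcome vector.
#' @param B number of repeats (study default 500).
#' @param train_fraction training share of each split (default 0.7).
#' @param seed master seed; per-repeat seeds are derived from it.
#' @param threshold probability cutoff for recall/F1.
#' @return an `eval_summary`: per-metric `mean`, `ci_low`, `ci_high`, plus
#'   `B`, `split` and the per-repeat metric matrix in `$repeats`.
#' @export
subsample_evaluate <- function(model_spec, x, labels, B = 500,
                               train_fraction = 0.7, seed = 1L,
                               threshold = 0.5) {
  if (B < 1) stop("B must be >= 1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  x <- as.data.frame(x)
  metrics <- matrix(NA_real_, B, 4,
                    dimnames = list(NULL, c("auroc", "auprc", "recall", "f1")))
  for (b in seq_len(B)) {
    tr <- stratified_split(labels, train_fraction, seed + b)
    te <- setdiff(seq_along(labels), tr)
    predictor <- model_spec(x[tr, , drop = FALSE], labels[tr])
    p <- predictor(x[te, , drop = FALSE])
    y <- labels[te]
    pred <- as.numeric(p >= threshold)
    metrics[b, ] <- c(auroc(p, y), auprc(p, y),
                      recall_score(pred, y), f1_score(pred, y))
  }
  summarise <- function(v) c(mean = mean(v),
                             ci_low = unname(stats::quantile(v, 0.025, type = 7)),
                             ci_high = unname(stats::quantile(v, 0.975, type = 7)))
  structure(list(metrics = apply(metrics, 2, summarise),
                 repeats = metrics, B = B, split = train_fraction,
                 threshold = threshold, seed = seed),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("<eval_summary> B = ", x$B, " stratified ",
      round(100 * x$split), "/", round(100 * (1 - x$split)), " splits\n", sep = "")
  m <- x$metrics
  for (nm in colnames(m))
    cat(sprintf("  %-7s mean %.3f (95%% CI %.3f-%.3f)\n",
                nm, m["mean", nm], m["ci_low", nm], m["ci_high", nm]))
  invisible(x)
}

#' Class-ratio versus calibration experiment
#'
#' Fixes a stratified held-out test set at the original class ratio, then
#' for each requested ratio undersamples the majority class of the
#' remaining training rows ([kmeans_undersample()]), fits the model on the
#' rebalanced training data, and evaluates on the common original-ratio
#' test set: AUROC, AUPRC, recall, F1 (0.5 threshold), Brier score and a
#' reliability curve. Optionally the repeated-subsampling protocol is also
#' run within each rebalanced training dataset for percentile intervals.
#' Training at balanced ratios typically raises recall/F1 while worsening
#' the Brier score, because undersampling shifts the model intercept by
#' roughly the log of the sampling ratio.
#'
#' @param cohort a fully imputed `emr_cohort`.
#' @param ratios as in [build_ratio_datasets()].
#' @param model_spec fitter closure; default plain logistic regression.
#' @param seed integer seed.
#' @param test_fraction held-out share (default 0.3).
#' @param B subsampling repeats within each training dataset; `B = 0`
#'   skips that part.
#' @param nstart k-means restarts.
#' @param threshold probability cutoff for recall/F1.
#' @return a `ratio_experiment` object: `table` (one row of common-test
#'   metrics per ratio, including `"original"`), `reliability` (list of
#'   curves), `subsample` (list of `eval_summary` or `NULL`).
#' @export
ratio_experiment <- function(cohort,
                             ratios = list(c(1, 10), c(1, 5), c(1, 2), c(1, 1)),
                             model_spec = model_logistic(), seed = 1L,
                             test_fraction = 0.3, B = 100, nstart = 10L,
                             threshold = 0.5) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (anyNA(cohort$observed)) stop("missing values present; impute first")
  y <- cohort$outcome
  tr_rows <- stratified_split(y, 1 - test_fraction, seed)
  te_rows <- setdiff(seq_along(y), tr_rows)
  x <- as.data.frame(cohort$observed)
  x_test <- x[te_rows, , drop = FALSE]; y_test <- y[te_rows]

  train_cohort <- emr_cohort(cohort$observed[tr_rows, , drop = FALSE],
                             y[tr_rows], cohort$meta)
  datasets <- build_ratio_datasets(train_cohort, ratios = ratios,
                                   seed = seed + 1L, nstart = nstart)
  rows <- list(); curves <- list(); subs <- list()
  for (nm in names(datasets)) {
    idx <- datasets[[nm]]$indices
    x_tr <- x[tr_rows, , drop = FALSE][idx, , drop = FALSE]
    y_tr <- y[tr_rows][idx]
    predictor <- model_spec(x_tr, y_tr)
    p <- pmin(pmax(predictor(x_test), 0), 1)
    pred <- as.numeric(p >= threshold)
    rows[[nm]] <- data.frame(
      ratio = nm, n_train = length(idx),
      auroc = auroc(p, y_test), auprc = auprc(p, y_test),
      recall = recall_score(pred, y_test), f1 = f1_score(pred, y_test),
      brier = brier(p, y_test), stringsAsFactors = FALSE)
    curves[[nm]] <- reliability_curve(p, y_test)
    subs[[nm]] <- if (B > 0)
      subsample_evaluate(model_spec, x_tr, y_tr, B = B, seed = seed + 2L,
                         threshold = threshold) else NULL
  }
  structure(list(table = do.call(rbind, rows), reliability = curves,
                 subsample = subs, seed = seed,
                 test_rows = te_rows),
            class = "ratio_experiment")
}

#' @export
print.ratio_experiment <- function(x, ...) {
  cat("<ratio_experiment> common original-ratio test set metrics\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
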