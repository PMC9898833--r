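#' Start a variable-selection trace
#'
#' Accumulates the bookkeeping of the screening-and-selection cascade:
#' chi-square exclusions, univariate logistic exclusions, expert
#' reintroductions, variable groups and the forward-selection path.
#'
#' @param candidates character vector of starting candidate variables.
#' @return an empty `selection_trace`.
#' @export
selection_trace <- function(candidates = character()) {
  structure(list(candidates = candidates,
                 chi_square_excluded = NULL,
                 univariate_excluded = NULL,
                 separation_flagged = character(),
                 reintroduced = character(),
                 groups = list(),
                 group_metrics = NULL,
                 forward_path = NULL,
                 final_variables = character()),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  cat("  candidates:", length(x$candidates), "\n")
  if (!is.null(x$chi_square_excluded))
    cat("  chi-square excluded:", nrow(x$chi_square_excluded), "\n")
  if (!is.null(x$univariate_excluded))
    cat("  univariate excluded:", nrow(x$univariate_excluded), "\n")
  if (length(x$separation_flagged))
    cat("  separation-flagged:", paste(x$separation_flagged, collapse = ", "), "\n")
  if (length(x$reintroduced))
    cat("  reintroduced:", paste(x$reintroduced, collapse = ", "), "\n")
  if (!is.null(x$forward_path)) {
    cat("  forward path:\n")
    print(x$forward_path, row.names = FALSE, digits = 4)
  }
  if (length(x$final_variables))
    cat("  final:", paste(x$final_variables, collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square prefilter of categorical predictors
#'
#' Pearson chi-square (no continuity correction) on each variable x
#' outcome contingency table; variables with P greater than `alpha`
#' (default .10) are excluded. Levels with a zero margin are dropped from
#' the table and noted. Statistic, degrees of freedom and P value are
#' recorded for every variable.
#'
#' @param cohort an `emr_cohort`; variables must be categorical (ordinal
#'   L/N/H codes, discrete codes or binary diagnoses).
#' @param variables names to test; default all ordinal/discrete/diagnosis
#'   variables.
#' @param alpha exclusion threshold on the P value.
#' @param trace optional `selection_trace` to update.
#' @return the updated `selection_trace`; its `chi_square_excluded` holds
#'   the excluded rows and `candidates` the survivors. The full test table
#'   is in the `"tests"` attribute.
#' @export
chi_square_filter <- function(cohort, variables = NULL, alpha = 0.10,
                              trace = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (is.null(variables))
    variables <- variables_of_kind(cohort, c("ordinal", "discrete", "diagnosis"))
  idx <- match(variables, cohort$meta$name)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(variables[is.na(idx)], collapse = ", "))
  if (any(cohort$meta$kind[idx] == "continuous"))
    stop("chi-square filter requires categorical variables; discretize first")
  rows <- lapply(seq_along(idx), function(i) {
    x <- cohort$observed[, idx[i]]
    ok <- !is.na(x)
    tab <- table(x[ok], cohort$outcome[ok])
    dropped_levels <- sum(rowSums(tab) == 0) + sum(colSums(tab) == 0)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(data.frame(variable = variables[i], statistic = NA_real_,
                        df = NA_integer_, p = NA_real_,
                        note = "degenerate table", stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(variable = variables[i],
               statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = unname(ct$p.value),
               note = if (dropped_levels) "zero-margin level dropped" else "",
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  excluded <- tests[!is.na(tests$p) & tests$p > alpha, , drop = FALSE]
  if (is.null(trace)) trace <- selection_trace(variables)
  trace$chi_square_excluded <- excluded
  trace$candidates <- setdiff(trace$candidates, excluded$variable)
  attr(trace, "tests") <- tests
  trace
}

wald_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = exp(beta - z * se), high = exp(beta + z * se))
}

#' Univariate logistic-regression prefilter
#'
#' One-predictor logistic fit per candidate; the Wald P value of the
#' slope decides exclusion (P greater than `alpha`, default .05). Ordinal
#' L/N/H codes enter as a single numeric predictor, so the odds ratio
#' refers to one ordinal step. A fit showing (quasi-)separation is
#' flagged and kept aside for the separation report instead of being
#' judged on its unreliable P value.
#'
#' @param cohort an `emr_cohort`.
#' @param variables candidates; default the trace candidates.
#' @param alpha exclusion threshold on the Wald P value.
#' @param trace optional `selection_trace` to update.
#' @param separation_threshold passed to [detect_separation()].
#' @return updated `selection_trace`; the full table (OR, 95\% CI, P,
#'   separation flag) is in the `"tests"` attribute.
#' @export
univariate_lr_filter <- function(cohort, variables = NULL, alpha = 0.05,
                                 trace = NULL, separation_threshold = 10) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (is.null(variables)) {
    if (is.null(trace)) stop("supply variables or a trace with candidates")
    variables <- trace$candidates
  }
  idx <- match(variables, cohort$meta$name)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(variables[is.na(idx)], collapse = ", "))
  rows <- lapply(seq_along(idx), function(i) {
    x <- cohort$observed[, idx[i]]
    ok <- !is.na(x)
    fit <- fit_multivariate_lr(x = data.frame(x = x[ok]),
                               outcome = cohort$outcome[ok],
                               separation_threshold = separation_threshold)
    data.frame(variable = variables[i], or = fit$odds_ratios[1],
               ci_low = fit$ci_low[1], ci_high = fit$ci_high[1],
               p = fit$p_values[1], separation = fit$separation_flag,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  flagged <- tests$variable[tests$separation]
  excluded <- tests[!tests$separation & !is.na(tests$p) & tests$p > alpha, ,
                    drop = FALSE]
  if (is.null(trace)) trace <- selection_trace(variables)
  trace$univariate_excluded <- excluded
  trace$separation_flagged <- union(trace$separation_flagged, flagged)
  trace$candidates <- setdiff(trace$candidates, excluded$variable)
  attr(trace, "tests") <- tests
  trace
}

#' Reintroduce expert-chosen variables into the candidate set
#'
#' Variables excluded on statistical grounds can be clinically relevant;
#' this moves previously excluded variables back into the candidate set,
#' tagged as expert reintroductions. Reintroducing a variable that was
#' never excluded is an error.
#'
#' @param trace a `selection_trace`.
#' @param variables character vector (may be empty).
#' @return the updated trace.
#' @export
reintroduce <- function(trace, variables) {
  stopifnot(inherits(trace, "selection_trace"))
  if (!length(variables)) return(trace)
  excluded <- c(if (!is.null(trace$chi_square_excluded)) trace$chi_square_excluded$variable,
                if (!is.null(trace$univariate_excluded)) trace$univariate_excluded$variable)
  unknown <- setdiff(variables, excluded)
  if (length(unknown))
    stop("cannot reintroduce variable(s) never excluded: ",
         paste(unknown, collapse = ", "))
  trace$reintroduced <- union(trace$reintroduced, variables)
  trace$candidates <- union(trace$candidates, variables)
  trace
}

#' Multivariate logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit reported as odds ratios with 95\%
#' confidence intervals. Wald intervals (`exp(beta +- 1.96 se)`) are the
#' default; `ci_method = "bootstrap"` instead refits on `B` stratified
#' 70\% subsamples and takes percentile intervals of the per-coefficient
#' odds ratios. Convergence and separation diagnostics are always
#' populated; a separated fit is flagged rather than silently reported.
#'
#' @param cohort an `emr_cohort`, or `NULL` when `x` is given directly.
#' @param variables columns to use (cohort interface).
#' @param x,outcome direct data-frame interface.
#' @param ci_method `"wald"` or `"bootstrap"`.
#' @param B bootstrap refits when `ci_method = "bootstrap"`.
#' @param seed seed for the bootstrap refits.
#' @param separation_threshold `|coefficient|` above which (or on
#'   non-convergence with boundary fitted probabilities) the separation
#'   flag trips.
#' @return an `lr_fit` with `coefficients`, `odds_ratios`, `ci_low`,
#'   `ci_high`, `p_values`, `intercept`, `converged`, `separation_flag`,
#'   `n_obs` and the underlying `glm` object.
#' @export
fit_multivariate_lr <- function(cohort = NULL, variables = NULL,
                                x = NULL, outcome = NULL,
                                ci_method = c("wald", "bootstrap"),
                                B = 200, seed = 1L,
                                separation_threshold = 10) {
  ci_method <- match.arg(ci_method)
  if (is.null(x)) {
    stopifnot(inherits(cohort, "emr_cohort"))
    if (is.null(variables)) variables <- cohort$meta$name
    idx <- match(variables, cohort$meta$name)
    if (anyNA(idx)) stop("unknown variable(s): ",
                         paste(variables[is.na(idx)], collapse = ", "))
    x <- as.data.frame(cohort$observed[, idx, drop = FALSE])
    outcome <- cohort$outcome
  }
  x <- as.data.frame(x)
  if (anyNA(x)) stop("missing values in selected columns; impute first")
  const <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(const))
    stop("zero variance column(s): ", paste(names(x)[const], collapse = ", "))
  dat <- cbind(x, .y = outcome)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)))
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope_rows <- rownames(co) != "(Intercept)"
  beta <- co[slope_rows, "Estimate"]
  se <- co[slope_rows, "Std. Error"]
  p <- co[slope_rows, "Pr(>|z|)"]
  ci <- t(vapply(seq_along(beta), function(i) wald_ci(beta[i], se[i]),
                 numeric(2)))
  result <- structure(list(
    variable_names = names(x),
    coefficients = unname(beta),
    odds_ratios = unname(exp(beta)),
    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
    p_values = unname(p),
    intercept = unname(co["(Intercept)", "Estimate"]),
    converged = fit$converged,
    separation_flag = FALSE,
    n_obs = nrow(x),
    ci_method = ci_method,
    glm = fit), class = "lr_fit")
  result$separation_flag <- detect_separation(result, separation_threshold)
  if (ci_method == "bootstrap") {
    boots <- matrix(NA_real_, B, length(beta))
    for (b in seq_len(B)) {
      tr <- stratified_split(outcome, 0.7, seed + b)
      fb <- suppressWarnings(
        stats::glm(.y ~ ., data = dat[tr, , drop = FALSE],
                   family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)))
      cb <- stats::coef(fb)
      boots[b, ] <- exp(cb[names(cb) != "(Intercept)"])
    }
    result$ci_low <- apply(boots, 2, stats::quantile, 0.025, na.rm = TRUE)
    result$ci_high <- apply(boots, 2, stats::quantile, 0.975, na.rm = TRUE)
  }
  result
}

#' @export
print.lr_fit <- function(x, ...) {
  cat("<lr_fit> n =", x$n_obs,
      if (!x$converged) "[NOT CONVERGED]" else "",
      if (x$separation_flag) "[SEPARATION - unreliable]" else "", "\n")
  print(data.frame(variable = x$variable_names,
                   OR = round(x$odds_ratios, 3),
                   ci_low = round(x$ci_low, 3),
                   ci_high = round(x$ci_high, 3),
                   p = signif(x$p_values, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.lr_fit <- function(object, ...) {
  data.frame(variable = object$variable_names,
             coefficient = object$coefficients,
             odds_ratio = object$odds_ratios,
             ci_low = object$ci_low, ci_high = object$ci_high,
             p_value = object$p_values,
             stringsAsFactors = FALSE)
}

#' @export
coef.lr_fit <- function(object, ...) {
  stats::setNames(c(object$intercept, object$coefficients),
                  c("(Intercept)", object$variable_names))
}

#' @export
predict.lr_fit <- function(object, newdata, type = "response", ...) {
  suppressWarnings(
    as.numeric(stats::predict(object$glm, newdata = as.data.frame(newdata),
                              type = type)))
}

#' Detect (quasi-)complete separation in a logistic fit
#'
#' A predictor combination that perfectly predicts the outcome drives the
#' maximum-likelihood coefficients toward infinity; the symptoms are
#' enormous coefficients and fitted probabilities pinned at 0/1. The flag
#' trips when any slope magnitude exceeds `threshold`, or when the
#' optimizer stopped without convergence while fitted probabilities sit on
#' the boundary.
#'
#' @param fit an `lr_fit`.
#' @param threshold coefficient-magnitude cutoff (default 10, i.e. an
#'   odds ratio above about 2.2e4 per unit step).
#' @return logical flag.
#' @export
detect_separation <- function(fit, threshold = 10) {
  stopifnot(inherits(fit, "lr_fit"))
  if (is.infinite(threshold) && threshold > 0) {
    warning("infinite threshold: separation can never be detected")
    return(FALSE)
  }
  if (any(abs(fit$coefficients) > threshold)) return(TRUE)
  if (!fit$converged && !is.null(fit$glm)) {
    mu <- stats::fitted(fit$glm)
    if (any(mu < 1e-8 | mu > 1 - 1e-8)) return(TRUE)
  }
  FALSE
}

#' Forward selection over variable groups by mean AUROC
#'
#' Scores each group standalone with the repeated-subsampling logistic
#' evaluator, starts from the best group, then tries the remaining groups
#' in descending standalone order: a group's variables join the model only
#' if the mean AUROC strictly improves. The same split seeds are reused at
#' every step so comparisons are paired.
#'
#' @param cohort an `emr_cohort` (fully observed columns for the grouped
#'   variables).
#' @param groups named list of character vectors.
#' @param B subsampling repeats per evaluation.
#' @param seed integer seed.
#' @param train_fraction split used by the evaluator.
#' @param trace optional `selection_trace` to update.
#' @return updated `selection_trace` with `group_metrics`, `forward_path`
#'   and `final_variables`.
#' @export
forward_group_selection <- function(cohort, groups, B = 50, seed = 1L,
                                    train_fraction = 0.7, trace = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (length(groups) < 1 || is.null(names(groups)))
    stop("groups must be a named list")
  all_vars <- unique(unlist(groups))
  idx <- match(all_vars, cohort$meta$name)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(all_vars[is.na(idx)], collapse = ", "))
  x <- as.data.frame(cohort$observed)
  y <- cohort$outcome
  eval_vars <- function(vars) {
    s <- tryCatch(
      subsample_evaluate(model_logistic(vars), x, y, B = B, seed = seed,
                         train_fraction = train_fraction),
      error = function(e) NULL)
    s
  }
  standalone <- lapply(groups, function(g) eval_vars(g))
  metrics <- data.frame(
    group = names(groups),
    auroc = vapply(standalone, function(s)
      if (is.null(s)) NA_real_ else s$metrics["mean", "auroc"], numeric(1)),
    recall = vapply(standalone, function(s)
      if (is.null(s)) NA_real_ else s$metrics["mean", "recall"], numeric(1)),
    f1 = vapply(standalone, function(s)
      if (is.null(s)) NA_real_ else s$metrics["mean", "f1"], numeric(1)),
    ci_low = vapply(standalone, function(s)
      if (is.null(s)) NA_real_ else s$metrics["ci_low", "auroc"], numeric(1)),
    ci_high = vapply(standalone, function(s)
      if (is.null(s)) NA_real_ else s$metrics["ci_high", "auroc"], numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(-metrics$auroc, seq_len(nrow(metrics)), na.last = TRUE)
  if (all(is.na(metrics$auroc))) stop("evaluator failed on every group")
  base_i <- ord[1]
  current_vars <- groups[[base_i]]
  best_auroc <- metrics$auroc[base_i]
  path <- list(data.frame(group = metrics$group[base_i],
                          auroc_before = NA_real_, auroc_after = best_auroc,
                          accepted = TRUE, note = "base group",
                          stringsAsFactors = FALSE))
  for (i in ord[-1]) {
    g <- metrics$group[i]
    if (is.na(metrics$auroc[i])) {
      path[[length(path) + 1L]] <- data.frame(
        group = g, auroc_before = best_auroc, auroc_after = NA_real_,
        accepted = FALSE, note = "evaluator failed", stringsAsFactors = FALSE)
      next
    }
    cand <- union(current_vars, groups[[i]])
    s <- eval_vars(cand)
    after <- if (is.null(s)) NA_real_ else s$metrics["mean", "auroc"]
    accept <- !is.na(after) && after > best_auroc
    path[[length(path) + 1L]] <- data.frame(
      group = g, auroc_before = best_auroc, auroc_after = after,
      accepted = accept,
      note = if (is.null(s)) "evaluator failed" else "",
      stringsAsFactors = FALSE)
    if (accept) {
      current_vars <- cand
      best_auroc <- after
    }
  }
  if (is.null(trace)) trace <- selection_trace(all_vars)
  trace$groups <- groups
  trace$group_metrics <- metrics
  trace$forward_path <- do.call(rbind, path)
  trace$final_variables <- current_vars
  trace
}

#' Principal-component logistic regression
#'
#' Fits a logistic model on PC scores instead of the raw sparse diagnosis
#' indicators. Because the scores are dense and mutually orthogonal, the
#' fit converges where the raw fit suffers separation and
#' multicollinearity. Components are then ranked for interpretation: those
#' with Wald P below `alpha`, ordered by the magnitude of their log odds
#' ratio, and each is unpacked into its top-loading original variables.
#'
#' @param scores n x k PC score matrix from [pc_transform()].
#' @param outcome 0/1 outcome vector.
#' @param model the `pc_model` that produced the scores.
#' @param alpha significance level for the interpretation rule.
#' @param top_m variables reported per significant component.
#' @param ... passed to [fit_multivariate_lr()].
#' @return a `pc_regression` object: `fit` (`lr_fit` on the scores),
#'   `pc_table` (per-component OR, CI, P), `significant_components`
#'   (ranked), `interpretation` (loading report) and `risk_factors` (the
#'   union of top-loading variables over significant components).
#' @export
pc_regression <- function(scores, outcome, model, alpha = 0.05, top_m = 3, ...) {
  stopifnot(inherits(model, "pc_model"))
  scores <- as.matrix(scores)
  fit <- fit_multivariate_lr(x = as.data.frame(scores), outcome = outcome, ...)
  pc_table <- data.frame(component = seq_len(ncol(scores)),
                         or = fit$odds_ratios,
                         ci_low = fit$ci_low, ci_high = fit$ci_high,
                         p = fit$p_values, stringsAsFactors = FALSE)
  sig <- pc_table[!is.na(pc_table$p) & pc_table$p < alpha, , drop = FALSE]
  sig <- sig[order(-abs(log(sig$or))), , drop = FALSE]
  interp <- if (nrow(sig))
    loading_report(model, sig$component, top_m = top_m) else list()
  risk <- unique(unlist(lapply(interp, function(d) d$variable)))
  structure(list(fit = fit, pc_table = pc_table,
                 significant_components = sig$component,
                 interpretation = interp,
                 risk_factors = risk),
            class = "pc_regression")
}

#' @export
print.pc_regression <- function(x, ...) {
  cat("<pc_regression> k =", nrow(x$pc_table), "components",
      if (x$fit$separation_flag) "[SEPARATION]" else "", "\n")
  print(x$pc_table, row.names = FALSE, digits = 3)
  if (length(x$risk_factors))
    cat("  interpreted risk factors:", paste(x$risk_factors, collapse = ", "), "\n")
  invisible(x)
}

zoo_default_grids <- function(p) {
  list(
    lr = list(list()),
    lasso = lapply(c(0.001, 0.01, 0.1), function(l) list(lambda = l)),
    rf = lapply(unique(c(max(1, floor(sqrt(p))), max(1, floor(p / 2)))),
                function(m) list(mtry = m, num.trees = 200)),
    gbm = lapply(c(2, 4), function(d)
      list(max_depth = d, nrounds = 50, eta = 0.3)),
    svm = lapply(c(0.1, 1, 10), function(cst) list(cost = cst))
  )
}

zoo_fitter <- function(model, params) {
  switch(model,
    lr = model_logistic(),
    lasso = function(x, y) {
      xm <- as.matrix(x)
      fit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 1,
                            lambda = params$lambda)
      function(x_new) as.numeric(
        stats::predict(fit, newx = as.matrix(x_new), type = "response"))
    },
    rf = function(x, y) {
      dat <- as.data.frame(x); dat$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                            num.trees = params$num.trees, mtry = params$mtry,
                            probability = TRUE, seed = 1L, num.threads = 1L)
      function(x_new) stats::predict(fit, data = as.data.frame(x_new),
                                     num.threads = 1L)$predictions[, "1"]
    },
    gbm = function(x, y) {
      fit <- xgboost::xgboost(as.matrix(x), factor(y, levels = c(0, 1)),
                              max_depth = params$max_depth,
                              learning_rate = params$eta,
                              nrounds = params$nrounds,
                              objective = "binary:logistic",
                              nthreads = 1L, verbosity = 0L, seed = 1L)
      function(x_new)
        as.numeric(stats::predict(fit, as.matrix(x_new), type = "response"))
    },
    svm = function(x, y) {
      fit <- e1071::svm(as.matrix(x), factor(y, levels = c(0, 1)),
                        kernel = "radial", cost = params$cost,
                        probability = TRUE)
      function(x_new) {
        p <- stats::predict(fit, as.matrix(x_new), probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    },
    stop("unknown model: ", model))
}

cv_auroc <- function(fitter, x, y, folds = 5, seed = 1L) {
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in c(0, 1)) {
    rows <- which(y == cl)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  aucs <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f; te <- !tr
    if (length(unique(y[te])) < 2) return(NA_real_)
    predictor <- fitter(x[tr, , drop = FALSE], y[tr])
    auroc(predictor(x[te, , drop = FALSE]), y[te])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Comparison model zoo with grid-searched hyperparameters
#'
#' Trains the study's comparison models — logistic regression, LASSO,
#' random forest, gradient boosting, and an RBF support vector machine —
#' each tuned by grid search under stratified 5-fold cross-validated
#' AUROC, then evaluated with the repeated-subsampling protocol.
#'
#' @param cohort an `emr_cohort` (typically imputed and rebalanced).
#' @param models subset of `c("lr","lasso","rf","gbm","svm")`.
#' @param grids named list of per-model parameter lists; defaults cover a
#'   small standard grid per model.
#' @param cv_folds cross-validation folds for tuning.
#' @param B subsampling repeats for the final evaluation.
#' @param seed integer seed.
#' @return a named list per model: `best_params`, `cv_auroc`, `eval`
#'   (an `eval_summary`).
#' @export
train_model_zoo <- function(cohort, models = c("lr", "lasso", "rf", "gbm", "svm"),
                            grids = NULL, cv_folds = 5, B = 100, seed = 1L) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (anyNA(cohort$observed)) stop("missing values present; impute first")
  x <- as.data.frame(cohort$observed)
  y <- cohort$outcome
  if (is.null(grids)) grids <- zoo_default_grids(ncol(x))
  out <- list()
  for (model in models) {
    grid <- grids[[model]]
    if (is.null(grid)) grid <- list(list())
    best <- NULL
    for (params in grid) {
      a <- cv_auroc(zoo_fitter(model, params), x, y, folds = cv_folds,
                    seed = seed)
      if (is.null(best) || a > best$auroc) best <- list(params = params, auroc = a)
    }
    ev <- subsample_evaluate(zoo_fitter(model, best$params), x, y, B = B,
                             seed = seed)
    out[[model]] <- list(best_params = best$params, cv_auroc = best$auroc,
                         eval = ev)
  }
  out
}
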