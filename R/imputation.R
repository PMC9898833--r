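#' Cohen's kappa for two categorical vectors
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} where
#' \eqn{p_o} is the observed agreement fraction and \eqn{p_e} the expected
#' agreement under independent marginals. When the expected agreement is 1
#' (a single shared category) the ratio is 0/0; the function returns 1 if
#' the observed agreement is also perfect and 0 otherwise.
#'
#' @param truth,pred equal-length vectors of category labels.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  truth <- as.character(truth); pred <- as.character(pred)
  levels <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  n <- sum(tab)
  if (n == 0) stop("no observations")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < 1e-12) return(if (p_o > 1 - 1e-12) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Coefficient of determination against held-out values
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the held-out truth, so a constant prediction equal to
#' that mean scores exactly 0.
#'
#' @param truth,pred numeric vectors.
#' @return R-squared (at most 1; can be negative for predictions worse
#'   than the mean).
#' @export
r_squared <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / ss_tot
}

stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no observed values")
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # tie -> smallest value
}

# Temporary mean/mode fills of covariate columns, computed from currently
# observed values only (single-sweep protocol: fills are never propagated).
temp_fill <- function(observed, meta) {
  filled <- observed
  for (j in seq_len(ncol(observed))) {
    miss <- is.na(observed[, j])
    if (!any(miss)) next
    vals <- observed[!miss, j]
    if (!length(vals)) stop("variable with all values missing: ",
                            meta$name[j], "; screen it out first")
    fill <- if (meta$kind[j] == "continuous") mean(vals) else stat_mode(vals)
    filled[miss, j] <- fill
  }
  filled
}

fit_forest <- function(x_train, y, classification, num_trees, seed) {
  dat <- as.data.frame(x_train)
  dat$.target <- if (classification) factor(y) else y
  ranger::ranger(dependent.variable.name = ".target", data = dat,
                 num.trees = num_trees, seed = seed,
                 num.threads = 1L)
}

predict_forest <- function(fit, x_new, classification) {
  p <- stats::predict(fit, data = as.data.frame(x_new),
                      num.threads = 1L)$predictions
  if (classification) as.numeric(as.character(p)) else as.numeric(p)
}

#' Random-forest single imputation
#'
#' Implements the four-step single-sweep protocol. For each variable with
#' missing cells (processed in ascending order of missing fraction): rows
#' observed for the variable form the training set and rows missing it the
#' test set; remaining missing covariate cells are temporarily filled with
#' the mean (continuous) or mode (discrete) of the currently observed
#' values; a regression forest (continuous target) or classification
#' forest (discrete/ordinal/diagnosis target) is trained and its
#' predictions fill the missing cells. Temporary fills are discarded after
#' each variable: later fits always see the original observed values.
#'
#' @param cohort an `emr_cohort`; every variable to impute must have at
#'   least one observed value.
#' @param num_trees trees per forest (default 100).
#' @param seed integer; the per-variable forest seed is derived from it.
#' @return the cohort with no missing cells. The original mask is attached
#'   as the `"imputed_cells"` attribute.
#' @export
rf_impute <- function(cohort, num_trees = 100, seed = 1L) {
  stopifnot(inherits(cohort, "emr_cohort"))
  mask <- cohort$mask
  meta <- cohort$meta
  frac <- colMeans(mask)
  if (any(frac == 1))
    stop("variable with all values missing: ",
         paste(meta$name[frac == 1], collapse = ", "),
         "; screen it out first")
  excl <- which(meta$impute_exclude & frac > 0)
  if (length(excl))
    stop("variable(s) flagged impute_exclude have missing values: ",
         paste(meta$name[excl], collapse = ", "))
  targets <- which(frac > 0 & !meta$impute_exclude)
  if (!length(targets)) return(cohort)
  targets <- targets[order(frac[targets], targets)]  # ascending missingness
  observed <- cohort$observed
  result <- observed
  for (j in targets) {
    train <- !mask[, j]
    test <- mask[, j]
    covar <- temp_fill(observed[, -j, drop = FALSE], meta[-j, , drop = FALSE])
    classification <- meta$kind[j] != "continuous"
    fit <- fit_forest(covar[train, , drop = FALSE], observed[train, j],
                      classification, num_trees, seed = seed + j)
    result[test, j] <- predict_forest(fit, covar[test, , drop = FALSE],
                                      classification)
  }
  out <- emr_cohort(result, cohort$outcome, meta, complete = cohort$complete)
  attr(out, "imputed_cells") <- mask
  out
}

#' Constant-strategy baseline imputation
#'
#' Fills every missing cell of a variable with a single constant computed
#' from its observed values: the mean or median for continuous variables,
#' or the mode (smallest value on ties) for any kind. Used as the
#' comparison arm for [rf_impute()].
#'
#' @param cohort an `emr_cohort`.
#' @param strategy one of `"mean"`, `"median"`, `"mode"`.
#' @return the cohort with no missing cells.
#' @export
baseline_impute <- function(cohort, strategy = c("mean", "mode", "median")) {
  stopifnot(inherits(cohort, "emr_cohort"))
  strategy <- match.arg(strategy)
  observed <- cohort$observed
  meta <- cohort$meta
  for (j in seq_len(ncol(observed))) {
    miss <- is.na(observed[, j])
    if (!any(miss)) next
    if (strategy %in% c("mean", "median") && meta$kind[j] != "continuous")
      stop(strategy, " imputation is invalid for ", meta$kind[j],
           " variable: ", meta$name[j])
    vals <- observed[!miss, j]
    if (!length(vals))
      stop("variable with all values missing: ", meta$name[j],
           "; screen it out first")
    fill <- switch(strategy,
                   mean = mean(vals),
                   median = stats::median(vals),
                   mode = stat_mode(vals))
    observed[miss, j] <- fill
  }
  out <- emr_cohort(observed, cohort$outcome, meta, complete = cohort$complete)
  attr(out, "imputed_cells") <- cohort$mask
  out
}

#' Validate imputation quality on held-out observed values
#'
#' For each evaluable variable the observed rows are split into a training
#' part (default 80\%) and a validation part (20\%); the imputation model
#' (random forest or a constant baseline) is trained on the training part
#' and scored on the held-out values: the coefficient of determination
#' R-squared for continuous variables, Cohen's kappa for the rest.
#' Variables with fewer observed rows than `min_obs` are reported as not
#' evaluable rather than silently skipped.
#'
#' @param cohort an `emr_cohort`.
#' @param split held-out fraction of the observed rows (default 0.2).
#' @param seed integer seed.
#' @param method `"rf"` or one of the constant baselines `"mean"`,
#'   `"mode"`, `"median"` (means/medians apply to continuous variables,
#'   the mode to the rest; with a constant baseline each variable
#'   automatically uses its kind-appropriate constant).
#' @param variables names to evaluate; defaults to all non-excluded
#'   variables that have missing cells (the imputation targets), or all
#'   non-excluded variables if nothing is missing.
#' @param min_obs minimum observed rows for a variable to be evaluable.
#' @param num_trees trees per forest.
#' @return an `imputation_report`: `per_variable` data frame (name, kind,
#'   metric, value, n_train, n_validation, note) and `summary` with the
#'   median and IQR of R-squared over continuous variables and of kappa
#'   over the rest.
#' @export
evaluate_imputation <- function(cohort, split = 0.2, seed = 1L,
                                method = c("rf", "mean", "mode", "median"),
                                variables = NULL, min_obs = 25,
                                num_trees = 100) {
  stopifnot(inherits(cohort, "emr_cohort"))
  method <- match.arg(method)
  if (split <= 0 || split >= 1) stop("split must lie in (0,1)")
  meta <- cohort$meta
  mask <- cohort$mask
  if (is.null(variables)) {
    frac <- colMeans(mask)
    variables <- meta$name[!meta$impute_exclude & frac > 0]
    if (!length(variables)) variables <- meta$name[!meta$impute_exclude]
  }
  idx <- match(variables, meta$name)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(variables[is.na(idx)], collapse = ", "))
  rows <- vector("list", length(idx))
  set.seed(seed)
  for (i in seq_along(idx)) {
    j <- idx[i]
    obs_rows <- which(!mask[, j])
    kind <- meta$kind[j]
    metric <- if (kind == "continuous") "R2" else "kappa"
    if (length(obs_rows) < min_obs) {
      rows[[i]] <- data.frame(name = meta$name[j], kind = kind,
                              metric = metric, value = NA_real_,
                              n_train = NA_integer_, n_validation = NA_integer_,
                              note = "not evaluable: too few observed rows",
                              stringsAsFactors = FALSE)
      next
    }
    n_val <- max(1L, round(split * length(obs_rows)))
    val <- sample(obs_rows, n_val)
    train <- setdiff(obs_rows, val)
    truth <- cohort$observed[val, j]
    y_train <- cohort$observed[train, j]
    if (method == "rf") {
      covar <- temp_fill(cohort$observed[, -j, drop = FALSE],
                         meta[-j, , drop = FALSE])
      classification <- kind != "continuous"
      fit <- fit_forest(covar[train, , drop = FALSE], y_train,
                        classification, num_trees, seed = seed + j)
      pred <- predict_forest(fit, covar[val, , drop = FALSE], classification)
    } else {
      const <- if (kind == "continuous") {
        switch(method, mean = mean(y_train), median = stats::median(y_train),
               mode = stat_mode(y_train))
      } else stat_mode(y_train)
      pred <- rep(const, length(truth))
    }
    value <- if (kind == "continuous") r_squared(truth, pred)
             else cohen_kappa(truth, pred)
    note <- if (is.na(value)) "not evaluable: constant validation values" else ""
    rows[[i]] <- data.frame(name = meta$name[j], kind = kind, metric = metric,
                            value = value, n_train = length(train),
                            n_validation = length(val), note = note,
                            stringsAsFactors = FALSE)
  }
  per_variable <- do.call(rbind, rows)
  summ <- function(metric) {
    v <- per_variable$value[per_variable$metric == metric & !is.na(per_variable$value)]
    if (!length(v)) return(c(median = NA_real_, iqr = NA_real_, n = 0))
    c(median = stats::median(v), iqr = stats::IQR(v), n = length(v))
  }
  structure(list(per_variable = per_variable,
                 summary = list(R2 = summ("R2"), kappa = summ("kappa")),
                 method = method, split = split, seed = seed),
            class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("<imputation_report> method: ", x$method,
      ", validation split ", x$split, "\n", sep = "")
  s <- x$summary
  if (s$R2[["n"]] > 0)
    cat(sprintf("  continuous R2: median %.3f (IQR %.3f) over %d variable(s)\n",
                s$R2[["median"]], s$R2[["iqr"]], as.integer(s$R2[["n"]])))
  if (s$kappa[["n"]] > 0)
    cat(sprintf("  discrete kappa: median %.3f (IQR %.3f) over %d variable(s)\n",
                s$kappa[["median"]], s$kappa[["iqr"]], as.integer(s$kappa[["n"]])))
  ne <- x$per_variable$name[x$per_variable$note != ""]
  if (length(ne)) cat("  not evaluable:", paste(ne, collapse = ", "), "\n")
  invisible(x)
}
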