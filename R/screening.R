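#' Merge synonymous diagnosis columns
#'
#' Free-text diagnoses yield several column names for one clinical entity.
#' Given a many-to-one mapping of original names to unified names, the
#' mapped binary diagnosis columns are combined by logical OR (a patient
#' carries the unified diagnosis if any synonym column is set). Every
#' rename is recorded in a merge log attached as the `"merge_log"`
#' attribute.
#'
#' @param cohort an `emr_cohort`.
#' @param mapping data frame with columns `original` and `unified`.
#' @return the cohort with merged columns; unified columns take the
#'   position of the first mapped original.
#' @export
merge_synonyms <- function(cohort, mapping) {
  stopifnot(inherits(cohort, "emr_cohort"))
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  if (nrow(mapping) == 0) {
    attr(cohort, "merge_log") <- data.frame(original = character(),
                                            unified = character(),
                                            stringsAsFactors = FALSE)
    return(cohort)
  }
  if (!all(c("original", "unified") %in% names(mapping)))
    stop("mapping needs columns 'original' and 'unified'")
  unknown <- setdiff(mapping$original, cohort$meta$name)
  if (length(unknown))
    stop("mapping references unknown variable(s): ", paste(unknown, collapse = ", "))
  kinds <- cohort$meta$kind[match(mapping$original, cohort$meta$name)]
  if (any(kinds != "diagnosis"))
    stop("only diagnosis variables can be merged; offending: ",
         paste(mapping$original[kinds != "diagnosis"], collapse = ", "))

  or_combine <- function(mat) {
    # 1 if any synonym is 1; NA only if all informative cells are NA-or-0
    # with at least one NA; else 0
    any1 <- rowSums(mat == 1, na.rm = TRUE) > 0
    anyna <- rowSums(is.na(mat)) > 0
    out <- ifelse(any1, 1, ifelse(anyna, NA_real_, 0))
    out
  }

  nm <- cohort$meta$name
  unified_names <- unique(mapping$unified)
  drop_idx <- integer(); new_cols <- list(); new_pos <- integer()
  observed <- cohort$observed
  complete <- cohort$complete
  for (u in unified_names) {
    orig <- mapping$original[mapping$unified == u]
    idx <- match(orig, nm)
    new_cols[[u]] <- list(
      obs = or_combine(observed[, idx, drop = FALSE]),
      com = if (is.null(complete)) NULL else or_combine(complete[, idx, drop = FALSE])
    )
    new_pos[u] <- min(idx)
    drop_idx <- c(drop_idx, idx)
  }
  keep <- setdiff(seq_along(nm), drop_idx)
  # rebuild in order: unified column sits at its first original's slot
  order_slots <- c(stats::setNames(keep, nm[keep]), new_pos)
  order_slots <- sort(order_slots)
  obs_out <- matrix(NA_real_, nrow(observed), length(order_slots),
                    dimnames = list(NULL, names(order_slots)))
  com_out <- if (is.null(complete)) NULL else obs_out
  meta_rows <- list()
  for (i in seq_along(order_slots)) {
    colname <- names(order_slots)[i]
    if (colname %in% unified_names) {
      obs_out[, i] <- new_cols[[colname]]$obs
      if (!is.null(com_out)) com_out[, i] <- new_cols[[colname]]$com
      meta_rows[[i]] <- data.frame(
        name = colname, kind = "diagnosis", ref_low = NA_real_,
        ref_high = NA_real_, synonym_group = colname, impute_exclude = FALSE,
        stringsAsFactors = FALSE)
    } else {
      j <- match(colname, nm)
      obs_out[, i] <- observed[, j]
      if (!is.null(com_out)) com_out[, i] <- complete[, j]
      meta_rows[[i]] <- cohort$meta[j, , drop = FALSE]
    }
  }
  meta_out <- do.call(rbind, meta_rows)
  rownames(meta_out) <- NULL
  out <- emr_cohort(obs_out, cohort$outcome, meta_out, complete = com_out)
  attr(out, "merge_log") <- data.frame(original = mapping$original,
                                       unified = mapping$unified,
                                       stringsAsFactors = FALSE)
  out
}

new_screen_report <- function(kept, dropped, threshold, criterion) {
  structure(list(kept = kept, dropped = dropped, threshold = threshold,
                 criterion = criterion),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> criterion: ", x$criterion,
      " (threshold ", x$threshold, ")\n", sep = "")
  cat("  kept:    ", length(x$kept), " variable(s)\n", sep = "")
  cat("  dropped: ", nrow(x$dropped), " variable(s)\n", sep = "")
  if (nrow(x$dropped)) print(utils::head(x$dropped, 10))
  invisible(x)
}

#' Filter variables by missing fraction
#'
#' A variable is dropped when its fraction of missing cells is greater
#' than or equal to the threshold (the boundary drops: a variable missing
#' in exactly 80\% of patients is filtered out at the default threshold).
#'
#' @param cohort an `emr_cohort`.
#' @param threshold missing-fraction threshold in (0, 1\]; default 0.8.
#' @return a `screen_report` with `kept` (names), `dropped` (data frame of
#'   variable, reason, value) and the threshold used.
#' @export
filter_missingness <- function(cohort, threshold = 0.8) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  frac <- colMeans(cohort$mask)
  drop <- frac >= threshold
  dropped <- data.frame(variable = cohort$meta$name[drop],
                        reason = rep("missingness", sum(drop)),
                        value = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  new_screen_report(cohort$meta$name[!drop], dropped, threshold, "missingness")
}

#' Filter sparse diagnosis variables by prevalence
#'
#' Diagnosis indicators are kept only when they appear in strictly more
#' than `threshold` of the population. With `per_class = TRUE` (the
#' default) the prevalence is computed within each outcome class and the
#' variable is kept if it clears the threshold in either class, so a
#' diagnosis common among the rare positives is not lost to the majority
#' denominator. Non-diagnosis variables are always kept.
#'
#' @param cohort an `emr_cohort`.
#' @param threshold prevalence threshold; comparison is strict (`>`).
#' @param per_class compute prevalence within each outcome class.
#' @return a `screen_report`.
#' @export
filter_prevalence <- function(cohort, threshold = 0.05, per_class = TRUE) {
  stopifnot(inherits(cohort, "emr_cohort"))
  diag_vars <- variables_of_kind(cohort, "diagnosis")
  idx <- match(diag_vars, cohort$meta$name)
  for (j in idx) {
    vals <- cohort$observed[, j]
    if (!all(vals %in% c(0, 1) | is.na(vals)))
      stop("non-binary variable passed to prevalence filter: ",
           cohort$meta$name[j])
  }
  prev_of <- function(x) mean(x == 1, na.rm = TRUE)
  keep <- logical(length(idx)); value <- numeric(length(idx))
  for (i in seq_along(idx)) {
    x <- cohort$observed[, idx[i]]
    if (per_class) {
      p1 <- prev_of(x[cohort$outcome == 1L])
      p0 <- prev_of(x[cohort$outcome == 0L])
      value[i] <- max(p1, p0, na.rm = TRUE)
    } else {
      value[i] <- prev_of(x)
    }
    keep[i] <- is.finite(value[i]) && value[i] > threshold
  }
  kept <- c(setdiff(cohort$meta$name, diag_vars), diag_vars[keep])
  kept <- cohort$meta$name[cohort$meta$name %in% kept]  # preserve order
  dropped <- data.frame(variable = diag_vars[!keep],
                        reason = rep("prevalence", sum(!keep)),
                        value = value[!keep],
                        stringsAsFactors = FALSE)
  new_screen_report(kept, dropped, threshold, "prevalence")
}

#' Apply a screen report to a cohort
#' @param cohort an `emr_cohort`.
#' @param report a `screen_report`.
#' @return the cohort restricted to the kept variables.
#' @export
apply_screen <- function(cohort, report) {
  stopifnot(inherits(report, "screen_report"))
  subset_cohort(cohort, report$kept)
}

#' Discretize continuous labs into low / normal / high
#'
#' Maps every continuous variable onto the ordinal codes 0 (L: below the
#' reference range), 1 (N: within it, bounds inclusive) and 2 (H: above
#' it), using the per-variable reference range in the cohort metadata.
#' Missing values stay missing; the variable kind becomes `"ordinal"`, so
#' already-coded columns are never re-converted.
#'
#' @param cohort an `emr_cohort` whose continuous variables all carry a
#'   reference range.
#' @return the cohort with continuous columns replaced by ordinal codes.
#' @export
discretize_lnh <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  cont <- which(cohort$meta$kind == "continuous")
  observed <- cohort$observed
  complete <- cohort$complete
  meta <- cohort$meta
  for (j in cont) {
    lo <- meta$ref_low[j]; hi <- meta$ref_high[j]
    if (is.na(lo) || is.na(hi))
      stop("missing reference range for variable: ", meta$name[j])
    code <- function(x) ifelse(is.na(x), NA_real_,
                               ifelse(x < lo, 0, ifelse(x > hi, 2, 1)))
    observed[, j] <- code(observed[, j])
    if (!is.null(complete)) complete[, j] <- code(complete[, j])
    meta$kind[j] <- "ordinal"
  }
  emr_cohort(observed, cohort$outcome, meta, complete = complete)
}
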