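#' Cohort container for emergency-medicine tabular data
#'
#' An `emr_cohort` bundles the patient-by-variable matrix together with the
#' missingness mask, the binary outcome and per-variable metadata. When the
#' cohort is synthetic the ground-truth complete matrix is retained so that
#' imputation quality can be measured against it.
#'
#' @param observed numeric matrix (patients x variables); `NA` marks a
#'   missing cell.
#' @param outcome integer vector of 0/1 outcome labels, one per row.
#' @param meta data frame with one row per variable and columns
#'   `name`, `kind` (one of `"continuous"`, `"discrete"`, `"diagnosis"`,
#'   `"ordinal"`), `ref_low`, `ref_high` (reference range for continuous
#'   variables, otherwise `NA`), `synonym_group`, and `impute_exclude`
#'   (logical; identifier-style variables such as age and gender that are
#'   used as predictors but never imputed).
#' @param complete optional numeric matrix of the same shape holding the
#'   ground truth with no missing entries; defaults to `observed` when that
#'   has no missing cells.
#'
#' @return An object of class `emr_cohort`: a list with elements
#'   `observed`, `complete` (may be `NULL` for real data), `mask`
#'   (logical matrix, `TRUE` where `observed` is missing), `outcome`, `meta`.
#' @export
emr_cohort <- function(observed, outcome, meta, complete = NULL) {
  observed <- as.matrix(observed)
  storage.mode(observed) <- "double"
  if (is.null(complete) && !anyNA(observed)) complete <- observed
  if (!is.null(complete)) {
    complete <- as.matrix(complete)
    storage.mode(complete) <- "double"
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("name", "kind")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("meta lacks required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("ref_low", "ref_high")) if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  if (is.null(meta$synonym_group)) meta$synonym_group <- meta$name
  if (is.null(meta$impute_exclude)) meta$impute_exclude <- FALSE
  if (nrow(meta) != ncol(observed))
    stop("meta has ", nrow(meta), " rows but observed has ", ncol(observed), " columns")
  if (anyDuplicated(meta$name))
    stop("duplicated variable names in meta")
  colnames(observed) <- meta$name
  if (length(outcome) != nrow(observed))
    stop("outcome length ", length(outcome), " != number of rows ", nrow(observed))
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L)))
    stop("outcome values must be 0 or 1")
  bad_kind <- setdiff(unique(meta$kind), c("continuous", "discrete", "diagnosis", "ordinal"))
  if (length(bad_kind))
    stop("unknown variable kind(s): ", paste(bad_kind, collapse = ", "))
  if (!is.null(complete)) {
    if (!identical(dim(complete), dim(observed)))
      stop("complete and observed must have identical dimensions")
    if (anyNA(complete))
      stop("complete matrix must have no missing entries")
    colnames(complete) <- meta$name
  }
  structure(
    list(
      observed = observed,
      complete = complete,
      mask = is.na(observed),
      outcome = outcome,
      meta = meta
    ),
    class = "emr_cohort"
  )
}

#' @export
print.emr_cohort <- function(x, ...) {
  n <- nrow(x$observed)
  m <- ncol(x$observed)
  cat("<emr_cohort> ", n, " patients x ", m, " variables\n", sep = "")
  cat("  outcome: ", sum(x$outcome == 1L), " positive / ", sum(x$outcome == 0L),
      " negative (prevalence ", sprintf("%.1f%%", 100 * mean(x$outcome)), ")\n", sep = "")
  kinds <- table(x$meta$kind)
  cat("  kinds:   ", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  missing: ", sprintf("%.1f%%", 100 * mean(x$mask)), " of cells",
      if (is.null(x$complete)) "" else " (ground truth retained)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.emr_cohort <- function(object, ...) {
  frac <- colMeans(object$mask)
  out <- data.frame(
    name = object$meta$name,
    kind = object$meta$kind,
    missing_fraction = unname(frac),
    stringsAsFactors = FALSE
  )
  out
}

#' Variables of a given kind
#' @param cohort an `emr_cohort`.
#' @param kind one or more variable kinds.
#' @return character vector of variable names.
#' @export
variables_of_kind <- function(cohort, kind) {
  stopifnot(inherits(cohort, "emr_cohort"))
  cohort$meta$name[cohort$meta$kind %in% kind]
}

#' Restrict a cohort to a subset of variables
#' @param cohort an `emr_cohort`.
#' @param keep character vector of variable names to retain (order kept as
#'   in the cohort).
#' @return the subset `emr_cohort`.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "emr_cohort"))
  unknown <- setdiff(keep, cohort$meta$name)
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  idx <- which(cohort$meta$name %in% keep)
  emr_cohort(
    observed = cohort$observed[, idx, drop = FALSE],
    outcome = cohort$outcome,
    meta = cohort$meta[idx, , drop = FALSE],
    complete = if (is.null(cohort$complete)) NULL else cohort$complete[, idx, drop = FALSE]
  )
}

#' Write a cohort to plain-text CSV files
#'
#' Writes the observed matrix plus outcome (`cohort.csv`, empty cells mark
#' missing values), the variable metadata (`meta.csv`) and the missingness
#' mask (`mask.csv`) into a directory.
#'
#' @param cohort an `emr_cohort`.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  meta_path <- file.path(dir, "meta.csv")
  mask_path <- file.path(dir, "mask.csv")
  df <- as.data.frame(cohort$observed)
  df$outcome <- cohort$outcome
  utils::write.csv(df, cohort_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$meta, meta_path, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(cohort$mask) * 1L, mask_path, row.names = FALSE)
  invisible(c(cohort = cohort_path, meta = meta_path, mask = mask_path))
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `cohort.csv` and `meta.csv`.
#' @return an `emr_cohort` (no ground-truth matrix).
#' @export
read_cohort <- function(dir) {
  cohort_path <- file.path(dir, "cohort.csv")
  meta_path <- file.path(dir, "meta.csv")
  for (p in c(cohort_path, meta_path))
    if (!file.exists(p)) stop("missing file: ", p)
  df <- utils::read.csv(cohort_path, na.strings = "", check.names = FALSE)
  meta <- utils::read.csv(meta_path, na.strings = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"outcome" %in% names(df)) stop("cohort.csv lacks an 'outcome' column")
  outcome <- df$outcome
  df$outcome <- NULL
  emr_cohort(as.matrix(df), outcome, meta)
}
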