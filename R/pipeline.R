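#' Default pipeline configuration
#'
#' All study defaults preset: 0.8 missingness threshold, 0.05 prevalence
#' threshold, ratios 1:10/1:5/1:2/1:1, 500 subsampling repeats over 70/30
#' splits, 0.982 cumulative-variance target. Any element can be overridden
#' through `...` or by supplying a YAML file to [run_pipeline()].
#'
#' @param ... overrides of individual elements.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # input: either a directory with cohort.csv/meta.csv, or a simulate spec
    cohort_dir = NULL,
    simulate = list(n_pos = 100, n_neg = 1900, n_continuous = 8,
                    n_discrete = 3, n_diagnosis = 6,
                    diagnosis_prevalence = 0.1, effect_sizes = 0.8,
                    diagnosis_effect = 1,
                    missing_rate = 0.3, missing_mechanism = "MAR"),
    synonym_map = NULL,            # path to CSV(original,unified) or data frame
    miss_threshold = 0.8,
    prev_threshold = 0.05,
    prev_per_class = TRUE,
    discretize = TRUE,
    impute = list(num_trees = 100, split = 0.2, min_obs = 25),
    ratios = list(c(1, 10), c(1, 5), c(1, 2), c(1, 1)),
    variance_threshold = 0.982,
    pc_k = NULL,                   # explicit rank overrides the variance rule
    chi_alpha = 0.10,
    uni_alpha = 0.05,
    expert_variables = character(),
    groups = NULL,                 # named list; NULL = auto-grouped candidates
    eval_B = 100,
    train_fraction = 0.7,
    test_fraction = 0.3,
    out_dir = NULL
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    raw <- yaml::read_yaml(config)
    cfg <- default_pipeline_config()
    cfg[names(raw)] <- raw
    if (!is.null(cfg$ratios))
      cfg$ratios <- lapply(cfg$ratios, function(r) {
        if (is.character(r)) as.numeric(strsplit(r, ":")[[1]]) else as.numeric(r)
      })
    return(cfg)
  }
  if (is.list(config)) {
    cfg <- default_pipeline_config()
    cfg[names(config)] <- config
    return(cfg)
  }
  stop("config must be a pipeline_config, a list, or a YAML path")
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config validation: out_dir is required")
  if (cfg$miss_threshold <= 0 || cfg$miss_threshold > 1)
    stop("config validation: miss_threshold must lie in (0,1]")
  if (cfg$prev_threshold < 0 || cfg$prev_threshold >= 1)
    stop("config validation: prev_threshold must lie in [0,1)")
  if (cfg$variance_threshold <= 0 || cfg$variance_threshold > 1)
    stop("config validation: variance_threshold must lie in (0,1]")
  if (cfg$eval_B < 1) stop("config validation: eval_B must be >= 1")
  if (!is.null(cfg$cohort_dir) && !dir.exists(cfg$cohort_dir))
    stop("config validation: cohort_dir does not exist: ", cfg$cohort_dir)
  if (!is.null(cfg$synonym_map) && is.character(cfg$synonym_map) &&
      !file.exists(cfg$synonym_map))
    stop("config validation: synonym_map file not found: ", cfg$synonym_map)
  invisible(cfg)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  path
}

#' Run the full preprocessing-and-modeling pipeline
#'
#' Executes the stages in their canonical order — screen (synonym merge,
#' missingness filter, prevalence filter, L/N/H discretization), impute,
#' rebalance, PCA-reduce the diagnosis track, select/fit, evaluate — on a
#' loaded or simulated cohort, writing every intermediate artifact plus a
#' machine-readable manifest into the run directory. A failing stage halts
#' the run with the stage name; artifacts written before the failure
#' persist.
#'
#' @param config a `pipeline_config`, plain list of overrides, or a YAML
#'   file path.
#' @return the run directory path (invisibly); artifacts inside include
#'   `manifest.json` linking every file to the configuration and seed.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(load_pipeline_config(config))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  artifacts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- input -----------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(cfg$cohort_dir)) {
      read_cohort(cfg$cohort_dir)
    } else {
      spec <- do.call(cohort_spec, c(cfg$simulate, list(seed = cfg$seed)))
      generate_cohort(spec)
    }
  })
  artifacts$input <- write_cohort(cohort, file.path(out, "00_input"))

  # --- screening -------------------------------------------------------
  screened <- stage("screen", {
    if (!is.null(cfg$synonym_map)) {
      mapping <- if (is.character(cfg$synonym_map))
        utils::read.csv(cfg$synonym_map, stringsAsFactors = FALSE)
      else as.data.frame(cfg$synonym_map)
      cohort <- merge_synonyms(cohort, mapping)
    }
    miss_report <- filter_missingness(cohort, cfg$miss_threshold)
    cohort <- apply_screen(cohort, miss_report)
    prev_report <- filter_prevalence(cohort, cfg$prev_threshold,
                                     per_class = cfg$prev_per_class)
    cohort <- apply_screen(cohort, prev_report)
    artifacts$screen <- write_json_artifact(
      list(missingness = list(kept = miss_report$kept,
                              dropped = miss_report$dropped),
           prevalence = list(kept = prev_report$kept,
                             dropped = prev_report$dropped)),
      file.path(out, "01_screen_report.json"))
    cohort
  })
  artifacts$screened <- write_cohort(screened, file.path(out, "01_screened"))

  # --- imputation ------------------------------------------------------
  imputed <- stage("impute", {
    rep <- evaluate_imputation(screened, split = cfg$impute$split,
                               seed = cfg$seed, min_obs = cfg$impute$min_obs,
                               num_trees = cfg$impute$num_trees)
    artifacts$impute_report <- write_json_artifact(
      list(per_variable = rep$per_variable, summary = rep$summary),
      file.path(out, "02_imputation_report.json"))
    rf_impute(screened, num_trees = cfg$impute$num_trees, seed = cfg$seed)
  })
  artifacts$imputed <- write_cohort(imputed, file.path(out, "02_imputed"))

  # labs stay continuous for imputation and clustering; the ordinal L/N/H
  # coding applies to the risk-factor analysis track
  modeling_cohort <- if (isTRUE(cfg$discretize) &&
                           length(variables_of_kind(imputed, "continuous")))
    discretize_lnh(imputed) else imputed

  # --- rebalance -------------------------------------------------------
  datasets <- stage("rebalance", {
    lab_vars <- variables_of_kind(imputed, c("continuous", "ordinal", "discrete"))
    reb_cohort <- if (length(lab_vars)) subset_cohort(imputed, lab_vars) else imputed
    build_ratio_datasets(reb_cohort, ratios = cfg$ratios, seed = cfg$seed)
  })
  artifacts$rebalance <- write_json_artifact(
    lapply(datasets, function(d) list(ratio = d$ratio, indices = d$indices,
                                      provenance = d$provenance)),
    file.path(out, "03_ratio_datasets.json"))

  # --- sparse reduction (diagnosis track) ------------------------------
  diag_vars <- variables_of_kind(imputed, "diagnosis")
  pc <- NULL
  if (length(diag_vars) >= 2) {
    pc <- stage("reduce", {
      xd <- imputed$observed[, diag_vars, drop = FALSE]
      model <- pca_fit(xd)
      model$k <- if (!is.null(cfg$pc_k)) as.integer(cfg$pc_k)
                 else select_k(model, cfg$variance_threshold)
      artifacts$pc_model <- write_json_artifact(
        list(center = as.list(model$center),
             eigenvalues = model$eigenvalues,
             eigenvectors = apply(model$vectors, 2, as.numeric, simplify = FALSE),
             variable_names = model$variable_names, k = model$k),
        file.path(out, "04_pc_model.json"))
      model
    })
  }

  # --- selection and final fit (lab track, 1:1 dataset) ----------------
  selection <- stage("select", {
    ds11 <- datasets[["1:1"]]
    if (is.null(ds11)) ds11 <- datasets[[length(datasets)]]
    lab_vars <- variables_of_kind(modeling_cohort, c("ordinal", "discrete"))
    if (!length(lab_vars)) return(NULL)
    sel_cohort <- subset_cohort(modeling_cohort, lab_vars)
    sel_cohort <- emr_cohort(sel_cohort$observed[ds11$indices, , drop = FALSE],
                             sel_cohort$outcome[ds11$indices], sel_cohort$meta)
    tr <- chi_square_filter(sel_cohort, alpha = cfg$chi_alpha)
    tr <- univariate_lr_filter(sel_cohort, alpha = cfg$uni_alpha, trace = tr)
    expert <- intersect(cfg$expert_variables,
                        c(tr$chi_square_excluded$variable,
                          tr$univariate_excluded$variable))
    tr <- reintroduce(tr, expert)
    groups <- cfg$groups
    if (is.null(groups)) {
      # auto-group: statistically significant candidates in chunks of 3,
      # expert reintroductions as their own group
      sig <- setdiff(tr$candidates, tr$reintroduced)
      groups <- split(sig, ceiling(seq_along(sig) / 3))
      names(groups) <- paste0("group", seq_along(groups))
      if (length(tr$reintroduced))
        groups[[paste0("group", length(groups) + 1L)]] <- tr$reintroduced
    }
    groups <- Filter(length, groups)
    if (length(groups) >= 1)
      tr <- forward_group_selection(sel_cohort, groups, B = min(cfg$eval_B, 50),
                                    seed = cfg$seed,
                                    train_fraction = cfg$train_fraction,
                                    trace = tr)
    fit <- if (length(tr$final_variables))
      fit_multivariate_lr(sel_cohort, tr$final_variables) else NULL
    list(trace = tr, fit = fit)
  })
  if (!is.null(selection)) {
    artifacts$selection <- write_json_artifact(
      list(chi_square_excluded = selection$trace$chi_square_excluded,
           univariate_excluded = selection$trace$univariate_excluded,
           reintroduced = selection$trace$reintroduced,
           group_metrics = selection$trace$group_metrics,
           forward_path = selection$trace$forward_path,
           final_variables = selection$trace$final_variables,
           fit = if (!is.null(selection$fit)) summary(selection$fit) else NULL),
      file.path(out, "05_selection.json"))
  }

  # --- diagnosis-track regression --------------------------------------
  pcreg <- NULL
  if (!is.null(pc)) {
    pcreg <- stage("pc_regression", {
      xd <- imputed$observed[, diag_vars, drop = FALSE]
      raw_fit <- tryCatch(
        fit_multivariate_lr(x = as.data.frame(xd), outcome = imputed$outcome),
        error = function(e) NULL)
      scores <- pc_transform(pc, xd)
      pr <- pc_regression(scores, imputed$outcome, pc)
      artifacts$pc_regression <- write_json_artifact(
        list(raw_separation = if (is.null(raw_fit)) NA else raw_fit$separation_flag,
             pc_table = pr$pc_table,
             significant_components = pr$significant_components,
             risk_factors = pr$risk_factors),
        file.path(out, "06_pc_regression.json"))
      pr
    })
  }

  # --- evaluation ------------------------------------------------------
  evaluation <- stage("evaluate", {
    lab_vars <- variables_of_kind(modeling_cohort,
                                  c("continuous", "ordinal", "discrete"))
    eval_cohort <- if (length(lab_vars))
      subset_cohort(modeling_cohort, lab_vars) else modeling_cohort
    ratio_experiment(eval_cohort, ratios = cfg$ratios, seed = cfg$seed,
                     test_fraction = cfg$test_fraction, B = cfg$eval_B)
  })
  artifacts$evaluation <- write_json_artifact(
    list(table = evaluation$table,
         reliability = evaluation$reliability),
    file.path(out, "07_evaluation.json"))

  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   artifacts = lapply(artifacts, unname),
                   created = "run_pipeline")
  write_json_artifact(manifest, file.path(out, "manifest.json"))
  invisible(out)
}

#' Assemble human-readable report tables from a completed run
#'
#' Reads the artifacts of a [run_pipeline()] run directory and writes CSV
#' report tables: per-variable missingness summary, the chi-square and
#' univariate filter tables, group comparison, final multivariate odds
#' ratios, diagnosis prevalence counts and the PC regression table.
#' Sections whose artifacts are absent are skipped and listed in the
#' report manifest. Regeneration is idempotent.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return invisibly, the paths written.
#' @export
render_report <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json")))
    stop("not a completed run directory (no manifest.json): ", run_dir)
  report_dir <- file.path(run_dir, "report")
  if (!dir.exists(report_dir)) dir.create(report_dir)
  written <- character(); skipped <- character()
  emit <- function(df, name) {
    p <- file.path(report_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written <- c(written, p)
  }

  inp <- file.path(run_dir, "00_input")
  if (dir.exists(inp)) {
    cohort <- read_cohort(inp)
    emit(data.frame(variable = cohort$meta$name, kind = cohort$meta$kind,
                    missing_fraction = colMeans(cohort$mask)),
         "table_missingness.csv")
    diag_vars <- variables_of_kind(cohort, "diagnosis")
    if (length(diag_vars)) {
      idx <- match(diag_vars, cohort$meta$name)
      pos <- cohort$outcome == 1L
      emit(data.frame(
        variable = diag_vars,
        n_positive = colSums(cohort$observed[pos, idx, drop = FALSE] == 1,
                             na.rm = TRUE),
        n_negative = colSums(cohort$observed[!pos, idx, drop = FALSE] == 1,
                             na.rm = TRUE)), "table_prevalence.csv")
    }
  } else skipped <- c(skipped, "missingness/prevalence")

  sel_path <- file.path(run_dir, "05_selection.json")
  if (file.exists(sel_path)) {
    sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
    if (!is.null(sel$chi_square_excluded) && length(sel$chi_square_excluded))
      emit(as.data.frame(sel$chi_square_excluded), "table_chisq_excluded.csv")
    if (!is.null(sel$univariate_excluded) && length(sel$univariate_excluded))
      emit(as.data.frame(sel$univariate_excluded), "table_univariate_excluded.csv")
    if (!is.null(sel$group_metrics))
      emit(as.data.frame(sel$group_metrics), "table_groups.csv")
    if (!is.null(sel$fit))
      emit(as.data.frame(sel$fit), "table_multivariate.csv")
  } else skipped <- c(skipped, "selection")

  pcr_path <- file.path(run_dir, "06_pc_regression.json")
  if (file.exists(pcr_path)) {
    pcr <- jsonlite::read_json(pcr_path, simplifyVector = TRUE)
    emit(as.data.frame(pcr$pc_table), "table_pc_regression.csv")
  } else skipped <- c(skipped, "pc_regression")

  ev_path <- file.path(run_dir, "07_evaluation.json")
  if (file.exists(ev_path)) {
    ev <- jsonlite::read_json(ev_path, simplifyVector = TRUE)
    emit(as.data.frame(ev$table), "table_ratio_metrics.csv")
  } else skipped <- c(skipped, "evaluation")

  write_json_artifact(list(written = written, skipped_sections = skipped),
                      file.path(report_dir, "report_manifest.json"))
  invisible(written)
}
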