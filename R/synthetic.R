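#' Specification of a synthetic EMR cohort
#'
#' Describes a cohort with the statistical pathologies the preprocessing
#' pipeline targets: heavy class imbalance, per-variable structured
#' missingness, and sparse binary diagnosis indicators including perfectly
#' separating ones. Defaults emulate the sudden-death study shape: roughly
#' 5\% positive prevalence, mixed continuous / discrete / diagnosis
#' variables, and sparse diagnosis prevalences.
#'
#' Continuous variables are class-conditional Gaussians: the effect size of
#' variable j is the mean shift (in SD units) added to positive-class rows.
#' With `dependence > 0` all continuous variables share a latent factor, so
#' they are mutually informative and random-forest imputation has signal to
#' recover. Discrete variables are either i.i.d. categorical
#' (`discrete_dependence = 0`) or noisy quantile-binned copies of a
#' continuous partner variable. Diagnosis variables are Bernoulli at the
#' given prevalence; `diagnosis_effect` shifts the prevalence of positives
#' on the log-odds scale, and variables listed in `separating_vars` occur
#' only in positive rows (quasi-complete separation by construction).
#'
#' @param n_pos,n_neg positive / negative class sizes (`n_pos + n_neg >= 2`).
#' @param n_continuous,n_discrete,n_diagnosis variable counts per kind.
#' @param discrete_levels number of categories per discrete variable
#'   (recycled).
#' @param discrete_probs optional list of per-variable category probability
#'   vectors (used when `discrete_dependence = 0`).
#' @param diagnosis_prevalence per-variable probability in \[0,1\] (recycled).
#' @param effect_sizes per-continuous-variable mean shift for positives
#'   (recycled).
#' @param diagnosis_effect per-diagnosis-variable log-odds shift of the
#'   prevalence in positives (recycled).
#' @param dependence shared-latent-factor loading in \[0,1) for continuous
#'   variables.
#' @param discrete_dependence correlation in \[0,1) between a discrete
#'   variable's latent score and its continuous partner.
#' @param missing_rate per-variable missingness fraction in \[0,1\]
#'   (recycled; 0 = fully observed).
#' @param missing_mechanism one of `"MCAR"`, `"MAR"`, `"MNAR"` per variable
#'   (recycled).
#' @param mar_driver name of the fully observed variable whose value drives
#'   MAR missingness; defaults to the first variable with missing rate 0.
#' @param separating_vars character vector of diagnosis variable names
#'   forced to zero in all negative rows.
#' @param ref_low,ref_high reference range used for every continuous
#'   variable (the generator draws standard-normal marginals, so the
#'   default (-1, 1) band is the central ~68\%).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   cohort.
#'
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [apply_missingness()]
#' @export
cohort_spec <- function(n_pos = 977, n_neg = 17959,
                        n_continuous = 10, n_discrete = 5, n_diagnosis = 8,
                        discrete_levels = 3, discrete_probs = NULL,
                        diagnosis_prevalence = 0.08,
                        effect_sizes = 0.8, diagnosis_effect = 0,
                        dependence = 0.5, discrete_dependence = 0.7,
                        missing_rate = 0, missing_mechanism = "MCAR",
                        mar_driver = NULL,
                        separating_vars = character(),
                        ref_low = -1, ref_high = 1,
                        seed = 1L) {
  check_count <- function(x, nm, min = 0L) {
    if (length(x) != 1L || is.na(x) || x < min || x != round(x))
      stop("invalid field '", nm, "': must be a single integer >= ", min)
    as.integer(x)
  }
  check_unit <- function(x, nm) {
    if (anyNA(x) || any(x < 0) || any(x > 1))
      stop("invalid field '", nm, "': values must lie in [0,1]")
    as.numeric(x)
  }
  n_pos <- check_count(n_pos, "n_pos"); n_neg <- check_count(n_neg, "n_neg")
  if (n_pos + n_neg < 2) stop("invalid field 'n_pos/n_neg': need n_pos + n_neg >= 2")
  n_continuous <- check_count(n_continuous, "n_continuous")
  n_discrete <- check_count(n_discrete, "n_discrete")
  n_diagnosis <- check_count(n_diagnosis, "n_diagnosis")
  if (n_continuous + n_discrete + n_diagnosis < 1)
    stop("invalid field 'n_continuous/n_discrete/n_diagnosis': at least one variable required")
  diagnosis_prevalence <- rep_len(check_unit(diagnosis_prevalence, "diagnosis_prevalence"),
                                  max(n_diagnosis, 1L))
  missing_rate <- check_unit(missing_rate, "missing_rate")
  missing_mechanism <- toupper(as.character(missing_mechanism))
  bad <- setdiff(unique(missing_mechanism), c("MCAR", "MAR", "MNAR"))
  if (length(bad))
    stop("invalid field 'missing_mechanism': ", paste(bad, collapse = ", "))
  check_unit(dependence, "dependence"); check_unit(discrete_dependence, "discrete_dependence")
  if (dependence >= 1 || discrete_dependence >= 1)
    stop("invalid field 'dependence': must be < 1")
  discrete_levels <- rep_len(as.integer(discrete_levels), max(n_discrete, 1L))
  if (n_discrete > 0 && any(discrete_levels < 2))
    stop("invalid field 'discrete_levels': need >= 2 categories")
  seed <- check_count(seed, "seed")
  structure(
    list(n_pos = n_pos, n_neg = n_neg,
         n_continuous = n_continuous, n_discrete = n_discrete,
         n_diagnosis = n_diagnosis,
         discrete_levels = discrete_levels, discrete_probs = discrete_probs,
         diagnosis_prevalence = diagnosis_prevalence,
         effect_sizes = rep_len(as.numeric(effect_sizes), max(n_continuous, 1L)),
         diagnosis_effect = rep_len(as.numeric(diagnosis_effect), max(n_diagnosis, 1L)),
         dependence = as.numeric(dependence),
         discrete_dependence = as.numeric(discrete_dependence),
         missing_rate = missing_rate, missing_mechanism = missing_mechanism,
         mar_driver = mar_driver,
         separating_vars = as.character(separating_vars),
         ref_low = as.numeric(ref_low), ref_high = as.numeric(ref_high),
         seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic EMR cohort
#'
#' Draws a complete ground-truth matrix according to a [cohort_spec()] and
#' then applies the requested per-variable missingness. The ground truth is
#' retained in the cohort so downstream recovery tests can compare imputed
#' values against it.
#'
#' @param spec a [cohort_spec()].
#' @return an `emr_cohort` with exactly `n_pos` positive and `n_neg`
#'   negative rows.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  outcome <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))

  cols <- list(); meta <- list()
  cont_names <- if (spec$n_continuous > 0) sprintf("lab_%02d", seq_len(spec$n_continuous)) else character()
  # continuous: shared latent factor + idiosyncratic noise + class shift
  if (spec$n_continuous > 0) {
    z <- rnorm(n)
    a <- sqrt(spec$dependence)
    b <- sqrt(1 - spec$dependence)
    for (j in seq_len(spec$n_continuous)) {
      x <- a * z + b * rnorm(n) + spec$effect_sizes[j] * outcome
      cols[[cont_names[j]]] <- x
      meta[[length(meta) + 1L]] <- data.frame(
        name = cont_names[j], kind = "continuous",
        ref_low = spec$ref_low, ref_high = spec$ref_high,
        synonym_group = cont_names[j], impute_exclude = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (spec$n_discrete > 0) {
    for (j in seq_len(spec$n_discrete)) {
      nm <- sprintf("cat_%02d", j)
      L <- spec$discrete_levels[j]
      if (spec$discrete_dependence > 0 && spec$n_continuous > 0) {
        partner <- cols[[cont_names[((j - 1L) %% spec$n_continuous) + 1L]]]
        r <- spec$discrete_dependence
        latent <- r * partner + sqrt(1 - r^2) * rnorm(n)
        brk <- stats::quantile(latent, probs = seq(0, 1, length.out = L + 1L))
        brk[1] <- -Inf; brk[length(brk)] <- Inf
        x <- as.integer(cut(latent, breaks = unique(brk), labels = FALSE)) - 1L
      } else {
        probs <- if (!is.null(spec$discrete_probs)) spec$discrete_probs[[j]] else rep(1 / L, L)
        x <- sample.int(L, n, replace = TRUE, prob = probs) - 1L
      }
      cols[[nm]] <- as.numeric(x)
      meta[[length(meta) + 1L]] <- data.frame(
        name = nm, kind = "discrete", ref_low = NA_real_, ref_high = NA_real_,
        synonym_group = nm, impute_exclude = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (spec$n_diagnosis > 0) {
    diag_names <- sprintf("dx_%02d", seq_len(spec$n_diagnosis))
    sep_unknown <- setdiff(spec$separating_vars, diag_names)
    if (length(sep_unknown))
      stop("invalid field 'separating_vars': unknown diagnosis variable(s) ",
           paste(sep_unknown, collapse = ", "))
    for (j in seq_len(spec$n_diagnosis)) {
      nm <- diag_names[j]
      p <- spec$diagnosis_prevalence[j]
      p_pos <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) +
                               spec$diagnosis_effect[j])
      x <- numeric(n)
      x[outcome == 1L] <- rbinom(spec$n_pos, 1L, p_pos)
      if (nm %in% spec$separating_vars) {
        x[outcome == 0L] <- 0
      } else {
        x[outcome == 0L] <- rbinom(spec$n_neg, 1L, p)
      }
      cols[[nm]] <- x
      meta[[length(meta) + 1L]] <- data.frame(
        name = nm, kind = "diagnosis", ref_low = NA_real_, ref_high = NA_real_,
        synonym_group = nm, impute_exclude = FALSE, stringsAsFactors = FALSE)
    }
  } else if (length(spec$separating_vars)) {
    stop("invalid field 'separating_vars': no diagnosis variables in spec")
  }

  complete <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  cohort <- emr_cohort(complete, outcome, meta, complete = complete)

  rates <- rep_len(spec$missing_rate, ncol(complete))
  mechs <- rep_len(spec$missing_mechanism, ncol(complete))
  if (any(rates > 0)) {
    driver <- spec$mar_driver
    if (is.null(driver) && any(mechs == "MAR" & rates > 0)) {
      cand <- which(rates == 0)
      if (!length(cand))
        stop("MAR requested but no fully observed variable is available as driver")
      driver <- meta$name[cand[1L]]
    }
    cohort <- apply_missingness(cohort, rate = rates, mechanism = mechs,
                                mar_driver = driver, seed = spec$seed + 1L)
  }
  cohort
}

#' Apply per-variable missingness to a cohort
#'
#' Masks cells of the observed matrix under one of the three canonical
#' missingness mechanisms. MCAR masks cells by an independent Bernoulli
#' draw at the requested rate. MAR splits rows at the median of a named
#' fully observed driver variable and masks rows above the median at three
#' times the rate of rows below it (expected overall rate equals the
#' request). MNAR masks the cells whose own value lies in the top `rate`
#' quantile of the variable, so missingness depends on the unobserved value
#' itself.
#'
#' @param cohort an `emr_cohort` with a retained complete matrix.
#' @param rate scalar or per-variable vector of target missing fractions in
#'   \[0,1\].
#' @param mechanism scalar or per-variable vector over
#'   `c("MCAR","MAR","MNAR")`.
#' @param mar_driver name of the fully observed variable driving MAR
#'   missingness. It must itself have no missing cells and rate 0.
#' @param seed integer seed for the stochastic mechanisms.
#' @return the cohort with updated `observed` and `mask`; the complete
#'   matrix is untouched.
#' @export
apply_missingness <- function(cohort, rate, mechanism = "MCAR",
                              mar_driver = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (is.null(cohort$complete))
    stop("apply_missingness needs a cohort with a retained complete matrix")
  m <- ncol(cohort$complete)
  rate <- rep_len(as.numeric(rate), m)
  if (anyNA(rate) || any(rate < 0 | rate > 1)) stop("rates must lie in [0,1]")
  mechanism <- rep_len(toupper(as.character(mechanism)), m)
  bad <- setdiff(unique(mechanism), c("MCAR", "MAR", "MNAR"))
  if (length(bad)) stop("unknown mechanism(s): ", paste(bad, collapse = ", "))
  nm <- cohort$meta$name
  if (any(mechanism == "MAR" & rate > 0)) {
    if (is.null(mar_driver)) stop("MAR requires a named driver variable")
    di <- match(mar_driver, nm)
    if (is.na(di)) stop("unknown MAR driver variable: ", mar_driver)
    if (rate[di] > 0 || anyNA(cohort$observed[, di]))
      stop("MAR driver variable '", mar_driver, "' must be fully observed")
  }
  set.seed(seed)
  n <- nrow(cohort$complete)
  observed <- cohort$complete
  for (j in seq_len(m)) {
    r <- rate[j]
    if (r == 0) next
    miss <- switch(mechanism[j],
      MCAR = runif(n) < r,
      MAR = {
        drv <- cohort$complete[, match(mar_driver, nm)]
        hi <- drv > stats::median(drv)
        # two-tier rates averaging to r: high tier at min(1, 1.5 r)
        p_hi <- min(1, 1.5 * r)
        p_lo <- max(0, 2 * r - p_hi)
        p <- ifelse(hi, p_hi, p_lo)
        runif(n) < p
      },
      MNAR = {
        x <- cohort$complete[, j]
        k <- round(r * n)
        miss <- rep(FALSE, n)
        if (k > 0) miss[order(x, seq_len(n), decreasing = TRUE)[seq_len(k)]] <- TRUE
        miss
      })
    observed[miss, j] <- NA_real_
  }
  emr_cohort(observed, cohort$outcome, cohort$meta, complete = cohort$complete)
}
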