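#' Principal-component model via covariance eigendecomposition
#'
#' Centers the columns of `X`, forms the sample covariance
#' `C = X'X / (n - 1)` and eigendecomposes it. Because `C` is real
#' symmetric it has a full set of orthonormal eigenvectors; the components
#' are the eigenvectors sorted by descending eigenvalue, with the sign of
#' each fixed so that its largest-magnitude loading is positive. Tiny
#' negative eigenvalues from floating-point noise (above -1e-10) are
#' clamped to zero.
#'
#' @param x numeric matrix (n x m, `n >= 2`, no missing values).
#' @return an object of class `pc_model` with elements `center`,
#'   `eigenvalues` (descending), `vectors` (m x m orthonormal, columns =
#'   components), `variable_names`, `n`, and `k` (selected rank, `NULL`
#'   until [select_k()] is applied).
#' @seealso [select_k()], [pc_transform()], [loading_report()]
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values present; impute or screen first")
  if (nrow(x) < 2) stop("need at least 2 rows")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(x)))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  C <- crossprod(xc) / (nrow(x) - 1)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- eig$values
  lambda[lambda < 0 & lambda > -1e-10] <- 0
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- nms
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(list(center = stats::setNames(center, nms),
                 eigenvalues = lambda, vectors = V,
                 variable_names = nms, n = nrow(x), k = NULL),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  ev <- x$eigenvalues
  total <- sum(ev)
  cat("<pc_model> ", length(ev), " components over ", x$n, " samples\n", sep = "")
  if (total > 0) {
    frac <- cumsum(ev) / total
    shown <- utils::head(seq_along(ev), 8)
    cat("  cumulative variance:",
        paste(sprintf("PC%d %.3f", shown, frac[shown]), collapse = ", "), "\n")
  }
  if (!is.null(x$k)) cat("  selected rank k =", x$k, "\n")
  invisible(x)
}

#' Select the component rank by cumulative explained variance
#'
#' Returns the smallest `k` such that the leading `k` eigenvalues explain
#' at least `variance_threshold` of the total variance. The study default
#' is 0.982 (17 components on the original diagnosis data).
#'
#' @param model a `pc_model`.
#' @param variance_threshold fraction in (0, 1\].
#' @return the selected rank `k` (integer). Assign it back via
#'   `model$k <- select_k(model, ...)` or use the `model` argument of
#'   [pc_transform()].
#' @export
select_k <- function(model, variance_threshold = 0.982) {
  stopifnot(inherits(model, "pc_model"))
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]")
  total <- sum(model$eigenvalues)
  if (total <= 0) stop("degenerate data: total variance is zero")
  frac <- cumsum(model$eigenvalues) / total
  if (variance_threshold == 1) return(sum(model$eigenvalues > 0))
  as.integer(which(frac >= variance_threshold)[1])
}

#' Project data onto the leading principal components
#'
#' Computes `Y = (X - center) P` where `P` holds the first `k`
#' eigenvectors, reducing the m sparse original features to k dense,
#' mutually orthogonal scores.
#'
#' @param model a `pc_model`.
#' @param x matrix with the same columns the model was fitted on.
#' @param k number of components; defaults to `model$k`, or all if unset.
#' @return n x k score matrix with columns `PC1..PCk`.
#' @export
pc_transform <- function(model, x, k = NULL) {
  stopifnot(inherits(model, "pc_model"))
  x <- as.matrix(x)
  m <- length(model$variable_names)
  if (ncol(x) != m)
    stop("column mismatch: model has ", m, " variables, x has ", ncol(x))
  if (is.null(k)) k <- if (!is.null(model$k)) model$k else m
  if (k < 1 || k > m) stop("k must lie in 1..", m)
  xc <- sweep(x, 2, model$center)
  y <- xc %*% model$vectors[, seq_len(k), drop = FALSE]
  colnames(y) <- paste0("PC", seq_len(k))
  y
}

#' @export
predict.pc_model <- function(object, newdata, k = NULL, ...) {
  pc_transform(object, newdata, k = k)
}

#' Rank original variables by loading magnitude per component
#'
#' The loading of an original variable on a component reflects that
#' variable's importance in the component; ranking variables by absolute
#' loading turns significant components into interpretable risk-factor
#' lists.
#'
#' @param model a `pc_model`.
#' @param components integer vector of component indices.
#' @param top_m number of variables to report per component.
#' @return named list of data frames (`variable`, `loading`), one per
#'   component, sorted by `abs(loading)` descending.
#' @export
loading_report <- function(model, components, top_m = 3) {
  stopifnot(inherits(model, "pc_model"))
  m <- length(model$variable_names)
  if (any(components < 1 | components > m))
    stop("components must lie in 1..", m)
  out <- lapply(components, function(j) {
    l <- model$vectors[, j]
    ord <- order(abs(l), decreasing = TRUE)
    utils::head(data.frame(variable = model$variable_names[ord],
                           loading = unname(l[ord]),
                           stringsAsFactors = FALSE), top_m)
  })
  names(out) <- paste0("PC", components)
  out
}

#' Explained-variance fractions of a fitted component model
#' @param model a `pc_model`.
#' @return numeric vector of per-component variance fractions (sums to 1).
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pc_model"))
  total <- sum(model$eigenvalues)
  if (total <= 0) stop("degenerate data: total variance is zero")
  model$eigenvalues / total
}
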