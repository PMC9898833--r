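#' Centroid-proximal k-means undersampling
#'
#' Clusters the majority-class rows into `k` groups with Euclidean k-means
#' on z-scored features and returns, for each cluster, the index of the
#' real member row closest to the cluster centroid. Because a centroid is
#' an average and not necessarily a real patient, the nearest real member
#' stands in for it, so every returned row exists in the source data.
#' Ties are broken toward the lowest row index; should a cluster come out
#' empty its centroid is re-seeded at the unselected row farthest from the
#' selected set, so exactly `k` distinct rows are always returned.
#'
#' @param x numeric matrix of majority-class rows (no missing values).
#' @param k number of representatives to keep, `1 <= k <= nrow(x)`.
#' @param seed integer seed.
#' @param nstart number of seeded k-means restarts; best total
#'   within-cluster sum of squares kept.
#' @param standardize z-score columns before clustering (default `TRUE`;
#'   Euclidean distance is scale-sensitive across lab units).
#' @return integer vector of `k` distinct row indices into `x`, ascending.
#' @export
kmeans_undersample <- function(x, k, seed = 1L, nstart = 10L,
                               standardize = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values present; impute before undersampling")
  n <- nrow(x)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1)
    stop("k must be a single positive integer")
  if (k > n) stop("k (", k, ") exceeds number of majority rows (", n, ")")
  k <- as.integer(k)
  if (k == n) return(seq_len(n))

  if (standardize) {
    # z-score columns; constant columns contribute nothing to the distance
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  } else {
    xs <- x
  }

  dup <- duplicated(xs)
  n_distinct <- n - sum(dup)
  if (k >= n_distinct) {
    # not enough distinct points for k clusters: take one index per distinct
    # row, then pad with the lowest unused indices
    sel <- which(!dup)[seq_len(min(k, n_distinct))]
    if (length(sel) < k)
      sel <- sort(c(sel, setdiff(seq_len(n), sel)[seq_len(k - length(sel))]))
    return(sort(sel))
  }

  best <- NULL
  for (r in seq_len(nstart)) {
    set.seed(seed + r - 1L)
    init <- xs[!dup, , drop = FALSE][sample.int(n_distinct, k), , drop = FALSE]
    km <- tryCatch(
      stats::kmeans(xs, centers = init, iter.max = 100L),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(xs, centers = init, iter.max = 200L))
      })
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed to converge on every restart")

  sel <- integer(0)
  for (cl in seq_len(k)) {
    members <- which(best$cluster == cl)
    if (!length(members)) next
    d <- rowSums((xs[members, , drop = FALSE] -
                    matrix(best$centers[cl, ], length(members),
                           ncol(xs), byrow = TRUE))^2)
    sel <- c(sel, members[which.min(d)])  # which.min ties -> first = lowest index
  }
  sel <- unique(sel)
  # guard: re-seed any shortfall at the farthest unselected point
  while (length(sel) < k) {
    rest <- setdiff(seq_len(n), sel)
    dmin <- vapply(rest, function(i) {
      min(rowSums((xs[sel, , drop = FALSE] -
                     matrix(xs[i, ], length(sel), ncol(xs), byrow = TRUE))^2))
    }, numeric(1))
    sel <- c(sel, rest[which.max(dmin)])
  }
  sort(sel)
}

#' Build ratio datasets by undersampling the majority class
#'
#' For each requested minority:majority ratio `(a, b)` the majority class
#' is undersampled to `k = round(n_minority * b / a)` rows (clamped to the
#' available majority count) via [kmeans_undersample()]; all minority rows
#' are always retained. The untouched original-ratio dataset is appended,
#' so the default four ratios yield five datasets.
#'
#' @param cohort an `emr_cohort` with a fully imputed observed matrix.
#' @param ratios list of 2-vectors `c(minority, majority)`; default
#'   `list(c(1,10), c(1,5), c(1,2), c(1,1))`.
#' @param seed integer seed.
#' @param nstart restarts passed to [kmeans_undersample()].
#' @return a list of `ratio_dataset` objects, each with `ratio`,
#'   `indices` (row indices into the cohort) and `provenance`.
#' @export
build_ratio_datasets <- function(cohort,
                                 ratios = list(c(1, 10), c(1, 5), c(1, 2), c(1, 1)),
                                 seed = 1L, nstart = 10L) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (anyNA(cohort$observed))
    stop("missing values present; impute before undersampling")
  minority <- which(cohort$outcome == 1L)
  majority <- which(cohort$outcome == 0L)
  if (length(minority) > length(majority)) {
    tmp <- minority; minority <- majority; majority <- tmp
  }
  out <- vector("list", length(ratios) + 1L)
  for (i in seq_along(ratios)) {
    ratio <- ratios[[i]]
    if (length(ratio) != 2L || any(ratio <= 0))
      stop("each ratio must be a positive pair c(minority, majority)")
    k <- round(length(minority) * ratio[2] / ratio[1])
    if (k < 1) stop("ratio ", ratio[1], ":", ratio[2], " implies k < 1")
    k <- min(k, length(majority))
    sel <- kmeans_undersample(cohort$observed[majority, , drop = FALSE], k,
                              seed = seed + i, nstart = nstart)
    out[[i]] <- structure(
      list(ratio = ratio,
           indices = sort(c(minority, majority[sel])),
           provenance = list(seed = seed + i, k = k, nstart = nstart)),
      class = "ratio_dataset")
  }
  out[[length(ratios) + 1L]] <- structure(
    list(ratio = c(length(minority), length(majority)),
         indices = sort(c(minority, majority)),
         provenance = list(seed = NA_integer_, k = length(majority),
                           nstart = NA_integer_, original = TRUE)),
    class = "ratio_dataset")
  names(out) <- c(vapply(ratios, function(r) paste0(r[1], ":", r[2]), ""),
                  "original")
  out
}

#' @export
print.ratio_dataset <- function(x, ...) {
  cat("<ratio_dataset> ratio ", x$ratio[1], ":", x$ratio[2], ", ",
      length(x$indices), " rows selected\n", sep = "")
  invisible(x)
}
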