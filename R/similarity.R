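# Temporal-shape comparison: banded DTW, the bounded mirror-normalized DTW
# distance, Pearson correlation, hierarchical clustering and tree export.

#' Dynamic time warping distance
#'
#' Optimal-alignment cost between two series under the standard
#' match/insert/delete step pattern with local cost `|x_i - y_j|`,
#' optionally restricted to a Sakoe-Chiba band so that only cells with
#' `|i - j| <= band` are evaluated.
#'
#' @param x,y numeric vectors (lengths may differ).
#' @param band non-negative integer half-width of the Sakoe-Chiba band, or
#'   `NULL` for the full cost matrix. Must be at least the length
#'   difference, otherwise no warping path exists.
#' @return the DTW distance (non-negative scalar).
#' @export
dtw_distance <- function(x, y, band = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty series", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("series contain NA", call. = FALSE)
  if (is.null(band)) {
    band <- -1L
  } else {
    band <- as.integer(band)
    if (band < abs(length(x) - length(y)))
      stop("band half-width ", band, " is infeasible for lengths ",
           length(x), " and ", length(y), call. = FALSE)
  }
  .dtw_cost(x, y, band)
}

default_band <- function(T) max(10L, as.integer(ceiling(0.1 * T)))

znorm <- function(x) {
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) return(NULL)
  (x - mu) / sd_pop
}

#' Bounded DTW distance between temporal shapes
#'
#' A scale-free DTW variant bounded in \[0, 1\]: each series is first
#' z-normalized (population SD), the banded DTW distance of the normalized
#' series is computed, and it is divided by the mean of each normalized
#' series' sum of absolute differences (SAD) from its mirror image (its
#' reflection about the zero mean, i.e. `-s`), which is the maximal
#' pointwise-dissimilarity scale. Residual values above 1 from pathological
#' warps are clipped to 1.
#'
#' @param x,y numeric vectors of nonzero variance.
#' @param band Sakoe-Chiba half-width; `NULL` uses
#'   `max(10, ceil(0.1 * T))` with `T` the longer length.
#' @return a distance in \[0, 1\].
#' @export
time_dtw_distance <- function(x, y, band = NULL) {
  xz <- znorm(as.numeric(x)); yz <- znorm(as.numeric(y))
  if (is.null(xz) || is.null(yz))
    stop("zero-variance series: bounded DTW undefined for constant taxa",
         call. = FALSE)
  if (is.null(band)) band <- default_band(max(length(x), length(y)))
  d <- dtw_distance(xz, yz, band = band)
  normalizer <- mean(c(2 * sum(abs(xz)), 2 * sum(abs(yz))))
  min(1, d / normalizer)
}

new_distance_matrix <- function(values, labels, metric, extra = NULL) {
  dimnames(values) <- list(labels, labels)
  attr(values, "metric") <- metric
  for (nm in names(extra)) attr(values, nm) <- extra[[nm]]
  class(values) <- c("mbtime_dist", "matrix", "array")
  values
}

#' @export
print.mbtime_dist <- function(x, ...) {
  cat(sprintf("<mbtime_dist> %s, %d x %d\n", attr(x, "metric"), nrow(x),
              ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Pairwise taxon distance matrix
#'
#' Computes the symmetric taxa-by-taxa distance matrix under one of three
#' metrics: the bounded DTW distance (`"time_dtw"`), raw banded DTW
#' (`"dtw"`), or Pearson distance `1 - r` (`"pearson"`; the raw correlation
#' matrix is kept in the `"correlation"` attribute).
#'
#' @param dataset an `mbtime_dataset`.
#' @param metric `"time_dtw"`, `"dtw"` or `"pearson"`.
#' @param band Sakoe-Chiba half-width for the DTW metrics (`NULL` =
#'   default).
#' @return an `mbtime_dist` matrix over taxa.
#' @export
distance_matrix <- function(dataset, metric = c("time_dtw", "dtw",
                                                "pearson"),
                            band = NULL) {
  stopifnot_dataset(dataset)
  metric <- match.arg(metric)
  A <- dataset$abundance
  k <- nrow(A)
  if (k < 2) stop("need >= 2 taxa", call. = FALSE)
  if (metric == "pearson") {
    if (n_time(dataset) < 3)
      stop("Pearson distance needs >= 3 time points", call. = FALSE)
    const <- apply(A, 1, stats::var) == 0
    if (any(const))
      stop("constant taxa have undefined correlation: ",
           paste(dataset$taxa[const], collapse = ", "), call. = FALSE)
    r <- stats::cor(t(A))
    d <- 1 - r
    diag(d) <- 0
    return(new_distance_matrix(d, dataset$taxa, "pearson_distance",
                               extra = list(correlation = r)))
  }
  vals <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      vals[i, j] <- vals[j, i] <-
        if (metric == "time_dtw")
          time_dtw_distance(A[i, ], A[j, ], band = band)
        else dtw_distance(A[i, ], A[j, ], band = band)
    }
  }
  new_distance_matrix(vals, dataset$taxa, metric)
}

#' Hierarchical clustering of taxa
#'
#' Agglomerative clustering over a precomputed distance matrix.
#'
#' @param dist an `mbtime_dist` over taxa (complete, no missing entries).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return an `hclust` tree with taxa as leaves.
#' @export
cluster_taxa <- function(dist, linkage = "average") {
  if (anyNA(dist)) {
    bad <- rownames(dist)[apply(is.na(dist), 1, any)]
    stop("distance matrix has missing entries for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::hclust(stats::as.dist(dist), method = linkage)
}

#' Export a cluster tree as Newick
#'
#' Branch lengths derive from the merge heights.
#'
#' @param tree an `hclust` from [cluster_taxa()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
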