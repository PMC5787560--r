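# Community-state typing: Jensen-Shannon divergence between time points and
# K-medoids (PAM) clustering with driver-taxa summaries.

kl_term <- function(p, m) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / m[nz]))
}

#' Jensen-Shannon divergence between two compositions
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`, natural
#' log, zero-probability terms contributing 0. Inputs are rescaled to sum
#' to 1. The value lies in \[0, ln 2\].
#'
#' @param p,q non-negative vectors with positive sums.
#' @return the divergence (scalar).
#' @export
jsd <- function(p, q) {
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("compositions must have positive sums", call. = FALSE)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  0.5 * kl_term(p, m) + 0.5 * kl_term(q, m)
}

#' Pairwise Jensen-Shannon divergence over time points
#'
#' Columns are scaled to probability distributions, then all pairs of time
#' points are compared with [jsd()].
#'
#' @param dataset an `mbtime_dataset`; every column must have a positive
#'   sum.
#' @return an `mbtime_dist` matrix over time points (labelled by time
#'   stamp).
#' @export
jsd_matrix <- function(dataset) {
  stopifnot_dataset(dataset)
  A <- dataset$abundance
  sums <- colSums(A)
  if (any(sums <= 0))
    stop("all-zero time point(s): ",
         paste(dataset$times[sums <= 0], collapse = ", "), call. = FALSE)
  P <- sweep(A, 2, sums, "/")
  T <- ncol(P)
  vals <- matrix(0, T, T)
  for (i in seq_len(T - 1)) {
    for (j in (i + 1):T) {
      vals[i, j] <- vals[j, i] <- jsd(P[, i], P[, j])
    }
  }
  new_distance_matrix(vals, format(dataset$times, trim = TRUE), "jsd",
                      extra = list(times = dataset$times))
}

pam_objective <- function(d, medoids) sum(apply(d[, medoids, drop = FALSE],
                                                1, min))

#' K-medoids (PAM) clustering on a precomputed distance matrix
#'
#' Classic partitioning around medoids: a greedy BUILD phase picks `k`
#' initial medoids, then SWAP iterations exchange a medoid with a
#' non-medoid whenever that lowers the total distance of points to their
#' nearest medoid, until no improving swap exists. Given the matrix the
#' algorithm is deterministic (ties break towards the lowest index); `seed`
#' is accepted for interface symmetry with the stochastic generators.
#'
#' @param dist symmetric distance matrix (e.g. from [jsd_matrix()]).
#' @param k number of clusters, `2 <= k < nrow(dist)`.
#' @param seed unused except to keep call sites reproducible-by-contract.
#' @return a list of class `mbtime_kmedoids`: `labels` (cluster id per
#'   point, medoid-indexed 1..k), `medoids` (point indices), `objective`,
#'   `objective_trace` (total cost after BUILD and after each SWAP pass).
#' @export
kmedoids <- function(dist, k, seed = 1) {
  d <- unclass(dist)
  n <- nrow(d)
  k <- as.integer(k)
  if (k < 2 || k >= n)
    stop("`k` must satisfy 2 <= k < number of points", call. = FALSE)
  # BUILD
  medoids <- which.min(rowSums(d))
  while (length(medoids) < k) {
    cur <- apply(d[, medoids, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(c) {
      if (c %in% medoids) return(-Inf)
      sum(pmax(cur - d[, c], 0))
    }, 0)
    medoids <- c(medoids, which.max(gain))
  }
  trace <- pam_objective(d, medoids)
  # SWAP: best-improvement passes
  repeat {
    best <- 0; best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (c in seq_len(n)) {
        if (c %in% medoids) next
        cand <- medoids; cand[mi] <- c
        delta <- pam_objective(d, cand) - trace[length(trace)]
        if (delta < best - 1e-12) {
          best <- delta; best_swap <- cand
        }
      }
    }
    if (is.null(best_swap)) break
    medoids <- best_swap
    trace <- c(trace, pam_objective(d, medoids))
  }
  medoids <- sort(medoids)
  labels <- apply(d[, medoids, drop = FALSE], 1, which.min)
  structure(list(labels = as.integer(labels), medoids = medoids,
                 objective = trace[length(trace)],
                 objective_trace = trace, k = k),
            class = "mbtime_kmedoids")
}

#' @export
print.mbtime_kmedoids <- function(x, ...) {
  cat(sprintf("<mbtime_kmedoids> k = %d, objective = %.4f, sizes: %s\n",
              x$k, x$objective,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Community-state typing of time points
#'
#' Filters rare taxa, converts to relative abundances (if not already),
#' computes the Jensen-Shannon divergence matrix over time points, clusters
#' them with [kmedoids()], and summarizes each state's drivers: the
#' per-state mean relative abundance of every taxon, ordered by
#' between-state contrast (max minus min of the state means). An advisory
#' silhouette-width table over a small range of `k` and a taxon dendrogram
#' for heatmap row ordering are attached.
#'
#' @param dataset an `mbtime_dataset` (raw counts or relative).
#' @param k number of community states.
#' @param rare_cutoff prevalence cutoff applied first (default 0.7).
#' @param seed passed to [kmedoids()].
#' @return a list of class `mbtime_states`: `times`, `conditions`,
#'   `labels`, `medoids`, `k`, `driver_table` (taxa x states means with a
#'   `contrast` column, sorted), `silhouette` (data.frame k, mean width),
#'   `taxon_order` (heatmap ordering), `jsd` (the distance matrix).
#' @export
community_state_report <- function(dataset, k = 2, rare_cutoff = 0.7,
                                   seed = 1) {
  stopifnot_dataset(dataset)
  dataset <- filter_rare_taxa(dataset, rare_cutoff)
  if (!nrow(dataset$abundance))
    stop("no taxa survive the rare-taxa cutoff", call. = FALSE)
  rel <- if (dataset$normalization == "relative") dataset
         else {
           d <- dataset; d$normalization <- "none"
           normalize_relative(d)
         }
  D <- jsd_matrix(rel)
  km <- kmedoids(D, k, seed = seed)
  state_means <- sapply(seq_len(k), function(s)
    rowMeans(rel$abundance[, km$labels == s, drop = FALSE]))
  colnames(state_means) <- paste0("state", seq_len(k))
  contrast <- apply(state_means, 1, max) - apply(state_means, 1, min)
  ord <- order(contrast, decreasing = TRUE)
  driver <- data.frame(taxon = rel$taxa[ord],
                       state_means[ord, , drop = FALSE],
                       contrast = contrast[ord], row.names = NULL)
  sil <- silhouette_table(D, max_k = min(6, ncol(rel$abundance) - 1),
                          seed = seed)
  taxon_order <- if (nrow(rel$abundance) >= 3 &&
                     all(apply(rel$abundance, 1, stats::var) > 0)) {
    tr <- cluster_taxa(distance_matrix(rel, metric = "pearson"))
    tr$labels[tr$order]
  } else rel$taxa
  structure(list(times = rel$times, conditions = rel$conditions,
                 labels = km$labels, medoids = km$medoids, k = k,
                 driver_table = driver, silhouette = sil,
                 taxon_order = taxon_order, jsd = D),
            class = "mbtime_states")
}

silhouette_table <- function(D, max_k = 6, seed = 1) {
  d <- unclass(D)
  ks <- seq(2, max(2, max_k))
  width <- vapply(ks, function(k) {
    km <- kmedoids(D, k, seed = seed)
    mean_silhouette(d, km$labels)
  }, 0)
  data.frame(k = ks, mean_silhouette = width)
}

mean_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' @export
print.mbtime_states <- function(x, ...) {
  cat(sprintf("<mbtime_states> k = %d over %d time points; sizes: %s\n",
              x$k, length(x$labels),
              paste(tabulate(x$labels, x$k), collapse = "/")))
  cat("top drivers:\n")
  print(utils::head(x$driver_table, 5))
  invisible(x)
}
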