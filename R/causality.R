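# Granger causality network inference: pairwise F tests, L1-penalized
# multivariate regression, and their intersection.

lag_stack <- function(series_matrix, lag) {
  # rows = taxa, columns = time; returns list(y_rows, X) where X has one
  # column per (taxon, lag) in taxon-major order
  T <- ncol(series_matrix)
  idx <- (lag + 1):T
  X <- NULL
  cn <- character(0)
  for (i in seq_len(nrow(series_matrix))) {
    for (l in seq_len(lag)) {
      X <- cbind(X, series_matrix[i, idx - l])
      cn <- c(cn, sprintf("%s.l%d", rownames(series_matrix)[i], l))
    }
  }
  colnames(X) <- cn
  list(idx = idx, X = X)
}

#' Pairwise Granger causality test
#'
#' Tests whether past values of `x` improve prediction of `y` beyond `y`'s
#' own past: the restricted model regresses `y_t` on its own `lag` past
#' values and an intercept, the unrestricted model adds the `lag` past
#' values of `x`, and the nested models are compared with an F test.
#'
#' @param x candidate causal series (numeric vector).
#' @param y affected series, same length as `x`.
#' @param lag number of past values used (>= 1).
#' @return a list with `F`, `p_value`, `lag`, `df1`, `df2`.
#' @export
pairwise_granger <- function(x, y, lag = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  lag <- as.integer(lag)
  if (lag < 1) stop("`lag` must be >= 1", call. = FALSE)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  n <- length(y)
  if (n <= 2 * lag + 1)
    stop("series too short for lag ", lag, call. = FALSE)
  idx <- (lag + 1):n
  Yl <- sapply(seq_len(lag), function(l) y[idx - l])
  Xl <- sapply(seq_len(lag), function(l) x[idx - l])
  yy <- y[idx]
  restricted <- cbind(1, Yl)
  unrestricted <- cbind(1, Yl, Xl)
  qr_u <- qr(unrestricted)
  if (qr_u$rank < ncol(unrestricted))
    stop("singular design (constant or collinear series)", call. = FALSE)
  rss_r <- sum(qr.resid(qr(restricted), yy)^2)
  rss_u <- sum(qr.resid(qr_u, yy)^2)
  df1 <- lag
  df2 <- length(yy) - 2 * lag - 1
  F <- ((rss_r - rss_u) / df1) / (rss_u / df2)
  list(F = unname(F), p_value = stats::pf(F, df1, df2, lower.tail = FALSE),
       lag = lag, df1 = df1, df2 = df2)
}

#' Multivariate Granger-Lasso adjacency
#'
#' For every target taxon, fits an L1-penalized regression of its present
#' values on the lag-stacked past values of all taxa (each series
#' z-standardized first so the shared penalty is scale-fair). The penalty is
#' chosen by 5-fold cross-validation on a logarithmic grid with a
#' deterministic fold assignment derived from `seed`, at the parsimonious
#' one-standard-error rule. An edge i -> j is reported when any lag of
#' taxon i survives in taxon j's model.
#'
#' @param dataset an `mbtime_dataset`.
#' @param lag number of past values stacked per taxon.
#' @param seed integer seed controlling the cross-validation folds.
#' @param lambda `"1se"` (default) or `"min"` cross-validation rule, or a
#'   fixed non-negative numeric penalty.
#' @param transform `"none"` fits on the abundances as given; `"log10"`
#'   applies [log_scale()] first (recommended for heavy-tailed count or
#'   log-normal-like abundance data, where a linear lag model on the raw
#'   scale is dominated by the largest values).
#' @return a taxa-by-taxa numeric matrix `W` with `W[i, j]` the largest
#'   absolute surviving coefficient of taxon i in taxon j's model (0 = no
#'   edge); diagonal (self-lags) zeroed.
#' @export
granger_lasso <- function(dataset, lag = 1, seed = 1, lambda = "1se",
                          transform = c("none", "log10")) {
  stopifnot_dataset(dataset)
  transform <- match.arg(transform)
  lag <- as.integer(lag)
  T <- n_time(dataset)
  if (T <= 2 * lag + 2)
    stop("need more than 2*lag + 2 time points", call. = FALSE)
  A <- if (transform == "log10") log_scale(dataset) else dataset$abundance
  sds <- apply(A, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("dropping constant taxa from penalized regression: ",
            paste(dataset$taxa[const], collapse = ", "), call. = FALSE)
    A <- A[!const, , drop = FALSE]
  }
  k <- nrow(A)
  if (k < 2) stop("need >= 2 non-constant taxa", call. = FALSE)
  Z <- t(scale(t(A)))            # z-standardize each taxon series
  rownames(Z) <- rownames(A)
  st <- lag_stack(Z, lag)
  nobs <- length(st$idx)
  W <- matrix(0, k, k, dimnames = list(rownames(A), rownames(A)))
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(1:5, nobs))
  for (j in seq_len(k)) {
    yy <- Z[j, st$idx]
    if (is.numeric(lambda)) {
      fit <- glmnet::glmnet(st$X, yy, alpha = 1,
                            lambda = sort(unique(c(lambda,
                                                   lambda * 2^(0:8))),
                                          decreasing = TRUE))
      co <- as.numeric(stats::coef(fit, s = lambda))[-1]
    } else {
      cv <- glmnet::cv.glmnet(st$X, yy, alpha = 1, foldid = foldid)
      s <- if (identical(lambda, "min")) cv$lambda.min else cv$lambda.1se
      co <- as.numeric(stats::coef(cv, s = s))[-1]
    }
    co[abs(co) <= 1e-8] <- 0
    mx <- matrix(co, nrow = lag)            # lags x taxa
    W[, j] <- apply(abs(mx), 2, max)
  }
  diag(W) <- 0
  W
}

#' Build a directed causality network over taxa
#'
#' Rare taxa are filtered first; then directed edges are inferred by the
#' chosen method: `"pairwise"` keeps ordered pairs whose Granger F test
#' survives Benjamini-Hochberg correction across all ordered pairs at
#' `alpha`; `"lasso"` keeps the support of [granger_lasso()];
#' `"intersection"` keeps edges found by both. Node attributes carry the
#' stationarity flag of each taxon when a stationarity report is supplied.
#'
#' @param dataset an `mbtime_dataset`.
#' @param method `"pairwise"`, `"lasso"` or `"intersection"`.
#' @param lag shared lag order.
#' @param alpha adjusted-p threshold for pairwise edges.
#' @param rare_cutoff prevalence cutoff applied first (default 0.5).
#' @param seed seed for the lasso cross-validation folds.
#' @param stationarity optional `data.frame` from [stationarity_report()];
#'   matched to taxa by name.
#' @param transform `"none"` or `"log10"`; see [granger_lasso()]. Applied
#'   to both the pairwise tests and the penalized fits.
#' @return an `igraph` directed graph; edges carry `method`, `statistic`,
#'   `p_value`, `adjusted_p`, `lag`; the full pairwise table is in the
#'   graph attribute `"pairwise_table"` when computed.
#' @export
build_network <- function(dataset, method = c("pairwise", "lasso",
                                              "intersection"),
                          lag = 1, alpha = 0.05, rare_cutoff = 0.5,
                          seed = 1, stationarity = NULL,
                          transform = c("none", "log10")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  stopifnot_dataset(dataset)
  dataset <- filter_rare_taxa(dataset, rare_cutoff)
  k <- nrow(dataset$abundance)
  if (k < 3)
    stop("fewer than 3 taxa remain after rare-taxa filtering", call. = FALSE)
  taxa <- dataset$taxa
  A <- if (transform == "log10") log_scale(dataset) else dataset$abundance

  pairwise_tab <- NULL
  if (method %in% c("pairwise", "intersection")) {
    pairs <- expand.grid(source = seq_len(k), target = seq_len(k))
    pairs <- pairs[pairs$source != pairs$target, ]
    res <- lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs$source[r]; j <- pairs$target[r]
      tryCatch(pairwise_granger(A[i, ], A[j, ], lag = lag),
               error = function(e) list(F = NA_real_, p_value = NA_real_))
    })
    pairwise_tab <- data.frame(
      source = taxa[pairs$source], target = taxa[pairs$target],
      F = vapply(res, `[[`, 0, "F"),
      p_value = vapply(res, `[[`, 0, "p_value"), row.names = NULL)
    pairwise_tab$adjusted_p <- stats::p.adjust(pairwise_tab$p_value,
                                               method = "BH")
  }
  lasso_W <- if (method %in% c("lasso", "intersection"))
    granger_lasso(dataset, lag = lag, seed = seed,
                  transform = transform) else NULL

  edges <- switch(method,
    pairwise = {
      keep <- !is.na(pairwise_tab$adjusted_p) &
        pairwise_tab$adjusted_p < alpha
      cbind(pairwise_tab[keep, c("source", "target")],
            statistic = pairwise_tab$F[keep],
            p_value = pairwise_tab$p_value[keep],
            adjusted_p = pairwise_tab$adjusted_p[keep])
    },
    lasso = {
      idx <- which(lasso_W != 0, arr.ind = TRUE)
      data.frame(source = rownames(lasso_W)[idx[, 1]],
                 target = colnames(lasso_W)[idx[, 2]],
                 statistic = lasso_W[idx],
                 p_value = NA_real_, adjusted_p = NA_real_)
    },
    intersection = {
      keep <- !is.na(pairwise_tab$adjusted_p) &
        pairwise_tab$adjusted_p < alpha
      pw <- pairwise_tab[keep, , drop = FALSE]
      in_lasso <- mapply(function(s, t)
        s %in% rownames(lasso_W) && t %in% rownames(lasso_W) &&
          lasso_W[s, t] != 0,
        pw$source, pw$target)
      pw <- pw[as.logical(in_lasso), , drop = FALSE]
      if (nrow(pw))
        cbind(pw[, c("source", "target")], statistic = pw$F,
              p_value = pw$p_value, adjusted_p = pw$adjusted_p)
      else data.frame(source = character(0), target = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0))
    })
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, k, name = taxa)
  if (!is.null(stationarity)) {
    m <- match(taxa, stationarity$taxon)
    igraph::V(g)$stationary <- stationarity$stationary[m]
  }
  if (nrow(edges)) {
    g <- igraph::add_edges(
      g, rbind(match(edges$source, taxa), match(edges$target, taxa)))
    igraph::E(g)$statistic <- edges$statistic
    igraph::E(g)$p_value <- edges$p_value
    igraph::E(g)$adjusted_p <- edges$adjusted_p
  }
  igraph::E(g)$method <- rep(method, igraph::ecount(g))
  igraph::E(g)$lag <- rep(lag, igraph::ecount(g))
  g <- igraph::set_graph_attr(g, "method", method)
  g <- igraph::set_graph_attr(g, "lag", lag)
  if (!is.null(pairwise_tab))
    g <- igraph::set_graph_attr(g, "pairwise_table", pairwise_tab)
  g
}

#' Query a causality network around one taxon
#'
#' @param graph an `igraph` from [build_network()].
#' @param node taxon name.
#' @param direction `"causes"` (taxa this node points at) or `"caused-by"`
#'   (taxa pointing at this node).
#' @return character vector of neighbor taxa.
#' @export
query_network <- function(graph, node, direction = c("causes",
                                                     "caused-by")) {
  direction <- match.arg(direction)
  if (!node %in% igraph::V(graph)$name)
    stop("node not in graph: ", node, call. = FALSE)
  mode <- if (direction == "causes") "out" else "in"
  nb <- igraph::neighbors(graph, node, mode = mode)
  nb$name
}

#' Write a network edge list as TSV
#'
#' @param graph an `igraph` from [build_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   method = igraph::E(graph)$method,
                   statistic = igraph::E(graph)$statistic,
                   p_value = igraph::E(graph)$p_value,
                   adjusted_p = igraph::E(graph)$adjusted_p,
                   lag = igraph::E(graph)$lag)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
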