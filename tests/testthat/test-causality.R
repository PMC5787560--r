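test_that("pairwise Granger F matches independent nested regressions", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(40:80, 1); lag <- sample(1:3, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pairwise_granger(x, y, lag = lag)
    # independent route: lm() fits and the textbook F formula
    d <- data.frame(y = y[(lag + 1):n])
    for (l in 1:lag) {
      d[[paste0("yl", l)]] <- y[(lag + 1 - l):(n - l)]
      d[[paste0("xl", l)]] <- x[(lag + 1 - l):(n - l)]
    }
    f_r <- lm(stats::reformulate(paste0("yl", 1:lag), "y"), data = d)
    f_u <- lm(stats::reformulate(c(paste0("yl", 1:lag),
                                   paste0("xl", 1:lag)), "y"), data = d)
    rss_r <- sum(residuals(f_r)^2); rss_u <- sum(residuals(f_u)^2)
    F_oracle <- ((rss_r - rss_u) / lag) /
      (rss_u / (nrow(d) - 2 * lag - 1))
    expect_equal(got$F, F_oracle, tolerance = 1e-8)
    # cross-check against lmtest's implementation
    gt <- lmtest::grangertest(y ~ x, order = lag,
                              data = data.frame(x = x, y = y))
    expect_equal(got$F, gt$F[2], tolerance = 1e-8)
    expect_equal(got$p_value, gt$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("a perfectly shifted copy yields overwhelming evidence", {
  set.seed(3)
  x <- rnorm(100)
  y <- c(0, x[-100])                      # y_t = x_{t-1}
  res <- pairwise_granger(x, y, lag = 1)
  expect_gt(res$F, 1e4)
  expect_lt(res$p_value, 1e-50)
})

test_that("planted driver edges are detected and direction is respected", {
  detected <- 0; reverse_rejected <- 0; n_rep <- 30
  adj <- matrix(c(0, 0.8, 0, 0.2), 2, 2, byrow = TRUE)
  for (s in seq_len(n_rep)) {
    ds <- simulate_var(adj, n_time = 200, seed = s)
    A <- log_scale(ds)
    detected <- detected +
      (pairwise_granger(A[1, ], A[2, ], 1)$p_value < 0.01)
    reverse_rejected <- reverse_rejected +
      (pairwise_granger(A[2, ], A[1, ], 1)$p_value < 0.05)
  }
  expect_gte(detected / n_rep, 0.95)
  expect_lte(reverse_rejected / n_rep, 0.2)   # null-rate behaviour
})

test_that("degenerate designs raise errors", {
  expect_error(pairwise_granger(rep(1, 50), rnorm(50), 1), "singular")
  expect_error(pairwise_granger(rnorm(5), rnorm(5), 2), "too short")
  expect_error(pairwise_granger(rnorm(10), rnorm(9), 1), "lengths differ")
})

test_that("the lasso recovers a planted sparse VAR support", {
  adj <- matrix(0, 10, 10); diag(adj) <- 0.2
  adj[1, 2] <- adj[3, 4] <- adj[5, 6] <- 0.7
  truth <- c("taxon_1->taxon_2", "taxon_3->taxon_4", "taxon_5->taxon_6")
  ok <- 0; n_rep <- 20
  for (s in seq_len(n_rep)) {
    ds <- simulate_var(adj, n_time = 300, seed = s)
    W <- granger_lasso(ds, lag = 1, seed = s, transform = "log10")
    e <- which(W != 0, arr.ind = TRUE)
    en <- paste0(rownames(W)[e[, 1]], "->", colnames(W)[e[, 2]])
    ok <- ok + (all(truth %in% en) && sum(!en %in% truth) <= 2)
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("extreme penalties give the expected degenerate supports", {
  ds <- simulate_var(matrix(c(0.3, 0.5, 0, 0.3), 2, 2, byrow = TRUE),
                     n_time = 120, seed = 9)
  W_inf <- granger_lasso(ds, lag = 1, seed = 1, lambda = 1e6,
                         transform = "log10")
  expect_true(all(W_inf == 0))
  W_0 <- granger_lasso(ds, lag = 1, seed = 1, lambda = 1e-10,
                       transform = "log10")
  expect_true(all(W_0[upper.tri(W_0) | lower.tri(W_0)] != 0))

  cds <- rand_dataset(k = 3, T = 30, seed = 2)
  cds$abundance[3, ] <- 2
  expect_warning(granger_lasso(cds, lag = 1, seed = 1), "constant")
})

test_that("network construction respects method semantics", {
  adj <- matrix(0, 5, 5); diag(adj) <- 0.2
  adj[1, 2] <- 0.8; adj[2, 3] <- 0.8
  ds <- simulate_var(adj, n_time = 250, seed = 4)
  g_pw <- build_network(ds, "pairwise", rare_cutoff = 0, seed = 1,
                        transform = "log10")
  g_ls <- build_network(ds, "lasso", rare_cutoff = 0, seed = 1,
                        transform = "log10")
  g_in <- build_network(ds, "intersection", rare_cutoff = 0, seed = 1,
                        transform = "log10")
  edge_ids <- function(g) apply(igraph::as_edgelist(g), 1, paste,
                                collapse = "->")
  expect_true(all(edge_ids(g_in) %in% edge_ids(g_pw)))
  expect_true(all(edge_ids(g_in) %in% edge_ids(g_ls)))
  expect_true(all(c("taxon_1->taxon_2", "taxon_2->taxon_3") %in%
                    edge_ids(g_in)))
  expect_equal(sort(igraph::V(g_pw)$name), sort(ds$taxa))
  # graph construction is deterministic given the dataset
  g_in2 <- build_network(ds, "intersection", rare_cutoff = 0, seed = 1,
                         transform = "log10")
  expect_identical(edge_ids(g_in), edge_ids(g_in2))

  expect_error(build_network(rand_dataset(k = 2, T = 30), "pairwise",
                             rare_cutoff = 0), "fewer than 3")
})

test_that("stationarity flags decorate nodes and queries navigate edges", {
  ds <- simulate_var(matrix(c(0, 0.8, 0, 0.2), 2, 2, byrow = TRUE),
                     n_time = 150, seed = 2)
  extra <- rand_dataset(k = 1, T = 150, seed = 8)
  ds$abundance <- rbind(ds$abundance, filler = extra$abundance)
  ds$taxa <- c(ds$taxa[1:2], "filler")
  rownames(ds$abundance) <- ds$taxa
  st <- stationarity_report(ds, transform = "log10")
  g <- build_network(ds, "pairwise", rare_cutoff = 0, seed = 1,
                     stationarity = st, transform = "log10")
  expect_equal(length(igraph::V(g)$stationary), 3)
  expect_true("taxon_2" %in% query_network(g, "taxon_1", "causes"))
  expect_true("taxon_1" %in% query_network(g, "taxon_2", "caused-by"))
  expect_error(query_network(g, "nope"), "not in graph")

  p <- tempfile(fileext = ".tsv")
  write_edge_list(g, p)
  back <- utils::read.delim(p)
  expect_equal(nrow(back), igraph::ecount(g))
  expect_true(all(c("source", "target", "statistic", "adjusted_p") %in%
                    names(back)))
})
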