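test_that("relative normalization scales columns to unit sum", {
  ds <- mbtime_dataset(matrix(c(2, 3, 5, 1, 1, 2), 3, 2), times = 1:2)
  rel <- normalize_relative(ds)
  expect_equal(unname(rel$abundance[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(rel$abundance)), c(1, 1))
  expect_equal(rel$normalization, "relative")
  expect_error(normalize_relative(rel), "already normalized")

  zero <- mbtime_dataset(matrix(c(1, 2, 0, 0), 2, 2), times = 1:2)
  expect_warning(relz <- normalize_relative(zero), "all-zero")
  expect_equal(unname(relz$abundance[, 2]), c(0, 0))
})

test_that("rarefaction subsamples without replacement to exact depth", {
  ds <- rand_dataset(k = 8, T = 6, seed = 2)
  ds$abundance <- round(ds$abundance * 10)
  r <- rarefy(ds, depth = 50, seed = 9)
  expect_true(all(colSums(r$abundance) == 50))
  expect_true(all(r$abundance <= ds$abundance))
  expect_equal(r$normalization, "rarefied")

  # seed determinism
  r2 <- rarefy(ds, depth = 50, seed = 9)
  expect_identical(r$abundance, r2$abundance)
  expect_false(identical(r$abundance,
                         rarefy(ds, depth = 50, seed = 10)$abundance))

  # depth equal to a column total returns that column unchanged
  one <- mbtime_dataset(matrix(c(4, 6, 0), 3, 1), times = 1)
  expect_equal(unname(rarefy(one, depth = 10, seed = 1)$abundance[, 1]),
               c(4, 6, 0))
  # forced outcome
  forced <- mbtime_dataset(matrix(c(1000, 0, 0), 3, 1), times = 1)
  expect_equal(unname(rarefy(forced, depth = 100, seed = 1)$abundance[, 1]),
               c(100, 0, 0))

  expect_error(rarefy(normalize_relative(rand_dataset()), 10, 1),
               "raw counts")
  frac <- mbtime_dataset(matrix(c(1.5, 2), 2, 1), times = 1)
  expect_error(rarefy(frac, 2, 1), "not integers")
})

test_that("columns below depth are dropped with a warning", {
  ds <- mbtime_dataset(matrix(c(100, 100, 3, 2), 2, 2), times = 1:2)
  expect_warning(r <- rarefy(ds, depth = 50, seed = 1), "below depth")
  expect_equal(ncol(r$abundance), 1)
  expect_equal(r$times, 1)
})

test_that("rarefaction curves reach observed richness and match the
           hypergeometric expectation", {
  counts <- rep(40L, 10)                     # 10 taxa, even, total 400
  ds <- mbtime_dataset(matrix(counts, 10, 1), times = 1)
  colnames(ds$abundance) <- "S"
  full <- rarefaction_curve(ds, "S", depths = 400, replicates = 5,
                            seed = 1)
  expect_equal(full$mean_richness, 10)       # exact at full depth

  reps <- 40
  depths <- c(1, 5, 20, 60, 150, 400)
  cur <- rarefaction_curve(ds, "S", depths = depths, replicates = reps,
                           seed = 4)
  expect_true(all(diff(cur$mean_richness) >= 0))
  for (i in seq_along(depths)) {
    exp_rich <- expected_richness(counts, depths[i])
    se <- sqrt(10 * 0.25 / reps)             # richness variance <= k/4
    expect_lt(abs(cur$mean_richness[i] - exp_rich), 3 * se + 1e-9)
  }

  single <- mbtime_dataset(matrix(25, 1, 1), times = 1)
  colnames(single$abundance) <- "S"
  sc <- rarefaction_curve(single, "S", depths = c(1, 10, 25),
                          replicates = 3, seed = 1)
  expect_equal(sc$mean_richness, rep(1, 3))

  expect_error(rarefaction_curve(ds, "S", depths = 500, replicates = 2,
                                 seed = 1), "exceeds")
})

test_that("rare-taxa filtering matches its prevalence semantics and nests", {
  pres <- rbind(seven = c(rep(1, 7), rep(0, 3)),
                six = c(rep(1, 6), rep(0, 4)),
                all10 = rep(1, 10))
  ds <- mbtime_dataset(pres * 5, times = 1:10)
  kept <- filter_rare_taxa(ds, 0.7)$taxa
  expect_true("seven" %in% kept)
  expect_false("six" %in% kept)
  expect_equal(filter_rare_taxa(ds, 0)$taxa, ds$taxa)
  expect_equal(filter_rare_taxa(ds, 1)$taxa, "all10")
  expect_error(filter_rare_taxa(ds, 1.2), "\\[0, 1\\]")

  # monotone nesting across cutoffs on noisy data
  nds <- rand_dataset(k = 30, T = 15, seed = 5, zeros = 150)
  cuts <- c(0, 0.2, 0.5, 0.8, 1)
  keeps <- lapply(cuts, function(c) filter_rare_taxa(nds, c)$taxa)
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(keeps[[i + 1]] %in% keeps[[i]]))
})

test_that("log scaling and moving averages follow their definitions", {
  ds <- mbtime_dataset(matrix(c(0, 99, 9, 999), 2, 2), times = 1:2)
  ls <- log_scale(ds, pseudocount = 1)
  expect_equal(unname(ls), matrix(c(0, 2, 1, 3), 2, 2))
  expect_equal(unname(ds$abundance[1, 1]), 0)   # original untouched
  expect_error(log_scale(ds, pseudocount = 0), "> 0")
  # monotonicity
  x <- sort(runif(10, 0, 50))
  expect_true(all(diff(log10(x + 1)) > 0))

  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1, 1.5, 2.5, 3.5))
  expect_equal(moving_average(5:9, 1), 5:9)
  expect_equal(moving_average(rep(7, 6), 4), rep(7, 6))
  expect_error(moving_average(1:5, 0), ">= 1")
})

test_that("quartile segregation splits by mean abundance", {
  m <- matrix(rep(1:8, times = 4), 8, 4)   # taxon i constant at level i
  ds <- mbtime_dataset(m, times = 1:4, taxa = paste0("t", 1:8))
  q <- quartile_segregate(ds)
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_equal(names(q)[q == "Q4"], c("t7", "t8"))

  set.seed(8)
  big <- mbtime_dataset(matrix(rlnorm(100 * 5), 100, 5), times = 1:5,
                        taxa = sprintf("t%03d", 1:100))
  qb <- quartile_segregate(big)
  top25 <- names(sort(rowMeans(big$abundance),
                      decreasing = TRUE))[1:25]
  expect_setequal(names(qb)[qb == "Q4"], top25)

  ties <- mbtime_dataset(matrix(1, 8, 3), times = 1:3,
                         taxa = paste0("t", 1:8))
  q1 <- quartile_segregate(ties)
  expect_identical(q1, quartile_segregate(ties))  # deterministic
  expect_equal(as.integer(table(q1)), rep(2L, 4))

  small <- rand_dataset(k = 3, T = 4, seed = 1)
  expect_warning(qs <- quartile_segregate(small), "fewer than 4")
  expect_equal(length(unique(qs)), 1)
})
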