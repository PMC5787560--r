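# Seeded generators with planted structure, for testing every analytical
# workflow without external data. Latent dynamics are Gaussian; abundances
# are made non-negative by exponentiation (log-normal marginals), which
# avoids the spurious zero-inflation that truncation would inject into the
# prevalence logic.

latent_to_abundance <- function(Z, scale = 100) scale * exp(Z)

sim_dataset <- function(abund, seed, source, truth) {
  ds <- mbtime_dataset(abund, times = seq_len(ncol(abund)),
                       source = source)
  attr(ds, "truth") <- truth
  attr(ds, "seed") <- seed
  ds
}

#' Simulate a VAR(1) community with planted causal edges
#'
#' Latent dynamics `z_t = adjacency' z_{t-1} + noise` (entry
#' `adjacency[i, j]` is the influence of taxon i on taxon j), exponentiated
#' to non-negative abundances. The planted edge list (nonzero off-diagonal
#' entries) is recorded as ground truth.
#'
#' @param adjacency k x k coefficient matrix with spectral radius < 1.
#' @param n_time number of time points.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed (fully determines the output).
#' @return an `mbtime_dataset` with a `"truth"` attribute: a `data.frame`
#'   of planted `source`/`target` taxa.
#' @export
simulate_var <- function(adjacency, n_time = 200, noise_sd = 1, seed = 1) {
  adjacency <- as.matrix(adjacency)
  k <- nrow(adjacency)
  if (k != ncol(adjacency)) stop("adjacency must be square", call. = FALSE)
  if (max(Mod(eigen(adjacency, only.values = TRUE)$values)) >= 1)
    stop("unstable adjacency: spectral radius must be < 1", call. = FALSE)
  set.seed(as.integer(seed))
  burn <- 50L
  Z <- matrix(0, k, n_time + burn)
  for (t in 2:(n_time + burn))
    Z[, t] <- t(adjacency) %*% Z[, t - 1] +
      stats::rnorm(k, sd = noise_sd)
  Z <- Z[, burn + seq_len(n_time), drop = FALSE]
  taxa <- paste0("taxon_", seq_len(k))
  rownames(Z) <- taxa
  idx <- which(adjacency != 0 & row(adjacency) != col(adjacency),
               arr.ind = TRUE)
  truth <- data.frame(source = taxa[idx[, 1]], target = taxa[idx[, 2]],
                      coefficient = adjacency[idx], row.names = NULL)
  sim_dataset(latent_to_abundance(Z), seed, "var_sim", truth)
}

#' Simulate a mix of stationary and unit-root taxa
#'
#' Stationary taxa follow white noise; unit-root taxa follow a random walk
#' (cumulative sum of the same noise). Planted labels are recorded.
#'
#' @param n_stationary,n_unit_root counts of each dynamic type.
#' @param n_time number of time points.
#' @param seed integer seed.
#' @return an `mbtime_dataset`; `attr(, "truth")` is a `data.frame` of
#'   `taxon`, `unit_root`.
#' @export
simulate_unit_root_mix <- function(n_stationary = 10, n_unit_root = 2,
                                   n_time = 200, seed = 1) {
  set.seed(as.integer(seed))
  k <- n_stationary + n_unit_root
  Z <- matrix(stats::rnorm(k * n_time), k, n_time)
  if (n_unit_root > 0) {
    ur <- n_stationary + seq_len(n_unit_root)
    # scale the walk's innovations down so its level stays numerically tame
    Z[ur, ] <- t(apply(Z[ur, , drop = FALSE] * 0.25, 1, cumsum))
  }
  taxa <- c(sprintf("stationary_%d", seq_len(n_stationary)),
            sprintf("walk_%d", seq_len(n_unit_root)))
  rownames(Z) <- taxa
  truth <- data.frame(taxon = taxa,
                      unit_root = rep(c(FALSE, TRUE),
                                      c(n_stationary, n_unit_root)),
                      row.names = NULL)
  sim_dataset(latent_to_abundance(Z), seed, "unit_root_sim", truth)
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a community alternating between two planted states
#'
#' Each time point's composition is a Dirichlet draw centred on its block's
#' composition, with `concentration` controlling how tightly draws cluster
#' around the centre.
#'
#' @param composition_a,composition_b probability vectors of equal length
#'   (the two state centres).
#' @param block_pattern integer vector of 1s and 2s giving the planted
#'   state of each consecutive time point, e.g. `rep(1:2, each = 30)`.
#' @param concentration Dirichlet precision (larger = tighter states).
#' @param seed integer seed.
#' @param scale total count per time point (compositions are scaled to
#'   pseudo-counts).
#' @return an `mbtime_dataset`; `attr(, "truth")` is the planted label
#'   vector.
#' @export
simulate_two_states <- function(composition_a, composition_b,
                                block_pattern = rep(1:2, each = 30),
                                concentration = 100, seed = 1,
                                scale = 1e4) {
  if (length(composition_a) != length(composition_b))
    stop("state compositions must have equal length", call. = FALSE)
  if (abs(sum(composition_a) - 1) > 1e-8 ||
      abs(sum(composition_b) - 1) > 1e-8)
    stop("state compositions must sum to 1", call. = FALSE)
  if (!all(block_pattern %in% 1:2))
    stop("block_pattern entries must be 1 or 2", call. = FALSE)
  set.seed(as.integer(seed))
  centres <- rbind(composition_a, composition_b)
  A <- vapply(block_pattern, function(b)
    scale * rdirichlet_one(concentration * centres[b, ]),
    numeric(length(composition_a)))
  rownames(A) <- paste0("taxon_", seq_len(nrow(A)))
  sim_dataset(A, seed, "two_state_sim", as.integer(block_pattern))
}

#' Simulate planted temporal shape groups
#'
#' Two groups of taxa share a sinusoidal latent trend, the second group's
#' trend phase-shifted by half a period, plus independent noise. Useful for
#' testing shape clustering.
#'
#' @param n_per_group taxa per group.
#' @param n_time number of time points.
#' @param noise_sd additive latent noise SD (trend amplitude is 1).
#' @param seed integer seed.
#' @return an `mbtime_dataset`; `attr(, "truth")` gives each taxon's group.
#' @export
simulate_shape_groups <- function(n_per_group = 5, n_time = 60,
                                  noise_sd = 0.25, seed = 1) {
  set.seed(as.integer(seed))
  t <- seq_len(n_time)
  base1 <- sin(2 * pi * t / 20)
  base2 <- sin(2 * pi * t / 20 + pi)
  k <- 2 * n_per_group
  Z <- rbind(matrix(rep(base1, each = n_per_group), n_per_group,
                    byrow = FALSE),
             matrix(rep(base2, each = n_per_group), n_per_group,
                    byrow = FALSE)) +
    matrix(stats::rnorm(k * n_time, sd = noise_sd), k, n_time)
  rownames(Z) <- c(sprintf("groupA_%d", seq_len(n_per_group)),
                   sprintf("groupB_%d", seq_len(n_per_group)))
  truth <- rep(1:2, each = n_per_group)
  sim_dataset(latent_to_abundance(Z), seed, "shape_sim", truth)
}

#' Hand-constructed prevalence fixture
#'
#' A small dataset over 10 time points whose presence patterns realize each
#' prevalence class under the default thresholds; the hand-derived expected
#' calls are stored as ground truth.
#'
#' @return an `mbtime_dataset`; `attr(, "truth")` maps taxon to expected
#'   class.
#' @export
make_prevalence_fixture <- function() {
  # presence patterns over 10 points; expected calls derived by hand:
  #  core:       1111111111  prevalence 1                        -> core
  #  persistent: 1110000000  prev 0.3 > 0.2, run 3/3 = 1 >= 0.9  -> persistent
  #  transient:  1010101101  prev 0.6, run 2/6 = 0.33 <= 0.75    -> transient
  #  other_low:  1000000000  prev 0.1 (fails every rule)         -> other
  #  tail_run:   1111111100  prev 0.8, run 8/8 = 1 >= 0.9        -> persistent
  #  gap_walk:   1101101101  prev 0.7, run 2/7 = 0.29 <= 0.75    -> transient
  #  mid_gap:    1111101111  prev 0.9, run 5/9 = 0.56 <= 0.75    -> transient
  #  amb:        1111111101  prev 0.9, run 8/9 = 0.89 in the gap
  #              between the persistent (>= 0.9) and transient
  #              (<= 0.75) run rules                             -> other
  pat <- rbind(
    core       = c(1,1,1,1,1,1,1,1,1,1),
    persistent = c(1,1,1,0,0,0,0,0,0,0),
    transient  = c(1,0,1,0,1,0,1,1,0,1),
    other_low  = c(1,0,0,0,0,0,0,0,0,0),
    tail_run   = c(1,1,1,1,1,1,1,1,0,0),
    gap_walk   = c(1,1,0,1,1,0,1,1,0,1),
    mid_gap    = c(1,1,1,1,1,0,1,1,1,1),
    amb        = c(1,1,1,1,1,1,1,1,0,1))
  truth <- c(core = "core", persistent = "persistent",
             transient = "transient", other_low = "other",
             tail_run = "persistent", gap_walk = "transient",
             mid_gap = "transient", amb = "other")
  abund <- pat * (seq_len(nrow(pat)) * 10)   # distinct positive levels
  ds <- mbtime_dataset(abund, times = 1:10, source = "prevalence_fixture")
  attr(ds, "truth") <- truth
  ds
}

#' Write a simulated dataset as on-disk abundance + metadata + truth files
#'
#' Emits the plain-TSV abundance table, the four-column metadata table, and
#' a ground-truth sidecar, so end-to-end command-line runs can start from
#' disk artifacts.
#'
#' @param dataset an `mbtime_dataset` (typically from a generator above).
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(dataset, dir) {
  stopifnot_dataset(dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample_ids <- sprintf("%s_t%03d", dataset$source,
                        seq_along(dataset$times))
  ab_path <- file.path(dir, "abundance.tsv")
  m <- dataset$abundance
  colnames(m) <- sample_ids
  utils::write.table(
    data.frame(taxon = dataset$taxa, m, check.names = FALSE),
    ab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(
    data.frame(sample_id = sample_ids, source = dataset$source,
               time = dataset$times, condition = dataset$conditions),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- attr(dataset, "truth")
  if (is.null(truth)) truth <- data.frame(note = "no planted structure")
  if (!is.data.frame(truth))
    truth <- data.frame(item = names(truth) %||% seq_along(truth),
                        value = unname(truth))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(abundance = ab_path, metadata = meta_path,
              truth = truth_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
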