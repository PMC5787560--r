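# Normalization, filtering and smoothing of abundance matrices.

#' Convert counts to relative abundances
#'
#' Divides each time-point column by its sum. All-zero columns are left as
#' zero with a warning.
#'
#' @param dataset an unnormalized `mbtime_dataset`.
#' @return the dataset with `normalization = "relative"`.
#' @export
normalize_relative <- function(dataset) {
  stopifnot_dataset(dataset)
  if (dataset$normalization != "none")
    stop("dataset is already normalized (", dataset$normalization, ")",
         call. = FALSE)
  sums <- colSums(dataset$abundance)
  zero <- sums == 0
  if (any(zero)) {
    warning("all-zero column(s) left unscaled at time(s): ",
            paste(dataset$times[zero], collapse = ", "), call. = FALSE)
    sums[zero] <- 1
  }
  out <- dataset
  out$abundance <- sweep(dataset$abundance, 2, sums, "/")
  out$normalization <- "relative"
  out
}

#' Rarefy each time point to an even sequencing depth
#'
#' Each column is replaced by a without-replacement subsample of its reads
#' (multivariate hypergeometric) totalling exactly `depth`. Columns whose
#' total is below `depth` are dropped with a warning.
#'
#' @param dataset an unnormalized `mbtime_dataset` with integer counts.
#' @param depth target depth (reads per time point).
#' @param seed integer seed; the operation is reproducible given
#'   (dataset, depth, seed).
#' @return the dataset with `normalization = "rarefied"`.
#' @export
rarefy <- function(dataset, depth, seed) {
  stopifnot_dataset(dataset)
  if (dataset$normalization != "none")
    stop("rarefaction applies to raw counts only", call. = FALSE)
  counts <- dataset$abundance
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts are not integers; skip rarefaction on pre-normalized data",
         call. = FALSE)
  counts <- round(counts)
  depth <- as.integer(depth)
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("no time point reaches depth ", depth, call. = FALSE)
  if (any(!keep))
    warning("dropping time point(s) below depth ", depth, ": ",
            paste(dataset$times[!keep], collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  sub <- apply(counts[, keep, drop = FALSE], 2, subsample_column,
               depth = depth)
  mbtime_dataset(sub, times = dataset$times[keep],
                 taxa = dataset$taxa,
                 conditions = dataset$conditions[keep],
                 source = dataset$source, lineages = dataset$lineages,
                 normalization = "rarefied", depth = depth)
}

# draw `depth` reads without replacement from a count vector
subsample_column <- function(counts, depth) {
  reads <- rep.int(seq_along(counts), counts)
  tabulate(reads[sample.int(length(reads), depth)],
           nbins = length(counts))
}

#' Rarefaction curve for one time point
#'
#' Mean observed richness (taxa with count > 0) over repeated
#' without-replacement subsamples at each requested depth.
#'
#' @param dataset an unnormalized `mbtime_dataset` with integer counts.
#' @param sample_id column name (or time-point index) to profile.
#' @param depths ascending integer vector of subsampling depths; all must be
#'   at most the column total.
#' @param replicates subsamples averaged per depth.
#' @param seed integer seed.
#' @return a `data.frame` with columns `sample_id`, `depth`,
#'   `mean_richness`, and attribute `replicates`.
#' @export
rarefaction_curve <- function(dataset, sample_id, depths, replicates = 10,
                              seed = 1) {
  stopifnot_dataset(dataset)
  if (is.numeric(sample_id)) sample_id <- colnames(dataset$abundance)[sample_id]
  if (!sample_id %in% colnames(dataset$abundance))
    stop("unknown sample: ", sample_id, call. = FALSE)
  counts <- round(dataset$abundance[, sample_id])
  total <- sum(counts)
  depths <- sort(as.integer(depths))
  if (any(depths > total))
    stop("depth ", depths[depths > total][1], " exceeds sample total ",
         total, call. = FALSE)
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  mean_rich <- vapply(depths, function(d) {
    mean(vapply(seq_len(replicates), function(r)
      sum(subsample_column(counts, d) > 0), 0))
  }, 0)
  out <- data.frame(sample_id = sample_id, depth = depths,
                    mean_richness = mean_rich)
  attr(out, "replicates") <- replicates
  out
}

#' Drop taxa present in fewer than a fraction of time points
#'
#' Retains taxa with abundance > 0 in at least `cutoff` of the time points
#' (a cutoff of 0.7 keeps taxa occurring in at least 70% of samples).
#'
#' @param dataset an `mbtime_dataset`.
#' @param cutoff fraction in \[0, 1\].
#' @return the filtered dataset.
#' @export
filter_rare_taxa <- function(dataset, cutoff) {
  stopifnot_dataset(dataset)
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1)
    stop("`cutoff` must lie in [0, 1]", call. = FALSE)
  prev <- rowMeans(dataset$abundance > 0)
  keep <- prev >= cutoff
  out <- dataset
  out$abundance <- dataset$abundance[keep, , drop = FALSE]
  out$taxa <- dataset$taxa[keep]
  if (!is.null(dataset$lineages)) out$lineages <- dataset$lineages[keep]
  out
}

#' Log-scaled view of the abundance matrix
#'
#' Returns `log10(x + pseudocount)` elementwise; the dataset itself is not
#' modified. The default pseudocount is 1 for count-scale data and half the
#' smallest nonzero value for proportion-scale data.
#'
#' @param dataset an `mbtime_dataset`.
#' @param pseudocount strictly positive offset, or `NULL` for the default.
#' @return a numeric matrix of the same shape as the abundance matrix.
#' @export
log_scale <- function(dataset, pseudocount = NULL) {
  stopifnot_dataset(dataset)
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(dataset)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("`pseudocount` must be > 0", call. = FALSE)
  log10(dataset$abundance + pseudocount)
}

default_pseudocount <- function(dataset) {
  if (dataset$normalization == "relative") {
    nz <- dataset$abundance[dataset$abundance > 0]
    if (length(nz)) min(nz) / 2 else 0.5
  } else 1
}

#' Trailing moving average
#'
#' Mean over the last `window` observations; the first `window - 1`
#' positions use the available prefix (no look-ahead).
#'
#' @param series numeric vector.
#' @param window integer window length, `1 <= window <= length(series)`.
#' @return smoothed numeric vector of the same length.
#' @export
moving_average <- function(series, window) {
  window <- as.integer(window)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (window > length(series))
    stop("`window` exceeds series length", call. = FALSE)
  cs <- cumsum(series)
  out <- numeric(length(series))
  head <- seq_len(min(window - 1L, length(series)))
  out[head] <- cs[head] / head
  if (length(series) >= window) {
    idx <- window:length(series)
    out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  }
  out
}

#' Assign taxa to abundance quartiles
#'
#' Ranks taxa by mean abundance across time and splits the ranking into four
#' groups at its 25/50/75 percentiles; Q4 holds the most abundant taxa.
#' Useful for plotting taxa of comparable scale together.
#'
#' @param dataset an `mbtime_dataset` with at least 4 taxa.
#' @return named factor over taxa with levels `Q1` (lowest) to `Q4`
#'   (highest); with fewer than 4 taxa, a single-group fallback with a
#'   warning.
#' @export
quartile_segregate <- function(dataset) {
  stopifnot_dataset(dataset)
  means <- rowMeans(dataset$abundance)
  if (length(means) < 4) {
    warning("fewer than 4 taxa; returning a single group", call. = FALSE)
    f <- factor(rep("Q1", length(means)), levels = "Q1")
    names(f) <- dataset$taxa
    return(f)
  }
  # ties broken by label order for a deterministic assignment
  rk <- rank(means, ties.method = "first")
  q <- cut(rk, breaks = stats::quantile(rk, probs = seq(0, 1, 0.25)),
           include.lowest = TRUE, labels = paste0("Q", 1:4))
  names(q) <- dataset$taxa
  q
}
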