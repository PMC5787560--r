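# Diversity summaries and prevalence classification.

#' Richness per time point
#'
#' Number of taxa with abundance > 0 in each time-point column.
#'
#' @param dataset an `mbtime_dataset`.
#' @return integer vector over time points.
#' @export
richness <- function(dataset) {
  stopifnot_dataset(dataset)
  as.integer(colSums(dataset$abundance > 0))
}

#' Shannon diversity of one abundance vector
#'
#' Computes \eqn{-\sum_i p_i \ln p_i} over the positive entries, where
#' \eqn{p_i} are the proportions within the vector (natural log). The value
#' is invariant to rescaling, so counts and proportions give the same index.
#'
#' @param column non-negative numeric vector.
#' @return the Shannon index; `NA` with a warning for an all-zero vector.
#' @export
shannon_index <- function(column) {
  if (any(column < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(column)
  if (s == 0) {
    warning("all-zero abundance vector: Shannon index undefined",
            call. = FALSE)
    return(NA_real_)
  }
  p <- column[column > 0] / s
  -sum(p * log(p)) + 0       # + 0 normalizes IEEE negative zero
}

#' Richness and Shannon diversity across the timeline
#'
#' @param dataset an `mbtime_dataset`.
#' @return a `data.frame` with columns `time`, `condition`, `richness`,
#'   `shannon`.
#' @export
diversity_series <- function(dataset) {
  stopifnot_dataset(dataset)
  data.frame(
    time = dataset$times,
    condition = dataset$conditions,
    richness = richness(dataset),
    shannon = suppressWarnings(
      apply(dataset$abundance, 2, shannon_index)),
    row.names = NULL)
}

longest_run <- function(present) {
  r <- rle(present)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Classify taxa as core, persistent, transient or other
#'
#' Presence is abundance > 0. With `prevalence` the fraction of time points a
#' taxon is present in and `run fraction` its longest consecutive presence
#' run divided by its total presence count:
#' \itemize{
#'   \item core: present at every time point;
#'   \item persistent: prevalence above `persistent_prevalence` and run
#'     fraction at least `persistent_run`;
#'   \item transient: prevalence at least `transient_prevalence` and run
#'     fraction at most `transient_run`;
#'   \item other: anything else (including absent taxa).
#' }
#' Precedence is core > persistent > transient; the rule regions can
#' otherwise overlap for unusual threshold choices.
#'
#' @param dataset an `mbtime_dataset` with at least 2 time points.
#' @param persistent_prevalence persistent rule: prevalence must exceed this
#'   (default 0.20).
#' @param persistent_run persistent rule: run fraction must be at least this
#'   (default 0.90).
#' @param transient_prevalence transient rule: prevalence must be at least
#'   this (default 0.60).
#' @param transient_run transient rule: run fraction must be at most this
#'   (default 0.75).
#' @return a `data.frame` with columns `taxon`, `prevalence`,
#'   `longest_run_fraction`, `call`.
#' @export
classify_prevalence <- function(dataset,
                                persistent_prevalence = 0.20,
                                persistent_run = 0.90,
                                transient_prevalence = 0.60,
                                transient_run = 0.75) {
  stopifnot_dataset(dataset)
  if (n_time(dataset) < 2)
    stop("prevalence classification needs >= 2 time points", call. = FALSE)
  pres <- dataset$abundance > 0
  prevalence <- rowMeans(pres)
  run_frac <- vapply(seq_len(nrow(pres)), function(i) {
    np <- sum(pres[i, ])
    if (np == 0) return(NA_real_)
    longest_run(pres[i, ]) / np
  }, 0)
  call <- ifelse(prevalence == 1, "core",
          ifelse(prevalence > persistent_prevalence &
                 !is.na(run_frac) & run_frac >= persistent_run, "persistent",
          ifelse(prevalence >= transient_prevalence &
                 !is.na(run_frac) & run_frac <= transient_run, "transient",
                 "other")))
  data.frame(taxon = dataset$taxa, prevalence = prevalence,
             longest_run_fraction = run_frac, call = call,
             row.names = NULL)
}
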