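# Two-window differential abundance: fold changes, rank-sum tests, BH
# correction.

resolve_range <- function(dataset, range, condition = NULL, what = "range") {
  if (!is.null(condition)) {
    idx <- which(dataset$conditions == condition)
    if (!length(idx))
      stop("no time points with condition '", condition, "'", call. = FALSE)
    return(idx)
  }
  if (length(range) != 2)
    stop(what, " must be an inclusive (start, end) index pair",
         call. = FALSE)
  range <- as.integer(range)
  if (range[1] < 1 || range[2] > n_time(dataset) || range[1] > range[2])
    stop(what, " out of bounds", call. = FALSE)
  range[1]:range[2]
}

rank_sum_p <- function(v1, v2) {
  if (length(unique(c(v1, v2))) == 1) return(1)   # all ties: no evidence
  n <- max(length(v1), length(v2))
  ties <- any(duplicated(c(v1, v2)))
  suppressWarnings(stats::wilcox.test(
    v1, v2, exact = (n <= 20 && !ties), correct = TRUE)$p.value)
}

#' Compare taxa between two time windows
#'
#' For every taxon: mean abundance over each window, log2 fold change with
#' a pseudocount (default half the smallest nonzero abundance in the
#' dataset), a two-sided Wilcoxon rank-sum test of the two windows'
#' abundance vectors, Benjamini-Hochberg correction across taxa, and an
#' `eliminated` flag for taxa present in window 1 but absent from
#' window 2. Windows may be given as inclusive time-index pairs or by
#' metadata condition label.
#'
#' @param dataset an `mbtime_dataset`.
#' @param range1,range2 inclusive (start, end) time-point index pairs;
#'   ignored when the corresponding condition is given.
#' @param cond1,cond2 optional condition labels selecting the windows
#'   instead of index pairs.
#' @param pseudocount offset inside the log2 ratio; `NULL` for the default.
#' @return a `data.frame` sorted by `|log_fold_change|` descending with
#'   columns `taxon`, `mean1`, `mean2`, `log_fold_change`, `p_value`,
#'   `adjusted_p`, `eliminated`.
#' @export
compare_ranges <- function(dataset, range1 = NULL, range2 = NULL,
                           cond1 = NULL, cond2 = NULL, pseudocount = NULL) {
  stopifnot_dataset(dataset)
  idx1 <- resolve_range(dataset, range1, cond1, "range1")
  idx2 <- resolve_range(dataset, range2, cond2, "range2")
  if (length(intersect(idx1, idx2)))
    stop("the two ranges overlap", call. = FALSE)
  if (length(idx1) < 3 || length(idx2) < 3)
    stop("each range needs >= 3 time points", call. = FALSE)
  if (is.null(pseudocount)) {
    nz <- dataset$abundance[dataset$abundance > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 0.5
  }
  A <- dataset$abundance
  mean1 <- rowMeans(A[, idx1, drop = FALSE])
  mean2 <- rowMeans(A[, idx2, drop = FALSE])
  lfc <- log2((mean2 + pseudocount) / (mean1 + pseudocount))
  p <- vapply(seq_len(nrow(A)), function(i)
    rank_sum_p(A[i, idx1], A[i, idx2]), 0)
  out <- data.frame(taxon = dataset$taxa, mean1 = mean1, mean2 = mean2,
                    log_fold_change = lfc, p_value = p,
                    adjusted_p = stats::p.adjust(p, method = "BH"),
                    eliminated = mean1 > 0 & mean2 == 0,
                    row.names = NULL)
  attr(out, "pseudocount") <- pseudocount
  out[order(abs(out$log_fold_change), decreasing = TRUE), , drop = FALSE]
}
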