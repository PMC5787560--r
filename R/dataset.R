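#' Construct a longitudinal microbiome dataset
#'
#' The central container of the package: a taxa-by-timepoint abundance matrix
#' for a single source (subject or environment), with strictly increasing
#' time stamps, a condition label per time point, and a record of which
#' normalization (if any) has been applied.
#'
#' @param abundance numeric matrix, taxa in rows, time points in columns.
#'   Row names are taxon labels; they are taken from `taxa` if unset.
#' @param times numeric vector of time stamps, one per column, strictly
#'   increasing.
#' @param taxa character vector of taxon labels (defaults to rownames).
#' @param conditions character vector of per-timepoint condition labels
#'   (defaults to `""`).
#' @param source single string identifying the subject/environment.
#' @param lineages optional character vector of semicolon-delimited taxonomy
#'   strings, one per taxon.
#' @param normalization `"none"`, `"relative"`, or `"rarefied"`.
#' @param depth rarefaction depth when `normalization = "rarefied"`.
#'
#' @return An object of class `mbtime_dataset`: a list with elements
#'   `abundance`, `taxa`, `times`, `conditions`, `source`, `lineages`,
#'   `normalization`, `depth`.
#' @export
mbtime_dataset <- function(abundance, times, taxa = rownames(abundance),
                           conditions = NULL, source = "sample",
                           lineages = NULL,
                           normalization = c("none", "relative", "rarefied"),
                           depth = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  normalization <- match.arg(normalization)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(nrow(abundance)))
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(abundance))
    stop("`taxa` must have one entry per abundance row", call. = FALSE)
  if (anyDuplicated(taxa))
    stop("taxon labels must be unique", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) != ncol(abundance))
    stop("`times` must have one entry per abundance column", call. = FALSE)
  if (ncol(abundance) >= 2 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundances must be finite and non-negative", call. = FALSE)
  if (is.null(conditions)) conditions <- rep("", length(times))
  conditions <- as.character(conditions)
  if (length(conditions) != length(times))
    stop("`conditions` must have one entry per time point", call. = FALSE)
  if (!is.null(lineages)) {
    lineages <- as.character(lineages)
    if (length(lineages) != length(taxa))
      stop("`lineages` must have one entry per taxon", call. = FALSE)
  }
  rownames(abundance) <- taxa
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("t", seq_along(times))
  structure(
    list(abundance = abundance, taxa = taxa, times = times,
         conditions = conditions, source = as.character(source)[1],
         lineages = lineages, normalization = normalization,
         depth = depth),
    class = "mbtime_dataset")
}

#' @export
print.mbtime_dataset <- function(x, ...) {
  norm <- x$normalization
  if (identical(norm, "rarefied")) norm <- sprintf("rarefied(depth=%g)", x$depth)
  cat(sprintf("<mbtime_dataset> source '%s': %d taxa x %d time points [%s]\n",
              x$source, nrow(x$abundance), ncol(x$abundance), norm))
  cat(sprintf("  time range: %g .. %g; conditions: %s\n",
              min(x$times), max(x$times),
              paste(unique(x$conditions), collapse = ", ")))
  if (!is.null(x$lineages)) cat("  lineages: present\n")
  invisible(x)
}

#' Plot taxon trajectories
#'
#' Draws every taxon's abundance trajectory against time on one panel.
#'
#' @param x an `mbtime_dataset`.
#' @param log10_scale plot `log10(x + pseudocount)` rather than raw values.
#' @param pseudocount offset used when `log10_scale = TRUE`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mbtime_dataset <- function(x, log10_scale = FALSE, pseudocount = 1, ...) {
  m <- t(x$abundance)
  if (log10_scale) m <- log10(m + pseudocount)
  graphics::matplot(x$times, m, type = "l", lty = 1,
                    xlab = "time", ylab = if (log10_scale) "log10 abundance"
                    else "abundance",
                    main = x$source, ...)
  invisible(x)
}

n_time <- function(dataset) ncol(dataset$abundance)

stopifnot_dataset <- function(dataset) {
  if (!inherits(dataset, "mbtime_dataset"))
    stop("expected an `mbtime_dataset` object", call. = FALSE)
  invisible(dataset)
}

#' Write a dataset to a canonical TSV dump
#'
#' Writes taxa as rows and time-ordered columns, with a header row of time
#' stamps and a second header row of condition labels, so the file round-trips
#' through [read_dataset_tsv()].
#'
#' @param dataset an `mbtime_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(dataset, path) {
  stopifnot_dataset(dataset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#time", format(dataset$times, trim = TRUE)),
                   collapse = "\t"), con)
  writeLines(paste(c("#condition", dataset$conditions), collapse = "\t"), con)
  for (i in seq_len(nrow(dataset$abundance))) {
    writeLines(paste(c(dataset$taxa[i],
                       format(dataset$abundance[i, ], trim = TRUE,
                              digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a canonical dataset TSV dump
#'
#' Inverse of [write_dataset_tsv()].
#'
#' @param path file written by [write_dataset_tsv()].
#' @param source source label to attach.
#' @return an `mbtime_dataset` with `normalization = "none"`.
#' @export
read_dataset_tsv <- function(path, source = "sample") {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#time") ||
      !startsWith(lines[2], "#condition"))
    stop("not a dataset TSV dump: ", path, call. = FALSE)
  times <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1])
  # strsplit drops trailing empty fields; pad blank condition labels back
  conditions <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  if (length(conditions) < length(times))
    conditions <- c(conditions,
                    rep("", length(times) - length(conditions)))
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  taxa <- vapply(body, `[`, "", 1L)
  mat <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(length(times))))
  mbtime_dataset(mat, times = times, taxa = taxa, conditions = conditions,
                 source = source)
}
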