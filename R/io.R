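# Ingestion of abundance and metadata tables (QIIME-classic / plain TSV).

TAXONOMY_COLUMN_NAMES <- c("Consensus Lineage", "ConsensusLineage",
                           "taxonomy", "Taxonomy")

#' Read a taxa-by-sample abundance table
#'
#' Supports two dialects: the QIIME-classic OTU table (header line beginning
#' `#OTU ID` or `#OTU_ID`, optional trailing taxonomy column named
#' `Consensus Lineage` or `taxonomy`) and a plain tab-delimited table whose
#' first column is the row identifier and remaining columns are numeric.
#'
#' @param path file path.
#' @param format `"auto"` (detect from the header), `"qiime_classic"` or
#'   `"tsv"`.
#' @return A list of class `mbtime_abundance` with elements `row_ids`,
#'   `lineages` (or `NULL`), `sample_ids` and `counts` (rows x samples
#'   numeric matrix).
#' @export
read_abundance_table <- function(path,
                                 format = c("auto", "qiime_classic", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  first_line <- if (length(lines)) lines[1] else ""
  # QIIME exports often carry a leading '# Constructed from biom file' comment
  while (length(lines) && grepl("^#", lines[1]) &&
         !grepl("^#OTU[ _]ID", lines[1]))
    lines <- lines[-1]
  if (!length(lines)) {
    if (format == "qiime_classic")
      stop("malformed QIIME-classic header (expected '#OTU ID'): ",
           first_line, call. = FALSE)
    stop("no header line found in ", path, call. = FALSE)
  }
  if (format == "auto")
    format <- if (grepl("^#OTU[ _]ID", lines[1])) "qiime_classic" else "tsv"
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (format == "qiime_classic" && !grepl("^#OTU[ _]ID", header[1]))
    stop("malformed QIIME-classic header (expected '#OTU ID'): ",
         lines[1], call. = FALSE)
  if (length(header) < 2)
    stop("header has no sample columns: ", lines[1], call. = FALSE)
  tax_col <- which(header %in% TAXONOMY_COLUMN_NAMES)
  if (length(tax_col) > 1)
    stop("multiple taxonomy columns in header", call. = FALSE)
  sample_cols <- setdiff(seq_along(header)[-1], tax_col)
  sample_ids <- header[sample_cols]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)

  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1] + 1L,
         " has ", nf[nf != length(header)][1], " fields, expected ",
         length(header), call. = FALSE)
  row_ids <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(row_ids))
    stop("duplicate row ids: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  counts <- matrix(NA_real_, nrow = length(body), ncol = length(sample_cols),
                   dimnames = list(row_ids, sample_ids))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][sample_cols]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric abundance at row '%s', sample '%s'",
                   row_ids[i], sample_ids[bad[1]]), call. = FALSE)
    neg <- which(vals < 0)
    if (length(neg))
      stop(sprintf("negative abundance at row '%s', sample '%s'",
                   row_ids[i], sample_ids[neg[1]]), call. = FALSE)
    counts[i, ] <- vals
  }
  lineages <- if (length(tax_col)) vapply(body, `[`, "", tax_col) else NULL
  structure(list(row_ids = row_ids, lineages = lineages,
                 sample_ids = sample_ids, counts = counts),
            class = "mbtime_abundance")
}

#' @export
print.mbtime_abundance <- function(x, ...) {
  cat(sprintf("<mbtime_abundance> %d rows x %d samples%s\n",
              length(x$row_ids), length(x$sample_ids),
              if (is.null(x$lineages)) "" else " (with lineages)"))
  invisible(x)
}

#' Read a sample metadata table
#'
#' Expects a tab-delimited file with a header and columns `sample_id`,
#' `source`, `time`, `condition` (any order; extra columns are kept).
#'
#' @param path file path.
#' @return a `data.frame` with `time` numeric.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  required <- c("sample_id", "source", "time", "condition")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  tm <- suppressWarnings(as.numeric(meta$time))
  if (anyNA(tm))
    stop("non-numeric time value(s): ",
         paste(unique(meta$time[is.na(tm)]), collapse = ", "), call. = FALSE)
  meta$time <- tm
  meta
}

#' Join abundance and metadata into a time-ordered dataset
#'
#' Selects the metadata rows of one source, checks that each referenced
#' sample exists as an abundance column, and assembles the taxa-by-timepoint
#' matrix with columns sorted by ascending time.
#'
#' @param table an `mbtime_abundance` from [read_abundance_table()].
#' @param meta a metadata `data.frame` from [read_metadata()].
#' @param source the source (subject) to extract.
#' @return an `mbtime_dataset` with `normalization = "none"`.
#' @export
build_dataset <- function(table, meta, source) {
  if (!inherits(table, "mbtime_abundance"))
    stop("`table` must come from read_abundance_table()", call. = FALSE)
  rows <- meta[meta$source == source, , drop = FALSE]
  if (!nrow(rows))
    stop("no metadata rows for source '", source, "'", call. = FALSE)
  if (anyDuplicated(rows$time))
    stop("tied time stamps within source '", source,
         "'; one observation per time point is required", call. = FALSE)
  missing <- setdiff(rows$sample_id, table$sample_ids)
  if (length(missing))
    stop("samples in metadata missing from abundance table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- rows[order(rows$time), , drop = FALSE]
  mat <- table$counts[, rows$sample_id, drop = FALSE]
  if (length(unique(round(diff(rows$time), 10))) > 1)
    warning("non-uniform time spacing for source '", source,
            "'; algorithms treat points as equally spaced ordinals",
            call. = FALSE)
  mbtime_dataset(mat, times = rows$time, taxa = table$row_ids,
                 conditions = rows$condition, source = source,
                 lineages = table$lineages)
}

split_lineage <- function(lineage) {
  ranks <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  trimws(ranks)
}

#' Aggregate OTU rows to a taxonomic level
#'
#' Rows sharing the same lineage prefix up to `level` ranks are summed.
#' Blank or missing ranks are grouped under `"Unclassified"` at that rank.
#' Column sums are conserved.
#'
#' @param dataset an `mbtime_dataset` whose `lineages` are populated.
#' @param level 1-based rank depth (e.g. with greengenes lineages, 2 =
#'   phylum, 6 = genus).
#' @return an aggregated `mbtime_dataset` labelled by the deepest retained
#'   rank.
#' @export
aggregate_to_level <- function(dataset, level) {
  stopifnot_dataset(dataset)
  if (is.null(dataset$lineages))
    stop("no lineage information; supply a QIIME-classic table with a ",
         "taxonomy column, or a tsv whose row ids are already taxa labels",
         call. = FALSE)
  level <- as.integer(level)
  if (level < 1) stop("`level` must be >= 1", call. = FALSE)
  keys <- vapply(dataset$lineages, function(lin) {
    ranks <- split_lineage(lin)
    if (length(ranks) < level)
      ranks <- c(ranks, rep("", level - length(ranks)))
    ranks <- ranks[seq_len(level)]
    if (!nzchar(sub("^[a-z]__", "", ranks[level])))
      ranks[level] <- "Unclassified"
    paste(ranks, collapse = ";")
  }, "", USE.NAMES = FALSE)
  labels <- vapply(strsplit(keys, ";", fixed = TRUE),
                   function(r) r[length(r)], "")
  # keep full prefix as the identity, last rank as the display label;
  # disambiguate duplicate display labels with the full prefix
  uk <- unique(keys)
  agg <- t(vapply(uk, function(k)
    colSums(dataset$abundance[keys == k, , drop = FALSE]),
    numeric(ncol(dataset$abundance))))
  lab <- labels[match(uk, keys)]
  dup <- lab %in% lab[duplicated(lab)]
  lab[dup] <- uk[dup]
  mbtime_dataset(agg, times = dataset$times, taxa = lab,
                 conditions = dataset$conditions, source = dataset$source,
                 lineages = uk, normalization = dataset$normalization,
                 depth = dataset$depth)
}
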