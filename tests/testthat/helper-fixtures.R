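# In-code fixture builders (no stored data files).

write_qiime_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "# Constructed from biom file",
    paste("#OTU ID", "S1", "S2", "S3", "S4", "Consensus Lineage",
          sep = "\t"),
    paste("otu1", 5, 0, 2, 1,
          "k__Bacteria;p__Firmicutes;c__Clostridia", sep = "\t"),
    paste("otu2", 1, 3, 0, 0,
          "k__Bacteria;p__Bacteroidetes;c__Bacteroidia", sep = "\t"),
    paste("otu3", 0, 7, 4, 9,
          "k__Bacteria;p__Firmicutes;c__Bacilli", sep = "\t")),
    path)
  path
}

write_meta_fixture <- function(path = tempfile(fileext = ".tsv"),
                               sample_ids = c("S1", "S2", "S3", "S4"),
                               source = "subjA",
                               times = seq_along(sample_ids),
                               conditions = rep("ctrl",
                                                length(sample_ids))) {
  utils::write.table(
    data.frame(sample_id = sample_ids, source = source, time = times,
               condition = conditions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_tsv_fixture <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(taxon = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# small random dataset with positive abundances
rand_dataset <- function(k = 5, T = 20, seed = 1, zeros = 0) {
  set.seed(seed)
  A <- matrix(stats::rlnorm(k * T, 2, 0.6), k, T)
  if (zeros > 0) A[sample.int(k * T, zeros)] <- 0
  rownames(A) <- paste0("tx", seq_len(k))
  mbtime_dataset(A, times = seq_len(T))
}
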