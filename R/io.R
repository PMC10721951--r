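#' Read a gene-level expression table from TSV or CSV
#'
#' The delimiter is auto-detected from the header line (tab preferred over
#' comma). Columns `gene_id`, `tpm`, `fpkm` are required (case-insensitive);
#' duplicate gene ids and negative expression values are rejected with the
#' offending row number.
#'
#' @param path Path to the file.
#' @return A data.frame with columns `gene_id` (character), `tpm`, `fpkm`
#'   (numeric), plus any extra columns present in the file.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) {
    stop_epibarrier("epibarrier_io_error",
                    sprintf("expression table not found: '%s'", path))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("gene_id", "tpm", "fpkm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop_epibarrier("epibarrier_io_error",
                    sprintf("missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  tab$gene_id <- as.character(tab$gene_id)
  dup <- which(duplicated(tab$gene_id))
  if (length(dup) > 0L) {
    stop_epibarrier("epibarrier_io_error",
                    sprintf("duplicated gene_id '%s' at row %d",
                            tab$gene_id[dup[1L]], dup[1L]))
  }
  for (m in c("tpm", "fpkm")) {
    if (!is.numeric(tab[[m]])) {
      stop_epibarrier("epibarrier_io_error",
                      sprintf("column '%s' is not numeric", m))
    }
    neg <- which(tab[[m]] < 0)
    if (length(neg) > 0L) {
      stop_epibarrier("epibarrier_io_error",
                      sprintf("negative %s at row %d (gene '%s')",
                              m, neg[1L], tab$gene_id[neg[1L]]))
    }
  }
  tab
}

# canonical on-disk dialect: tab-separated, header, no quotes, no rownames
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
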