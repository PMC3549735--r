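#' Write a dissimilarity matrix to TSV
#'
#' Square tab-separated matrix with a header row/column of sample IDs,
#' preceded by `#`-comment lines recording the measure configuration and
#' package version.
#'
#' @param dm a `diss_matrix` (or plain symmetric matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diss_tsv <- function(dm, path) {
  D <- if (inherits(dm, "diss_matrix")) dm$D else as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(dm, "diss_matrix")) {
    writeLines(sprintf("# measure=%s k=%d order=%s metasig=%s",
                       dm$spec$measure, dm$spec$k,
                       ifelse(is.na(dm$spec$order), "NA", dm$spec$order),
                       as.character(packageVersion("metasig"))), con)
  }
  writeLines(paste(c("sample", colnames(D)), collapse = "\t"), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(rownames(D)[i],
                       format(D[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dissimilarity matrix written by [write_diss_tsv()]
#'
#' @param path TSV path (leading `#` comment lines are skipped).
#' @return a symmetric numeric matrix with sample-ID dimnames.
#' @export
read_diss_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, row.names = 1L)
  D <- as.matrix(df)
  if (nrow(D) != ncol(D)) stop("matrix in ", path, " is not square")
  colnames(D) <- rownames(D)
  D
}

#' Write a dissimilarity matrix in PHYLIP distance format
#'
#' Lower-precision interchange dialect accepted by classic tree tools:
#' first line the number of samples, then one row per sample with the
#' (possibly truncated to 10 characters) ID followed by the distances.
#'
#' @param dm a `diss_matrix` or symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diss_phylip <- function(dm, path) {
  D <- if (inherits(dm, "diss_matrix")) dm$D else as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  ids <- sprintf("%-10s", substr(rownames(D), 1L, 10L))
  for (i in seq_len(nrow(D))) {
    writeLines(paste0(ids[i], paste(sprintf("%.6f", D[i, ]),
                                    collapse = "  ")), con)
  }
  invisible(path)
}
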