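#' Count k-tuples in a supplemented read set
#'
#' Counts every length-`k` window lying fully inside a read over the fixed
#' lexicographic A<C<G<T tuple order (see [all_kmers()]).  Windows that
#' contain any non-ACGT character are skipped; tuples never span read
#' boundaries.  The read set must already be strand-supplemented, which
#' makes the counts exactly strand-symmetric:
#' `count(w) == count(reverse complement of w)` for every tuple `w`.
#'
#' @param rs a supplemented [read_set()].
#' @param k tuple size; `4^k` cells are allocated, so `k` is capped at
#'   `max_k` (default 12) as a memory guard.
#' @param max_k override for the memory guard.
#' @return object of class `kmer_counts`: list with `k`, `counts` (named
#'   numeric vector of length `4^k`), `n` (total counted windows) and
#'   `sample_id`.  If no read is long enough, all counts are 0 and `n = 0`
#'   (with a warning, not an error).
#' @export
#' @examples
#' rs <- supplement_complements(read_set("AAAA"))
#' count_kmers(rs, 2)$counts[c("AA", "TT")]  # 3 3
count_kmers <- function(rs, k, max_k = 12L) {
  stopifnot(inherits(rs, "read_set"))
  k <- .as_count(k, "k")
  if (k > max_k) {
    stop("k = ", k, " exceeds max_k = ", max_k,
         " (4^k memory guard); pass a larger max_k to override")
  }
  if (!rs$supplemented) {
    stop("read set must be strand-supplemented before counting; ",
         "call supplement_complements() first")
  }
  counts <- Biostrings::oligonucleotideFrequency(rs$reads, width = k,
                                                 simplify.as = "collapse")
  counts <- as.numeric(counts)
  names(counts) <- all_kmers(k)
  n <- sum(counts)
  if (n == 0) {
    warning("no length-", k, " window in any read of '", rs$sample_id,
            "'; signature is all zero")
  }
  structure(list(k = k, counts = counts, n = n, sample_id = rs$sample_id),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> sample:", x$sample_id, " k =", x$k,
      " n =", format(x$n, big.mark = ","), "\n")
  invisible(x)
}

#' Normalise a count vector to a frequency vector
#'
#' `f = c / n`, so the components sum to 1.
#'
#' @param cv a `kmer_counts` object with `n > 0`.
#' @return object of class `kmer_freqs`: list with `k`, `freqs` (named,
#'   length `4^k`, summing to 1) and `sample_id`.
#' @export
to_frequencies <- function(cv) {
  stopifnot(inherits(cv, "kmer_counts"))
  if (cv$n == 0) stop("empty signature: total tuple count is 0")
  structure(list(k = cv$k, freqs = cv$counts / cv$n, sample_id = cv$sample_id),
            class = "kmer_freqs")
}

#' @export
print.kmer_freqs <- function(x, ...) {
  cat("<kmer_freqs> sample:", x$sample_id, " k =", x$k, "\n")
  invisible(x)
}

#' Write a signature to a TSV file
#'
#' Plain-text cache of a sample signature: one row per tuple with columns
#' `tuple`, `count`, `frequency`.
#'
#' @param cv a `kmer_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(cv, path) {
  stopifnot(inherits(cv, "kmer_counts"))
  freqs <- if (cv$n > 0) cv$counts / cv$n else rep(0, length(cv$counts))
  df <- data.frame(tuple = names(cv$counts), count = cv$counts,
                   frequency = freqs, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature written by [write_signature_tsv()]
#'
#' @param path TSV path.
#' @param sample_id sample label (defaults to the file name).
#' @return a `kmer_counts` object.
#' @export
read_signature_tsv <- function(path, sample_id = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric"))
  k <- nchar(df$tuple[1L])
  if (nrow(df) != 4^k || !identical(df$tuple, all_kmers(k))) {
    stop("not a valid signature file: ", path)
  }
  counts <- setNames(df$count, df$tuple)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  }
  structure(list(k = as.integer(k), counts = counts, n = sum(counts),
                 sample_id = sample_id),
            class = "kmer_counts")
}
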