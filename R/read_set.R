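#' Construct a read set
#'
#' A `read_set` holds one sample's nucleotide reads.  Reads are stored as a
#' [Biostrings::DNAStringSet] over the alphabet `{A,C,G,T,N}` (uppercased on
#' input).  Before k-tuple counting the set must be supplemented with the
#' complements of the reads so both genome strands contribute equally; see
#' [supplement_complements()].
#'
#' @param reads character vector or `DNAStringSet` of reads.
#' @param sample_id label for the sample.
#' @param supplemented logical; `TRUE` only if `reads` already contains the
#'   complements (second half) of the original reads (first half).
#' @return an object of class `read_set` with elements `reads`,
#'   `sample_id`, `supplemented`.
#' @export
#' @examples
#' rs <- read_set(c("ACGT", "GGNA"), sample_id = "s1")
#' length(rs$reads)
read_set <- function(reads, sample_id = "sample", supplemented = FALSE) {
  if (is.character(reads)) {
    if (length(reads) == 0L) stop("empty read set")
    bad <- grepl("[^ACGTNacgtn]", reads)
    if (any(bad)) {
      stop("read ", which(bad)[1L], " contains letters outside {A,C,G,T,N}")
    }
    reads <- Biostrings::DNAStringSet(toupper(reads))
  } else if (!methods::is(reads, "DNAStringSet")) {
    stop("`reads` must be a character vector or a DNAStringSet")
  }
  if (length(reads) == 0L) stop("empty read set")
  structure(
    list(reads = reads, sample_id = as.character(sample_id)[1L],
         supplemented = isTRUE(supplemented)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> sample:", x$sample_id, "-", length(x$reads), "reads",
      if (x$supplemented) "(strand-supplemented)" else "(un-supplemented)",
      "\n")
  invisible(x)
}

#' Load reads from a FASTA or FASTQ file
#'
#' Parses a (possibly gzip-compressed) FASTA or FASTQ file into an
#' un-supplemented [read_set()].  FASTQ quality strings are discarded:
#' the signature method uses base calls only.  Sequence letters are
#' uppercased.
#'
#' @param path path to the sequence file.
#' @param format `"auto"` (guess from the file extension), `"fasta"` or
#'   `"fastq"`.
#' @param sample_id sample label; defaults to the file name without
#'   extensions.
#' @return an un-supplemented `read_set`, reads in file order.
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq"),
                       sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2|xz)$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(reads) == 0L) stop("no reads in ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(gz|bz2|xz)$", "", basename(path))
    sample_id <- sub("\\.[A-Za-z]+$", "", sample_id)
  }
  read_set(reads, sample_id = sample_id)
}

#' Supplement a read set with read complements
#'
#' NGS reads come from either strand of the source genomes and the strand
#' of origin is unknown, so every read is paired with its complement before
#' counting.  By default the biological reverse complement is appended (the
#' sequence actually present on the opposite strand); `reverse = FALSE`
#' appends the base-wise complement without reversal.  Either choice makes
#' the resulting k-tuple counts strand-symmetric.
#'
#' @param rs an un-supplemented `read_set`.
#' @param reverse append reverse complements (default) rather than
#'   unreversed base-wise complements.
#' @return a `read_set` with `2 * length(rs$reads)` reads (originals first)
#'   and the `supplemented` flag set.
#' @export
#' @examples
#' rs <- supplement_complements(read_set(c("GATC", "CC")))
#' as.character(rs$reads)  # "GATC" "CC" "GATC" "GG"
supplement_complements <- function(rs, reverse = TRUE) {
  stopifnot(inherits(rs, "read_set"))
  if (rs$supplemented) {
    stop("read set '", rs$sample_id, "' is already supplemented")
  }
  comp <- if (reverse) {
    Biostrings::reverseComplement(rs$reads)
  } else {
    Biostrings::complement(rs$reads)
  }
  read_set(c(rs$reads, comp), sample_id = rs$sample_id, supplemented = TRUE)
}

# supplement unless the caller already did
.ensure_supplemented <- function(rs) {
  if (rs$supplemented) rs else supplement_complements(rs)
}
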