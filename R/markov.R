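#' Fit a Markov background model to a sample's reads
#'
#' Estimates an order-`r` Markov chain over `{A,C,G,T}` from all windows of
#' the supplemented read set, to serve as the null ("background") model for
#' expected k-tuple frequencies.  Order 0 is the i.i.d. model whose
#' parameters are the single-nucleotide frequencies.  For `r >= 1`,
#' transition probabilities are ratios of `(r+1)`-tuple to `r`-tuple window
#' counts, and the initial distribution is the observed frequency of each
#' r-tuple over all windows (a stationary-type estimate; read starts are
#' arbitrary fragmentation points and carry no signal).  Because the read
#' set contains both strands, the fitted model is strand-symmetric.
#'
#' Contexts never observed get an all-zero transition row (no pseudocounts
#' by default); tuples whose expected frequency is 0 are handled at the
#' measure level.  For degenerate inputs an additive `pseudocount` can be
#' supplied, which is added to every tuple count used in estimation.
#'
#' @param rs a supplemented [read_set()].
#' @param order Markov order `r >= 0`.
#' @param pseudocount additive pseudocount (default 0).
#' @return object of class `markov_bg`: list with `order`, `base_probs`
#'   (length-4), `initial` (length `4^r`; scalar 1 for order 0) and
#'   `transitions` (`4^r x 4` row-stochastic matrix; `NULL` for order 0).
#' @export
fit_markov <- function(rs, order, pseudocount = 0) {
  stopifnot(inherits(rs, "read_set"))
  r <- .as_count(order, "order", min = 0L)
  if (!rs$supplemented) {
    stop("read set must be strand-supplemented before fitting; ",
         "call supplement_complements() first")
  }
  oligo <- function(w) {
    as.numeric(Biostrings::oligonucleotideFrequency(
      rs$reads, width = w, simplify.as = "collapse")) + pseudocount
  }
  c1 <- oligo(1L)
  if (sum(c1) == 0) stop("insufficient data for order ", r, ": no bases")
  base_probs <- setNames(c1 / sum(c1), .bases)
  if (r == 0L) {
    initial <- 1
    transitions <- NULL
  } else {
    cr <- oligo(r)
    cr1 <- oligo(r + 1L)
    if (sum(cr1) == 0) {
      stop("insufficient data for order ", r, ": no window of length ",
           r + 1L, " in any read")
    }
    initial <- setNames(cr / sum(cr), all_kmers(r))
    tm <- matrix(cr1, ncol = 4L, byrow = TRUE,
                 dimnames = list(all_kmers(r), .bases))
    tot <- rowSums(tm)
    transitions <- tm / ifelse(tot > 0, tot, 1)  # unseen context -> zero row
  }
  structure(list(order = r, base_probs = base_probs, initial = initial,
                 transitions = transitions, sample_id = rs$sample_id),
            class = "markov_bg")
}

#' @export
print.markov_bg <- function(x, ...) {
  cat("<markov_bg> sample:", x$sample_id, " order:", x$order,
      " base probs:", paste(sprintf("%s=%.3f", .bases, x$base_probs),
                            collapse = " "), "\n")
  invisible(x)
}

#' Expected frequency of one or more tuples under a background model
#'
#' Under the order-0 model, `E f(w) = prod_j p(w_j)`.  Under order `r >= 1`,
#' `E f(w) = p(w_1..w_r) * prod_{j=1}^{k-r} p(w_{j+r} | w_j..w_{j+r-1})`.
#' An unseen context contributes probability 0 (not an error).
#'
#' @param bg a `markov_bg`.
#' @param w character vector of tuples over `{A,C,G,T}`; each must have
#'   length at least `max(order, 1)`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
expected_frequency <- function(bg, w) {
  stopifnot(inherits(bg, "markov_bg"))
  if (any(grepl("[^ACGT]", w))) stop("tuples must be over {A,C,G,T}")
  r <- bg$order
  vapply(w, function(word) {
    k <- nchar(word)
    if (k < max(r, 1L)) {
      stop("tuple '", word, "' shorter than model order ", r)
    }
    letters <- strsplit(word, "")[[1L]]
    if (r == 0L) {
      prod(bg$base_probs[letters])
    } else {
      p <- bg$initial[substr(word, 1L, r)]
      if (k > r) {
        for (j in seq_len(k - r)) {
          ctx <- substr(word, j, j + r - 1L)
          p <- p * bg$transitions[ctx, letters[j + r]]
        }
      }
      unname(p)
    }
  }, numeric(1L))
}

#' Expected frequencies of all 4^k tuples
#'
#' Vectorised companion to [expected_frequency()]: returns the full
#' expected-frequency vector over [all_kmers()] order, computed by a
#' prefix-extension recursion.  When every context was observed the vector
#' sums to 1 for any `k >= order`.
#'
#' @param bg a `markov_bg`.
#' @param k tuple size, `k >= max(order, 1)`.
#' @return numeric vector of length `4^k` (named for `k <= 8`).
#' @export
expected_freqs <- function(bg, k) {
  stopifnot(inherits(bg, "markov_bg"))
  k <- .as_count(k, "k")
  r <- bg$order
  if (k < r) stop("k must be >= model order ", r)
  if (r == 0L) {
    out <- unname(bg$base_probs)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        out <- as.vector(t(outer(out, unname(bg$base_probs))))
      }
    }
  } else {
    out <- unname(bg$initial)
    tr <- unname(bg$transitions)
    m <- r
    while (m < k) {
      ctx <- ((seq_len(4L^m) - 1L) %% 4L^r) + 1L
      out <- rep(out, each = 4L) * as.vector(t(tr[ctx, , drop = FALSE]))
      m <- m + 1L
    }
  }
  if (k <= 8L) names(out) <- all_kmers(k)
  out
}

#' Expected tuple counts under a background model
#'
#' Scales [expected_freqs()] by the total tuple count `n`, giving the
#' expectation `n * p_i` used to centralise observed counts.
#'
#' @param bg a `markov_bg`.
#' @param k tuple size.
#' @param n total tuple count (`>= 0`).
#' @return object of class `expected_counts`: list with `k`, `expected`
#'   (length `4^k`) and `n`.
#' @export
expected_counts <- function(bg, k, n) {
  n <- .as_count(n, "n", min = 0L)
  structure(list(k = .as_count(k, "k"), expected = n * expected_freqs(bg, k),
                 n = n),
            class = "expected_counts")
}

#' Export / import a background model as JSON
#'
#' Round-trippable plain-text serialisation (order, base probabilities,
#' initial distribution, transition matrix) for reproducibility.
#'
#' @param bg a `markov_bg`.
#' @param path output (input) path.
#' @return `write_markov_json()` returns `path` invisibly;
#'   `read_markov_json()` returns a `markov_bg`.
#' @export
write_markov_json <- function(bg, path) {
  stopifnot(inherits(bg, "markov_bg"))
  obj <- list(order = bg$order,
              sample_id = bg$sample_id,
              base_probs = as.list(bg$base_probs),
              initial = if (bg$order > 0) as.list(bg$initial) else list(),
              transitions = if (bg$order > 0) {
                apply(bg$transitions, 1L, as.list, simplify = FALSE)
              } else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_markov_json
#' @export
read_markov_json <- function(path) {
  obj <- jsonlite::read_json(path)
  r <- as.integer(obj$order)
  base_probs <- setNames(vapply(obj$base_probs, as.numeric, numeric(1L)),
                         names(obj$base_probs))
  if (r == 0L) {
    initial <- 1
    transitions <- NULL
  } else {
    initial <- setNames(vapply(obj$initial, as.numeric, numeric(1L)),
                        names(obj$initial))
    transitions <- do.call(rbind, lapply(obj$transitions, function(row) {
      vapply(row, as.numeric, numeric(1L))
    }))
    rownames(transitions) <- names(obj$transitions)
  }
  structure(list(order = r, base_probs = base_probs, initial = initial,
                 transitions = transitions,
                 sample_id = obj$sample_id %||% "sample"),
            class = "markov_bg")
}
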