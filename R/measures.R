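#' d2 dissimilarity between two count vectors
#'
#' Cosine-type dissimilarity on raw k-tuple counts:
#' `d2 = (1 - sum(cX * cY) / (||cX|| * ||cY||)) / 2`.
#' Counts are non-negative, so the value lies in `[0, 0.5]`; 0 for
#' identical signatures, 0.5 for disjoint support.
#'
#' @param cX,cY `kmer_counts` with equal `k` and positive norms.
#' @return a number in `[0, 0.5]`.
#' @export
d2 <- function(cX, cY) {
  .check_pair(cX, cY)
  x <- cX$counts
  y <- cY$counts
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm count vector")
  0.5 * (1 - sum(x * y) / (nx * ny))
}

#' d2S dissimilarity with Markov background centralisation
#'
#' Counts are centralised by their background expectation,
#' `ct_i = c_i - n * p_i` with `p` from each sample's own fitted Markov
#' model, and compared with the self-standardised D2S statistic
#' `D2S = sum(ctX_i * ctY_i / sqrt(ctX_i^2 + ctY_i^2))`, normalised to
#' `d2S = (1 - D2S / (NX * NY)) / 2` where
#' `NX = sqrt(sum(ctX_i^2 / sqrt(ctX_i^2 + ctY_i^2)))` (and symmetrically
#' `NY`).  Tuples with `ctX_i = ctY_i = 0` are skipped (`0/0 := 0`).
#'
#' The value lies in `[0, 1]`: 0 for identical samples, 1 when tuple
#' enrichments are perfectly anti-correlated, and expectation 0.5 for two
#' samples drawn independently from the same source.
#'
#' @param cX,cY `kmer_counts` with equal `k` and `n > 0`.
#' @param bgX,bgY `markov_bg` of equal order, fitted per sample.
#' @return a number in `[0, 1]`.
#' @export
d2s <- function(cX, cY, bgX, bgY) {
  .check_pair(cX, cY, bgX, bgY)
  tX <- cX$counts - cX$n * expected_freqs(bgX, cX$k)
  tY <- cY$counts - cY$n * expected_freqs(bgY, cY$k)
  if (all(tX == 0) || all(tY == 0)) {
    stop("degenerate signature: all centralized counts are zero")
  }
  denom <- sqrt(tX^2 + tY^2)
  keep <- denom > 0
  d2s_stat <- sum(tX[keep] * tY[keep] / denom[keep])
  nX <- sqrt(sum(tX[keep]^2 / denom[keep]))
  nY <- sqrt(sum(tY[keep]^2 / denom[keep]))
  0.5 * (1 - d2s_stat / (nX * nY))
}

#' d2* dissimilarity with Markov background standardisation
#'
#' As [d2s()] but with expectation-based standardisation:
#' `D2* = sum(ctX_i * ctY_i / sqrt(nX pX_i * nY pY_i))` and
#' `d2* = (1 - D2* / (sqrt(sum(ctX_i^2 / (nX pX_i))) *
#' sqrt(sum(ctY_i^2 / (nY pY_i))))) / 2`.  Tuples with `pX_i = 0` or
#' `pY_i = 0` are skipped in all three sums.
#'
#' @inheritParams d2s
#' @return a number in `[0, 1]`.
#' @export
d2star <- function(cX, cY, bgX, bgY) {
  .check_pair(cX, cY, bgX, bgY)
  pX <- expected_freqs(bgX, cX$k)
  pY <- expected_freqs(bgY, cY$k)
  keep <- pX > 0 & pY > 0
  if (!any(keep)) stop("every tuple skipped: zero expected frequencies")
  tX <- cX$counts[keep] - cX$n * pX[keep]
  tY <- cY$counts[keep] - cY$n * pY[keep]
  nX <- sqrt(sum(tX^2 / (cX$n * pX[keep])))
  nY <- sqrt(sum(tY^2 / (cY$n * pY[keep])))
  if (nX == 0 || nY == 0) {
    stop("degenerate signature: all centralized counts are zero")
  }
  d2star_stat <- sum(tX * tY / sqrt(cX$n * pX[keep] * cY$n * pY[keep]))
  0.5 * (1 - d2star_stat / (nX * nY))
}

#' lp-norm distances between frequency vectors
#'
#' Manhattan (`l1`), Euclidean (`l2`) and Chebyshev (`l-infinity`)
#' distances between two k-tuple frequency vectors.
#'
#' @param fX,fY `kmer_freqs` with equal `k`.
#' @return named numeric vector `c(Ma, Eu, Ch)`; `Ma` lies in `[0, 2]`,
#'   `Ch` in `[0, 1]`.
#' @export
lp_distances <- function(fX, fY) {
  stopifnot(inherits(fX, "kmer_freqs"), inherits(fY, "kmer_freqs"))
  if (fX$k != fY$k) stop("tuple sizes differ: ", fX$k, " vs ", fY$k)
  d <- abs(fX$freqs - fY$freqs)
  c(Ma = sum(d), Eu = sqrt(sum(d^2)), Ch = max(d))
}

#' Composition-vector (CVTree-style) dissimilarity
#'
#' Measures how the k-tuple frequencies of the two samples deviate from
#' their order-(k-2) Markov expectations in a correlated way.  With
#' `a_i = f_i / E[f_i | M_(k-2)] - 1` per sample, the correlation
#' `C = sum(aX_i * aY_i) / (||aX|| * ||aY||)` is mapped to the
#' dissimilarity `(1 - C) / 2` in `[0, 1]`.  Tuples whose expected
#' frequency is 0 in either sample are skipped.
#'
#' @param fX,fY `kmer_freqs` with equal `k >= 2`.
#' @param bgX,bgY `markov_bg` of order exactly `k - 2`, fitted per sample.
#' @return a number in `[0, 1]`.
#' @export
hao_dissimilarity <- function(fX, fY, bgX, bgY) {
  stopifnot(inherits(fX, "kmer_freqs"), inherits(fY, "kmer_freqs"))
  k <- fX$k
  if (k != fY$k) stop("tuple sizes differ: ", k, " vs ", fY$k)
  if (k < 2L) stop("the composition-vector measure requires k >= 2")
  if (bgX$order != k - 2L || bgY$order != k - 2L) {
    stop("backgrounds must have order k - 2 = ", k - 2L)
  }
  eX <- expected_freqs(bgX, k)
  eY <- expected_freqs(bgY, k)
  keep <- eX > 0 & eY > 0
  if (!any(keep)) stop("every tuple skipped: zero expected frequencies")
  aX <- fX$freqs[keep] / eX[keep] - 1
  aY <- fY$freqs[keep] / eY[keep] - 1
  nX <- sqrt(sum(aX^2))
  nY <- sqrt(sum(aY^2))
  if (nX == 0 || nY == 0) stop("zero-norm composition vector")
  corr <- sum(aX * aY) / (nX * nY)
  (1 - corr) / 2
}

# relative-abundance odds ratios of all 4^k words of one sample:
# rho* (k = 2), gamma* (k = 3) or the balanced tetranucleotide tau*
# (k = 4).  Frequencies of each span are normalised over that span's own
# in-read windows; gapped-pattern frequencies (e.g. f(XNZ)) are the
# corresponding marginals of the full-span word frequencies.
.odds_ratios <- function(rs, k) {
  freq <- function(w) {
    cc <- as.numeric(Biostrings::oligonucleotideFrequency(
      rs$reads, width = w, simplify.as = "collapse"))
    tot <- sum(cc)
    if (tot == 0) stop("no window of length ", w, " in sample '",
                       rs$sample_id, "'")
    cc / tot
  }
  arr <- function(v, w) aperm(array(v, rep(4L, w)), rev(seq_len(w)))
  f1 <- freq(1L)
  idx <- .letter_index(k)
  if (k == 2L) {
    f2 <- arr(freq(2L), 2L)
    f2[idx] / (f1[idx[, 1L]] * f1[idx[, 2L]])
  } else if (k == 3L) {
    f2 <- arr(freq(2L), 2L)
    f3 <- arr(freq(3L), 3L)
    fXNZ <- apply(f3, c(1L, 3L), sum)
    i1 <- idx[, 1L]; i2 <- idx[, 2L]; i3 <- idx[, 3L]
    (f3[idx] * f1[i1] * f1[i2] * f1[i3]) /
      (f2[cbind(i1, i2)] * f2[cbind(i2, i3)] * fXNZ[cbind(i1, i3)])
  } else if (k == 4L) {
    f2 <- arr(freq(2L), 2L)
    f3 <- arr(freq(3L), 3L)
    f4 <- arr(freq(4L), 4L)
    fXNZ <- apply(f3, c(1L, 3L), sum)       # one-gap pair, span 3
    fXNMW <- apply(f4, c(1L, 4L), sum)      # two-gap pair, span 4
    fXYNW <- apply(f4, c(1L, 2L, 4L), sum)  # gapped triples, span 4
    fXNZW <- apply(f4, c(1L, 3L, 4L), sum)
    i1 <- idx[, 1L]; i2 <- idx[, 2L]; i3 <- idx[, 3L]; i4 <- idx[, 4L]
    num <- f4[idx] * f2[cbind(i1, i2)] * fXNZ[cbind(i1, i3)] *
      fXNMW[cbind(i1, i4)] * f2[cbind(i2, i3)] * fXNZ[cbind(i2, i4)] *
      f2[cbind(i3, i4)]
    den <- f3[cbind(i1, i2, i3)] * fXYNW[cbind(i1, i2, i4)] *
      fXNZW[cbind(i1, i3, i4)] * f3[cbind(i2, i3, i4)] *
      f1[i1] * f1[i2] * f1[i3] * f1[i4]
    num / den
  } else {
    stop("odds-ratio measures are defined for k in {2, 3, 4}")
  }
}

# mean absolute difference of odds-ratio vectors with the 4^-k prefactor;
# words whose odds ratio is undefined (0/0 etc.) in either sample are
# skipped with a warning
.willner_delta <- function(oX, oY) {
  keep <- is.finite(oX) & is.finite(oY)
  if (!all(keep)) {
    warning(sum(!keep), " word(s) skipped: zero denominator frequency")
  }
  if (!any(keep)) stop("every word skipped: degenerate frequencies")
  sum(abs(oX[keep] - oY[keep])) / length(oX)
}

#' Relative-abundance odds-ratio dissimilarity (delta_k)
#'
#' Dinucleotide, trinucleotide and tetranucleotide "genome signature"
#' dissimilarities: `delta_k = 4^-k * sum_w |odds_w(X) - odds_w(Y)|` where
#' the per-word odds ratios are `rho*` (k = 2), `gamma*` (k = 3) or the
#' balanced Karlin tetranucleotide ratio `tau*` (k = 4).  Words with a zero
#' denominator frequency in either sample are skipped with a warning.
#'
#' @param rsX,rsY supplemented [read_set()]s.
#' @param k word size, one of 2, 3, 4.
#' @return a non-negative number; 0 for identical samples.
#' @export
willner_dissimilarity <- function(rsX, rsY, k) {
  k <- .as_count(k, "k")
  if (!k %in% 2:4) stop("odds-ratio measures are defined for k in {2, 3, 4}")
  rsX <- .ensure_supplemented(rsX)
  rsY <- .ensure_supplemented(rsY)
  .willner_delta(.odds_ratios(rsX, k), .odds_ratios(rsY, k))
}

#' Specify a dissimilarity measure configuration
#'
#' Fixes the 14-measure roster used throughout the package:
#' `d2`; `d2S` and `d2star` each with Markov background order 0-3;
#' `Ma`, `Eu`, `Ch`; `Hao` (background order fixed at `k - 2`); and
#' `Willner` (odds ratios, `k` restricted to 2-4).
#'
#' @param measure measure name, one of
#'   `"d2"`, `"d2S"`, `"d2star"`, `"Ma"`, `"Eu"`, `"Ch"`, `"Hao"`,
#'   `"Willner"`.
#' @param k tuple size (2-12).
#' @param order Markov background order, required for `d2S`/`d2star`
#'   (0-3, with `k >= order + 1`); ignored otherwise (`Hao` always uses
#'   `k - 2`).
#' @return object of class `measure_spec`.
#' @export
#' @examples
#' measure_spec("d2S", k = 5, order = 0)
measure_spec <- function(measure, k, order = NULL) {
  roster <- c("d2", "d2S", "d2star", "Ma", "Eu", "Ch", "Hao", "Willner")
  if (!is.character(measure) || length(measure) != 1L ||
      !measure %in% roster) {
    stop("unknown measure; must be one of: ", paste(roster, collapse = ", "))
  }
  k <- .as_count(k, "k", min = 1L)
  if (measure %in% c("d2S", "d2star")) {
    if (is.null(order)) stop(measure, " requires a Markov `order` (0-3)")
    order <- .as_count(order, "order", min = 0L)
    if (order > 3L) stop("background order must be 0-3 for ", measure)
    if (k < order + 1L) {
      stop(measure, " requires k >= order + 1 (k = ", k,
           ", order = ", order, ")")
    }
  } else if (measure == "Hao") {
    if (k < 2L) stop("Hao requires k >= 2 (background order k - 2 >= 0)")
    order <- k - 2L
  } else if (measure == "Willner") {
    if (!k %in% 2:4) stop("Willner is defined only for k in {2, 3, 4}")
    order <- NA_integer_
  } else {
    order <- NA_integer_
  }
  structure(list(measure = measure, k = k, order = order),
            class = "measure_spec")
}

#' @export
print.measure_spec <- function(x, ...) {
  cat("<measure_spec>", format(x), "\n")
  invisible(x)
}

#' @export
format.measure_spec <- function(x, ...) {
  lbl <- if (x$measure %in% c("d2S", "d2star")) {
    paste0(x$measure, "|M", x$order)
  } else {
    x$measure
  }
  paste0(lbl, " k=", x$k)
}

# per-sample artifacts a measure needs, computed once and reused across
# all pairs of a matrix
.prep_sample <- function(rs, spec) {
  rs <- .ensure_supplemented(rs)
  out <- list(sample_id = rs$sample_id)
  m <- spec$measure
  if (m == "Willner") {
    out$odds <- .odds_ratios(rs, spec$k)
    return(out)
  }
  cv <- count_kmers(rs, spec$k)
  if (m == "d2") {
    out$counts <- cv
  } else if (m %in% c("d2S", "d2star")) {
    out$counts <- cv
    out$bg <- fit_markov(rs, spec$order)
  } else if (m %in% c("Ma", "Eu", "Ch")) {
    out$freqs <- to_frequencies(cv)
  } else if (m == "Hao") {
    out$freqs <- to_frequencies(cv)
    out$bg <- fit_markov(rs, spec$k - 2L)
  }
  out
}

.pair_diss <- function(a, b, spec) {
  switch(spec$measure,
    d2 = d2(a$counts, b$counts),
    d2S = d2s(a$counts, b$counts, a$bg, b$bg),
    d2star = d2star(a$counts, b$counts, a$bg, b$bg),
    Ma = unname(lp_distances(a$freqs, b$freqs)["Ma"]),
    Eu = unname(lp_distances(a$freqs, b$freqs)["Eu"]),
    Ch = unname(lp_distances(a$freqs, b$freqs)["Ch"]),
    Hao = hao_dissimilarity(a$freqs, b$freqs, a$bg, b$bg),
    Willner = .willner_delta(a$odds, b$odds)
  )
}

#' Dissimilarity between two samples under a measure specification
#'
#' Dispatches to the configured measure, supplementing the read sets and
#' fitting any required background models on the fly.  Deterministic given
#' its inputs.
#'
#' @param rsX,rsY [read_set()]s (supplemented or not).
#' @param spec a [measure_spec()].
#' @return a single non-negative dissimilarity.
#' @export
dissimilarity <- function(rsX, rsY, spec) {
  stopifnot(inherits(spec, "measure_spec"))
  .pair_diss(.prep_sample(rsX, spec), .prep_sample(rsY, spec), spec)
}

#' Pairwise dissimilarity matrix over a set of samples
#'
#' Computes signatures and background models once per sample, then fills
#' the symmetric matrix of pairwise dissimilarities (zero diagonal).
#'
#' @param samples list of [read_set()]s (at least 2) with unique
#'   `sample_id`s.
#' @param spec a [measure_spec()].
#' @return object of class `diss_matrix`: list with `D` (symmetric numeric
#'   matrix, sample ids as dimnames) and `spec`.
#' @export
dissimilarity_matrix <- function(samples, spec) {
  stopifnot(inherits(spec, "measure_spec"))
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need at least 2 samples")
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1L))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids)
  }
  preps <- lapply(samples, .prep_sample, spec = spec)
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- tryCatch(.pair_diss(preps[[i]], preps[[j]], spec),
                    error = function(e) {
                      stop("pair (", ids[i], ", ", ids[j], "): ",
                           conditionMessage(e), call. = FALSE)
                    })
      D[i, j] <- D[j, i] <- v
    }
  }
  structure(list(D = D, spec = spec), class = "diss_matrix")
}

#' @export
print.diss_matrix <- function(x, ...) {
  cat("<diss_matrix>", format(x$spec), "-", nrow(x$D), "samples\n")
  print(round(x$D[seq_len(min(6L, nrow(x$D))), seq_len(min(6L, ncol(x$D)))],
              4L))
  invisible(x)
}

#' @export
as.matrix.diss_matrix <- function(x, ...) x$D

#' @export
as.dist.diss_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$D, diag = diag, upper = upper)
}

.check_pair <- function(cX, cY, bgX = NULL, bgY = NULL) {
  stopifnot(inherits(cX, "kmer_counts"), inherits(cY, "kmer_counts"))
  if (cX$k != cY$k) stop("tuple sizes differ: ", cX$k, " vs ", cY$k)
  if (cX$n == 0 || cY$n == 0) stop("empty signature: total tuple count is 0")
  if (!is.null(bgX)) {
    stopifnot(inherits(bgX, "markov_bg"), inherits(bgY, "markov_bg"))
    if (bgX$order != bgY$order) {
      stop("background orders differ: ", bgX$order, " vs ", bgY$order)
    }
    if (cX$k < bgX$order + 1L) {
      stop("k must be >= background order + 1")
    }
  }
  invisible(TRUE)
}
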