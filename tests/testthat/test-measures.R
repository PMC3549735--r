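# construct bare signature/background objects so formula examples can be
# exercised with exact hand-chosen numbers
mk_counts <- function(counts, k = NULL, id = "x") {
  k <- k %||% as.integer(log(length(counts), 4))
  structure(list(k = k, counts = setNames(counts, all_kmers(k)),
                 n = sum(counts), sample_id = id),
            class = "kmer_counts")
}
mk_freqs <- function(freqs, k = NULL, id = "x") {
  k <- k %||% as.integer(log(length(freqs), 4))
  structure(list(k = k, freqs = setNames(freqs, all_kmers(k)),
                 sample_id = id),
            class = "kmer_freqs")
}
mk_bg0 <- function(p, id = "x") {
  structure(list(order = 0L, base_probs = setNames(p, c("A", "C", "G", "T")),
                 initial = 1, transitions = NULL, sample_id = id),
            class = "markov_bg")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("d2 matches the hand-computed cosine form", {
  x <- mk_counts(c(3, 1, 0, 2))
  expect_equal(d2(x, x), 0)
  expect_equal(d2(mk_counts(c(2, 0, 0, 0)), mk_counts(c(0, 1, 1, 0))), 0.5)
  expect_equal(d2(mk_counts(c(2, 0, 0, 0)), mk_counts(c(1, 1, 0, 0))),
               0.5 * (1 - 2 / (2 * sqrt(2))))
  expect_error(d2(x, mk_counts(c(0, 0, 0, 0))), "empty signature")
})

test_that("d2S and d2* are 0 on identical samples and honour hand examples", {
  set.seed(21)
  rs <- supp(random_reads(30, min_len = 30, max_len = 60))
  for (k in c(2, 5)) {
    cv <- count_kmers(rs, k)
    bg <- fit_markov(rs, 0)
    expect_equal(d2s(cv, cv, bg, bg), 0, tolerance = 1e-12)
    expect_equal(d2star(cv, cv, bg, bg), 0, tolerance = 1e-12)
  }

  # d2*: k = 1, uniform p, n = 100, centralized counts (10,-10,0,0) in
  # both samples -> D2* = 8, both norms sqrt(8) -> dissimilarity 0
  cX <- mk_counts(c(35, 15, 25, 25), k = 1L)
  bg <- mk_bg0(rep(0.25, 4))
  expect_equal(d2star(cX, cX, bg, bg), 0, tolerance = 1e-14)

  # perfectly anti-correlated enrichment -> d2S = 1
  cY <- mk_counts(c(15, 35, 25, 25), k = 1L)
  expect_equal(d2s(cX, cY, bg, bg), 1, tolerance = 1e-14)
  expect_equal(d2star(cX, cY, bg, bg), 1, tolerance = 1e-14)

  bg1 <- bg
  bg1$order <- 1L
  expect_error(d2s(cX, cX, bg, bg1), "orders differ")
})

test_that("degenerate centralized signatures error", {
  cX <- mk_counts(c(25, 25, 25, 25), k = 1L)
  bg <- mk_bg0(rep(0.25, 4))
  expect_error(d2s(cX, cX, bg, bg), "degenerate")
  expect_error(d2star(cX, cX, bg, bg), "degenerate")
})

test_that("lp distances match hand arithmetic", {
  fX <- mk_freqs(c(1, 0, 0, 0))
  fY <- mk_freqs(c(0, 1, 0, 0))
  expect_equal(lp_distances(fX, fX), c(Ma = 0, Eu = 0, Ch = 0))
  expect_equal(lp_distances(fX, fY), c(Ma = 2, Eu = sqrt(2), Ch = 1))
  expect_equal(lp_distances(mk_freqs(c(0.5, 0.5, 0, 0)),
                            mk_freqs(rep(0.25, 4))),
               c(Ma = 1, Eu = 0.5, Ch = 0.25))
})

test_that("composition-vector dissimilarity maps correlation to [0,1]", {
  set.seed(31)
  rs <- supp(random_reads(30, min_len = 30, max_len = 60))
  fv <- to_frequencies(count_kmers(rs, 3))
  bg <- fit_markov(rs, 1)
  expect_equal(hao_dissimilarity(fv, fv, bg, bg), 0, tolerance = 1e-12)

  # engineered deviation vectors aX = f/E - 1 on k = 2 under uniform E
  fX <- mk_freqs(rep(0.0625, 16) * (1 + rep(c(1, 0, -1, 0), 4)))
  fY <- mk_freqs(rep(0.0625, 16) * (1 + rep(c(1, 0, 1, 0), 4)))
  bg2 <- mk_bg0(rep(0.25, 4))
  expect_equal(hao_dissimilarity(fX, fY, bg2, bg2), 0.5, tolerance = 1e-12)
  # anti-correlated deviations -> 1
  fZ <- mk_freqs(rep(0.0625, 16) * (1 - rep(c(1, 0, -1, 0), 4)))
  expect_equal(hao_dissimilarity(fX, fZ, bg2, bg2), 1, tolerance = 1e-12)
  expect_error(hao_dissimilarity(fX, fY, mk_bg0(rep(0.25, 4)),
                                 fit_markov(rs, 1)), "order")
})

test_that("odds-ratio (Willner) measure: identity, LLN limit, oracle", {
  set.seed(41)
  rs <- supp(random_reads(20, min_len = 20, max_len = 40))
  for (k in 2:4) {
    expect_equal(willner_dissimilarity(rs, rs, k), 0)
  }

  # long i.i.d. uniform samples: all odds ratios -> 1, delta2 -> 0
  s1 <- supplement_complements(iid_read_set(100, 5000, seed = 1,
                                            sample_id = "u1"))
  s2 <- supplement_complements(iid_read_set(100, 5000, seed = 2,
                                            sample_id = "u2"))
  expect_lt(willner_dissimilarity(s1, s2, 2), 0.01)
  o <- metasig:::.odds_ratios(s1, 2)
  expect_lt(max(abs(o - 1)), 0.05)

  # single-word toy: rho*_AA differing by 1 with all others equal
  oX <- rep(1, 16); names(oX) <- all_kmers(2)
  oY <- oX; oX["AA"] <- 2
  expect_equal(metasig:::.willner_delta(oX, oY), 1 / 16)

  # zero-denominator words are skipped with a warning
  oX["CC"] <- NaN
  expect_warning(v <- metasig:::.willner_delta(oX, oY), "skipped")
  expect_equal(v, 1 / 16)
})

test_that("every measure matches its naive oracle on small read sets", {
  set.seed(51)
  for (rep in 1:8) {
    readsX <- random_reads(12, min_len = 15, max_len = 30)
    readsY <- random_reads(12, min_len = 15, max_len = 30)
    rsX <- supp(readsX, sample_id = "X")
    rsY <- supp(readsY, sample_id = "Y")
    k <- sample(2:3, 1)
    cX <- count_kmers(rsX, k); cY <- count_kmers(rsY, k)
    fX <- to_frequencies(cX); fY <- to_frequencies(cY)

    expect_equal(d2(cX, cY), naive_d2(cX$counts, cY$counts),
                 tolerance = 1e-12)

    for (r in 0:1) {
      bgX <- fit_markov(rsX, r); bgY <- fit_markov(rsY, r)
      pX <- expected_freqs(bgX, k); pY <- expected_freqs(bgY, k)
      expect_equal(d2s(cX, cY, bgX, bgY),
                   naive_d2s(cX$counts, cY$counts, cX$n, cY$n, pX, pY),
                   tolerance = 1e-12)
      expect_equal(d2star(cX, cY, bgX, bgY),
                   naive_d2star(cX$counts, cY$counts, cX$n, cY$n, pX, pY),
                   tolerance = 1e-12)
    }

    ld <- lp_distances(fX, fY)
    expect_equal(unname(ld["Ma"]), sum(abs(fX$freqs - fY$freqs)),
                 tolerance = 1e-12)

    bgX <- fit_markov(rsX, k - 2); bgY <- fit_markov(rsY, k - 2)
    expect_equal(hao_dissimilarity(fX, fY, bgX, bgY),
                 naive_hao(fX$freqs, fY$freqs, expected_freqs(bgX, k),
                           expected_freqs(bgY, k)),
                 tolerance = 1e-12)

    suppressWarnings(
      expect_equal(willner_dissimilarity(rsX, rsY, k),
                   naive_willner(c(readsX, naive_revcomp(readsX)),
                                 c(readsY, naive_revcomp(readsY)), k),
                   tolerance = 1e-12))
  }
})

test_that("measures are symmetric and respect their ranges", {
  set.seed(61)
  for (rep in 1:5) {
    rsX <- supp(random_reads(15, min_len = 20, max_len = 50), sample_id = "X")
    rsY <- supp(random_reads(15, min_len = 20, max_len = 50), sample_id = "Y")
    for (spec in list(measure_spec("d2", 3), measure_spec("d2S", 3, 1),
                      measure_spec("d2star", 3, 0), measure_spec("Ma", 3),
                      measure_spec("Eu", 3), measure_spec("Ch", 3),
                      measure_spec("Hao", 3), measure_spec("Willner", 3))) {
      vxy <- suppressWarnings(dissimilarity(rsX, rsY, spec))
      vyx <- suppressWarnings(dissimilarity(rsY, rsX, spec))
      expect_equal(vxy, vyx, tolerance = 1e-12, label = format(spec))
      expect_gte(vxy, 0)
      lim <- switch(spec$measure, d2 = 0.5, d2S = 1, d2star = 1, Hao = 1,
                    Ma = 2, Ch = 1, Inf)
      expect_lte(vxy, lim)
      vxx <- suppressWarnings(dissimilarity(rsX, rsX, spec))
      expect_equal(vxx, 0, tolerance = 1e-10, label = format(spec))
    }
  }
})

test_that("measure_spec enforces the 14-measure roster rules", {
  expect_error(measure_spec("Willner", 5), "k in \\{2, 3, 4\\}")
  expect_error(measure_spec("Hao", 1), "k >= 2")
  expect_error(measure_spec("d2S", 5), "order")
  expect_error(measure_spec("d2S", 2, 2), "order \\+ 1")
  expect_error(measure_spec("d2star", 4, 4), "0-3")
  expect_error(measure_spec("banana", 4), "unknown measure")
  expect_equal(measure_spec("Hao", 5)$order, 3L)
  expect_equal(format(measure_spec("d2S", 5, 0)), "d2S|M0 k=5")
  # the full roster is 14 configurations
  roster <- c("d2", paste0("d2S|M", 0:3), paste0("d2star|M", 0:3),
              "Ma", "Eu", "Ch", "Hao", "Willner")
  expect_length(roster, 14)
})

test_that("dissimilarity matrix equals looped per-pair calls", {
  set.seed(71)
  samples <- lapply(1:4, function(i) {
    supp(random_reads(12, min_len = 25, max_len = 50),
         sample_id = paste0("s", i))
  })
  spec <- measure_spec("d2S", 4, 0)
  dm <- dissimilarity_matrix(samples, spec)
  expect_true(isSymmetric(dm$D))
  expect_equal(unname(diag(dm$D)), rep(0, 4))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(dm$D[i, j],
                   dissimilarity(samples[[i]], samples[[j]], spec),
                   tolerance = 1e-12)
    }
  }
  two <- dissimilarity_matrix(samples[c(1, 1)], spec)
  expect_equal(unname(two$D), matrix(0, 2, 2))
  expect_error(dissimilarity_matrix(samples[1], spec), "at least 2")
})

test_that("independent same-source samples give mean d2S and d2* near 0.5", {
  # depth-10000 spec scale lives in the acceptance suite; this is a
  # lighter sanity version at depth 2000, k = 4
  set.seed(81)
  vals_s <- vals_star <- numeric(12)
  for (i in 1:12) {
    a <- supplement_complements(iid_read_set(2000, 100, sample_id = "a"))
    b <- supplement_complements(iid_read_set(2000, 100, sample_id = "b"))
    ca <- count_kmers(a, 4); cb <- count_kmers(b, 4)
    ba <- fit_markov(a, 0); bb <- fit_markov(b, 0)
    vals_s[i] <- d2s(ca, cb, ba, bb)
    vals_star[i] <- d2star(ca, cb, ba, bb)
  }
  expect_equal(mean(vals_s), 0.5, tolerance = 0.05)
  expect_equal(mean(vals_star), 0.5, tolerance = 0.05)
})

test_that("matrix TSV and PHYLIP exports round-trip / validate", {
  set.seed(91)
  samples <- lapply(1:3, function(i) {
    supp(random_reads(10, min_len = 20, max_len = 40),
         sample_id = paste0("s", i))
  })
  dm <- dissimilarity_matrix(samples, measure_spec("Eu", 3))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_diss_tsv(dm, tsv)
  expect_equal(read_diss_tsv(tsv), dm$D, tolerance = 1e-12)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_diss_phylip(dm, phy)
  first <- readLines(phy)[1]
  expect_match(first, "3")
})
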