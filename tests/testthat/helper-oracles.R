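# Independent brute-force oracles used to validate the package's fast
# paths.  Everything here is written directly from the formulas, without
# calling the implementation under test.

BASES <- c("A", "C", "G", "T")

naive_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# substring-enumeration k-mer counter; windows with non-ACGT letters skipped
naive_count <- function(reads, k) {
  words <- all_kmers(k)
  counts <- setNames(numeric(4^k), words)
  for (r in reads) {
    L <- nchar(r)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(r, i, i + k - 1)
      if (!grepl("[^ACGT]", w)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

# per-word expected frequency straight from the product formulas
naive_expected_freq <- function(base_probs, initial, transitions, order, w) {
  letters <- strsplit(w, "")[[1]]
  if (order == 0) {
    return(prod(base_probs[letters]))
  }
  p <- initial[paste(letters[1:order], collapse = "")]
  for (j in seq_len(length(letters) - order)) {
    ctx <- paste(letters[j:(j + order - 1)], collapse = "")
    p <- p * transitions[ctx, letters[j + order]]
  }
  unname(p)
}

# naive transcriptions of the measure formulas on raw vectors ------------

naive_d2 <- function(x, y) {
  0.5 * (1 - sum(x * y) / sqrt(sum(x^2)) / sqrt(sum(y^2)))
}

naive_d2s <- function(cx, cy, nx, ny, px, py) {
  tx <- cx - nx * px
  ty <- cy - ny * py
  den <- sqrt(tx^2 + ty^2)
  ok <- den > 0
  D <- sum((tx * ty / den)[ok])
  Nx <- sqrt(sum((tx^2 / den)[ok]))
  Ny <- sqrt(sum((ty^2 / den)[ok]))
  0.5 * (1 - D / (Nx * Ny))
}

naive_d2star <- function(cx, cy, nx, ny, px, py) {
  ok <- px > 0 & py > 0
  tx <- (cx - nx * px)[ok]
  ty <- (cy - ny * py)[ok]
  D <- sum(tx * ty / sqrt(nx * px[ok] * ny * py[ok]))
  Nx <- sqrt(sum(tx^2 / (nx * px[ok])))
  Ny <- sqrt(sum(ty^2 / (ny * py[ok])))
  0.5 * (1 - D / (Nx * Ny))
}

naive_hao <- function(fx, fy, ex, ey) {
  ok <- ex > 0 & ey > 0
  ax <- fx[ok] / ex[ok] - 1
  ay <- fy[ok] / ey[ok] - 1
  C <- sum(ax * ay) / sqrt(sum(ax^2)) / sqrt(sum(ay^2))
  (1 - C) / 2
}

# gapped-word frequency of the supplemented read string set, counted by
# direct window enumeration ("." = any base); span = nchar(pattern)
naive_gapped_freq <- function(reads, pattern) {
  span <- nchar(pattern)
  hits <- 0
  total <- 0
  for (r in reads) {
    L <- nchar(r)
    if (L < span) next
    for (i in seq_len(L - span + 1)) {
      w <- substr(r, i, i + span - 1)
      if (grepl("[^ACGT]", w)) next
      total <- total + 1
      if (grepl(paste0("^", pattern, "$"), w)) hits <- hits + 1
    }
  }
  hits / total
}

# odds ratios by direct enumeration (k in 2:4), then delta by mean |diff|
naive_odds <- function(reads, k) {
  f <- function(pat) naive_gapped_freq(reads, pat)
  words <- all_kmers(k)
  vapply(words, function(w) {
    l <- strsplit(w, "")[[1]]
    if (k == 2) {
      f(w) / (f(l[1]) * f(l[2]))
    } else if (k == 3) {
      f(w) * f(l[1]) * f(l[2]) * f(l[3]) /
        (f(paste0(l[1], l[2])) * f(paste0(l[2], l[3])) *
           f(paste0(l[1], ".", l[3])))
    } else {
      num <- f(w) * f(paste0(l[1], l[2])) * f(paste0(l[1], ".", l[3])) *
        f(paste0(l[1], "..", l[4])) * f(paste0(l[2], l[3])) *
        f(paste0(l[2], ".", l[4])) * f(paste0(l[3], l[4]))
      den <- f(paste0(l[1], l[2], l[3])) * f(paste0(l[1], l[2], ".", l[4])) *
        f(paste0(l[1], ".", l[3], l[4])) * f(paste0(l[2], l[3], l[4])) *
        f(l[1]) * f(l[2]) * f(l[3]) * f(l[4])
      num / den
    }
  }, numeric(1))
}

naive_willner <- function(readsX, readsY, k) {
  ox <- naive_odds(readsX, k)
  oy <- naive_odds(readsY, k)
  ok <- is.finite(ox) & is.finite(oy)
  sum(abs(ox[ok] - oy[ok])) / 4^k
}

# O(n^3) UPGMA recomputing every cluster distance from the original
# matrix (mean over all cross pairs) -- a different algorithm from the
# package's running update
naive_upgma_heights <- function(M) {
  n <- nrow(M)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  copheno <- matrix(0, n, n)
  while (length(clusters) > 1) {
    nc <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(nc - 1)) {
      for (j in seq.int(i + 1, nc)) {
        d <- mean(M[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    copheno[clusters[[i]], clusters[[j]]] <- best[1]
    copheno[clusters[[j]], clusters[[i]]] <- best[1]
    heights <- c(heights, best[1] / 2)
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(heights = heights, cophenetic = copheno)
}

# exhaustive small-parsimony: minimise label changes over all internal
# state assignments of a cluster_tree merge structure
exhaustive_parsimony <- function(tree, labels) {
  grp <- factor(unname(labels[tree$labels]))
  leaf_state <- as.integer(grp)
  nstates <- nlevels(grp)
  nint <- nrow(tree$merge)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nstates)), nint)))
  best <- Inf
  for (row in seq_len(nrow(grid))) {
    st <- grid[row, ]
    cost <- 0
    for (m in seq_len(nint)) {
      for (ch in tree$merge[m, ]) {
        s <- if (ch < 0) leaf_state[-ch] else st[ch]
        cost <- cost + (s != st[m])
      }
    }
    best <- min(best, cost)
  }
  best
}

# random test-data generators -------------------------------------------

random_reads <- function(n, min_len = 5, max_len = 30, with_n = FALSE,
                         alphabet = BASES) {
  if (with_n) alphabet <- c(alphabet, "N")
  vapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1)
    paste(sample(alphabet, L, replace = TRUE,
                 prob = c(rep(1, 4), 0.15)[seq_along(alphabet)]),
          collapse = "")
  }, character(1))
}

random_diss_matrix <- function(n) {
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  M
}

# build a clade-perfect dissimilarity matrix: small within-group, large
# (and group-pair-specific) between-group distances
clade_matrix <- function(group_sizes) {
  n <- sum(group_sizes)
  g <- rep(seq_along(group_sizes), group_sizes)
  M <- matrix(0, n, n)
  between <- matrix(runif(length(group_sizes)^2, 5, 10),
                    length(group_sizes))
  between <- (between + t(between)) / 2
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      M[i, j] <- M[j, i] <- if (g[i] == g[j]) runif(1, 0.1, 1) else
        between[g[i], g[j]]
    }
  }
  ids <- paste0("s", seq_len(n))
  dimnames(M) <- list(ids, ids)
  list(M = M, labels = setNames(paste0("G", g), ids))
}

supp <- function(reads, ...) supplement_complements(read_set(reads, ...))
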