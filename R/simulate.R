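#' Generate a pool of synthetic genomes
#'
#' Stand-ins for real microbial genomes: each genome is sampled from its
#' own order-1 Markov source, the shared uniform transition matrix plus a
#' genome-specific *tilt* of magnitude proportional to `distinctness`.
#' Genuinely different species have compositional signatures whose
#' deviations from the i.i.d. background are essentially uncorrelated
#' with one another; independent random tilts do not guarantee this (two
#' genomes can be accidental compositional near-twins).  The generator
#' therefore builds tilts that are doubly centred (every genome's
#' stationary base composition is exactly uniform, so any abundance
#' mixture shares a single i.i.d. background) and Chargaff-symmetric
#' (the chain reads identically on both strands, so no tilt signal is
#' cancelled by complement supplementation), and then decorrelates the
#' genomes' exact 5-tuple signature deviations: pools of up to 6 genomes
#' get an exactly orthonormal tilt frame chosen among random rotations,
#' larger pools a greedy least-correlated selection from surplus
#' candidates.  `distinctness = 0` gives i.i.d.-uniform genomes with
#' statistically indistinguishable signatures.
#'
#' @param n number of genomes.
#' @param length genome length in bases (`>= 1000`).
#' @param distinctness divergence scale in `[0, 1]` (default 0.5, a
#'   moderately divergent community; transition probabilities then
#'   deviate from 0.25 by about 0.1 rms).
#' @param seed optional RNG seed.
#' @param ids genome identifiers (default `g1..gn`).
#' @return object of class `genome_pool`: list with `ids`, `sequences`
#'   (character vector) and `lengths`.
#' @export
synth_genomes <- function(n, length, distinctness = 0.5, seed = NULL,
                          ids = NULL) {
  n <- .as_count(n, "n")
  length <- .as_count(length, "length", min = 1000L)
  stopifnot(distinctness >= 0, distinctness <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- ids %||% paste0("g", seq_len(n))
  mats <- .decorrelated_transitions(n, scale = 0.7 * distinctness)
  seqs <- vapply(mats, function(tr) .sample_markov_string(length, tr),
                 character(1L))
  structure(list(ids = ids, sequences = seqs, lengths = nchar(seqs)),
            class = "genome_pool")
}

# n transition matrices 0.25 + scale * tilt whose strand-symmetrized
# 5-mer signature deviations are mutually near-uncorrelated.
#
# Tilt design constraints (all motivated by what "n different species"
# looks like to complement-supplemented counting):
#   - zero row sums: rows stay stochastic;
#   - zero column sums: stationary composition pinned at uniform, so any
#     abundance mixture of the genomes shares one i.i.d. background;
#   - Chargaff (strand) symmetry p(x->y) = p(comp y -> comp x): the
#     chain reads the same on both strands, so none of the tilt signal
#     is cancelled by reverse-complement supplementation.
# That constraint space has dimension 6.  For n <= 6 the tilts are an
# exactly orthonormal frame in it, chosen among random rotations as the
# one whose *lifted* k-mer deviations are least correlated; for larger
# pools (e.g. the 113-genome designs) orthogonality is impossible and a
# greedy max-min-correlation selection from surplus candidates is used.
.decorrelated_transitions <- function(n, scale, n_rotations = 40L,
                                      n_candidates = max(8L * n, 200L)) {
  rev4 <- 4:1
  center_sym <- function(m) {
    m <- m - rowMeans(m) - rep(colMeans(m), each = 4L) + mean(m)
    (m + t(m)[rev4, rev4]) / 2
  }
  as_trans <- function(tilt) {
    tilt <- tilt / sqrt(sum(tilt^2))
    tr <- 0.25 + scale * tilt
    tr[tr < 0.01] <- 0.01               # keep the chain mixing
    tr <- tr / rowSums(tr)
    dimnames(tr) <- list(.bases, .bases)
    tr
  }
  if (scale == 0) {
    u <- matrix(0.25, 4L, 4L, dimnames = list(.bases, .bases))
    return(rep(list(u), n))
  }
  if (n <= 6L) {
    # fixed orthonormal basis of the 6-dim constraint space
    seeds <- diag(16L)
    raw <- vapply(seq_len(16L), function(i) {
      as.vector(center_sym(matrix(seeds[, i], 4L)))
    }, numeric(16L))
    qb <- qr(raw)
    B6 <- qr.Q(qb)[, seq_len(qb$rank), drop = FALSE]
    best <- NULL
    best_score <- Inf
    for (r in seq_len(n_rotations)) {
      rot <- qr.Q(qr(matrix(rnorm(6L * n), 6L)))[, seq_len(n), drop = FALSE]
      mats <- lapply(seq_len(n), function(g) {
        as_trans(matrix(B6 %*% rot[, g], 4L))
      })
      devs <- vapply(mats, .signature_deviation, numeric(4L^5))
      C <- abs(stats::cor(devs))
      diag(C) <- 0
      if (max(C) < best_score) {
        best_score <- max(C)
        best <- mats
      }
    }
    return(best)
  }
  cand <- vector("list", n_candidates)
  devs <- matrix(0, 4L^5, n_candidates)
  for (j in seq_len(n_candidates)) {
    cand[[j]] <- as_trans(center_sym(matrix(rnorm(16L), 4L)))
    devs[, j] <- .signature_deviation(cand[[j]])
  }
  C <- abs(stats::cor(devs))
  diag(C) <- 0
  sel <- as.integer(which(C == min(C[C > 0]), arr.ind = TRUE)[1L, ])
  while (length(sel) < n) {
    rest <- setdiff(seq_len(n_candidates), sel)
    worst <- vapply(rest, function(j) max(C[j, sel]), numeric(1L))
    sel <- c(sel, rest[which.min(worst)])
  }
  cand[sel[seq_len(n)]]
}

# exact strand-symmetrized k-mer frequency deviation of an order-1 chain
# from the i.i.d. model with the chain's stationary composition; the
# symmetrization (w averaged with its reverse complement) matches what
# complement-supplemented counting observes
.signature_deviation <- function(trans, k = 5L) {
  ev <- eigen(t(trans))
  i <- which.max(Re(ev$values))
  pi_st <- abs(Re(ev$vectors[, i]))
  pi_st <- pi_st / sum(pi_st)
  bg1 <- structure(list(order = 1L, base_probs = setNames(pi_st, .bases),
                        initial = setNames(pi_st, .bases),
                        transitions = trans, sample_id = "synth"),
                   class = "markov_bg")
  bg0 <- structure(list(order = 0L, base_probs = setNames(pi_st, .bases),
                        initial = 1, transitions = NULL,
                        sample_id = "synth"),
                   class = "markov_bg")
  dev <- expected_freqs(bg1, k) - expected_freqs(bg0, k)
  (dev + dev[.revcomp_perm(k)]) / 2
}

# index permutation mapping each k-mer to its reverse complement
.revcomp_perm <- function(k) {
  words <- all_kmers(k)
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", words), ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1L))
  match(rc, words)
}

# serial order-1 Markov sampling; cumulative-row comparison keeps the
# per-base cost to a few scalar ops
.sample_markov_string <- function(len, trans, init = rep(0.25, 4L)) {
  cum <- t(apply(trans, 1L, cumsum))
  c1 <- cum[, 1L]
  c2 <- cum[, 2L]
  c3 <- cum[, 3L]
  u <- runif(len)
  s <- integer(len)
  s[1L] <- sample.int(4L, 1L, prob = init)
  if (len > 1L) {
    for (i in 2:len) {
      si <- s[i - 1L]
      s[i] <- 1L + (u[i] > c1[si]) + (u[i] > c2[si]) + (u[i] > c3[si])
    }
  }
  paste(.bases[s], collapse = "")
}

#' Load a genome pool from a FASTA file
#'
#' Allows the simulators to run on user-supplied (real) genomes instead of
#' synthetic ones.
#'
#' @param path FASTA path (plain or gzip).
#' @return a `genome_pool`.
#' @export
genome_pool_from_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no genomes in ", path)
  seqs <- toupper(as.character(dss))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("genomes must be over {A,C,G,T}")
  }
  structure(list(ids = sub("\\s.*$", "", names(dss)),
                 sequences = unname(seqs), lengths = unname(nchar(seqs))),
            class = "genome_pool")
}

#' @export
print.genome_pool <- function(x, ...) {
  cat("<genome_pool>", length(x$ids), "genomes,",
      format(sum(x$lengths), big.mark = ","), "bases total\n")
  invisible(x)
}

#' Zipf (power-law) relative abundance profile
#'
#' Rank-abundance profile `f(i; alpha, N) = i^-alpha / sum_n n^-alpha`,
#' `i = 1..N`.  The defaults `alpha = 0.3, N = 113` describe a mildly
#' uneven community of 113 genomes.
#'
#' @param alpha power-law exponent (`>= 0`).
#' @param N number of taxa.
#' @return numeric simplex vector of length `N`.
#' @export
#' @examples
#' zipf_profile(1, 2)  # 2/3, 1/3
zipf_profile <- function(alpha = 0.3, N = 113L) {
  N <- .as_count(N, "N")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  v <- seq_len(N)^(-alpha)
  v / sum(v)
}

.check_profile <- function(p) {
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("abundance profile must be non-negative and sum to 1")
  }
  invisible(p)
}

#' Multiplicative perturbation of an abundance profile
#'
#' Each component is multiplied by an independent folded-normal factor
#' `|Normal(1, sd)|` and the vector is renormalised to the simplex, so
#' the noise scale is proportional to the component itself.  Used to
#' derive well-separated group-centre profiles from a base profile.
#'
#' The default `sd = 1` (unit relative spread, equivalently
#' `p_i <- |Normal(p_i, p_i)|`) is calibrated against published centre
#' realisations of this design, which are unattainable under the
#' much tighter `sd = p_i` variant; pass `sd = p` to get that variant.
#'
#' @param p simplex abundance vector.
#' @param seed optional RNG seed.
#' @param sd standard deviation(s) of the multiplier, recycled over
#'   components.
#' @return a simplex vector of the same length.
#' @export
perturb_multiplicative <- function(p, seed = NULL, sd = 1) {
  .check_profile(p)
  if (!is.null(seed)) set.seed(seed)
  q <- p * abs(rnorm(length(p), mean = 1, sd = sd))
  q / sum(q)
}

#' Additive half-normal perturbation of an abundance profile
#'
#' Adds `|Normal(0, p_i)|` to each component and renormalises.  Zero
#' components stay zero.  Used to scatter within-group sample profiles
#' around a group centre and to add noise along gradients.
#'
#' @inheritParams perturb_multiplicative
#' @return a simplex vector of the same length.
#' @export
perturb_additive <- function(p, seed = NULL) {
  .check_profile(p)
  if (!is.null(seed)) set.seed(seed)
  q <- p + abs(rnorm(length(p), mean = 0, sd = p))
  q / sum(q)
}

#' Grouped community design (group-structured abundance profiles)
#'
#' Builds `centers` group-centre profiles and scatters `per_group`
#' member profiles around each centre with [perturb_additive()].
#' Centres come either from repeated [perturb_multiplicative()] applied
#' to a base profile (`mode = "perturb"`, the low-complexity 5-species
#' design) or from random genome re-orderings of a Zipf profile
#' (`mode = "zipf"`, the high-complexity design).
#'
#' @param centers number of groups (`>= 2`).
#' @param per_group samples per group.
#' @param base base profile for `mode = "perturb"` (default the
#'   5-species profile `(0.05, 0.10, 0.20, 0.25, 0.40)`).
#' @param mode `"perturb"` or `"zipf"`.
#' @param alpha,N Zipf parameters for `mode = "zipf"`.
#' @param seed optional RNG seed.
#' @return list with `profiles` (samples x genomes matrix, rows on the
#'   simplex), `group` (character vector `G1..`), and `centers` (matrix of
#'   centre profiles).
#' @export
group_design <- function(centers = 3L, per_group = 30L,
                         base = c(0.05, 0.10, 0.20, 0.25, 0.40),
                         mode = c("perturb", "zipf"),
                         alpha = 0.3, N = 113L, seed = NULL) {
  centers <- .as_count(centers, "centers", min = 2L)
  per_group <- .as_count(per_group, "per_group")
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ctr <- if (mode == "perturb") {
    .check_profile(base)
    t(vapply(seq_len(centers), function(i) perturb_multiplicative(base),
             numeric(length(base))))
  } else {
    z <- zipf_profile(alpha, N)
    t(vapply(seq_len(centers), function(i) z[sample.int(N)], numeric(N)))
  }
  profiles <- matrix(0, centers * per_group, ncol(ctr))
  group <- character(centers * per_group)
  row <- 0L
  for (g in seq_len(centers)) {
    for (s in seq_len(per_group)) {
      row <- row + 1L
      profiles[row, ] <- perturb_additive(ctr[g, ])
      group[row] <- paste0("G", g)
    }
  }
  list(profiles = profiles, group = group, centers = ctr)
}

#' Gradient community design (abundances shifting along an axis)
#'
#' Two presets emulating gradient-structured communities:
#' \describe{
#'   \item{`bump5`}{5 species; species 1 held constant at `const_level`
#'     (before normalisation) and species 2-5 following Gaussian bumps
#'     `exp(-(x - c_j)^2 / (2 sigma^2))` over the 0-based sample index
#'     `x`, with centres `c(0, 5, 10, 15)` and `sigma = 2.5` so that
#'     neighbouring bumps overlap.  Gradient value = sample index.}
#'   \item{`zipf_alpha`}{`N`-genome Zipf profiles whose exponent walks
#'     `alpha_i = alpha0 + alpha_step * (i - 1)` (defaults 0.275 to 0.75
#'     by 0.025 over 20 samples).  Gradient value = `alpha_i`.}
#' }
#' Additive half-normal noise ([perturb_additive()]) is applied to every
#' profile unless `noise = FALSE`.
#'
#' @param n_samples number of samples (benchmark preset: 20).
#' @param mode `"bump5"` or `"zipf_alpha"`.
#' @param sigma Gaussian bump width (bump5).
#' @param const_level unnormalised abundance of the constant species
#'   (bump5).
#' @param centers bump centres on the 0-based sample index axis (bump5).
#' @param alpha0,alpha_step,N Zipf gradient parameters (zipf_alpha).
#' @param noise apply additive perturbation (default `TRUE`).
#' @param seed optional RNG seed.
#' @return list with `profiles` (samples x genomes) and `gradient`
#'   (numeric vector of gradient values).
#' @export
gradient_design <- function(n_samples = 20L, mode = c("bump5", "zipf_alpha"),
                            sigma = 2.5, const_level = 0.5,
                            centers = c(0, 5, 10, 15),
                            alpha0 = 0.275, alpha_step = 0.025, N = 113L,
                            noise = TRUE, seed = NULL) {
  n_samples <- .as_count(n_samples, "n_samples", min = 2L)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "bump5") {
    profiles <- matrix(0, n_samples, 1L + length(centers))
    gradient <- seq_len(n_samples) - 1
    for (i in seq_len(n_samples)) {
      x <- gradient[i]
      raw <- c(const_level, exp(-(x - centers)^2 / (2 * sigma^2)))
      p <- raw / sum(raw)
      profiles[i, ] <- if (noise) perturb_additive(p) else p
    }
  } else {
    gradient <- alpha0 + alpha_step * (seq_len(n_samples) - 1)
    profiles <- matrix(0, n_samples, N)
    for (i in seq_len(n_samples)) {
      p <- zipf_profile(gradient[i], N)
      profiles[i, ] <- if (noise) perturb_additive(p) else p
    }
  }
  list(profiles = profiles, gradient = gradient)
}

#' Community specification for read sampling
#'
#' Bundles a genome pool, per-sample abundance profiles and sequencing
#' parameters; one call to [sample_reads()] per sample draws the reads.
#'
#' @param pool a `genome_pool`.
#' @param profiles samples x genomes matrix of simplex abundance rows.
#' @param depth reads per sample (benchmark presets 1e3, 1e4, 1e5; any
#'   positive integer allowed).
#' @param read_length read length in nt (benchmark preset 200).
#' @param error_rate per-base uniform substitution rate (default 0:
#'   error-free sampling).
#' @param seed base RNG seed; sample `i` uses `seed + i` so samples are
#'   individually reproducible.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(pool, profiles, depth = 10000L,
                           read_length = 200L, error_rate = 0,
                           seed = NULL) {
  stopifnot(inherits(pool, "genome_pool"))
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(pool$ids)) {
    stop("profiles must have one column per genome")
  }
  apply(profiles, 1L, .check_profile)
  depth <- .as_count(depth, "depth")
  read_length <- .as_count(read_length, "read_length")
  stopifnot(error_rate >= 0, error_rate < 1)
  if (read_length > min(pool$lengths)) {
    stop("read_length (", read_length, ") exceeds the shortest genome (",
         min(pool$lengths), ")")
  }
  structure(list(pool = pool, profiles = profiles, depth = depth,
                 read_length = read_length, error_rate = error_rate,
                 seed = seed),
            class = "community_spec")
}

#' Draw one sample's shotgun reads from a community
#'
#' For each of `depth` reads: a genome is chosen with probability equal to
#' its relative abundance, a strand uniformly, and a start position
#' uniformly along the genome; the read is the corresponding substring
#' (reverse-complemented for the minus strand).  Sampling is error-free
#' unless the community's `error_rate` is positive, in which case each
#' base is substituted by a uniformly chosen different base with that
#' probability.  Genome choice is by organism abundance (not
#' length-weighted); pass length-weighted profiles for base-level
#' abundances.
#'
#' @param cs a [community_spec()].
#' @param sample_index which profile row to sample.
#' @return an un-supplemented [read_set()] of `depth` reads named
#'   `sample_<index>`, with the genome of origin of each read in
#'   `attr(, "origin")`.
#' @export
sample_reads <- function(cs, sample_index) {
  stopifnot(inherits(cs, "community_spec"))
  sample_index <- .as_count(sample_index, "sample_index")
  if (sample_index > nrow(cs$profiles)) {
    stop("sample_index exceeds the number of profiles")
  }
  if (!is.null(cs$seed)) set.seed(cs$seed + sample_index)
  prof <- cs$profiles[sample_index, ]
  ng <- length(cs$pool$ids)
  rl <- cs$read_length
  g <- sample.int(ng, cs$depth, replace = TRUE, prob = prof)
  reads <- character(cs$depth)
  for (j in seq_len(ng)) {
    idx <- which(g == j)
    if (!length(idx)) next
    L <- cs$pool$lengths[j]
    starts <- sample.int(L - rl + 1L, length(idx), replace = TRUE)
    reads[idx] <- substring(cs$pool$sequences[j], starts, starts + rl - 1L)
  }
  minus <- runif(cs$depth) < 0.5
  if (any(minus)) {
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  }
  if (cs$error_rate > 0) {
    reads <- .substitute_errors(reads, cs$error_rate)
  }
  rs <- read_set(reads, sample_id = sprintf("sample_%03d", sample_index))
  attr(rs, "origin") <- g
  attr(rs, "strand") <- ifelse(minus, "-", "+")
  rs
}

.substitute_errors <- function(reads, rate) {
  chars <- strsplit(reads, "")
  vapply(chars, function(v) {
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
      for (h in hit) {
        v[h] <- sample(setdiff(.bases, v[h]), 1L)
      }
    }
    paste(v, collapse = "")
  }, character(1L))
}

#' Convenience generator for i.i.d. read sets
#'
#' Draws `n_reads` reads of `read_length` whose bases are i.i.d. from
#' `base_probs`; used as the null "same source" generator in calibration
#' experiments.
#'
#' @param n_reads number of reads.
#' @param read_length read length in nt.
#' @param base_probs base probabilities over A,C,G,T (default uniform).
#' @param seed optional RNG seed.
#' @param sample_id sample label.
#' @return an un-supplemented [read_set()].
#' @export
iid_read_set <- function(n_reads, read_length, base_probs = rep(0.25, 4L),
                         seed = NULL, sample_id = "iid") {
  n_reads <- .as_count(n_reads, "n_reads")
  read_length <- .as_count(read_length, "read_length")
  stopifnot(length(base_probs) == 4L, abs(sum(base_probs) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  big <- paste(sample(.bases, n_reads * read_length, replace = TRUE,
                      prob = base_probs), collapse = "")
  starts <- (seq_len(n_reads) - 1L) * read_length + 1L
  read_set(substring(big, starts, starts + read_length - 1L),
           sample_id = sample_id)
}
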