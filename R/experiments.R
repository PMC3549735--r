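# Benchmark experiments: self-contained simulate -> signature -> measure
# -> evaluate pipelines mirroring the package's calibration claims.  They
# are what the acceptance checks and the acceptance report script run.

#' Self-dissimilarity of a sample under d2S and d2* backgrounds
#'
#' Generates one i.i.d.-uniform read sample and computes `d2S|M0` and
#' `d2*|M0` between the sample and an identical copy of itself for each
#' requested tuple size.  Both are identically 0 for a self-comparison,
#' which this experiment verifies numerically.
#'
#' @param n_reads,read_length sample dimensions.
#' @param k_values tuple sizes to check.
#' @param seed RNG seed.
#' @return data frame with columns `k`, `d2S`, `d2star`.
#' @export
experiment_self <- function(n_reads = 1000L, read_length = 200L,
                            k_values = 2:8, seed = 1L) {
  rs <- supplement_complements(
    iid_read_set(n_reads, read_length, seed = seed, sample_id = "self"))
  bg <- fit_markov(rs, 0L)
  out <- lapply(k_values, function(k) {
    cv <- count_kmers(rs, k)
    data.frame(k = k, d2S = d2s(cv, cv, bg, bg),
               d2star = d2star(cv, cv, bg, bg))
  })
  do.call(rbind, out)
}

#' Independence limit of d2S / d2* between unrelated samples
#'
#' Draws pairs of samples independently from the same i.i.d. nucleotide
#' source and computes `d2S|M0` (and `d2*|M0`) at tuple size `k` for each
#' pair.  For completely independent samples the expectation of both
#' dissimilarities is 0.5, the midpoint of their range.
#'
#' @param n_pairs number of replicate pairs.
#' @param depth reads per sample.
#' @param read_length read length in nt.
#' @param k tuple size.
#' @param seed base seed; pair `i` uses seeds derived from `seed + i`.
#' @return data frame with one row per pair (`d2S`, `d2star`).
#' @export
experiment_independence <- function(n_pairs = 50L, depth = 10000L,
                                    read_length = 200L, k = 5L, seed = 1L) {
  out <- vapply(seq_len(n_pairs), function(i) {
    a <- supplement_complements(
      iid_read_set(depth, read_length, seed = seed + 2L * i,
                   sample_id = "a"))
    b <- supplement_complements(
      iid_read_set(depth, read_length, seed = seed + 2L * i + 1L,
                   sample_id = "b"))
    ca <- count_kmers(a, k)
    cb <- count_kmers(b, k)
    ba <- fit_markov(a, 0L)
    bb <- fit_markov(b, 0L)
    c(d2s(ca, cb, ba, bb), d2star(ca, cb, ba, bb))
  }, numeric(2L))
  data.frame(pair = seq_len(n_pairs), d2S = out[1L, ], d2star = out[2L, ])
}

#' Gradient-recovery experiment (Gaussian-bump design)
#'
#' Full pipeline benchmark of the 20-sample gradient community: 5
#' synthetic order-1 Markov genomes (generated once from `seed`), the
#' Gaussian-bump abundance design with additive half-normal noise,
#' error-free read sampling, a `d2S|M0` dissimilarity matrix at tuple
#' size `k`, PCoA, and `|PCC|` between PC1 and the sample index.
#'
#' @param n_reps number of design + sequencing replicates.
#' @param n_samples samples per replicate.
#' @param depth reads per sample.
#' @param read_length read length in nt.
#' @param k tuple size.
#' @param genome_length synthetic genome length.
#' @param distinctness genome divergence (see [synth_genomes()]).
#' @param seed RNG seed.
#' @return numeric vector of `|PCC|` values, one per replicate.
#' @export
experiment_gradient <- function(n_reps = 10L, n_samples = 20L,
                                depth = 10000L, read_length = 200L, k = 5L,
                                genome_length = 1000000L,
                                distinctness = 0.5, seed = 1L) {
  pool <- synth_genomes(5L, genome_length, distinctness = distinctness,
                        seed = seed)
  spec <- measure_spec("d2S", k, 0L)
  vapply(seq_len(n_reps), function(rep) {
    set.seed(seed + 1000L + rep)
    des <- gradient_design(n_samples, mode = "bump5")
    cs <- community_spec(pool, des$profiles, depth = depth,
                         read_length = read_length)
    samples <- lapply(seq_len(n_samples), function(i) sample_reads(cs, i))
    dm <- dissimilarity_matrix(samples, spec)
    gradient_pcc(pcoa_ord(dm), des$gradient)
  }, numeric(1L))
}

#' Group-recovery experiment (3-group perturbation design)
#'
#' Full pipeline benchmark of the grouped community: 5 synthetic genomes
#' (generated once from `seed`), 3 group centres by multiplicative
#' perturbation of the base profile `(0.05, 0.10, 0.20, 0.25, 0.40)`,
#' `per_group` members per centre by additive half-normal noise,
#' error-free reads, a `d2S|M0` matrix at tuple size `k`, UPGMA, and the
#' Monte Carlo parsimony test.
#'
#' @param n_reps number of replicates.
#' @param per_group samples per group.
#' @param depth reads per sample.
#' @param read_length read length in nt.
#' @param k tuple size.
#' @param genome_length synthetic genome length.
#' @param distinctness genome divergence.
#' @param n_perm permutations for the parsimony test.
#' @param seed RNG seed.
#' @return data frame with one row per replicate (`score`, `p_value`).
#' @export
experiment_groups <- function(n_reps = 20L, per_group = 10L,
                              depth = 10000L, read_length = 200L, k = 5L,
                              genome_length = 1000000L, distinctness = 0.5,
                              n_perm = 1000L, seed = 1L) {
  pool <- synth_genomes(5L, genome_length, distinctness = distinctness,
                        seed = seed)
  spec <- measure_spec("d2S", k, 0L)
  out <- vapply(seq_len(n_reps), function(rep) {
    set.seed(seed + 2000L + rep)
    des <- group_design(centers = 3L, per_group = per_group)
    cs <- community_spec(pool, des$profiles, depth = depth,
                         read_length = read_length)
    samples <- lapply(seq_len(nrow(des$profiles)),
                      function(i) sample_reads(cs, i))
    dm <- dissimilarity_matrix(samples, spec)
    pt <- parsimony_test(upgma(dm), setNames(des$group, rownames(dm$D)),
                         n_perm = n_perm)
    c(pt$score, pt$p_value)
  }, numeric(2L))
  data.frame(replicate = seq_len(n_reps), score = out[1L, ],
             p_value = out[2L, ])
}
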