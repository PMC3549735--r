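---
title: "Methods: alignment-free comparison of metagenomic samples with k-tuple signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free comparison of metagenomic samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-metagenome shotgun sequencing yields, for each community sample, a
bag of short reads from the mixture of genomes present.  Assembly is hard
and reference databases are incomplete, so *alignment-free* comparison is
attractive: summarise each sample by the counts of all $4^k$ nucleotide
words of length $k$ (its *sequence signature*), and define beta-diversity
between samples as a dissimilarity between signatures.  `metasig`
implements the full stack: signature extraction, fourteen dissimilarity
measures, the clustering / ordination evaluation machinery, and community
simulators for benchmarking.

## Signatures

Reads come from either strand with unknown orientation, so each read set
is supplemented with the reverse complement of every read before counting
(`supplement_complements()`).  This makes counts exactly strand-symmetric:
`count(w) = count(revcomp(w))`.  Counting (`count_kmers()`) slides a
window of length $k$ within each read; windows containing a non-ACGT
letter are skipped, and windows never span read boundaries.  The index
order of the $4^k$ cells is lexicographic with $A<C<G<T$, fixed across
the package.  The phrase "a read and its complement" leaves
open whether the complement is reversed; we append the reverse complement
(the sequence physically present on the opposite strand) and expose
`reverse = FALSE` for the unreversed variant -- totals and strand
symmetry are unaffected either way.

## Background models

The centralised measures need the expected count of each word under a
null model of the background sequence.  `fit_markov()` estimates an
order-$r$ Markov chain ($r = 0$ is the i.i.d. model) from the same
supplemented read set used for counting, so the model is
strand-symmetric by construction.  Transition probabilities are ratios
of $(r{+}1)$-window to $r$-window counts; the initial distribution is
the observed $r$-word frequency over *all* windows rather than read
starts, because fragmentation points carry no information.  Expected
word frequencies follow the product formulas (order 0: product of base
probabilities; order $r$: initial probability of the first $r$ letters
times the chain of transitions).  Two numerical notes:

* unseen contexts get probability 0 rather than an error; the measures
  skip zero-expectation words, since sparse high-$k$ signatures make
  zeros routine.  An additive pseudocount is available for degenerate
  inputs but is off by default;
* one subtlety verified by simulation: when an *asymmetric* i.i.d.
  source is fitted at order 1 after supplementation, the transition rows
  do **not** converge to the base probabilities -- supplementation pools
  each transition $x \to y$ with $\mathrm{comp}(y) \to \mathrm{comp}(x)$.
  Only for strand-symmetric sources ($p_A = p_T$, $p_C = p_G$) does the
  naive expectation hold, and the test suite asserts it in that form.

## The fourteen measures

With counts $c_{X,i}$, totals $n_X$, frequencies $f_X = c_X / n_X$ and
background probabilities $p_{X,i}$ (fitted per sample), the roster is:

* **d2** — cosine-type dissimilarity on raw counts,
  $\tfrac12(1 - \sum_i c_{X,i} c_{Y,i} / \lVert c_X\rVert \lVert c_Y\rVert) \in [0, 0.5]$.
* **d2S | M0..M3** — centralised counts
  $\tilde c_{X,i} = c_{X,i} - n_X p_{X,i}$, self-standardised:
  $D_2^S = \sum_i \tilde c_{X,i}\tilde c_{Y,i} / \sqrt{\tilde c_{X,i}^2 + \tilde c_{Y,i}^2}$,
  normalised to $[0,1]$.  Terms with $\tilde c_{X,i} = \tilde c_{Y,i} = 0$
  are skipped ($0/0 := 0$).
* **d2\* | M0..M3** — expectation-standardised:
  $D_2^* = \sum_i \tilde c_{X,i}\tilde c_{Y,i} / \sqrt{n_X p_{X,i} n_Y p_{Y,i}}$.
  Words with zero expectation in either sample are skipped in all three
  sums.  The printed normalisation of this formula in the source
  literature has an apparent typo (both sums over $X$); we use the
  symmetric form, which is the only one for which $d_2^*(X, X) = 0$, a
  property the text itself states.
* **Ma, Eu, Ch** — $\ell_1$, $\ell_2$, $\ell_\infty$ distances on
  frequency vectors.
* **Hao** — the composition-vector measure: with
  $a_{X,i} = f_{X,i}/E[f_{X,i} \mid M_{k-2}] - 1$, the correlation $C$
  between $a_X$ and $a_Y$ is returned as the dissimilarity $(1 - C)/2$.
  The literature presents $C$ itself (a similarity); any monotone
  transform preserves the orderings the method is scored by, and
  $(1-C)/2$ makes the value comparable with the other dissimilarities.
* **Willner** ($k = 2, 3, 4$) — mean absolute difference of
  relative-abundance odds ratios, $4^{-k}\sum_w |o_w(X) - o_w(Y)|$, with
  $\rho^*_{XY} = f_{XY}/(f_X f_Y)$ for dinucleotides, the standard
  $\gamma^*$ for trinucleotides, and for tetranucleotides the *balanced*
  Karlin form of $\tau^*$ (numerator
  $f_{XYZW} f_{XY} f_{XNZ} f_{XNMW} f_{YZ} f_{YNW} f_{ZW}$, denominator
  $f_{XYZ} f_{XYNW} f_{XNZW} f_{YZW} f_X f_Y f_Z f_W$): the printed
  formula is dimensionally unbalanced and omits one gapped term, so we
  restore the balanced form.  Gapped-pattern frequencies ($f_{XNZ}$,
  etc.) are computed over all in-read windows of the full span,
  normalised per span; words with a zero denominator are skipped with a
  warning.

Every formula is verified against an independent naive transcription to
$10^{-12}$, and all measures satisfy symmetry, identity
($m(X, X) = 0$) and their range bounds on randomised inputs.  For two
samples drawn independently from one source, `d2S` and `d2*` concentrate
around 0.5, the midpoint of their range -- the package's calibration
suite checks the mean over 50 deep pairs to within $\pm 0.02$.

## Evaluation machinery

**UPGMA** (`upgma()`) merges the closest pair at height $d/2$ with
size-weighted average-linkage updates; ties break deterministically by
smallest row then column index, so trees are reproducible.  The
implementation is checked against an $O(n^3)$ from-scratch oracle and
`phangorn`.  **Parsimony** (`parsimony_score()`) is Fitch small parsimony
with unordered group labels; a clade-perfect tree with $c$ groups scores
exactly $c - 1$.  The **Monte Carlo test** permutes labels on the fixed
observed tree (group sizes preserved) and reports the plain fraction of
permutations with score $\le$ observed, as the method's description
specifies; an add-one variant is available.  Because the permutation
score is discrete, the plain p-value is super-uniform under the null;
the calibration test therefore applies the Kolmogorov-Smirnov check to
the randomised PIT
$p^* = P(\mathrm{perm} < \mathrm{obs}) + U \cdot P(\mathrm{perm} = \mathrm{obs})$,
which is exactly uniform.  **PCoA** (`pcoa_ord()`) is classical metric
MDS via double-centring and eigendecomposition, keeping positive-
eigenvalue axes; gradient recovery is scored as $|\mathrm{PCC}|$ between
PC1 and the known gradient, the absolute value absorbing eigenvector
sign ambiguity.

## The community simulators

The simulators reproduce the statistical designs used to benchmark the
measures; sequencing presets are depths of 1,000 / 10,000 / 100,000
error-free 200-nt reads per sample (an optional uniform substitution
rate is available, since platform-specific error models were found not
to change the conclusions and are out of scope).

**Abundance designs.**  The grouped (low-complexity) design perturbs the
base profile $(0.05, 0.10, 0.20, 0.25, 0.40)$ multiplicatively into 3
group centres and scatters 30 (or a scaled-down 10) members per centre
with additive half-normal noise $|N(0, p_i)|$ followed by
renormalisation.  One documented conflict: the design's text says the
centre multiplier has "standard deviation equal to the value of the
component", but its own printed centre realisation is a $>10\sigma$
event under that reading and a $<1.3\sigma$ event under a unit-relative
spread multiplier $|N(1,1)|$ (equivalently $p_i \leftarrow |N(p_i, p_i)|$).
We follow the printed realisations: `perturb_multiplicative()` defaults
to `sd = 1`, and the literal variant is available via `sd = p`.  The
high-complexity designs use Zipf rank-abundances
$f(i; \alpha, N) \propto i^{-\alpha}$ with $\alpha = 0.3$, $N = 113$
(group centres are random genome re-orderings of this profile), and the
$\alpha$-gradient walks $\alpha$ from 0.275 to 0.75 by 0.025.  The
5-species gradient design holds one species constant (level 0.5 before
normalisation) and drives the other four with Gaussian bumps of width
$\sigma = 2.5$ centred at sample indexes 0, 5, 10, 15 -- the exact
functional forms of the original four curves are not published, and
overlapping Gaussian bumps are our approximation.

**Synthetic genomes.**  No external genome downloads are required: each
genome is drawn from its own order-1 Markov source
(`synth_genomes()`), and a FASTA loader lets all designs rerun on real
genomes.  What a synthetic stand-in must emulate is that *distinct
species have distinct, mutually uncorrelated signatures*.  Three
constructive constraints implement this:

1. tilts of the transition matrix have zero row sums (stochasticity) and
   zero column sums, pinning every genome's stationary base composition
   at uniform so that any abundance mixture shares a single i.i.d.
   background -- genomes differ in word structure, not base composition;
2. tilts are Chargaff-symmetric ($p(x \to y) = p(\bar y \to \bar x)$, as
   real double-stranded genomes are under Chargaff's second rule), so no
   tilt signal is cancelled by reverse-complement supplementation;
3. within the resulting 6-dimensional tilt space, pools of up to 6
   genomes receive an exactly orthonormal tilt frame, chosen among
   random rotations as the one whose exact 5-mer signature deviations
   are least correlated; larger pools (the 113-genome designs) use
   greedy max-min-correlation selection from surplus candidates.

The `distinctness` parameter (default 0.5) scales tilt magnitude;
transition probabilities then deviate from 0.25 by about 0.1 rms, and
pure-genome samples at depth 10,000 are separated by `d2S|M0` values of
0.3-0.6 against a same-genome noise floor below 0.01.  What the
generator does *not* emulate: GC-content variation between genomes
(deliberately excluded -- a dominant shared composition axis scrambles
gradient embeddings and is largely removed by the M0 background anyway),
repeats, mobile elements, and any higher-order structure beyond order 1.
A green benchmark therefore establishes that the measures recover
abundance-driven structure among compositionally distinct genomes; it
does not certify behaviour on real genomes' richer structure.

## Design choices where the design was open

* *p-value form*: plain fraction $r/n$ (as the method describes), with
  `add_one = TRUE` for the $(r+1)/(n+1)$ variant.
* *PCC sign*: absolute value, since eigenvector signs are arbitrary.
* *Genome choice in read sampling*: organism-level abundance (profile
  probability), not length-weighted; pass length-weighted profiles if
  base-level abundance is wanted.
* *Initial distribution of $M_r$*: overall $r$-word frequencies, not
  read starts.
* *k cap*: 12 by default ($4^k$ memory guard), overridable.
* *Willner gapped frequencies*: marginals of full-span word frequencies
  over all in-read windows, each span normalised by its own window
  count.

## Known limitations

* The $M_r$ domain requires $k \ge r$ (and the measures $k \ge r + 1$),
  which is why high-order backgrounds are undefined at small $k$ -- the
  "NA" cells of the measure-by-$k$ rosters.
* UPGMA tie-breaking is deterministic but convention-specific; other
  implementations may return different (equally valid) tie topologies.
* The simulators' runtime is dominated by the serial Markov genome
  sampler (~1-2 s/Mb); benchmark scales in the tests are chosen to keep
  the whole suite within minutes.
* Real-data analyses (mammalian gut, ocean, human gut) run through the
  same CLI but require user-supplied reads; nothing is downloaded.
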