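---
title: "Methods: k-mer measures of genetic diversity and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer measures of genetic diversity and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerdiv)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the design and
numerical choices made where more than one reasonable option existed.

## 1. Chance k-mer matching and the choice of k

A k-mer shared by two genomes is evidence of shared ancestry only if
sharing is unlikely to arise by chance. We model each genome as an i.i.d.
(multinomial) letter sequence: genome 1 of length $L$ with base
probabilities $p_{A1}, p_{T1}, p_{G1}, p_{C1}$, and a k-mer drawn from a
second composition. The per-position probability that both draws agree is

$$\Sigma_F = p_{A1}p_{A2} + p_{T1}p_{T2} + p_{G1}p_{G2} + p_{C1}p_{C2},$$

and for reverse-complement agreement $\Sigma_R$ swaps the partners (A with
T, G with C). Treating the $L-k+1$ window positions as independent, the
chance of at least one match is $1-(1-\Sigma^k)^{L-k+1}$, or
$1-(1-\Sigma^k)^{L}$ when $k \ll L$. Inverting the approximate form gives
the minimum k for a tolerated match probability $q$:
$k = \lceil \log_{\Sigma}(1-(1-q)^{1/L}) \rceil$, computed separately for
forward and reverse matching; `min_k()` recommends the larger of the two.

**Numerics.** $\Sigma^k$ reaches $10^{-60}$ for the lengths of interest
($L$ up to $10^{10}$, $k$ up to a few hundred), so all probabilities are
assembled in log space with `log1p()`/`expm1()`; `1-(1-q)^{1/L}` is
computed as `-expm1(log1p(-q)/L)` to survive $q = 10^{-6}$ against
$L = 10^{10}$.

**The ceiling convention.** `min_k()` applies the ceiling formula
literally. Published worked examples sometimes quote the k at which the
*rounded* probability reaches the target (e.g. a 19-mer against 3 Gb at
uniform composition gives 1.09%, quoted as 1%); `prob_chance_match()` is
the documented route to recover those rounded headline values, and the
formula itself is not adjusted.

**Validity of the independence approximation.** The closed form treats
overlapping windows as independent. For near-balanced compositions this is
accurate to Monte-Carlo resolution, but composition skew raises the
probability that a k-mer overlaps itself, clustering its occurrences and
pushing the true occurrence probability *below* the closed form. The bias
grows with skew and shrinks with k: at $p_A = p_T = 0.395$ it reaches
$\approx 0.23$ absolute at $k = 6$ ($L = 10^4$) and is still several
Monte-Carlo standard errors at $k = 10$, whereas at GC 48% it is
undetectable at $10^4$ trials for all $k \ge 5$. The approximation is
therefore *conservative* for choosing k — it can only overestimate chance
matching and hence over-size k. The test suite checks two-sided agreement
(within 3 binomial SE at $10^4$ trials) over 15 composition-by-k cells in
the validity regime (uniform and GC 48% at $k = 5..10$, GC 42% at
$k = 8..10$) and one-sided conservativeness for the strongly skewed
composition.

**Monte-Carlo model.** `monte_carlo_match()` draws the genome as
single-stranded text and tests the k-mer (forward tally) and its reverse
complement (reverse tally) against that same text, keeping the two match
modes separate. Genomes are sampled i.i.d. from the composition, matching
the analytic model.

## 2. Bounding nucleotide diversity from k-mer sharing

Under four idealizations — k long enough that every genomic k-mer is
unique, complete k-mer recovery, no sequencing error, SNP-only variation —
each pairwise difference between two haploid genomes creates at most $2k$
k-mers exclusive to one sample: $k$ windows cover the variant site on each
of the two alleles. Generalizing across ploidy $x$, the maximizing
conversion factor is

$$a(x) = \begin{cases} 2k/x^2 & 1 \le x \le 3 \\ k/(2x-1) & x \ge 4,
\end{cases}$$

and summing over all $\binom{n}{2}$ individual pairs and dividing by the
number of haplotype pairs $\binom{nx}{2}$ gives

$$\frac{\sum_{i<j} |K_i \cup K_j| - |K_i \cap K_j|}{a(x)\binom{nx}{2}}
  \le \pi.$$

Equality is achieved by isolated SNPs in haploids (verified
constructively in the tests); clustered SNPs (< k apart), k-mer recurrence
elsewhere in the genome, and shared heterozygosity all make the inequality
strict.

**Units.** $\pi$ appears in two conventions: an average pairwise
*difference count* and a *per-site* value (count / L). The bound is
computed in difference-count units, matching the set sizes on the left;
the neutral expectation $2xN_e\mu/(1+\tfrac43 2xN_e\mu)$ is per site. The
missing per-site normalization between the two conventions is deliberate:
both are exposed (`true_pi()` returns both; `pi_bound_from_kmers()`
documents its units) rather than silently reconciled.

**$\binom{nx}{2}$** uses the total haplotype count regardless of
within-individual homozygosity; with two haplotypes per diploid individual
the within-individual pair is included.

## 3. Counting, thresholding, dissimilarity

Counting slides a width-k window over each sequence; windows containing
non-ACGT characters are skipped (a practical concession to FASTQ reality
with no effect on simulated data). The canonical form of a k-mer is the
lexicographic minimum of the k-mer and its reverse complement under
A < C < G < T — the convention is stated explicitly because introductory
worked examples often ignore canonicalization while read data demand it;
both modes are exposed (`canonical = TRUE/FALSE`). Tables are sparse:
absent k-mers implicitly have count zero, standing in for the full
$4^k$-dimensional vector. For $k \le 32$ counting uses a rolling 2-bit
encoding in C++ (numeric order on codes equals lexicographic order on
strings, so the canonical minimum is a single integer comparison); longer
k falls back to explicit strings.

Sequencing errors mostly create k-mers seen once or twice, so counts below
a threshold $t$ (default 5 in the experiment) are zeroed per sample
*before* any dissimilarity computation or frequency normalization — the
order matters for Bray–Curtis and is fixed here as threshold-then-
normalize.

The three dissimilarities on thresholded tables are Jaccard
($1 - |K_i \cap K_j| / |K_i \cup K_j|$ on key sets), Bray–Curtis
($1 - \sum_b \min(f_{ib}, f_{jb})$ on per-sample relative frequencies,
whose denominator is exactly 2 after normalization), and cosine
($1 - C_i \cdot C_j / \lVert C_i\rVert\,\lVert C_j\rVert$ on raw counts,
which scale invariance makes normalization-free). All three are verified
against dense $4^k$-vector reference implementations for $k \le 6$.

**Population score.** A panel of n individuals yields
$\binom{n}{2}$ pairwise values; the package summarizes them by their
arithmetic mean. How a sampled population should collapse to one number is
genuinely open; the mean is the natural estimator of expected pairwise
dissimilarity and mirrors π's own definition as a mean over pairs.

## 4. Counting-bloom-filter compression

A counting bloom filter is an array of $m$ counters; inserting a k-mer
with count $c$ adds $c$ to each of $h$ hashed positions. Design choices:

* **Double hashing.** $pos_i = (h_a + i\,h_b) \bmod m$ from two seeded
  64-bit string hashes (FNV-1a with a splitmix-style finalizer, $h_b$
  forced odd). This is standard bloom-filter practice emulating $h$
  independent functions; position uniformity is chi-square-tested.
* **Saturating 16-bit counters.** Counters cap at 65535 (saturating, not
  wrapping), matching the compressed array's unsigned 16-bit layout.
  Absent saturation, $\sum \text{counters} = h \sum \text{counts}$ — a
  conservation law the tests enforce.
* **Defaults** $m = 10{,}000$ and $h = 2$. Both configurable; two filters
  are comparable only when $(m, h, \text{seed})$ coincide, because only
  then are hash collisions consistent across samples.

Collisions merge distinct k-mers into shared counters, which can only
*increase* profile overlap: compressed cosine dissimilarity is deflated
relative to raw, monotonically in the compression ratio, while the ranking
of populations is preserved (Spearman ≥ 0.95 at $m = 10^4$ against
collision-free arrays in the tests). Thresholding is applied before
compression, consistent with zeroing error counts before any
dissimilarity computation.

## 5. The synthetic population and read generator

The generator replaces a forward-simulation + tree-sequence + Illumina
read-simulator stack with a minimal neutral model that preserves the one
quantity the analyses need: a panel of haplotypes with *exactly known* π.

* **Genealogy.** A Kingman coalescent for $n \cdot x$ haplotypes (while
  $j$ lineages remain, wait $\mathrm{Exp}(\binom{j}{2})$, merge a random
  pair). No recombination: a single genealogy spans the locus.
* **Mutations.** Poisson with rate $\theta L / 2$ per unit branch length,
  placed on branches proportionally to length, one mutation per site
  (infinite sites; distinct positions are drawn without replacement, the
  exact equivalent of rejection-resampling multiple hits). Derived alleles
  are uniform over the three non-ancestral bases. The expected per-site π
  of the sample equals θ; the generator refuses θ ≥ 0.75, the per-site
  diversity ceiling. At small θ the infinite-sites expectation matches the
  saturating finite-sites form $\theta/(1+\tfrac43\theta)$ to within 15%,
  which the tests verify across 100 seeds.
* **Reference.** A random i.i.d. sequence with configurable GC fraction
  (default 0.36 in the experiment, a plant-like nuclear value), standing
  in for a real chromosome segment. Repetitive structure, motif content
  and local composition heterogeneity of real genomes are deliberately
  absent — so passing tests demonstrate correctness of the measures under
  the model, not robustness to genomic repeat structure.
* **Reads.** Uniform random start positions, alternating equally among the
  individual's $x$ haplotypes, random strand;
  $\mathrm{round}(\text{coverage} \cdot x L / \text{read length})$ reads
  of fixed length (default 150 bp); independent per-base substitutions at
  the stated error rate (default 0.1%), no indels, fixed quality symbol at
  the Phred equivalent of the error rate. Uniform starts undersample the
  outermost read-length of the sequence, so the terminal k-mers of a
  haplotype are recovered only rarely — an edge property shared with real
  shotgun data that the tests account for by asserting exact recovery of
  the *interior* k-mer set.

Everything is reproducible: each function takes a seed, saves and restores
the caller's RNG state, and the experiment driver derives all per-stage
seeds from one master seed, giving byte-identical outputs end to end.

## 6. The scaling experiment

`run_experiment()` sweeps diversity levels and measures how population
scores track true π. The default study conditions, chosen once:

| parameter | value | why |
|---|---|---|
| diversity grid | 40 θ levels, 30 in (0, 0.025], 10 in (0.03, 0.1] | spans per-site π 0–0.1 with density in the regression range |
| locus, sample | L = 20 kb, 10 diploids | desk-scale panel of 20 chromosomes |
| reads | 150 bp, 30× (10× for robustness checks), 0.1% error | short-read regime where thresholding matters |
| counting | canonical, k ∈ {10, 30}, threshold 5 | short k for high diversity, long k for precision |
| CBF | m = 10⁴, h = 2, shared seed | small-array compression setting |

One record is one population (score = mean over the 45 pairs), regressed
by OLS on exact per-site π restricted to π ≤ 0.025 — above that the scores
plateau (most k-mers already differ between samples), which
`plateau_check()` quantifies as the ratio of high-range to low-range
slopes. Failures in a single (replicate, θ, k) cell are logged and
skipped so long sweeps survive degenerate draws.

At these problem sizes the Bray–Curtis (k = 30) regression attains
R² ≈ 0.94–0.97 depending on the master seed, and the bloom-filter cosine
(k = 10) R² tracks the raw-count cosine to within ≈ 0.01–0.03. Two
scale-dependent effects keep the scaled-down R² below what larger loci
give: count-profile noise shrinks with locus length, and — more
importantly — without recombination the whole locus shares one genealogy,
so tree-shape variance adds panel-level scatter that a recombining locus
would average away. Recombination is out of scope for the generator by
design; the consequence for R² is a known limitation, not an artifact.

## 7. Known limitations

* SNP-only variation: no indels, structural variants, selection or
  demography in the generator; the bound's assumptions exclude them too.
* The i.i.d. reference underestimates chance k-mer sharing in repetitive
  real genomes; the chance-match theory is the tool to reason about that,
  but the simulations do not exercise it.
* The independence approximation behind the closed-form chance-match
  probability biases high for strongly skewed compositions at small k
  (section 1); its inversion remains conservative for choosing k.
* Bray–Curtis and cosine scores have a finite-coverage noise floor (a
  monomorphic panel does not score exactly zero), so intercepts of
  score-vs-π regressions are positive.
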