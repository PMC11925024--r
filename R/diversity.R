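#' Ploidy conversion factor between pairwise differences and exclusive k-mers
#'
#' The number of k-mers exclusive to one of two individuals is bounded by a
#' ploidy-dependent multiple of the number of pairwise haplotype
#' differences. The maximizing factor is `2k / x^2` for ploidy `x` in 1..3
#' (two individuals homozygous for different alleles: 2k exclusive k-mers
#' per `x^2` pairwise differences) and `k / (2x - 1)` for `x >= 4` (a SNP on
#' a single haplotype: k exclusive k-mers per `2x - 1` differences).
#'
#' @param x Ploidy level (integer `>= 1`).
#' @param k k-mer length.
#' @return The conversion factor `a(x)`.
#' @examples
#' ploidy_factor(1, 21)  # 42 = 2k, the haploid case
#' ploidy_factor(2, 10)  # 5
#' @export
ploidy_factor <- function(x, k) {
  stopifnot(is.numeric(x), length(x) == 1L, is.numeric(k), k >= 1)
  if (x < 1) stop("ploidy must be >= 1")
  if (x <= 3) 2 * k / x^2 else k / (2 * x - 1)
}

kmer_key_set <- function(x) {
  if (inherits(x, "kmer_count_table")) return(names(x$counts))
  if (is.character(x)) return(unique(x))
  if (is.numeric(x) && !is.null(names(x))) return(names(x))
  stop("expected a kmer_count_table, a character vector of k-mers, ",
       "or a named count vector")
}

#' Number of k-mers exclusive to one of two samples
#'
#' `|K_i union K_j| - |K_i intersect K_j|`: the size of the symmetric
#' difference of two k-mer sets.
#'
#' @param set_i,set_j k-mer sets: character vectors, named count vectors, or
#'   [kmer_count_table] objects (keys are used).
#' @return A non-negative integer count.
#' @export
symmetric_difference_count <- function(set_i, set_j) {
  a <- kmer_key_set(set_i)
  b <- kmer_key_set(set_j)
  kl <- unique(nchar(c(a, b)))
  if (length(kl) > 1L) stop("k-mers of mixed lengths in the two sets")
  length(union(a, b)) - length(intersect(a, b))
}

#' Upper-bound nucleotide diversity from sample-exclusive k-mers
#'
#' Under error-free, complete k-mer sets and SNP-only variation, the mean
#' number of k-mers exclusive to one member of a sample pair, divided by the
#' ploidy conversion factor `a(x)` and the number of haplotype pairs
#' `choose(n*x, 2)`, is bounded above by the sample's nucleotide diversity
#' expressed as an average pairwise difference count.
#'
#' @param samples A list of `n >= 2` k-mer sets (one per individual), in any
#'   form accepted by [symmetric_difference_count()].
#' @param x Ploidy level.
#' @param k k-mer length used to build the sets.
#' @return The bound value, in average-pairwise-difference units.
#' @seealso [ploidy_factor()], [true_pi()]
#' @export
pi_bound_from_kmers <- function(samples, x, k) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of at least 2 samples")
  n <- length(samples)
  total <- 0
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      total <- total + symmetric_difference_count(samples[[i]], samples[[j]])
  total / (ploidy_factor(x, k) * choose(n * x, 2))
}

#' Expected nucleotide diversity in a neutral population at equilibrium
#'
#' Returns `2*x*Ne*mu / (1 + (4/3) * 2*x*Ne*mu)` for effective population
#' size `Ne`, per-base per-generation mutation probability `mu` and ploidy
#' `x`. The denominator saturates the expectation at the theoretical
#' maximum per-site diversity of 0.75.
#'
#' @param Ne Effective population size (`> 0`).
#' @param mu Mutation probability per base per generation, in `[0, 1)`.
#' @param x Ploidy level.
#' @return Expected per-site diversity, strictly less than 0.75.
#' @examples
#' expected_pi_neutral(1e4, 1e-8, x = 2)
#' @export
expected_pi_neutral <- function(Ne, mu, x = 2) {
  stopifnot(Ne > 0, mu >= 0, mu < 1, x >= 1)
  m <- 2 * x * Ne * mu
  m / (1 + 4 / 3 * m)
}

#' Nei's nucleotide diversity from allele frequencies
#'
#' Per locus computes `(1 - sum(p_i^2)) * n / (n - 1)` from the allele
#' frequency vector, then reports the per-locus values together with their
#' mean and sum.
#'
#' @param allele_freqs A list of per-locus allele frequency vectors (each
#'   summing to 1), or a single frequency vector.
#' @param n Number of sequences in the sample (`>= 2`).
#' @return A list with `per_locus`, `mean` and `total`.
#' @export
nei_pi <- function(allele_freqs, n) {
  stopifnot(n >= 2)
  if (!is.list(allele_freqs)) allele_freqs <- list(allele_freqs)
  per_locus <- vapply(allele_freqs, function(p) {
    if (abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies at a locus must sum to 1")
    (1 - sum(p^2)) * n / (n - 1)
  }, numeric(1))
  list(per_locus = per_locus, mean = mean(per_locus), total = sum(per_locus))
}

#' Watterson's diversity estimator
#'
#' `S` segregating sites scaled by the harmonic number `sum(1/a)` for
#' `a = 1 .. n-1`.
#'
#' @param S Number of segregating sites (`>= 0`).
#' @param n Number of sequences in the sample (`>= 2`).
#' @return The estimate `theta_w`.
#' @export
watterson_theta <- function(S, n) {
  stopifnot(S >= 0)
  if (n < 2) stop("n must be >= 2")
  S / sum(1 / seq_len(n - 1))
}

#' Exact nucleotide diversity of an aligned haplotype panel
#'
#' Mean Hamming distance over all pairs of haplotypes, reported both as a
#' difference count and per site.
#'
#' @param haplotypes Character vector of `>= 2` equal-length sequences.
#' @return A list with `total` (mean pairwise difference count), `per_site`
#'   (`total / L`), and `n_pairs`.
#' @export
true_pi <- function(haplotypes) {
  stopifnot(is.character(haplotypes), length(haplotypes) >= 2)
  if (length(unique(nchar(haplotypes))) != 1L)
    stop("haplotypes must have equal length")
  d <- cpp_pairwise_hamming(haplotypes)
  m <- length(haplotypes)
  total <- sum(d[upper.tri(d)]) / choose(m, 2)
  list(total = total, per_site = unname(total / nchar(haplotypes[[1]])),
       n_pairs = choose(m, 2))
}

#' Write a pairwise difference matrix as TSV
#'
#' @param haplotypes Character vector of equal-length sequences.
#' @param path Output file path.
#' @param ids Optional sequence identifiers (default `hap1..hapm`).
#' @return `path`, invisibly.
#' @export
write_difference_matrix <- function(haplotypes, path, ids = NULL) {
  d <- cpp_pairwise_hamming(haplotypes)
  if (is.null(ids)) ids <- paste0("hap", seq_along(haplotypes))
  dimnames(d) <- list(ids, ids)
  utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
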