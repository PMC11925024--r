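#' K-mer dissimilarity between two samples
#'
#' The three standard k-mer dissimilarity statistics on a pair of count
#' tables with matching k:
#'
#' * `kmer_jaccard()` uses presence/absence only:
#'   `1 - |intersection| / |union|` of the key sets.
#' * `kmer_bray_curtis()` works on relative frequencies: after normalizing
#'   each table to sum to 1, `1 - sum(pmin(f_i, f_j))` over the union of
#'   keys (the textbook `1 - 2 sum(min) / (sum_i + sum_j)` with both sums
#'   equal to 1). Absent k-mers contribute 0.
#' * `kmer_cosine()` is one minus the cosine of the angle between the two
#'   count vectors over the union of keys; it is invariant to uniform
#'   rescaling of either sample.
#'
#' @param table_i,table_j [kmer_count_table] objects with the same `k`.
#' @return A dissimilarity in `[0, 1]`; 0 for identical profiles, 1 for
#'   disjoint key sets.
#' @examples
#' a <- count_kmers("ATGCATGC", k = 3)
#' b <- count_kmers("ATGCATGA", k = 3)
#' kmer_jaccard(a, b)
#' kmer_bray_curtis(a, b)
#' kmer_cosine(a, b)
#' @export
kmer_jaccard <- function(table_i, table_j) {
  check_pair(table_i, table_j)
  ki <- names(table_i$counts)
  kj <- names(table_j$counts)
  n_union <- length(union(ki, kj))
  if (n_union == 0) stop("Jaccard dissimilarity undefined for two empty tables")
  1 - length(intersect(ki, kj)) / n_union
}

#' @rdname kmer_jaccard
#' @export
kmer_bray_curtis <- function(table_i, table_j) {
  check_pair(table_i, table_j)
  if (!length(table_i$counts) || !length(table_j$counts))
    stop("Bray-Curtis dissimilarity undefined for an empty table")
  fi <- to_frequencies(table_i)
  fj <- to_frequencies(table_j)
  shared <- intersect(names(fi), names(fj))
  1 - sum(pmin(fi[shared], fj[shared]))
}

#' @rdname kmer_jaccard
#' @export
kmer_cosine <- function(table_i, table_j) {
  check_pair(table_i, table_j)
  ci <- as.numeric(table_i$counts)
  cj <- as.numeric(table_j$counts)
  ni <- sqrt(sum(ci^2))
  nj <- sqrt(sum(cj^2))
  if (ni == 0 || nj == 0)
    stop("cosine dissimilarity undefined for a zero count vector")
  idx <- match(names(table_i$counts), names(table_j$counts))
  hit <- !is.na(idx)
  dot <- sum(ci[hit] * cj[idx[hit]])
  # guard rounding: the ratio can exceed 1 by ~1e-16 for identical tables
  max(0, 1 - dot / (ni * nj))
}

check_pair <- function(table_i, table_j) {
  stopifnot(inherits(table_i, "kmer_count_table"),
            inherits(table_j, "kmer_count_table"))
  if (table_i$k != table_j$k)
    stop("count tables have different k (", table_i$k, " vs ", table_j$k, ")")
  invisible(TRUE)
}

metric_fun <- function(metric) {
  switch(metric,
         jaccard = kmer_jaccard,
         braycurtis = ,
         bray_curtis = kmer_bray_curtis,
         cosine = kmer_cosine,
         stop("unknown metric '", metric,
              "'; use jaccard, braycurtis or cosine"))
}

#' Pairwise k-mer dissimilarity matrix for a set of samples
#'
#' Applies the count threshold to every sample, then the chosen metric to
#' all sample pairs.
#'
#' @param samples List of [kmer_count_table] objects (named or not).
#' @param metric `"jaccard"`, `"braycurtis"` or `"cosine"`.
#' @param threshold Minimum k-mer count retained per sample before the
#'   metric is computed (see [apply_threshold()]).
#' @return A symmetric matrix of class `kmer_dissim` with zero diagonal and
#'   attributes `metric`, `k` and `threshold`.
#' @export
kmer_dissimilarity_matrix <- function(samples, metric = "braycurtis",
                                      threshold = 0) {
  stopifnot(is.list(samples), length(samples) >= 2)
  fun <- metric_fun(metric)
  samples <- lapply(samples, apply_threshold, t = threshold)
  n <- length(samples)
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      v <- fun(samples[[i]], samples[[j]])
      d[i, j] <- v
      d[j, i] <- v
    }
  structure(d, class = c("kmer_dissim", "matrix"),
            metric = metric, k = samples[[1]]$k, threshold = threshold)
}

#' Population-level summary of a dissimilarity matrix
#'
#' The arithmetic mean of the `choose(n, 2)` off-diagonal entries: the
#' estimator of the expected pairwise dissimilarity in the population,
#' mirroring how nucleotide diversity averages over sequence pairs.
#'
#' @param d A square symmetric dissimilarity matrix (e.g. from
#'   [kmer_dissimilarity_matrix()]).
#' @return A single numeric score.
#' @export
population_score <- function(d) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  mean(d[upper.tri(d)])
}

#' Write a dissimilarity matrix as square TSV
#'
#' @param d A `kmer_dissim` (or plain) matrix.
#' @param path Output path; sample IDs form the header row and first column.
#' @return `path`, invisibly.
#' @export
write_dissimilarity_matrix <- function(d, path) {
  utils::write.table(unclass(d), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
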