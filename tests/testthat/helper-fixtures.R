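# shared fixtures built in code

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# plant a substitution at 1-based position `pos`
mutate_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
  paste(chars, collapse = "")
}

# random sparse count table over ACGT k-mers
random_table <- function(n_kmers, k, max_count = 50, canonical = FALSE) {
  kmers <- unique(replicate(n_kmers, random_dna(k)))
  if (canonical) kmers <- unique(canonicalize(kmers))
  counts <- sample.int(max_count, length(kmers), replace = TRUE)
  names(counts) <- kmers
  kmer_count_table(counts, k = k, canonical = canonical)
}

# all 4^k k-mer strings, in lexicographic order
all_kmers <- function(k) {
  g <- do.call(expand.grid,
               rev(replicate(k, c("A", "C", "G", "T"), simplify = FALSE)))
  sort(apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = ""))
}

# dense-vector reference implementations of the three metrics
dense_vector <- function(table, keys) {
  v <- numeric(length(keys))
  names(v) <- keys
  v[names(table$counts)] <- table$counts
  v
}

dense_jaccard <- function(ti, tj, keys) {
  a <- dense_vector(ti, keys) > 0
  b <- dense_vector(tj, keys) > 0
  1 - sum(a & b) / sum(a | b)
}

dense_bray_curtis <- function(ti, tj, keys) {
  a <- dense_vector(ti, keys)
  b <- dense_vector(tj, keys)
  a <- a / sum(a)
  b <- b / sum(b)
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

dense_cosine <- function(ti, tj, keys) {
  a <- dense_vector(ti, keys)
  b <- dense_vector(tj, keys)
  1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# haploid pair with SNPs at given positions; returns sequences + k-mer sets
snp_pair <- function(L, positions, k) {
  s1 <- random_dna(L)
  s2 <- s1
  for (p in positions) s2 <- mutate_at(s2, p)
  list(seqs = c(s1, s2),
       sets = list(count_kmers(s1, k), count_kmers(s2, k)))
}
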