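#' Counting bloom filter compression of a k-mer count table
#'
#' A counting bloom filter (CBF) compresses a sparse k-mer count vector
#' into a fixed-size array of `m` saturating 16-bit counters. Each k-mer is
#' mapped to `h` positions by double hashing
#' (`pos_i = (h_a + i * h_b) mod m`), and each position is incremented by
#' the k-mer's count, saturating at 65535. Distinct k-mers may collide, but
#' when the same `(m, h, seed)` parameters are shared across samples the
#' collisions are consistent, so compressed arrays remain comparable.
#'
#' @param table A [kmer_count_table].
#' @param m Array length (default 10000 elements).
#' @param h Number of hash functions (default 2).
#' @param seed Hashing seed shared across all filters to be compared.
#' @return An object of class `counting_bloom_filter` with fields
#'   `counters` (integer vector of length `m`), `m`, `h`, `seed`, and the
#'   source table's `k`.
#' @export
cbf_compress <- function(table, m = 10000L, h = 2L, seed = 1L) {
  stopifnot(inherits(table, "kmer_count_table"), m >= 1, h >= 1)
  counters <- cpp_cbf_compress(names(table$counts),
                               as.integer(table$counts),
                               as.integer(m), as.integer(h),
                               as.integer(seed))
  structure(list(counters = counters, m = as.integer(m), h = as.integer(h),
                 seed = as.integer(seed), k = table$k),
            class = "counting_bloom_filter")
}

#' @export
print.counting_bloom_filter <- function(x, ...) {
  cat(sprintf("counting bloom filter: m = %d, h = %d, seed = %d, load = %s\n",
              x$m, x$h, x$seed, format(sum(x$counters), big.mark = ",")))
  invisible(x)
}

#' Hash positions of k-mers in a counting bloom filter
#'
#' The `h` double-hashed array positions each k-mer maps to, for given
#' filter parameters. Deterministic in `(kmer, m, h, seed)`.
#'
#' @param kmers Character vector of k-mers.
#' @inheritParams cbf_compress
#' @return An integer matrix with one row per k-mer and `h` columns of
#'   0-based positions in `[0, m)`.
#' @export
cbf_hash_positions <- function(kmers, m = 10000L, h = 2L, seed = 1L) {
  stopifnot(m >= 1, h >= 1)
  cpp_cbf_positions(as.character(kmers), as.integer(m), as.integer(h),
                    as.integer(seed))
}

#' Cosine dissimilarity between two counting bloom filters
#'
#' Applies the cosine dissimilarity directly to the two counter arrays.
#' The filters must share `(m, h, seed)`; otherwise their collision
#' patterns differ and the arrays are incomparable.
#'
#' @param f1,f2 `counting_bloom_filter` objects.
#' @return A dissimilarity in `[0, 1]`.
#' @export
cbf_cosine <- function(f1, f2) {
  stopifnot(inherits(f1, "counting_bloom_filter"),
            inherits(f2, "counting_bloom_filter"))
  if (f1$m != f2$m || f1$h != f2$h || f1$seed != f2$seed)
    stop("filters are incomparable: (m, h, seed) must match")
  a <- as.numeric(f1$counters)
  b <- as.numeric(f2$counters)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine dissimilarity undefined for an all-zero filter")
  max(0, 1 - sum(a * b) / (na * nb))
}

CBF_MAGIC <- 0x43424631L  # "CBF1"

#' Serialize a counting bloom filter
#'
#' Binary layout: a 16-byte header of four little-endian 32-bit fields
#' (magic, m, h, seed) followed by `m` little-endian unsigned 16-bit
#' counters. `cbf_write_tsv()` offers a plain-text debug export
#' (`position<TAB>count` for non-zero counters).
#'
#' @param filter A `counting_bloom_filter`.
#' @param path File path.
#' @return `write_cbf()`/`cbf_write_tsv()` return `path` invisibly;
#'   `read_cbf()` returns a `counting_bloom_filter` (its `k` is unknown
#'   after round-trip and set to `NA`).
#' @export
write_cbf <- function(filter, path) {
  stopifnot(inherits(filter, "counting_bloom_filter"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(CBF_MAGIC, filter$m, filter$h, filter$seed), con,
           size = 4L, endian = "little")
  writeBin(as.integer(filter$counters), con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_cbf
#' @export
read_cbf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
  if (length(hdr) != 4L || hdr[1] != CBF_MAGIC)
    stop("not a counting-bloom-filter file: ", path)
  m <- hdr[2]
  counters <- readBin(con, "integer", n = m, size = 2L, signed = FALSE,
                      endian = "little")
  if (length(counters) != m) stop("truncated filter file: ", path)
  structure(list(counters = counters, m = m, h = hdr[3], seed = hdr[4],
                 k = NA_integer_),
            class = "counting_bloom_filter")
}

#' @rdname write_cbf
#' @export
cbf_write_tsv <- function(filter, path) {
  stopifnot(inherits(filter, "counting_bloom_filter"))
  nz <- which(filter$counters > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#m=%d h=%d seed=%d", filter$m, filter$h, filter$seed),
             con)
  if (length(nz))
    writeLines(paste(nz - 1L, filter$counters[nz], sep = "\t"), con)
  invisible(path)
}
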