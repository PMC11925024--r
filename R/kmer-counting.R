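#' Construct a k-mer count table
#'
#' A `kmer_count_table` is a sparse map from k-mer string to positive count
#' for one sample, plus the k-mer length and whether counting was canonical
#' (k-mer and reverse complement identified). Absent k-mers implicitly have
#' count 0, so the table stands in for the full 4^k-dimensional count
#' vector.
#'
#' @param counts Named integer vector (names are k-mers, values `>= 1`).
#' @param k k-mer length.
#' @param canonical Logical; were counts collapsed over reverse complements?
#' @return An object of class `kmer_count_table`.
#' @export
kmer_count_table <- function(counts, k, canonical = TRUE) {
  counts <- counts[counts >= 1]
  if (length(counts) && any(nchar(names(counts)) != k))
    stop("all k-mer keys must have length k = ", k)
  structure(list(counts = counts, k = as.integer(k),
                 canonical = isTRUE(canonical)),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("k-mer count table: k = %d, %s, %d distinct k-mers, %s instances\n",
              x$k, if (x$canonical) "canonical" else "stranded",
              length(x$counts), format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement (alphabet order A < C < G < T). K-mers
#' containing ambiguous characters return `NA`, signalling the caller to
#' skip them.
#'
#' @param kmers Character vector of k-mers over `{A, C, G, T}`.
#' @return Character vector of canonical k-mers (`NA` where ambiguous).
#' @examples
#' canonicalize(c("AT", "TG"))  # "AT", "CA"
#' @export
canonicalize <- function(kmers) {
  cpp_canonicalize(as.character(kmers))
}

#' Count k-mers in a set of sequences
#'
#' Slides a width-`k` window over each sequence and counts occurrences,
#' optionally collapsing each window onto its canonical form. Windows
#' containing non-ACGT characters are skipped.
#'
#' @param sequences Character vector of sequences (or an
#'   `XStringSet`, which is coerced).
#' @param k k-mer length (`>= 1`).
#' @param canonical Collapse reverse complements together (default `TRUE`).
#' @return A [kmer_count_table].
#' @examples
#' count_kmers("ATGCA", k = 2, canonical = FALSE)$counts
#' count_kmers("ATGCA", k = 2)$counts  # TG and CA merge as CA
#' @export
count_kmers <- function(sequences, k, canonical = TRUE) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  stopifnot(k >= 1)
  counts <- cpp_count_kmers(as.character(sequences), as.integer(k), canonical)
  kmer_count_table(counts, k = k, canonical = canonical)
}

#' Remove low-count k-mers
#'
#' Retains exactly the entries with count `>= t`, emulating the practice of
#' zeroing error-dominated low-multiplicity k-mers before any dissimilarity
#' computation.
#'
#' @param table A [kmer_count_table].
#' @param t Minimum count to retain (`>= 0`).
#' @return A filtered [kmer_count_table].
#' @export
apply_threshold <- function(table, t) {
  stopifnot(inherits(table, "kmer_count_table"), t >= 0)
  kmer_count_table(table$counts[table$counts >= t], k = table$k,
                   canonical = table$canonical)
}

#' Relative k-mer frequencies
#'
#' Divides each count by the total so the frequencies sum to 1.
#'
#' @param table A non-empty [kmer_count_table].
#' @return A named numeric vector of frequencies.
#' @export
to_frequencies <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (!length(table$counts))
    stop("cannot normalize an empty count table")
  table$counts / sum(table$counts)
}

#' K-mer frequency spectrum
#'
#' Histogram of count multiplicities: how many distinct k-mers were seen
#' exactly 1, 2, ... times. The low-multiplicity end of the spectrum is
#' dominated by sequencing errors in read data.
#'
#' @param table A [kmer_count_table].
#' @return A data frame with columns `multiplicity` and `n_kmers`.
#' @export
kmer_spectrum <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (!length(table$counts))
    return(data.frame(multiplicity = integer(), n_kmers = integer()))
  tab <- table(table$counts)
  data.frame(multiplicity = as.integer(names(tab)),
             n_kmers = as.integer(tab))
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character sequences; the format is inferred from the file extension
#' (`.fastq`/`.fq`, optionally gzipped, read as FASTQ; everything else as
#' FASTA).
#'
#' @param path Input file path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Serialize a k-mer count table to / from two-column TSV
#'
#' Writes `kmer<TAB>count` rows below a header line of the form
#' `#k=<k> canonical=<0|1>`.
#'
#' @param table A [kmer_count_table].
#' @param path File path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a [kmer_count_table].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d canonical=%d", table$k,
                     as.integer(table$canonical)), con)
  if (length(table$counts))
    writeLines(paste(names(table$counts), table$counts, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#k=", lines[1]))
    stop("missing '#k=<k> canonical=<0|1>' header in ", path)
  hdr <- regmatches(lines[1],
                    regexec("^#k=(\\d+) canonical=([01])$", lines[1]))[[1]]
  if (length(hdr) != 3) stop("malformed count-table header in ", path)
  k <- as.integer(hdr[2])
  canonical <- hdr[3] == "1"
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body))
    return(kmer_count_table(stats::setNames(integer(), character()), k,
                            canonical))
  parts <- strsplit(body, "\t", fixed = TRUE)
  counts <- as.integer(vapply(parts, `[[`, character(1), 2))
  names(counts) <- vapply(parts, `[[`, character(1), 1)
  kmer_count_table(counts, k = k, canonical = canonical)
}
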