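#' Simulate a neutral population sample with known true diversity
#'
#' Generates a random reference of length `L` with the requested GC
#' fraction, draws a Kingman coalescent genealogy for the `n * x` sampled
#' haplotypes, drops infinite-sites mutations on its branches at per-site
#' rate `theta` (so the expected per-site diversity of the sample is
#' `theta`), and assigns each derived allele uniformly among the three
#' non-ancestral bases. Because every mutation hits a distinct site, the
#' exact nucleotide diversity of the returned haplotypes is known in closed
#' form and is reported alongside them.
#'
#' @param L Sequence length in bases.
#' @param n Number of individuals sampled (`>= 2`).
#' @param x Ploidy level (haplotypes per individual; default 2).
#' @param theta Scaled mutation parameter per site; the expected per-site
#'   pairwise diversity of the sample. Must be below 0.75, the per-site
#'   diversity ceiling.
#' @param gc GC fraction of the random reference, in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return An object of class `haplotype_panel`: a list with the
#'   `reference`, the `haplotypes` (character vector of length `n * x`),
#'   `individual` assignments, segregating site `positions`, the exact
#'   diversity `pi_total` (mean pairwise difference count) and
#'   `pi_per_site`, and the simulation parameters.
#' @examples
#' p <- simulate_panel(L = 1000, n = 4, x = 2, theta = 0.01, seed = 7)
#' p$pi_per_site
#' @export
simulate_panel <- function(L, n, x = 2L, theta, gc = 0.5, seed = 1L) {
  stopifnot(L >= 1, n >= 2, x >= 1, theta >= 0, gc >= 0, gc <= 1)
  if (theta >= 0.75)
    stop("theta = ", theta, " implies per-site diversity above the 0.75 ceiling")
  seed <- as.integer(seed)  # force before snapshotting the RNG state
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ref_chars <- sample(c("A", "T", "G", "C"), L, replace = TRUE,
                      prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  m <- n * x

  # Kingman coalescent: while j lineages remain, wait Exp(choose(j, 2)) and
  # merge a random pair.  Each branch records the tips beneath it and its
  # length; the root lineage carries no branch.
  tips <- lapply(seq_len(m), identity)
  birth <- numeric(m)
  branch_tips <- vector("list", 2L * (m - 1L))
  branch_len <- numeric(2L * (m - 1L))
  nb <- 0L
  t_now <- 0
  while (length(tips) > 1L) {
    j <- length(tips)
    t_now <- t_now + stats::rexp(1, rate = choose(j, 2))
    pair <- sample.int(j, 2L)
    for (idx in pair) {
      nb <- nb + 1L
      branch_tips[[nb]] <- tips[[idx]]
      branch_len[nb] <- t_now - birth[idx]
    }
    merged <- c(tips[[pair[1]]], tips[[pair[2]]])
    keep <- setdiff(seq_len(j), pair)
    tips <- c(tips[keep], list(merged))
    birth <- c(birth[keep], t_now)
  }
  branch_tips <- branch_tips[seq_len(nb)]
  branch_len <- branch_len[seq_len(nb)]

  # Mutations: Poisson with rate (theta * L / 2) per unit branch length,
  # placed on branches proportionally to length; infinite sites means each
  # mutation occupies a distinct position.
  total_len <- sum(branch_len)
  n_mut <- stats::rpois(1, theta * L / 2 * total_len)
  if (n_mut > L)
    stop("theta too large for infinite-sites placement: ", n_mut,
         " mutations for ", L, " sites")
  hap_sites <- vector("list", m)
  positions <- integer(0)
  allele_count <- integer(0)
  derived <- character(0)
  if (n_mut > 0) {
    on_branch <- sample.int(nb, n_mut, replace = TRUE, prob = branch_len)
    positions <- sort(sample.int(L, n_mut))
    bases <- c("A", "C", "G", "T")
    derived <- vapply(positions, function(p)
      sample(setdiff(bases, ref_chars[p]), 1L), character(1))
    allele_count <- lengths(branch_tips)[on_branch]
    for (i in seq_len(n_mut))
      for (tip in branch_tips[[on_branch[i]]])
        hap_sites[[tip]] <- c(hap_sites[[tip]], i)
  }

  haplotypes <- vapply(seq_len(m), function(tip) {
    chars <- ref_chars
    s <- hap_sites[[tip]]
    if (length(s)) chars[positions[s]] <- derived[s]
    paste(chars, collapse = "")
  }, character(1))
  names(haplotypes) <- paste0("ind", rep(seq_len(n), each = x),
                              "_hap", rep(seq_len(x), n))

  pi_total <- if (n_mut > 0)
    sum(allele_count * (m - allele_count)) / choose(m, 2) else 0

  structure(list(reference = paste(ref_chars, collapse = ""),
                 haplotypes = haplotypes,
                 individual = rep(seq_len(n), each = x),
                 positions = positions,
                 pi_total = pi_total,
                 pi_per_site = pi_total / L,
                 L = as.integer(L), n = as.integer(n), x = as.integer(x),
                 theta = theta, gc = gc, seed = as.integer(seed)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(paste0("haplotype panel: %d individuals x ploidy %d, L = %d, ",
                     "%d segregating sites, pi = %.4g/site\n"),
              x$n, x$x, x$L, length(x$positions), x$pi_per_site))
  invisible(x)
}

#' Simulate short reads from one individual of a panel
#'
#' Draws reads of fixed length with uniformly random start positions,
#' alternating equally among the individual's `x` haplotypes and choosing a
#' random strand per read, then applies independent per-base substitution
#' errors at the stated rate. The read count is
#' `round(coverage * x * L / read_length)`, so the expected sequencing depth
#' over the individual's diploid (or polyploid) genome equals `coverage`.
#'
#' @param panel A [simulate_panel()] result.
#' @param individual Individual index in `1..n`.
#' @param coverage Target depth per haploid genome copy set (`> 0`).
#' @param read_length Read length in bases (`<= L`).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return An object of class `read_set`: `sequences`, `qualities` (fixed
#'   symbol at the Phred equivalent of `error_rate`), `individual`,
#'   `coverage`, `read_length`, `error_rate`, `seed`.
#' @export
simulate_reads <- function(panel, individual, coverage, read_length = 150L,
                           error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"),
            individual >= 1, individual <= panel$n,
            error_rate >= 0, error_rate < 1)
  if (coverage <= 0) stop("coverage must be positive")
  if (read_length > panel$L) stop("read_length must not exceed L")
  seed <- as.integer(seed)  # force before snapshotting the RNG state
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  haps <- panel$haplotypes[panel$individual == individual]
  x <- length(haps)
  n_reads <- round(coverage * x * panel$L / read_length)
  if (n_reads < 1) stop("coverage too low: zero reads requested")

  hap_idx <- rep_len(seq_len(x), n_reads)
  starts <- sample.int(panel$L - read_length + 1L, n_reads, replace = TRUE)
  revstrand <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)
  seqs <- substring(haps[hap_idx], starts, starts + read_length - 1L)
  if (any(revstrand))
    seqs[revstrand] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[revstrand])))

  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_length, error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(n_err > 0)) {
      chars <- strsplit(seqs[i], "")[[1]]
      pos <- sample.int(read_length, n_err[i])
      for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      seqs[i] <- paste(chars, collapse = "")
    }
  }

  q <- if (error_rate > 0) min(40L, max(2L, round(-10 * log10(error_rate))))
       else 40L
  qual <- strrep(rawToChar(as.raw(q + 33L)), read_length)
  names(seqs) <- sprintf("ind%d_read%d", individual, seq_len(n_reads))
  structure(list(sequences = seqs,
                 qualities = rep(qual, n_reads),
                 individual = as.integer(individual),
                 coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: individual %d, %d x %d bp reads, error %.3g\n",
              x$individual, length(x$sequences), x$read_length,
              x$error_rate))
  invisible(x)
}

#' Write a haplotype panel to FASTA plus a metadata sidecar
#'
#' Writes `haplotypes.fasta`, `reference.fasta` and `panel.tsv` (segregating
#' site positions, exact diversity, seed and parameters) into `dir`.
#'
#' @param panel A `haplotype_panel`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- try({
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(panel$haplotypes),
      file.path(dir, "haplotypes.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(reference = panel$reference)),
      file.path(dir, "reference.fasta"))
    meta <- data.frame(
      field = c("L", "n", "ploidy", "theta", "gc", "seed",
                "pi_total", "pi_per_site", "positions"),
      value = c(panel$L, panel$n, panel$x, panel$theta, panel$gc, panel$seed,
                panel$pi_total, panel$pi_per_site,
                paste(panel$positions, collapse = ",")))
    utils::write.table(meta, file.path(dir, "panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed writing panel to ", dir, ": ", attr(ok, "condition")$message)
  invisible(dir)
}

#' Write a read set to FASTQ
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  ok <- try({
    seqs <- Biostrings::DNAStringSet(reads$sequences)
    quals <- Biostrings::BStringSet(reads$qualities)
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = quals)
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed writing reads to ", path, ": ",
         attr(ok, "condition")$message)
  invisible(path)
}
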