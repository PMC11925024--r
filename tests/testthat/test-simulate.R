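test_that("panels report their exact diversity and respect the seed", {
  p <- simulate_panel(L = 2000, n = 5, x = 2, theta = 0.01, seed = 101)
  expect_length(p$haplotypes, 10)
  expect_true(all(nchar(p$haplotypes) == 2000))
  expect_equal(table(p$individual), table(rep(1:5, each = 2)))
  # reported diversity equals the brute-force pairwise mean
  expect_equal(p$pi_per_site, true_pi(p$haplotypes)$per_site)
  expect_equal(p$pi_total, true_pi(p$haplotypes)$total)
  # determinism
  q <- simulate_panel(L = 2000, n = 5, x = 2, theta = 0.01, seed = 101)
  expect_identical(p$haplotypes, q$haplotypes)
  expect_false(identical(
    p$haplotypes,
    simulate_panel(L = 2000, n = 5, x = 2, theta = 0.01, seed = 102)$haplotypes))

  mono <- simulate_panel(L = 1000, n = 4, x = 2, theta = 0, seed = 1)
  expect_equal(length(unique(mono$haplotypes)), 1L)
  expect_equal(mono$pi_total, 0)
  expect_error(simulate_panel(L = 1000, n = 4, x = 2, theta = 0.8, seed = 1),
               "0.75")
})

test_that("mean realized diversity rises with theta and tracks its target", {
  set.seed(61)
  mean_pi <- vapply(c(1e-3, 1e-2, 5e-2), function(th)
    mean(vapply(1:20, function(i)
      simulate_panel(L = 1500, n = 5, x = 2, theta = th,
                     seed = sample.int(1e6, 1))$pi_per_site,
      numeric(1))), numeric(1))
  expect_true(all(diff(mean_pi) > 0))

  # per-site expectation approximately theta for small theta
  set.seed(62)
  th <- 0.01
  pis <- vapply(1:100, function(i)
    simulate_panel(L = 2000, n = 5, x = 2, theta = th,
                   seed = sample.int(1e6, 1))$pi_per_site, numeric(1))
  expect_lt(abs(mean(pis) / th - 1), 0.15)
})

test_that("reference GC fraction is honored", {
  p <- simulate_panel(L = 20000, n = 2, x = 1, theta = 0, gc = 0.2,
                      seed = 9)
  chars <- strsplit(p$reference, "")[[1]]
  expect_lt(abs(mean(chars %in% c("G", "C")) - 0.2), 0.02)
})

test_that("reads tile the haplotypes at the requested depth and error rate", {
  p <- simulate_panel(L = 3000, n = 3, x = 2, theta = 0.01, seed = 71)
  r <- simulate_reads(p, individual = 2, coverage = 10, read_length = 100,
                      error_rate = 0, seed = 5)
  # coverage within 5% of the request
  total_bases <- sum(nchar(r$sequences))
  expect_lt(abs(total_bases / (2 * 3000) / 10 - 1), 0.05)
  # error-free reads are exact substrings of a haplotype or its revcomp
  haps <- p$haplotypes[p$individual == 2]
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(haps)))
  hit <- vapply(r$sequences, function(s)
    any(vapply(c(haps, rcs), function(h) grepl(s, h, fixed = TRUE),
               logical(1))), logical(1))
  expect_true(all(hit))
  # determinism
  r2 <- simulate_reads(p, individual = 2, coverage = 10, read_length = 100,
                       error_rate = 0, seed = 5)
  expect_identical(r$sequences, r2$sequences)
  expect_error(simulate_reads(p, 1, coverage = 0), "positive")
  expect_error(simulate_reads(p, 1, coverage = 5, read_length = 4000),
               "exceed L")
})

test_that("the observed substitution rate matches the requested error rate", {
  p <- simulate_panel(L = 3000, n = 2, x = 1, theta = 0, seed = 81)
  # same seed, with and without errors: starts and strands coincide, so
  # paired mismatches are exactly the injected substitutions
  clean <- simulate_reads(p, 1, coverage = 40, read_length = 150,
                          error_rate = 0, seed = 6)
  noisy <- simulate_reads(p, 1, coverage = 40, read_length = 150,
                          error_rate = 0.01, seed = 6)
  mm <- sum(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                   clean$sequences, noisy$sequences))
  n_bases <- sum(nchar(noisy$sequences))
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(mm / n_bases - 0.01), 3 * se)
})

test_that("error-free deep reads recover the interior haplotype k-mer set", {
  # uniform read starts undersample the outermost read-length of sequence,
  # so exact recovery is asserted for the interior; read k-mers are always
  # a subset of the haplotypes' k-mers
  set.seed(91)
  rl <- 150L
  hits <- vapply(1:20, function(i) {
    p <- simulate_panel(L = 1200, n = 2, x = 2, theta = 0.005,
                        seed = sample.int(1e6, 1))
    haps <- p$haplotypes[p$individual == 1]
    r <- simulate_reads(p, 1, coverage = 10, read_length = rl,
                        error_rate = 0, seed = sample.int(1e6, 1))
    truth <- names(count_kmers(haps, 21)$counts)
    interior <- names(count_kmers(substring(haps, rl, p$L - rl + 1),
                                  21)$counts)
    got <- names(count_kmers(r$sequences, 21)$counts)
    all(got %in% truth) && all(interior %in% got)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("panels and reads round-trip through FASTA/FASTQ", {
  p <- simulate_panel(L = 500, n = 3, x = 2, theta = 0.01, seed = 33)
  dir <- withr::local_tempdir()
  write_panel(p, dir)
  haps <- read_sequences(file.path(dir, "haplotypes.fasta"))
  expect_identical(unname(haps), unname(p$haplotypes))
  expect_length(haps, p$n * p$x)
  ref <- read_sequences(file.path(dir, "reference.fasta"))
  expect_identical(unname(ref), p$reference)
  meta <- read.delim(file.path(dir, "panel.tsv"))
  expect_equal(as.numeric(meta$value[meta$field == "pi_per_site"]),
               p$pi_per_site)

  r <- simulate_reads(p, 1, coverage = 5, read_length = 80, seed = 2)
  fq <- file.path(dir, "reads.fastq")
  write_reads(r, fq)
  back <- read_sequences(fq)
  expect_identical(unname(back), unname(r$sequences))
  # FASTQ records pair equal-length sequence and quality strings
  lines <- readLines(fq)
  expect_equal(nchar(lines[seq(2, length(lines), by = 4)]),
               nchar(lines[seq(4, length(lines), by = 4)]))
  # byte-identical regeneration under the same seed
  fq2 <- file.path(dir, "reads2.fastq")
  write_reads(simulate_reads(p, 1, coverage = 5, read_length = 80, seed = 2),
              fq2)
  expect_identical(readLines(fq), readLines(fq2))
})
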