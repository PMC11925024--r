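#' Base composition of a genome model
#'
#' A base composition holds the per-base sampling probabilities of a
#' multinomial (i.i.d.) genome model: each base of a random genome is drawn
#' independently with probabilities `pA`, `pT`, `pG`, `pC`.
#'
#' @param pA,pT,pG,pC Probabilities of drawing A, T, G and C. Must be
#'   non-negative and sum to 1 (within `1e-12`).
#' @return An object of class `base_composition` (a named numeric vector).
#' @examples
#' base_composition()                  # uniform
#' base_composition(0.29, 0.29, 0.21, 0.21)  # GC content 42%
#' @export
base_composition <- function(pA = 0.25, pT = 0.25, pG = 0.25, pC = 0.25) {
  p <- c(A = pA, T = pT, G = pG, C = pC)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("base probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop("base probabilities must sum to 1 (got ", sum(p), ")")
  structure(p, class = "base_composition")
}

as_base_composition <- function(x) {
  if (inherits(x, "base_composition")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(base_composition(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("cannot interpret input as a base composition")
}

#' Per-position match probabilities between two genome models
#'
#' `sigma_forward()` is the probability that one base drawn from each of two
#' compositions is the same letter; `sigma_reverse()` is the probability that
#' the two draws are reverse complements (A-T or G-C pairing). These are the
#' per-position building blocks of the chance-match probability for k-mers.
#'
#' @param comp1,comp2 Base compositions (see [base_composition()]).
#'   `comp2` defaults to `comp1`.
#' @return A probability in `[0, 1]`.
#' @examples
#' sigma_forward(base_composition())           # 0.25
#' sigma_reverse(base_composition(1, 0, 0, 0)) # 0: A never pairs with A
#' @export
sigma_forward <- function(comp1, comp2 = comp1) {
  p <- as_base_composition(comp1)
  q <- as_base_composition(comp2)
  unname(p["A"] * q["A"] + p["T"] * q["T"] + p["G"] * q["G"] + p["C"] * q["C"])
}

#' @rdname sigma_forward
#' @export
sigma_reverse <- function(comp1, comp2 = comp1) {
  p <- as_base_composition(comp1)
  q <- as_base_composition(comp2)
  unname(p["A"] * q["T"] + p["T"] * q["A"] + p["G"] * q["C"] + p["C"] * q["G"])
}

#' Probability that a random k-mer occurs in a random genome by chance
#'
#' For a k-mer drawn from `comp2` and a genome of length `L` drawn from
#' `comp1`, returns the probability of finding the k-mer at least once in the
#' genome by chance alone. The exact form uses all `L - k + 1` window
#' positions; the approximate form (valid for `k << L`) uses `L` positions.
#' Forward matching tests letter-identical occurrence; reverse matching tests
#' occurrence as a reverse complement. Computation is carried out in log
#' space so that genome lengths up to 1e10 and k up to a few hundred do not
#' underflow.
#'
#' @param comp1 Base composition of the genome searched.
#' @param comp2 Base composition the k-mer is drawn from (defaults to
#'   `comp1`).
#' @param L Genome length in bases (`>= 1`).
#' @param k k-mer length in bases (`>= 1`; `k <= L` required in exact mode).
#' @param strand `"forward"` or `"reverse"`.
#' @param exact If `TRUE` use the exact `L - k + 1` window count, otherwise
#'   the `k << L` approximation.
#' @return A probability in `[0, 1]`.
#' @examples
#' # a 19-mer against a 3 Gb uniform-composition genome: about 1%
#' prob_chance_match(base_composition(), L = 3e9, k = 19, exact = FALSE)
#' @export
prob_chance_match <- function(comp1, comp2 = comp1, L, k,
                              strand = c("forward", "reverse"),
                              exact = TRUE) {
  strand <- match.arg(strand)
  stopifnot(is.numeric(L), length(L) == 1L, L >= 1,
            is.numeric(k), length(k) == 1L, k >= 1)
  if (exact && k > L) stop("exact mode requires k <= L")
  sigma <- if (strand == "forward") sigma_forward(comp1, comp2)
           else sigma_reverse(comp1, comp2)
  n_windows <- if (exact) L - k + 1 else L
  if (sigma >= 1) return(1)     # degenerate composition: every draw matches
  if (sigma <= 0) return(0)
  # 1 - (1 - sigma^k)^n, with sigma^k as exp(k log sigma) in log space
  log_sigma_k <- k * log(sigma)
  -expm1(n_windows * log1p(-exp(log_sigma_k)))
}

#' Minimum k-mer length for a tolerated chance-match probability
#'
#' Inverts the approximate chance-match probability to find the smallest
#' integer k-mer length at which the probability of a chance match between a
#' random k-mer and a genome of length `L` is at most `q`, separately for
#' forward matches (`k_forward`) and reverse-complement matches
#' (`k_reverse`), via the ceiling formula
#' `ceil(log_sigma(1 - (1 - q)^(1/L)))`. The recommended choice of k is the
#' larger of the two.
#'
#' @inheritParams prob_chance_match
#' @param q Tolerated chance-match probability, in `(0, 1)`.
#' @return A list with components `k_forward`, `k_reverse` and `k` (their
#'   maximum).
#' @examples
#' # GC content 21%, 10 Gb genome, q = 1e-6: k = 34
#' min_k(base_composition(0.395, 0.395, 0.105, 0.105), L = 1e10, q = 1e-6)$k
#' @export
min_k <- function(comp1, comp2 = comp1, L, q) {
  stopifnot(is.numeric(L), length(L) == 1L, L >= 1,
            is.numeric(q), length(q) == 1L, q > 0, q < 1)
  sF <- sigma_forward(comp1, comp2)
  sR <- sigma_reverse(comp1, comp2)
  if (sF >= 1 || sR >= 1)
    stop("degenerate composition: no finite k achieves the target probability")
  # 1 - (1-q)^(1/L), computed stably for tiny q / huge L
  target <- -expm1(log1p(-q) / L)
  k_one <- function(sigma) {
    if (sigma <= 0) return(1L)
    max(1L, as.integer(ceiling(log(target) / log(sigma))))
  }
  kF <- k_one(sF)
  kR <- k_one(sR)
  list(k_forward = kF, k_reverse = kR, k = max(kF, kR))
}

#' Monte-Carlo verification of the chance-match probability
#'
#' Repeatedly draws a random genome of length `L` and a random k-mer from
#' the same base composition, and tallies how often the k-mer occurs in the
#' genome text (forward) and how often its reverse complement does
#' (reverse). The empirical hit fractions estimate the exact chance-match
#' probabilities and can be compared against [prob_chance_match()].
#'
#' @param comp Base composition for both the genome and the k-mer.
#' @param k k-mer length (`k <= L`).
#' @param L Genome length.
#' @param trials Number of Monte-Carlo trials (`>= 1`).
#' @param seed Integer seed; the same seed reproduces identical tallies.
#' @return A list with `forward` and `reverse` empirical probabilities,
#'   `hits` (the raw tallies) and `trials`.
#' @export
monte_carlo_match <- function(comp, k, L, trials, seed = 1L) {
  comp <- as_base_composition(comp)
  stopifnot(trials >= 1)
  if (k > L) stop("k must not exceed L")
  seed <- as.integer(seed)  # force before snapshotting the RNG state
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- cpp_monte_carlo_match(as.numeric(comp[c("A", "C", "G", "T")]),
                                as.integer(k), as.integer(L),
                                as.integer(trials))
  list(forward = unname(hits["forward"]) / trials,
       reverse = unname(hits["reverse"]) / trials,
       hits = hits, trials = trials)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
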