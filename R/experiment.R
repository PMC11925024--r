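#' Configuration for a diversity-scaling experiment
#'
#' Bundles every knob of the score-versus-diversity experiment: the
#' diversity sweep (a grid of per-site `theta` values, each simulated
#' `replicates` times), the population (`L`, `n`, `ploidy`, `gc`), the
#' sequencing model (`coverage` levels, `read_length`, `error_rate`), the
#' k-mer analysis (`k` values, count `threshold`, `metrics`), the optional
#' counting-bloom-filter pipeline for the cosine metric, and the master
#' `seed` from which all per-stage seeds are derived.
#'
#' @param theta_grid Numeric vector of per-site scaled mutation rates.
#' @param replicates Panels simulated per theta value.
#' @param L Sequence length per panel.
#' @param n Individuals per panel.
#' @param ploidy Haplotypes per individual.
#' @param gc Reference GC fraction.
#' @param k Integer vector of k-mer lengths.
#' @param coverage Numeric vector of sequencing depths.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution error probability.
#' @param threshold Minimum k-mer count retained per sample.
#' @param metrics Character vector among `"jaccard"`, `"braycurtis"`,
#'   `"cosine"`.
#' @param cbf `NULL` to disable, or a list with elements `m`, `h`, `seed`;
#'   when enabled, every cosine computation is repeated on compressed
#'   filters and recorded with `pipeline = "cbf"`.
#' @param pi_max Default upper diversity limit for regressions.
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(theta_grid, replicates = 1L, L = 20000L,
                              n = 10L, ploidy = 2L, gc = 0.36,
                              k = c(10L, 30L), coverage = 30,
                              read_length = 150L, error_rate = 0.001,
                              threshold = 5L, metrics = c("braycurtis",
                                                          "cosine"),
                              cbf = list(m = 10000L, h = 2L, seed = 77L),
                              pi_max = 0.025, seed = 1L) {
  stopifnot(length(theta_grid) >= 1, all(theta_grid >= 0),
            replicates >= 1, length(k) >= 1, length(coverage) >= 1,
            length(metrics) >= 1, pi_max > 0, pi_max < 0.75)
  metrics <- match.arg(metrics, c("jaccard", "braycurtis", "cosine"),
                       several.ok = TRUE)
  if (!is.null(cbf))
    stopifnot(is.list(cbf), all(c("m", "h", "seed") %in% names(cbf)))
  structure(list(theta_grid = theta_grid, replicates = as.integer(replicates),
                 L = as.integer(L), n = as.integer(n),
                 ploidy = as.integer(ploidy), gc = gc,
                 k = as.integer(k), coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, threshold = as.integer(threshold),
                 metrics = metrics, cbf = cbf, pi_max = pi_max,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' Files ending in `.yaml`/`.yml` are parsed with the yaml package (if
#' installed); everything else is parsed as JSON. Fields missing from the
#' file fall back to [experiment_config()] defaults.
#'
#' @param path Config file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(experiment_config, cfg)
}

#' Run the score-versus-diversity experiment
#'
#' For every replicate of every theta value: simulate a neutral panel,
#' simulate reads for each individual at each coverage, count canonical
#' k-mers at each k, apply the count threshold, and record the population
#' mean of every requested dissimilarity metric (and, when the CBF pipeline
#' is enabled, of cosine dissimilarity on the compressed arrays). All
#' per-stage seeds derive deterministically from the master seed, so
#' identical configs yield identical record tables. A failure in one
#' (replicate, theta, k) cell is logged as a warning and skipped.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-panel progress with timings.
#' @return A data frame with one row per (panel, k, coverage, metric,
#'   pipeline): columns `replicate`, `theta`, `pi_total`, `pi_per_site`,
#'   `k`, `coverage`, `metric`, `pipeline`, `score`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  n_panels <- config$replicates * length(config$theta_grid)
  seeds_per_panel <- 1L + config$n * length(config$coverage)
  old <- .Random.seed_get()
  set.seed(config$seed)
  seed_pool <- matrix(sample.int(.Machine$integer.max,
                                 n_panels * seeds_per_panel),
                      nrow = seeds_per_panel)
  .Random.seed_restore(old)

  rows <- list()
  panel_id <- 0L
  for (rep_i in seq_len(config$replicates)) {
    for (theta in config$theta_grid) {
      panel_id <- panel_id + 1L
      t0 <- proc.time()[["elapsed"]]
      seeds <- seed_pool[, panel_id]
      res <- tryCatch(
        run_panel(config, rep_i, theta, seeds),
        error = function(e) {
          warning(sprintf("panel failed (replicate %d, theta %.4g): %s",
                          rep_i, theta, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(res)) rows[[panel_id]] <- res
      if (verbose)
        message(sprintf("panel %d/%d (theta %.4g) done in %.1fs",
                        panel_id, n_panels, theta,
                        proc.time()[["elapsed"]] - t0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_panel <- function(config, rep_i, theta, seeds) {
  panel <- simulate_panel(config$L, config$n, config$ploidy, theta,
                          gc = config$gc, seed = seeds[1])
  rows <- list()
  si <- 1L
  for (cov in config$coverage) {
    read_sets <- vector("list", config$n)
    for (ind in seq_len(config$n)) {
      si <- si + 1L
      read_sets[[ind]] <- simulate_reads(panel, ind, cov,
                                         config$read_length,
                                         config$error_rate,
                                         seed = seeds[si])
    }
    for (k in config$k) {
      res <- tryCatch({
        tables <- lapply(read_sets, function(r)
          apply_threshold(count_kmers(r$sequences, k), config$threshold))
        scores <- panel_scores(tables, config)
        data.frame(replicate = rep_i, theta = theta,
                   pi_total = panel$pi_total,
                   pi_per_site = panel$pi_per_site,
                   k = k, coverage = cov,
                   metric = scores$metric, pipeline = scores$pipeline,
                   score = scores$score)
      }, error = function(e) {
        warning(sprintf("cell failed (replicate %d, theta %.4g, k %d): %s",
                        rep_i, theta, k, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

# population scores (already-thresholded tables) for each metric + pipeline
panel_scores <- function(tables, config) {
  metric <- character(0); pipeline <- character(0); score <- numeric(0)
  for (m in config$metrics) {
    d <- kmer_dissimilarity_matrix(tables, metric = m, threshold = 0)
    metric <- c(metric, m); pipeline <- c(pipeline, "raw")
    score <- c(score, population_score(d))
    if (m == "cosine" && !is.null(config$cbf)) {
      filters <- lapply(tables, cbf_compress, m = config$cbf$m,
                        h = config$cbf$h, seed = config$cbf$seed)
      n <- length(filters)
      vals <- numeric(0)
      for (i in seq_len(n - 1L))
        for (j in seq.int(i + 1L, n))
          vals <- c(vals, cbf_cosine(filters[[i]], filters[[j]]))
      metric <- c(metric, "cosine"); pipeline <- c(pipeline, "cbf")
      score <- c(score, mean(vals))
    }
  }
  list(metric = metric, pipeline = pipeline, score = score)
}

filter_records <- function(records, metric = NULL, k = NULL,
                           coverage = NULL, pipeline = NULL,
                           pi_max = Inf, pi_min = -Inf) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(metric)) keep <- keep & records$metric == metric
  if (!is.null(k)) keep <- keep & records$k == k
  if (!is.null(coverage)) keep <- keep & records$coverage == coverage
  if (!is.null(pipeline)) keep <- keep & records$pipeline == pipeline
  keep <- keep & records$pi_per_site <= pi_max & records$pi_per_site > pi_min
  records[keep, , drop = FALSE]
}

#' Regress population scores on true per-site diversity
#'
#' Ordinary least squares of `score` on `pi_per_site` over the records
#' matching the given metric/k/coverage/pipeline, restricted to
#' `pi_per_site <= pi_max`.
#'
#' @param records Record table from [run_experiment()].
#' @param metric,k,coverage,pipeline Optional filters (`NULL` = no filter).
#' @param pi_max Upper per-site diversity limit for the fit.
#' @return A list of class `score_regression`: `slope`, `intercept`,
#'   `r_squared`, `n`, `pi_range`.
#' @export
regress_scores <- function(records, metric = NULL, k = NULL,
                           coverage = NULL, pipeline = "raw",
                           pi_max = 0.025) {
  sub <- filter_records(records, metric, k, coverage, pipeline,
                        pi_max = pi_max)
  if (nrow(sub) < 3) stop("fewer than 3 records in the regression range")
  if (stats::var(sub$score) == 0)
    stop("scores have zero variance; R-squared is undefined")
  fit <- stats::lm(score ~ pi_per_site, data = sub)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(sub),
                 pi_range = range(sub$pi_per_site)),
            class = "score_regression")
}

#' @export
print.score_regression <- function(x, ...) {
  cat(sprintf("score ~ pi: slope %.4g, intercept %.4g, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Saturation check: slope ratio between high- and low-diversity ranges
#'
#' Fits OLS slopes of score on per-site diversity separately on a low and a
#' high diversity range and returns their ratio. A ratio well below 1
#' indicates the score has plateaued at high diversity.
#'
#' @inheritParams regress_scores
#' @param low_range,high_range Two-element `(min, max]` per-site diversity
#'   intervals.
#' @return A list with `ratio`, `slope_low`, `slope_high` and point counts.
#' @export
plateau_check <- function(records, metric = NULL, k = NULL, coverage = NULL,
                          pipeline = "raw", low_range = c(0, 0.02),
                          high_range = c(0.04, Inf)) {
  slope_in <- function(rng) {
    sub <- filter_records(records, metric, k, coverage, pipeline,
                          pi_max = rng[2], pi_min = rng[1])
    if (nrow(sub) < 3)
      stop("fewer than 3 records in diversity range (",
           rng[1], ", ", rng[2], "]")
    fit <- stats::lm(score ~ pi_per_site, data = sub)
    list(slope = unname(stats::coef(fit)[2]), n = nrow(sub))
  }
  lo <- slope_in(low_range)
  hi <- slope_in(high_range)
  list(ratio = hi$slope / lo$slope, slope_low = lo$slope,
       slope_high = hi$slope, n_low = lo$n, n_high = hi$n)
}

#' Compare the raw-count and bloom-filter cosine pipelines
#'
#' Regresses raw-cosine and CBF-cosine population scores against true
#' per-site diversity over the same records, and reports both fits, the
#' difference in R-squared, and the Spearman rank correlation between the
#' paired scores.
#'
#' @inheritParams regress_scores
#' @return A list with `raw` and `cbf` (`score_regression` objects),
#'   `r_squared_diff` and `spearman`.
#' @export
compare_raw_cbf <- function(records, k = NULL, coverage = NULL,
                            pi_max = 0.025) {
  raw <- filter_records(records, "cosine", k, coverage, "raw")
  cbf <- filter_records(records, "cosine", k, coverage, "cbf")
  if (!nrow(raw) || !nrow(cbf))
    stop("need both raw and cbf cosine records")
  key <- function(d) paste(d$replicate, d$theta, d$k, d$coverage)
  idx <- match(key(raw), key(cbf))
  if (anyNA(idx)) stop("raw and cbf records do not pair up")
  list(raw = regress_scores(records, "cosine", k, coverage, "raw", pi_max),
       cbf = regress_scores(records, "cosine", k, coverage, "cbf", pi_max),
       r_squared_diff = abs(
         regress_scores(records, "cosine", k, coverage, "raw",
                        pi_max)$r_squared -
         regress_scores(records, "cosine", k, coverage, "cbf",
                        pi_max)$r_squared),
       spearman = stats::cor(raw$score, cbf$score[idx],
                             method = "spearman"))
}

#' Write experiment records or regression summaries as TSV
#'
#' @param x A record data frame or a list of `score_regression` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(names(x), function(nm) {
      r <- x[[nm]]
      data.frame(name = nm, slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, n = r$n,
                 pi_min = r$pi_range[1], pi_max = r$pi_range[2])
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
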