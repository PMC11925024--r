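small_config <- function(...) {
  experiment_config(theta_grid = c(0.002, 0.01, 0.03),
                    replicates = 1L, L = 1500L, n = 4L, ploidy = 2L,
                    k = c(10L, 15L), coverage = c(10), read_length = 100L,
                    error_rate = 0.001, threshold = 2L,
                    metrics = c("braycurtis", "cosine"),
                    cbf = list(m = 5000L, h = 2L, seed = 77L),
                    seed = 123L, ...)
}

test_that("the sweep emits one record per (panel, k, coverage, metric, pipeline)", {
  cfg <- small_config()
  rec <- run_experiment(cfg)
  # 3 thetas x 2 k x 1 coverage x (braycurtis, cosine raw, cosine cbf)
  expect_equal(nrow(rec), 3 * 2 * 1 * 3)
  expect_setequal(unique(rec$metric), c("braycurtis", "cosine"))
  expect_setequal(unique(rec$pipeline), c("raw", "cbf"))
  expect_true(all(rec$score >= 0 & rec$score <= 1))
  expect_true(all(rec$pi_per_site >= 0))
  # same config and master seed: identical tables end to end
  expect_identical(run_experiment(cfg), rec)
})

test_that("a monomorphic sweep leaves only the finite-coverage noise floor", {
  cfg <- experiment_config(theta_grid = 0, L = 1500L, n = 3L, ploidy = 2L,
                           k = 15L, coverage = 30, error_rate = 0.001,
                           threshold = 5L,
                           metrics = c("jaccard", "braycurtis", "cosine"),
                           cbf = NULL, seed = 5L)
  rec <- run_experiment(cfg)
  expect_true(all(rec$pi_per_site == 0))
  # identical genomes: presence/absence nearly coincides, count profiles
  # retain small read-sampling noise
  expect_lt(rec$score[rec$metric == "jaccard"], 0.02)
  expect_lt(rec$score[rec$metric == "cosine"], 0.05)
  expect_lt(rec$score[rec$metric == "braycurtis"], 0.15)
})

test_that("scores rise with diversity on average", {
  cfg <- experiment_config(theta_grid = c(0.001, 0.02), replicates = 10L,
                           L = 1200L, n = 4L, ploidy = 2L, k = 15L,
                           coverage = 10, threshold = 2L,
                           metrics = "braycurtis", cbf = NULL, seed = 42L)
  rec <- run_experiment(cfg)
  lo <- mean(rec$score[rec$theta == 0.001])
  hi <- mean(rec$score[rec$theta == 0.02])
  expect_gt(hi, lo)
})

test_that("regression output matches direct least-squares sums", {
  # exactly collinear records give R^2 = 1 and the planted coefficients
  rec <- data.frame(replicate = 1, theta = 1:10, pi_total = 1:10,
                    pi_per_site = (1:10) / 1000, k = 10L, coverage = 30,
                    metric = "cosine", pipeline = "raw",
                    score = 0.03 + 5 * (1:10) / 1000)
  fit <- suppressWarnings(regress_scores(rec, pi_max = 1))  # exact fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 5)
  expect_equal(fit$intercept, 0.03)

  set.seed(71)
  rec$score <- rec$score + rnorm(10, 0, 0.01)
  fit <- regress_scores(rec, pi_max = 1)
  x <- rec$pi_per_site; y <- rec$score
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(fit$slope, beta)
  expect_equal(fit$r_squared, 1 - ss_res / ss_tot)

  expect_error(regress_scores(rec[1:2, ], pi_max = 1), "fewer than 3")
  rec$score <- 0.5
  expect_error(regress_scores(rec, pi_max = 1), "zero variance")
})

test_that("the plateau ratio separates saturating from linear score curves", {
  pi <- seq(0.001, 0.1, length.out = 40)
  base <- data.frame(replicate = 1, theta = pi, pi_total = pi * 1000,
                     pi_per_site = pi, k = 30L, coverage = 30,
                     metric = "braycurtis", pipeline = "raw", score = NA)
  saturating <- transform(base, score = pmin(10 * pi_per_site, 0.25))
  lin <- transform(base, score = 3 * pi_per_site)
  expect_lt(plateau_check(saturating)$ratio, 0.05)
  expect_equal(plateau_check(lin)$ratio, 1, tolerance = 1e-8)
  expect_error(plateau_check(lin, high_range = c(0.5, 1)), "fewer than 3")
})

test_that("raw and CBF cosine pipelines are compared on paired records", {
  cfg <- small_config()
  rec <- run_experiment(cfg)
  # identical records passed as both pipelines: zero R^2 difference
  fake <- rec[rec$pipeline == "raw" & rec$metric == "cosine" &
                rec$k == 10, ]
  fake2 <- transform(fake, pipeline = "cbf")
  cmp <- compare_raw_cbf(rbind(fake, fake2), k = 10, pi_max = 1)
  expect_equal(cmp$r_squared_diff, 0)
  expect_equal(cmp$spearman, 1)
  expect_error(compare_raw_cbf(fake, k = 10), "both raw and cbf")
})

test_that("configs round-trip through JSON and records through TSV", {
  cfg <- small_config()
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(theta_grid = cfg$theta_grid, L = cfg$L,
                            n = cfg$n, ploidy = cfg$ploidy,
                            k = cfg$k, coverage = cfg$coverage,
                            threshold = cfg$threshold,
                            metrics = cfg$metrics, seed = cfg$seed),
                       js, auto_unbox = FALSE, digits = NA)
  cfg2 <- read_experiment_config(js)
  expect_equal(cfg2$theta_grid, cfg$theta_grid)
  expect_equal(cfg2$k, cfg$k)
  expect_equal(cfg2$seed, cfg$seed)

  rec <- data.frame(replicate = 1, theta = 0.01, pi_total = 10,
                    pi_per_site = 0.01, k = 10L, coverage = 30,
                    metric = "cosine", pipeline = "raw", score = 0.2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_records(rec, tsv)
  expect_equal(read.delim(tsv), rec)
})
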