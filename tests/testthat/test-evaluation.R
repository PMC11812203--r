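toy_known <- function(n = 6) {
  known_pair_table(data.frame(slc_id = sprintf("S%02d", seq_len(n)),
                              target_id = sprintf("M%02d", seq_len(n)),
                              target_kind = "metabolite"))
}

test_that("simulated random tables avoid the known set and are seeded", {
  known <- known_pair_table(data.frame(slc_id = c("S1", "S2"),
                                       target_id = c("M1", "M2"),
                                       target_kind = "metabolite"))
  rs <- simulate_random_pairs(known, c("M1", "M2", "M3"), n = 50, seed = 7)
  for (tab in rs) {
    expect_false(any(paste(tab$slc_id, tab$target_id) %in%
                       c("S1 M1", "S2 M2")))
    expect_identical(tab$slc_id, known$slc_id)
  }
  rs2 <- simulate_random_pairs(known, c("M1", "M2", "M3"), n = 50, seed = 7)
  expect_identical(rs, rs2)
  # at the scale of the curated known table: 100 tables of 667 rows
  big <- simulate_random_pairs(toy_known(667), sprintf("M%03d", 1:700),
                               n = 100, seed = 1)
  expect_length(big, 100L)
  expect_true(all(vapply(big, nrow, integer(1)) == 667L))
  # a single known metabolite per SLC covering the whole universe cannot move
  expect_error(simulate_random_pairs(
    known_pair_table(data.frame(slc_id = "S1", target_id = "M1",
                                target_kind = "metabolite")),
    "M1", n = 2, seed = 1), "universe exhausted")
})

test_that("recovery curves count strict exceedance and never increase", {
  rc <- recovery_curve(c(5, 20, 50))
  expect_equal(rc$fraction[rc$cutoff == 10], 2 / 3)
  expect_equal(rc$fraction[rc$cutoff == 20], 1 / 3)  # strictly greater
  expect_true(all(recovery_curve(rep(0, 5))$fraction == 0))
  expect_true(all(recovery_curve(c(101, 150))$fraction == 1))
  set.seed(51)
  expect_true(all(diff(recovery_curve(rnorm(40, 30, 25))$fraction) <= 0))
})

test_that("threshold optimization maximizes the mean fractional difference", {
  set.seed(52)
  base <- rnorm(40)
  rand_sets <- replicate(20, rnorm(40), simplify = FALSE)
  # no signal: objective near zero everywhere
  flat <- optimize_tod(base, rand_sets, grid = c(-1, 0, 1))
  expect_true(all(abs(flat$diagnostics$objective) < 0.05, na.rm = TRUE))
  # known shifted +2 SD: positive objective, maximized in the interior
  known <- rnorm(40, mean = 2)
  grid <- c(-2, -1, 0, 1, 2)
  opt <- optimize_tod(known, rand_sets, grid = grid)
  # oracle: exhaustive evaluation from first principles
  objective <- sapply(grid, function(tod) {
    if (tod > max(known)) return(NA_real_)
    q <- known_quantiles(known, tod)
    kf <- sapply(1:100, function(co) mean(3 * subscore(known, tod, q) > co))
    rf <- rowMeans(sapply(rand_sets, function(v)
      sapply(1:100, function(co) mean(3 * subscore(v, tod, q) > co))))
    mean(kf - rf)
  })
  expect_equal(opt$diagnostics$objective, objective)
  expect_equal(opt$best, grid[which.max(objective)])
  expect_gt(max(objective, na.rm = TRUE), 0)
  expect_equal(optimize_tod(known, rand_sets, grid = 0.5)$best, 0.5)
})

test_that("bootstrap statistics are seeded and sized", {
  expect_equal(bootstrap_stat(rep(4, 10), B = 25, seed = 1), rep(4, 25))
  b1 <- bootstrap_stat(rnorm(30), B = 100, stat = "median", seed = 9)
  set.seed(99)  # scramble the RNG in between
  b2 <- bootstrap_stat(rnorm(30), B = 100, stat = "median", seed = 9)
  expect_false(identical(b1, b2))  # different values under different data
  v <- runif(15)
  expect_identical(bootstrap_stat(v, B = 100, seed = 3),
                   bootstrap_stat(v, B = 100, seed = 3))
  expect_length(bootstrap_stat(v, B = 100, seed = 3), 100L)
})

test_that("trapezoidal ROC AUC equals the normalized Mann-Whitney U", {
  expect_equal(roc_pr(c(0.9, 0.8), c(0.1, 0.2))$roc_auc, 1.0)
  expect_equal(roc_pr(c(1, 2, 3), c(1, 2, 3))$roc_auc, 0.5)
  expect_equal(roc_pr(2, c(1, 3))$roc_auc, 0.5)
  set.seed(53)
  for (i in 1:20) {
    pos <- sample(1:6, sample(1:8, 1), replace = TRUE)
    neg <- sample(1:6, sample(1:8, 1), replace = TRUE)
    expect_equal(roc_pr(pos, neg)$roc_auc, oracle_auc(pos, neg))
  }
})

test_that("ROC AUC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(54)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  ours <- roc_pr(pos, neg)$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref)
})

test_that("per-SLC ranking drops zero scores and averages ties", {
  conf <- data.frame(slc_id = "S1", metabolite_id = c("a", "b", "c"),
                     confidence = c(10, 5, 0))
  r <- rank_predictions(conf)
  expect_equal(r$rank, c(1, 2))
  expect_equal(r$percentile, c(0.5, 1))
  expect_false("c" %in% r$metabolite_id)
  conf2 <- data.frame(slc_id = "S1", metabolite_id = letters[1:4],
                      confidence = c(9, 9, 3, 1))
  expect_equal(rank_predictions(conf2)$rank, c(1.5, 1.5, 3, 4))
  conf3 <- data.frame(slc_id = "S1", metabolite_id = sprintf("m%03d", 1:100),
                      confidence = 100:1)
  r3 <- rank_predictions(conf3)
  expect_equal(sum(r3$percentile <= 0.04), 4L)
  expect_message(rank_predictions(data.frame(slc_id = "S9",
                                             metabolite_id = "m",
                                             confidence = 0)), "excluded")
})

test_that("pathway enrichment matches exact hypergeometric enumeration", {
  pw <- pathway_table(data.frame(pathway_id = "P1",
                                 metabolite_id = paste0("m", 1:5)))
  universe <- paste0("m", 1:10)
  res <- pathway_enrichment(paste0("m", 1:4), pw, universe)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper(4, 5, 10, 4), tolerance = 1e-12)
  # disjoint selection: overlap 0 is certain under the one-sided tail
  res2 <- pathway_enrichment(paste0("m", 6:9), pw[pw$metabolite_id %in%
                                                    paste0("m", 1:3), ],
                             universe)
  expect_equal(res2$overlap, 0L)
  expect_equal(res2$p, 1)
  res3 <- pathway_enrichment(universe, pw, universe)
  expect_equal(res3$p, 1)
  expect_error(pathway_enrichment(character(0), pw, universe), "empty")
  expect_error(pathway_enrichment("zz", pw, universe), "subset")
})

test_that("a 667-pair table partitions into 466 training and 201 test pairs", {
  known <- toy_known(667)
  part <- partition_known(known, split = 0.7, seed = 5)
  expect_equal(nrow(part$train), 466L)
  expect_equal(nrow(part$test), 201L)
  expect_equal(nrow(part$train) + nrow(part$test), 667L)
  part2 <- partition_known(known, split = 0.7, seed = 5)
  expect_identical(part$train$slc_id, part2$train$slc_id)
})

test_that("train/test cycles re-optimize thresholds and separate known from random", {
  sc <- get_default_scores()
  res <- suppressMessages(train_test_cycle(
    sc$corr, sc$panel$known, unique(sc$corr$metabolite_id),
    default_score_params(), grid = c(0, 1), split = 0.7, iters = 2,
    n_random = 5, seed = 61))
  expect_equal(nrow(res), 2L)
  expect_equal(res$n_train, rep(floor(0.7 * 20), 2))
  expect_true(all(res$mean_score_test > res$mean_score_random))
  expect_true(all(res$roc_auc > 0.8))
  set.seed(77)
  res2 <- suppressMessages(train_test_cycle(
    sc$corr, sc$panel$known, unique(sc$corr$metabolite_id),
    default_score_params(), grid = c(0, 1), split = 0.7, iters = 2,
    n_random = 5, seed = 61))
  expect_identical(res, res2)
})
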