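panel_pair <- function(x, y, slc = "SLC1", met = "met1") {
  n <- length(x)
  expr <- make_om(matrix(x, 1, n), "pseudocounts", features = slc,
                  samples = sprintf("c%02d", 1:n))
  metab <- make_om(matrix(y, 1, n), features = met,
                   samples = sprintf("c%02d", 1:n))
  list(expr = expr, metab = metab)
}

test_that("Spearman rho matches the rank-difference oracle", {
  pp <- panel_pair(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                   c(1, 3, 2, 4, 5, 6, 7, 8, 9, 10))
  tab <- correlate_panel(pp$expr, pp$metab, "SLC1", "d1", min_overlap = 10)
  expect_equal(tab$rho, oracle_spearman(1:10, c(1, 3, 2, 4, 5:10)))
  pp2 <- panel_pair(1:10, 2 * (1:10))
  expect_equal(correlate_panel(pp2$expr, pp2$metab, "SLC1", "d1")$rho, 1)
})

test_that("rho and p agree with cor.test on random pairwise-missing data", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    y[sample(30, 5)] <- NA
    pp <- panel_pair(x, y)
    tab <- suppressMessages(correlate_panel(pp$expr, pp$metab, "SLC1", "d1"))
    ok <- complete.cases(x, y)
    ct <- cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    expect_equal(tab$rho, unname(ct$estimate))
    expect_equal(tab$p, ct$p.value)
    expect_equal(tab$n_samples, sum(ok))
  }
})

test_that("correlation is invariant to strictly monotone transforms", {
  set.seed(22)
  x <- rgamma(25, 2); y <- x + rnorm(25)
  pp <- panel_pair(x, y)
  base <- correlate_panel(pp$expr, pp$metab, "SLC1", "d1")$rho
  pp2 <- panel_pair(log(x), exp(y / 10))
  expect_equal(correlate_panel(pp2$expr, pp2$metab, "SLC1", "d1")$rho, base)
})

test_that("constant variables give missing rho with a warning; sparse pairs drop", {
  pp <- panel_pair(1:12, rep(1, 12))
  expect_warning(tab <- correlate_panel(pp$expr, pp$metab, "SLC1", "d1"),
                 "constant")
  expect_true(is.na(tab$rho))
  y <- c(rnorm(5), rep(NA, 7))
  pp2 <- panel_pair(rnorm(12), y)
  expect_message(tab2 <- correlate_panel(pp2$expr, pp2$metab, "SLC1", "d1"),
                 "omitted")
  expect_equal(nrow(tab2), 0L)
})

test_that("BH adjustment matches the step-up oracle within each family", {
  tab <- data.frame(slc_id = "S1", dataset_id = "d1",
                    metabolite_id = paste0("m", 1:4),
                    p = c(0.01, 0.02, 0.03, 0.04))
  out <- bh_adjust(tab)
  expect_equal(out$p_adj, rep(0.04, 4))
  set.seed(23)
  tab2 <- data.frame(slc_id = rep(c("S1", "S2"), each = 6),
                     dataset_id = "d1",
                     metabolite_id = rep(paste0("m", 1:6), 2),
                     p = runif(12))
  out2 <- bh_adjust(tab2)
  for (s in c("S1", "S2")) {
    idx <- out2$slc_id == s
    expect_equal(out2$p_adj[idx], oracle_bh(tab2$p[idx]))
  }
  expect_true(all(out2$p_adj >= out2$p))
  # invariant to row order
  perm <- sample(nrow(tab2))
  out3 <- bh_adjust(tab2[perm, ])
  expect_equal(out3$p_adj, out2$p_adj[perm])
  # single-row family and p = 1
  one <- bh_adjust(data.frame(slc_id = "S", dataset_id = "d",
                              metabolite_id = "m", p = 1))
  expect_equal(one$p_adj, 1)
})

test_that("transformed rho is the z-score of |rho| within each metabolite", {
  tab <- data.frame(slc_id = paste0("S", 1:3), metabolite_id = "m1",
                    dataset_id = "d1", rho = c(0.9, -0.5, 0.1))
  tr <- transform_rho(tab)
  expect_equal(tr$table$rho_transformed, oracle_zscore(c(0.9, 0.5, 0.1)))
  expect_equal(tr$table$rho_transformed[1], 1.0)  # (0.9-0.5)/0.4
  expect_equal(tr$stats$mean_abs_rho, 0.5)
  expect_equal(tr$stats$sd_abs_rho, 0.4)
  # value at the metabolite mean maps to zero
  tab2 <- data.frame(slc_id = paste0("S", 1:3), metabolite_id = "m",
                     dataset_id = "d", rho = c(0.2, 0.5, 0.8))
  expect_equal(transform_rho(tab2)$table$rho_transformed[2], 0)
})

test_that("transformed rho has mean 0, sample SD 1 per group; degenerate warns", {
  set.seed(24)
  tab <- data.frame(slc_id = rep(paste0("S", 1:8), 2),
                    metabolite_id = rep(c("m1", "m2"), each = 8),
                    dataset_id = "d1", rho = runif(16, -1, 1))
  tr <- transform_rho(tab)$table
  for (m in c("m1", "m2")) {
    v <- tr$rho_transformed[tr$metabolite_id == m]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  same <- data.frame(slc_id = paste0("S", 1:4), metabolite_id = "m",
                     dataset_id = "d", rho = rep(0.3, 4))
  expect_warning(tr2 <- transform_rho(same), "zero spread|missing")
  expect_true(all(is.na(tr2$table$rho_transformed)))
})

test_that("dataset concordance recovers identity, negation, and known swaps", {
  a <- data.frame(slc_id = rep(paste0("S", 1:2), each = 2),
                  metabolite_id = rep(c("m1", "m2"), 2),
                  dataset_id = "d1", rho = c(0.1, 0.4, 0.7, 0.9))
  b <- a; b$dataset_id <- "d2"
  expect_equal(dataset_concordance(a, b)$rho, 1)
  b2 <- b; b2$rho <- -b2$rho
  expect_equal(dataset_concordance(a, b2)$rho, -1)
  b3 <- b
  b3$rho <- c(0.1, 0.7, 0.4, 0.9)  # one swapped pair among four
  expect_equal(dataset_concordance(a, b3)$rho,
               oracle_spearman(a$rho, b3$rho))
  expect_error(dataset_concordance(a[1:2, ], b[1:2, ]), "fewer than 3")
  sub <- a[c(1, 2, 3), c("slc_id", "metabolite_id")]
  expect_equal(dataset_concordance(a, b, subset = sub)$n_pairs, 3L)
})
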