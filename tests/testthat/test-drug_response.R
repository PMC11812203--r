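test_that("the prediction grid spans -3.21..1.00 inclusively in 0.01 steps", {
  g <- dose_grid()
  expect_length(g, 422L)
  expect_equal(g[1], -3.21)
  expect_equal(g[length(g)], 1.00)
  expect_equal(unique(round(diff(g), 10)), 0.01)
})

test_that("panels require at least two strictly increasing doses per drug", {
  v <- data.frame(drug_id = "D1", cell_line = c("a", "b"), dose = -1,
                  logfold = c(0, 0.1))
  expect_error(drug_panel(v), "fewer than 2 doses")
})

test_that("expression groups are disjoint extremes with stable tie-breaking", {
  expr <- make_om(matrix(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), 1),
                  "pseudocounts", features = "SLC1",
                  samples = sprintf("c%02d", 1:10))
  grp <- expression_groups(expr, "SLC1")
  expect_equal(grp$high, c("c01", "c02"))
  expect_equal(grp$low, c("c09", "c10"))
  expect_length(intersect(grp$high, grp$low), 0)
  grp5 <- expression_groups(expr, "SLC1", frac = 0.5)
  expect_length(c(grp5$high, grp5$low), 10L)
  # ties at the boundary resolved by cell-line id
  tied <- make_om(matrix(rep(1, 10), 1), "pseudocounts", features = "SLC1",
                  samples = sprintf("c%02d", 10:1))
  g1 <- expression_groups(tied, "SLC1")
  expect_equal(g1$high, c("c01", "c02"))
  expect_error(expression_groups(expr, "SLC1", lines = sprintf("c%02d", 1:5)),
               "at least 10")
})

test_that("curve fitting reproduces constants and straight lines", {
  d <- rep(ASSAY_DOSES, each = 4)
  expect_equal(fit_curve(d, rep(1, length(d))), rep(1, 422))
  line <- 0.4 * d - 0.2
  pred <- fit_curve(d, line)
  expect_equal(pred, 0.4 * dose_grid() - 0.2, tolerance = 1e-6)
  expect_error(fit_curve(rep(-1, 5), rnorm(5)), "distinct doses")
})

test_that("curve comparison recovers planted offsets and is antisymmetric", {
  g <- dose_grid()
  set.seed(71)
  high <- -1 / (1 + 10^(-(g + 1))) + 0.25
  low <- -1 / (1 + 10^(-(g + 1))) + rnorm(422, sd = 1e-4)
  cmp <- compare_curves(high, low)
  expect_equal(cmp$mean_diff, 0.25, tolerance = 1e-3)
  expect_false(cmp$degenerate)
  flip <- compare_curves(low, high)
  expect_equal(flip$mean_diff, -cmp$mean_diff, tolerance = 1e-12)
  expect_equal(flip$p, cmp$p)
  same <- compare_curves(high, high)
  expect_true(same$degenerate)
  expect_equal(same$mean_diff, 0)
})

test_that("dose effect tracks the monotonicity of the curve difference", {
  g <- dose_grid()
  up <- dose_effect(g * 0.1, rep(0, 422), g)
  expect_equal(up$rho, 1)
  down <- dose_effect(-g, rep(0, 422), g)
  expect_equal(down$rho, -1)
  expect_equal(down$abs_rho, 1)
  flat <- dose_effect(rep(0.3, 422), rep(0, 422), g)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$rho))
})

test_that("null thresholds are deterministic under the seed", {
  fx <- get_drug_fixture()
  n1 <- null_thresholds(fx$panel, "DRUG03", n_iter = 8, seed = 42)
  n2 <- null_thresholds(fx$panel, "DRUG03", n_iter = 8, seed = 42)
  expect_identical(n1, n2)
  expect_equal(n1$n_used, 8L)
  expect_true(n1$null_sd_logp > 0)
})

test_that("planted SLC-drug shifts are detected with the right direction", {
  fx <- get_drug_fixture()
  res <- predict_drug_interactions(
    fx$expr, fx$panel, slc_ids = fx$truth$slc_id,
    n_iter = 30, seed = 91)
  a <- res$associations
  for (i in seq_len(nrow(fx$truth))) {
    row <- a[a$slc_id == fx$truth$slc_id[i] &
               a$drug_id == fx$truth$drug_id[i], ]
    expect_true(row$predicted)
    expect_equal(row$direction,
                 if (fx$truth$shift[i] < 0) "sensitising" else "attenuating")
    expect_equal(abs(row$mean_diff), abs(fx$truth$shift[i]),
                 tolerance = 0.1)
  }
  expect_equal(nrow(predict_drug_interactions(fx$expr, fx$panel,
                                              character(0))$associations), 0L)
  # prediction set is monotone in the null thresholds: every flagged pair
  # clears both gates, so raising either gate only removes predictions
  flagged <- a[a$predicted, ]
  expect_true(all(-log10(flagged$p) >
                    flagged$null_mean_logp + 2 * flagged$null_sd_logp))
  expect_true(all(flagged$abs_mean_diff >
                    flagged$null_mean_absdiff + 2 * flagged$null_sd_absdiff))
})

test_that("swapping group labels negates differences but keeps magnitudes", {
  fx <- get_drug_fixture()
  dg <- fx$truth$drug_id[1]
  slc <- fx$truth$slc_id[1]
  treated <- unique(fx$panel$viability$cell_line)
  grp <- expression_groups(fx$expr, slc, lines = treated)
  ph <- fx$panel$viability[fx$panel$viability$drug_id == dg &
                             fx$panel$viability$cell_line %in% grp$high, ]
  pl <- fx$panel$viability[fx$panel$viability$drug_id == dg &
                             fx$panel$viability$cell_line %in% grp$low, ]
  ch <- fit_curve(ph$dose, ph$logfold)
  cl <- fit_curve(pl$dose, pl$logfold)
  fwd <- compare_curves(ch, cl); rev <- compare_curves(cl, ch)
  expect_equal(fwd$mean_diff, -rev$mean_diff)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$abs_mean_diff, rev$abs_mean_diff)
  de_f <- dose_effect(ch, cl); de_r <- dose_effect(cl, ch)
  expect_equal(de_f$rho, -de_r$rho)
  expect_equal(de_f$abs_rho, de_r$abs_rho)
})
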