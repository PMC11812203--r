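# SLC-drug association from expression-stratified dose-response curves with
# resampled drug-specific null thresholds.

# The 8 assay doses and the prediction grid (log10 micromolar); the inclusive
# grid from -3.21 to 1.00 in 0.01 steps has 422 points.
ASSAY_DOSES <- c(-3.21, -2.61, -2.01, -1.40, -0.81, -0.20, 0.40, 1.00)
DOSE_GRID_N <- 422L

#' Prediction grid of log10 doses
#'
#' Uniform grid from -3.21 to 1.00 in steps of 0.01 (inclusive endpoints, 422
#' points) on which fitted dose-response curves are evaluated and compared.
#'
#' @return numeric vector of log10 doses.
#' @export
dose_grid <- function() seq(-3.21, 1.00, by = 0.01)

#' Assemble a drug viability panel
#'
#' @param viability long data frame with columns `drug_id`, `cell_line`,
#'   `dose` (log10) and `logfold` (log-fold viability change).
#' @param drug_meta optional data frame with `drug_id`, `name`, `target`.
#' @return list of class `drug_panel` with elements `viability` and
#'   `drug_meta`. Each drug must be assayed at two or more strictly
#'   increasing doses.
#' @export
drug_panel <- function(viability, drug_meta = NULL) {
  require_columns(viability, c("drug_id", "cell_line", "dose", "logfold"),
                  "viability table")
  doses <- lapply(split(viability$dose, viability$drug_id),
                  function(d) sort(unique(d)))
  bad <- names(doses)[vapply(doses, length, integer(1)) < 2L]
  if (length(bad) > 0L) {
    stop("drug(s) with fewer than 2 doses: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(drug_meta)) {
    drug_meta <- data.frame(drug_id = names(doses), name = names(doses),
                            target = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(viability = viability, drug_meta = drug_meta),
            class = "drug_panel")
}

#' Load a drug repurposing panel from its file triplet
#'
#' Reads the (cell-line info, treatment metadata, log-fold viability) triplet
#' of delimited files: treatments map viability columns to a drug and a dose;
#' the viability matrix has cell lines in rows and treatment columns.
#'
#' @param cell_info_path delimited file with a `cell_line` column (extra
#'   columns are kept as annotations).
#' @param treatment_path delimited file with columns `column_name`,
#'   `drug_id`, `dose`, optional `name` and `target`.
#' @param logfold_path delimited matrix, first column cell-line id, remaining
#'   columns named as in `treatment_path$column_name`.
#' @return a [drug_panel()].
#' @export
load_drug_panel <- function(cell_info_path, treatment_path, logfold_path) {
  info <- read_table_auto(cell_info_path)
  require_columns(info, "cell_line", "cell-line info")
  trt <- read_table_auto(treatment_path)
  require_columns(trt, c("column_name", "drug_id", "dose"),
                  "treatment metadata")
  lf <- read_table_auto(logfold_path)
  lines <- as.character(lf[[1L]])
  lf <- lf[, -1L, drop = FALSE]
  missing_cols <- setdiff(trt$column_name, names(lf))
  if (length(missing_cols) > 0L) {
    stop("viability matrix lacks treatment column(s): ",
         paste(head(missing_cols, 5L), collapse = ", "), call. = FALSE)
  }
  long <- do.call(rbind, lapply(seq_len(nrow(trt)), function(i) {
    data.frame(drug_id = trt$drug_id[i], cell_line = lines,
               dose = trt$dose[i], logfold = lf[[trt$column_name[i]]],
               stringsAsFactors = FALSE)
  }))
  long <- long[is.finite(long$logfold), , drop = FALSE]
  keep <- intersect(c("drug_id", "name", "target"), names(trt))
  meta <- unique(trt[keep])
  if (!"name" %in% names(meta)) meta$name <- meta$drug_id
  if (!"target" %in% names(meta)) meta$target <- NA_character_
  drug_panel(long, meta)
}

#' High/low expression groups for one SLC
#'
#' Cell lines are ranked by the SLC's expression in descending order (ties
#' broken by cell-line id for determinism); the first `floor(frac * n)` form
#' the high-expression group and the last `floor(frac * n)` the
#' low-expression group.
#'
#' @param expr [omics_matrix()] of normalized expression.
#' @param slc_id gene to stratify on.
#' @param frac group fraction (default 0.2).
#' @param lines optional restriction to these cell lines (e.g. lines treated
#'   with a drug).
#' @return list with character vectors `high` and `low` (disjoint).
#' @export
expression_groups <- function(expr, slc_id, frac = 0.2, lines = NULL) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (!slc_id %in% feature_ids(expr)) {
    stop("unknown SLC: ", slc_id, call. = FALSE)
  }
  ids <- sample_ids(expr)
  if (!is.null(lines)) ids <- intersect(ids, lines)
  e <- expr$values[slc_id, ids]
  ids <- ids[is.finite(e)]
  if (length(ids) < 10L) {
    stop("need at least 10 cell lines, got ", length(ids), call. = FALSE)
  }
  e <- expr$values[slc_id, ids]
  ord <- ids[order_stable(e, ids, decreasing = TRUE)]
  k <- floor(frac * length(ord))
  list(high = ord[seq_len(k)],
       low = ord[seq.int(length(ord) - k + 1L, length(ord))])
}

#' Fit a smoothed dose-response curve and predict on the grid
#'
#' A locally weighted polynomial smoother (quadratic, span 0.75 by default)
#' is fitted to all (dose, viability) points of a group of cell lines and
#' evaluated at every grid point; grid points outside the observed dose range
#' use the smoother's boundary fit.
#'
#' @param doses log10 dose of each observation.
#' @param viabilities log-fold viability of each observation.
#' @param grid prediction grid (default [dose_grid()]).
#' @param span,degree smoother span and local polynomial degree.
#' @return numeric vector of predicted viabilities, one per grid point.
#' @export
fit_curve <- function(doses, viabilities, grid = dose_grid(), span = 0.75,
                      degree = 2) {
  ok <- is.finite(doses) & is.finite(viabilities)
  doses <- doses[ok]; viabilities <- viabilities[ok]
  if (length(unique(doses)) < 2L) {
    stop("need at least 2 distinct doses", call. = FALSE)
  }
  if (length(doses) < 3L) stop("need at least 3 points", call. = FALSE)
  if (diff(range(viabilities)) == 0) {
    return(rep(viabilities[1L], length(grid)))
  }
  fit <- loess(viabilities ~ doses, span = span, degree = degree,
               control = loess.control(surface = "direct"))
  as.numeric(predict(fit, data.frame(doses = grid)))
}

#' Compare two predicted dose-response curves
#'
#' Paired two-sided t-test of the predicted viabilities across grid points,
#' plus the mean difference (high minus low). Identical curves (zero variance
#' of differences) return a missing p with the `degenerate` flag set.
#'
#' @param pred_high,pred_low predictions on the same grid.
#' @return list with `p`, `mean_diff`, `abs_mean_diff`, `degenerate`.
#' @export
compare_curves <- function(pred_high, pred_low) {
  stopifnot(length(pred_high) == length(pred_low))
  d <- pred_high - pred_low
  if (sd(d) == 0) {
    return(list(p = NA_real_, mean_diff = mean(d),
                abs_mean_diff = abs(mean(d)), degenerate = TRUE))
  }
  tt <- t.test(pred_high, pred_low, paired = TRUE)
  list(p = tt$p.value, mean_diff = mean(d), abs_mean_diff = abs(mean(d)),
       degenerate = FALSE)
}

#' Dose dependence of the curve difference
#'
#' Spearman correlation of the pairwise difference between the two predicted
#' curves against the grid dose: a strong monotone trend indicates an
#' expression-linked, dose-dependent effect.
#'
#' @param pred_high,pred_low predictions on the same grid.
#' @param grid the dose grid the predictions live on.
#' @return list with `rho`, `abs_rho`, `p`, `degenerate` (constant
#'   difference).
#' @export
dose_effect <- function(pred_high, pred_low, grid = dose_grid()) {
  stopifnot(length(pred_high) == length(pred_low),
            length(pred_high) == length(grid))
  d <- pred_high - pred_low
  if (diff(range(d)) == 0) {
    return(list(rho = NA_real_, abs_rho = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  ct <- cor.test(d, grid, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), abs_rho = abs(unname(ct$estimate)),
       p = ct$p.value, degenerate = FALSE)
}

# Extract (dose, logfold) observations of a drug for a set of cell lines.
drug_points <- function(panel, drug_id, lines) {
  v <- panel$viability
  v[v$drug_id == drug_id & v$cell_line %in% lines, c("dose", "logfold")]
}

#' Drug-specific null thresholds from random group picking
#'
#' Repeatedly draws two disjoint random groups of `floor(frac * n)` of the
#' cell lines treated with the drug, fits and compares their curves exactly
#' as the high/low expression contrast does, and records `-log10(p)` and the
#' absolute mean difference. Their means and standard deviations form the
#' null expectation a candidate association must exceed by two standard
#' deviations. Degenerate iterations are dropped (an error if more than half
#' are).
#'
#' @param panel a [drug_panel()].
#' @param drug_id drug to resample.
#' @param n_iter number of random picks (default 100).
#' @param frac group fraction (default 0.2).
#' @param seed optional integer seed.
#' @param span,degree forwarded to [fit_curve()].
#' @return list with `null_mean_logp`, `null_sd_logp`, `null_mean_absdiff`,
#'   `null_sd_absdiff`, `n_used`.
#' @export
null_thresholds <- function(panel, drug_id, n_iter = 100, frac = 0.2,
                            seed = NULL, span = 0.75, degree = 2) {
  if (!is.null(seed)) set.seed(seed)
  v <- panel$viability[panel$viability$drug_id == drug_id, , drop = FALSE]
  if (nrow(v) == 0L) stop("unknown drug: ", drug_id, call. = FALSE)
  lines <- sort(unique(v$cell_line))
  k <- floor(frac * length(lines))
  if (2L * k > length(lines) || k < 2L) {
    stop("too few cell lines for two disjoint groups of fraction ", frac,
         call. = FALSE)
  }
  logp <- absd <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    pick <- sample(lines, 2L * k)
    g1 <- pick[seq_len(k)]
    g2 <- pick[seq.int(k + 1L, 2L * k)]
    p1 <- drug_points(panel, drug_id, g1)
    p2 <- drug_points(panel, drug_id, g2)
    c1 <- fit_curve(p1$dose, p1$logfold, span = span, degree = degree)
    c2 <- fit_curve(p2$dose, p2$logfold, span = span, degree = degree)
    cmp <- compare_curves(c1, c2)
    if (cmp$degenerate) next
    logp[i] <- -log10(cmp$p)
    absd[i] <- cmp$abs_mean_diff
  }
  used <- is.finite(logp)
  if (sum(!used) > 0L) {
    message(sum(!used), " degenerate null iteration(s) dropped")
  }
  if (mean(used) < 0.5) {
    stop("more than half of the null iterations degenerate for drug ",
         drug_id, call. = FALSE)
  }
  list(null_mean_logp = mean(logp[used]), null_sd_logp = sd(logp[used]),
       null_mean_absdiff = mean(absd[used]), null_sd_absdiff = sd(absd[used]),
       n_used = sum(used))
}

#' Predict SLC-drug interactions from expression-stratified dose response
#'
#' For every (SLC, drug) combination: cell lines treated with the drug are
#' split into high/low expression groups, smoothed dose-response curves are
#' fitted per group and compared (paired t-test, mean difference), and the
#' dose dependence of the curve difference is measured. A pair is flagged
#' `predicted` only when both its `-log10(p)` and its absolute mean
#' difference exceed the drug-specific null mean by at least two null
#' standard deviations ([null_thresholds()]). The shortlist ranks predicted
#' pairs by the sum of the descending ranks of absolute mean difference and
#' absolute dose-effect rho, truncated to `top_n`.
#'
#' @param expr [omics_matrix()] of normalized expression.
#' @param panel a [drug_panel()].
#' @param slc_ids SLC genes to test.
#' @param frac expression-group fraction (default 0.2).
#' @param n_iter null iterations per drug (default 100).
#' @param top_n shortlist size (default 50).
#' @param seed optional integer seed (drives the null resampling).
#' @param span,degree forwarded to [fit_curve()].
#' @return list with `associations` (data frame of class `drug_association`)
#'   and `shortlist`.
#' @export
predict_drug_interactions <- function(expr, panel, slc_ids, frac = 0.2,
                                      n_iter = 100, top_n = 50, seed = NULL,
                                      span = 0.75, degree = 2) {
  if (!is.null(seed)) set.seed(seed)
  drugs <- unique(panel$viability$drug_id)
  slc_ids <- intersect(slc_ids, feature_ids(expr))
  empty <- data.frame(
    slc_id = character(), drug_id = character(), p = numeric(),
    mean_diff = numeric(), abs_mean_diff = numeric(), dose_rho = numeric(),
    dose_p = numeric(), null_mean_logp = numeric(), null_sd_logp = numeric(),
    null_mean_absdiff = numeric(), null_sd_absdiff = numeric(),
    predicted = logical(), direction = character(), stringsAsFactors = FALSE)
  if (length(slc_ids) == 0L || length(drugs) == 0L) {
    return(list(associations = empty, shortlist = empty))
  }
  rows <- list()
  for (dg in drugs) {
    nt <- null_thresholds(panel, dg, n_iter = n_iter, frac = frac,
                          span = span, degree = degree)
    treated <- unique(panel$viability$cell_line[panel$viability$drug_id == dg])
    for (slc in slc_ids) {
      grp <- expression_groups(expr, slc, frac = frac, lines = treated)
      ph <- drug_points(panel, dg, grp$high)
      pl <- drug_points(panel, dg, grp$low)
      ch <- fit_curve(ph$dose, ph$logfold, span = span, degree = degree)
      cl <- fit_curve(pl$dose, pl$logfold, span = span, degree = degree)
      cmp <- compare_curves(ch, cl)
      de <- dose_effect(ch, cl)
      predicted <- !cmp$degenerate && is.finite(cmp$p) &&
        (-log10(cmp$p) > nt$null_mean_logp + 2 * nt$null_sd_logp) &&
        (cmp$abs_mean_diff > nt$null_mean_absdiff + 2 * nt$null_sd_absdiff)
      rows[[length(rows) + 1L]] <- data.frame(
        slc_id = slc, drug_id = dg, p = cmp$p, mean_diff = cmp$mean_diff,
        abs_mean_diff = cmp$abs_mean_diff, dose_rho = de$rho,
        dose_p = de$p, null_mean_logp = nt$null_mean_logp,
        null_sd_logp = nt$null_sd_logp,
        null_mean_absdiff = nt$null_mean_absdiff,
        null_sd_absdiff = nt$null_sd_absdiff, predicted = predicted,
        direction = if (isTRUE(cmp$mean_diff < 0)) "sensitising" else "attenuating",
        stringsAsFactors = FALSE)
    }
  }
  assoc <- do.call(rbind, rows)
  class(assoc) <- c("drug_association", "data.frame")
  short <- assoc[assoc$predicted, , drop = FALSE]
  if (nrow(short) > 0L) {
    rank_sum <- rank(-short$abs_mean_diff, ties.method = "average") +
      rank(-abs(short$dose_rho), ties.method = "average")
    short <- short[order(rank_sum), , drop = FALSE]
    short <- head(short, top_n)
  }
  list(associations = assoc, shortlist = short)
}
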