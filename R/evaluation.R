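# Permutation nulls, threshold optimization, benchmarking and train/test
# machinery for the confidence score.

#' Simulated random pair tables (permutation null)
#'
#' Builds `n` tables shaped like the known table: the SLC column is kept
#' fixed while the metabolite column is shuffled, and any row that would
#' reproduce a known pair is redrawn from the metabolite universe excluding
#' that SLC's known substrates. No row of any table occurs in the known
#' table.
#'
#' @param known a [known_pair_table()] (metabolite rows are used).
#' @param universe metabolite ids to draw replacements from.
#' @param n number of tables (default 100).
#' @param seed optional integer seed for determinism.
#' @return list of `n` data frames (`slc_id`, `target_id`), class
#'   `random_pair_set`, attribute `seed`.
#' @export
simulate_random_pairs <- function(known, universe, n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  known <- known[known$target_kind == "metabolite", , drop = FALSE]
  known_by_slc <- split(known$target_id, known$slc_id)
  known_key <- paste(known$slc_id, known$target_id, sep = "\r")
  universe <- unique(as.character(universe))
  tables <- vector("list", n)
  for (t in seq_len(n)) {
    met <- sample(known$target_id)
    clash <- which(paste(known$slc_id, met, sep = "\r") %in% known_key)
    for (i in clash) {
      pool <- setdiff(universe, known_by_slc[[known$slc_id[i]]])
      if (length(pool) == 0L) {
        stop("no valid random assignment for SLC ", known$slc_id[i],
             ": universe exhausted", call. = FALSE)
      }
      met[i] <- pool[sample.int(length(pool), 1L)]
    }
    tables[[t]] <- data.frame(slc_id = known$slc_id, target_id = met,
                              stringsAsFactors = FALSE)
  }
  structure(tables, class = "random_pair_set", seed = seed)
}

#' Fraction of scores above each confidence-score cutoff
#'
#' @param scores numeric vector of confidence scores.
#' @param cutoffs integer cutoffs swept (default 1 to 100).
#' @return data frame (`cutoff`, `fraction`), class `recovery_curve`;
#'   `fraction` is the proportion of scores strictly greater than the cutoff
#'   and is non-increasing in the cutoff.
#' @export
recovery_curve <- function(scores, cutoffs = 1:100) {
  fraction <- vapply(cutoffs, function(co) mean(scores > co), numeric(1))
  if (length(scores) == 0L) fraction <- rep(0, length(cutoffs))
  structure(data.frame(cutoff = cutoffs, fraction = fraction),
            class = c("recovery_curve", "data.frame"))
}

#' Optimize a threshold of discovery by mean fractional difference
#'
#' For each candidate threshold, the known values and each random-table value
#' set are sub-scored against the known-pair quantile array built with that
#' threshold ([known_quantiles()], [subscore()], multiplied by `weight`), and
#' the objective is the mean over the cutoff grid of (fraction of known pairs
#' above the cutoff minus the mean fraction of random pairs above it). The
#' candidate maximizing the objective wins; ties break toward the smaller
#' threshold. Candidates exceeding the known maximum leave no valid quantile
#' array and get `NA` objective.
#'
#' @param known_values finite values of the known pairs (e.g. transformed
#'   rho in one dataset).
#' @param random_value_sets list of value vectors, one per simulated random
#'   table.
#' @param grid candidate thresholds.
#' @param weight score weight applied to sub-scores (default 3, the
#'   cell-panel weight).
#' @param cutoffs cutoff grid (default 1 to 100).
#' @return list with `best` (the winning threshold) and `diagnostics` (data
#'   frame of candidate and objective).
#' @export
optimize_tod <- function(known_values, random_value_sets, grid, weight = 3,
                         cutoffs = 1:100) {
  if (length(grid) == 0L) stop("empty candidate grid", call. = FALSE)
  known_values <- known_values[is.finite(known_values)]
  objective <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    tod <- grid[g]
    if (tod > max(known_values)) next
    q <- known_quantiles(known_values, tod)
    kf <- recovery_curve(weight * subscore(known_values, tod, q),
                         cutoffs)$fraction
    rf <- rowMeans(vapply(
      random_value_sets,
      function(v) recovery_curve(weight * subscore(v, tod, q),
                                 cutoffs)$fraction,
      numeric(length(cutoffs))))
    objective[g] <- mean(kf - rf)
  }
  if (all(is.na(objective))) {
    stop("no candidate threshold admits a valid quantile array", call. = FALSE)
  }
  ord <- order(grid)
  best <- grid[ord][which.max(objective[ord])]  # ties -> smaller threshold
  list(best = best,
       diagnostics = data.frame(tod = grid, objective = objective))
}

#' Bootstrap a summary statistic
#'
#' @param values numeric vector resampled with replacement at its own size.
#' @param B number of bootstrap replicates (default 100).
#' @param stat `"mean"` or `"median"` (the latter for median-rank
#'   benchmarking).
#' @param seed optional integer seed.
#' @return numeric vector of `B` statistic values.
#' @export
bootstrap_stat <- function(values, B = 100, stat = c("mean", "median"),
                           seed = NULL) {
  stat <- match.arg(stat)
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- if (stat == "mean") mean else median
  vapply(seq_len(B),
         function(i) f(values[sample.int(length(values), replace = TRUE)]),
         numeric(1))
}

#' ROC and precision-recall AUC by the trapezoidal rule
#'
#' Thresholds sweep the pooled score set from high to low; all items at a
#' tied score enter simultaneously. Both curve areas are integrated with the
#' trapezoidal rule, which makes the ROC AUC equal to the normalized
#' Mann-Whitney U statistic (ties counted half).
#'
#' @param pos_scores scores of the positive (known) pairs.
#' @param neg_scores scores of the negative (simulated random) pairs.
#' @return list with `roc_auc`, `pr_auc`, and the curve point data frames
#'   `roc` (fpr, tpr) and `pr` (recall, precision).
#' @export
roc_pr <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos_scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(neg_scores >= t), numeric(1))
  tpr <- tp / length(pos_scores)
  fpr <- fp / length(neg_scores)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  roc_auc <- trapz(roc$fpr, roc$tpr)
  precision <- tp / (tp + fp)
  recall <- tpr
  pr <- data.frame(recall = c(0, recall), precision = c(precision[1L], precision))
  pr_auc <- trapz(pr$recall, pr$precision)
  list(roc_auc = roc_auc, pr_auc = pr_auc, roc = roc, pr = pr)
}

#' Rank each SLC's predictions by confidence score
#'
#' Within each SLC, metabolites with a strictly positive confidence score are
#' ranked in descending score order (ties share the mean rank); the rank
#' percentile is rank divided by the number of non-zero-score metabolites.
#' Zero-score metabolites are unranked; SLCs with no non-zero score are
#' excluded with a message.
#'
#' @param conf a `confidence_table` from [confidence_scores()].
#' @return data frame with `slc_id`, `metabolite_id`, `confidence`, `rank`,
#'   `percentile`.
#' @export
rank_predictions <- function(conf) {
  require_columns(conf, c("slc_id", "metabolite_id", "confidence"),
                  "confidence table")
  nz <- conf[conf$confidence > 0, , drop = FALSE]
  dropped <- setdiff(unique(conf$slc_id), unique(nz$slc_id))
  if (length(dropped) > 0L) {
    message(length(dropped), " SLC(s) with no non-zero-score metabolite excluded")
  }
  if (nrow(nz) == 0L) {
    return(data.frame(slc_id = character(), metabolite_id = character(),
                      confidence = numeric(), rank = numeric(),
                      percentile = numeric(), stringsAsFactors = FALSE))
  }
  parts <- lapply(split(nz, nz$slc_id), function(d) {
    d$rank <- rank(-d$confidence, ties.method = "average")
    d$percentile <- d$rank / nrow(d)
    d
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[c("slc_id", "metabolite_id", "confidence", "rank", "percentile")]
}

#' Hypergeometric pathway over-representation
#'
#' One-sided hypergeometric test per pathway for over-representation of the
#' selected metabolites, restricted to the given universe, with BH adjustment
#' across pathways.
#'
#' @param selected metabolite ids called as predictions (must lie in
#'   `universe`).
#' @param pathways a [pathway_table()].
#' @param universe background metabolite ids.
#' @return data frame with `pathway_id`, `pathway_size`, `overlap`, `p`,
#'   `p_adj`, sorted by `p`.
#' @export
pathway_enrichment <- function(selected, pathways, universe) {
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (length(selected) == 0L) stop("empty selected set", call. = FALSE)
  if (!all(selected %in% universe)) {
    stop("selected metabolites must be a subset of the universe", call. = FALSE)
  }
  members <- split(pathways$metabolite_id, pathways$pathway_id)
  rows <- lapply(names(members), function(pw) {
    inpw <- intersect(members[[pw]], universe)
    k <- length(intersect(inpw, selected))
    p <- phyper(k - 1L, length(inpw), length(universe) - length(inpw),
                length(selected), lower.tail = FALSE)
    data.frame(pathway_id = pw, pathway_size = length(inpw), overlap = k,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Random 70/30 partition of the known pair table
#'
#' @param known a [known_pair_table()].
#' @param split training fraction (default 0.7); the training set holds
#'   `floor(split * n)` pairs.
#' @param seed optional integer seed.
#' @return list with `train` and `test` row subsets of `known`.
#' @export
partition_known <- function(known, split = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(known)
  n_train <- floor(split * n)
  idx <- sample.int(n, n_train)
  list(train = known[idx, , drop = FALSE],
       test = known[-idx, , drop = FALSE])
}

#' Train/test cycles for the confidence score
#'
#' Repeatedly partitions the known pairs (70/30 by default), re-optimizes the
#' per-dataset thresholds of discovery on the training pairs only
#' ([optimize_tod()] against simulated random tables), scores all pairs with
#' training-derived quantile arrays, and reports test-set metrics against
#' simulated random sets of the same size: mean scores, the fraction of test
#' pairs recovered above the locally optimal score cutoff, the fraction
#' ranked in the top `top_frac` of their SLC's non-zero predictions, and
#' ROC/PR AUC.
#'
#' @param corr a `correlation_table` (all datasets, with `rho_transformed`).
#' @param known a [known_pair_table()] of at least 20 metabolite pairs.
#' @param universe metabolite ids for random redraws.
#' @param params a [score_params()]; its `tod` entries are re-optimized per
#'   iteration, everything else is kept.
#' @param grid candidate thresholds for [optimize_tod()].
#' @param split training fraction (default 0.7).
#' @param iters number of iterations (default 10).
#' @param n_random simulated random tables per use (default 50).
#' @param top_frac rank-percentile cutoff counted as a top prediction
#'   (default 0.04).
#' @param dep,adj optional dependency table / adjacency matrix forwarded to
#'   [confidence_scores()].
#' @param seed optional integer seed.
#' @return data frame with one row per iteration: `n_train`, `n_test`,
#'   per-dataset optimized thresholds (`tod_<dataset>`), `mean_score_test`,
#'   `mean_score_random`, `best_cutoff`, `frac_recovered`, `frac_top`,
#'   `roc_auc`, `pr_auc`.
#' @export
train_test_cycle <- function(corr, known, universe, params, grid,
                             split = 0.7, iters = 10, n_random = 50,
                             top_frac = 0.04, dep = NULL, adj = NULL,
                             seed = NULL) {
  known <- known[known$target_kind == "metabolite", , drop = FALSE]
  if (nrow(known) < 20L) stop("need at least 20 known pairs", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  datasets <- intersect(names(params$tod), unique(corr$dataset_id))
  corr_key <- paste(corr$slc_id, corr$metabolite_id, corr$dataset_id,
                    sep = "\r")
  values_of <- function(pairs, d) {
    v <- corr$rho_transformed[match(paste(pairs$slc_id, pairs$target_id, d,
                                          sep = "\r"), corr_key)]
    v[is.finite(v)]
  }
  rows <- vector("list", iters)
  for (it in seq_len(iters)) {
    part <- partition_known(known, split)
    train <- part$train
    test <- part$test
    rand_train <- simulate_random_pairs(known, universe, n_random)
    tod_new <- params$tod
    for (d in datasets) {
      kv <- values_of(train, d)
      if (length(kv) < 11L) next  # keep the incoming threshold
      rvs <- lapply(rand_train, values_of, d = d)
      tod_new[[d]] <- optimize_tod(kv, rvs, grid,
                                   weight = params$weight_a)$best
    }
    p_it <- score_params(tod = tod_new,
                         tod_prime = params$tod_prime,
                         crispr_p_cutoff = params$crispr_p_cutoff,
                         weight_a = params$weight_a,
                         weight_b = params$weight_b,
                         weight_c = params$weight_c,
                         adjacency_radius = params$adjacency_radius)
    conf <- confidence_scores(corr, known_pair_table(train), p_it,
                              dep = dep, adj = adj)
    conf_key <- paste(conf$slc_id, conf$metabolite_id, sep = "\r")
    score_of <- function(pairs) {
      s <- conf$confidence[match(paste(pairs$slc_id, pairs$target_id,
                                       sep = "\r"), conf_key)]
      s[is.na(s)] <- 0
      s
    }
    test_scores <- score_of(data.frame(slc_id = test$slc_id,
                                       target_id = test$target_id))
    rand_test <- simulate_random_pairs(known_pair_table(test), universe,
                                       n_random)
    rand_scores <- lapply(rand_test, score_of)
    kf <- recovery_curve(test_scores)$fraction
    rf <- rowMeans(vapply(rand_scores,
                          function(s) recovery_curve(s)$fraction,
                          numeric(100L)))
    best_cutoff <- which.max(kf - rf)
    ranks <- rank_predictions(conf)
    rank_key <- paste(ranks$slc_id, ranks$metabolite_id, sep = "\r")
    pct <- ranks$percentile[match(paste(test$slc_id, test$target_id,
                                        sep = "\r"), rank_key)]
    rp <- roc_pr(test_scores, unlist(rand_scores))
    row <- data.frame(iteration = it, n_train = nrow(train),
                      n_test = nrow(test), stringsAsFactors = FALSE)
    for (d in datasets) row[[paste0("tod_", d)]] <- tod_new[[d]]
    row$mean_score_test <- mean(test_scores)
    row$mean_score_random <- mean(unlist(rand_scores))
    row$best_cutoff <- best_cutoff
    row$frac_recovered <- kf[best_cutoff]
    row$frac_top <- mean(!is.na(pct) & pct <= top_frac)
    row$roc_auc <- rp$roc_auc
    row$pr_auc <- rp$pr_auc
    rows[[it]] <- row
  }
  do.call(rbind, rows)
}
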