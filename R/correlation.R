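# Panel-wise SLC-metabolite Spearman correlation, BH adjustment, the
# per-metabolite standardized ("transformed") rho, and cross-panel
# concordance.

#' Correlate SLC expression with metabolite levels across a panel
#'
#' For every (SLC, metabolite) pair, Spearman's rank correlation is computed
#' across the cell lines shared by the expression and metabolite matrices,
#' using pairwise-complete values, average ranks for ties, and the
#' large-sample t approximation for the p-value. Pairs with fewer than
#' `min_overlap` complete observations are omitted (a message reports the
#' count); pairs where either variable is constant are emitted with missing
#' rho/p and a warning.
#'
#' @param expr [omics_matrix()] of normalized expression (genes x cell
#'   lines).
#' @param metab [omics_matrix()] of metabolite levels (metabolites x cell
#'   lines).
#' @param slc_ids SLC gene ids to correlate (must be rows of `expr`).
#' @param dataset_id label recorded in the `dataset_id` column.
#' @param min_overlap minimum number of complete shared cell lines per pair.
#' @return data frame of class `correlation_table` with columns `slc_id`,
#'   `metabolite_id`, `dataset_id`, `n_samples`, `rho`, `p`.
#' @export
correlate_panel <- function(expr, metab, slc_ids, dataset_id,
                            min_overlap = 10) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(metab, "omics_matrix"))
  slc_ids <- intersect(slc_ids, feature_ids(expr))
  shared <- intersect(sample_ids(expr), sample_ids(metab))
  if (length(shared) < min_overlap) {
    stop("only ", length(shared), " shared cell lines; need at least ",
         min_overlap, call. = FALSE)
  }
  ev <- expr$values[slc_ids, shared, drop = FALSE]
  mv <- metab$values[, shared, drop = FALSE]
  mets <- rownames(mv)
  n_dropped <- 0L
  n_constant <- 0L
  rows <- vector("list", length(slc_ids))
  for (i in seq_along(slc_ids)) {
    x <- ev[i, ]
    rho <- p <- rep(NA_real_, length(mets))
    nn <- integer(length(mets))
    keep <- rep(TRUE, length(mets))
    for (j in seq_along(mets)) {
      y <- mv[j, ]
      ok <- is.finite(x) & is.finite(y)
      nn[j] <- sum(ok)
      if (nn[j] < min_overlap) {
        keep[j] <- FALSE
        n_dropped <- n_dropped + 1L
        next
      }
      xs <- x[ok]; ys <- y[ok]
      if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
        n_constant <- n_constant + 1L
        next  # row kept with missing rho/p
      }
      ct <- cor.test(xs, ys, method = "spearman", exact = FALSE)
      rho[j] <- unname(ct$estimate)
      p[j] <- ct$p.value
    }
    rows[[i]] <- data.frame(
      slc_id = rep(slc_ids[i], sum(keep)), metabolite_id = mets[keep],
      dataset_id = rep(dataset_id, sum(keep)), n_samples = nn[keep],
      rho = rho[keep], p = p[keep], stringsAsFactors = FALSE
    )
  }
  if (n_dropped > 0L) {
    message(n_dropped, " pair(s) below the overlap threshold omitted")
  }
  if (n_constant > 0L) {
    warning(n_constant, " pair(s) with a constant variable: rho/p missing",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment within each (SLC, dataset) family
#'
#' Correlation p-values are adjusted per gene: the step-up procedure is
#' applied separately within every (slc_id, dataset_id) family across that
#' SLC's metabolites.
#'
#' @param table a `correlation_table` with a `p` column.
#' @return the table with a `p_adj` column added (input row order preserved).
#' @export
bh_adjust <- function(table) {
  require_columns(table, c("slc_id", "dataset_id", "p"), "correlation table")
  fam <- interaction(table$slc_id, table$dataset_id, drop = TRUE)
  table$p_adj <- NA_real_
  for (f in levels(fam)) {
    idx <- which(fam == f)
    table$p_adj[idx] <- p.adjust(table$p[idx], method = "BH")
  }
  table
}

#' Standardize absolute correlations per metabolite (transformed rho)
#'
#' Raw rho values are not comparable between metabolites because correlation
#' strength varies metabolite to metabolite. Within each (metabolite,
#' dataset), the absolute rho of a pair is centered by the mean and scaled by
#' the sample standard deviation of absolute rho over all SLCs, giving the
#' transformed rho used for thresholding and sub-scoring. Groups with fewer
#' than three finite rho values or zero spread yield missing transformed rho
#' with a warning.
#'
#' @param table a `correlation_table` with a `rho` column.
#' @return list with `table` (input plus `rho_transformed`) and `stats`
#'   (per-(metabolite, dataset) mean and sample SD of absolute rho).
#' @export
transform_rho <- function(table) {
  require_columns(table, c("metabolite_id", "dataset_id", "rho"),
                  "correlation table")
  key <- interaction(table$metabolite_id, table$dataset_id, drop = TRUE)
  table$rho_transformed <- NA_real_
  stats_rows <- vector("list", nlevels(key))
  n_degenerate <- 0L
  for (k in seq_len(nlevels(key))) {
    idx <- which(key == levels(key)[k])
    a <- abs(table$rho[idx])
    fin <- is.finite(a)
    mu <- mean(a[fin])
    sdv <- sd(a[fin])
    if (sum(fin) < 3L || !is.finite(sdv) || sdv == 0) {
      n_degenerate <- n_degenerate + 1L
      mu <- if (sum(fin) > 0L) mu else NA_real_
      sdv <- NA_real_
    } else {
      table$rho_transformed[idx] <- (a - mu) / sdv
    }
    stats_rows[[k]] <- data.frame(
      metabolite_id = table$metabolite_id[idx[1L]],
      dataset_id = table$dataset_id[idx[1L]],
      n_slcs = sum(fin), mean_abs_rho = mu, sd_abs_rho = sdv,
      stringsAsFactors = FALSE
    )
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " (metabolite, dataset) group(s) with <3 SLCs or ",
            "zero spread: transformed rho missing", call. = FALSE)
  }
  list(table = table, stats = do.call(rbind, stats_rows))
}

#' Concordance of two correlation tables
#'
#' Spearman correlation of the raw rho values of two panels over their
#' mutually overlapping (SLC, metabolite) pairs, optionally restricted to a
#' subset of pairs (e.g. the known set).
#'
#' @param a,b `correlation_table`s (single dataset each).
#' @param subset optional data frame with columns `slc_id`, `metabolite_id`
#'   restricting the comparison.
#' @return list with `rho`, `p` and `n_pairs`.
#' @export
dataset_concordance <- function(a, b, subset = NULL) {
  key <- function(d) paste(d$slc_id, d$metabolite_id, sep = "\r")
  m <- merge(a[c("slc_id", "metabolite_id", "rho")],
             b[c("slc_id", "metabolite_id", "rho")],
             by = c("slc_id", "metabolite_id"), suffixes = c("_a", "_b"))
  if (!is.null(subset)) {
    m <- m[key(m) %in% key(subset), , drop = FALSE]
  }
  m <- m[is.finite(m$rho_a) & is.finite(m$rho_b), , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("fewer than 3 overlapping pairs with finite rho", call. = FALSE)
  }
  ct <- cor.test(m$rho_a, m$rho_b, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(m))
}
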