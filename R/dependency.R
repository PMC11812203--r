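# CRISPR gene-dependency contrast: metabolite differences between the most-
# and least-dependent cell lines for each SLC.

#' Metabolite contrast between most- and least-dependent cell lines
#'
#' For each SLC, cell lines shared with the metabolite matrix and carrying a
#' negative gene-effect score (knockout reduces growth) are ranked by effect
#' score ascending. The first `floor(frac * n)` lines (most negative = most
#' dependent) form the top group and the last `floor(frac * n)` the bottom
#' group; ties in effect score are broken by cell-line id. Every metabolite's
#' z-scored levels are compared between the groups with a two-sided Wilcoxon
#' rank-sum test (exact for small tie-free groups, otherwise the normal
#' approximation with tie correction), and p-values are BH-adjusted across
#' metabolites within the SLC. SLCs with fewer than `min_lines` eligible
#' lines are skipped with a message.
#'
#' @param effect [omics_matrix()] of kind `"gene_effect"` (genes x cell
#'   lines).
#' @param metab_z [omics_matrix()] of kind `"metabolite_zscore"`.
#' @param slc_ids SLC gene ids to scan.
#' @param frac fraction of eligible lines in each extreme group (default
#'   0.2).
#' @param min_lines minimum number of eligible lines per SLC (default 10).
#' @return data frame of class `dependency_table` with columns `slc_id`,
#'   `metabolite_id`, `n_top`, `n_bottom`, `p`, `p_adj`, `direction` (sign of
#'   the top-vs-bottom median shift).
#' @export
dependency_scan <- function(effect, metab_z, slc_ids, frac = 0.2,
                            min_lines = 10) {
  stopifnot(inherits(effect, "omics_matrix"), inherits(metab_z, "omics_matrix"))
  if (effect$kind != "gene_effect") {
    stop("expected a gene_effect matrix", call. = FALSE)
  }
  shared <- intersect(sample_ids(effect), sample_ids(metab_z))
  slc_ids <- intersect(slc_ids, feature_ids(effect))
  mets <- feature_ids(metab_z)
  out <- vector("list", length(slc_ids))
  n_skipped <- 0L
  n_sparse <- 0L
  for (i in seq_along(slc_ids)) {
    slc <- slc_ids[i]
    es <- effect$values[slc, shared]
    eligible <- shared[is.finite(es) & es < 0]
    if (length(eligible) < min_lines) {
      n_skipped <- n_skipped + 1L
      next
    }
    es <- effect$values[slc, eligible]
    ord <- order_stable(es, eligible)
    k <- floor(frac * length(eligible))
    top <- eligible[ord][seq_len(k)]
    bottom <- eligible[ord][seq.int(length(eligible) - k + 1L, length(eligible))]
    p <- rep(NA_real_, length(mets))
    direction <- rep(NA_real_, length(mets))
    for (j in seq_along(mets)) {
      x <- metab_z$values[mets[j], top]
      y <- metab_z$values[mets[j], bottom]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2L || length(y) < 2L) {
        n_sparse <- n_sparse + 1L
        next
      }
      if (length(unique(c(x, y))) == 1L) {
        p[j] <- 1
        direction[j] <- 0
        next
      }
      p[j] <- suppressWarnings(wilcox.test(x, y)$p.value)
      direction[j] <- sign(median(x) - median(y))
    }
    out[[i]] <- data.frame(
      slc_id = slc, metabolite_id = mets, n_top = k, n_bottom = k,
      p = p, p_adj = p.adjust(p, method = "BH"), direction = direction,
      stringsAsFactors = FALSE
    )
  }
  if (n_skipped > 0L) {
    message(n_skipped, " SLC(s) skipped: fewer than ", min_lines,
            " cell lines with negative effect scores")
  }
  if (n_sparse > 0L) {
    warning(n_sparse, " (SLC, metabolite) contrast(s) with <2 finite values ",
            "per group: p missing", call. = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(slc_id = character(), metabolite_id = character(),
                      n_top = integer(), n_bottom = integer(), p = numeric(),
                      p_adj = numeric(), direction = numeric(),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("dependency_table", "data.frame")
  out
}
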