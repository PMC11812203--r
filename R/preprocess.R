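# Count normalization and tissue-wise metabolite standardization.

#' Median-ratio normalization of RNA-Seq counts
#'
#' Library-size correction by the median-of-ratios method: each sample's size
#' factor is the median, over genes with a strictly positive geometric mean
#' across samples, of the ratio of its count to that geometric mean.
#' Pseudocounts are counts divided by the sample's factor. Genes whose total
#' across samples falls below `min_total` are dropped before factor
#' estimation and from the output. Factor estimation is delegated to the
#' median-of-ratios implementation in DESeq2 (log-space geometric means;
#' genes containing a zero are excluded from the median but retained in the
#' output).
#'
#' @param counts an [omics_matrix()] of kind `"counts"` with no missing
#'   values and at least two samples.
#' @param min_total minimum per-gene total across samples (default 10).
#' @return list with `pseudocounts` (an [omics_matrix()] of kind
#'   `"pseudocounts"`) and `size_factors` (named numeric, one per sample).
#' @export
mrn_normalize <- function(counts, min_total = 10) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$kind != "counts") stop("expected a counts matrix", call. = FALSE)
  v <- counts$values
  if (anyNA(v)) stop("counts must be complete for normalization", call. = FALSE)
  if (ncol(v) < 2L) stop("need at least two samples", call. = FALSE)
  v <- v[rowSums(v) >= min_total, , drop = FALSE]
  if (nrow(v) == 0L) {
    stop("normalization error: no gene passes the total-count filter",
         call. = FALSE)
  }
  log_geo <- rowMeans(log(v))
  if (!any(is.finite(log_geo))) {
    stop("normalization error: no gene with a strictly positive geometric ",
         "mean across samples", call. = FALSE)
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(v)
  bad <- names(sf)[!is.finite(sf) | sf <= 0]
  if (length(bad) > 0L) {
    stop("normalization error: zero median ratio for sample(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pseudo <- sweep(v, 2L, sf, "/")
  list(
    pseudocounts = omics_matrix(pseudo, "pseudocounts",
                                counts$sample_annotations),
    size_factors = sf
  )
}

#' Tissue-wise z-scoring of metabolite levels
#'
#' Within each tissue group, each metabolite's values are centered by the
#' group mean and scaled by the group sample standard deviation (n - 1
#' denominator), computed over non-missing values, removing tissue-specific
#' baseline differences before dependency contrasts. Groups with fewer than
#' two finite values, or with zero spread, yield missing z-scores for that
#' (tissue, metabolite) with a warning rather than an error.
#'
#' @param metab an [omics_matrix()] of kind `"metabolite_level"`.
#' @param tissue_map named character vector mapping every sample id to a
#'   tissue label.
#' @return an [omics_matrix()] of kind `"metabolite_zscore"`.
#' @export
tissue_zscore <- function(metab, tissue_map) {
  stopifnot(inherits(metab, "omics_matrix"))
  samples <- sample_ids(metab)
  missing_lab <- setdiff(samples, names(tissue_map))
  if (length(missing_lab) > 0L) {
    stop("no tissue label for sample(s): ",
         paste(head(missing_lab, 5L), collapse = ", "), call. = FALSE)
  }
  tissues <- as.character(tissue_map[samples])
  out <- metab$values
  n_degenerate <- 0L
  for (tis in unique(tissues)) {
    idx <- which(tissues == tis)
    block <- metab$values[, idx, drop = FALSE]
    mu <- rowMeans(block, na.rm = TRUE)
    sdv <- apply(block, 1L, sd, na.rm = TRUE)
    n_fin <- rowSums(is.finite(block))
    degenerate <- n_fin < 2L | !is.finite(sdv) | sdv == 0
    z <- (block - mu) / sdv
    z[degenerate, ] <- NA_real_
    out[, idx] <- z
    n_degenerate <- n_degenerate + sum(degenerate)
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " (tissue, metabolite) group(s) with <2 values or ",
            "zero spread set to missing", call. = FALSE)
  }
  omics_matrix(out, "metabolite_zscore",
               setNames(tissues, samples))
}
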