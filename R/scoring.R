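# The confidence score: threshold-of-discovery gating, decile sub-scores
# against the known-pair distribution, adjacency aggregation, and the
# weighted combination across evidence sources.
#
# ToD and ToD' are tuned independently per dataset, so ToD' may exceed ToD
# (it does for two of the three public panels); the half-point band of the
# adjacency sub-score is then empty and values below ToD' score 0.

#' Confidence-score parameters
#'
#' Bundles the per-dataset thresholds of discovery (`tod`, on transformed
#' rho), the lower adjacency thresholds (`tod_prime`, half-point band
#' between `tod_prime` and `tod`), the CRISPR adjusted-p cutoff, the three
#' evidence weights and the adjacency radius. [default_score_params()]
#' returns the tuned values used for the three public panels: ToD 0.0
#' (NCI60), 0.0 (CCLE2019), 1.0 (CCL180); ToD' 0.1, 0.1, 0.2; CRISPR cutoff
#' 0.16; a = 3, b = 1, c = 1; radius 2.
#'
#' @param tod named numeric: threshold of discovery per dataset.
#' @param tod_prime named numeric: adjacency threshold per dataset; must not
#'   exceed the matching `tod`.
#' @param crispr_p_cutoff adjusted-p cutoff for the gene-dependency
#'   sub-score, in (0, 1].
#' @param weight_a,weight_b,weight_c non-negative weights for the cell-panel
#'   sum, the gene-dependency sub-score and the adjacency score.
#' @param adjacency_radius positive integer radius in conversion steps.
#' @return list of class `score_params`.
#' @export
score_params <- function(tod, tod_prime, crispr_p_cutoff = 0.16,
                         weight_a = 3, weight_b = 1, weight_c = 1,
                         adjacency_radius = 2) {
  if (is.null(names(tod)) || is.null(names(tod_prime))) {
    stop("tod and tod_prime must be named by dataset", call. = FALSE)
  }
  if (!setequal(names(tod), names(tod_prime))) {
    stop("tod and tod_prime must cover the same datasets", call. = FALSE)
  }
  if (crispr_p_cutoff <= 0 || crispr_p_cutoff > 1) {
    stop("crispr_p_cutoff must be in (0, 1]", call. = FALSE)
  }
  if (min(weight_a, weight_b, weight_c) < 0) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (adjacency_radius < 1) stop("adjacency_radius must be >= 1", call. = FALSE)
  structure(list(tod = tod, tod_prime = tod_prime,
                 crispr_p_cutoff = crispr_p_cutoff,
                 weight_a = weight_a, weight_b = weight_b,
                 weight_c = weight_c,
                 adjacency_radius = as.integer(adjacency_radius)),
            class = "score_params")
}

#' @rdname score_params
#' @export
default_score_params <- function() {
  score_params(
    tod = c(NCI60 = 0.0, CCLE2019 = 0.0, CCL180 = 1.0),
    tod_prime = c(NCI60 = 0.1, CCLE2019 = 0.1, CCL180 = 0.2),
    crispr_p_cutoff = 0.16,
    weight_a = 3, weight_b = 1, weight_c = 1,
    adjacency_radius = 2
  )
}

#' Decile quantile array of the known-pair value distribution
#'
#' Eleven quantiles (0th to 100th percentile in 10% steps, linear
#' interpolation between order statistics) of the values observed for known
#' pairs, with the 0th percentile overridden by the threshold of discovery.
#' Interior quantiles falling below the threshold are raised to it so the
#' array stays non-decreasing; intervals below the threshold are unreachable
#' anyway because values under it score zero. A threshold above the maximum
#' known value leaves no valid interval and is an error.
#'
#' @param values finite known-pair values (at least 11).
#' @param tod threshold of discovery.
#' @return numeric vector of length 11, class `quantile_array`, attribute
#'   `tod`.
#' @export
known_quantiles <- function(values, tod) {
  values <- values[is.finite(values)]
  if (length(values) < 11L) {
    stop("need at least 11 finite known values, got ", length(values),
         call. = FALSE)
  }
  q <- unname(quantile(values, probs = seq(0, 1, 0.1), type = 7))
  if (tod > q[11L]) {
    stop("threshold of discovery ", tod, " exceeds the known maximum ",
         q[11L], ": quantile array would be non-monotone", call. = FALSE)
  }
  q[1L] <- tod
  q[q < tod] <- tod
  structure(q, class = "quantile_array", tod = tod)
}

#' Decile sub-score of a value against the known-pair distribution
#'
#' Zero below the threshold of discovery; otherwise the index j of the
#' interval `q[j-1] <= v < q[j]` of the known-pair quantile array (1 to 10),
#' capped at 11 for values at or above the known maximum. Missing values
#' score 0.
#'
#' @param v numeric vector of values (transformed rho, or -log10 adjusted p
#'   for the gene-dependency source).
#' @param tod threshold of discovery.
#' @param q a [known_quantiles()] array built with the same `tod`.
#' @return integer vector of sub-scores in 0..11.
#' @export
subscore <- function(v, tod, q) {
  s <- pmin(findInterval(v, q), 11L)
  s[!is.finite(v) | v < tod] <- 0L
  as.integer(s)
}

#' Piecewise adjacency sub-score
#'
#' Correlations to metabolites adjacent to the candidate substrate are scored
#' against the same known-pair quantile array, but with a softer gate: values
#' in the half-point band `tod_prime < v <= tod` contribute 0.5, values above
#' `tod` contribute their decile interval index (capped at 11), and values at
#' or below `tod_prime` (or missing) contribute 0. The zero branch takes
#' precedence, so when `tod_prime > tod` (the thresholds are tuned
#' independently) the half-point band is empty and everything up to
#' `tod_prime` scores 0.
#'
#' @param v numeric vector of transformed rho values of SLC-neighbor pairs.
#' @param tod,tod_prime per-dataset thresholds.
#' @param q a [known_quantiles()] array for the dataset.
#' @return numeric vector with values in `{0, 0.5, 1, ..., 11}`.
#' @export
adjacency_subscore <- function(v, tod, tod_prime, q) {
  v[!is.finite(v)] <- -Inf  # missing never contributes
  s <- pmin(findInterval(v, q), 11)
  s[v <= tod] <- 0.5
  s[v <= tod_prime] <- 0
  s
}

#' Confidence scores for SLC-metabolite pairs
#'
#' Combines the evidence sources into
#' `confidence = a * (sum of per-dataset sub-scores) + b * gene_dep + c * adjacency`.
#' Per dataset, the transformed rho of each pair is sub-scored against the
#' decile quantile array of the known pairs measured in that dataset
#' ([known_quantiles()] with the dataset's threshold of discovery). The
#' gene-dependency sub-score uses `-log10(p_adj)` from the dependency scan,
#' scored against the known pairs' `-log10(p_adj)` distribution with the
#' `-log10` of the CRISPR cutoff as threshold, and only when
#' `p_adj < crispr_p_cutoff`. The adjacency score of a pair sums, over
#' datasets and over metabolites within `adjacency_radius` conversion steps
#' of the candidate substrate that are measured in that dataset, the
#' [adjacency_subscore()] of the SLC-neighbor transformed rho (the candidate
#' itself, distance 0, never contributes). Missing evidence contributes 0.
#'
#' @param corr a `correlation_table` covering all datasets, with
#'   `rho_transformed` (see [transform_rho()]).
#' @param known a [known_pair_table()]; metabolite rows define the known set.
#' @param params a [score_params()].
#' @param dep optional `dependency_table` from [dependency_scan()].
#' @param adj optional `adjacency_matrix` from [conversion_distances()].
#' @return data frame of class `confidence_table`: one row per (slc_id,
#'   metabolite_id) present in `corr`, with one `subscore_<dataset>` column
#'   per dataset, `cell_panel_score`, `gene_dep_subscore`, `adjacency_score`
#'   and `confidence`.
#' @export
confidence_scores <- function(corr, known, params, dep = NULL, adj = NULL) {
  stopifnot(inherits(params, "score_params"))
  require_columns(corr, c("slc_id", "metabolite_id", "dataset_id",
                          "rho_transformed"), "correlation table")
  datasets <- intersect(names(params$tod), unique(corr$dataset_id))
  if (length(datasets) == 0L) {
    stop("no dataset in the correlation table matches the parameters",
         call. = FALSE)
  }
  known <- known[known$target_kind == "metabolite", , drop = FALSE]
  known_key <- paste(known$slc_id, known$target_id, sep = "\r")
  pair_key <- paste(corr$slc_id, corr$metabolite_id, sep = "\r")

  # per-dataset value matrices (SLC x metabolite) and known quantile arrays
  slcs <- unique(corr$slc_id)
  mets <- unique(corr$metabolite_id)
  vmat <- list()
  qarr <- list()
  for (d in datasets) {
    sub <- corr[corr$dataset_id == d, , drop = FALSE]
    m <- matrix(NA_real_, length(slcs), length(mets),
                dimnames = list(slcs, mets))
    m[cbind(sub$slc_id, sub$metabolite_id)] <- sub$rho_transformed
    vmat[[d]] <- m
    kv <- sub$rho_transformed[paste(sub$slc_id, sub$metabolite_id,
                                    sep = "\r") %in% known_key]
    kv <- kv[is.finite(kv)]
    if (length(kv) == 0L) {
      stop("no known-pair values measured in dataset ", d, call. = FALSE)
    }
    qarr[[d]] <- known_quantiles(kv, params$tod[[d]])
  }

  pairs <- unique(corr[c("slc_id", "metabolite_id")])
  res <- data.frame(slc_id = pairs$slc_id,
                    metabolite_id = pairs$metabolite_id,
                    stringsAsFactors = FALSE)
  sub_sum <- numeric(nrow(res))
  for (d in datasets) {
    v <- vmat[[d]][cbind(res$slc_id, res$metabolite_id)]
    s <- subscore(v, params$tod[[d]], qarr[[d]])
    res[[paste0("subscore_", d)]] <- s
    sub_sum <- sub_sum + s
  }
  res$cell_panel_score <- params$weight_a * sub_sum

  # gene-dependency sub-score on -log10 adjusted p
  res$gene_dep_subscore <- 0L
  if (!is.null(dep) && nrow(dep) > 0L) {
    dep_key <- paste(dep$slc_id, dep$metabolite_id, sep = "\r")
    kv <- -log10(dep$p_adj[dep_key %in% known_key])
    kv <- kv[is.finite(kv)]
    tod_g <- -log10(params$crispr_p_cutoff)
    if (length(kv) == 0L) {
      stop("no known-pair values in the dependency table", call. = FALSE)
    }
    q_g <- known_quantiles(kv, tod_g)
    idx <- match(paste(res$slc_id, res$metabolite_id, sep = "\r"), dep_key)
    p_adj <- dep$p_adj[idx]
    v <- ifelse(!is.na(p_adj) & p_adj < params$crispr_p_cutoff,
                -log10(p_adj), NA_real_)
    res$gene_dep_subscore <- subscore(v, tod_g, q_g)
  }

  # adjacency score: neighbors within radius, per dataset where measured
  res$adjacency_score <- 0
  if (!is.null(adj)) {
    nb_cache <- new.env(parent = emptyenv())
    get_nb <- function(met) {
      if (!is.null(nb_cache[[met]])) return(nb_cache[[met]])
      nb <- if (met %in% rownames(adj)) {
        intersect(neighbors_within(adj, met, params$adjacency_radius), mets)
      } else character(0)
      nb_cache[[met]] <- nb
      nb
    }
    adj_score <- numeric(nrow(res))
    for (i in seq_len(nrow(res))) {
      nb <- get_nb(res$metabolite_id[i])
      if (length(nb) == 0L) next
      total <- 0
      for (d in datasets) {
        v <- vmat[[d]][res$slc_id[i], nb]
        total <- total + sum(adjacency_subscore(
          v, params$tod[[d]], params$tod_prime[[d]], qarr[[d]]))
      }
      adj_score[i] <- total
    }
    res$adjacency_score <- adj_score
  }

  res$confidence <- res$cell_panel_score +
    params$weight_b * res$gene_dep_subscore +
    params$weight_c * res$adjacency_score
  res$known <- paste(res$slc_id, res$metabolite_id, sep = "\r") %in% known_key
  class(res) <- c("confidence_table", "data.frame")
  res
}
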