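# Shared fixtures. Expensive objects (the default synthetic panel and the
# scores computed from it) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_once <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

make_om <- function(values, kind = "metabolite_level", features = NULL,
                    samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  rownames(values) <- features %||% sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  omics_matrix(values, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The printed worked example: one candidate pair with transformed rho
# (-0.97, 0.96, 0.019) across the three panels, an adjusted dependency p of
# 9.7e-5, and six measured neighbors. Known-pair values are chosen so the
# candidate falls in the printed decile intervals: CCLE2019 in [50%, 60%),
# gene dependency in [70%, 80%), two NCI60 neighbors in [80%, 90%), two
# CCLE2019 neighbors in [80%, 90%), one CCL180 neighbor in the half-point
# band and one in [90%, 100%).
worked_example_fixture <- function() {
  known_vals <- list(
    NCI60    = c(-1.0, -0.6, -0.2, 0.2, 0.5, 0.8, 1.1, 1.5, 1.9, 2.4, 3.0),
    CCLE2019 = c(-0.5, 0.1, 0.4, 0.6, 0.7, 0.9, 1.0, 1.3, 1.7, 2.2, 3.0),
    CCL180   = c(0.1, 0.3, 0.5, 0.8, 1.1, 1.4, 1.7, 2.0, 2.4, 2.8, 3.4))
  kslc <- sprintf("KSLC%02d", 1:11)
  kmet <- sprintf("KMET%02d", 1:11)
  corr <- do.call(rbind, lapply(names(known_vals), function(d) {
    data.frame(slc_id = kslc, metabolite_id = kmet, dataset_id = d,
               n_samples = 60L, rho = NA_real_, p = NA_real_,
               p_adj = NA_real_, rho_transformed = known_vals[[d]],
               stringsAsFactors = FALSE)
  }))
  target <- data.frame(
    slc_id = "SLCQ", metabolite_id = "glutamate",
    dataset_id = c("NCI60", "CCLE2019", "CCL180"), n_samples = 60L,
    rho = NA_real_, p = NA_real_, p_adj = NA_real_,
    rho_transformed = c(-0.97, 0.96, 0.019), stringsAsFactors = FALSE)
  neighbors <- data.frame(
    slc_id = "SLCQ",
    metabolite_id = c("nb1", "nb2", "nb3", "nb4", "nb5", "nb6"),
    dataset_id = c("NCI60", "NCI60", "CCLE2019", "CCLE2019", "CCL180",
                   "CCL180"),
    n_samples = 60L, rho = NA_real_, p = NA_real_, p_adj = NA_real_,
    rho_transformed = c(2.0, 2.1, 1.8, 1.9, 0.6, 3.0),
    stringsAsFactors = FALSE)
  corr <- rbind(corr, target, neighbors)
  class(corr) <- c("correlation_table", "data.frame")
  known <- known_pair_table(data.frame(
    slc_id = kslc, target_id = kmet, target_kind = "metabolite",
    stringsAsFactors = FALSE))
  dep <- data.frame(
    slc_id = c(kslc, "SLCQ"), metabolite_id = c(kmet, "glutamate"),
    n_top = 20L, n_bottom = 20L,
    p_adj = 10^(-c(0.9, 1.2, 1.5, 1.9, 2.3, 2.8, 3.3, 3.9, 4.2, 4.8, 5.5,
                   -log10(9.7e-5))),
    stringsAsFactors = FALSE)
  dep$p <- dep$p_adj
  graph <- reaction_graph(data.frame(
    from = c("glutamate", "glutamate", "glutamate", "nb3", "glutamate", "nb5"),
    to = c("nb1", "nb2", "nb3", "nb4", "nb5", "nb6"),
    stringsAsFactors = FALSE))
  list(corr = corr, known = known, dep = dep,
       adj = conversion_distances(graph),
       params = default_score_params())
}

# Default synthetic study panel and everything the scoring pipeline derives
# from it.
get_default_panel <- function() {
  cache_once("panel", function() synth_panel(synth_config(seed = 101)))
}

get_default_scores <- function() {
  cache_once("scores", function() {
    panel <- get_default_panel()
    norm <- mrn_normalize(panel$counts)
    slcs <- grep("^SLC", feature_ids(norm$pseudocounts), value = TRUE)
    corr <- do.call(rbind, lapply(names(panel$metab), function(d) {
      bh_adjust(correlate_panel(norm$pseudocounts, panel$metab[[d]], slcs,
                                dataset_id = d))
    }))
    corr <- transform_rho(corr)$table
    mz <- tissue_zscore(panel$metab$CCLE2019, panel$tissue_map)
    dep <- suppressMessages(dependency_scan(panel$gene_effect, mz, slcs))
    adj <- conversion_distances(panel$graph)
    conf <- confidence_scores(corr, panel$known, default_score_params(),
                              dep = dep, adj = adj)
    list(panel = panel, corr = corr, dep = dep, adj = adj, conf = conf)
  })
}

# Small drug panel with planted shifts for the dose-response module.
get_drug_fixture <- function() {
  cache_once("drug", function() {
    config <- synth_config(n_cell_lines = 120, n_tissues = 3, n_slcs = 13,
                           n_background_genes = 60, n_planted_pairs = 11,
                           n_background_metabolites = 20, n_drugs = 4,
                           n_planted_drug_pairs = 2, drug_shift = 1.0,
                           noise_sd = 0.1, seed = 202)
    panel <- synth_panel(config)
    norm <- mrn_normalize(panel$counts)
    drug <- synth_drug_panel(config, norm$pseudocounts)
    list(config = config, expr = norm$pseudocounts, panel = drug$panel,
         truth = drug$truth)
  })
}
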