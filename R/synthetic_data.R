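# Seeded generator for synthetic panels carrying the statistical structure
# the prediction method assumes: library-size variation in counts, planted
# monotone expression-metabolite dependence at a target Spearman rho, tissue
# structure, derivative propagation along a known reaction graph, dependency
# coupling, and partially overlapping dataset subsets.

SYNTH_DATASETS <- c("CCLE2019", "NCI60", "CCL180")

#' Configuration for the synthetic panel generator
#'
#' Defaults describe the study conditions the test-bench panels emulate: 200
#' cell lines over 4 tissues, 30 SLC genes (20 of them planted with a true
#' substrate at target absolute Spearman rho 0.6), two derivative metabolites
#' per substrate decaying along the reaction graph, 50 unrelated background
#' metabolites, three panel replicates with partially overlapping cell-line
#' subsets, and a small drug screen with planted dose-response shifts.
#'
#' @param n_cell_lines,n_tissues panel size and tissue groups.
#' @param n_slcs,n_background_genes SLC genes and filler genes (the filler
#'   stabilizes median-ratio normalization).
#' @param n_planted_pairs SLCs given a true substrate (must not exceed
#'   `n_slcs`).
#' @param n_derivatives derivative metabolites chained to each substrate.
#' @param n_background_metabolites metabolites independent of every SLC.
#' @param target_abs_rho target absolute Spearman correlation of planted
#'   pairs, in (0, 1).
#' @param derivative_decay latent correlation decay per conversion step, in
#'   (0, 1].
#' @param measurement_reliability latent-to-observation correlation of each
#'   dataset's metabolite measurement.
#' @param tissue_sd SD of tissue-specific metabolite offsets.
#' @param count_dispersion negative-binomial dispersion of counts.
#' @param library_size_range uniform range of per-sample library factors.
#' @param dataset_fraction fraction of cell lines measured in each dataset.
#' @param n_drugs,n_planted_drug_pairs drug screen size and planted
#'   SLC-drug pairs.
#' @param drug_shift planted viability offset (log-fold) between high- and
#'   low-expression lines.
#' @param noise_sd viability measurement noise SD.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cell_lines = 200, n_tissues = 4, n_slcs = 30,
                         n_background_genes = 170, n_planted_pairs = 20,
                         n_derivatives = 2, n_background_metabolites = 50,
                         target_abs_rho = 0.6, derivative_decay = 0.7,
                         measurement_reliability = 0.95, tissue_sd = 0.3,
                         count_dispersion = 0.15,
                         library_size_range = c(0.5, 2),
                         dataset_fraction = 0.85, n_drugs = 6,
                         n_planted_drug_pairs = 3, drug_shift = 1.0,
                         noise_sd = 0.1, seed = 1) {
  if (n_planted_pairs > n_slcs) {
    stop("n_planted_pairs must not exceed n_slcs", call. = FALSE)
  }
  if (target_abs_rho <= 0 || target_abs_rho >= 1) {
    stop("target_abs_rho must be in (0, 1)", call. = FALSE)
  }
  if (derivative_decay <= 0 || derivative_decay > 1) {
    stop("derivative_decay must be in (0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

# Latent pearson correlation needed so the observed pair reaches the target
# Spearman rho. The observed correlation is attenuated by count noise,
# measurement reliability and tissue offsets; the bivariate-normal link
# rho_s = (6/pi) asin(r/2) converts pearson to Spearman. Solved by bisection
# (uniroot); a target beyond what the noise admits is an error.
calibrate_latent_cor <- function(target, attenuation) {
  f <- function(r) (6 / pi) * asin(attenuation * r / 2) - target
  if (f(1) < 0) {
    stop("unattainable target_abs_rho ", target, ": maximum reachable ",
         "Spearman rho under the configured noise is ",
         round((6 / pi) * asin(attenuation / 2), 3), call. = FALSE)
  }
  uniroot(f, c(0, 1), tol = 1e-9)$root
}

#' Generate a synthetic multi-omics panel
#'
#' Produces every input the scoring pipeline consumes: a counts matrix with
#' library-size variation, three metabolite panels drawn from shared latent
#' metabolite levels with independent measurement noise and partially
#' overlapping cell-line subsets, a tissue map, the known-pair table of
#' planted substrates, the reaction graph (a substrate-derivative chain per
#' planted pair plus a random background network), a gene-effect matrix whose
#' negative scores track substrate dependence for planted SLCs, and a pathway
#' table. Deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `counts`, `metab` (named list of
#'   [omics_matrix()], one per dataset), `tissue_map`, `known`, `graph`,
#'   `gene_effect`, `pathways`, `truth` (planted pairs with signs) and
#'   `config`.
#' @export
synth_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cell_lines
  lines <- sprintf("CL%03d", seq_len(n))
  tissue_map <- setNames(
    sprintf("tissue%02d", rep_len(seq_len(config$n_tissues), n)), lines)

  slcs <- sprintf("SLC%02d", seq_len(config$n_slcs))
  bg_genes <- sprintf("GENE%03d", seq_len(config$n_background_genes))
  genes <- c(slcs, bg_genes)

  # latent per-gene drivers and negative-binomial counts with library factors
  sd_g <- 1.2
  z <- matrix(rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, lines))
  mu_g <- setNames(c(rep(6, length(slcs)),
                     runif(length(bg_genes), 1, 7)), genes)
  lib <- runif(n, config$library_size_range[1], config$library_size_range[2])
  mu <- exp(mu_g + sd_g * z) * rep(lib, each = length(genes))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$count_dispersion),
                   length(genes), n, dimnames = list(genes, lines))

  # attenuation budget: count noise, measurement noise, tissue offsets
  expr_att <- sd_g / sqrt(sd_g^2 + config$count_dispersion + exp(-6))
  rel <- config$measurement_reliability
  atten <- expr_att * rel / sqrt(1 + config$tissue_sd^2)
  rho_latent <- calibrate_latent_cor(config$target_abs_rho, atten)

  # latent metabolite levels shared across datasets
  planted_slcs <- slcs[seq_len(config$n_planted_pairs)]
  subs <- sprintf("MET_SUB%02d", seq_len(config$n_planted_pairs))
  sign_k <- sample(c(-1, 1), config$n_planted_pairs, replace = TRUE)
  derivs <- if (config$n_derivatives > 0) {
    outer(seq_len(config$n_planted_pairs), seq_len(config$n_derivatives),
          function(k, s) sprintf("MET_D%d_%02d", s, k))
  } else NULL
  bg_mets <- sprintf("MET_BG%02d", seq_len(config$n_background_metabolites))
  mets <- c(subs, as.vector(derivs), bg_mets)

  latent <- matrix(NA_real_, length(mets), n, dimnames = list(mets, lines))
  for (k in seq_len(config$n_planted_pairs)) {
    zs <- z[planted_slcs[k], ]
    latent[subs[k], ] <- sign_k[k] *
      (rho_latent * zs + sqrt(1 - rho_latent^2) * rnorm(n))
    parent <- latent[subs[k], ]
    for (s in seq_len(config$n_derivatives)) {
      child <- config$derivative_decay * parent +
        sqrt(1 - config$derivative_decay^2) * rnorm(n)
      latent[derivs[k, s], ] <- child
      parent <- child
    }
  }
  latent[bg_mets, ] <- rnorm(length(bg_mets) * n)

  # per-metabolite tissue offsets standardized to exact spread tissue_sd so
  # the attenuation entering the calibration is the same for every pair
  tissue_off <- matrix(rnorm(length(mets) * config$n_tissues),
                       length(mets), config$n_tissues,
                       dimnames = list(mets, NULL))
  if (config$n_tissues >= 2L) {
    tissue_off <- t(apply(tissue_off, 1L, function(o) {
      (o - mean(o)) / sd(o) * config$tissue_sd
    }))
  } else {
    tissue_off[] <- 0
  }
  tissue_idx <- as.integer(factor(tissue_map[lines],
                                  levels = sort(unique(tissue_map))))

  metab <- list()
  for (d in SYNTH_DATASETS) {
    sub_lines <- sort(sample(lines, round(config$dataset_fraction * n)))
    obs <- rel * latent[, sub_lines, drop = FALSE] +
      sqrt(1 - rel^2) * matrix(rnorm(length(mets) * length(sub_lines)),
                               length(mets), length(sub_lines)) +
      tissue_off[, tissue_idx[match(sub_lines, lines)], drop = FALSE]
    metab[[d]] <- omics_matrix(obs, "metabolite_level",
                               tissue_map[sub_lines])
  }

  # gene effect: planted SLCs are depended on by their high-expression lines
  ge <- matrix(-0.3 + 0.3 * rnorm(length(slcs) * n), length(slcs), n,
               dimnames = list(slcs, lines))
  for (k in seq_len(config$n_planted_pairs)) {
    ge[planted_slcs[k], ] <- -(0.8 + 0.4 * z[planted_slcs[k], ]) +
      0.2 * rnorm(n)
  }

  # reaction graph: one substrate-derivative chain per planted pair,
  # plus a random tree with extra edges over background metabolites
  edges <- list()
  for (k in seq_len(config$n_planted_pairs)) {
    chain <- c(subs[k], derivs[k, ])
    if (length(chain) > 1L) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = chain[-length(chain)], to = chain[-1L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(bg_mets) > 1L) {
    parent <- vapply(seq_along(bg_mets)[-1L],
                     function(i) bg_mets[sample.int(i - 1L, 1L)], character(1))
    edges[[length(edges) + 1L]] <- data.frame(from = parent,
                                              to = bg_mets[-1L],
                                              stringsAsFactors = FALSE)
    extra <- min(10L, length(bg_mets))
    a <- sample(bg_mets, extra)
    b <- sample(bg_mets, extra)
    keep <- a != b
    edges[[length(edges) + 1L]] <- data.frame(from = a[keep], to = b[keep],
                                              stringsAsFactors = FALSE)
  }
  graph <- reaction_graph(unique(do.call(rbind, edges)), nodes = mets)

  known <- known_pair_table(data.frame(
    slc_id = planted_slcs, target_id = subs, target_kind = "metabolite",
    evidence = "planted", stringsAsFactors = FALSE))

  pw <- rbind(
    data.frame(pathway_id = rep(sprintf("PW_SUB%02d",
                                        seq_len(config$n_planted_pairs)),
                                each = 1L + config$n_derivatives),
               metabolite_id = as.vector(t(cbind(subs, derivs))),
               stringsAsFactors = FALSE),
    data.frame(pathway_id = sprintf("PW_BG%02d",
                                    (seq_along(bg_mets) - 1L) %/% 10L + 1L),
               metabolite_id = bg_mets, stringsAsFactors = FALSE))

  list(counts = omics_matrix(counts, "counts", tissue_map),
       metab = metab, tissue_map = tissue_map, known = known, graph = graph,
       gene_effect = omics_matrix(ge, "gene_effect", tissue_map),
       pathways = pathway_table(pw),
       truth = data.frame(slc_id = planted_slcs, metabolite_id = subs,
                          sign = sign_k, target_abs_rho = config$target_abs_rho,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Generate a synthetic drug-viability panel
#'
#' Log-fold viability follows a four-parameter logistic in log10 dose at the
#' 8 assay doses, with Gaussian measurement noise. For each planted
#' (SLC, drug) pair the curve is shifted vertically by half the configured
#' `drug_shift` upward for the top-expression fifth of cell lines and
#' downward for the bottom fifth, so the high-vs-low predicted-curve mean
#' difference recovers the shift; the sign alternates between planted pairs
#' (attenuating, then sensitising). Deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @param expr [omics_matrix()] of expression for the same cell lines
#'   (counts or pseudocounts; only ranks are used).
#' @return list with `panel` (a [drug_panel()]) and `truth` (planted
#'   SLC-drug pairs with their signed shifts).
#' @export
synth_drug_panel <- function(config, expr) {
  stopifnot(inherits(config, "synth_config"), inherits(expr, "omics_matrix"))
  set.seed(config$seed + 1L)
  lines <- sample_ids(expr)
  n <- length(lines)
  drugs <- sprintf("DRUG%02d", seq_len(config$n_drugs))
  slcs <- feature_ids(expr)
  n_plant <- min(config$n_planted_drug_pairs, config$n_drugs, length(slcs))
  truth <- data.frame(slc_id = slcs[seq_len(n_plant)],
                      drug_id = drugs[seq_len(n_plant)],
                      shift = config$drug_shift * (-1)^(seq_len(n_plant) + 1L),
                      stringsAsFactors = FALSE)
  rows <- vector("list", config$n_drugs)
  for (i in seq_along(drugs)) {
    ec50 <- runif(1, -1.5, 0)
    hill <- runif(1, 0.8, 1.5)
    maxkill <- runif(1, 1.5, 3)
    base <- -maxkill / (1 + 10^(-hill * (ASSAY_DOSES - ec50)))
    shift_line <- setNames(numeric(n), lines)
    hit <- which(truth$drug_id == drugs[i])
    if (length(hit) == 1L) {
      grp <- expression_groups(expr, truth$slc_id[hit], frac = 0.2,
                               lines = lines)
      shift_line[grp$high] <- truth$shift[hit] / 2
      shift_line[grp$low] <- -truth$shift[hit] / 2
    }
    vi <- outer(shift_line, base, "+") +
      matrix(rnorm(n * length(ASSAY_DOSES), sd = config$noise_sd),
             n, length(ASSAY_DOSES))
    rows[[i]] <- data.frame(
      drug_id = drugs[i],
      cell_line = rep(lines, times = length(ASSAY_DOSES)),
      dose = rep(ASSAY_DOSES, each = n),
      logfold = as.vector(vi), stringsAsFactors = FALSE)
  }
  meta <- data.frame(drug_id = drugs, name = drugs,
                     target = ifelse(drugs %in% truth$drug_id, "planted",
                                     NA_character_),
                     stringsAsFactors = FALSE)
  list(panel = drug_panel(do.call(rbind, rows), meta), truth = truth)
}
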