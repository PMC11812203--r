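# Conversion-step distances between metabolites in the reaction network.

#' Pairwise conversion-step distances between metabolites
#'
#' Unweighted shortest-path distances on the (undirected) reaction graph:
#' distance k means k conversion edges separate the two metabolites;
#' unreachable pairs are non-adjacent and carry `Inf`. Currency-like hub
#' metabolites participating in very many reactions can be pruned before the
#' distance computation, either implicitly (`max_degree`) or explicitly
#' (`exclude`); pruned nodes drop out of the matrix and are recorded in the
#' `"removed_nodes"` attribute.
#'
#' @param graph a [reaction_graph()].
#' @param max_degree optional hub guard: nodes with degree above it are
#'   removed before distances are computed.
#' @param exclude optional explicit metabolite ids to remove.
#' @return square numeric matrix of class `adjacency_matrix` (0 diagonal,
#'   symmetric, `Inf` = non-adjacent) with attribute `removed_nodes`.
#' @export
conversion_distances <- function(graph, max_degree = NULL, exclude = NULL) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (length(graph$nodes) == 0L) stop("empty reaction graph", call. = FALSE)
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  removed <- character(0)
  if (!is.null(exclude)) {
    removed <- intersect(graph$nodes, exclude)
  }
  if (!is.null(max_degree)) {
    deg <- igraph::degree(g)
    removed <- union(removed, names(deg)[deg > max_degree])
  }
  if (length(removed) > 0L) {
    g <- igraph::delete_vertices(g, removed)
  }
  if (igraph::vcount(g) == 0L) {
    stop("no metabolites left after hub pruning", call. = FALSE)
  }
  d <- igraph::distances(g)
  structure(d, class = c("adjacency_matrix", class(d)),
            removed_nodes = removed)
}

#' Metabolites within k conversion steps of a query metabolite
#'
#' @param adj an `adjacency_matrix` from [conversion_distances()].
#' @param metabolite_id query metabolite (must be present in the matrix).
#' @param k adjacency radius in conversion steps (default 2; `k = 0` gives
#'   the empty set, the query itself is never returned).
#' @return character vector of metabolite ids with `1 <= distance <= k`.
#' @export
neighbors_within <- function(adj, metabolite_id, k = 2) {
  if (!metabolite_id %in% rownames(adj)) {
    stop("unknown metabolite: ", metabolite_id, call. = FALSE)
  }
  d <- adj[metabolite_id, ]
  names(d)[d >= 1 & d <= k]
}

#' Persist / restore an adjacency matrix as a long-form table
#'
#' Only reachable pairs (finite distance, a < b) are written; absent pairs
#' read back as non-adjacent.
#'
#' @param adj an `adjacency_matrix`.
#' @param path TSV path with columns `met_a`, `met_b`, `steps`.
#' @param config optional run configuration for the provenance header.
#' @return `path` (write) / the `adjacency_matrix` (read).
#' @export
write_adjacency <- function(adj, path, config = NULL) {
  ids <- rownames(adj)
  idx <- which(upper.tri(adj) & is.finite(adj), arr.ind = TRUE)
  df <- data.frame(met_a = ids[idx[, 1L]], met_b = ids[idx[, 2L]],
                   steps = adj[idx], stringsAsFactors = FALSE)
  # carry isolated nodes as zero-distance self rows so ids survive round-trip
  iso <- ids[rowSums(is.finite(adj)) == 1L]
  if (length(iso) > 0L) {
    df <- rbind(df, data.frame(met_a = iso, met_b = iso, steps = 0,
                               stringsAsFactors = FALSE))
  }
  write_table_prov(df, path, config)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("met_a", "met_b", "steps"), "adjacency table")
  ids <- sort(unique(c(df$met_a, df$met_b)))
  m <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  off <- df$met_a != df$met_b
  m[cbind(df$met_a[off], df$met_b[off])] <- df$steps[off]
  m[cbind(df$met_b[off], df$met_a[off])] <- df$steps[off]
  structure(m, class = c("adjacency_matrix", class(m)),
            removed_nodes = character(0))
}
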