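# Domain containers and file readers/writers shared by all pipeline stages.

MATRIX_KINDS <- c("counts", "pseudocounts", "metabolite_level",
                  "metabolite_zscore", "gene_effect")

#' Construct an omics matrix
#'
#' A light container for a features-by-samples numeric grid: raw or
#' median-ratio-normalized expression counts, metabolite concentration levels,
#' tissue-wise metabolite z-scores, or CRISPR gene-effect scores. Missing
#' values are allowed (and preserved); duplicate feature or sample ids are
#' not.
#'
#' @param values numeric matrix with feature row names and sample column
#'   names.
#' @param kind one of `"counts"`, `"pseudocounts"`, `"metabolite_level"`,
#'   `"metabolite_zscore"`, `"gene_effect"`.
#' @param sample_annotations optional named character vector mapping sample id
#'   to tissue label.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, kind, sample_annotations = NULL) {
  kind <- match.arg(kind, MATRIX_KINDS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("values must carry feature row names and sample column names",
         call. = FALSE)
  }
  dup_f <- unique(fid[duplicated(fid)])
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_f) > 0L) {
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  if (length(dup_s) > 0L) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(fid)) || any(!nzchar(sid))) {
    stop("feature and sample ids must be non-empty", call. = FALSE)
  }
  if (kind == "counts" && any(values < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (!is.null(sample_annotations)) {
    if (is.null(names(sample_annotations))) {
      stop("sample_annotations must be named by sample id", call. = FALSE)
    }
    sample_annotations <- sample_annotations[intersect(sid, names(sample_annotations))]
  }
  structure(list(values = values, kind = kind,
                 sample_annotations = sample_annotations),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%d missing)\n",
              x$kind, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and sample ids of an omics matrix
#'
#' @param x an [omics_matrix()].
#' @return character vector of ids in storage order.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Load a feature-by-sample matrix from GCT or delimited text
#'
#' The `gct` dialect is GCT 1.2: a `#1.2` version line, a dimensions line,
#' then a header of `Name`, `Description` and sample columns. The `delimited`
#' dialect is a plain headered table (tab or comma, auto-detected) whose first
#' column holds feature ids. `NA`, `NaN` and empty cells become missing
#' values; they are never replaced by zero.
#'
#' @param path file to read.
#' @param kind matrix kind, see [omics_matrix()].
#' @param dialect `"delimited"` or `"gct"`.
#' @return an [omics_matrix()].
#' @export
load_matrix <- function(path, kind, dialect = c("delimited", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "gct") {
    lines <- readLines(path, n = 2L)
    if (length(lines) < 2L || !grepl("^#1\\.2", lines[1L])) {
      stop("parse error in ", path, " line 1: expected GCT version line '#1.2'",
           call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("parse error in ", path, " line 2: expected '<nrow>\\t<ncol>'",
           call. = FALSE)
    }
    df <- read.delim(path, sep = "\t", skip = 2L, check.names = FALSE,
                     stringsAsFactors = FALSE,
                     na.strings = c("", "NA", "NaN"))
    if (ncol(df) < 3L || names(df)[1L] != "Name") {
      stop("parse error in ", path, " line 3: expected 'Name' and ",
           "'Description' columns", call. = FALSE)
    }
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    if (nrow(vals) != dims[1L] || ncol(vals) != dims[2L]) {
      stop("parse error in ", path, ": dimension line says ", dims[1L], "x",
           dims[2L], " but body has ", nrow(vals), "x", ncol(vals),
           call. = FALSE)
    }
  } else {
    df <- read_table_auto(path)
    if (ncol(df) < 2L) {
      stop("parse error in ", path, " line 1: header must name an id column ",
           "and at least one sample", call. = FALSE)
    }
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  omics_matrix(vals, kind)
}

#' Write a matrix in GCT 1.2 or delimited form
#'
#' @param x an [omics_matrix()].
#' @param path output file.
#' @param dialect `"delimited"` (tab-separated) or `"gct"`.
#' @param id_column header of the id column in delimited output.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, dialect = c("delimited", "gct"),
                         id_column = "feature_id") {
  stopifnot(inherits(x, "omics_matrix"))
  dialect <- match.arg(dialect)
  v <- x$values
  if (dialect == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    df <- data.frame(Name = rownames(v), Description = rownames(v),
                     v, check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_column
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Harmonize raw metabolite names against a synonym table
#'
#' Metabolomics panels annotate the same compound under different names; a
#' curated synonym table maps raw annotations to canonical ids. Matching is
#' case-insensitive after trimming surrounding whitespace. Names absent from
#' the table pass through unchanged and are listed in the `unmapped` report.
#' Two distinct input names resolving to the same canonical id would merge
#' rows ambiguously and raise an error.
#'
#' @param names character vector of raw metabolite names.
#' @param table data frame with columns `raw_name`, `canonical_id`.
#' @return list with `ids` (canonicalized vector, same length/order as
#'   `names`) and `unmapped` (raw names not found in the table).
#' @export
harmonize_names <- function(names, table) {
  require_columns(table, c("raw_name", "canonical_id"), "synonym table")
  key <- tolower(trimws(table$raw_name))
  if (anyDuplicated(key)) {
    stop("synonym table raw_name not unique after trimming/casefolding",
         call. = FALSE)
  }
  if (any(!nzchar(table$canonical_id))) {
    stop("synonym table canonical_id must be non-empty", call. = FALSE)
  }
  lut <- setNames(as.character(table$canonical_id), key)
  probe <- tolower(trimws(names))
  hit <- probe %in% names(lut)
  ids <- ifelse(hit, unname(lut[probe]), names)
  dup_ids <- unique(ids[duplicated(ids)])
  if (length(dup_ids) > 0L) {
    stop("harmonization collision: multiple input names map to ",
         paste(dup_ids, collapse = ", "), call. = FALSE)
  }
  list(ids = ids, unmapped = unique(names[!hit]))
}

#' Load a curated table of known SLC-target pairs
#'
#' @param path headered TSV/CSV with columns `slc_id`, `target_id`,
#'   `target_kind` (`metabolite` or `drug`) and optional `evidence`.
#' @return validated data frame of class `known_pair_table`.
#' @export
load_known_pairs <- function(path) {
  df <- read_table_auto(path)
  known_pair_table(df)
}

#' @rdname load_known_pairs
#' @param df data frame to validate in place of a file.
#' @export
known_pair_table <- function(df) {
  require_columns(df, c("slc_id", "target_id", "target_kind"), "known pairs")
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  df$slc_id <- as.character(df$slc_id)
  df$target_id <- as.character(df$target_id)
  if (any(is.na(df$slc_id) | !nzchar(df$slc_id)) ||
      any(is.na(df$target_id) | !nzchar(df$target_id))) {
    stop("known pairs: slc_id and target_id must be non-empty", call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$target_kind), c("metabolite", "drug"))
  if (length(bad_kind) > 0L) {
    stop("known pairs: target_kind must be 'metabolite' or 'drug', got ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("slc_id", "target_id")])) {
    stop("known pairs: duplicated (slc_id, target_id) rows", call. = FALSE)
  }
  class(df) <- c("known_pair_table", "data.frame")
  df
}

#' Build or load a metabolite reaction graph
#'
#' Nodes are metabolite ids and each undirected edge is one conversion step in
#' the reaction network; self-loops are rejected.
#'
#' @param path headered edge list with columns `from`, `to`.
#' @return list of class `reaction_graph` with elements `nodes` and `edges`.
#' @export
load_reaction_graph <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("from", "to"), "reaction graph edge list")
  reaction_graph(data.frame(from = as.character(df$from),
                            to = as.character(df$to),
                            stringsAsFactors = FALSE))
}

#' @rdname load_reaction_graph
#' @param edges data frame with columns `from`, `to`.
#' @param nodes optional node ids (isolated nodes allowed); edge endpoints
#'   must all be listed when given.
#' @export
reaction_graph <- function(edges, nodes = NULL) {
  require_columns(edges, c("from", "to"), "reaction graph edge list")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    loops <- unique(edges$from[edges$from == edges$to])
    stop("reaction graph: self-loop edge(s) at ",
         paste(loops, collapse = ", "), call. = FALSE)
  }
  endpoint <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- endpoint
  } else {
    nodes <- unique(as.character(nodes))
    stray <- setdiff(endpoint, nodes)
    if (length(stray) > 0L) {
      stop("reaction graph: edges reference unknown node(s) ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "reaction_graph")
}

#' Load a pathway membership table
#'
#' @param path headered TSV/CSV with columns `pathway_id`, `metabolite_id`.
#' @return validated data frame of class `pathway_table`.
#' @export
load_pathways <- function(path) {
  df <- read_table_auto(path)
  pathway_table(df)
}

#' @rdname load_pathways
#' @param df data frame to validate in place of a file.
#' @export
pathway_table <- function(df) {
  require_columns(df, c("pathway_id", "metabolite_id"), "pathway table")
  df$pathway_id <- as.character(df$pathway_id)
  df$metabolite_id <- as.character(df$metabolite_id)
  if (anyDuplicated(df[c("pathway_id", "metabolite_id")])) {
    stop("pathway table: duplicated (pathway_id, metabolite_id) rows",
         call. = FALSE)
  }
  class(df) <- c("pathway_table", "data.frame")
  df
}
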