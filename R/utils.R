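# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Detect the field separator of a headered text file from its first
# non-comment line: tab wins over comma (tabs never occur in our csv headers).
detect_sep <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("empty file: ", path, call. = FALSE)
    if (!startsWith(line, "#")) break
  }
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

# Read a headered delimited table, skipping provenance/comment lines.
read_table_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% detect_sep(path)
  read.delim(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("", "NA", "NaN"))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# Provenance header written as a single machine-readable comment line; the
# stored JSON round-trips to the run configuration that produced the file.
provenance_line <- function(config = NULL) {
  payload <- list(
    tool = "slcscore",
    version = as.character(utils::packageVersion("slcscore")),
    config = config
  )
  paste0("#% ", jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                 null = "null"))
}

#' Write a table with a provenance header
#'
#' Writes a data frame as a headered TSV preceded by a `#%`-prefixed comment
#' line holding the package version and, when given, the full run
#' configuration as JSON. [read_provenance()] recovers the configuration.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param config optional run configuration list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table_prov <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the provenance header of a pipeline output file
#'
#' @param path file previously written by [write_table_prov()].
#' @return list with elements `tool`, `version` and `config` (the run
#'   configuration recorded at write time, or `NULL`).
#' @export
read_provenance <- function(path) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0L || !startsWith(line, "#% ")) {
    stop("no provenance header in ", path, call. = FALSE)
  }
  jsonlite::fromJSON(sub("^#% ", "", line), simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

# Stable deterministic ordering used wherever ranks feed a group split: ties
# in the primary key are broken by the id, never by input order.
order_stable <- function(primary, ids, decreasing = FALSE) {
  order(if (decreasing) -xtfrm(primary) else xtfrm(primary), ids)
}
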