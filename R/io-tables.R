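# One TSV dialect everywhere: UTF-8, tab-separated, LF endings, '#'
# comment lines, no quoting. Each schema lists required columns and the
# columns that must parse as numbers.

TABLE_SCHEMAS <- list(
  colony = list(
    columns = c("strain", "ade_phenotype", "leu_phenotype", "count"),
    numeric = "count"
  ),
  plating = list(
    columns = c("strain", "timepoint_hr", "replicate", "lys_colonies",
                "viable_colonies", "dilution_selective", "dilution_permissive"),
    numeric = c("timepoint_hr", "replicate", "lys_colonies", "viable_colonies",
                "dilution_selective", "dilution_permissive")
  ),
  droplet = list(
    columns = c("strain", "time_hr", "locus", "n_total", "n_positive"),
    numeric = c("time_hr", "n_total", "n_positive")
  ),
  cq = list(
    columns = c("strain", "locus", "control_locus", "replicate",
                "cq_ip_target", "cq_input_target", "cq_ip_control",
                "cq_input_control", "input_dilution"),
    numeric = c("replicate", "cq_ip_target", "cq_input_target",
                "cq_ip_control", "cq_input_control", "input_dilution")
  ),
  spore = list(
    columns = c("source", "n_tetrads", "ura_phenotype", "g418_phenotype", "count"),
    numeric = c("n_tetrads", "count")
  )
)

#' Read a validated TSV table
#'
#' @param path TSV file; `#` lines are comments.
#' @param schema_id one of `"colony"`, `"plating"`, `"droplet"`, `"cq"`,
#'   `"spore"`.
#' @return data.frame with typed columns; row order preserved.
#' @export
readTable <- function(path, schema_id) {
  schema <- TABLE_SCHEMAS[[match.arg(schema_id, names(TABLE_SCHEMAS))]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) stop("empty input: ", path, call. = FALSE)
  unknown <- setdiff(names(df), schema$columns)
  if (length(unknown)) {
    stop("unknown column(s) for schema '", schema_id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(schema$columns, names(df))
  if (length(missing)) {
    stop("missing column(s) for schema '", schema_id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[schema$columns]
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("column '%s', row %d: not a number ('%s')",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write a table in the shared TSV dialect
#'
#' Emits UTF-8, tab-delimited, LF-terminated output with a commented
#' header line recording the package version.
#'
#' @param df data.frame.
#' @param path output file.
#' @param schema_id optional schema to validate against before writing.
#' @return `path`, invisibly.
#' @export
writeTable <- function(df, path, schema_id = NULL) {
  if (!is.null(schema_id)) {
    schema <- TABLE_SCHEMAS[[match.arg(schema_id, names(TABLE_SCHEMAS))]]
    missing <- setdiff(schema$columns, names(df))
    if (length(missing)) {
      stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    df <- df[schema$columns]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("BIRquant"))
  writeLines(sprintf("# BIRquant %s", version), con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write a spore table in the spore TSV schema
#'
#' @param table a [sporeTable()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSporeTable <- function(table, path) {
  stopifnot(inherits(table, "sporeTable"))
  cn <- table$counts
  df <- data.frame(
    source = table$source,
    n_tetrads = table$n_tetrads,
    ura_phenotype = c("plus", "plus", "minus", "minus"),
    g418_phenotype = c("sensitive", "resistant", "sensitive", "resistant"),
    count = c(cn[["ura_plus_g418s"]], cn[["ura_plus_g418r"]],
              cn[["ura_minus_g418s"]], cn[["ura_minus_g418r"]]),
    stringsAsFactors = FALSE
  )
  writeTable(df, path, "spore")
}

#' Read a spore table from the spore TSV schema
#'
#' @param path TSV file.
#' @return a [sporeTable()].
#' @export
readSporeTable <- function(path) {
  df <- readTable(path, "spore")
  pick <- function(u, g) {
    v <- df$count[df$ura_phenotype == u & df$g418_phenotype == g]
    if (length(v) != 1L) stop("spore table must have one row per class", call. = FALSE)
    v
  }
  sporeTable(
    ura_plus_g418s = pick("plus", "sensitive"),
    ura_plus_g418r = pick("plus", "resistant"),
    ura_minus_g418s = pick("minus", "sensitive"),
    ura_minus_g418r = pick("minus", "resistant"),
    source = df$source[1L],
    n_tetrads = if (df$source[1L] == "tetrad") df$n_tetrads[1L] else NA_integer_
  )
}
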