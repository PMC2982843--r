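# Column schemas for the pipeline's TSV tables. Units are embedded in the
# documentation of each producing function; the missing-value marker is "NA".

schemas <- list(
  gene_catalog = c(gene_id = "character", orf_length_bp = "integer",
                   probe_start_bp = "integer", probe_end_bp = "integer"),
  truth = c(gene_id = "character", true_tr = "numeric",
            half_life_min = "numeric", kd = "numeric", ra_true = "numeric",
            true_density = "numeric"),
  rate_table = c(gene_id = "character", orf_length_bp = "integer",
                 tr_au = "numeric", tr = "numeric",
                 ind_tr_nodil = "numeric", ind_tr = "numeric",
                 ra = "numeric", half_life_min = "numeric",
                 density_per_kb = "numeric", pols_per_gene = "numeric",
                 dilution_pct = "numeric")
)

#' Read a typed TSV table with schema validation
#'
#' Reads a tab-separated table with a header row and validates it against
#' a named schema (column name -> type, one of `character`, `integer`,
#' `numeric`). Unknown or missing columns raise a schema error naming
#' them; cells that fail numeric conversion raise a parse error with the
#' row number. `NA` is the missing marker.
#'
#' @param path Path to a TSV file.
#' @param schema Named character vector of column types, or the name of a
#'   built-in schema (`"gene_catalog"`, `"truth"`, `"rate_table"`).
#' @return A data frame with typed columns in schema order.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1 && is.null(names(schema))) {
    if (!schema %in% names(schemas)) stop("unknown built-in schema: ", schema)
    schema <- schemas[[schema]]
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  extra_cols <- setdiff(names(raw), names(schema))
  if (length(missing_cols) > 0)
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (length(extra_cols) > 0)
    stop("schema error in ", path, ": unknown column(s) ",
         paste(extra_cols, collapse = ", "))
  out <- raw[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]))
    if (length(bad) > 0)
      stop("parse error in ", path, ", column ", col, ", row ", bad[1],
           ": not numeric: '", out[[col]][bad[1]], "'")
    out[[col]] <- if (type == "integer") as.integer(round(vals)) else vals
  }
  out
}

#' Write a table as TSV
#'
#' Tab-separated, header row, no quoting, `NA` as the missing marker.
#' Numeric values are written at full precision (round-trips through
#' [read_table()] within 1e-12).
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  write.table(format_numeric(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

format_numeric <- function(x) {
  for (col in names(x)) {
    if (is.double(x[[col]]))
      x[[col]] <- ifelse(is.na(x[[col]]), NA,
                         formatC(x[[col]], digits = 17, format = "g"))
  }
  x
}

#' Write a signal matrix as TSV
#'
#' Columns: `gene_id` then one column per array; array names encode the
#' experiment index (e.g. `exp3_rep2`).
#'
#' @param x A [signal_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a signal matrix from TSV
#'
#' Inverse of [write_signal_matrix()]; the experiment of each array is
#' parsed from its column name (the integer before `_rep`).
#'
#' @param path Path to a TSV written by [write_signal_matrix()].
#' @return A [signal_matrix()].
#' @export
read_signal_matrix <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(raw))
    stop("schema error in ", path, ": missing column gene_id")
  if (ncol(raw) < 2) stop("schema error in ", path, ": no array columns")
  arr <- setdiff(names(raw), "gene_id")
  exp_str <- sub("^[^0-9]*([0-9]+)_rep[0-9]+$", "\\1", arr)
  if (any(exp_str == arr))
    stop("cannot parse experiment index from array name(s): ",
         paste(arr[exp_str == arr], collapse = ", "))
  values <- as.matrix(raw[arr])
  if (!is.numeric(values)) stop("parse error in ", path, ": non-numeric cells")
  rownames(values) <- raw$gene_id
  signal_matrix(values, as.integer(exp_str))
}
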