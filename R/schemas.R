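#' Table schemas for pipeline interchange files
#'
#' Every table that moves between pipeline stages is a TSV with a header row,
#' gene identifiers (opaque strings) in the first column where applicable, and
#' a registered schema that fixes column names, types and the formatting used
#' on write. Schemas are looked up by id.
#'
#' @format Internal registry; see [read_table()] and [write_table()].
#' @name schemas
NULL

# type is one of "character", "integer", "numeric", "logical", "pvalue",
# "slope". pvalue/numeric print at full precision; slope prints with 4
# decimals. key = TRUE marks columns whose combination must be unique.
.schema_registry <- local({
  col <- function(name, type, key = FALSE) {
    list(name = name, type = type, key = key)
  }
  reg <- list(
    counts = list(
      cols = list(col("gene_id", "character", key = TRUE)),
      dynamic = "integer"   # any further columns are integer sample counts
    ),
    timecourse = list(
      cols = list(
        col("gene_id", "character", key = TRUE),
        col("condition", "character", key = TRUE),
        col("timepoint", "integer", key = TRUE),
        col("replicate", "integer", key = TRUE),
        col("expression", "numeric")
      )
    ),
    annotation = list(
      cols = list(
        col("gene_id", "character", key = TRUE),
        col("high_confidence", "logical"),
        col("utr3_length", "numeric"),
        col("cds_length", "numeric"),
        col("utr3_free_energy", "numeric"),
        col("cds_utr3_ratio", "numeric"),
        col("readthrough_candidate", "logical"),
        col("bicistronic", "logical"),
        col("polycistronic", "logical"),
        col("utr3_intron", "logical"),
        col("utr3_stop_density", "numeric")
      )
    ),
    truth = list(
      cols = list(
        col("gene_id", "character", key = TRUE),
        col("class", "character"),
        col("fold_change", "numeric"),
        col("decay_rate", "slope"),
        col("is_up_regulated", "logical")
      )
    ),
    de_result = list(
      cols = list(
        col("gene_id", "character", key = TRUE),
        col("mean_control", "numeric"),
        col("mean_mutant", "numeric"),
        col("fold_change", "numeric"),
        col("p_value", "pvalue"),
        col("direction", "character")
      )
    ),
    reactivation_result = list(
      cols = list(
        col("gene_id", "character", key = TRUE),
        col("slope_exp", "slope"),
        col("slope_ctrl", "slope"),
        col("relative_slope", "slope"),
        col("pearson_r", "slope"),
        col("perm_p", "pvalue"),
        col("fold_decay_4h", "numeric"),
        col("flag_control_drift", "logical"),
        col("flag_leaky_rescue", "logical"),
        col("flag_low_annotation", "logical"),
        col("is_target", "logical")
      )
    ),
    classes = list(
      cols = list(
        col("gene_id", "character", key = TRUE),
        col("class", "character")
      )
    ),
    contingency = list(
      cols = list(
        col("cell", "character", key = TRUE),
        col("count", "integer")
      )
    ),
    histogram = list(
      cols = list(
        col("bin_left", "numeric", key = TRUE),
        col("bin_right", "numeric"),
        col("count", "integer")
      )
    ),
    read_accounting = list(
      cols = list(
        col("sample_id", "character", key = TRUE),
        col("feature", "character", key = TRUE),
        col("feature_reads", "integer"),
        col("total_reads", "integer")
      )
    ),
    qpcr = list(
      cols = list(
        col("sample_id", "character", key = TRUE),
        col("target_ct", "numeric"),
        col("reference_ct", "numeric")
      )
    )
  )
  reg
})

schema_get <- function(schema) {
  if (!schema %in% names(.schema_registry)) {
    stop("unknown table schema: '", schema, "'", call. = FALSE)
  }
  .schema_registry[[schema]]
}

.coerce_column <- function(x, type, colname) {
  switch(type,
    character = as.character(x),
    logical = {
      v <- as.logical(x)
      if (anyNA(v)) stop("non-logical cells in column '", colname, "'", call. = FALSE)
      v
    },
    integer = {
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v)) stop("non-numeric cells in column '", colname, "'", call. = FALSE)
      if (any(v != round(v))) {
        stop("non-integer cells in column '", colname, "'", call. = FALSE)
      }
      as.integer(round(v))
    },
    {
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v) && !all(is.na(x) | x == "NA")) {
        stop("non-numeric cells in column '", colname, "'", call. = FALSE)
      }
      if (anyNA(v)) stop("missing values in column '", colname, "'", call. = FALSE)
      v
    }
  )
}

#' Read a pipeline table
#'
#' Reads a TSV, checks the header against the named schema, coerces every
#' column to its declared type, and rejects missing values and duplicate keys
#' (for the `counts` schema, duplicate gene identifiers).
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Schema id, e.g. `"counts"`, `"timecourse"`, `"annotation"`,
#'   `"de_result"`, `"reactivation_result"`, `"truth"`.
#' @return A `data.frame` of typed records, one row per input data line.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t5\t7", "g2\t0\t3"), tf)
#' read_table(tf, "counts")
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- schema_get(schema)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  fixed <- vapply(sc$cols, `[[`, "", "name")
  missing_cols <- setdiff(fixed, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema '", schema, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), fixed)
  if (length(extra) > 0 && is.null(sc$dynamic)) {
    stop("schema '", schema, "': unexpected column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- raw[, c(fixed, extra), drop = FALSE]
  for (cl in sc$cols) {
    out[[cl$name]] <- .coerce_column(raw[[cl$name]], cl$type, cl$name)
  }
  for (nm in extra) {
    out[[nm]] <- .coerce_column(raw[[nm]], sc$dynamic, nm)
  }
  keys <- fixed[vapply(sc$cols, `[[`, FALSE, "key")]
  if (length(keys) > 0 && nrow(out) > 0) {
    keystr <- do.call(paste, c(out[keys], sep = "\r"))
    if (anyDuplicated(keystr)) {
      dup <- out[[keys[1]]][duplicated(keystr)][1]
      stop("schema '", schema, "': duplicate key (first offender: '",
           dup, "')", call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

.format_column <- function(x, type) {
  switch(type,
    character = as.character(x),
    logical = ifelse(x, "TRUE", "FALSE"),
    integer = format(as.integer(x), scientific = FALSE, trim = TRUE),
    pvalue = formatC(x, format = "g", digits = 15),
    slope = formatC(round(x, 4), format = "f", digits = 4),
    # numeric: full precision, locale-independent
    formatC(x, format = "g", digits = 15)
  )
}

#' Write a pipeline table
#'
#' Writes records as a TSV with deterministic column order and fixed numeric
#' formatting: full precision for p-values and general numerics, 4 decimals
#' for slope-type columns. Writing the same records twice yields byte-identical
#' files.
#'
#' @param records A `data.frame` conforming to the schema.
#' @param path Output path.
#' @param schema Schema id (see [read_table()]).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema) {
  sc <- schema_get(schema)
  fixed <- vapply(sc$cols, `[[`, "", "name")
  missing_cols <- setdiff(fixed, names(records))
  if (length(missing_cols) > 0) {
    stop("schema '", schema, "': records lack column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(records), fixed)
  if (length(extra) > 0 && is.null(sc$dynamic)) {
    stop("schema '", schema, "': unexpected column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ord <- c(fixed, extra)
  cols <- character(0)
  body <- vector("list", length(ord))
  types <- c(stats::setNames(vapply(sc$cols, `[[`, "", "type"), fixed),
             stats::setNames(rep(sc$dynamic %||% "numeric", length(extra)), extra))
  for (i in seq_along(ord)) {
    body[[i]] <- .format_column(records[[ord[i]]], types[[ord[i]]])
  }
  lines <- paste(ord, collapse = "\t")
  if (nrow(records) > 0) {
    mat <- do.call(cbind, body)
    lines <- c(lines, apply(mat, 1L, paste, collapse = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
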