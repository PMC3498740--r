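# Long-format expression datasets: the in-memory twin of the template file.
#
# A template is a TSV/CSV with an optional commented metadata header
# ("#key: value" lines) followed by a header row naming the columns
# gene_id, spatial_id, condition, time, replicate, value (order-free;
# condition/time/replicate optional). Values are already-normalized
# expression measurements; missing is an explicit state, never 0.

.record_cols <- c("gene_id", "spatial_id", "condition", "time", "replicate", "value")

#' Construct an expression dataset
#'
#' @param records A data.frame with columns `gene_id`, `spatial_id`,
#'   `condition`, `time`, `replicate`, `value`. Missing optional columns are
#'   filled with defaults (`condition = "default"`, `time = ""`,
#'   `replicate = 1`).
#' @param metadata A named list of experiment metadata (`project_name`,
#'   `subjects`, `conditions`, `source_note`). The `conditions` field is
#'   always recomputed from the records so the two cannot drift apart.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(records, metadata = list()) {
  stopifnot(is.data.frame(records))
  if (!all(c("gene_id", "spatial_id", "value") %in% names(records))) {
    stop("records need at least gene_id, spatial_id and value columns; found: ",
         paste(names(records), collapse = ", "))
  }
  n <- nrow(records)
  if (is.null(records$condition)) records$condition <- rep("default", n)
  if (is.null(records$time)) records$time <- rep("", n)
  if (is.null(records$replicate)) records$replicate <- rep(1L, n)
  records$gene_id <- trimws(as.character(records$gene_id))
  records$spatial_id <- trimws(as.character(records$spatial_id))
  records$condition <- as.character(records$condition)
  records$condition[is.na(records$condition) | records$condition == ""] <- "default"
  records$time <- as.character(records$time)
  records$time[is.na(records$time)] <- ""
  records$replicate <- as.integer(records$replicate)
  records$replicate[is.na(records$replicate)] <- 1L
  records$value <- as.numeric(records$value)
  if (any(records$gene_id == "")) stop("empty gene_id after trimming")
  if (any(records$spatial_id == "")) stop("empty spatial_id after trimming")
  if (any(is.infinite(records$value))) stop("non-finite expression value")
  records <- records[, .record_cols]
  rownames(records) <- NULL
  key <- do.call(paste, c(records[c("gene_id", "spatial_id", "condition",
                                    "time", "replicate")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate record at row ", dup, ": (",
         paste(unlist(records[dup, 1:5]), collapse = ", "), ")")
  }
  meta <- list(
    project_name = metadata$project_name %||% "",
    subjects     = metadata$subjects %||% "",
    conditions   = sort(unique(records$condition)),
    source_note  = metadata$source_note %||% ""
  )
  structure(list(metadata = meta, records = records),
            class = "expression_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_dataset <- function(x, ...) {
  r <- x$records
  cat("Expression dataset: ", length(unique(r$gene_id)), " genes x ",
      length(unique(r$spatial_id)), " spatial ids, ",
      nrow(r), " records\n", sep = "")
  if (nzchar(x$metadata$project_name))
    cat("  project:    ", x$metadata$project_name, "\n", sep = "")
  cat("  conditions: ", paste(x$metadata$conditions, collapse = ", "), "\n",
      sep = "")
  nmiss <- sum(is.na(r$value))
  if (nmiss > 0) cat("  missing values: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' Genes present in a dataset
#' @param ds An `expression_dataset`.
#' @return Character vector of distinct gene ids, lexicographically sorted.
#' @export
dataset_genes <- function(ds) sort(unique(ds$records$gene_id))

#' Read an expression template file
#'
#' Parses a long-format template: optional leading `#key: value` metadata
#' lines, then a header row naming (order-free) the columns `gene_id`,
#' `spatial_id`, `value` and optionally `condition`, `time`, `replicate`.
#' Empty cells and the strings `NA`/`nan` in the value column become an
#' explicit missing state.
#'
#' @param path Template file.
#' @param dialect One of `"tsv"`, `"csv"`, `"spreadsheet"`; defaults to a
#'   guess from the file extension (`.csv` is CSV, `.xlsx`/`.xls` is
#'   spreadsheet, anything else TSV). The spreadsheet reader requires the
#'   readxl package and translates to the same record model.
#' @return An [expression_dataset()].
#' @export
read_template <- function(path, dialect = c("auto", "tsv", "csv", "spreadsheet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("template file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, csv = "csv", xlsx = , xls = "spreadsheet", "tsv")
  }
  if (dialect == "spreadsheet") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("spreadsheet import needs the 'readxl' package")
    }
    tab <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                         stringsAsFactors = FALSE)
    meta <- list()
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    lines <- readLines(path, warn = FALSE)
    meta_lines <- grep("^#", lines, value = TRUE)
    meta <- .parse_meta(meta_lines)
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 1) stop("template has no header row: ", path)
    tab <- utils::read.table(text = body, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             quote = "\"", comment.char = "")
  }
  names(tab) <- trimws(tolower(names(tab)))
  mandatory <- c("gene_id", "spatial_id", "value")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop("template is missing mandatory column(s) ",
         paste(miss, collapse = ", "), "; found columns: ",
         paste(names(tab), collapse = ", "))
  }
  vraw <- trimws(tab$value)
  vraw[vraw %in% c("", "NA", "na", "NaN", "nan", "NULL")] <- NA_character_
  val <- suppressWarnings(as.numeric(vraw))
  bad <- which(!is.na(vraw) & is.na(val))
  if (length(bad)) {
    stop("non-numeric value '", vraw[bad[1]], "' in column 'value', data row ",
         bad[1])
  }
  tab$value <- val
  expression_dataset(tab, meta)
}

.parse_meta <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([A-Za-z_ ]+):\\s*(.*)$", lines))
  meta <- list()
  for (m in kv) {
    if (length(m) == 3) {
      key <- gsub(" ", "_", tolower(trimws(m[2])))
      meta[[key]] <- trimws(m[3])
    }
  }
  meta
}

#' Write an expression template file
#'
#' Writes the canonical plain-TSV template: `#key: value` metadata lines
#' followed by a header row and one record per line. Missing values are
#' written as `NA`. `read_template()` round-trips the result exactly.
#'
#' @param ds An `expression_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- ds$metadata
  writeLines(c(
    paste0("#project_name: ", m$project_name),
    paste0("#subjects: ", m$subjects),
    paste0("#conditions: ", paste(m$conditions, collapse = ",")),
    paste0("#source_note: ", m$source_note)
  ), con)
  r <- ds$records
  r$value <- ifelse(is.na(r$value), "NA",
                    format(r$value, scientific = FALSE, trim = TRUE, digits = 15))
  utils::write.table(r, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate replicate measurements
#'
#' Collapses records to exactly one value per (gene, spatial id, condition,
#' time). Missing replicates are ignored; a group whose replicates are all
#' missing stays missing. Idempotent.
#'
#' @param ds An `expression_dataset`.
#' @param stat `"mean"` (default) or `"median"`.
#' @return An `expression_dataset` with `replicate = 1` throughout.
#' @export
aggregate_replicates <- function(ds, stat = c("mean", "median")) {
  stopifnot(inherits(ds, "expression_dataset"))
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  r <- ds$records
  key <- interaction(r$gene_id, r$spatial_id, r$condition, r$time,
                     drop = TRUE, lex.order = TRUE, sep = "\r")
  agg <- function(v) { v <- v[!is.na(v)]; if (!length(v)) NA_real_ else f(v) }
  vals <- tapply(r$value, key, agg)
  first <- !duplicated(key)
  out <- r[first, c("gene_id", "spatial_id", "condition", "time")]
  out$replicate <- 1L
  out$value <- as.numeric(vals[as.character(key[first])])
  expression_dataset(out, ds$metadata)
}

#' Derive a condition-difference dataset
#'
#' Builds the relative expression view: for each (gene, spatial id, time)
#' measured in both conditions, the new value is `value(cond_a) -
#' value(cond_b)`; pairs missing on either side stay missing. The result
#' carries the single condition label `"a-b"` and is meant to be painted on
#' a symmetric diverging scale so that zero maps to the midpoint color.
#'
#' @param ds An `expression_dataset` with replicates already aggregated.
#' @param cond_a,cond_b Condition names present in `ds`.
#' @return An `expression_dataset` with one condition `"cond_a-cond_b"`.
#' @export
derive_difference <- function(ds, cond_a, cond_b) {
  stopifnot(inherits(ds, "expression_dataset"))
  have <- ds$metadata$conditions
  for (cn in c(cond_a, cond_b)) {
    if (!cn %in% have) {
      stop("unknown condition '", cn, "'; available: ",
           paste(have, collapse = ", "))
    }
  }
  r <- aggregate_replicates(ds)$records
  a <- r[r$condition == cond_a, ]
  b <- r[r$condition == cond_b, ]
  key <- function(d) paste(d$gene_id, d$spatial_id, d$time, sep = "\r")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  a <- a[match(common, ka), ]
  bval <- b$value[match(common, kb)]
  out <- data.frame(
    gene_id = a$gene_id, spatial_id = a$spatial_id,
    condition = paste0(cond_a, "-", cond_b), time = a$time,
    replicate = 1L, value = a$value - bval,
    stringsAsFactors = FALSE
  )
  meta <- ds$metadata
  meta$source_note <- paste0("difference ", cond_a, " - ", cond_b)
  expression_dataset(out, meta)
}
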