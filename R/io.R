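# Readers and writers: delimited expression tables, GEO SOFT GDS full
# tables, pattern-gene reports (TSV + JSON) and threshold config files.

.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix
#'
#' Expects a header row of sample labels and a first column of gene or
#' probeset identifiers.  Parsing is strict: ragged rows, duplicate sample
#' labels and non-numeric cells are errors naming the offending line;
#' missing cells (`NA` or empty) are kept as `NA`, never silently zeroed.
#' Numeric parsing is locale-independent (dot decimal separator).
#'
#' @param path Path to a TSV (or CSV, by extension or explicit `sep`) file.
#' @param sep Field separator; inferred from the extension by default.
#' @param naStrings Cell values treated as missing.
#' @return A numeric matrix with gene IDs as row names and sample labels as
#'   column names.
#' @seealso [writeExpressionTable()], [readDetectionCalls()]
#' @export
readExpressionTable <- function(path, sep = NULL, naStrings = c("NA", "")) {
  cells <- .readDelimitedCells(path, .sepForPath(path, sep))
  labels <- cells$header
  mat <- matrix(NA_real_, nrow = length(cells$rows), ncol = length(labels),
                dimnames = list(cells$ids, labels))
  for (r in seq_along(cells$rows)) {
    raw <- cells$rows[[r]]
    raw[raw %in% naStrings] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      .stopValidation("line %d of %s: non-numeric cell '%s' in column '%s'",
                      cells$lineNo[r], path, raw[bad[1L]], labels[bad[1L]])
    }
    mat[r, ] <- num
  }
  mat
}

#' Read a detection-call (A/M/P) matrix
#'
#' Same layout as [readExpressionTable()] but cells are the call characters
#' A, M or P.
#'
#' @inheritParams readExpressionTable
#' @return A character matrix with the same layout conventions.
#' @export
readDetectionCalls <- function(path, sep = NULL) {
  cells <- .readDelimitedCells(path, .sepForPath(path, sep))
  mat <- do.call(rbind, cells$rows)
  dimnames(mat) <- list(cells$ids, cells$header)
  bad <- matrix(!(mat %in% c("A", "M", "P")), nrow = nrow(mat))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    .stopValidation("line %d of %s: unexpected detection call '%s' (expected A, M or P)",
                    cells$lineNo[w[1L]], path, mat[w[1L], w[2L]])
  }
  mat
}

# Shared strict tokenizer: returns header labels (validated unique), row
# ids, row cell strings and source line numbers.
.readDelimitedCells <- function(path, sep) {
  if (!file.exists(path)) .stopValidation("file not found: %s", path)
  nFields <- utils::count.fields(path, sep = sep, quote = "\"",
                                 comment.char = "")
  if (length(nFields) < 2L) {
    .stopValidation("%s: need a header row and at least one data row", path)
  }
  ragged <- which(nFields != nFields[1L])
  if (length(ragged)) {
    .stopValidation("%s: ragged row(s) at line(s) %s (expected %d fields)",
                    path, paste(utils::head(ragged, 5L), collapse = ", "),
                    nFields[1L])
  }
  lines <- readLines(path)
  split <- strsplit(lines, sep, fixed = TRUE)
  header <- split[[1L]][-1L]
  if (anyDuplicated(header)) {
    .stopValidation("%s: duplicate sample label(s): %s", path,
                    paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  rows <- lapply(split[-1L], `[`, -1L)
  list(header = header,
       ids = vapply(split[-1L], `[[`, character(1), 1L),
       rows = rows,
       lineNo = seq_along(rows) + 1L)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionTable()]: header of sample labels, first
#' column `gene` holding row names, full numeric precision.
#'
#' @param values Numeric matrix with dimnames.
#' @param path Output path.
#' @param idColumn Name for the identifier column.
#' @export
writeExpressionTable <- function(values, path, idColumn = "gene") {
  df <- data.frame(id = rownames(values) %||% seq_len(nrow(values)),
                   values, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a two-column mapping table (TSV)
#'
#' Used for probeset-to-gene maps and sample-to-replicate-group tables.
#'
#' @param path Path to a two-column TSV with a header row.
#' @return A named character vector (names = first column).
#' @export
readTwoColumnMap <- function(path) {
  if (!file.exists(path)) .stopValidation("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) .stopValidation("%s: expected two columns", path)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read a GEO SOFT GDS full table
#'
#' Parses the SOFT full-table export of a curated GEO DataSet: the table
#' between `!dataset_table_begin` and `!dataset_table_end` with an `ID_REF`
#' probeset column, an optional `IDENTIFIER` gene-symbol column, one value
#' column per sample (GSM accession) and, when present, paired
#' detection-call columns (a column named `<sample>_CALL`, or the literal
#' SOFT heading `Detection Call` following its value column, holding
#' A/M/P).  `^SUBSET` annotations are collected as a candidate replicate
#' grouping (sample -> subset description).  Truncated files (no table end
#' marker) are an error, never a partial read.
#'
#' @param path Path to a SOFT-format GDS file.
#' @return A list with elements `values` (numeric probesets-by-samples
#'   matrix), `calls` (congruent character matrix or NULL), `probesetMap`
#'   (named vector probeset -> gene symbol, or NULL) and `replicateGroups`
#'   (named vector sample -> subset description, or NULL).
#' @export
readGDS <- function(path) {
  if (!file.exists(path)) .stopValidation("file not found: %s", path)
  lines <- readLines(path)
  begin <- grep("^!dataset_table_begin", lines)
  end <- grep("^!dataset_table_end", lines)
  if (length(begin) != 1L) {
    .stopValidation("%s: malformed SOFT file: expected one !dataset_table_begin marker",
                    path)
  }
  if (length(end) != 1L || end <= begin + 1L) {
    .stopValidation("%s: truncated SOFT file: missing !dataset_table_end", path)
  }

  ## subset annotations -> candidate replicate grouping
  groups <- character()
  desc <- NA_character_
  ids <- character()
  flush <- function() {
    if (length(ids) && !is.na(desc)) {
      groups[ids] <<- desc
    }
  }
  for (ln in lines[seq_len(begin - 1L)]) {
    if (startsWith(ln, "^SUBSET")) {
      flush(); desc <- NA_character_; ids <- character()
    } else if (startsWith(ln, "!subset_description")) {
      desc <- sub("^!subset_description\\s*=\\s*", "", ln)
    } else if (startsWith(ln, "!subset_sample_id")) {
      ids <- strsplit(sub("^!subset_sample_id\\s*=\\s*", "", ln), ",")[[1L]]
      ids <- trimws(ids)
    }
  }
  flush()

  tab <- strsplit(lines[seq.int(begin + 1L, end - 1L)], "\t", fixed = TRUE)
  header <- tab[[1L]]
  body <- tab[-1L]
  if (header[1L] != "ID_REF") {
    .stopValidation("%s: malformed SOFT table: first column must be ID_REF", path)
  }
  if (any(lengths(body) != length(header))) {
    .stopValidation("%s: ragged SOFT table row(s)", path)
  }
  probesets <- vapply(body, `[[`, character(1), 1L)
  identCol <- which(header == "IDENTIFIER")
  probesetMap <- NULL
  if (length(identCol)) {
    probesetMap <- stats::setNames(
      vapply(body, `[[`, character(1), identCol[1L]), probesets)
  }
  callIdx <- which(grepl("_CALL$", header, ignore.case = TRUE) |
                     header == "Detection Call")
  valueIdx <- setdiff(seq_along(header), c(1L, identCol, callIdx))
  sampleNames <- header[valueIdx]
  values <- matrix(NA_real_, nrow = length(body), ncol = length(valueIdx),
                   dimnames = list(probesets, sampleNames))
  for (r in seq_along(body)) {
    raw <- body[[r]][valueIdx]
    raw[raw %in% c("null", "NA", "")] <- NA
    values[r, ] <- suppressWarnings(as.numeric(raw))
  }
  calls <- NULL
  if (length(callIdx)) {
    ## pair each call column with the value column immediately before it
    owner <- vapply(callIdx, function(ci) {
      prev <- max(valueIdx[valueIdx < ci])
      match(prev, valueIdx)
    }, integer(1))
    calls <- matrix(NA_character_, nrow = length(body), ncol = length(valueIdx),
                    dimnames = dimnames(values))
    for (j in seq_along(callIdx)) {
      calls[, owner[j]] <- vapply(body, `[[`, character(1), callIdx[j])
    }
  }
  if (length(groups) == 0L) groups <- NULL
  list(values = values, calls = calls, probesetMap = probesetMap,
       replicateGroups = groups)
}

#' Write a pattern-gene report
#'
#' Serialises the calls of a [PatternCallSet-class].  The TSV dialect
#' mirrors the downloadable pattern-gene table: one row per call with
#' comma-joined sample lists and numbers rendered to 2 decimals.  The JSON
#' dialect keeps full numeric precision and exact list structure, and
#' round-trips through [readPatternReport()] without loss.  Row order is
#' deterministic (gene, then class).  An empty call set produces a
#' header-only TSV / an empty JSON array.
#'
#' @param callSet A [PatternCallSet-class].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
writePatternReport <- function(callSet, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is(callSet, "PatternCallSet"))
  calls <- callSet@calls
  if (format == "tsv") {
    df <- as.data.frame(callSet)
    for (col in c("dpm", "ctm", "rpm")) {
      df[[col]] <- ifelse(is.na(df[[col]]), "",
                          formatC(df[[col]], digits = 2, format = "f"))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(calls)), function(r) {
      list(gene = calls$gene[r],
           pattern = as.character(calls$pattern[r]),
           dataset = callSet@datasetId,
           k = calls$k[r],
           samples = as.list(calls$samples[[r]]),
           spm = as.list(calls$spm[[r]]),
           dpm = calls$dpm[r], ctm = calls$ctm[r], rpm = calls$rpm[r])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a pattern-gene report back
#'
#' @param path Path written by [writePatternReport()].
#' @param format `"tsv"` or `"json"`.
#' @return A [S4Vectors::DataFrame] of calls in the [PatternCallSet-class]
#'   column layout, with a `dataset` column.  JSON reports reproduce the
#'   written calls exactly; TSV reports carry scores rounded to 2 decimals.
#' @export
readPatternReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopValidation("file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = "character")
    toNum <- function(v) {
      out <- suppressWarnings(as.numeric(v))
      out[!is.na(v) & v == ""] <- NA_real_
      out
    }
    DataFrame(
      gene = df$gene,
      pattern = factor(df$pattern, levels = .patternClassLevels),
      k = as.integer(df$k),
      samples = IRanges::CharacterList(strsplit(df$samples, ",", fixed = TRUE)),
      spm = IRanges::NumericList(lapply(strsplit(df$spm, ",", fixed = TRUE),
                                        as.numeric)),
      dpm = toNum(df$dpm), ctm = toNum(df$ctm), rpm = toNum(df$rpm),
      dataset = df$dataset)
  } else {
    recs <- jsonlite::read_json(path)
    if (length(recs) == 0L) {
      out <- .recordsToDataFrame(list())
      out$dataset <- character()
      return(out)
    }
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    DataFrame(
      gene = vapply(recs, function(r) r$gene, character(1)),
      pattern = factor(vapply(recs, function(r) r$pattern, character(1)),
                       levels = .patternClassLevels),
      k = vapply(recs, function(r) as.integer(r$k), integer(1)),
      samples = IRanges::CharacterList(
        lapply(recs, function(r) unlist(r$samples, use.names = FALSE))),
      spm = IRanges::NumericList(
        lapply(recs, function(r) as.numeric(unlist(r$spm)))),
      dpm = vapply(recs, function(r) num(r$dpm), numeric(1)),
      ctm = vapply(recs, function(r) num(r$ctm), numeric(1)),
      rpm = vapply(recs, function(r) num(r$rpm), numeric(1)),
      dataset = vapply(recs, function(r) r$dataset, character(1)))
  }
}

#' Read classification thresholds from a config file
#'
#' Accepts either YAML (when the `yaml` package is available) or a flat
#' `key = value` / `key: value` text file; keys are the
#' [patternThresholds()] argument names.  Unknown keys are an error.
#'
#' @param path Config file path.
#' @return A [PatternThresholds-class].
#' @export
readThresholds <- function(path) {
  if (!file.exists(path)) .stopValidation("file not found: %s", path)
  vals <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE) &&
      requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\\s*[:=]\\s*")
    vals <- lapply(parts, function(p) utils::type.convert(p[2L], as.is = TRUE))
    names(vals) <- vapply(parts, `[[`, character(1), 1L)
  }
  known <- names(formals(patternThresholds))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    .stopValidation("unknown threshold key(s) in %s: %s", path,
                    paste(unknown, collapse = ", "))
  }
  do.call(patternThresholds, vals)
}
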