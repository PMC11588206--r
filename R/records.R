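# Data model for kinetic measurements and queries, TSV readers/writers, and
# identifier canonicalization against local mapping tables.

RECORD_COLUMNS <- c(
  "param_type", "value_log10", "substrate_id", "reaction_id", "ec",
  "family_id", "protein_id", "organism", "direction", "source"
)

QUERY_COLUMNS <- setdiff(RECORD_COLUMNS, "value_log10")

# Group keys are joined with "|"; identifiers must not contain it.
KEY_SEP <- "|"

# Linear-value unit conversions to standard units (molar for KM, 1/s for kcat).
UNIT_FACTORS <- c(
  "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6, "nM" = 1e-9,
  "1/s" = 1, "s^-1" = 1, "1/min" = 1 / 60, "1/h" = 1 / 3600
)

abort_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("bmkin_validation_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a table of kinetic measurement records
#'
#' A `kinetic_records` object is a data frame with one row per measurement of
#' a Michaelis constant (KM, molar) or turnover number (kcat, 1/s), stored on
#' the log10 scale, together with the categorical annotations that drive the
#' multilevel models: substrate, reaction, EC number, protein family, protein
#' identifier, organism and reaction direction. Missing annotations are `NA`,
#' never empty strings: a missing protein identifier is a first-class state
#' that selects the wider residual-noise regime.
#'
#' @param df data frame containing at least `param_type`, `value_log10`,
#'   `reaction_id` and `ec`; other columns are filled with `NA` when absent.
#' @param strict if `TRUE` (default), any invalid row is an error; otherwise
#'   invalid rows are dropped and reported via the `"rejected"` attribute.
#' @return A `kinetic_records` data frame. When `strict = FALSE` the attribute
#'   `"rejected"` holds a data frame of dropped row indices and reasons.
#' @export
kinetic_records <- function(df, strict = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("param_type", "value_log10", "reaction_id", "ec")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_validation(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in setdiff(RECORD_COLUMNS, names(df))) df[[col]] <- NA_character_
  df <- df[RECORD_COLUMNS]
  for (col in setdiff(RECORD_COLUMNS, "value_log10")) {
    x <- as.character(df[[col]])
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    df[[col]] <- x
  }
  df$value_log10 <- as.numeric(df$value_log10)

  problems <- validate_record_rows(df)
  if (length(problems) > 0) {
    bad <- as.integer(names(problems))
    msgs <- sprintf("row %s: %s", names(problems), unlist(problems))
    if (strict) {
      abort_validation(paste0(
        "invalid record row(s):\n  ", paste(msgs, collapse = "\n  ")
      ))
    }
    rejected <- data.frame(
      row = bad, reason = unlist(problems), stringsAsFactors = FALSE
    )
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
    message(length(bad), " record(s) rejected during validation")
  } else {
    rejected <- data.frame(row = integer(), reason = character())
  }
  structure(df,
    class = c("kinetic_records", "data.frame"),
    rejected = rejected
  )
}

# Per-row invariant checks; returns a named list (row index -> first problem).
validate_record_rows <- function(df) {
  problems <- list()
  note <- function(i, msg) {
    key <- as.character(i)
    if (is.null(problems[[key]])) problems[[key]] <<- msg
  }
  for (i in seq_len(nrow(df))) {
    pt <- df$param_type[i]
    if (is.na(pt) || !pt %in% c("KM", "kcat")) {
      note(i, "param_type must be 'KM' or 'kcat'")
      next
    }
    if (!is.finite(df$value_log10[i])) note(i, "value_log10 is not finite")
    if (pt == "KM" && is.na(df$substrate_id[i])) {
      note(i, "KM record lacks substrate_id")
    }
    if (is.na(df$reaction_id[i])) note(i, "missing reaction_id")
    ec <- df$ec[i]
    if (is.na(ec) || !valid_ec(ec)) {
      note(i, "ec must have 1-4 non-empty dot-separated components")
    }
    dir <- df$direction[i]
    if (!is.na(dir) && !dir %in% c("forward", "backward")) {
      note(i, "direction must be 'forward' or 'backward'")
    }
    for (col in c("substrate_id", "reaction_id", "family_id", "protein_id",
                  "organism")) {
      v <- df[[col]][i]
      if (!is.na(v) && grepl(KEY_SEP, v, fixed = TRUE)) {
        note(i, paste0(col, " contains reserved separator '", KEY_SEP, "'"))
      }
    }
  }
  problems
}

valid_ec <- function(ec) {
  parts <- strsplit(ec, ".", fixed = TRUE)[[1]]
  length(parts) >= 1 && length(parts) <= 4 && all(nzchar(parts))
}

#' Read kinetic measurement records from a tab-separated file
#'
#' The file must have a header row. Values may be given directly on the log10
#' standard-unit scale in a `value_log10` column, or on the linear scale in a
#' `value` column with a `unit` column (supported units: M, mM, uM, nM for
#' KM; 1/s, 1/min, 1/h for kcat); linear values are converted to log10
#' standard units (molar, 1/s). Non-positive linear values are row errors.
#'
#' @param path path to a UTF-8 TSV file.
#' @param strict if `FALSE`, invalid rows are dropped and reported instead of
#'   raising an error.
#' @return A [kinetic_records] data frame.
#' @export
read_kinetic_records <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (!"value_log10" %in% names(df)) {
    if (!all(c("value", "unit") %in% names(df))) {
      abort_validation(
        "file must contain a 'value_log10' column or 'value' + 'unit' columns"
      )
    }
    conv <- convert_linear_values(as.numeric(df$value), df$unit)
    df$value_log10 <- conv$value_log10
    bad <- which(!is.na(conv$problem))
    if (length(bad) > 0 && strict) {
      abort_validation(paste0(
        "invalid linear value(s):\n  ",
        paste(sprintf("row %d: %s", bad, conv$problem[bad]), collapse = "\n  ")
      ))
    }
  }
  kinetic_records(df, strict = strict)
}

convert_linear_values <- function(value, unit) {
  n <- length(value)
  out <- rep(NA_real_, n)
  problem <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(value[i])) {
      problem[i] <- "missing value"
    } else if (is.na(unit[i]) || !unit[i] %in% names(UNIT_FACTORS)) {
      problem[i] <- paste0("unknown unit '", unit[i], "'")
    } else if (value[i] <= 0) {
      problem[i] <- "non-positive linear value (log undefined)"
    } else {
      out[i] <- log10(value[i] * UNIT_FACTORS[[unit[i]]])
    }
  }
  list(value_log10 = out, problem = problem)
}

#' Write kinetic records to a tab-separated file
#'
#' @param records a [kinetic_records] data frame.
#' @param path output path.
#' @export
write_kinetic_records <- function(records, path) {
  df <- as.data.frame(records)
  df$value_log10 <- sprintf("%.15g", df$value_log10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a table of query parameters
#'
#' Queries carry the same categorical fields as measurement records but no
#' observed value; `param_type`, `reaction_id` and `ec` are always required,
#' while `substrate_id`, `family_id` and `protein_id` may be absent (`NA`).
#'
#' @param df data frame of query fields.
#' @return A `query_parameters` data frame.
#' @export
query_parameters <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("param_type", "reaction_id", "ec")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_validation(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in setdiff(QUERY_COLUMNS, names(df))) df[[col]] <- NA_character_
  df <- df[QUERY_COLUMNS]
  for (col in QUERY_COLUMNS) {
    x <- as.character(df[[col]])
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    df[[col]] <- x
  }
  chk <- df
  chk$value_log10 <- 0
  problems <- validate_record_rows(chk)
  # KM queries may legitimately lack nothing that records may: substrate still
  # required because the KM hierarchy is rooted at the substrate.
  if (length(problems) > 0) {
    msgs <- sprintf("row %s: %s", names(problems), unlist(problems))
    abort_validation(paste0(
      "invalid query row(s):\n  ", paste(msgs, collapse = "\n  ")
    ))
  }
  structure(df, class = c("query_parameters", "data.frame"))
}

#' Read query parameters from a TSV file
#' @param path path to a TSV file with a header naming the query columns.
#' @return A [query_parameters] data frame.
#' @export
read_query_parameters <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  query_parameters(df)
}

#' Read an identifier mapping table
#'
#' Mapping tables translate foreign metabolite/reaction identifiers (any
#' namespace) into the canonical namespace used internally. Each table is a
#' two-column TSV (`foreign_id`, `canonical_id`); the mapping must be a
#' function (one canonical id per foreign id).
#'
#' @param path path to a two-column TSV.
#' @param namespace label for the table (defaults to the file name).
#' @return A `mapping_table` data frame with attribute `namespace`.
#' @export
read_mapping_table <- function(path, namespace = NULL) {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("foreign_id", "canonical_id") %in% names(df))) {
    abort_validation("mapping table needs columns foreign_id, canonical_id")
  }
  mapping_table(df, namespace %||% basename(path))
}

#' @rdname read_mapping_table
#' @param df data frame with columns `foreign_id`, `canonical_id`.
#' @export
mapping_table <- function(df, namespace = "local") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)[c("foreign_id", "canonical_id")]
  dup <- unique(df$foreign_id[duplicated(df$foreign_id)])
  conflicting <- dup[vapply(dup, function(k) {
    length(unique(df$canonical_id[df$foreign_id == k])) > 1
  }, logical(1))]
  if (length(conflicting) > 0) {
    abort_validation(paste0(
      "conflicting mappings for foreign id(s): ",
      paste(conflicting, collapse = ", ")
    ))
  }
  df <- df[!duplicated(df$foreign_id), , drop = FALSE]
  structure(df, class = c("mapping_table", "data.frame"), namespace = namespace)
}

# Combine mapping tables into one named lookup vector, checking cross-table
# conflicts and rejecting chained mappings (a canonical id that is itself
# remapped elsewhere), which would break idempotence.
combine_mapping_tables <- function(tables) {
  if (inherits(tables, "mapping_table")) tables <- list(tables)
  all_f <- character(); all_c <- character()
  for (tb in tables) {
    for (i in seq_len(nrow(tb))) {
      f <- tb$foreign_id[i]; cn <- tb$canonical_id[i]
      j <- match(f, all_f)
      if (!is.na(j)) {
        if (all_c[j] != cn) {
          abort_validation(paste0(
            "conflicting mappings across tables for '", f, "': '",
            all_c[j], "' vs '", cn, "'"
          ))
        }
      } else {
        all_f <- c(all_f, f); all_c <- c(all_c, cn)
      }
    }
  }
  chained <- all_c[all_c %in% all_f & all_c != all_f[match(all_c, all_f)]]
  chained <- unique(chained[!is.na(chained)])
  if (length(chained) > 0) {
    abort_validation(paste0(
      "chained mapping(s) (canonical id remapped again): ",
      paste(chained, collapse = ", ")
    ))
  }
  stats::setNames(all_c, all_f)
}

#' Canonicalize metabolite and reaction identifiers
#'
#' Replaces `substrate_id` and `reaction_id` with canonical identifiers where
#' a mapping exists; identifiers absent from all tables are kept verbatim and
#' reported in the `"unmapped_ids"` attribute. Canonicalization is idempotent
#' because chained mappings are rejected when the tables are combined.
#'
#' @param records a [kinetic_records] or [query_parameters] data frame.
#' @param tables a [mapping_table] or list of them.
#' @return `records` with canonical identifiers and attribute `"unmapped_ids"`.
#' @export
canonicalize_ids <- function(records, tables) {
  lookup <- combine_mapping_tables(tables)
  unmapped <- character()
  for (col in c("substrate_id", "reaction_id")) {
    x <- records[[col]]
    hit <- !is.na(x) & x %in% names(lookup)
    unmapped <- c(unmapped, unique(x[!is.na(x) & !hit]))
    x[hit] <- unname(lookup[x[hit]])
    records[[col]] <- x
  }
  attr(records, "unmapped_ids") <- unique(unmapped)
  records
}

#' Write predictions to a TSV file
#'
#' Writes the query fields plus `mean_log10`, `sd_log10`, `matched_levels`
#' (encoded as `level:0/1` pairs joined by `;`) and a logical `balanced`
#' column. Numeric columns are written with 15 significant digits so that a
#' read-back reproduces them to at least 12 decimal digits.
#'
#' @param predictions data frame as returned by [predictive_distribution]
#'   (rows bound together), or any data frame with the expected columns.
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  df <- as.data.frame(predictions)
  if (is.null(df$balanced)) df$balanced <- FALSE
  cols <- c(intersect(QUERY_COLUMNS, names(df)),
            "mean_log10", "sd_log10", "matched_levels", "balanced")
  if (nrow(df) == 0) {
    df <- df[, intersect(cols, names(df)), drop = FALSE]
    for (col in setdiff(cols, names(df))) df[[col]] <- character(0)
    df <- df[cols]
  } else {
    for (col in c("mean_log10", "sd_log10")) {
      if (is.null(df[[col]])) abort_validation(paste0("missing column ", col))
    }
    if (is.null(df$matched_levels)) df$matched_levels <- ""
    df <- df[cols]
    df$mean_log10 <- sprintf("%.15g", as.numeric(df$mean_log10))
    df$sd_log10 <- sprintf("%.15g", as.numeric(df$sd_log10))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions]
#' @param path path to the TSV file.
#' @return data frame with numeric `mean_log10`, `sd_log10`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = "character")
  df$mean_log10 <- as.numeric(df$mean_log10)
  df$sd_log10 <- as.numeric(df$sd_log10)
  df$balanced <- as.logical(df$balanced)
  df
}

# Encode/decode matched-level flags for the prediction TSV.
encode_matched_levels <- function(levels, matched) {
  paste(sprintf("%s:%d", levels, as.integer(matched)), collapse = ";")
}

#' @export
print.kinetic_records <- function(x, ...) {
  cat(sprintf("kinetic records: %d measurement(s) (%s)\n", nrow(x),
              paste(unique(x$param_type), collapse = ", ")))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat(sprintf("  %d row(s) rejected at validation\n", nrow(rej)))
  }
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
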