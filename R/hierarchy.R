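# Nested group-path construction for the KM and kcat multilevel hierarchies.
#
# A group path is the ordered list of (level name, group key) pairs placing a
# measurement in the model hierarchy, coarse to fine. Keys accumulate: a fine
# key is its parent key plus one refinement, joined with the reserved "|"
# separator, so equality of a fine key implies equality of all coarser keys.

KM_LEVELS <- c("substrate", "ec_reaction", "family", "protein")
KCAT_LEVELS <- c("ec1", "ec2", "ec3", "reaction_direction", "family", "protein")

#' Hierarchy schemas for the KM and kcat models
#'
#' The KM hierarchy is rooted at the substrate (Michaelis constants for a
#' substrate are conserved across reactions), then nests the (EC, reaction)
#' pair, the protein family and the protein identifier. The kcat hierarchy
#' replaces the substrate with the nested one-, two- and three-component EC
#' prefixes, then the (EC, reaction, direction) triple — forward and backward
#' turnover numbers are distinct parameters — then family and protein.
#'
#' @param param_type `"KM"` or `"kcat"`.
#' @return A `group_schema` list with elements `param_type`, `levels` (coarse
#'   to fine) and `path_fun` (the function mapping a record row to its path).
#' @export
group_schema <- function(param_type = c("KM", "kcat")) {
  param_type <- match.arg(param_type)
  if (param_type == "KM") {
    structure(list(param_type = "KM", levels = KM_LEVELS,
                   path_fun = km_group_path),
              class = "group_schema")
  } else {
    structure(list(param_type = "kcat", levels = KCAT_LEVELS,
                   path_fun = kcat_group_path),
              class = "group_schema")
  }
}

#' @export
print.group_schema <- function(x, ...) {
  cat(sprintf("group schema for %s: %s\n", x$param_type,
              paste(x$levels, collapse = " > ")))
  invisible(x)
}

#' Nested EC-number prefixes
#'
#' Returns the 1-, 2- and 3-component prefixes of an EC number that exist and
#' are concrete. A wildcard component (`-`) or the end of a short EC string
#' terminates the expansion: `"4.2.1.-"` yields `"4"`, `"4.2"`, `"4.2.1"` and
#' `"2.-.-.-"` yields only `"2"`.
#'
#' @param ec EC number string with 1-4 dot-separated components.
#' @return Character vector of 0-3 dot-joined prefixes, coarse to fine.
#' @export
ec_prefixes <- function(ec) {
  if (length(ec) != 1 || is.na(ec) || !nzchar(ec)) {
    abort_validation("ec must be a non-empty string")
  }
  if (!valid_ec(ec)) {
    abort_validation(paste0("malformed EC number: '", ec, "'"))
  }
  parts <- strsplit(ec, ".", fixed = TRUE)[[1]]
  keep <- 0
  for (p in parts[seq_len(min(3, length(parts)))]) {
    if (p == "-") break
    keep <- keep + 1
  }
  if (keep == 0) return(character(0))
  vapply(seq_len(keep), function(k) paste(parts[seq_len(k)], collapse = "."),
         character(1))
}

# One row of a records/query data frame -> named list of fields.
row_fields <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort_validation("expected a single record/query row")
    x <- as.list(x)
  }
  x
}

make_path <- function(levels, keys) {
  structure(list(levels = levels, keys = keys), class = "group_path")
}

#' @export
print.group_path <- function(x, ...) {
  cat("group path (coarse > fine):\n")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %-18s %s\n", x$levels[i], x$keys[i]))
  }
  invisible(x)
}

#' Group path of a KM record or query
#'
#' Levels, coarse to fine: substrate; substrate x (EC, reaction); ... x
#' protein family; ... x protein. A missing family or protein truncates the
#' path from the fine end.
#'
#' @param x one record/query row (data frame row or named list).
#' @return A `group_path` with 1-4 levels.
#' @export
km_group_path <- function(x) {
  f <- row_fields(x)
  if (is.na(f$substrate_id %||% NA)) {
    abort_validation("KM group path requires substrate_id")
  }
  keys <- f$substrate_id
  levels <- "substrate"
  if (!is.na(f$reaction_id %||% NA) && !is.na(f$ec %||% NA)) {
    keys <- c(keys, paste(keys[length(keys)], f$ec, f$reaction_id, sep = KEY_SEP))
    levels <- c(levels, "ec_reaction")
    if (!is.na(f$family_id %||% NA)) {
      keys <- c(keys, paste(keys[length(keys)], f$family_id, sep = KEY_SEP))
      levels <- c(levels, "family")
      if (!is.na(f$protein_id %||% NA)) {
        keys <- c(keys, paste(keys[length(keys)], f$protein_id, sep = KEY_SEP))
        levels <- c(levels, "protein")
      }
    }
  }
  make_path(levels, keys)
}

#' Group path of a kcat record or query
#'
#' Levels, coarse to fine: EC class; EC class.subclass; EC sub-subclass;
#' (EC, reaction, direction); ... x protein family; ... x protein. Wildcard
#' or absent EC components drop the corresponding prefix levels (the reaction
#' level then attaches to the deepest concrete EC prefix); a missing family
#' or protein truncates from the fine end.
#'
#' @param x one record/query row (data frame row or named list).
#' @return A `group_path` with 1-6 levels.
#' @export
kcat_group_path <- function(x) {
  f <- row_fields(x)
  if (is.na(f$direction %||% NA)) {
    abort_validation("kcat group path requires direction")
  }
  if (!f$direction %in% c("forward", "backward")) {
    abort_validation("direction must be 'forward' or 'backward'")
  }
  prefixes <- ec_prefixes(f$ec %||% NA)
  if (length(prefixes) == 0) {
    abort_validation("kcat group path requires at least one concrete EC component")
  }
  # accumulate keys on "|" so fine keys extend coarse keys verbatim
  keys <- vapply(prefixes, function(p) {
    gsub(".", KEY_SEP, p, fixed = TRUE)
  }, character(1))
  levels <- c("ec1", "ec2", "ec3")[seq_along(prefixes)]
  if (!is.na(f$reaction_id %||% NA)) {
    keys <- c(keys, paste(keys[length(keys)], f$ec, f$reaction_id, f$direction,
                          sep = KEY_SEP))
    levels <- c(levels, "reaction_direction")
    if (!is.na(f$family_id %||% NA)) {
      keys <- c(keys, paste(keys[length(keys)], f$family_id, sep = KEY_SEP))
      levels <- c(levels, "family")
      if (!is.na(f$protein_id %||% NA)) {
        keys <- c(keys, paste(keys[length(keys)], f$protein_id, sep = KEY_SEP))
        levels <- c(levels, "protein")
      }
    }
  }
  make_path(levels, unname(keys))
}

#' Group path under a schema
#' @param schema a [group_schema].
#' @param x one record/query row.
#' @return A `group_path`.
#' @export
group_path <- function(schema, x) schema$path_fun(x)
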