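# Fit serialization: a directory holding the posterior draws as TSV plus a
# JSON manifest (schema, node table, priors, sampler settings), so that
# prediction can run without refitting.

#' Serialize a fitted model to a directory
#'
#' Writes `manifest.json` (schema, priors, MCMC settings, scale groups),
#' `nodes.tsv` (group-node table: key, level, parent), `records.tsv` (the
#' canonicalized training records, needed for the residual model and
#' variance summaries) and `draws_chain<k>.tsv` (one column per monitored
#' quantity, one row per retained iteration).
#'
#' @param fit a `bmm_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bmm_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- fit$design
  manifest <- list(
    package = "bmkin",
    param_type = d$schema$param_type,
    levels = d$levels,
    scale_by = d$scale_by,
    scale_keys = d$scale_keys,
    priors = fit$priors,
    mcmc = fit$mcmc,
    n_chains = fit$n_chains,
    n_iter = fit$n_iter,
    divergences = fit$divergences
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(
    data.frame(key = d$node_key, level = d$node_level, parent = d$node_parent),
    file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_kinetic_records(structure(d$records, class = c("kinetic_records", "data.frame")),
                        file.path(dir, "records.tsv"))
  for (k in seq_along(fit$chains)) {
    m <- fit$chains[[k]]
    df <- as.data.frame(m)
    df[] <- lapply(df, function(v) sprintf("%.15g", v))
    utils::write.table(df, file.path(dir, sprintf("draws_chain%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a serialized fit
#' @param dir directory written by [write_bmm_fit].
#' @return A `bmm_fit` object.
#' @export
read_bmm_fit <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    abort_validation(paste0("no fit manifest at ", man_path))
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  records <- read_kinetic_records(file.path(dir, "records.tsv"))
  schema <- group_schema(man$param_type)
  design <- build_design(records, schema, scale_by = man$scale_by)
  stopifnot(identical(design$scale_keys, man$scale_keys))
  chain_files <- sort(list.files(dir, pattern = "^draws_chain[0-9]+\\.tsv$",
                                 full.names = TRUE))
  chains <- lapply(chain_files, function(f) {
    df <- utils::read.delim(f, sep = "\t", check.names = FALSE)
    as.matrix(df)
  })
  pr <- man$priors
  structure(list(
    design = design,
    chains = chains,
    n_chains = man$n_chains,
    n_iter = man$n_iter,
    priors = pr,
    mcmc = man$mcmc,
    divergences = man$divergences,
    cache = new.env(parent = emptyenv())
  ), class = "bmm_fit")
}
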