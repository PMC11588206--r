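# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small KM dataset: 6 substrates x 3 reactions x 2 families x 2 proteins,
# 6 observations per leaf (432 records).
small_km_sim <- function() {
  cached("small_km_sim", function() {
    simulate_kinetics(sim_config("KM", level_counts = c(6, 3, 2, 2),
                                 obs_per_leaf = 6, seed = 42))
  })
}

small_km_fit <- function() {
  cached("small_km_fit", function() {
    sim <- small_km_sim()
    fit_bmm(build_design(sim$records, group_schema("KM")),
            chains = 2, warmup = 400, iter = 400, seed = 7)
  })
}

# Longer run on the same data for diagnostics-sensitive checks.
converged_km_fit <- function() {
  cached("converged_km_fit", function() {
    sim <- small_km_sim()
    fit_bmm(build_design(sim$records, group_schema("KM")),
            chains = 4, warmup = 1000, iter = 1000, seed = 7)
  })
}

# One valid record row as a list, for path/constructor tests.
km_record_row <- function(...) {
  utils::modifyList(list(
    param_type = "KM", value_log10 = -3.5, substrate_id = "S1",
    reaction_id = "R1", ec = "2.7.1.1", family_id = "F1", protein_id = "P1",
    organism = "ORG1", direction = NA_character_, source = "test"
  ), list(...))
}

kcat_record_row <- function(...) {
  utils::modifyList(list(
    param_type = "kcat", value_log10 = 1.2, substrate_id = NA_character_,
    reaction_id = "R1", ec = "2.7.1.1", family_id = "F1", protein_id = "P1",
    organism = "ORG1", direction = "forward", source = "test"
  ), list(...))
}

record_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Query row for a record (drops the value).
as_query <- function(row) {
  row$value_log10 <- NULL
  row
}

# Thin wrappers over internal accessors used across test files.
hyperdraws <- function(fit) bmkin:::hyperparameter_draws(fit)
scale_draws <- function(fit) bmkin:::scale_effect_draws(fit)
draw_matrix_public <- function(fit, cols = NULL) bmkin:::draw_matrix(fit, cols)
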