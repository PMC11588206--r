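test_that("design construction counts groups and flags regimes", {
  rec <- kinetic_records(record_df(
    km_record_row(substrate_id = "S1"),
    km_record_row(substrate_id = "S1", value_log10 = -3.2),
    km_record_row(substrate_id = "S2", protein_id = NA)
  ))
  d <- build_design(rec, group_schema("KM"))
  expect_equal(sum(d$node_level == 1), 2) # two distinct substrates
  expect_equal(d$n, 3)
  # record without protein id -> regime 2 ("without")
  no_prot <- d$records$value_log10[!d$has_protein]
  expect_length(no_prot, 1)
  # identical full paths -> identical leaf index
  same <- which(d$records$value_log10 %in% c(-3.5, -3.2))
  expect_equal(d$leaf[same[1]], d$leaf[same[2]])
  expect_error(build_design(rec[0, ], group_schema("KM")),
               class = "bmkin_validation_error")
})

test_that("single-group posterior centers on the generating mean", {
  set.seed(31)
  y <- rnorm(200, -3, 0.1)
  rec <- kinetic_records(data.frame(
    param_type = "KM", value_log10 = y, substrate_id = "S1",
    reaction_id = "R1", ec = "1.1.1.1"
  ))
  fit <- fit_bmm(build_design(rec, group_schema("KM")),
                 chains = 2, warmup = 400, iter = 400, seed = 5)
  b0 <- draw_matrix_public(fit, "b0")
  expect_lt(abs(mean(b0) - (-3)), 3 * sd(b0))
})

test_that("hyperparameters are recovered on synthetic data", {
  sim <- small_km_sim()
  fit <- small_km_fit()
  hp <- colMeans(hyperdraws(fit))
  truth <- sim$truth
  expect_lt(abs(hp[["b0"]] - truth$beta0), 0.8)
  for (l in names(truth$tau)) {
    expect_lt(abs(hp[[paste0("tau_", l)]] - truth$tau[[l]]), 0.2)
  }
  expect_lt(abs(hp[["tau_w"]] - truth$tau_w), 0.15)
})

test_that("the two residual regimes separate when the generator separates them", {
  fit <- small_km_fit()
  hp <- hyperdraws(fit)
  # generator: sd 0.2 with protein id, 0.6 without
  expect_gt(mean(exp(hp[, "gamma_without"])), mean(exp(hp[, "gamma_with"])))
  expect_lt(abs(mean(exp(hp[, "gamma_with"])) - 0.2), 0.08)
  expect_lt(abs(mean(exp(hp[, "gamma_without"])) - 0.6), 0.15)
})

test_that("permuting training rows leaves the posterior draws identical", {
  sim <- small_km_sim()
  df <- as.data.frame(sim$records)
  perm <- withr::with_seed(1, sample(nrow(df)))
  rec_perm <- kinetic_records(df[perm, , drop = FALSE])
  f1 <- fit_bmm(build_design(sim$records, group_schema("KM")),
                chains = 2, warmup = 200, iter = 200, seed = 11)
  f2 <- fit_bmm(build_design(rec_perm, group_schema("KM")),
                chains = 2, warmup = 200, iter = 200, seed = 11)
  expect_equal(f1$chains, f2$chains)
})

test_that("adding a constant to y shifts the intercept and nothing else", {
  sim <- small_km_sim()
  df <- as.data.frame(sim$records)
  df$value_log10 <- df$value_log10 + 2
  f_shift <- fit_bmm(build_design(kinetic_records(df), group_schema("KM")),
                     chains = 2, warmup = 400, iter = 400, seed = 7)
  f_base <- small_km_fit()
  hb <- colMeans(hyperdraws(f_base)); hs <- colMeans(hyperdraws(f_shift))
  expect_lt(abs((hs[["b0"]] - hb[["b0"]]) - 2), 0.2)
  for (nm in setdiff(names(hb), "b0")) {
    expect_lt(abs(hs[[nm]] - hb[[nm]]), 0.12)
  }
})

test_that("reaction scale effects rank-correlate with the generating log-sds", {
  sim <- cached("scale_sim", function() {
    simulate_kinetics(sim_config("KM", level_counts = c(10, 4, 1, 1),
                                 obs_per_leaf = 30, tau_w = 0.4, seed = 77))
  })
  fit <- fit_bmm(build_design(sim$records, group_schema("KM")),
                 chains = 2, warmup = 400, iter = 400, seed = 8)
  w_hat <- colMeans(scale_draws(fit))
  w_true <- sim$truth$w[names(w_hat)]
  expect_equal(length(w_hat), 40)
  expect_gt(cor(w_hat, w_true, method = "spearman"), 0.5)
})

test_that("split R-hat is 1 for constant chains and large for disjoint chains", {
  const <- matrix(2.5, nrow = 100, ncol = 1, dimnames = list(NULL, "x"))
  expect_identical(split_rhat(list(const, const))[["x"]], 1)
  # duplicated stationary chains: near 1 (split halves differ slightly)
  set.seed(2)
  m <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(abs(split_rhat(list(m, m))[["x"]] - 1), 0.05)
  # disjoint supports
  a <- matrix(rnorm(200, 0, 0.1), ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(rnorm(200, 10, 0.1), ncol = 1, dimnames = list(NULL, "x"))
  expect_gt(split_rhat(list(a, b))[["x"]], 3)
  fake <- structure(list(chains = list(a, b), n_chains = 2, n_iter = 200,
                         divergences = 0L), class = "bmm_fit")
  expect_false(diagnose(fake)$pass)
  expect_error(split_rhat(list(a)), class = "bmkin_validation_error")
})

test_that("a healthy long run passes diagnostics at the 1.02 threshold", {
  fit <- converged_km_fit()
  dg <- diagnose(fit, rhat_threshold = 1.02)
  expect_true(dg$pass)
  expect_equal(dg$divergences, 0L)
  expect_true(all(is.finite(dg$rhat)))
})

test_that("variance decomposition recovers the generating shares", {
  sim <- small_km_sim()
  fit <- small_km_fit()
  shares <- variance_decomposition(fit)
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  # generating shares from the truth: realized residual variance per record
  truth <- sim$truth
  rec <- as.data.frame(sim$records)
  sig2 <- exp(2 * (log(ifelse(is.na(rec$protein_id), truth$config$sigma_without,
                              truth$config$sigma_with)) +
                     truth$w[rec$reaction_id]))
  gen_tot <- sum(truth$tau^2) + mean(sig2)
  gen_shares <- c(truth$tau^2, residual = mean(sig2)) / gen_tot
  expect_equal(names(shares), names(gen_shares))
  expect_true(all(abs(shares - gen_shares) < 0.12))
})

test_that("with no group signal the residual takes nearly all variance", {
  sim <- simulate_kinetics(sim_config("KM", level_counts = c(4, 2, 1, 1),
                                      obs_per_leaf = 20, tau = c(0, 0, 0, 0),
                                      tau_w = 0, seed = 3))
  fit <- fit_bmm(build_design(sim$records, group_schema("KM")),
                 chains = 2, warmup = 300, iter = 300, seed = 4)
  expect_gt(variance_decomposition(fit)[["residual"]], 0.8)
})

test_that("fits serialize and reload to identical predictions", {
  fit <- small_km_fit()
  dir <- tempfile("fitdir")
  write_bmm_fit(fit, dir)
  fit2 <- read_bmm_fit(dir)
  q <- as_query(km_record_row(substrate_id = "S01", reaction_id = "R01_1",
                              ec = as.data.frame(small_km_sim()$records)$ec[1],
                              family_id = "F_R01_1_1",
                              protein_id = "P_R01_1_1_1"))
  p1 <- predictive_distribution(fit, q)
  p2 <- predictive_distribution(fit2, q)
  expect_equal(p1$mean_log10, p2$mean_log10, tolerance = 1e-10)
  expect_equal(p1$sd_log10, p2$sd_log10, tolerance = 1e-10)
  expect_equal(p1$matched_levels, p2$matched_levels)
})

test_that("organism-based scale grouping is a configuration switch", {
  sim <- small_km_sim()
  d <- build_design(sim$records, group_schema("KM"), scale_by = "organism")
  expect_equal(length(d$scale_keys), 5) # generator assigns 5 organisms
  fit <- fit_bmm(d, chains = 2, warmup = 200, iter = 200, seed = 9)
  expect_equal(ncol(scale_draws(fit)), 5)
})
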