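# Independent oracle: condition the joint Gaussian of (x, Ax) on Ax = 0 using
# plain solve(), a separately coded path from balance_parameters().
condition_oracle <- function(m, C, A) {
  S12 <- C %*% t(A)
  S22 <- A %*% C %*% t(A)
  K <- S12 %*% solve(S22)
  list(mean = as.numeric(m - K %*% (A %*% m)),
       cov = C - K %*% t(S12))
}

test_that("free energies convert to ln Keq by -dG/(RT)", {
  expect_equal(dg_to_ln_keq(0, 1)$mean, 0)
  rt <- 8.314462618e-3 * 298.15
  expect_equal(dg_to_ln_keq(-rt, 0.5)$mean, 1)
  expect_equal(dg_to_ln_keq(-5.708, 1, 298.15)$mean, log(10), tolerance = 1e-3)
  expect_equal(dg_to_ln_keq(-5.708, 2 * rt, 298.15)$sd, 2)
  expect_error(dg_to_ln_keq(1, 1, temperature = -3),
               class = "bmkin_validation_error")
})

test_that("the Haldane row encodes the textbook uni-uni relationship", {
  s <- reaction_stoichiometry("RX", c("S", "P"), c(-1, 1))
  labels <- c("ln_keq|RX", "ln_kcat_fwd|RX", "ln_kcat_bwd|RX",
              "ln_km|S", "ln_km|P")
  row <- haldane_row(s, labels)
  # ln Keq - ln kcat+ + ln kcat- + ln KM_S - ln KM_P = 0
  # <=> Keq = (kcat+/kcat-) (KM_P / KM_S): check by symbolic substitution
  kcat_f <- 2.3; kcat_b <- -0.7; km_s <- -8; km_p <- -6.5
  keq <- (kcat_f - kcat_b) + (km_p - km_s)
  x <- c(keq, kcat_f, kcat_b, km_s, km_p)
  expect_equal(sum(row * x), 0)
  expect_equal(row, c(1, -1, 1, 1, -1))

  # symmetric case satisfied by Keq = 1 (ln Keq = 0)
  x_sym <- c(0, 1.5, 1.5, -4, -4)
  expect_equal(sum(row * x_sym), 0)

  # doubling stoichiometric coefficients doubles the KM part
  s2 <- reaction_stoichiometry("RX", c("S", "P"), c(-2, 2))
  row2 <- haldane_row(s2, labels)
  expect_equal(row2[4:5], 2 * row[4:5])
  expect_equal(row2[1:3], row[1:3])

  expect_error(haldane_row(s, labels[-4]), "missing",
               class = "bmkin_validation_error")
})

test_that("excluded species (water, protons) drop out of KM terms", {
  s <- reaction_stoichiometry("RX", c("S", "MNXM2", "P"), c(-1, -1, 1))
  labels <- c("ln_keq|RX", "ln_kcat_fwd|RX", "ln_kcat_bwd|RX",
              "ln_km|S", "ln_km|P")
  row <- haldane_row(s, labels) # no ln_km|MNXM2 label needed
  expect_equal(row, c(1, -1, 1, 1, -1))
})

test_that("balancing matches closed-form two-parameter conditioning", {
  mk_priors <- function(sds) {
    structure(list(labels = c("x1", "x2"), mean = c(0, 2), sd = sds,
                   A = matrix(c(1, -1), 1, 2)),
              class = "thermo_prior_set")
  }
  # equal sds: midpoint
  bal <- balance_parameters(mk_priors(c(1, 1)))
  expect_equal(bal$mean, c(1, 1), tolerance = 1e-12)
  # tighter prior wins: inverse-variance weighting
  bal2 <- balance_parameters(mk_priors(c(0.1, 1)))
  m_star <- (0 / 0.1^2 + 2 / 1^2) / (1 / 0.1^2 + 1 / 1^2)
  expect_equal(bal2$mean, c(m_star, m_star), tolerance = 1e-12)
  expect_lt(abs(bal2$mean[1] - 0), abs(bal2$mean[1] - 2))
})

test_that("already consistent priors are left unchanged in the mean", {
  priors <- structure(list(labels = c("x1", "x2"), mean = c(1.3, 1.3),
                           sd = c(0.5, 0.7), A = matrix(c(1, -1), 1, 2)),
                      class = "thermo_prior_set")
  bal <- balance_parameters(priors)
  expect_equal(bal$mean, c(1.3, 1.3), tolerance = 1e-12)
  # covariance still shrinks along the constraint direction
  expect_lt(bal$cov[1, 1], 0.5^2)
  expect_equal(as.numeric(bal$A %*% bal$cov %*% t(bal$A)), 0,
               tolerance = 1e-9)
})

test_that("balance equals the Gaussian-conditioning oracle on random systems", {
  set.seed(17)
  for (rep in 1:25) {
    p <- 6
    m <- rnorm(p, 0, 2)
    sds <- runif(p, 0.2, 1.5)
    A <- matrix(rnorm(12), 2, p)
    priors <- structure(list(labels = paste0("x", 1:p), mean = m, sd = sds,
                             A = A),
                        class = "thermo_prior_set")
    bal <- balance_parameters(priors)
    orc <- condition_oracle(m, diag(sds^2), A)
    expect_equal(bal$mean, orc$mean, tolerance = 1e-9)
    expect_equal(bal$cov, orc$cov, tolerance = 1e-9)
    expect_lte(consistency_residual(bal), 1e-9)
    # shrinkage: prior minus posterior covariance is PSD
    expect_gte(min(eigen(diag(sds^2) - bal$cov, symmetric = TRUE)$values),
               -1e-9)
    # idempotence: re-balancing from the balanced mean moves nothing
    priors2 <- priors; priors2$mean <- bal$mean
    bal2 <- balance_parameters(priors2)
    expect_equal(bal2$mean, bal$mean, tolerance = 1e-9)
  }
})

test_that("dependent constraint rows are reported as errors", {
  A <- rbind(c(1, -1, 0), c(2, -2, 0))
  priors <- structure(list(labels = c("x1", "x2", "x3"), mean = c(0, 1, 2),
                           sd = c(1, 1, 1), A = A),
                      class = "thermo_prior_set")
  expect_error(balance_parameters(priors), "dependent",
               class = "bmkin_validation_error")
})

test_that("an empirical covariance from joint samples steers the update", {
  # x1 tight, x2 loose, constraint x1 = x2: the loose parameter moves more
  set.seed(4)
  n <- 20000
  samples <- cbind(rnorm(n, 0, 0.1), rnorm(n, 1, 1))
  priors <- structure(list(labels = c("x1", "x2"), mean = c(0, 1),
                           sd = c(0.1, 1), A = matrix(c(1, -1), 1, 2)),
                      class = "thermo_prior_set")
  bal <- balance_parameters(priors, correlation_samples = samples)
  expect_lt(abs(bal$mean[1] - 0), abs(bal$mean[2] - 1) + 1e-12)
  expect_lte(consistency_residual(bal), 1e-9)
})

test_that("constraint residuals behave as reported", {
  toy <- generate_thermo_toy(seed = 9)
  bal <- balance_parameters(toy$priors)
  expect_lte(consistency_residual(bal), 1e-9)
  # the unbalanced (noisy) priors are not consistent
  fake <- structure(list(labels = toy$priors$labels, mean = toy$priors$mean,
                         A = toy$priors$A),
                    class = "balanced_parameters")
  expect_gt(consistency_residual(fake), 1e-6)
  # residual is invariant under a consistent permutation of labels
  perm <- rev(seq_along(toy$priors$labels))
  fake_perm <- structure(list(labels = toy$priors$labels[perm],
                              mean = toy$priors$mean[perm],
                              A = toy$priors$A[, perm, drop = FALSE]),
                         class = "balanced_parameters")
  expect_equal(consistency_residual(fake_perm), consistency_residual(fake))
})

test_that("the generated toy truth is exactly Haldane-consistent", {
  toy <- generate_thermo_toy(seed = 2)
  expect_equal(max(abs(toy$priors$A %*% toy$truth)), 0, tolerance = 1e-12)
  # zero perturbation: balancing returns the truth
  pr0 <- toy$priors; pr0$mean <- unname(toy$truth)
  bal0 <- balance_parameters(pr0)
  expect_equal(bal0$mean, unname(toy$truth), tolerance = 1e-9)
})

test_that("balancing moves noisy priors toward the consistent truth", {
  errs <- sapply(1:50, function(s) {
    toy <- generate_thermo_toy(seed = 400 + s)
    bal <- balance_parameters(toy$priors)
    c(prior = sqrt(mean((toy$priors$mean - toy$truth)^2)),
      balanced = sqrt(mean((bal$mean - toy$truth)^2)))
  })
  expect_lt(mean(errs["balanced", ]), mean(errs["prior", ]))
})
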