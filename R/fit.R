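# Bayesian multilevel location-scale model for one parameter type (KM or
# kcat), fitted by Gibbs/slice MCMC through JAGS.
#
# Location: y_i ~ Normal(mu_i, sigma_i) with
#   mu_i = beta0 + sum over observed levels l of u_l[g_l(i)],
#   u_l[.] ~ Normal(0, tau_l).
# Scale (heteroscedastic residuals on the log-sd scale):
#   log sigma_i = gamma_regime(i) + w_group(i),
# with two population intercepts gamma_with / gamma_without for observations
# with/without an annotated protein identifier, and a group effect w (by
# reaction, or optionally by organism) with sd tau_w.
#
# The sampler uses the hierarchically centered parameterization: each group
# node is drawn around its parent's value, a_l = parent + u_l. This is the
# standard Gibbs parameterization for nested normal hierarchies and mixes far
# better than the flat (zero-centered) one for the population intercept.

#' Build the model design for a set of records
#'
#' Assigns every record its nested group path under the schema, builds dense
#' node indices (one node per distinct group key, each pointing at its parent
#' node), the residual regime flag (protein identifier annotated or not) and
#' the scale-model grouping index. Records whose paths are truncated simply
#' attach at the deepest level they have; no missing group is imputed.
#'
#' Records are sorted into a canonical order first, so the design — and hence
#' the MCMC output for a given seed — is invariant under permutation of the
#' input rows.
#'
#' @param records a [kinetic_records] data frame, all of one `param_type`.
#' @param schema a [group_schema] matching the records' `param_type`.
#' @param scale_by grouping of the residual scale effects: `"reaction"`
#'   (default) or `"organism"`.
#' @return A `bmm_design` list.
#' @export
build_design <- function(records, schema, scale_by = c("reaction", "organism")) {
  scale_by <- match.arg(scale_by)
  if (nrow(records) == 0) abort_validation("no records to build a design from")
  if (!all(records$param_type == schema$param_type)) {
    abort_validation(paste0(
      "all records must have param_type '", schema$param_type, "'"
    ))
  }
  df <- as.data.frame(records)
  paths <- lapply(seq_len(nrow(df)), function(i) group_path(schema, df[i, ]))
  full_key <- vapply(paths, function(p) p$keys[length(p$keys)], character(1))
  ord <- order(full_key, is.na(df$protein_id), df$organism, df$value_log10,
               df$source, method = "radix")
  df <- df[ord, , drop = FALSE]
  paths <- paths[ord]
  rownames(df) <- NULL

  levels <- schema$levels
  L <- length(levels)
  # node bookkeeping: nodes[key] -> index; per node its level and parent
  node_key <- character(0)
  node_level <- integer(0)
  node_parent <- integer(0) # 0 = root (population intercept)
  node_of <- new.env(parent = emptyenv())
  leaf <- integer(nrow(df))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    parent <- 0L
    for (j in seq_along(p$levels)) {
      k <- p$keys[j]
      idx <- node_of[[k]]
      if (is.null(idx)) {
        node_key <- c(node_key, k)
        node_level <- c(node_level, match(p$levels[j], levels))
        node_parent <- c(node_parent, parent)
        idx <- length(node_key)
        node_of[[k]] <- idx
      }
      parent <- idx
    }
    leaf[i] <- parent
  }

  has_protein <- !is.na(df$protein_id)
  regime <- ifelse(has_protein, 1L, 2L) # 1 = with protein id, 2 = without
  scale_raw <- if (scale_by == "reaction") df$reaction_id else df$organism
  scale_raw[is.na(scale_raw)] <- "(unknown)"
  scale_keys <- sort(unique(scale_raw))
  sgrp <- match(scale_raw, scale_keys)

  structure(list(
    schema = schema,
    records = df,
    y = df$value_log10,
    n = nrow(df),
    levels = levels,
    node_key = node_key,
    node_level = node_level,
    node_parent = node_parent,
    leaf = leaf,
    has_protein = has_protein,
    regime = regime,
    scale_by = scale_by,
    scale_keys = scale_keys,
    sgrp = sgrp
  ), class = "bmm_design")
}

#' @export
print.bmm_design <- function(x, ...) {
  cat(sprintf("bmm design (%s): %d observations, %d group nodes\n",
              x$schema$param_type, x$n, length(x$node_key)))
  tab <- table(factor(x$levels[x$node_level], levels = x$levels))
  for (l in names(tab)) cat(sprintf("  %-18s %d group(s)\n", l, tab[[l]]))
  cat(sprintf("  scale groups (%s): %d; without protein id: %d/%d\n",
              x$scale_by, length(x$scale_keys), sum(!x$has_protein), x$n))
  invisible(x)
}

#' Weakly informative prior configuration
#'
#' Defaults (resolved against the data at fit time where `NULL`): population
#' intercept Normal(sample mean, 2 x sample sd); per-level group sds
#' HalfNormal(1) on the log10 scale; scale-model intercepts Normal(log sample
#' sd, 1) on the log-sd scale; scale-group sd HalfNormal(0.5).
#'
#' @param beta0_mean,beta0_sd prior for the population intercept.
#' @param tau_scale half-normal scale(s) for the per-level group sds
#'   (recycled across levels).
#' @param gamma_mean,gamma_sd prior for the two scale-model intercepts.
#' @param tau_w_scale half-normal scale for the scale-group effect sd.
#' @return A `prior_config` list.
#' @export
prior_config <- function(beta0_mean = NULL, beta0_sd = NULL, tau_scale = 1,
                         gamma_mean = NULL, gamma_sd = 1, tau_w_scale = 0.5) {
  for (v in list(beta0_sd, tau_scale, gamma_sd, tau_w_scale)) {
    if (!is.null(v) && any(v <= 0)) abort_validation("prior scales must be > 0")
  }
  structure(list(beta0_mean = beta0_mean, beta0_sd = beta0_sd,
                 tau_scale = tau_scale, gamma_mean = gamma_mean,
                 gamma_sd = gamma_sd, tau_w_scale = tau_w_scale),
            class = "prior_config")
}

resolve_priors <- function(priors, y, L) {
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  list(
    beta0_mean = priors$beta0_mean %||% mean(y),
    beta0_sd = priors$beta0_sd %||% (2 * sdy),
    tau_scale = rep_len(priors$tau_scale, L),
    gamma_mean = priors$gamma_mean %||% log(sdy),
    gamma_sd = priors$gamma_sd,
    tau_w_scale = priors$tau_w_scale
  )
}

bmm_model_code <- "
model {
  b0 ~ dnorm(b0_mean, 1 / b0_sd^2)
  for (l in 1:L) { tau[l] ~ dnorm(0, 1 / tau_scale[l]^2) T(0,) }
  node[1] <- b0
  for (j in 2:M) { node[j] ~ dnorm(node[parent[j]], 1 / tau[nlev[j]]^2) }
  g[1] ~ dnorm(g_mean, 1 / g_sd^2)
  g[2] ~ dnorm(g_mean, 1 / g_sd^2)
  tauw ~ dnorm(0, 1 / tauw_scale^2) T(0,)
  for (r in 1:G) { w[r] ~ dnorm(0, 1 / tauw^2) }
  for (i in 1:n) {
    y[i] ~ dnorm(node[leaf[i]], exp(-2 * (g[regime[i]] + w[sgrp[i]])))
  }
}
"

#' Fit the multilevel location-scale model by MCMC
#'
#' Runs JAGS (Gibbs/slice sampling) on the hierarchically centered
#' parameterization and returns posterior draws of the population intercept,
#' all group nodes, the per-level group sds, the two scale intercepts, the
#' scale-group effects and their sd, together with the design and sampler
#' metadata. Deterministic given `seed` and the JAGS version.
#'
#' @param design a [build_design] result.
#' @param priors a [prior_config]; `NULL` fields resolve against the data.
#' @param chains number of chains (>= 2).
#' @param warmup adaptation + burn-in iterations per chain.
#' @param iter retained sampling iterations per chain.
#' @param seed integer seed (mandatory).
#' @param target_accept accepted for interface compatibility with
#'   Hamiltonian samplers; the Gibbs engine has no such tuning knob and the
#'   value is recorded but unused.
#' @param quiet suppress JAGS progress output.
#' @return A `bmm_fit` object.
#' @export
fit_bmm <- function(design, priors = prior_config(), chains = 4,
                    warmup = 1000, iter = 1000, seed, target_accept = 0.95,
                    quiet = TRUE) {
  if (missing(seed)) abort_validation("seed is mandatory")
  if (chains < 2) abort_validation("at least 2 chains are required")
  if (design$n < 1) abort_validation("empty design")
  L <- length(design$levels)
  pr <- resolve_priors(priors, design$y, L)
  M <- length(design$node_key) + 1L # +1 for the root slot holding b0
  dat <- list(
    y = design$y, n = design$n, L = L, M = M, G = length(design$scale_keys),
    parent = c(1L, design$node_parent + 1L), # root's slot is node[1]
    nlev = c(1L, design$node_level),
    leaf = design$leaf + 1L,
    regime = design$regime, sgrp = design$sgrp,
    b0_mean = pr$beta0_mean, b0_sd = pr$beta0_sd,
    tau_scale = pr$tau_scale, g_mean = pr$gamma_mean, g_sd = pr$gamma_sd,
    tauw_scale = pr$tau_w_scale
  )
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(as.integer(seed)) + 1000L * ch) %% 2147483647L)
  })
  n_adapt <- max(100L, as.integer(floor(warmup / 2)))
  n_burn <- max(0L, as.integer(warmup) - n_adapt)
  run <- function() {
    jm <- rjags::jags.model(textConnection(bmm_model_code), data = dat,
                            inits = inits, n.chains = chains,
                            n.adapt = n_adapt, quiet = quiet)
    if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, c("b0", "tau", "g", "tauw", "node", "w"),
                        n.iter = iter, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  chains_list <- lapply(samples, function(m) as.matrix(m))

  structure(list(
    design = design,
    chains = chains_list,
    n_chains = chains,
    n_iter = iter,
    priors = pr,
    mcmc = list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                target_accept = target_accept, engine = "JAGS"),
    divergences = 0L, # Gibbs/slice sampling has no divergent transitions
    cache = new.env(parent = emptyenv())
  ), class = "bmm_fit")
}

#' @export
print.bmm_fit <- function(x, ...) {
  cat(sprintf("bmm fit (%s): %d obs, %d chains x %d draws (seed %s)\n",
              x$design$schema$param_type, x$design$n, x$n_chains, x$n_iter,
              format(x$mcmc$seed)))
  s <- hyperparameter_summary(x)
  print(round(s, 4))
  invisible(x)
}

# Combined draw matrix (all chains stacked), columns as named by JAGS.
# Stacking is cached per fit (fits carry a cache environment).
draw_matrix <- function(fit, cols = NULL) {
  cache <- fit$cache
  m <- if (!is.null(cache)) cache$combined else NULL
  if (is.null(m)) {
    m <- do.call(rbind, fit$chains)
    if (!is.null(cache)) cache$combined <- m
  }
  if (is.null(cols)) m else m[, cols, drop = FALSE]
}

n_draws <- function(fit) fit$n_chains * fit$n_iter

# Hyperparameter draws with readable names: b0, tau_<level>, gamma_with,
# gamma_without, tau_w.
hyperparameter_draws <- function(fit) {
  lv <- fit$design$levels
  cols <- c("b0", sprintf("tau[%d]", seq_along(lv)), "g[1]", "g[2]", "tauw")
  m <- draw_matrix(fit, cols)
  colnames(m) <- c("b0", paste0("tau_", lv), "gamma_with", "gamma_without",
                   "tau_w")
  m
}

hyperparameter_summary <- function(fit) {
  m <- hyperparameter_draws(fit)
  t(apply(m, 2, function(v) {
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))
  }))
}

# Draws of the zero-centered group effects u for one node: node value minus
# parent value (the root's value is b0).
node_draws <- function(fit) {
  M <- length(fit$design$node_key) + 1L
  draw_matrix(fit, sprintf("node[%d]", seq_len(M)))
}

#' Group-effect draws for every node
#' @param fit a `bmm_fit`.
#' @return matrix (draws x nodes) of zero-centered group effects, columns
#'   named by group key.
#' @export
group_effect_draws <- function(fit) {
  nd <- node_draws(fit)
  parent_slot <- c(fit$design$node_parent + 1L)
  u <- nd[, -1, drop = FALSE] - nd[, parent_slot, drop = FALSE]
  colnames(u) <- fit$design$node_key
  u
}

# Scale-effect draws (draws x scale groups), columns named by group key.
scale_effect_draws <- function(fit) {
  G <- length(fit$design$scale_keys)
  m <- draw_matrix(fit, sprintf("w[%d]", seq_len(G)))
  colnames(m) <- fit$design$scale_keys
  m
}

# Per-draw residual sd for each training observation (draws x n). Can be
# large; computed on demand.
residual_sd_draws <- function(fit) {
  g <- draw_matrix(fit, c("g[1]", "g[2]"))
  w <- scale_effect_draws(fit)
  exp(g[, fit$design$regime, drop = FALSE] + w[, fit$design$sgrp, drop = FALSE])
}

# Posterior mean of sigma_i^2 averaged over training observations, computed
# per unique (regime, scale group) combination to avoid the full matrix.
mean_residual_var <- function(fit) {
  d <- fit$design
  g2 <- exp(2 * draw_matrix(fit, c("g[1]", "g[2]")))
  w2 <- exp(2 * scale_effect_draws(fit))
  combos <- unique(data.frame(r = d$regime, s = d$sgrp))
  counts <- mapply(function(r, s) sum(d$regime == r & d$sgrp == s),
                   combos$r, combos$s)
  vals <- mapply(function(r, s) mean(g2[, r] * w2[, s]), combos$r, combos$s)
  sum(vals * counts) / d$n
}

#' Share of variance explained per hierarchy level
#'
#' For each level l the share is the posterior mean of tau_l^2 divided by the
#' total (sum of all posterior-mean tau^2 plus the posterior mean residual
#' variance averaged over training observations); the residual share is
#' included so the shares sum to one.
#'
#' @param fit a `bmm_fit`.
#' @return named numeric vector over the schema levels plus `"residual"`.
#' @export
variance_decomposition <- function(fit) {
  lv <- fit$design$levels
  tau2 <- colMeans(draw_matrix(fit, sprintf("tau[%d]", seq_along(lv)))^2)
  res <- mean_residual_var(fit)
  tot <- sum(tau2) + res
  stats::setNames(c(tau2, res) / tot, c(lv, "residual"))
}
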