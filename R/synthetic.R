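# Synthetic kinetic datasets drawn from the model's own generative structure
# (nested group effects with level-specific sds, two-regime heteroscedastic
# residuals with reaction-specific scale effects), with known ground truth.
# Used for parameter-recovery, calibration and end-to-end tests.

#' Generator configuration
#'
#' Defaults emulate a mid-sized KM study: 12 substrates x 4 reactions x 2
#' protein families x 2 proteins (192 leaves) with 16 observations each
#' (~3000 records); group sds 0.8/0.4/0.2/0.1 log10 units from coarse to
#' fine (the coarse levels dominate, mirroring substrate and reaction being
#' the strongest determinants of KM and kcat); residual sd 0.2 for records
#' with a protein identifier and 0.6 without; reaction scale-effect sd 0.3;
#' 30% of records lack a protein identifier.
#'
#' For `param_type = "kcat"` the hierarchy has six levels and `level_counts`
#' is (EC classes, subclasses per class, sub-subclasses per subclass,
#' reactions per sub-subclass, families per reaction, proteins per family);
#' every reaction is generated in both directions.
#'
#' @param param_type `"KM"` or `"kcat"`.
#' @param level_counts integer vector of per-level branching factors (length
#'   4 for KM, 6 for kcat).
#' @param obs_per_leaf observations per finest group.
#' @param beta0 true population intercept (log10 units).
#' @param tau true group sds per level (same length as the hierarchy).
#' @param sigma_with,sigma_without true residual sds for records with/without
#'   a protein identifier (the generator stores their logs as the true scale
#'   intercepts).
#' @param tau_w true sd of the reaction-level scale effects (log-sd scale).
#' @param missing_protein_frac fraction of records lacking a protein id.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(param_type = c("KM", "kcat"),
                       level_counts = NULL,
                       obs_per_leaf = 16,
                       beta0 = if (param_type == "KM") -4 else 1,
                       tau = NULL,
                       sigma_with = 0.2, sigma_without = 0.6,
                       tau_w = 0.3,
                       missing_protein_frac = 0.3,
                       seed = 1) {
  param_type <- match.arg(param_type)
  L <- if (param_type == "KM") 4L else 6L
  level_counts <- level_counts %||%
    if (param_type == "KM") c(12, 4, 2, 2) else c(3, 2, 2, 4, 2, 2)
  tau <- tau %||%
    if (param_type == "KM") c(0.8, 0.4, 0.2, 0.1) else c(0.5, 0.4, 0.3, 0.4, 0.2, 0.1)
  if (length(level_counts) != L || length(tau) != L) {
    abort_validation(sprintf("%s generator needs %d level counts and sds",
                             param_type, L))
  }
  if (any(level_counts < 1) || obs_per_leaf < 1) {
    abort_validation("counts must be >= 1")
  }
  if (any(tau < 0) || sigma_with <= 0 || sigma_without <= 0 || tau_w < 0) {
    abort_validation("sds must be non-negative (residual sds positive)")
  }
  if (missing_protein_frac < 0 || missing_protein_frac > 1) {
    abort_validation("missing_protein_frac must be in [0, 1]")
  }
  structure(list(param_type = param_type, level_counts = level_counts,
                 obs_per_leaf = obs_per_leaf, beta0 = beta0, tau = tau,
                 sigma_with = sigma_with, sigma_without = sigma_without,
                 tau_w = tau_w, missing_protein_frac = missing_protein_frac,
                 seed = seed),
            class = "sim_config")
}

# Leaf identifier tables. Identifiers embed level indices, so they are unique
# and never contain the reserved "|" separator.
km_leaf_table <- function(cf) {
  g <- expand.grid(p = seq_len(cf$level_counts[4]),
                   f = seq_len(cf$level_counts[3]),
                   r = seq_len(cf$level_counts[2]),
                   s = seq_len(cf$level_counts[1]))
  g <- g[order(g$s, g$r, g$f, g$p), , drop = FALSE]
  s_id <- sprintf("S%02d", g$s)
  r_id <- sprintf("R%02d_%d", g$s, g$r)
  data.frame(
    substrate_id = s_id,
    reaction_id = r_id,
    ec = sprintf("%d.%d.%d.%d", 1 + (g$s - 1) %% 6, 1 + (g$r - 1) %% 9,
                 1 + (g$s + g$r) %% 9, g$s * 10 + g$r),
    family_id = sprintf("F_%s_%d", r_id, g$f),
    protein_id = sprintf("P_%s_%d_%d", r_id, g$f, g$p),
    direction = "forward",
    stringsAsFactors = FALSE
  )
}

kcat_leaf_table <- function(cf) {
  lc <- cf$level_counts
  g <- expand.grid(p = seq_len(lc[6]), f = seq_len(lc[5]),
                   d = 1:2, r = seq_len(lc[4]),
                   e3 = seq_len(lc[3]), e2 = seq_len(lc[2]),
                   e1 = seq_len(lc[1]))
  g <- g[order(g$e1, g$e2, g$e3, g$r, g$d, g$f, g$p), , drop = FALSE]
  ec <- sprintf("%d.%d.%d.%d", g$e1, g$e2, g$e3, g$r)
  r_id <- sprintf("R%d_%d_%d_%d", g$e1, g$e2, g$e3, g$r)
  data.frame(
    substrate_id = NA_character_,
    reaction_id = r_id,
    ec = ec,
    family_id = sprintf("F_%s_%s_%d", r_id, c("f", "b")[g$d], g$f),
    protein_id = sprintf("P_%s_%s_%d_%d", r_id, c("f", "b")[g$d], g$f, g$p),
    direction = c("forward", "backward")[g$d],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic kinetic dataset with known ground truth
#'
#' Draws group effects per hierarchy level from Normal(0, tau_l), a scale
#' effect per reaction from Normal(0, tau_w), then for each observation
#' `value_log10 = beta0 + sum of its group effects + eps`, with `eps ~
#' Normal(0, exp(log sigma_regime + w_reaction))`. Records lacking a protein
#' identifier omit the protein-level effect and use the wider regime.
#' Deterministic given the config seed.
#'
#' @param config a [sim_config].
#' @return list with `records` (a [kinetic_records]) and `truth` (true
#'   hyperparameters plus every drawn group and scale effect, named by the
#'   same group keys the hierarchy module constructs).
#' @export
simulate_kinetics <- function(config) {
  cf <- config
  schema <- group_schema(cf$param_type)
  leaves <- if (cf$param_type == "KM") km_leaf_table(cf) else kcat_leaf_table(cf)
  L <- length(schema$levels)

  # group keys per leaf at every level, via the hierarchy module itself
  leaf_query <- leaves
  leaf_query$param_type <- cf$param_type
  key_mat <- t(vapply(seq_len(nrow(leaves)), function(i) {
    query_level_keys(schema, as.list(leaf_query[i, ]))
  }, character(L)))

  withr_seed(cf$seed, {
    u <- vector("list", L)
    for (l in seq_len(L)) {
      keys <- unique(key_mat[, l])
      u[[l]] <- stats::setNames(stats::rnorm(length(keys), 0, cf$tau[l]), keys)
    }
    reactions <- unique(leaves$reaction_id)
    w <- stats::setNames(stats::rnorm(length(reactions), 0, cf$tau_w), reactions)

    rows <- leaves[rep(seq_len(nrow(leaves)), each = cf$obs_per_leaf), ,
                   drop = FALSE]
    keyrep <- key_mat[rep(seq_len(nrow(leaves)), each = cf$obs_per_leaf), ,
                      drop = FALSE]
    n <- nrow(rows)
    has_protein <- stats::runif(n) >= cf$missing_protein_frac
    mu <- rep(cf$beta0, n)
    for (l in seq_len(L)) {
      contrib <- unname(u[[l]][keyrep[, l]])
      if (schema$levels[l] == "protein") contrib[!has_protein] <- 0
      mu <- mu + contrib
    }
    sig <- exp(log(ifelse(has_protein, cf$sigma_with, cf$sigma_without)) +
                 unname(w[rows$reaction_id]))
    value <- mu + stats::rnorm(n, 0, sig)

    df <- data.frame(
      param_type = cf$param_type,
      value_log10 = value,
      substrate_id = rows$substrate_id,
      reaction_id = rows$reaction_id,
      ec = rows$ec,
      family_id = rows$family_id,
      protein_id = ifelse(has_protein, rows$protein_id, NA_character_),
      organism = sprintf("ORG%d", 1 + seq_len(n) %% 5),
      direction = rows$direction,
      source = "synthetic",
      stringsAsFactors = FALSE
    )
    truth <- list(
      beta0 = cf$beta0, tau = stats::setNames(cf$tau, schema$levels),
      gamma_with = log(cf$sigma_with), gamma_without = log(cf$sigma_without),
      tau_w = cf$tau_w, u = u, w = w, config = cf
    )
    list(records = kinetic_records(df), truth = truth)
  })
}

#' Toy thermodynamic system with known consistent truth
#'
#' Builds a small reaction network (unit stoichiometries over a shared
#' metabolite pool), draws a parameter set that satisfies every Haldane
#' relationship exactly — ln Keq is computed from the drawn kcat and KM
#' values — and then perturbs the means with independent Gaussian noise to
#' form priors. Balancing the noisy priors should move them back toward the
#' consistent manifold.
#'
#' @param seed integer seed.
#' @param n_reactions number of reactions (chained over a metabolite pool).
#' @param noise_sd sd of the mean perturbation and of the priors (ln scale).
#' @return list with `priors` (a [thermo_prior_set]), `truth` (named vector
#'   in label order) and `stoichs`.
#' @export
generate_thermo_toy <- function(seed = 1, n_reactions = 3, noise_sd = 0.5) {
  withr_seed(seed, {
    mets <- sprintf("M%d", seq_len(n_reactions + 1))
    stoichs <- lapply(seq_len(n_reactions), function(r) {
      reaction_stoichiometry(sprintf("RX%d", r),
                             c(mets[r], mets[r + 1]), c(-1, 1))
    })
    km_truth <- stats::setNames(stats::rnorm(length(mets), log(1e-4), 1),
                                mets)
    labels <- character(0); truth <- numeric(0)
    add <- function(lab, val) {
      labels <<- c(labels, lab); truth <<- c(truth, val)
    }
    for (s in stoichs) {
      kf <- stats::rnorm(1, log(10), 1)
      kb <- stats::rnorm(1, log(1), 1)
      keq <- kf - kb + sum(s$coefficients * km_truth[s$metabolite_ids])
      add(label_keq(s$reaction_id), keq)
      add(label_kcat(s$reaction_id, "forward"), kf)
      add(label_kcat(s$reaction_id, "backward"), kb)
    }
    for (m in mets) add(paste0("ln_km", KEY_SEP, m), km_truth[[m]])
    prior_df <- data.frame(
      label = labels,
      mean = truth + stats::rnorm(length(truth), 0, noise_sd),
      sd = rep(noise_sd, length(truth)),
      stringsAsFactors = FALSE
    )
    priors <- thermo_prior_set(prior_df, stoichs, share_km = "metabolite",
                               exclude = character(0))
    list(priors = priors, truth = stats::setNames(truth, labels),
         stoichs = stoichs)
  })
}
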