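# Predictive distributions for query parameters: posterior location draws at
# the deepest matched hierarchy level, marginalization over unmatched levels
# via their group sds, and the heteroscedastic residual term.

# Align a query's group path with the fit's schema levels: returns one key
# per schema level (NA where the query carries no key for that level).
query_level_keys <- function(schema, query) {
  p <- group_path(schema, query)
  keys <- rep(NA_character_, length(schema$levels))
  keys[match(p$levels, schema$levels)] <- p$keys
  keys
}

#' Match a query against the training hierarchy
#'
#' For each schema level, `matched` is true iff the query carries a group key
#' at that level and that key occurred in the training data. Matching is
#' monotone in the hierarchy: once a level is unmatched, all finer levels are
#' unmatched (predictions never skip over an unknown coarse group to use a
#' finer one).
#'
#' @param fit a `bmm_fit`.
#' @param query one query row ([query_parameters] row or named list).
#' @return data frame with columns `level`, `matched`, `key`.
#' @export
match_levels <- function(fit, query) {
  q <- row_fields(query)
  if (!identical(q$param_type, fit$design$schema$param_type)) {
    abort_validation(paste0(
      "query param_type must be '", fit$design$schema$param_type, "'"
    ))
  }
  d <- fit$design
  keys <- query_level_keys(d$schema, q)
  matched <- logical(length(keys))
  ok <- TRUE
  for (l in seq_along(keys)) {
    hit <- ok && !is.na(keys[l]) && keys[l] %in% d$node_key[d$node_level == l]
    matched[l] <- isTRUE(hit)
    ok <- matched[l]
  }
  data.frame(level = d$levels, matched = matched, key = keys,
             stringsAsFactors = FALSE)
}

# Location draws for a query: node value at its deepest matched level, or the
# population intercept when nothing matches.
location_draws <- function(fit, ml) {
  deepest <- if (any(ml$matched)) max(which(ml$matched)) else 0L
  if (deepest == 0L) {
    draw_matrix(fit, "b0")[, 1]
  } else {
    slot <- match(ml$key[deepest], fit$design$node_key) + 1L
    draw_matrix(fit, sprintf("node[%d]", slot))[, 1]
  }
}

# Per-draw residual sd for a query: regime intercept by protein annotation,
# plus the scale-group effect if the query's reaction (or organism) was seen
# in training, else a fresh effect drawn from Normal(0, tau_w) per draw.
query_residual_sd_draws <- function(fit, q, rng_seed) {
  d <- fit$design
  regime <- if (!is.na(q$protein_id %||% NA)) 1L else 2L
  g <- draw_matrix(fit, sprintf("g[%d]", regime))[, 1]
  key <- if (d$scale_by == "reaction") q$reaction_id %||% NA else q$organism %||% NA
  idx <- match(key, d$scale_keys)
  if (!is.na(idx)) {
    w <- draw_matrix(fit, sprintf("w[%d]", idx))[, 1]
  } else {
    tauw <- draw_matrix(fit, "tauw")[, 1]
    w <- withr_seed(rng_seed, stats::rnorm(length(tauw), 0, tauw))
  }
  exp(g + w)
}

# Evaluate expr under a local RNG state (restores the caller's state).
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Predictive normal distribution for one query parameter
#'
#' Per posterior draw the location is the value of the deepest matched group
#' node. The predictive variance adds (i) the posterior variance of that
#' location, (ii) the posterior mean of the summed squared group sds of all
#' unmatched levels, and (iii), when `include_residual` is true (the
#' default), the posterior mean squared residual sd for the query's
#' annotation regime and scale group — so the reported uncertainty describes
#' a new measurement, not just the latent parameter.
#'
#' @param fit a `bmm_fit`.
#' @param query one query row.
#' @param include_residual include the residual-scatter term.
#' @param seed seed for the draw-level marginalization of the scale effect of
#'   an unseen reaction/organism (defaults to the fit's seed).
#' @return A `bmm_prediction` list: `mean_log10`, `sd_log10`,
#'   `matched_levels` (data frame), `query`, `include_residual`.
#' @export
predictive_distribution <- function(fit, query, include_residual = TRUE,
                                    seed = NULL) {
  q <- row_fields(query)
  ml <- match_levels(fit, q)
  loc <- location_draws(fit, ml)
  unmatched <- which(!ml$matched)
  v_unmatched <- 0
  if (length(unmatched) > 0) {
    tau <- draw_matrix(fit, sprintf("tau[%d]", unmatched))
    v_unmatched <- mean(rowSums(tau^2))
  }
  v <- stats::var(loc) + v_unmatched
  if (include_residual) {
    sig <- query_residual_sd_draws(fit, q, seed %||% fit$mcmc$seed)
    v <- v + mean(sig^2)
  }
  structure(list(
    mean_log10 = mean(loc),
    sd_log10 = sqrt(v),
    matched_levels = ml,
    query = q,
    include_residual = include_residual
  ), class = "bmm_prediction")
}

#' @export
print.bmm_prediction <- function(x, ...) {
  cat(sprintf("predicted log10 %s: %.3f +/- %.3f (matched: %s)\n",
              x$query$param_type, x$mean_log10, x$sd_log10,
              paste(x$matched_levels$level[x$matched_levels$matched],
                    collapse = ", ")))
  invisible(x)
}

#' Predict many query parameters at once
#'
#' Vectorized wrapper around [predictive_distribution] returning a data
#' frame ready for [write_predictions].
#'
#' @param fit a `bmm_fit`.
#' @param queries a [query_parameters] data frame.
#' @param include_residual include residual scatter in the reported sd.
#' @param seed seed for unseen-scale-group marginalization.
#' @return data frame: query columns + `mean_log10`, `sd_log10`,
#'   `matched_levels`, `balanced` (always `FALSE` here).
#' @export
predict_parameters <- function(fit, queries, include_residual = TRUE,
                               seed = NULL) {
  out <- as.data.frame(queries, stringsAsFactors = FALSE)
  out$mean_log10 <- NA_real_
  out$sd_log10 <- NA_real_
  out$matched_levels <- NA_character_
  for (i in seq_len(nrow(out))) {
    p <- predictive_distribution(fit, out[i, QUERY_COLUMNS, drop = FALSE],
                                 include_residual = include_residual,
                                 seed = if (is.null(seed)) NULL else seed + i)
    out$mean_log10[i] <- p$mean_log10
    out$sd_log10[i] <- p$sd_log10
    out$matched_levels[i] <- encode_matched_levels(p$matched_levels$level,
                                                  p$matched_levels$matched)
  }
  out$balanced <- FALSE
  out
}

#' Correlated joint samples for a set of queries
#'
#' Draws `n` samples of the log10 parameter values of all queries jointly.
#' Posterior draws are shared across queries, so queries whose paths share
#' group keys are correlated; unmatched group effects are drawn fresh per
#' sample but shared between queries that refer to the same unseen key.
#' Residual noise (if included) is independent per query.
#'
#' @param fit a `bmm_fit`.
#' @param queries a [query_parameters] data frame (same param_type as `fit`).
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @param include_residual add residual noise to each sample.
#' @return numeric matrix (n x number of queries).
#' @export
joint_samples <- function(fit, queries, n, seed, include_residual = TRUE) {
  if (n < 2) abort_validation("n must be >= 2")
  queries <- as.data.frame(queries, stringsAsFactors = FALSE)
  Q <- nrow(queries)
  d <- fit$design
  L <- length(d$levels)
  mls <- lapply(seq_len(Q), function(i) {
    match_levels(fit, queries[i, QUERY_COLUMNS, drop = FALSE])
  })
  locs <- vapply(mls, function(ml) location_draws(fit, ml), numeric(n_draws(fit)))
  tau <- draw_matrix(fit, sprintf("tau[%d]", seq_len(L)))
  tauw <- draw_matrix(fit, "tauw")[, 1]
  gmat <- draw_matrix(fit, c("g[1]", "g[2]"))
  wmat <- scale_effect_draws(fit)

  withr_seed(seed, {
    idx <- sample.int(n_draws(fit), n, replace = TRUE)
    out <- matrix(locs[idx, , drop = FALSE], nrow = n, ncol = Q)
    # shared unmatched effects: one draw per unique (level, key) per sample
    shared <- new.env(parent = emptyenv())
    for (qi in seq_len(Q)) {
      ml <- mls[[qi]]
      for (l in which(!ml$matched)) {
        key <- ml$key[l]
        if (is.na(key)) { # no key at this level: private effect
          out[, qi] <- out[, qi] + stats::rnorm(n, 0, tau[idx, l])
        } else {
          id <- paste0(l, KEY_SEP, key)
          eff <- shared[[id]]
          if (is.null(eff)) {
            eff <- stats::rnorm(n, 0, tau[idx, l])
            shared[[id]] <- eff
          }
          out[, qi] <- out[, qi] + eff
        }
      }
      if (include_residual) {
        q <- as.list(queries[qi, ])
        regime <- if (!is.na(q$protein_id %||% NA)) 1L else 2L
        skey <- if (d$scale_by == "reaction") q$reaction_id else q$organism
        sidx <- match(skey %||% NA, d$scale_keys)
        w <- if (!is.na(sidx)) wmat[idx, sidx] else stats::rnorm(n, 0, tauw[idx])
        out[, qi] <- out[, qi] + stats::rnorm(n, 0, exp(gmat[idx, regime] + w))
      }
    }
    out
  })
}
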