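# Cross-validation folds (random and grouped), point metrics (R^2, RMSE),
# the probabilistic NELPD metric, and uncertainty-calibration binning.

#' Cross-validation fold assignment
#'
#' `"measurement"` folds randomly partition rows into k near-equal parts.
#' Grouped schemes (`"protein"`, `"family"`, `"reaction"`) never split a
#' group across folds: groups are shuffled (seeded), stably sorted by
#' descending size, and assigned greedily to the currently smallest fold, so
#' fold sizes are as balanced as the group sizes permit. Records with a
#' missing grouping field form their own group per distinct `NA`-free key and
#' are pooled under one `"(missing)"` group otherwise. Deterministic given
#' the seed.
#'
#' @param records a [kinetic_records] data frame.
#' @param scheme `"measurement"`, `"protein"`, `"family"` or `"reaction"`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return A `fold_assignment` list: `scheme`, `k`, `fold` (integer per
#'   record), `seed`.
#' @export
make_folds <- function(records, scheme = c("measurement", "protein", "family",
                                           "reaction"),
                       k = 5, seed) {
  scheme <- match.arg(scheme)
  if (missing(seed)) abort_validation("seed is mandatory")
  if (k < 2) abort_validation("k must be >= 2")
  n <- nrow(records)
  if (scheme == "measurement") {
    if (n < k) abort_validation("fewer records than folds")
    fold <- withr_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    col <- c(protein = "protein_id", family = "family_id",
             reaction = "reaction_id")[[scheme]]
    key <- records[[col]]
    key[is.na(key)] <- "(missing)"
    groups <- unique(key)
    if (length(groups) < k) {
      abort_validation(sprintf(
        "grouped scheme '%s' has %d group(s) but k = %d folds were requested",
        scheme, length(groups), k))
    }
    sizes <- as.integer(table(key)[groups])
    ord <- withr_seed(seed, sample(seq_along(groups)))
    groups <- groups[ord]; sizes <- sizes[ord]
    ord2 <- order(-sizes) # stable: ties keep shuffled order
    groups <- groups[ord2]; sizes <- sizes[ord2]
    fold_size <- integer(k)
    group_fold <- integer(length(groups))
    for (i in seq_along(groups)) {
      f <- which.min(fold_size) # lowest index wins ties
      group_fold[i] <- f
      fold_size[f] <- fold_size[f] + sizes[i]
    }
    fold <- group_fold[match(key, groups)]
  }
  structure(list(scheme = scheme, k = k, fold = fold, seed = seed),
            class = "fold_assignment")
}

#' Coefficient of determination
#' @param pred_means predicted means.
#' @param observations observed values.
#' @return `1 - SS_res / SS_tot`, with `SS_tot` about the observation mean.
#' @export
r_squared <- function(pred_means, observations) {
  if (length(observations) < 2) abort_validation("need >= 2 observations")
  sst <- sum((observations - mean(observations))^2)
  if (sst == 0) abort_validation("zero observation variance")
  1 - sum((observations - pred_means)^2) / sst
}

#' Root mean squared error
#' @inheritParams r_squared
#' @export
rmse <- function(pred_means, observations) {
  sqrt(mean((observations - pred_means)^2))
}

#' Negative expected log predictive density
#'
#' Average negative log density of the observations under their predicted
#' normal distributions; lower is better. Unlike RMSE this rewards
#' per-observation uncertainties that match the true error scale.
#'
#' @param pred_means,pred_sds predicted normal means and sds (sds > 0).
#' @param observations observed values.
#' @return scalar NELPD (per-observation average).
#' @export
nelpd <- function(pred_means, pred_sds, observations) {
  if (any(pred_sds <= 0)) abort_validation("all predicted sds must be > 0")
  -mean(stats::dnorm(observations, pred_means, pred_sds, log = TRUE))
}

#' Uncertainty-calibration binning
#'
#' Bins test points by predicted sd (equal-count bins, stable order for
#' ties) or by a categorical key (metabolite, reaction), then compares each
#' bin's predicted root-mean-square sd with its empirical RMSE. A
#' well-calibrated model has ratio near 1 in every bin and a high Pearson
#' correlation across bins.
#'
#' @param pred_means,pred_sds predicted normal means and sds.
#' @param observations observed values.
#' @param by `"predicted_sd"` for quantile bins, or a character vector (one
#'   key per observation, e.g. metabolite or reaction ids) for categorical
#'   bins.
#' @param n_bins number of quantile bins (ignored for categorical `by`).
#' @return A `calibration_report` list: `bins` (data frame with
#'   `predicted_rms_sd`, `empirical_rmse`, `n`, `ratio`, `flagged`),
#'   `pearson_rho` (`NA` when fewer than 2 distinct bins), `global_rmse`.
#'   Bins whose empirical RMSE differs from the global RMSE by more than 25%
#'   are flagged.
#' @export
calibration_bins <- function(pred_means, pred_sds, observations,
                             by = "predicted_sd", n_bins = 10) {
  n <- length(observations)
  if (identical(by, "predicted_sd")) {
    if (n_bins < 2) abort_validation("n_bins must be >= 2")
    if (n < n_bins) abort_validation("need at least n_bins observations")
    ord <- order(pred_sds) # stable for ties
    bin_of <- integer(n)
    bin_of[ord] <- ceiling(seq_len(n) / (n / n_bins))
    bin_of[bin_of > n_bins] <- n_bins
    # collapse bins with identical sd content (all-equal sds -> one bin)
    labels <- as.character(bin_of)
  } else {
    if (length(by) != n) abort_validation("'by' must have one key per observation")
    labels <- as.character(by)
  }
  err <- observations - pred_means
  bins <- do.call(rbind, lapply(split(seq_len(n), labels), function(ix) {
    data.frame(
      predicted_rms_sd = sqrt(mean(pred_sds[ix]^2)),
      empirical_rmse = sqrt(mean(err[ix]^2)),
      n = length(ix)
    )
  }))
  # merge quantile bins that ended up with identical predicted sd (degenerate
  # all-equal input)
  if (identical(by, "predicted_sd") &&
      length(unique(signif(bins$predicted_rms_sd, 12))) == 1 &&
      nrow(bins) > 1) {
    bins <- data.frame(predicted_rms_sd = sqrt(mean(pred_sds^2)),
                       empirical_rmse = sqrt(mean(err^2)), n = n)
  }
  global <- sqrt(mean(err^2))
  bins$ratio <- bins$empirical_rmse / bins$predicted_rms_sd
  bins$flagged <- abs(bins$empirical_rmse - global) > 0.25 * global
  rho <- if (nrow(bins) >= 2 && stats::sd(bins$predicted_rms_sd) > 0 &&
             stats::sd(bins$empirical_rmse) > 0) {
    stats::cor(bins$predicted_rms_sd, bins$empirical_rmse)
  } else {
    NA_real_
  }
  structure(list(bins = bins, pearson_rho = rho, global_rmse = global,
                 by = if (identical(by, "predicted_sd")) "predicted_sd" else "categorical"),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration report (%s): %d bin(s), global RMSE %.3f, Pearson rho %s\n",
              x$by, nrow(x$bins), x$global_rmse,
              ifelse(is.na(x$pearson_rho), "NA", sprintf("%.3f", x$pearson_rho))))
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross-validated evaluation of the multilevel model
#'
#' For each fold: fit on the remaining records, predict the held-out fold,
#' and compute R^2, RMSE and NELPD. The workhorse behind the `evaluate`
#' subcommand.
#'
#' @param records a [kinetic_records] data frame (one param_type).
#' @param scheme fold scheme, see [make_folds].
#' @param k number of folds.
#' @param seed integer seed (folds and MCMC).
#' @param chains,warmup,iter MCMC settings per fold fit.
#' @param folds_to_run optionally evaluate only a subset of folds (e.g. `1`).
#' @return list with `per_fold` (data frame) and `pooled` (metrics over all
#'   held-out predictions), plus the pooled predictions.
#' @export
cross_validate <- function(records, scheme = "measurement", k = 5, seed,
                           chains = 2, warmup = 500, iter = 500,
                           folds_to_run = seq_len(k)) {
  if (missing(seed)) abort_validation("seed is mandatory")
  schema <- group_schema(records$param_type[1])
  fa <- make_folds(records, scheme, k = k, seed = seed)
  rows <- list(); preds <- list()
  for (f in folds_to_run) {
    train <- kinetic_records(as.data.frame(records)[fa$fold != f, , drop = FALSE])
    test <- as.data.frame(records)[fa$fold == f, , drop = FALSE]
    if (nrow(train) == 0 || nrow(test) < 2) next
    fit <- fit_bmm(build_design(train, schema), chains = chains,
                   warmup = warmup, iter = iter, seed = seed + f)
    pr <- predict_parameters(fit, test[QUERY_COLUMNS])
    pr$observed <- test$value_log10
    pr$fold <- f
    preds[[length(preds) + 1]] <- pr
    rows[[length(rows) + 1]] <- data.frame(
      fold = f, n_test = nrow(test),
      r_squared = r_squared(pr$mean_log10, test$value_log10),
      rmse = rmse(pr$mean_log10, test$value_log10),
      nelpd = nelpd(pr$mean_log10, pr$sd_log10, test$value_log10)
    )
  }
  all_pred <- do.call(rbind, preds)
  pooled <- data.frame(
    r_squared = r_squared(all_pred$mean_log10, all_pred$observed),
    rmse = rmse(all_pred$mean_log10, all_pred$observed),
    nelpd = nelpd(all_pred$mean_log10, all_pred$sd_log10, all_pred$observed)
  )
  list(scheme = scheme, k = k, seed = seed,
       per_fold = do.call(rbind, rows), pooled = pooled,
       predictions = all_pred)
}
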