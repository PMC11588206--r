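# Thermodynamic parameter balancing: project independent normal predictions
# of log kinetic parameters and equilibrium constants onto the subspace
# satisfying the Haldane relationships, by conditioning the prior Gaussian on
# the linear constraints. Internal scale is natural log; conversion from the
# models' log10 scale happens at the module boundary (ln = log10 * ln 10).

GAS_CONSTANT_KJ <- 8.314462618e-3 # kJ/(mol K)

# Species excluded from KM terms of Haldane constraints by convention.
DEFAULT_EXCLUDE <- c("WATER", "MNXM2", "h2o", "water", "PROTON", "MNXM1",
                     "h", "h+")

#' Reaction stoichiometry
#'
#' @param reaction_id reaction identifier.
#' @param metabolite_ids character vector of distinct metabolite identifiers.
#' @param coefficients signed stoichiometric coefficients (products positive,
#'   substrates negative, no zeros).
#' @return A `reaction_stoichiometry` list.
#' @export
reaction_stoichiometry <- function(reaction_id, metabolite_ids, coefficients) {
  if (length(metabolite_ids) != length(coefficients)) {
    abort_validation("metabolite_ids and coefficients differ in length")
  }
  if (anyDuplicated(metabolite_ids)) {
    abort_validation("duplicate metabolite in stoichiometry")
  }
  if (any(coefficients == 0)) abort_validation("zero stoichiometric coefficient")
  if (!any(coefficients < 0) || !any(coefficients > 0)) {
    abort_validation("need at least one substrate (<0) and one product (>0)")
  }
  structure(list(reaction_id = reaction_id,
                 metabolite_ids = as.character(metabolite_ids),
                 coefficients = as.numeric(coefficients)),
            class = "reaction_stoichiometry")
}

#' Read reaction stoichiometries from a TSV file
#'
#' Columns: `reaction_id`, `metabolite_id`, `coefficient` (signed; products
#' positive, substrates negative).
#'
#' @param path path to the TSV.
#' @return named list of [reaction_stoichiometry] objects.
#' @export
read_stoichiometries <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("reaction_id", "metabolite_id", "coefficient")
  if (!all(need %in% names(df))) {
    abort_validation(paste0("stoichiometry file needs columns: ",
                            paste(need, collapse = ", ")))
  }
  out <- lapply(split(df, df$reaction_id), function(g) {
    reaction_stoichiometry(g$reaction_id[1], g$metabolite_id, g$coefficient)
  })
  out[unique(df$reaction_id)]
}

#' Convert a standard transformed free energy to ln Keq
#'
#' ln Keq = -dG'/(R T) with R = 8.314462618 J/(mol K); the uncertainty scales
#' the same way. The free energy is taken as already transformed to the
#' compartment conditions (pH, ionic strength, ...).
#'
#' @param dg_mean,dg_sd standard free energy of reaction in kJ/mol and its sd.
#' @param temperature temperature in Kelvin (> 0).
#' @return list with `mean` and `sd` of ln Keq.
#' @export
dg_to_ln_keq <- function(dg_mean, dg_sd, temperature = 298.15) {
  if (any(temperature <= 0)) abort_validation("temperature must be > 0")
  if (any(dg_sd < 0)) abort_validation("dg_sd must be >= 0")
  rt <- GAS_CONSTANT_KJ * temperature
  list(mean = -dg_mean / rt, sd = dg_sd / rt)
}

# Parameter labels. KM labels either share across reactions by metabolite
# (default: affinities for a substrate are conserved across reactions) or are
# reaction-specific.
label_keq <- function(rxn) paste0("ln_keq", KEY_SEP, rxn)
label_kcat <- function(rxn, direction) {
  paste0("ln_kcat_", if (direction == "forward") "fwd" else "bwd", KEY_SEP, rxn)
}
label_km <- function(rxn, met, share_km) {
  if (share_km == "metabolite") paste0("ln_km", KEY_SEP, met)
  else paste0("ln_km", KEY_SEP, rxn, KEY_SEP, met)
}

#' Haldane constraint row for one reaction
#'
#' Encodes, over the labelled log-scale parameters,
#' `ln Keq - ln kcat+ + ln kcat- - sum_i n_i ln KM_i = 0`
#' with `n_i` the signed stoichiometric coefficient (products positive,
#' substrates negative). For a uni-uni reaction S -> P this is the textbook
#' Haldane relationship `Keq = (kcat+/kcat-) (KM_P/KM_S)`.
#'
#' @param stoich a [reaction_stoichiometry].
#' @param labels character vector of parameter labels defining the column
#'   order of the constraint system.
#' @param share_km `"metabolite"` (KM shared across reactions) or
#'   `"reaction"`.
#' @param exclude metabolites excluded from KM terms (water, protons).
#' @return numeric constraint row of `length(labels)`.
#' @export
haldane_row <- function(stoich, labels, share_km = c("metabolite", "reaction"),
                        exclude = DEFAULT_EXCLUDE) {
  share_km <- match.arg(share_km)
  row <- stats::setNames(numeric(length(labels)), labels)
  rxn <- stoich$reaction_id
  put <- function(lab, val) {
    if (!lab %in% labels) {
      abort_validation(paste0("label missing from system: ", lab))
    }
    row[lab] <<- row[lab] + val
  }
  put(label_keq(rxn), 1)
  put(label_kcat(rxn, "forward"), -1)
  put(label_kcat(rxn, "backward"), 1)
  for (i in seq_along(stoich$metabolite_ids)) {
    met <- stoich$metabolite_ids[i]
    if (met %in% exclude) next
    put(label_km(rxn, met, share_km), -stoich$coefficients[i])
  }
  unname(row)
}

#' Assemble a thermodynamic prior set
#'
#' @param priors data frame with columns `label`, `mean`, `sd` (natural-log
#'   scale). Duplicate labels (e.g. the same shared KM supplied by several
#'   reactions) are pooled by precision weighting.
#' @param stoichs list of [reaction_stoichiometry] for the reactions to
#'   balance.
#' @param share_km KM label sharing mode.
#' @param exclude metabolites excluded from KM constraint terms.
#' @param extra_constraints optional numeric matrix of additional constraint
#'   rows (e.g. thermodynamic cycle closures on ln Keq), columns in label
#'   order.
#' @return A `thermo_prior_set` list.
#' @export
thermo_prior_set <- function(priors, stoichs,
                             share_km = c("metabolite", "reaction"),
                             exclude = DEFAULT_EXCLUDE,
                             extra_constraints = NULL) {
  share_km <- match.arg(share_km)
  if (any(priors$sd <= 0)) abort_validation("all prior sds must be > 0")
  # pool duplicate labels by precision weighting
  pooled <- do.call(rbind, lapply(split(priors, priors$label), function(g) {
    prec <- sum(1 / g$sd^2)
    data.frame(label = g$label[1], mean = sum(g$mean / g$sd^2) / prec,
               sd = sqrt(1 / prec), stringsAsFactors = FALSE)
  }))
  pooled <- pooled[match(unique(priors$label), pooled$label), , drop = FALSE]
  labels <- pooled$label
  A <- do.call(rbind, lapply(stoichs, function(s) {
    haldane_row(s, labels, share_km = share_km, exclude = exclude)
  }))
  if (!is.null(extra_constraints)) {
    if (ncol(extra_constraints) != length(labels)) {
      abort_validation("extra_constraints must have one column per label")
    }
    A <- rbind(A, extra_constraints)
  }
  A <- unique(A)
  structure(list(labels = labels, mean = pooled$mean, sd = pooled$sd,
                 A = A, share_km = share_km, stoichs = stoichs),
            class = "thermo_prior_set")
}

#' Balance parameters onto the thermodynamically consistent manifold
#'
#' Conditions the prior Gaussian (independent by default, or with the
#' empirical covariance of `correlation_samples` when supplied) on the
#' constraint `A x = 0`:
#' `mean* = m - C A' (A C A')^-1 A m`,
#' `Cov* = C - C A' (A C A')^-1 A C`.
#' The balanced mean satisfies every Haldane row exactly and the balanced
#' covariance is the prior covariance shrunk along the constraint directions.
#'
#' @param priors a [thermo_prior_set].
#' @param correlation_samples optional matrix of joint samples (rows =
#'   samples, columns in label order, natural-log scale), e.g. from
#'   [joint_samples] after conversion with `log(10)`; supplies the prior
#'   covariance (means still come from `priors`).
#' @return A `balanced_parameters` list: `labels`, `mean`, `cov`, `A`.
#' @export
balance_parameters <- function(priors, correlation_samples = NULL) {
  m <- priors$mean
  p <- length(m)
  if (is.null(correlation_samples)) {
    C <- diag(priors$sd^2, nrow = p)
  } else {
    if (ncol(correlation_samples) != p) {
      abort_validation("correlation_samples must have one column per label")
    }
    C <- stats::cov(correlation_samples)
  }
  A <- priors$A
  if (is.null(A) || nrow(A) == 0) {
    return(structure(list(labels = priors$labels, mean = m, cov = C,
                          A = matrix(0, 0, p)),
                     class = "balanced_parameters"))
  }
  qrA <- qr(t(A))
  if (qrA$rank < nrow(A)) {
    dep <- setdiff(seq_len(nrow(A)), sort(qrA$pivot[seq_len(qrA$rank)]))
    abort_validation(paste0(
      "linearly dependent constraint row(s): ",
      paste(dep, collapse = ", "), " (deduplicate or drop them)"
    ))
  }
  S <- A %*% C %*% t(A)
  Sc <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(Sc)) {
    abort_validation(
      "A C A' is singular: constraints are degenerate under the prior covariance"
    )
  }
  Sinv <- chol2inv(Sc)
  CA <- C %*% t(A)
  mean_star <- as.numeric(m - CA %*% (Sinv %*% (A %*% m)))
  cov_star <- C - CA %*% Sinv %*% t(CA)
  cov_star <- (cov_star + t(cov_star)) / 2
  structure(list(labels = priors$labels, mean = mean_star, cov = cov_star,
                 A = A),
            class = "balanced_parameters")
}

#' Maximum absolute constraint residual of a balanced set
#' @param balanced a `balanced_parameters` object.
#' @param A optional constraint matrix (defaults to the one stored).
#' @return `max |A mean|` (0 for an empty constraint set).
#' @export
consistency_residual <- function(balanced, A = NULL) {
  A <- A %||% balanced$A
  if (is.null(A) || nrow(A) == 0) return(0)
  max(abs(A %*% balanced$mean))
}

#' @export
print.balanced_parameters <- function(x, ...) {
  cat(sprintf(
    "balanced parameters: %d labels, %d constraint(s), max |A mean| = %.2e\n",
    length(x$labels), nrow(x$A), consistency_residual(x)))
  df <- data.frame(label = x$labels, mean = x$mean, sd = sqrt(diag(x$cov)))
  print(utils::head(df, 10), row.names = FALSE)
  invisible(x)
}

#' Read a thermodynamic prior table
#'
#' TSV columns: `label`, `mean`, `sd`, optional `scale` (`ln` default, or
#' `log10`, converted to natural log).
#'
#' @param path path to the TSV.
#' @return data frame with columns `label`, `mean`, `sd` on the ln scale.
#' @export
read_thermo_priors <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "mean", "sd")
  if (!all(need %in% names(df))) {
    abort_validation(paste0("prior file needs columns: ",
                            paste(need, collapse = ", ")))
  }
  if (!is.null(df$scale)) {
    is10 <- df$scale == "log10"
    df$mean[is10] <- df$mean[is10] * log(10)
    df$sd[is10] <- df$sd[is10] * log(10)
  }
  df[c("label", "mean", "sd")]
}

#' Write a balanced parameter set (mean vector + dense covariance) as TSV
#' @param balanced a `balanced_parameters` object.
#' @param mean_path,cov_path output paths.
#' @export
write_balanced <- function(balanced, mean_path, cov_path) {
  utils::write.table(
    data.frame(label = balanced$labels,
               mean = sprintf("%.15g", balanced$mean),
               sd = sprintf("%.15g", sqrt(pmax(diag(balanced$cov), 0)))),
    mean_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  cov_df <- as.data.frame(balanced$cov)
  names(cov_df) <- balanced$labels
  cov_df[] <- lapply(cov_df, function(v) sprintf("%.15g", v))
  utils::write.table(cbind(label = balanced$labels, cov_df), cov_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mean_path)
}
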