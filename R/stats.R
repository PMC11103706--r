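# Nested mixed-effects comparison of force-field parameter sets.
#
# Observations are long-format metric values y indexed by (parameter_set,
# protein, replicate, metric). Replicates are nested within proteins; the
# parameter set is the fixed effect of interest. Metrics that are not
# Gaussian are Box-Cox transformed before modelling. Significance of the
# parameter-set effect comes from maximum-likelihood likelihood-ratio tests,
# univariate per metric or multivariate over stacked metrics with per-metric
# residual variances and inter-metric correlation; pairwise contrasts are
# Benjamini-Yekutieli adjusted.

#' Construct a metric observation table
#'
#' The unit of statistical analysis: one value per
#' (parameter_set, protein, replicate, metric).
#'
#' @param parameter_set,protein,metric Character vectors.
#' @param replicate Integer vector.
#' @param value Numeric vector (finite).
#' @return `data.frame` of class `metric_table`.
#' @export
metric_table <- function(parameter_set, protein, replicate, metric, value) {
  d <- data.frame(parameter_set = as.character(parameter_set),
                  protein = as.character(protein),
                  replicate = as.integer(replicate),
                  metric = as.character(metric),
                  value = as.numeric(value),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$value))) stop("metric values must be finite")
  key <- do.call(paste, d[c("parameter_set", "protein", "replicate", "metric")])
  if (anyDuplicated(key)) {
    stop("duplicate (parameter_set, protein, replicate, metric) records")
  }
  class(d) <- c("metric_table", "data.frame")
  d
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> %d observations: %d metric(s), %d parameter set(s), %d protein(s)\n",
              nrow(x), length(unique(x$metric)),
              length(unique(x$parameter_set)), length(unique(x$protein))))
  NextMethod()
}

#' Box-Cox transformation with design regressors
#'
#' Chooses the power-transform exponent lambda by maximising the profile
#' log-likelihood of a linear model of the transformed response on the
#' protein and parameter-set factors, then applies
#' \eqn{y^{(\lambda)} = (y^\lambda - 1)/\lambda} (natural log at lambda = 0).
#' Nonpositive responses (possible for signed percentage deviations) are
#' first shifted by `-min(y)` plus a small epsilon; the shift is recorded.
#'
#' @param y Numeric response.
#' @param protein,parameter_set Factors used as regressors.
#' @param lambda_grid Candidate lambda values.
#' @param shift Allow automatic shifting of nonpositive data (default TRUE).
#' @return List of class `boxcox_fit`: `lambda`, `lambda_ci` (95%
#'   profile-likelihood interval), `shift`, `transformed`.
#' @export
boxcox_fit <- function(y, protein, parameter_set,
                       lambda_grid = seq(-2, 2, by = 0.05), shift = TRUE) {
  off <- 0
  if (min(y) <= 0) {
    if (!shift) stop("response contains nonpositive values and shift = FALSE")
    off <- -min(y) + 1e-6 * max(diff(range(y)), 1)
  }
  ys <- y + off
  d <- data.frame(ys = ys, protein = factor(protein),
                  parameter_set = factor(parameter_set))
  has_prot <- nlevels(d$protein) > 1L
  has_ff <- nlevels(d$parameter_set) > 1L
  fm <- if (has_prot && has_ff) ys ~ protein + parameter_set
        else if (has_prot) ys ~ protein
        else if (has_ff) ys ~ parameter_set
        else ys ~ 1
  bc <- MASS::boxcox(fm, data = d, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  # 95% profile-likelihood interval
  in_ci <- bc$y > max(bc$y) - stats::qchisq(0.95, 1) / 2
  transformed <- if (abs(lambda) < 1e-12) log(ys) else (ys^lambda - 1) / lambda
  structure(list(lambda = lambda, lambda_ci = range(bc$x[in_ci]),
                 shift = off, transformed = transformed),
            class = "boxcox_fit")
}

.mixed_formula <- function(include_ff, cell_means = FALSE) {
  rhs <- "(1 | protein) + (1 | protein:replicate)"
  if (include_ff) {
    lhs <- if (cell_means) "value ~ 0 + parameter_set + " else "value ~ parameter_set + "
  } else {
    lhs <- "value ~ 1 + "
  }
  stats::as.formula(paste0(lhs, rhs))
}

#' Univariate nested mixed-effects model for one metric
#'
#' Fits `value ~ parameter_set + (1 | protein) + (1 | protein:replicate)` by
#' maximum likelihood: the parameter set is a fixed effect, proteins and
#' replicates-within-proteins are random intercepts. Unbalanced designs
#' (structures missing for some parameter sets) are handled by ML on the
#' available data.
#'
#' @param table A `metric_table` restricted to one metric.
#' @param include_ff Include the parameter-set fixed effect (set `FALSE` for
#'   the null model of the likelihood-ratio test).
#' @return List of class `mixed_model_fit`: `fixed_effects` (per-set cell
#'   means when `include_ff`), `var_protein`, `var_replicate`,
#'   `var_residual`, `loglik`, `n_params`, `converged`, and the underlying
#'   `lme4` fit as `model`.
#' @export
fit_univariate_mixed <- function(table, include_ff = TRUE) {
  stopifnot(is.data.frame(table))
  if (length(unique(table$metric)) != 1L) {
    stop("fit_univariate_mixed expects a single metric; got ",
         length(unique(table$metric)))
  }
  if (length(unique(table$protein)) < 2L) stop("need at least 2 proteins")
  d <- table
  d$protein <- factor(d$protein)
  d$replicate <- factor(d$replicate)
  d$parameter_set <- factor(d$parameter_set)

  # keep the data reachable from the formula environment so downstream
  # refits (emmeans) can recover it
  fm <- .mixed_formula(include_ff, cell_means = include_ff)
  fit_env <- new.env(parent = environment())
  fit_env$d <- d
  environment(fm) <- fit_env
  fit <- suppressMessages(lme4::lmer(
    fm, data = d, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L

  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  fe <- lme4::fixef(fit)
  if (include_ff) names(fe) <- sub("^parameter_set", "", names(fe))
  structure(list(
    fixed_effects = fe,
    var_protein = getv("protein"),
    var_replicate = getv("protein:replicate"),
    var_residual = stats::sigma(fit)^2,
    loglik = as.numeric(stats::logLik(fit)),
    n_params = attr(stats::logLik(fit), "df"),
    converged = conv,
    model = fit,
    data = d
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("<mixed_model_fit> logLik", format(x$loglik, digits = 6),
      if (!x$converged) "(NOT converged)", "\n")
  cat("  fixed effects:\n")
  print(round(x$fixed_effects, 4))
  cat(sprintf("  variances: protein %.4g, replicate %.4g, residual %.4g\n",
              x$var_protein, x$var_replicate, x$var_residual))
  invisible(x)
}

#' Likelihood-ratio test for a parameter-set effect
#'
#' Compares maximum-likelihood fits with and without the parameter-set fixed
#' effect. In univariate mode a single metric is modelled with `lme4`. In
#' multivariate mode all metrics are stacked long-form and modelled with
#' `nlme::lme` using a metric factor, per-metric residual variances
#' (`varIdent`) and an exchangeable inter-metric correlation (`corCompSymm`);
#' the full model frees one parameter-set effect per metric. The statistic is
#' \eqn{2(\ell_{full} - \ell_{null})} referred to a chi-squared distribution
#' with df equal to the number of freed parameters.
#'
#' @param table A `metric_table` (one metric unless `multivariate`).
#' @param multivariate Stack all metrics into one heteroscedastic correlated
#'   model (the multivariate mixed-effects likelihood-ratio test).
#' @return List of class `ff_lrt`: `statistic`, `df`, `p`, `loglik_full`,
#'   `loglik_null`, `reference` (`"chi-squared"`).
#' @export
lrt_parameter_set <- function(table, multivariate = FALSE) {
  k <- length(unique(table$parameter_set))
  if (k < 2L) stop("need at least two parameter sets to test")
  if (!multivariate) {
    full <- fit_univariate_mixed(table, include_ff = TRUE)
    null <- fit_univariate_mixed(table, include_ff = FALSE)
    if (!full$converged || !null$converged) {
      stop("mixed-model fit did not converge; refusing the likelihood-ratio test")
    }
    ll_f <- full$loglik; ll_n <- null$loglik
    df <- full$n_params - null$n_params
  } else {
    d <- table
    d$protein <- factor(d$protein)
    d$replicate <- factor(d$replicate)
    d$parameter_set <- factor(d$parameter_set)
    d$metric <- factor(d$metric)
    n_metrics <- nlevels(d$metric)
    ctrl <- nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200,
                             returnObject = TRUE)
    wts <- if (n_metrics > 1L) nlme::varIdent(form = ~ 1 | metric) else NULL
    cor <- if (n_metrics > 1L) nlme::corCompSymm() else NULL
    fit_one <- function(fixed) {
      nlme::lme(fixed, data = d, random = ~ 1 | protein / replicate,
                weights = wts, correlation = cor,
                method = "ML", control = ctrl)
    }
    fixed_full <- if (n_metrics > 1L) value ~ metric + metric:parameter_set
                  else value ~ parameter_set
    fixed_null <- if (n_metrics > 1L) value ~ metric else value ~ 1
    full <- fit_one(fixed_full)
    null <- fit_one(fixed_null)
    ll_f <- as.numeric(stats::logLik(full))
    ll_n <- as.numeric(stats::logLik(null))
    df <- n_metrics * (k - 1L)
  }
  stat <- 2 * (ll_f - ll_n)
  if (stat < -1e-6) {
    stop("full-model likelihood fell below the null model's; optimisation failure")
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 loglik_full = ll_f, loglik_null = ll_n,
                 reference = "chi-squared"),
            class = "ff_lrt")
}

#' @export
print.ff_lrt <- function(x, ...) {
  cat(sprintf("LRT: statistic %.3f on %d df, p = %.3g (%s reference)\n",
              x$statistic, x$df, x$p, x$reference))
  invisible(x)
}

#' Pairwise parameter-set contrasts for one metric
#'
#' For every pair of parameter sets (ordered older to newer), reports the
#' difference in the absolute value of the mean error,
#' \eqn{\Delta\mu = |\mu_{old}| - |\mu_{new}|} with
#' \eqn{\mu = \mathrm{mean}(\Delta q)} over all proteins and replicates, so
#' that a positive value means the newer set lies closer to experiment.
#' Raw p-values for the pairwise mean differences come from the fitted mixed
#' model via `emmeans` (unadjusted here; adjust with [by_adjust()] across the
#' full family of tests).
#'
#' @param fit A converged `mixed_model_fit` with the parameter-set effect.
#' @param table The `metric_table` the fit was computed from (untransformed
#'   values are used for \eqn{\Delta\mu}).
#' @param order Chronological order of the parameter sets, oldest first.
#'   Defaults to the benchmark chronology for the GROMOS set names, or the
#'   order of appearance otherwise.
#' @return `data.frame`: `older`, `newer`, `delta_mu`, `p_raw`.
#' @export
pairwise_contrasts <- function(fit, table, order = .default_order(table)) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (!fit$converged) stop("refusing contrasts from a non-converged fit")
  sets <- order
  if (length(sets) < 2L) stop("need at least two parameter sets")
  mu <- vapply(sets, function(s) mean(table$value[table$parameter_set == s]),
               numeric(1))
  em <- emmeans::emmeans(fit$model, "parameter_set", data = fit$data)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  # emmeans labels contrasts "A - B" in level order
  lookup_p <- function(a, b) {
    hit <- ct$contrast %in% c(paste(a, "-", b), paste(b, "-", a),
                              paste0("parameter_set", a, " - parameter_set", b),
                              paste0("parameter_set", b, " - parameter_set", a))
    ct$p.value[hit][1L]
  }
  pairs <- utils::combn(seq_along(sets), 2L)
  out <- data.frame(
    older = sets[pairs[1L, ]],
    newer = sets[pairs[2L, ]],
    delta_mu = abs(mu[pairs[1L, ]]) - abs(mu[pairs[2L, ]]),
    p_raw = mapply(lookup_p, sets[pairs[1L, ]], sets[pairs[2L, ]])
  )
  rownames(out) <- NULL
  out
}

#' Benjamini-Yekutieli false-discovery-rate adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' \eqn{p_{(i)}^{adj} = \min_{j \ge i} \min(1, p_{(j)} m c(m) / j)} with
#' \eqn{c(m) = \sum_{k=1}^m 1/k}. Output order matches input order; adjusted
#' values are monotone and never below the raw p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (FDRs).
#' @examples
#' by_adjust(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
by_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BY")
}

#' Significance stars
#'
#' @param p_adj Adjusted p-value(s) in `[0, 1]`.
#' @return `"***"` (p <= 0.001), `"**"` (<= 0.01), `"*"` (<= 0.05) or `"ns"`.
#' @export
significance_stars <- function(p_adj) {
  stopifnot(all(p_adj >= 0 & p_adj <= 1))
  ifelse(p_adj <= 0.001, "***",
         ifelse(p_adj <= 0.01, "**",
                ifelse(p_adj <= 0.05, "*", "ns")))
}

#' Compare force-field parameter sets across metrics
#'
#' The package's central model fit. For each metric the observations are
#' Box-Cox transformed (protein and parameter set as regressors), a nested
#' mixed-effects model is fitted by maximum likelihood, the parameter-set
#' effect is tested by a likelihood-ratio test, and all pairwise contrasts
#' are computed; the pairwise p-values are then adjusted to
#' Benjamini-Yekutieli false-discovery rates across the whole family. If
#' more than one metric is present, the multivariate stacked test (per-metric
#' residual variances, exchangeable inter-metric correlation) gives a single
#' overall p-value for the parameter-set effect.
#'
#' @param table A `metric_table` (any number of metrics).
#' @param order Chronological order of parameter sets, oldest first.
#' @param boxcox Transform each metric before modelling (default `TRUE`).
#' @param multivariate Also run the stacked multivariate test.
#' @return Object of class `ffcompare` with components `pairwise`
#'   (data.frame: `metric`, `older`, `newer`, `delta_mu`, `p_raw`, `p_adj`,
#'   `stars`), `per_metric_lrt`, `mvmelrt`, `fits`, `boxcox`.
#' @seealso [print.ffcompare()], [summary.ffcompare()], [coef.ffcompare()]
#' @export
.default_order <- function(table) {
  known <- intersect(parameter_set_order(), unique(table$parameter_set))
  if (length(known) == length(unique(table$parameter_set))) known
  else unique(table$parameter_set)
}

ffcompare <- function(table, order = .default_order(table),
                      boxcox = TRUE, multivariate = TRUE) {
  stopifnot(is.data.frame(table))
  metrics <- unique(table$metric)
  fits <- list(); bc <- list(); lrts <- list(); pw <- list()
  trans_all <- table
  for (m in metrics) {
    sub <- table[table$metric == m, , drop = FALSE]
    tsub <- sub
    if (boxcox) {
      b <- boxcox_fit(sub$value, sub$protein, sub$parameter_set)
      bc[[m]] <- b
      tsub$value <- b$transformed
      trans_all$value[trans_all$metric == m] <- b$transformed
    }
    fits[[m]] <- fit_univariate_mixed(tsub, include_ff = TRUE)
    lrts[[m]] <- lrt_parameter_set(tsub, multivariate = FALSE)
    contrasts_m <- pairwise_contrasts(fits[[m]], sub, order = order)
    contrasts_m <- cbind(metric = m, contrasts_m)
    pw[[m]] <- contrasts_m
  }
  pairwise <- do.call(rbind, pw)
  rownames(pairwise) <- NULL
  pairwise$p_adj <- by_adjust(pairwise$p_raw)
  pairwise$stars <- significance_stars(pairwise$p_adj)

  mv <- NULL
  if (multivariate && length(metrics) > 1L) {
    mv <- lrt_parameter_set(trans_all, multivariate = TRUE)
  }
  structure(list(pairwise = pairwise, per_metric_lrt = lrts,
                 mvmelrt = mv, fits = fits, boxcox = bc, order = order),
            class = "ffcompare")
}

#' @export
print.ffcompare <- function(x, ...) {
  cat("Force-field comparison (nested mixed-effects models)\n")
  cat("  parameter sets:", paste(x$order, collapse = " < "), "\n")
  if (!is.null(x$mvmelrt)) {
    cat(sprintf("  multivariate LRT: p = %.3g on %d df\n",
                x$mvmelrt$p, x$mvmelrt$df))
  }
  cat("  pairwise differences in |mean error| (positive favours the newer set):\n\n")
  tab <- x$pairwise
  tab$pair <- paste(tab$older, "->", tab$newer)
  wide <- stats::reshape(tab[, c("metric", "pair", "delta_mu", "stars")],
                         idvar = "metric", timevar = "pair",
                         v.names = c("delta_mu", "stars"), direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ffcompare <- function(object, ...) {
  lrt_p <- vapply(object$per_metric_lrt, `[[`, numeric(1), "p")
  out <- list(
    pairwise = object$pairwise,
    per_metric_p = lrt_p,
    mvmelrt_p = if (!is.null(object$mvmelrt)) object$mvmelrt$p else NA_real_,
    variance_components = t(vapply(object$fits, function(f) {
      c(protein = f$var_protein, replicate = f$var_replicate,
        residual = f$var_residual)
    }, numeric(3)))
  )
  class(out) <- "summary.ffcompare"
  out
}

#' @export
print.summary.ffcompare <- function(x, ...) {
  cat("Per-metric likelihood-ratio p-values:\n")
  print(signif(x$per_metric_p, 3))
  if (!is.na(x$mvmelrt_p)) {
    cat(sprintf("Multivariate (stacked) LRT p: %.3g\n", x$mvmelrt_p))
  }
  cat("Variance components (transformed scale):\n")
  print(signif(x$variance_components, 3))
  cat("Pairwise contrasts:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ffcompare <- function(object, ...) {
  m <- unique(object$pairwise$metric)
  pairs <- unique(paste(object$pairwise$older, "->", object$pairwise$newer))
  out <- matrix(NA_real_, length(m), length(pairs),
                dimnames = list(m, pairs))
  for (k in seq_len(nrow(object$pairwise))) {
    r <- object$pairwise[k, ]
    out[r$metric, paste(r$older, "->", r$newer)] <- r$delta_mu
  }
  out
}
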