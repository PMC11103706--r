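# Orchestration: per-replicate metric extraction from ensembles, boxplot
# summary data, and the end-to-end report bundle.

#' Per-replicate structural metrics for one ensemble
#'
#' Evaluates the metric battery frame by frame and averages over the frames
#' of the replicate (equal weights): backbone and native hydrogen-bond
#' counts, polar/nonpolar SASA (nm^2), radius of gyration (nm),
#' backbone-fit RMSD100 (nm) and DSSP class percentages.
#'
#' @param ens An `ensemble`.
#' @param reference The experimental reference `conformation` (same
#'   topology).
#' @param crit An [hbond_criterion()].
#' @param sasa_cfg A [sasa_config()], or `NULL` to skip the (relatively
#'   expensive) SASA metrics.
#' @return Named numeric vector of per-replicate means.
#' @export
ensemble_metrics <- function(ens, reference, crit = hbond_criterion(),
                             sasa_cfg = sasa_config()) {
  stopifnot(inherits(ens, "ensemble"), inherits(reference, "conformation"))
  conf <- ens$topology
  sel <- select_backbone(reference, exclude_termini = TRUE)
  nres <- n_residues(reference)
  nat <- native_hbond_count(ens, reference, crit)
  acc <- NULL
  for (fr in ens$frames) {
    conf$xyz <- fr
    d <- assign_dssp(conf)
    row <- c(
      bb_hbonds = hydrogen_bonds(conf, crit)$count,
      rgyr = radius_of_gyration(conf),
      rmsd100 = rmsd100(fit_rmsd(conf, reference, sel), nres),
      pct_alpha = unname(d$percentages["pct_alpha"]),
      pct_beta = unname(d$percentages["pct_beta"]),
      pct_310 = unname(d$percentages["pct_310"])
    )
    if (!is.null(sasa_cfg)) {
      s <- sasa(conf, sasa_cfg)
      row <- c(row, polar_sasa = s$polar, nonpolar_sasa = s$nonpolar)
    }
    acc <- if (is.null(acc)) row else acc + row
  }
  out <- acc / length(ens$frames)
  c(out, native_hbonds = nat$mean)
}

#' Percentage deviations of replicate metrics from the reference
#'
#' Computes [ensemble_metrics()] for a replicate and re-expresses every
#' metric with a nonzero reference value as the percentage deviation
#' \eqn{\Delta q\%} from the same quantity evaluated on the experimental
#' structure. `rmsd100` is kept on its natural nm scale (its reference value
#' is zero by construction).
#'
#' @inheritParams ensemble_metrics
#' @return Named numeric vector.
#' @export
delta_q_metrics <- function(ens, reference, crit = hbond_criterion(),
                            sasa_cfg = sasa_config()) {
  sim <- ensemble_metrics(ens, reference, crit, sasa_cfg)
  ref_ens <- read_ensemble(reference, list(reference$xyz))
  ref <- ensemble_metrics(ref_ens, reference, crit, sasa_cfg)
  out <- sim
  for (m in names(sim)) {
    if (m == "rmsd100") next
    out[m] <- if (ref[m] == 0) NA_real_ else delta_q_percent(sim[m], ref[m])
  }
  out
}

#' Boxplot summary statistics with outlier flagging
#'
#' Quartile-based summaries per (metric, parameter set): median, quartiles,
#' whiskers at the most extreme observations within 1.5 interquartile ranges
#' of the quartile boundaries, and the values flagged as outliers beyond
#' them.
#'
#' @param table A `metric_table`.
#' @return `data.frame` with one row per (metric, parameter_set):
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n`, `n_outliers`,
#'   `outliers` (comma-separated values).
#' @export
boxplot_summary <- function(table) {
  groups <- split(table, list(table$metric, table$parameter_set), drop = TRUE)
  rows <- lapply(groups, function(g) {
    v <- g$value
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    out <- v[v < lo | v > hi]
    data.frame(metric = g$metric[1L], parameter_set = g$parameter_set[1L],
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= lo]), whisker_hi = max(v[v <= hi]),
               n = length(v), n_outliers = length(out),
               outliers = paste(signif(sort(out), 6), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$metric, out$parameter_set), , drop = FALSE]
}

#' Run the full comparison pipeline
#'
#' Takes a long-format metric table (from a CSV file, an in-memory table or
#' the synthetic generator), fits the statistical framework and writes the
#' report bundle to `outdir`: `metrics.csv` (the input observations),
#' `boxplot_summary.csv`, `pairwise_report.csv` (pairwise
#' \eqn{\Delta\mu} with adjusted significance) and `mvmelrt.json` (overall
#' likelihood-ratio test and variance components). Outputs are deterministic
#' given the inputs and seed.
#'
#' @param config List with components: exactly one of `metrics_csv` (path),
#'   `table` (a `metric_table`) or `synth` (argument list for
#'   [gen_metric_table()]); `outdir` (required); optional `order`, `boxcox`,
#'   `multivariate`.
#' @return Invisibly, a list with the `ffcompare` fit and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir))
  sources <- c("metrics_csv", "table", "synth")
  given <- sources[vapply(sources, function(s) !is.null(config[[s]]), logical(1))]
  if (length(given) != 1L) {
    stop("config must provide exactly one of: ", paste(sources, collapse = ", "))
  }
  tab <- switch(given,
    metrics_csv = {
      d <- utils::read.csv(config$metrics_csv, stringsAsFactors = FALSE)
      metric_table(d$parameter_set, d$protein, d$replicate, d$metric, d$value)
    },
    table = config$table,
    synth = do.call(gen_metric_table, config$synth)
  )
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$outdir,
                     c("metrics.csv", "boxplot_summary.csv",
                       "pairwise_report.csv", "mvmelrt.json"))
  names(paths) <- c("metrics", "boxplot", "pairwise", "mvmelrt")

  message("writing ", paths["metrics"])
  utils::write.csv(tab, paths["metrics"], row.names = FALSE)
  message("summarising distributions")
  utils::write.csv(boxplot_summary(tab), paths["boxplot"], row.names = FALSE)

  message("fitting mixed-effects comparison")
  order <- if (!is.null(config$order)) config$order else
    intersect(parameter_set_order(), unique(tab$parameter_set))
  cmp <- ffcompare(tab, order = order,
                   boxcox = isTRUE(config$boxcox %||% TRUE),
                   multivariate = isTRUE(config$multivariate %||% TRUE))
  utils::write.csv(cmp$pairwise, paths["pairwise"], row.names = FALSE)

  s <- summary(cmp)
  jsonlite::write_json(list(
    mvmelrt_p = s$mvmelrt_p,
    mvmelrt_df = if (!is.null(cmp$mvmelrt)) cmp$mvmelrt$df else NA,
    reference = if (!is.null(cmp$mvmelrt)) cmp$mvmelrt$reference else NA,
    per_metric_p = as.list(s$per_metric_p),
    variance_components = as.data.frame(s$variance_components)
  ), paths["mvmelrt"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(comparison = cmp, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
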