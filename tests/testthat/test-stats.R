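test_that("metric tables reject duplicates and non-finite values", {
  expect_error(metric_table("A", "p1", c(1, 1), "m", c(1, 2)), "duplicate")
  expect_error(metric_table("A", "p1", 1, "m", NaN), "finite")
  t <- metric_table(c("A", "B"), "p1", 1, "m", c(0.1, 0.2))
  expect_s3_class(t, "metric_table")
})

test_that("Box-Cox recovers the generating transformation", {
  # lognormal data (1000 points, iid residuals around the regressor means):
  # lambda near 0
  tab <- gen_metric_table(n_proteins = 50, n_replicates = 10,
                          parameter_sets = "A",
                          sd_protein = 0.4, sd_replicate = 0,
                          sd_residual = 0.6, family = "lognormal", seed = 31)
  b <- boxcox_fit(tab$value, tab$protein, tab$parameter_set)
  expect_gte(0, b$lambda_ci[1])
  expect_lte(0, b$lambda_ci[2])
  expect_equal(b$transformed,
               if (abs(b$lambda) < 1e-12) log(tab$value)
               else (tab$value^b$lambda - 1) / b$lambda)
  # already-Gaussian residuals: lambda near 1 (shifted to positive support)
  tabn <- gen_metric_table(n_proteins = 50, n_replicates = 10,
                           parameter_sets = "A",
                           ff_offsets = c(A = 20),
                           sd_protein = 0.4, sd_replicate = 0,
                           sd_residual = 0.6, seed = 32)
  bn <- boxcox_fit(tabn$value, tabn$protein, tabn$parameter_set)
  expect_gte(1, bn$lambda_ci[1])
  expect_lte(1, bn$lambda_ci[2])
  # nonpositive data are shifted, and the shift is recorded
  y <- c(-1, 0, 1, 2, 5, 3, 2, 1)
  bs <- boxcox_fit(y, protein = rep("p", 8), parameter_set = rep("A", 8))
  expect_gt(bs$shift, 1)
  expect_error(boxcox_fit(y, rep("p", 8), rep("A", 8), shift = FALSE),
               "nonpositive")
})

test_that("mixed model log-likelihood matches a closed-form evaluation", {
  # oracle: evaluate the Gaussian likelihood of the claimed covariance
  # structure (protein + replicate-within-protein + residual) directly
  tab <- gen_metric_table(n_proteins = 8, n_replicates = 3,
                          parameter_sets = c("A", "B"),
                          ff_offsets = c(A = 0, B = 0.8), seed = 77)
  fit <- fit_univariate_mixed(tab)
  mu <- fit$fixed_effects[tab$parameter_set]
  ll <- 0
  for (p in unique(tab$protein)) {
    i <- which(tab$protein == p)
    r <- tab$replicate[i]
    S <- fit$var_protein +
      fit$var_replicate * outer(r, r, "==") +
      diag(fit$var_residual, length(i))
    ll <- ll + mvn_logdens(tab$value[i] - mu[i], S)
  }
  expect_equal(ll, fit$loglik, tolerance = 1e-6)
})

test_that("balanced-design variance components match nested ANOVA estimators", {
  tab <- gen_metric_table(n_proteins = 12, n_replicates = 4,
                          parameter_sets = c("A", "B", "C"),
                          sd_protein = 1.5, sd_replicate = 0.6,
                          sd_residual = 0.4, seed = 99)
  fit <- fit_univariate_mixed(tab, include_ff = FALSE)
  # REML on balanced nested data equals the method-of-moments (EMS) solution
  reml <- update(fit$model, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(reml))
  p <- 12; r <- 4; k <- 3
  gm <- mean(tab$value)
  pm <- tapply(tab$value, tab$protein, mean)
  cellm <- tapply(tab$value, paste(tab$protein, tab$replicate), mean)
  cell_of <- paste(tab$protein, tab$replicate)
  ss_prot <- r * k * sum((pm - gm)^2)
  ss_rep <- k * sum((cellm - pm[substr(names(cellm), 1, 3)])^2)
  ss_err <- sum((tab$value - cellm[cell_of])^2)
  ms_prot <- ss_prot / (p - 1)
  ms_rep <- ss_rep / (p * (r - 1))
  ms_err <- ss_err / (p * r * (k - 1))
  expect_equal(vc$vcov[vc$grp == "Residual"], ms_err, tolerance = 1e-4)
  expect_equal(vc$vcov[vc$grp == "protein:replicate"],
               (ms_rep - ms_err) / k, tolerance = 1e-4)
  expect_equal(vc$vcov[vc$grp == "protein"],
               (ms_prot - ms_rep) / (r * k), tolerance = 1e-4)
})

test_that("mixed fits behave on degenerate and symmetric data", {
  # no protein/replicate variability: components near zero
  tab <- gen_metric_table(n_proteins = 10, n_replicates = 3,
                          parameter_sets = c("A", "B"),
                          sd_protein = 0, sd_replicate = 0,
                          sd_residual = 0.3, seed = 12)
  fit <- fit_univariate_mixed(tab)
  expect_lt(fit$var_protein, 0.02)
  expect_lt(fit$var_replicate, 0.02)
  # swapped labels mirror the fixed effects
  tab2 <- tab
  tab2$parameter_set <- ifelse(tab$parameter_set == "A", "B", "A")
  fit2 <- fit_univariate_mixed(tab2)
  expect_equal(unname(fit$fixed_effects["A"]),
               unname(fit2$fixed_effects["B"]), tolerance = 1e-6)
  expect_equal(unname(fit$fixed_effects["B"]),
               unname(fit2$fixed_effects["A"]), tolerance = 1e-6)
})

test_that("parameter-set offsets are recovered on the benchmark design", {
  # 40 proteins x 3 replicates, planted effect +1.0 between two sets
  tab <- gen_metric_table(n_proteins = 40, n_replicates = 3,
                          parameter_sets = c("old", "new"),
                          ff_offsets = c(old = 0, new = 1),
                          sd_protein = 2, sd_replicate = 0.5,
                          sd_residual = 0.3, seed = 2024)
  fit <- fit_univariate_mixed(tab)
  est <- unname(fit$fixed_effects["new"] - fit$fixed_effects["old"])
  # 3 SE of the cell-mean difference under the design
  se <- sqrt(2 * (fit$var_replicate + fit$var_residual / 1) / (40 * 3))
  expect_lt(abs(est - 1), 3 * max(se, 0.05))
})

test_that("likelihood-ratio test handles identical and strongly separated data", {
  # perfectly balanced antisymmetric contrast: the set-effect MLE is exactly
  # zero, so full and null models attain identical likelihoods
  base <- gen_metric_table(n_proteins = 8, n_replicates = 2,
                           parameter_sets = "A", seed = 5)
  dup <- base
  dup$parameter_set <- "B"
  dup$value <- dup$value + ifelse(dup$replicate == 1L, 0.5, -0.5)
  both <- metric_table(c(base$parameter_set, dup$parameter_set),
                       c(base$protein, dup$protein),
                       c(base$replicate, dup$replicate),
                       c(base$metric, dup$metric),
                       c(base$value, dup$value))
  lrt0 <- lrt_parameter_set(both)
  expect_lt(lrt0$statistic, 1e-5)
  expect_gt(lrt0$p, 0.999)
  # planted effect: overwhelming rejection in nearly all simulations
  hits <- 0L
  for (s in 1:30) {
    tab <- gen_metric_table(n_proteins = 10, n_replicates = 3,
                            parameter_sets = c("A", "B"),
                            ff_offsets = c(A = 0, B = 2),
                            sd_protein = 1, sd_replicate = 0.3,
                            sd_residual = 0.3, seed = 1000 + s)
    if (lrt_parameter_set(tab)$p < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 29L)
  expect_error(lrt_parameter_set(base), "two parameter sets")
})

test_that("stochastic monotonicity: p falls as the planted effect grows", {
  ps <- vapply(c(0, 0.3, 1.5), function(eff) {
    tab <- gen_metric_table(n_proteins = 12, n_replicates = 3,
                            parameter_sets = c("A", "B"),
                            ff_offsets = c(A = 0, B = eff),
                            sd_protein = 1, sd_replicate = 0.3,
                            sd_residual = 0.3, seed = 444)
    lrt_parameter_set(tab)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("multivariate stacked test detects per-metric effects", {
  offs <- matrix(c(0, 0.8, 0, 0, 0, 0.4), 2, 3,
                 dimnames = list(c("A", "B"), c("m1", "m2", "m3")))
  tab <- gen_metric_table(n_proteins = 10, n_replicates = 3,
                          parameter_sets = c("A", "B"),
                          metrics = c("m1", "m2", "m3"), ff_offsets = offs,
                          sd_protein = 1, sd_replicate = 0.3,
                          sd_residual = 0.3, seed = 7)
  mv <- lrt_parameter_set(tab, multivariate = TRUE)
  expect_equal(mv$df, 3L)  # one freed parameter per metric
  expect_lt(mv$p, 0.01)
  expect_equal(mv$reference, "chi-squared")
  # null multivariate data: no strong rejection expected
  tab0 <- gen_metric_table(n_proteins = 10, n_replicates = 3,
                           parameter_sets = c("A", "B"),
                           metrics = c("m1", "m2"), ff_offsets = 0,
                           sd_protein = 1, sd_replicate = 0.3,
                           sd_residual = 0.3, seed = 8)
  expect_gt(lrt_parameter_set(tab0, multivariate = TRUE)$p, 0.001)
})

test_that("pairwise contrasts report all pairs with the documented sign", {
  tab <- gen_metric_table(n_proteins = 10, n_replicates = 3,
                          parameter_sets = parameter_set_order(),
                          ff_offsets = c(`45A4` = 2, `53A6` = 1.5,
                                         `54A7` = 0.5, `54A8` = 0.2),
                          sd_protein = 0.5, sd_replicate = 0.2,
                          sd_residual = 0.2, seed = 21)
  fit <- fit_univariate_mixed(tab)
  pw <- pairwise_contrasts(fit, tab)
  expect_equal(nrow(pw), 6L)  # 4 choose 2
  expect_true(all(pw$older != pw$newer))
  # values here are errors towards 0 for newer sets: every Delta-mu positive
  expect_true(all(pw$delta_mu > 0))
  # and the magnitudes match |mean error| differences computed directly
  mu <- tapply(tab$value, tab$parameter_set, mean)
  k <- which(pw$older == "45A4" & pw$newer == "54A8")
  expect_equal(pw$delta_mu[k], unname(abs(mu["45A4"]) - abs(mu["54A8"])),
               tolerance = 1e-12)
  # balanced antisymmetric sets: zero estimated contrast, p near 1
  base <- gen_metric_table(n_proteins = 8, n_replicates = 2,
                           parameter_sets = "A",
                           ff_offsets = c(A = 5), seed = 5)
  dup <- base
  dup$parameter_set <- "B"
  dup$value <- dup$value + ifelse(dup$replicate == 1L, 0.5, -0.5)
  both <- metric_table(c(base$parameter_set, dup$parameter_set),
                       c(base$protein, dup$protein),
                       c(base$replicate, dup$replicate),
                       c(base$metric, dup$metric),
                       c(base$value, dup$value))
  fitb <- fit_univariate_mixed(both)
  pwb <- pairwise_contrasts(fitb, both)
  expect_equal(pwb$delta_mu, 0, tolerance = 1e-6)
  expect_gt(pwb$p_raw, 0.99)
})

test_that("Benjamini-Yekutieli adjustment matches the hand formula", {
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_equal(by_adjust(0.02), 0.02)   # m = 1, c(1) = 1
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order preservation and p_adj >= p over random vectors
  set.seed(9)
  for (k in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- by_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # hand step-up evaluation
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    hand <- pmin(1, p[o] * m * cm / seq_len(m))
    hand <- rev(cummin(rev(hand)))
    expect_equal(adj[o], hand, tolerance = 1e-12)
  }
})

test_that("significance stars follow the reporting thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.001, 0.005, 0.04, 0.05, 0.5)),
               c("***", "***", "**", "*", "*", "ns"))
  expect_error(significance_stars(1.5))
})

test_that("ffcompare assembles the full report and recovers structure", {
  offs <- matrix(c(0, 1, 0, 0), 2, 2,
                 dimnames = list(c("53A6", "54A8"), c("m1", "m2")))
  tab <- gen_metric_table(n_proteins = 12, n_replicates = 3,
                          parameter_sets = c("53A6", "54A8"),
                          metrics = c("m1", "m2"), ff_offsets = offs,
                          sd_protein = 1, sd_replicate = 0.3,
                          sd_residual = 0.3, seed = 15)
  cmp <- ffcompare(tab)
  expect_s3_class(cmp, "ffcompare")
  expect_equal(nrow(cmp$pairwise), 2L)          # one pair per metric
  expect_true(all(cmp$pairwise$p_adj >= cmp$pairwise$p_raw - 1e-12))
  # the planted m1 effect is flagged, the null m2 is not stronger than m1
  p1 <- cmp$pairwise$p_adj[cmp$pairwise$metric == "m1"]
  p2 <- cmp$pairwise$p_adj[cmp$pairwise$metric == "m2"]
  expect_lt(p1, 0.05)
  expect_lt(p1, p2)
  expect_lt(cmp$mvmelrt$p, 0.05)
  # S3 surface
  expect_output(print(cmp), "pairwise differences")
  s <- summary(cmp)
  expect_named(s$per_metric_p, c("m1", "m2"))
  co <- coef(cmp)
  expect_equal(dim(co), c(2L, 1L))
})

test_that("full-pipeline recovery holds across seeds", {
  ok <- 0L; n_seed <- 25L
  for (s in seq_len(n_seed)) {
    tab <- gen_metric_table(n_proteins = 12, n_replicates = 2,
                            parameter_sets = c("A", "B"),
                            ff_offsets = c(A = 0, B = 0.6),
                            sd_protein = 1, sd_replicate = 0.3,
                            sd_residual = 0.3, seed = 5000 + s)
    fit <- fit_univariate_mixed(tab)
    est <- unname(fit$fixed_effects["B"] - fit$fixed_effects["A"])
    se <- sqrt(2 * (fit$var_replicate + fit$var_residual) / (12 * 2))
    if (abs(est - 0.6) <= 3 * se) ok <- ok + 1L
  }
  expect_gte(ok / n_seed, 0.9)
})
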