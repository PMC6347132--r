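# One standard replicate: birth-death tree, regression context, randomized
# Brownian trait. Seeds are derived from the master seed by counter so every
# battery is fully replayable.
standard_replicate <- function(seed, rep_id) {
  tree <- simulate_bd_tree(seed = child_seed(seed, rep_id * 10L + 1L))
  pars <- draw_experiment_params(seed = child_seed(seed, rep_id * 10L + 2L))
  y <- simulate_bm(tree, sigma2 = pars$sigma2, root_value = pars$root_value,
                   seed = child_seed(seed, rep_id * 10L + 3L))
  list(tree = tree, ctx = rr_context(tree), pars = pars, y = y)
}

#' Whole-tree power and Type-I-error battery
#'
#' For each of `n_trees` birth-death trees, simulates a Brownian trait
#' (random phylogenetic mean and sigma^2) and evaluates the whole-tree trend
#' and drift tests on five phenotypes derived from it: the untransformed
#' Brownian trait, trend transforms at the two threshold exponents
#' (`es_sig`), and drift transforms at the two threshold slopes
#' (`+/- ds_sig`, expressed in Brownian standard deviations per unit time:
#' the slope applied to the trait is `ds_sig * sqrt(sigma2)`, which keeps
#' the drift's detectability — and the `dev` it produces — independent of
#' the arbitrary trait scale). The Brownian null family is simulated once
#' per tree and shared across the five scenarios (the family depends only
#' on the tree).
#'
#' Correct identification means: verdict `"none"` for the Brownian scenario,
#' and a significant verdict of the matching direction for the transformed
#' scenarios; any-direction and ungated (rank-only) columns are also
#' reported.
#'
#' @param n_trees number of tree/trait replicates.
#' @param n_null Brownian null family size.
#' @param seed master seed.
#' @param es_sig named pair `c(minus = , plus = )` of trend exponents.
#' @param ds_sig drift slope magnitude (Brownian SD per unit time).
#' @param sd_rule direction gate for the trend verdict, see [search_trend()].
#' @param scenarios subset of
#'   `c("BM", "Trend+", "Trend-", "Drift+", "Drift-")`.
#' @return list with `replicates` (one row per tree x scenario) and
#'   `summary` (per-scenario correct-identification frequencies).
#' @export
run_table1 <- function(n_trees = 200, n_null = 100, seed = NULL,
                       es_sig = c(minus = 0.3, plus = 1.6), ds_sig = 0.25,
                       sd_rule = "direction",
                       scenarios = c("BM", "Trend+", "Trend-", "Drift+", "Drift-")) {
  rows <- vector("list", n_trees * length(scenarios))
  k <- 0L
  for (i in seq_len(n_trees)) {
    rep_i <- standard_replicate(seed, i)
    ctx <- rep_i$ctx
    nul <- null_pipeline(ctx, n_null, seed = child_seed(seed, i * 10L + 4L))
    sg <- sqrt(rep_i$pars$sigma2)
    for (sc in scenarios) {
      y2 <- switch(sc,
        "BM" = rep_i$y,
        "Trend+" = apply_trend(rep_i$y, rep_i$tree, es_sig[["plus"]]),
        "Trend-" = apply_trend(rep_i$y, rep_i$tree, es_sig[["minus"]]),
        "Drift+" = apply_drift(rep_i$y, rep_i$tree, ds_sig * sg),
        "Drift-" = apply_drift(rep_i$y, rep_i$tree, -ds_sig * sg))
      fit <- fit_rates(ctx, y2)
      tr_slope <- fast_slope(unname(ctx$branch_age), log_rescaled(abs(fit$rates)))
      ph <- c(y2, fit$node_estimates)
      dr_slope <- fast_slope(unname(ctx$ages), rescale01(unname(ph)))
      sd_stat <- sd_halves_stat(fit$rates, ctx)
      trend_p <- rank_p(tr_slope, nul$trend)
      drift_p <- rank_p(dr_slope, nul$drift)
      sd_p <- rank_p(sd_stat, nul$sd_ratio)
      dev <- if (sc %in% c("Drift+", "Drift-", "BM"))
        dev_metric(rep_i$y, y2, rep_i$tree, sigma = sg)
      else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(
        tree = i, scenario = sc, n_tips = ctx$n_tip,
        sigma2 = rep_i$pars$sigma2, root_value = rep_i$pars$root_value,
        trend_p = trend_p, drift_p = drift_p, sd_ratio_p = sd_p,
        trend_verdict = slope_verdict(trend_p, sd_p, sd_rule),
        drift_verdict = if (drift_p > 0.95) "+" else if (drift_p < 0.05) "-" else "none",
        dev = dev
      )
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(replicates, replicates$scenario), function(d) {
    sc <- as.character(d$scenario[1L])
    expect <- switch(sc, "BM" = "none",
                     "Trend+" = "+", "Trend-" = "-", "Drift+" = "+", "Drift-" = "-")
    uses_trend <- sc %in% c("BM", "Trend+", "Trend-")
    v <- if (uses_trend) d$trend_verdict else d$drift_verdict
    trend_sig <- d$trend_p > 0.95 | d$trend_p < 0.05
    drift_sig <- d$drift_p > 0.95 | d$drift_p < 0.05
    data.frame(scenario = sc, n = nrow(d),
               correct = mean(v == expect),
               detected_any = mean(v != "none"),
               trend_rank_sig = mean(trend_sig),
               drift_rank_sig = mean(drift_sig),
               mean_abs_dev = mean(abs(d$dev)))
  }))
  rownames(summary) <- NULL
  list(replicates = replicates, summary = summary,
       n_trees = n_trees, n_null = n_null, seed = seed, sd_rule = sd_rule)
}

#' Estimate the significance-threshold transform intensities
#'
#' Sweeps the trend exponent `es ~ U(-1, 3)` and the drift slope
#' `ds ~ U(-2, 2)` (in Brownian SD per unit time, applied as
#' `ds * sqrt(sigma2)`) over `n_trees` tree/trait replicates, records the
#' trend / drift rank-P of each transformed phenotype, regresses P on the
#' parameter, and solves the fitted line for the significance boundaries
#' (P = 0.95 upward, P = 0.05 downward). Because rank-P saturates at 0 and
#' 1, a quasibinomial logistic fit is reported alongside; note the
#' straight-line crossing is a biased (conservative, outward-shifted)
#' estimate of the boundary whenever the P curve saturates well inside the
#' sweep range.
#'
#' @param n_trees number of sweep replicates.
#' @param n_null Brownian null family size.
#' @param seed master seed.
#' @param sd_rule passed through to the trend verdict (recorded, not used in
#'   threshold estimation, which works on the rank-P values).
#' @return list with `es_sig` and `ds_sig` (named `c(minus, plus)`, from
#'   the straight-line fit), `logistic` (same quantities from the logistic
#'   fit), the fitted models, and the per-replicate `data`.
#' @export
estimate_sig_thresholds <- function(n_trees = 200, n_null = 100, seed = NULL,
                                    sd_rule = "direction") {
  rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    rep_i <- standard_replicate(seed, i)
    ctx <- rep_i$ctx
    nul <- null_pipeline(ctx, n_null, seed = child_seed(seed, i * 10L + 4L))
    y_tr <- apply_trend(rep_i$y, rep_i$tree, rep_i$pars$es)
    fit_tr <- fit_rates(ctx, y_tr)
    trend_p <- rank_p(fast_slope(unname(ctx$branch_age), log_rescaled(abs(fit_tr$rates))),
                      nul$trend)
    y_dr <- apply_drift(rep_i$y, rep_i$tree, rep_i$pars$ds * sqrt(rep_i$pars$sigma2))
    fit_dr <- fit_rates(ctx, y_dr)
    drift_p <- rank_p(fast_slope(unname(ctx$ages),
                                 rescale01(unname(c(y_dr, fit_dr$node_estimates)))),
                      nul$drift)
    rows[[i]] <- data.frame(tree = i, n_tips = ctx$n_tip,
                            sigma2 = rep_i$pars$sigma2,
                            es = rep_i$pars$es, ds = rep_i$pars$ds,
                            trend_p = trend_p, drift_p = drift_p)
  }
  data <- do.call(rbind, rows)
  es_fit <- threshold_fits(data$es, data$trend_p)
  ds_fit <- threshold_fits(data$ds, data$drift_p)
  list(es_sig = es_fit$linear, ds_sig = ds_fit$linear,
       logistic = list(es_sig = es_fit$logistic, ds_sig = ds_fit$logistic),
       models = list(es = es_fit$models, ds = ds_fit$models),
       data = data, n_trees = n_trees, n_null = n_null, seed = seed)
}

# Solve fitted P(x) = 0.05 (minus) and 0.95 (plus) for a linear and a
# logistic fit of rank-P on the transform parameter.
threshold_fits <- function(x, p) {
  lin <- stats::lm(p ~ x)
  a <- stats::coef(lin)[[1L]]; b <- stats::coef(lin)[[2L]]
  linear <- c(minus = (0.05 - a) / b, plus = (0.95 - a) / b)
  logit <- function(q) log(q / (1 - q))
  models <- list(linear = lin)
  logistic <- c(minus = NA_real_, plus = NA_real_)
  glm_fit <- tryCatch(
    stats::glm(p ~ x, family = stats::quasibinomial()),
    error = function(e) NULL, warning = function(w) suppressWarnings(
      stats::glm(p ~ x, family = stats::quasibinomial())))
  if (!is.null(glm_fit) && stats::coef(glm_fit)[[2L]] != 0) {
    al <- stats::coef(glm_fit)[[1L]]; bl <- stats::coef(glm_fit)[[2L]]
    logistic <- c(minus = (logit(0.05) - al) / bl, plus = (logit(0.95) - al) / bl)
    models$logistic <- glm_fit
  }
  list(linear = linear, logistic = logistic, models = models)
}

#' Check that tree size and Brownian rate do not drive the tests
#'
#' Regresses the recorded rank-P values of a completed battery on tip count
#' and on the drawn Brownian rate sigma^2, for the trend and the drift test
#' separately. Near-zero R-squared values indicate the tests are insensitive
#' to both.
#'
#' @param data per-replicate data frame with columns `n_tips`, `sigma2` and
#'   `trend_p` and/or `drift_p` (as produced by [run_table1()] or
#'   [estimate_sig_thresholds()]).
#' @return data frame with one row per (response, predictor) regression:
#'   slope, parametric p-value, R-squared.
#' @export
run_size_and_sigma_checks <- function(data) {
  specs <- expand.grid(response = intersect(c("trend_p", "drift_p"), names(data)),
                       predictor = c("n_tips", "sigma2"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    r <- specs$response[i]; px <- specs$predictor[i]
    m <- summary(stats::lm(data[[r]] ~ data[[px]]))
    data.frame(response = r, predictor = px,
               slope = m$coefficients[2L, 1L],
               p_value = m$coefficients[2L, 4L],
               r_squared = m$r.squared)
  }))
}
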