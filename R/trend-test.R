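#' Rescale a vector to the unit interval
#'
#' `(v - min) / (max - min)`. Both the observed and the Brownian-null rate
#' and phenotype vectors pass through this rescaling before their regression
#' slopes are compared, so that slopes are comparable across variables with
#' different natural ranges.
#'
#' @param v numeric vector with at least two distinct values.
#' @export
rescale01 <- function(v) {
  r <- range(v)
  if (!all(is.finite(r)) || r[1L] == r[2L]) stop("cannot rescale a constant vector")
  (v - r[1L]) / (r[2L] - r[1L])
}

# Rate magnitudes -> [0,1] -> log. The offset keeps the (rescaled) minimum
# finite; it is applied identically to observed and null pipelines, and the
# rank comparison is invariant to any such shared monotone adjustment.
log_rescaled <- function(x, eps = 1e-4) log(rescale01(x) + eps)

fast_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

# Column-wise OLS slopes of Y (matrix) on x.
slope_cols <- function(x, Y) {
  xc <- x - mean(x)
  as.vector(xc %*% Y) / sum(xc^2)
}

col_rescale01 <- function(M) {
  lo <- apply(M, 2L, min)
  hi <- apply(M, 2L, max)
  sweep(sweep(M, 2L, lo), 2L, hi - lo, `/`)
}

#' Rate-trend regression
#'
#' Regresses the log of the 0-1-rescaled rate magnitudes on branch age
#' (the root-distance of the element below each branch; `age_at = "midpoint"`
#' uses the branch midpoint instead). Rates are logged to reduce the
#' skewness of their distribution; a positive slope means rate magnitudes
#' increase towards the present.
#'
#' @param fit an [fit_rates()] result.
#' @param age_at `"child"` (default) or `"midpoint"`.
#' @return list with `slope`, `intercept`, `r.squared`, `p.parametric`
#'   (the within-regression t-test; the method's significance comes from
#'   [rank_p()] against Brownian nulls) and the regression `data`.
#' @export
trend_regression <- function(fit, age_at = c("child", "midpoint")) {
  stopifnot(inherits(fit, "rr_fit"))
  age_at <- match.arg(age_at)
  ctx <- fit$context
  x <- if (age_at == "child") ctx$branch_age else ctx$branch_mid_age
  if (length(x) < 3L) stop("fewer than 3 branches")
  yv <- log_rescaled(abs(fit$rates))
  m <- summary(stats::lm(yv ~ x))
  list(slope = m$coefficients[2L, 1L],
       intercept = m$coefficients[1L, 1L],
       r.squared = m$r.squared,
       p.parametric = m$coefficients[2L, 4L],
       data = data.frame(branch = names(fit$rates), age = unname(x),
                         log_rescaled_rate = unname(yv)))
}

#' Phenotypic-drift regression
#'
#' Regresses the 0-1-rescaled phenotype vector (ancestral node estimates
#' collated with observed tip values) on element age. A positive slope means
#' the phenotypic mean increases towards the present.
#'
#' @param fit an [fit_rates()] result.
#' @return list as in [trend_regression()].
#' @export
drift_regression <- function(fit) {
  stopifnot(inherits(fit, "rr_fit"))
  ph <- predict_phenotype_vector(fit)
  yv <- rescale01(ph$value)
  m <- summary(stats::lm(yv ~ ph$age))
  list(slope = m$coefficients[2L, 1L],
       intercept = m$coefficients[1L, 1L],
       r.squared = m$r.squared,
       p.parametric = m$coefficients[2L, 4L],
       data = data.frame(element = ph$element, age = ph$age,
                         rescaled_phenotype = unname(yv)))
}

# Ratio of rate SD in the older half of the tree to the recent half
# (branches assigned by midpoint age). Values < 1 indicate rate dispersion
# concentrated towards the present.
sd_halves_stat <- function(rates, ctx) {
  old <- ctx$branch_mid_age <= ctx$height / 2
  if (!any(old) || all(old)) stop("no branches on one side of half tree height")
  stats::sd(rates[old]) / stats::sd(rates[!old])
}

# Matrix version over columns of a rates matrix.
sd_halves_cols <- function(B, ctx) {
  old <- ctx$branch_mid_age <= ctx$height / 2
  csd <- function(M) {
    n <- nrow(M)
    m <- colMeans(M)
    sqrt((colSums(M^2) - n * m^2) / (n - 1))
  }
  csd(B[old, , drop = FALSE]) / csd(B[!old, , drop = FALSE])
}

# One full null pipeline on a tree: n BM traits (sigma^2 = 1), each fitted
# with the same ridge policy, yielding trend slopes, drift slopes and the
# SD-halves statistic per replicate.
null_pipeline <- function(ctx, n, lambda = "auto", seed = NULL) {
  Y <- simulate_bm(ctx$tree, sigma2 = 1, root_value = 0, seed = seed, nsim = n)
  res <- fit_rates_multi(ctx, Y, lambda = lambda)
  lr <- apply(abs(res$rates), 2L, log_rescaled)
  trend <- slope_cols(unname(ctx$branch_age), lr)
  phen <- col_rescale01(rbind(Y, res$node_estimates))
  ages_all <- unname(c(ctx$ages[seq_len(ctx$n_tip)], ctx$ages[ctx$n_tip + seq_len(ctx$n_node)]))
  drift <- slope_cols(ages_all, phen)
  sdr <- sd_halves_cols(res$rates, ctx)
  list(trend = trend, drift = drift, sd_ratio = sdr,
       rates = res$rates, phenotypes = phen)
}

#' Brownian null slope families
#'
#' Simulates `n` Brownian traits (`sigma^2 = 1`) on the tree and pushes each
#' through the full rate pipeline (ridge fit with the same penalty policy,
#' rescaling, logging) to obtain the family of null regression slopes the
#' observed slope is ranked against. Note the null trend slopes need not be
#' centred on zero: under Brownian motion rate magnitudes grow with distance
#' from the root, and the test is rank-based, not zero-based.
#'
#' @param tree a `phylo` or [rr_context()].
#' @param which `"trend"` or `"drift"`.
#' @param n family size (the method's default is 100).
#' @param seed optional integer seed.
#' @param lambda ridge penalty policy, as in [fit_rates()].
#' @return numeric vector of `n` null slopes.
#' @export
bm_null_slopes <- function(tree, which = c("trend", "drift"), n = 100,
                           seed = NULL, lambda = "auto") {
  which <- match.arg(which)
  stopifnot(n >= 1)
  ctx <- as_rr_context(tree)
  null_pipeline(ctx, n, lambda = lambda, seed = seed)[[which]]
}

#' Rank probability of an observed slope within a null family
#'
#' `P = (#\{null < observed\} + 1) / (n + 1)`. Values above 0.95 indicate a
#' significantly positive departure (increasing rates or phenotypic means
#' towards the present), values below 0.05 a significantly negative one.
#'
#' @param observed scalar statistic.
#' @param null numeric vector of null statistics.
#' @export
rank_p <- function(observed, null) {
  stopifnot(length(null) >= 1)
  (sum(null < observed) + 1) / (length(null) + 1)
}

#' Direction check on the dispersion of rates through time
#'
#' Computes the ratio of the standard deviation of rates on branches in the
#' older half of the tree to that in the more recent half (branches assigned
#' by midpoint age), and ranks it within the same statistic computed on each
#' Brownian null replicate. A significantly small ratio (rank P < 0.05) is
#' expected under a positive rate trend; a significantly large one under a
#' negative trend.
#'
#' @param fit an [fit_rates()] result.
#' @param null_sd_ratios numeric vector of null SD ratios (from the same
#'   null family used for the slope tests).
#' @return list with `statistic` and `p` (rank probability).
#' @export
sd_halves_check <- function(fit, null_sd_ratios) {
  stopifnot(inherits(fit, "rr_fit"))
  s <- sd_halves_stat(fit$rates, fit$context)
  list(statistic = s, p = rank_p(s, null_sd_ratios))
}

#' Whole-tree test for rate trends and phenotypic drift
#'
#' The main entry point: fits the phylogenetic ridge regression, computes
#' the trend (log rescaled rate magnitude vs age) and drift (rescaled
#' phenotype vs age) regression slopes, ranks each within a family of
#' `n_null` Brownian null slopes obtained on the same tree, and applies the
#' SD-halves direction check to the rates.
#'
#' A rate trend is reported (verdict `"+"` or `"-"`) when the slope rank is
#' significant (P > 0.95 or P < 0.05) *and* the SD-halves statistic ranks on
#' the concordant side of the null family (below / above the median for a
#' positive / negative trend); `sd_rule = "none"` disables the gate,
#' `"significance"` requires the SD check itself to be significant. Drift is
#' reported on the slope rank alone.
#'
#' @param tree a `phylo` or [rr_context()].
#' @param y named numeric vector of tip values.
#' @param n_null size of the Brownian null family.
#' @param seed optional integer seed (governs the null simulations).
#' @param lambda ridge penalty policy, as in [fit_rates()].
#' @param sd_rule `"direction"` (default), `"significance"`, or `"none"`.
#' @return an object of class `trend_report`.
#' @export
search_trend <- function(tree, y, n_null = 100, seed = NULL, lambda = "auto",
                         sd_rule = c("direction", "significance", "none")) {
  sd_rule <- match.arg(sd_rule)
  ctx <- as_rr_context(tree)
  y <- match_trait(ctx$tree, y)
  fit <- fit_rates(ctx, y, lambda = lambda)
  tr <- trend_regression(fit)
  dr <- drift_regression(fit)
  sd_stat <- sd_halves_stat(fit$rates, ctx)

  nul <- null_pipeline(ctx, n_null, lambda = lambda, seed = seed)
  trend_p <- rank_p(tr$slope, nul$trend)
  drift_p <- rank_p(dr$slope, nul$drift)
  sd_p <- rank_p(sd_stat, nul$sd_ratio)

  trend_verdict <- slope_verdict(trend_p, sd_p, sd_rule)
  drift_verdict <- if (drift_p > 0.95) "+" else if (drift_p < 0.05) "-" else "none"

  elements <- data.frame(
    element = ctx$labels,
    type = rep(c("tip", "node"), c(ctx$n_tip, ctx$n_node)),
    age = unname(ctx$ages),
    phenotype = unname(c(y, fit$node_estimates)),
    rescaled_phenotype = rescale01(unname(c(y, fit$node_estimates))),
    rate = NA_real_, log_rescaled_rate = NA_real_,
    row.names = NULL
  )
  elements$rate[ctx$branch_elems] <- unname(fit$rates)
  elements$log_rescaled_rate[ctx$branch_elems] <- unname(log_rescaled(abs(fit$rates)))

  structure(list(
    fit = fit,
    trend_slope = tr$slope, trend_p = trend_p,
    drift_slope = dr$slope, drift_p = drift_p,
    sd_ratio = sd_stat, sd_ratio_p = sd_p,
    trend_verdict = trend_verdict, drift_verdict = drift_verdict,
    n_null = n_null, seed = seed, sd_rule = sd_rule,
    elements = elements
  ), class = "trend_report")
}

slope_verdict <- function(p, sd_p, sd_rule) {
  if (p > 0.95) {
    ok <- switch(sd_rule, none = TRUE, direction = sd_p < 0.5, significance = sd_p < 0.05)
    if (ok) "+" else "none"
  } else if (p < 0.05) {
    ok <- switch(sd_rule, none = TRUE, direction = sd_p > 0.5, significance = sd_p > 0.95)
    if (ok) "-" else "none"
  } else "none"
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Trend/drift report (", x$n_null, " BM null slopes)\n", sep = "")
  cat(sprintf("  trend:  slope %+.4g  rank-P %.4f  verdict %s\n",
              x$trend_slope, x$trend_p, x$trend_verdict))
  cat(sprintf("  drift:  slope %+.4g  rank-P %.4f  verdict %s\n",
              x$drift_slope, x$drift_p, x$drift_verdict))
  cat(sprintf("  SD halves (old/recent): %.4g  rank-P %.4f\n",
              x$sd_ratio, x$sd_ratio_p))
  invisible(x)
}
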