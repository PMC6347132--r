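#' Impose a temporal trend in the evolutionary rate on a trait
#'
#' Transforms a tip trait `y` into `y * times^es / times`, where `times` are
#' the tip ages measured from the root. `es = 1` leaves the trait untouched
#' (pure Brownian motion); `es > 1` makes the phenotypic variance grow
#' faster than linearly with distance from the root (an accelerating rate);
#' `es < 1` the converse (a decelerating rate).
#'
#' @param y named numeric vector of tip values.
#' @param tree a `phylo` object.
#' @param es trend exponent (dimensionless).
#' @return transformed tip vector, same names and order as `y`.
#' @export
apply_trend <- function(y, tree, es) {
  stopifnot(is.finite(es))
  tree <- validate_tree(tree)
  y <- match_trait(tree, y)
  if (es == 1) return(y)
  t_tip <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (any(t_tip <= 0) && es < 1) stop("tip with age 0: trend transform undefined for es < 1")
  y * t_tip^es / t_tip
}

#' Impose a drift in the phenotypic mean on a trait
#'
#' Transforms a tip trait `y` into `y + times * ds`: the phenotypic mean
#' moves linearly with distance from the root at `ds` trait units per unit
#' time. `ds = 0` is the identity.
#'
#' @inheritParams apply_trend
#' @param ds drift slope (trait units per unit time).
#' @export
apply_drift <- function(y, tree, ds) {
  stopifnot(is.finite(ds))
  tree <- validate_tree(tree)
  y <- match_trait(tree, y)
  if (ds == 0) return(y)
  t_tip <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  y + t_tip * ds
}

#' Clade-restricted rate-trend transform
#'
#' Applies the rate-trend transform with exponent `2 * es_sig` to the tips of
#' a focal clade only; tips outside the clade are returned bit-identical.
#' This is the construction used to plant a clade-specific rate regime in the
#' clade-contrast validation batteries.
#'
#' @inheritParams apply_trend
#' @param clade a [clade_members()] selection.
#' @param es_sig the significance-threshold exponent; the clade receives
#'   twice this value.
#' @export
apply_clade_trend <- function(y, tree, clade, es_sig) {
  stopifnot(inherits(clade, "clade_selection"))
  tree <- validate_tree(tree)
  y <- match_trait(tree, y)
  sel <- names(y) %in% clade$tip_labels
  t_tip <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  y[sel] <- y[sel] * t_tip[sel]^(2 * es_sig) / t_tip[sel]
  y
}

#' Clade-restricted drift transform
#'
#' Adds `times * 2 * ds_sig * H_ratio` to the tips of a focal clade only,
#' where `H_ratio` is the ratio of tree height to clade height (so the drift
#' accumulated across the clade's own time span matches the intended
#' intensity regardless of where the clade sits in the tree).
#'
#' @inheritParams apply_clade_trend
#' @param ds_sig the significance-threshold drift slope; the clade receives
#'   twice this value, scaled by `H_ratio`.
#' @export
apply_clade_drift <- function(y, tree, clade, ds_sig) {
  stopifnot(inherits(clade, "clade_selection"))
  tree <- validate_tree(tree)
  y <- match_trait(tree, y)
  if (clade$clade_height <= 0) stop("clade height is zero")
  sel <- names(y) %in% clade$tip_labels
  t_tip <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  y[sel] <- y[sel] + t_tip[sel] * 2 * ds_sig * clade$H_ratio
  y
}

#' Drift intensity metric
#'
#' `dev` measures how far a drift transform displaces the phenotypic mean,
#' in trait standard deviations per unit time:
#' `dev = (mean(y_drifted) - mean(y_original)) / (sigma * tree_height)`,
#' where `sigma` is the trait's Brownian standard deviation per unit time
#' (by default the square root of the mean squared phylogenetically
#' independent contrast of the untransformed trait, the standard
#' Brownian-rate estimator). Comparing against the paired untransformed
#' trait isolates the displacement caused by the transform: `dev` is exactly
#' zero when no drift is applied, grows linearly with `|ds|`, and with a
#' drift of `ds` Brownian standard deviations per unit time it equals
#' `ds * mean(tip age) / tree_height` (about `0.75 * ds` on the birth-death
#' trees used in validation) up to estimation noise in `sigma`.
#'
#' @param y_original untransformed tip trait.
#' @param y_drifted drifted tip trait (same tips).
#' @param tree a `phylo` object.
#' @param sigma optional known Brownian standard deviation per unit time;
#'   estimated from `y_original` contrasts when `NULL`.
#' @export
dev_metric <- function(y_original, y_drifted, tree, sigma = NULL) {
  tree <- validate_tree(tree)
  y_original <- match_trait(tree, y_original)
  y_drifted <- match_trait(tree, y_drifted)
  if (is.null(sigma)) sigma <- sqrt(mean(ape::pic(y_original, tree)^2))
  if (sigma <= 0) stop("zero trait standard deviation")
  (mean(y_drifted) - mean(y_original)) / (sigma * tree_height(tree))
}

#' Rate-trend intensity metric
#'
#' `spread` compares the dispersion of a trait accrued in the recent half of
#' the tree to that accrued in the old half, normalized by the same figure
#' under Brownian motion. Concretely: over all elements (tips and nodes),
#' `R = range(values at age > H/2) / range(values at age <= H/2)`; the metric
#' is `R` divided by the mean of `R` across `n_bm_reference` Brownian
#' simulations on the same tree. Values below 1 indicate a decelerating rate
#' (`es < 1`), above 1 an accelerating rate.
#'
#' @param y_transformed tip trait after the trend transform.
#' @param tree a `phylo` object.
#' @param node_values values at internal nodes, named by node label. In
#'   simulation mode pass the true simulated states; otherwise pass
#'   ridge-estimated states (e.g. `fit_rates(...)$node_estimates`).
#' @param n_bm_reference number of Brownian reference simulations.
#' @param seed optional integer seed for the reference simulations.
#' @export
spread_metric <- function(y_transformed, tree, node_values, n_bm_reference = 100,
                          seed = NULL) {
  tree <- validate_tree(tree)
  y_transformed <- match_trait(tree, y_transformed)
  if (is.null(names(node_values))) stop("node_values must be named by node label")
  node_values <- node_values[tree$node.label]
  ages <- ape::node.depth.edgelength(tree)
  half <- max(ages[seq_len(ape::Ntip(tree))]) / 2
  recent <- ages > half
  if (!any(recent) || !any(!recent)) stop("no elements on one side of half tree height")
  half_ratio <- function(vals) {
    r_recent <- diff(range(vals[recent]))
    r_old <- diff(range(vals[!recent]))
    if (r_old == 0) stop("degenerate value range in the old half")
    r_recent / r_old
  }
  r_obs <- half_ratio(c(y_transformed, node_values))
  r_bm <- with_seed(seed, {
    vapply(seq_len(n_bm_reference), function(i) {
      sim <- simulate_bm(tree, sigma2 = 1, root_value = 0, internal = TRUE)
      half_ratio(c(sim, attr(sim, "node_values")))
    }, numeric(1L))
  })
  r_obs / mean(r_bm)
}
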