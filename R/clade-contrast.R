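#' Assign tree elements to focal clades or the background
#'
#' Labels every element (tip and node) of the tree by the focal clade that
#' contains it, or `"background"`. Focal clades must be pairwise disjoint.
#'
#' @param tree a `phylo` object.
#' @param clades a [clade_members()] selection or a list of them.
#' @return character vector over elements (named by element label).
#' @export
assign_groups <- function(tree, clades = list()) {
  tree <- validate_tree(tree)
  if (inherits(clades, "clade_selection")) clades <- list(clades)
  labels <- element_labels(tree)
  groups <- stats::setNames(rep("background", length(labels)), labels)
  if (length(clades) > 1L) {
    for (i in seq_len(length(clades) - 1L)) for (j in (i + 1L):length(clades)) {
      if (length(intersect(clades[[i]]$element_idx, clades[[j]]$element_idx)))
        stop("focal clades overlap: ", clades[[i]]$node_label, " and ",
             clades[[j]]$node_label)
    }
  }
  for (cl in clades) groups[cl$element_idx] <- cl$node_label
  groups
}

# Shared machinery: run both clade tests off a single Brownian null pipeline.
# Returns per-clade drift slopes/Ps, per-clade trend EMM contrasts/Ps, and
# (with two clades) the pairwise contrasts.
clade_contrast_engine <- function(ctx, y, clades, n_null, seed, lambda,
                                  do_trend = TRUE, do_drift = TRUE) {
  groups <- assign_groups(ctx$tree, clades)
  fit <- fit_rates(ctx, y, lambda = lambda)
  nul <- null_pipeline(ctx, n_null, lambda = lambda, seed = seed)
  ages_all <- unname(ctx$ages)
  out <- list(fit = fit, clades = clades, n_null = n_null)

  if (do_drift) {
    resc <- rescale01(c(y, fit$node_estimates))
    drift <- lapply(clades, function(cl) {
      idx <- cl$element_idx
      obs <- fast_slope(ages_all[idx], resc[idx])
      nulls <- slope_cols(ages_all[idx], nul$phenotypes[idx, , drop = FALSE])
      p <- rank_p(obs, nulls)
      list(clade = cl$node_label, slope = obs, p = p,
           verdict = if (p > 0.95) "+" else if (p < 0.05) "-" else "none")
    })
    names(drift) <- vapply(clades, `[[`, "", "node_label")
    out$drift <- drift
    if (length(clades) == 2L) {
      i1 <- clades[[1L]]$element_idx; i2 <- clades[[2L]]$element_idx
      obs_d <- fast_slope(ages_all[i1], resc[i1]) - fast_slope(ages_all[i2], resc[i2])
      null_d <- slope_cols(ages_all[i1], nul$phenotypes[i1, , drop = FALSE]) -
        slope_cols(ages_all[i2], nul$phenotypes[i2, , drop = FALSE])
      p <- rank_p(obs_d, null_d)
      out$drift_pair <- list(difference = obs_d, p = p,
                             verdict = if (p > 0.95) "+" else if (p < 0.05) "-" else "none")
    }
  }

  if (do_trend) {
    grp <- factor(groups[ctx$branch_elems],
                  levels = c("background", vapply(clades, `[[`, "", "node_label")))
    if (any(table(grp) < 3L)) stop("a group has fewer than 3 branches")
    age <- unname(ctx$branch_age)
    df <- data.frame(age = age, group = grp)
    M <- stats::model.matrix(~ age * group, df)
    qr_M <- qr(M)
    newdata <- data.frame(age = mean(age), group = factor(levels(grp), levels = levels(grp)))
    X_new <- stats::model.matrix(~ age * group, newdata)
    # contrast rows: each clade vs background, then clade1 vs clade2
    C <- X_new[-1L, , drop = FALSE] - X_new[rep(1L, nrow(X_new) - 1L), , drop = FALSE]
    rownames(C) <- paste0(levels(grp)[-1L], " - background")
    if (length(clades) == 2L) {
      C <- rbind(C, "clade1 - clade2" = X_new[2L, ] - X_new[3L, ])
    }
    lr_obs <- log_rescaled(abs(fit$rates))
    obs_contrasts <- as.vector(C %*% qr.coef(qr_M, lr_obs))
    lr_null <- apply(abs(nul$rates), 2L, log_rescaled)
    null_contrasts <- C %*% qr.coef(qr_M, lr_null)     # contrasts x n_null
    emm <- lapply(seq_len(nrow(C)), function(k) {
      p <- rank_p(obs_contrasts[k], null_contrasts[k, ])
      list(contrast = rownames(C)[k], estimate = obs_contrasts[k], p = p,
           verdict = if (p > 0.95) "+" else if (p < 0.05) "-" else "none")
    })
    names(emm) <- rownames(C)
    out$trend <- emm
    out$trend_model <- list(formula = ~ age * group, data = df,
                            reference_age = mean(age))
  }
  out
}

#' Clade-restricted drift test
#'
#' Tests whether the drift slope of a focal clade (regression of the
#' whole-tree 0-1-rescaled phenotype vector, restricted to the clade's
#' elements, on element age) departs from the Brownian motion expectation:
#' the observed clade slope is ranked within the same clade-restricted slope
#' computed on Brownian traits simulated on the full tree. With two clades
#' the difference between their slopes is additionally ranked within the
#' null slope differences.
#'
#' @param tree a `phylo` or [rr_context()].
#' @param y named numeric vector of tip values.
#' @param clades a [clade_members()] selection or list of (at most two).
#' @param n_null Brownian null family size.
#' @param seed optional integer seed.
#' @param lambda ridge penalty policy.
#' @return list with per-clade `slope`, `p`, `verdict`, and `drift_pair`
#'   when two clades are given.
#' @export
clade_drift_test <- function(tree, y, clades, n_null = 100, seed = NULL,
                             lambda = "auto") {
  ctx <- as_rr_context(tree)
  y <- match_trait(ctx$tree, y)
  if (inherits(clades, "clade_selection")) clades <- list(clades)
  res <- clade_contrast_engine(ctx, y, clades, n_null, seed, lambda,
                               do_trend = FALSE, do_drift = TRUE)
  res[c("drift", "drift_pair", "n_null")]
}

#' Age-adjusted clade rate comparison (estimated marginal means)
#'
#' Because the trend regression slope depends on where a clade sits in time,
#' clades are compared on their *adjusted* mean log-rescaled rate magnitude:
#' the linear model `log rescaled |rate| ~ age * group` is fitted over all
#' branches and each group's estimated marginal mean (EMM) is its prediction
#' at the grand-mean branch age. The contrast EMM(clade) - EMM(background)
#' (and EMM(clade1) - EMM(clade2) with two clades) is ranked within the same
#' contrast computed on each Brownian null replicate.
#'
#' @inheritParams clade_drift_test
#' @return list of contrasts, each with `estimate`, `p`, `verdict`.
#' @export
clade_trend_emm <- function(tree, y, clades, n_null = 100, seed = NULL,
                            lambda = "auto") {
  ctx <- as_rr_context(tree)
  y <- match_trait(ctx$tree, y)
  if (inherits(clades, "clade_selection")) clades <- list(clades)
  res <- clade_contrast_engine(ctx, y, clades, n_null, seed, lambda,
                               do_trend = TRUE, do_drift = FALSE)
  res[c("trend", "trend_model", "n_null")]
}

#' Full clade contrast report
#'
#' Runs both the clade drift test and the age-adjusted (EMM) rate-trend
#' contrast off a single family of Brownian null replicates.
#'
#' @inheritParams clade_drift_test
#' @return list with components `drift`, `drift_pair` (two clades only),
#'   `trend`, `fit`.
#' @export
clade_contrast <- function(tree, y, clades, n_null = 100, seed = NULL,
                           lambda = "auto") {
  ctx <- as_rr_context(tree)
  y <- match_trait(ctx$tree, y)
  if (inherits(clades, "clade_selection")) clades <- list(clades)
  stopifnot(length(clades) >= 1L, length(clades) <= 2L)
  clade_contrast_engine(ctx, y, clades, n_null, seed, lambda)
}

# Internal nodes (never the root) subtending at least min_tips tips and
# leaving a background of at least min_tips tips, so both groups of the
# contrast stay estimable.
eligible_clade_nodes <- function(ctx, min_tips = 20) {
  n_tip <- ctx$n_tip
  counts <- colSums(ctx$L_tip > 0)          # tips below each branch
  nodes <- ctx$branch_elems[ctx$branch_elems > n_tip]
  k <- counts[match(ctx$labels[nodes], colnames(ctx$L))]
  nodes[k >= min_tips & (n_tip - k) >= min_tips]
}

# Sample one clade or a disjoint pair among eligible nodes.
sample_clades <- function(ctx, n_clades, min_tips = 20, max_attempts = 100) {
  nodes <- eligible_clade_nodes(ctx, min_tips)
  if (length(nodes) < n_clades) return(NULL)
  if (n_clades == 1L) return(list(clade_members(ctx$tree, sample(rep(nodes, 2L), 1L))))
  for (i in seq_len(max_attempts)) {
    pick <- sample(nodes, 2L)
    a <- clade_members(ctx$tree, pick[1L])
    b <- clade_members(ctx$tree, pick[2L])
    if (length(intersect(a$element_idx, b$element_idx))) next
    # keep a usable background outside both clades
    if (ctx$n_tip - length(a$tip_labels) - length(b$tip_labels) >= min_tips)
      return(list(a, b))
  }
  NULL
}

#' Clade-contrast validation battery
#'
#' Reproduces the clade-level power / Type-I-error experiments: on each of
#' `n_trees` birth-death trees a Brownian trait is simulated, one or two
#' random disjoint clades (with at least `min_clade_tips` tips) are
#' transformed — trend clades by `y * times^(2 es_sig) / times`, drift
#' clades by `y + times * 2 ds_sig * H_ratio` with `ds_sig` expressed in
#' Brownian SD per unit time — and the clade tests are run
#' with `n_null` Brownian nulls. With `transform = FALSE` the clades are
#' left untransformed, measuring false-positive rates.
#'
#' @param n_trees replicate count.
#' @param mode `"trend"` or `"drift"`.
#' @param n_clades 1 (clade vs background) or 2 (also contrasted pairwise).
#' @param transform apply the clade transform (`FALSE` = Type-I-error run).
#' @param sign `"random"` (each clade's direction drawn independently),
#'   `"positive"`, `"negative"`, or `"opposite"` (two clades, first
#'   positive, second negative).
#' @param es_sig named pair `c(minus = , plus = )` of trend threshold
#'   exponents used for negative / positive clades.
#' @param ds_sig drift threshold slope (its sign follows the clade's drawn
#'   direction).
#' @param n_null Brownian null family size.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param min_clade_tips minimum clade size.
#' @return list with `replicates` (one row per clade test) and `summary`
#'   (detection frequencies by role and realized direction).
#' @export
run_clade_battery <- function(n_trees = 50, mode = c("trend", "drift"),
                              n_clades = 1, transform = TRUE,
                              sign = c("random", "positive", "negative", "opposite"),
                              es_sig = c(minus = 0.3, plus = 1.6), ds_sig = 0.25,
                              n_null = 100, seed = NULL, min_clade_tips = 20) {
  mode <- match.arg(mode)
  sign <- match.arg(sign)
  rows <- list()
  rep_id <- 0L
  while (rep_id < n_trees) {
    rep_id <- rep_id + 1L
    base <- child_seed(seed, rep_id * 10L)
    tree <- simulate_bd_tree(seed = child_seed(seed, rep_id * 10L + 1L))
    ctx <- rr_context(tree)
    pars <- draw_experiment_params(seed = child_seed(seed, rep_id * 10L + 2L))
    y <- simulate_bm(tree, sigma2 = pars$sigma2, root_value = pars$root_value,
                     seed = child_seed(seed, rep_id * 10L + 3L))
    clades <- with_seed(child_seed(seed, rep_id * 10L + 4L),
                        sample_clades(ctx, n_clades, min_clade_tips))
    if (is.null(clades)) { rep_id <- rep_id - 1L; next }  # tree had no usable pair

    dirs <- with_seed(child_seed(seed, rep_id * 10L + 5L), {
      switch(sign,
             random = sample(c(1, -1), length(clades), replace = TRUE),
             positive = rep(1, length(clades)),
             negative = rep(-1, length(clades)),
             opposite = c(1, rep(-1, length(clades) - 1L)))
    })
    y2 <- y
    if (transform) {
      for (k in seq_along(clades)) {
        y2 <- if (mode == "trend") {
          apply_clade_trend(y2, tree, clades[[k]],
                            if (dirs[k] > 0) es_sig[["plus"]] else es_sig[["minus"]])
        } else {
          # drift intensity in Brownian SD per unit time, as in run_table1
          apply_clade_drift(y2, tree, clades[[k]], dirs[k] * ds_sig * sqrt(pars$sigma2))
        }
      }
    }
    cc <- clade_contrast_engine(ctx, y2, clades, n_null,
                                seed = child_seed(seed, rep_id * 10L + 6L),
                                lambda = "auto",
                                do_trend = mode == "trend",
                                do_drift = mode == "drift")
    for (k in seq_along(clades)) {
      res_k <- if (mode == "trend") cc$trend[[k]] else cc$drift[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_id, role = "individual", clade = clades[[k]]$node_label,
        clade_tips = length(clades[[k]]$tip_labels),
        H_ratio = clades[[k]]$H_ratio,
        direction = if (transform) ifelse(dirs[k] > 0, "+", "-") else "BM",
        p = res_k$p, verdict = res_k$verdict,
        detected = res_k$verdict != "none"
      )
    }
    if (n_clades == 2L) {
      pair <- if (mode == "trend") cc$trend[["clade1 - clade2"]] else cc$drift_pair
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_id, role = "pairwise", clade = "pair",
        clade_tips = NA_integer_, H_ratio = NA_real_,
        direction = if (!transform) "BM" else if (dirs[1L] == dirs[2L]) "same" else "opposite",
        p = pair$p, verdict = pair$verdict, detected = pair$verdict != "none"
      )
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- stats::aggregate(detected ~ role + direction, replicates, mean)
  names(summary)[names(summary) == "detected"] <- "detection_rate"
  counts <- stats::aggregate(detected ~ role + direction, replicates, length)
  summary$n <- counts$detected
  list(replicates = replicates, summary = summary, mode = mode,
       n_clades = n_clades, transform = transform, n_null = n_null, seed = seed)
}
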