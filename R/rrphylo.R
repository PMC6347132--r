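#' Estimate the phenotype at the tree root
#'
#' The root value anchors the ridge regression: it is the weighted average of
#' the 10% most ancient tips (the tips whose root-path age is smallest, i.e.
#' the earliest-terminating lineages), with weights chosen so that older
#' species have more influence. The default weighting is inverse squared age
#' (`1 / age^2`), which honours that intent on root-distance ages; `"square_age"`
#' (`age^2`) is exposed for sensitivity analysis.
#'
#' @param tree a `phylo` object.
#' @param y named numeric vector of tip values.
#' @param fraction fraction of tips counted as "most ancient"
#'   (`max(1, round(fraction * N))` tips are used).
#' @param weighting `"inverse_square_age"` (default) or `"square_age"`.
#' @return the estimated root value (scalar).
#' @export
estimate_rootV <- function(tree, y, fraction = 0.1,
                           weighting = c("inverse_square_age", "square_age")) {
  weighting <- match.arg(weighting)
  tree <- validate_tree(tree)
  y <- match_trait(tree, y)
  ages <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  sel <- order(ages)[seq_len(max(1L, round(fraction * length(ages))))]
  w <- if (weighting == "inverse_square_age") 1 / ages[sel]^2 else ages[sel]^2
  stats::weighted.mean(y[sel], w)
}

#' Precomputed regression context for a tree
#'
#' Builds, once per tree, everything the ridge fits need: the design matrix
#' of root-path branch lengths (rows = elements, columns = branches), its
#' singular value decomposition restricted to tip rows, element ages and
#' branch ages. Passing the same context to [fit_rates()],
#' [search_trend()] and the clade tests avoids recomputing the
#' decomposition for each of the ~100 Brownian null replicates.
#'
#' @param tree a `phylo` object.
#' @return an object of class `rr_context`.
#' @export
rr_context <- function(tree) {
  tree <- validate_tree(tree)
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  n_elem <- n_tip + n_node
  root <- n_tip + 1L
  ages <- ape::node.depth.edgelength(tree)
  labels <- element_labels(tree)
  names(ages) <- labels

  branch_elems <- setdiff(seq_len(n_elem), root)
  col_of <- integer(n_elem)
  col_of[branch_elems] <- seq_along(branch_elems)

  parent_of <- integer(n_elem)
  edge_len <- numeric(n_elem)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_len[tree$edge[, 2L]] <- tree$edge.length

  # cladewise edge order lists every parent before its children, so one pass
  # propagates root paths down the tree
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  L <- matrix(0, n_elem, length(branch_elems),
              dimnames = list(labels, labels[branch_elems]))
  for (i in seq_len(nrow(tree_cw$edge))) {
    p <- tree_cw$edge[i, 1L]
    ch <- tree_cw$edge[i, 2L]
    L[ch, ] <- L[p, ]
    L[ch, col_of[ch]] <- edge_len[ch]
  }

  structure(list(
    tree = tree,
    n_tip = n_tip, n_node = n_node,
    labels = labels,
    ages = ages,
    height = max(ages[seq_len(n_tip)]),
    branch_elems = branch_elems,
    branch_age = ages[branch_elems],
    branch_mid_age = (ages[parent_of[branch_elems]] + ages[branch_elems]) / 2,
    L = L,
    L_tip = L[seq_len(n_tip), , drop = FALSE],
    L_node = L[n_tip + seq_len(n_node), , drop = FALSE],
    svd = svd(L[seq_len(n_tip), , drop = FALSE])
  ), class = "rr_context")
}

as_rr_context <- function(x) {
  if (inherits(x, "rr_context")) x else rr_context(x)
}

#' Design matrix of root-path branch lengths
#'
#' One row per element (tips first, then internal nodes in ape order), one
#' column per branch (indexed by the element below the branch); the entry is
#' the branch length if the branch lies on the element's root path, else 0.
#' Row sums therefore equal element ages.
#'
#' @param tree a `phylo` object or an [rr_context()].
#' @export
build_design_matrix <- function(tree) {
  as_rr_context(tree)$L
}

# Grid used for automatic ridge-penalty selection.
lambda_grid <- function() 10^seq(-6, 3, length.out = 40)

# Vectorized ridge fit over the columns of Y (tips x K), sharing one SVD.
# lambda: "auto" (per-column GCV minimizer over lambda_grid()) or a scalar.
fit_rates_multi <- function(ctx, Y, lambda = "auto",
                            root_weighting = "inverse_square_age") {
  n <- ctx$n_tip
  K <- ncol(Y)
  tip_ages <- ctx$ages[seq_len(n)]
  sel <- order(tip_ages)[seq_len(max(1L, round(0.1 * n)))]
  w <- if (root_weighting == "inverse_square_age") 1 / tip_ages[sel]^2 else tip_ages[sel]^2
  rootV <- as.vector(w %*% Y[sel, , drop = FALSE]) / sum(w)

  R <- sweep(Y, 2L, rootV)
  u <- ctx$svd$u; d <- ctx$svd$d; v <- ctx$svd$v
  Z <- crossprod(u, R)                       # n x K

  if (identical(lambda, "auto")) {
    grid <- lambda_grid()
    gcv <- vapply(grid, function(lam) {
      shr <- lam / (d^2 + lam)
      rss <- colSums((shr * Z)^2)
      edf <- sum(d^2 / (d^2 + lam))
      n * rss / (n - edf)^2
    }, numeric(K))
    gcv <- matrix(gcv, nrow = K)             # K x n_grid
    lam_k <- grid[max.col(-gcv, ties.method = "first")]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    lam_k <- rep(lambda, K)
  }

  denom <- outer(d^2, rep(1, K)) + matrix(lam_k, length(d), K, byrow = TRUE)
  B <- v %*% ((d * Z) / denom)               # branches x K
  nodes <- sweep(ctx$L_node %*% B, 2L, rootV, `+`)
  fitted <- sweep(ctx$L_tip %*% B, 2L, rootV, `+`)
  rownames(B) <- colnames(ctx$L)
  rownames(nodes) <- ctx$labels[ctx$n_tip + seq_len(ctx$n_node)]
  rownames(fitted) <- ctx$labels[seq_len(ctx$n_tip)]
  list(rates = B, node_estimates = nodes, rootV = rootV, lambda = lam_k,
       fitted = fitted)
}

#' Phylogenetic ridge regression rates and ancestral states
#'
#' Solves the normalized phylogenetic ridge regression: with `L` the tip
#' design matrix of root-path branch lengths and `rootV` the estimated root
#' value, the per-branch rates are
#' `b = argmin ||(y - rootV) - L b||^2 + lambda ||b||^2`.
#' Each rate is the phenotypic change per unit time along one branch;
#' ancestral states are `rootV + L_node b` and fitted tip values
#' `rootV + L_tip b`. The penalty keeps rates from taking extreme values on
#' short branches (this shrinkage is what distinguishes the method from
#' ordinary least squares). With `lambda = "auto"` the penalty minimizes the
#' generalized cross-validation (leave-one-out approximation) error of the
#' tip fits over a log-spaced grid.
#'
#' @param tree a `phylo` object or an [rr_context()].
#' @param y named numeric vector of tip values.
#' @param lambda ridge penalty: `"auto"` (default) or a non-negative scalar.
#' @param rootV optional fixed root value; default estimated via
#'   [estimate_rootV()].
#' @param root_weighting passed to [estimate_rootV()].
#' @return an object of class `rr_fit`: list with `rates` (named by the
#'   element below each branch), `node_estimates` (named by node label, root
#'   included), `rootV`, `lambda`, `fitted`, and the `context`.
#' @export
fit_rates <- function(tree, y, lambda = "auto", rootV = NULL,
                      root_weighting = c("inverse_square_age", "square_age")) {
  root_weighting <- match.arg(root_weighting)
  ctx <- as_rr_context(tree)
  y <- match_trait(ctx$tree, y)
  Y <- matrix(y, ncol = 1L, dimnames = list(names(y), NULL))
  if (is.null(rootV)) {
    res <- fit_rates_multi(ctx, Y, lambda = lambda, root_weighting = root_weighting)
  } else {
    # fixed rootV: bypass the internal estimate by centering manually
    res <- fit_rates_multi_fixed_root(ctx, Y, rootV, lambda)
  }
  structure(list(
    rates = res$rates[, 1L],
    node_estimates = res$node_estimates[, 1L],
    rootV = res$rootV[1L],
    lambda = res$lambda[1L],
    fitted = res$fitted[, 1L],
    y = y,
    context = ctx
  ), class = "rr_fit")
}

fit_rates_multi_fixed_root <- function(ctx, Y, rootV, lambda = "auto") {
  K <- ncol(Y)
  rootV <- rep_len(rootV, K)
  n <- ctx$n_tip
  R <- sweep(Y, 2L, rootV)
  u <- ctx$svd$u; d <- ctx$svd$d; v <- ctx$svd$v
  Z <- crossprod(u, R)
  if (identical(lambda, "auto")) {
    grid <- lambda_grid()
    gcv <- vapply(grid, function(lam) {
      shr <- lam / (d^2 + lam)
      n * colSums((shr * Z)^2) / (n - sum(d^2 / (d^2 + lam)))^2
    }, numeric(K))
    gcv <- matrix(gcv, nrow = K)
    lam_k <- grid[max.col(-gcv, ties.method = "first")]
  } else lam_k <- rep(lambda, K)
  denom <- outer(d^2, rep(1, K)) + matrix(lam_k, length(d), K, byrow = TRUE)
  B <- v %*% ((d * Z) / denom)
  nodes <- sweep(ctx$L_node %*% B, 2L, rootV, `+`)
  fitted <- sweep(ctx$L_tip %*% B, 2L, rootV, `+`)
  rownames(B) <- colnames(ctx$L)
  rownames(nodes) <- ctx$labels[ctx$n_tip + seq_len(ctx$n_node)]
  rownames(fitted) <- ctx$labels[seq_len(ctx$n_tip)]
  list(rates = B, node_estimates = nodes, rootV = rootV, lambda = lam_k,
       fitted = fitted)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("Phylogenetic ridge regression fit\n")
  cat("  tips:", x$context$n_tip, " branches:", length(x$rates), "\n")
  cat("  rootV:", format(x$rootV, digits = 6),
      " lambda:", format(x$lambda, digits = 4), "\n")
  cat("  rate magnitude range:", paste(format(range(abs(x$rates)), digits = 4),
                                       collapse = " .. "), "\n")
  invisible(x)
}

#' Phenotype vector over all elements
#'
#' Collates the ancestral (node) estimates with the observed tip values and
#' pairs each with its root-distance age; this is the input of the drift
#' regression.
#'
#' @param fit an [fit_rates()] result.
#' @return data frame with columns `element`, `type` (`"tip"`/`"node"`),
#'   `age`, `value`, in ape element order (tips first, root = first node).
#' @export
predict_phenotype_vector <- function(fit) {
  stopifnot(inherits(fit, "rr_fit"))
  ctx <- fit$context
  data.frame(
    element = ctx$labels,
    type = rep(c("tip", "node"), c(ctx$n_tip, ctx$n_node)),
    age = unname(ctx$ages),
    value = unname(c(fit$y, fit$node_estimates)),
    row.names = NULL
  )
}
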