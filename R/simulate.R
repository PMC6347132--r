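#' Simulate a birth-death tree retaining extinct lineages
#'
#' Draws rooted, generally non-ultrametric trees from a constant-rate
#' birth-death process (via [phytools::pbtree()]), stopping when `n_extant`
#' lineages are alive and keeping extinct lineages as fossil tips. Replicates
#' that die out early or end up with fewer than `min_tips` total tips are
#' rejected and redrawn. The defaults (birth 0.5, death 0.2, stop at 100
#' extant, keep trees with at least 80 tips) define the study conditions used
#' by every validation battery in the package; under them accepted trees have
#' on the order of 130-230 tips.
#'
#' @param birth,death speciation and extinction rates; `birth > death >= 0`.
#' @param min_tips minimum total (extant + extinct) tip count to accept.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param n_extant number of living lineages at which the simulation stops.
#' @param max_attempts rejection-sampling budget.
#' @return a `phylo` with node labels assigned, class also `bd_tree`.
#' @export
simulate_bd_tree <- function(birth = 0.5, death = 0.2, min_tips = 80, seed = NULL,
                             n_extant = 100, max_attempts = 200) {
  stopifnot(birth > death, death >= 0, min_tips >= 2)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      tree <- phytools::pbtree(b = birth, d = death, n = n_extant,
                               extant.only = FALSE, quiet = TRUE)
      if (is.null(tree) || ape::Ntip(tree) < min_tips) next
      # pbtree returns trees that went fully extinct before reaching n_extant
      # as-is; those are caught by the min_tips filter above.
      return(validate_tree(tree))
    }
    stop("no tree with >= ", min_tips, " tips in ", max_attempts, " attempts")
  })
}

#' Simulate Brownian motion traits on a tree
#'
#' Gaussian increments along each branch with variance `sigma2 * branch
#' length` (via [phytools::fastBM()]). Optionally returns the true states at
#' internal nodes (used by the simulation-mode [spread_metric()] and by
#' ancestral-state validation).
#'
#' @param tree a `phylo` object.
#' @param sigma2 Brownian rate (trait-variance per unit time).
#' @param root_value trait value at the root.
#' @param seed optional integer seed.
#' @param internal if `TRUE`, attach true node states as attribute
#'   `"node_values"` (named by node label).
#' @param nsim number of replicate traits; when > 1 a tips-by-`nsim` matrix is
#'   returned (no node states).
#' @return named numeric vector of tip values (or matrix when `nsim > 1`).
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL,
                        internal = FALSE, nsim = 1) {
  stopifnot(sigma2 > 0)
  tree <- validate_tree(tree)
  with_seed(seed, {
    if (nsim > 1L) {
      y <- phytools::fastBM(tree, a = root_value, sig2 = sigma2, nsim = nsim)
      return(y[tree$tip.label, , drop = FALSE])
    }
    n_tip <- ape::Ntip(tree)
    if (internal) {
      full <- phytools::fastBM(tree, a = root_value, sig2 = sigma2, internal = TRUE)
      tips <- full[seq_len(n_tip)]
      nodes <- full[n_tip + seq_len(tree$Nnode)]
      names(nodes) <- tree$node.label
      structure(tips[tree$tip.label], node_values = nodes)
    } else {
      y <- phytools::fastBM(tree, a = root_value, sig2 = sigma2)
      y[tree$tip.label]
    }
  })
}

#' Draw the randomized parameters of one simulation replicate
#'
#' Reproduces the experiment-level randomization of the validation study:
#' the phylogenetic mean (root value) is uniform on \[-10, 10\], the Brownian
#' rate sigma^2 is drawn from a discrete uniform over 300 equally spaced
#' values on \[0.01, 10\], the rate-trend exponent `es` is uniform on
#' \[-1, 3\] and the drift slope `ds` uniform on \[-2, 2\].
#'
#' @param seed optional integer seed.
#' @return list with `root_value`, `sigma2`, `es`, `ds`.
#' @export
draw_experiment_params <- function(seed = NULL) {
  with_seed(seed, {
    list(
      root_value = stats::runif(1L, -10, 10),
      sigma2 = sample(seq(0.01, 10, length.out = 300), 1L),
      es = stats::runif(1L, -1, 3),
      ds = stats::runif(1L, -2, 2)
    )
  })
}
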