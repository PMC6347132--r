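# Shared fixtures and independent oracles used across test files.

# Small named Newick fixtures.
nwk_cherry3 <- "((A:1,B:1):1,C:2);"          # ultrametric, 3 tips
nwk_fossil3 <- "((A:1,B:1):1,C:1.5);"        # C extinct
nwk_cat3 <- "((A:1,B:2):1,C:4);"             # caterpillar-ish, non-ultrametric
nwk_pair <- "(A:1,B:2);"

# Independent per-element root-path sum, walking the edge matrix upwards.
brute_ages <- function(tree) {
  n_elem <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  ages <- numeric(n_elem)
  for (e in seq_len(n_elem)) {
    cur <- e
    a <- 0
    while (cur != root) {
      row <- which(tree$edge[, 2L] == cur)
      a <- a + tree$edge.length[row]
      cur <- tree$edge[row, 1L]
    }
    ages[e] <- a
  }
  ages
}

# Independent recursive descendant scan.
brute_descendants <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  out <- node
  for (k in kids) out <- c(out, brute_descendants(tree, k))
  sort(out)
}

# A modest birth-death tree for pipeline tests (fixed seed, ~30-60 tips).
small_bd_tree <- function(seed = 5, n_extant = 25, min_tips = 20) {
  simulate_bd_tree(min_tips = min_tips, seed = seed, n_extant = n_extant)
}

# First non-root internal node subtending at least min_tips tips.
eligible_node_for_test <- function(tree, min_tips = 8) {
  n_tip <- ape::Ntip(tree)
  for (node in (n_tip + 2L):(n_tip + tree$Nnode)) {
    k <- sum(brute_descendants(tree, node) <= n_tip)
    if (k >= min_tips && k <= n_tip - min_tips) return(node)
  }
  stop("no eligible node in fixture tree")
}

# A disjoint pair of clades, each with at least min_tips tips.
disjoint_pair_for_test <- function(tree, min_tips = 8) {
  n_tip <- ape::Ntip(tree)
  nodes <- (n_tip + 2L):(n_tip + tree$Nnode)
  ok <- nodes[vapply(nodes, function(nd)
    sum(brute_descendants(tree, nd) <= n_tip) >= min_tips, logical(1))]
  for (i in seq_along(ok)) for (j in seq_along(ok)) {
    if (i >= j) next
    a <- brute_descendants(tree, ok[i]); b <- brute_descendants(tree, ok[j])
    if (!length(intersect(a, b)))
      return(list(clade_members(tree, ok[i]), clade_members(tree, ok[j])))
  }
  stop("no disjoint pair in fixture tree")
}
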