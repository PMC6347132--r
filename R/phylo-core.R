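#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the input contract
#' required throughout the package: a rooted tree with branch lengths and
#' unique tip labels. Internal nodes without labels are auto-labelled
#' `"N<k>"`, where `k` is the ape node number (root = `Ntip + 1`).
#'
#' @param text Newick string (used when `file` is missing).
#' @param file path to a Newick file.
#' @return an object of class `phylo` with a complete `node.label`.
#' @seealso [write_newick()], [element_ages()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  validate_tree(tree)
}

#' Write a phylogeny to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  if (is.null(file)) {
    ape::write.tree(tree, digits = digits)
  } else {
    ape::write.tree(tree, file = file, digits = digits)
    invisible(file)
  }
}

# Validate and normalize a tree: rooted, branch lengths present and positive,
# unique tip labels, internal nodes labelled.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("branch lengths are missing")
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length <= 0)
  if (length(bad)) {
    stop("non-positive or missing branch length on the branch above element '",
         element_labels(label_nodes(tree))[tree$edge[bad[1L], 2L]], "'")
  }
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate tip label: '", dup[1L], "'")
  label_nodes(tree)
}

label_nodes <- function(tree) {
  n_tip <- ape::Ntip(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0("N", n_tip + which(empty))
  tree$node.label <- lab
  tree
}

# Labels for all elements in ape numbering order: tips 1..N then nodes N+1..N+M.
element_labels <- function(tree) c(tree$tip.label, tree$node.label)

#' Root-distance ages for every tip and internal node
#'
#' Ages are measured from the root (root = 0, most recent tip = tree height),
#' i.e. the "age" of an element is the sum of branch lengths on its root path.
#' On non-ultrametric trees, extinct tips have age below the tree height.
#'
#' @param tree a `phylo` object (validated via [read_newick()] or
#'   [validate_tree()] semantics).
#' @return named numeric vector over all tips and nodes, in ape element order.
#' @export
element_ages <- function(tree) {
  tree <- validate_tree(tree)
  ages <- ape::node.depth.edgelength(tree)
  names(ages) <- element_labels(tree)
  ages
}

#' Height of the tree
#'
#' Maximum root-to-tip distance (the age of the most recent tip).
#' @param tree a `phylo` object.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

# Children adjacency list indexed by element number.
child_list <- function(tree) {
  n_elem <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_elem)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# Element numbers (tips and nodes) descending from `node`, focal node included.
descendant_elements <- function(tree, node) {
  kids <- child_list(tree)
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    stack <- c(stack, kids[[cur]])
  }
  sort(out)
}

#' Select a clade and compute its height ratio
#'
#' Identifies the tips and internal nodes subtended by a focal node, the
#' clade height (root-path age of the deepest member tip minus the age of the
#' focal node, i.e. the subtree's own time span) and `H_ratio`, the ratio of
#' tree height to clade height used to scale clade drift transforms.
#'
#' @param tree a `phylo` object.
#' @param node focal internal node: ape number or node label.
#' @return an object of class `clade_selection`: list with `node`,
#'   `node_label`, `tip_labels`, `tip_idx`, `element_idx` (tips + nodes,
#'   focal included), `clade_height`, `H_ratio`.
#' @export
clade_members <- function(tree, node) {
  tree <- validate_tree(tree)
  n_tip <- ape::Ntip(tree)
  if (is.character(node)) {
    idx <- match(node, element_labels(tree))
    if (is.na(idx)) stop("unknown element label '", node, "'")
    node <- idx
  }
  if (node <= n_tip) stop("focal element is a tip, not an internal node")
  elems <- descendant_elements(tree, node)
  tips <- elems[elems <= n_tip]
  if (length(tips) < 2L) stop("clade must subtend at least 2 tips")
  ages <- ape::node.depth.edgelength(tree)
  clade_height <- max(ages[tips]) - ages[node]
  if (clade_height <= 0) stop("clade height is zero")
  structure(list(
    node = node,
    node_label = element_labels(tree)[node],
    tip_labels = tree$tip.label[tips],
    tip_idx = tips,
    element_idx = elems,
    clade_height = clade_height,
    H_ratio = max(ages[seq_len(n_tip)]) / clade_height
  ), class = "clade_selection")
}

#' @export
print.clade_selection <- function(x, ...) {
  cat("Clade at node", x$node_label, "-", length(x$tip_labels), "tips,",
      "height", format(x$clade_height, digits = 4),
      "(H_ratio", format(x$H_ratio, digits = 4), ")\n")
  invisible(x)
}

#' Read / write a tip trait vector as CSV
#'
#' The on-disk format is a two-column CSV with header `tip,value`. Values are
#' returned as a named numeric vector; when `tree` is supplied the keys are
#' checked against (and ordered as) the tree's tip labels.
#'
#' @param file path to a CSV file.
#' @param tree optional `phylo` used to check and order the keys.
#' @return named numeric vector of tip values.
#' @export
read_trait_csv <- function(file, tree = NULL) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("tip", "value") %in% names(d))) stop("trait CSV must have columns 'tip' and 'value'")
  y <- stats::setNames(as.numeric(d$value), d$tip)
  if (!is.null(tree)) y <- match_trait(tree, y)
  y
}

#' @rdname read_trait_csv
#' @param y named numeric vector of tip values.
#' @export
write_trait_csv <- function(y, file) {
  utils::write.csv(data.frame(tip = names(y), value = unname(y)), file, row.names = FALSE)
  invisible(file)
}

# Check a trait vector against a tree and order it as tree$tip.label.
match_trait <- function(tree, y) {
  if (is.null(names(y))) stop("trait vector must be named by tip label")
  missing <- setdiff(tree$tip.label, names(y))
  if (length(missing)) stop("trait value missing for tip '", missing[1L], "'")
  extra <- setdiff(names(y), tree$tip.label)
  if (length(extra)) stop("trait key '", extra[1L], "' is not a tip of the tree")
  y <- y[tree$tip.label]
  if (any(!is.finite(y))) stop("non-finite trait value for tip '", names(y)[which(!is.finite(y))[1L]], "'")
  y
}
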