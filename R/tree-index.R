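# Internal flat-array view of a rooted phylo object.
#
# ape numbers tips 1..n and internal nodes (n+1)..(n+Nnode) with the root at
# n+1. All traversal-heavy code in the package works on this index rather
# than on the edge matrix directly.

.tree_index <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  root <- n_tip + 1L
  parent <- integer(n_all)
  blen <- numeric(n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (!is.null(phy$edge.length)) blen[phy$edge[, 2]] <- phy$edge.length
  children <- vector("list", n_all)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    children[[p]] <- c(children[[p]], phy$edge[e, 2])
  }
  # bottom-up order of internal nodes: in ape's postorder edge list every
  # edge below a node precedes that node's first appearance as a parent
  po_edge <- stats::setNames(ape::reorder.phylo(phy, "postorder")$edge, NULL)
  node_po <- unique(po_edge[, 1])
  # tips below each node
  n_desc <- integer(n_all)
  n_desc[seq_len(n_tip)] <- 1L
  for (v in node_po) n_desc[v] <- sum(n_desc[children[[v]]])
  # top-down order (root first)
  node_pre <- rev(node_po)
  list(
    n_tip = n_tip, n_all = n_all, root = root, parent = parent,
    blen = blen, children = children, node_po = node_po,
    node_pre = node_pre, n_desc = n_desc, tip_label = phy$tip.label
  )
}

# Order of all nodes (tips + internal) such that children precede parents.
.nodes_postorder <- function(ix) {
  c(seq_len(ix$n_tip), ix$node_po)
}

# Path of node ids from root down to (and including) `node`.
.root_path <- function(ix, node) {
  path <- integer(0)
  v <- node
  while (v != ix$root) {
    path <- c(v, path)
    v <- ix$parent[v]
  }
  c(ix$root, path)
}

# Resolve polytomies into caterpillars of zero-length branches and collapse
# single-child chains; used by every method that requires a binary tree.
.binarize <- function(phy) {
  phy <- ape::collapse.singles(phy)
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy, random = FALSE)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  phy
}
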