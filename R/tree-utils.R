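# Internal helpers on ape "phylo" objects. All node indices follow the ape
# convention: tips 1..Ntip, internals (Ntip+1)..(Ntip+Nnode).

.tree_root <- function(phy) {
  setdiff(unique(phy$edge[, 1]), phy$edge[, 2])[1]
}

.tree_children <- function(phy) {
  nn <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2])
  }
  ch
}

.tree_parents <- function(phy) {
  nn <- ape::Ntip(phy) + phy$Nnode
  par <- integer(nn)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

# All nodes in postorder (every child precedes its parent).
.postorder_nodes <- function(phy, children = .tree_children(phy)) {
  root <- .tree_root(phy)
  stack <- root
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  rev(out)
}

# Tip index sets per node, as integer vectors.
.clade_tips <- function(phy, children = .tree_children(phy),
                        postorder = .postorder_nodes(phy, children)) {
  nn <- ape::Ntip(phy) + phy$Nnode
  sets <- vector("list", nn)
  for (v in postorder) {
    if (v <= ape::Ntip(phy)) {
      sets[[v]] <- v
    } else {
      sets[[v]] <- sort(unlist(sets[children[[v]]], use.names = FALSE))
    }
  }
  sets
}

# Depth in edges from the root.
.node_depths <- function(phy, children = .tree_children(phy)) {
  nn <- ape::Ntip(phy) + phy$Nnode
  depth <- integer(nn)
  root <- .tree_root(phy)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      stack <- c(stack, c)
    }
  }
  depth
}

.lca_pair <- function(parents, depths, a, b) {
  while (depths[a] > depths[b]) a <- parents[a]
  while (depths[b] > depths[a]) b <- parents[b]
  while (a != b) {
    a <- parents[a]
    b <- parents[b]
  }
  a
}

.lca_set <- function(parents, depths, nodes) {
  Reduce(function(a, b) .lca_pair(parents, depths, a, b), nodes)
}

.is_binary_rooted <- function(phy) {
  ape::is.rooted(phy) && all(tabulate(phy$edge[, 1]) %in% c(0L, 2L))
}

# Deterministic sort key for a set of labels (used for rooting tie-breaks).
.labelset_key <- function(labels) {
  paste(sort(labels), collapse = "\x1f")
}
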