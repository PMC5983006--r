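#' Reconcile a gene tree against a species tree
#'
#' Maps every gene-tree node to the species tree by LCA mapping and
#' classifies each internal node as one gene event: speciation, duplication
#' or incongruence. Losses are quantified at duplication nodes only, as the
#' species-tree edge distance from the node's mapping to each child's
#' mapping.
#'
#' Classification rule at an internal node g with children mappings M(c):
#' if M(g) differs from both children's mappings the node is a speciation.
#' Otherwise (an apparent duplication, M(g) = M(c) for at least one child)
#' the species sets of the two child clades decide: an overlap proves two
#' gene copies co-existed in one species (true duplication); disjoint sets
#' admit an incongruence explanation (incomplete lineage sorting,
#' tree-estimation error, or selection) and are charged as a single
#' incongruence event with no losses.
#'
#' @param gtree Binary rooted gene tree ([ape::phylo]).
#' @param stree Species tree ([ape::phylo], topology only; polytomies
#'   allowed).
#' @param assignments Named character vector leaf label -> species label,
#'   or a `species_info` object (resolved against the gene-tree leaves).
#' @return An object of class `reconciliation`: per-node event labels
#'   (`$event`), loss counts (`$losses`), the gene-to-species node mapping
#'   (`$map`) and cumulative per-clade event counts (`$cum`, columns D, I,
#'   L), plus cached traversal structures used by the clustering phase.
#' @seealso [clade_event_counts()], [cluster_initial()]
#' @examples
#' g <- parse_newick("((a1:1,a2:1):1,b1:2);")
#' s <- parse_newick("(A,B);", topology_only = TRUE)
#' r <- reconcile(g, s, c(a1 = "A", a2 = "A", b1 = "B"))
#' r$event
#' @export
reconcile <- function(gtree, stree, assignments) {
  if (inherits(assignments, "species_info")) {
    assignments <- resolve_assignments(assignments, gtree$tip.label)
  }
  if (!.is_binary_rooted(gtree)) {
    stop("gene tree must be rooted and binary; see root_gene_tree()")
  }
  ntip <- ape::Ntip(gtree)
  miss <- setdiff(gtree$tip.label, names(assignments))
  if (length(miss)) stop("unassigned gene-tree leaf: ", miss[1])
  sp <- assignments[gtree$tip.label]
  bad <- setdiff(unique(sp), stree$tip.label)
  if (length(bad)) stop("species '", bad[1], "' is absent from the species tree")

  g_children <- .tree_children(gtree)
  g_post <- .postorder_nodes(gtree, g_children)
  g_tips <- .clade_tips(gtree, g_children, g_post)
  s_children <- .tree_children(stree)
  s_parents <- .tree_parents(stree)
  s_depths <- .node_depths(stree, s_children)
  sp_tip <- match(sp, stree$tip.label)  # species-tip index per gene tip

  nn <- ntip + gtree$Nnode
  map <- integer(nn)
  event <- character(nn)
  losses <- integer(nn)
  cum <- matrix(0L, nn, 3L, dimnames = list(NULL, c("D", "I", "L")))

  for (v in g_post) {
    if (v <= ntip) {
      map[v] <- sp_tip[v]
      event[v] <- "leaf"
      next
    }
    ch <- g_children[[v]]
    map[v] <- .lca_set(s_parents, s_depths, map[ch])
    sets <- lapply(ch, function(c) unique(sp_tip[g_tips[[c]]]))
    if (map[v] != map[ch[1]] && map[v] != map[ch[2]]) {
      event[v] <- "speciation"
    } else if (length(intersect(sets[[1]], sets[[2]]))) {
      event[v] <- "duplication"
      losses[v] <- sum(s_depths[map[ch]] - s_depths[map[v]])
    } else {
      event[v] <- "incongruence"
    }
    cum[v, ] <- cum[ch[1], ] + cum[ch[2], ] +
      c(event[v] == "duplication", event[v] == "incongruence", losses[v])
  }

  structure(list(gtree = gtree, stree = stree, assignments = sp,
                 map = map, event = event, losses = losses, cum = cum,
                 children = g_children, postorder = g_post,
                 clade_tips = g_tips, root = .tree_root(gtree)),
            class = "reconciliation")
}

#' Event counts in the clade rooted at a gene-tree node
#'
#' Sums duplication, incongruence and loss events over all internal nodes
#' of the clade rooted at `node`, including `node` itself; leaves
#' contribute nothing.
#'
#' @param rec A `reconciliation` object.
#' @param node Gene-tree node index (ape convention).
#' @return Named integer vector `c(D =, I =, L =)`.
#' @export
clade_event_counts <- function(rec, node) {
  stopifnot(inherits(rec, "reconciliation"))
  n <- ape::Ntip(rec$gtree) + rec$gtree$Nnode
  if (node < 1L || node > n) stop("node index out of range")
  c(D = unname(rec$cum[node, "D"]), I = unname(rec$cum[node, "I"]),
    L = unname(rec$cum[node, "L"]))
}

#' @export
print.reconciliation <- function(x, ...) {
  tot <- x$cum[x$root, ]
  cat("Reconciliation:", ape::Ntip(x$gtree), "genes,",
      ape::Ntip(x$stree), "species\n")
  cat("  events: D =", tot["D"], " I =", tot["I"], " L =", tot["L"], "\n")
  invisible(x)
}
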