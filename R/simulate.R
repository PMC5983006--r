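#' Simulate a gene family evolving along a species tree
#'
#' A single ancestral gene descends the species tree. On each species
#' branch every incoming gene copy duplicates once with probability
#' `dup_rate` (recorded as a D event) and every resulting copy is then lost
#' with probability `loss_rate` (recorded as an L event). At species-tree
#' internal nodes each surviving copy speciates into both child branches.
#' After the tree is built, each surviving speciation node is, with
#' probability `incong_rate`, turned into an incongruence by a
#' nearest-neighbour-interchange move that swaps one of its children with
#' the node's sibling — regrafting that lineage next to its species-tree
#' "uncle", the topological signature of incomplete lineage sorting — and
#' is relabelled I. Branch lengths are drawn from log-normal distributions
#' (terminal edges meanlog log(0.1), sdlog 0.3; internal edges meanlog
#' log(0.05), sdlog 0.2). Leaves are named `<species>_<index>`.
#'
#' If every lineage dies the simulation is retried (up to `max_tries`
#' times, consuming further random draws); with the same `seed` and rates
#' the output is bit-reproducible.
#'
#' Duplication rates may vary across the species tree: pass a named vector
#' whose names are species-tree tip (or internal node) labels; the rate of
#' an edge is looked up by its child's label, falling back to the
#' `".default"` entry (or 0).
#'
#' @param stree Binary rooted species tree ([ape::phylo]).
#' @param dup_rate Per-branch duplication probability in \[0, 1), scalar or
#'   named vector (see Details).
#' @param loss_rate Per-branch, per-copy loss probability in \[0, 1).
#' @param incong_rate Per-speciation-node incongruence probability in
#'   \[0, 1).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param max_tries Retries before giving up when the family goes extinct.
#' @return A list: `$gtree` (gene tree, node labels carry the true event
#'   codes S/D/I), `$assignments` (named vector leaf -> species), `$truth`
#'   (class `sim_truth`: `$totals` with D and I counted from the surviving
#'   tree's labels and L the number of loss events, `$per_node` data.frame
#'   of node/event, raw event counters `$simulated`, the seed and rates).
#' @export
simulate_family <- function(stree, dup_rate = 0.2, loss_rate = 0.1,
                            incong_rate = 0.05, seed = NULL, max_tries = 100L) {
  stopifnot(.is_binary_rooted(stree))
  .check_rate <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x >= 1)) {
      stop("'", nm, "' must be in [0, 1)")
    }
  }
  .check_rate(dup_rate, "dup_rate")
  .check_rate(loss_rate, "loss_rate")
  .check_rate(incong_rate, "incong_rate")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }

  labels_for <- function(phy) {
    labs <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label)
    labs
  }
  rate_of <- function(child_label) {
    if (length(dup_rate) == 1L && is.null(names(dup_rate))) return(unname(dup_rate))
    if (!is.null(child_label) && nzchar(child_label) && child_label %in% names(dup_rate)) {
      return(unname(dup_rate[child_label]))
    }
    if (".default" %in% names(dup_rate)) unname(dup_rate[".default"]) else 0
  }

  s_children <- .tree_children(stree)
  s_labels <- labels_for(stree)
  s_root <- .tree_root(stree)
  ntip_s <- ape::Ntip(stree)

  for (try in seq_len(max_tries)) {
    env <- new.env()
    env$D <- 0L
    env$I <- 0L
    env$L <- 0L
    env$leafn <- integer(ntip_s)

    at_node <- function(s) {
      if (s <= ntip_s) {
        env$leafn[s] <- env$leafn[s] + 1L
        return(list(leaf = TRUE,
                    label = paste0(stree$tip.label[s], "_", env$leafn[s]),
                    species = stree$tip.label[s]))
      }
      ch <- s_children[[s]]
      subs <- c(down_edge(ch[1]), down_edge(ch[2]))
      if (length(subs) == 0L) return(NULL)
      if (length(subs) == 1L) return(subs[[1]])
      list(leaf = FALSE, event = "S", children = subs)
    }
    # Evolve one copy down the edge into species node s; returns a list of
    # 0 or 1 surviving subtrees (a duplication's survivors join under one
    # D node).
    down_edge <- function(s) {
      ncopies <- 1L
      if (stats::runif(1) < rate_of(s_labels[s])) {
        env$D <- env$D + 1L
        ncopies <- 2L
      }
      subs <- list()
      for (k in seq_len(ncopies)) {
        if (stats::runif(1) < loss_rate) {
          env$L <- env$L + 1L
        } else {
          sub <- at_node(s)
          if (!is.null(sub)) subs <- c(subs, list(sub))
        }
      }
      if (length(subs) == 2L) {
        list(list(leaf = FALSE, event = "D", children = subs))
      } else {
        subs
      }
    }

    top <- at_node(s_root)
    if (is.null(top) || isTRUE(top$leaf)) next  # extinct or single survivor

    phy <- .sim_to_phylo(top)
    phy <- .apply_incongruence(phy, incong_rate, env)
    ne <- nrow(phy$edge)
    terminal <- phy$edge[, 2] <= ape::Ntip(phy)
    len <- numeric(ne)
    len[terminal] <- stats::rlnorm(sum(terminal), meanlog = log(0.1), sdlog = 0.3)
    len[!terminal] <- stats::rlnorm(sum(!terminal), meanlog = log(0.05), sdlog = 0.2)
    phy$edge.length <- len

    assignments <- stats::setNames(sub("_[0-9]+$", "", phy$tip.label), phy$tip.label)
    per_node <- data.frame(node = seq_len(ape::Ntip(phy) + phy$Nnode),
                           event = c(rep("leaf", ape::Ntip(phy)), phy$node.label),
                           stringsAsFactors = FALSE)
    totals <- c(D = sum(phy$node.label == "D"),
                I = sum(phy$node.label == "I"),
                L = env$L)
    truth <- structure(list(totals = totals, per_node = per_node,
                            simulated = c(D = env$D, I = env$I, L = env$L),
                            seed = seed,
                            rates = list(dup_rate = dup_rate,
                                         loss_rate = loss_rate,
                                         incong_rate = incong_rate)),
                       class = "sim_truth")
    return(list(gtree = phy, assignments = assignments, truth = truth))
  }
  stop("gene family went extinct in all ", max_tries, " simulation attempts")
}

# Nested-list simulation record -> phylo with event codes as node labels.
.sim_to_phylo <- function(rec) {
  as_newick <- function(x) {
    if (isTRUE(x$leaf)) return(x$label)
    paste0("(", paste(vapply(x$children, as_newick, character(1)), collapse = ","),
           ")", x$event)
  }
  ape::read.tree(text = paste0(as_newick(rec), ";"))
}

# NNI moves at surviving speciation nodes: with probability incong_rate,
# swap one child of the node with the node's sibling and relabel the node
# "I". Nodes are visited in increasing index order for determinism.
.apply_incongruence <- function(phy, incong_rate, env) {
  ntip <- ape::Ntip(phy)
  if (incong_rate <= 0 || phy$Nnode < 2L) return(phy)
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    if (phy$node.label[v - ntip] != "S") next
    parents <- .tree_parents(phy)
    if (parents[v] == 0L) next  # root has no sibling
    if (stats::runif(1) >= incong_rate) next
    p <- parents[v]
    sib <- setdiff(phy$edge[phy$edge[, 1] == p, 2], v)
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    child <- if (stats::runif(1) < 0.5) kids[1] else kids[2]
    i_sib <- which(phy$edge[, 1] == p & phy$edge[, 2] == sib)
    i_child <- which(phy$edge[, 1] == v & phy$edge[, 2] == child)
    phy$edge[i_sib, 2] <- child
    phy$edge[i_child, 2] <- sib
    phy$node.label[v - ntip] <- "I"
    env$I <- env$I + 1L
  }
  # the swaps invalidate the cached edge ordering; force a rebuild
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a simulated family to disk
#'
#' Writes `<prefix>.nwk` (gene tree), `<prefix>.info.txt` (species tree +
#' assignments) and `<prefix>.truth.csv` (per-node true events plus a
#' totals row).
#'
#' @param sim Result of [simulate_family()].
#' @param stree The species tree the family was simulated along.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_simulated_family <- function(sim, stree, prefix) {
  nwk <- paste0(prefix, ".nwk")
  info <- paste0(prefix, ".info.txt")
  truth <- paste0(prefix, ".truth.csv")
  ape::write.tree(sim$gtree, file = nwk)
  write_info_file(stree, sim$assignments, info)
  tot <- sim$truth$totals
  lines <- c("node,event",
             paste(sim$truth$per_node$node, sim$truth$per_node$event, sep = ","),
             paste0("totals,D=", tot["D"], ";I=", tot["I"], ";L=", tot["L"]))
  writeLines(lines, truth)
  invisible(c(nwk, info, truth))
}
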