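# Brute-force oracles, independent of the dynamic program and of the
# package's U-statistic implementation.

# All clade partitions of the gene tree, as lists of MIG root nodes.
enumerate_clade_partitions <- function(rec) {
  ntip <- ape::Ntip(rec$gtree)
  memo <- vector("list", length(rec$event))
  go <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    res <- if (v <= ntip) {
      list(v)
    } else {
      ch <- rec$children[[v]]
      left <- go(ch[1]); right <- go(ch[2])
      parts <- list(v)  # the whole clade as one MIG
      for (l in left) for (r in right) parts[[length(parts) + 1]] <- c(l, r)
      parts
    }
    memo[[v]] <<- res
    res
  }
  go(rec$root)
}

# Objective of a clade partition: weighted event costs of each MIG, plus a
# duplication-weight surcharge per extra MIG, plus (phase 2) the weighted
# relative spread of each non-singleton MIG under a fixed sigma_bar.
partition_objective <- function(rec, roots, w, sigma_bar = NULL, embedding = NULL) {
  ec <- sum(rec$cum[roots, "D"] * w$dup + rec$cum[roots, "I"] * w$incongruence +
              rec$cum[roots, "L"] * w$loss)
  obj <- ec + w$dup * (length(roots) - 1)
  if (!is.null(sigma_bar) && !is.na(sigma_bar)) {
    labs <- rec$gtree$tip.label
    for (v in roots) {
      mem <- labs[rec$clade_tips[[v]]]
      if (length(mem) >= 2) {
        obj <- obj + w$spread * (mig_sigma(embedding, mem) / sigma_bar - 1)
      }
    }
  }
  obj
}

# Exact one-tailed Mann-Whitney p by literal enumeration of all
# choose(n1+n2, n1) group relabellings (tiny n only).
mw_exact_enum <- function(xs, ys, alternative) {
  pooled <- c(xs, ys)
  n1 <- length(xs)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(xs, ys)
  subsets <- utils::combn(length(pooled), n1)
  us <- apply(subsets, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  if (alternative == "less") mean(us <= obs + 1e-9) else mean(us >= obs - 1e-9)
}

# Patristic-matrix spread via the pairwise identity (no embedding).
sigma_from_distances <- function(D, members) {
  d <- D[members, members, drop = FALSE]
  sqrt(sum(d^2) / (2 * length(members)^2))
}
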