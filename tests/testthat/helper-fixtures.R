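# Shared fixture builders. Species are uppercase letters; gene leaves are
# "<lowercase species letter><copy index>", e.g. a1, a2 belong to species A.

auto_amap <- function(labels) {
  stats::setNames(toupper(sub("[0-9]+$", "", labels)), labels)
}

make_rec <- function(gene_nwk, sp_nwk, amap = NULL) {
  g <- parse_newick(gene_nwk)
  s <- parse_newick(sp_nwk, topology_only = TRUE)
  if (is.null(amap)) amap <- auto_amap(g$tip.label)
  reconcile(g, s, amap)
}

# A reproducible batch of simulated families (varied rates) on a fixed
# 6-species tree, used by oracle-equivalence and partition-validity tests.
sim_stree6 <- function() {
  parse_newick("(((A,B),C),((D,E),F));", topology_only = TRUE)
}

sim_batch <- function(n, seed0 = 1000, stree = sim_stree6(),
                      max_tips = Inf) {
  out <- list()
  s <- seed0
  while (length(out) < n) {
    s <- s + 1
    rates <- list(dup = c(0, 0.15, 0.35)[(s %% 3) + 1],
                  loss = c(0, 0.1, 0.25)[(s %% 4) %% 3 + 1],
                  inc = c(0, 0.1, 0.3)[(s %% 5) %% 3 + 1])
    sim <- simulate_family(stree, dup_rate = rates$dup, loss_rate = rates$loss,
                           incong_rate = rates$inc, seed = s)
    if (ape::Ntip(sim$gtree) > max_tips) next
    out[[length(out) + 1]] <- sim
  }
  out
}
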