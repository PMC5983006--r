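test_that("score_mig is the weighted linear form", {
  w <- instability_weights()
  expect_equal(score_mig(c(D = 0, I = 0, L = 0), 0, w), 0)
  expect_equal(score_mig(c(D = 2, I = 1, L = 1), 0.5, w), 4)
  expect_equal(score_mig(c(D = 0, I = 1, L = 0), 0, w), 0.5)
  expect_error(instability_weights(dup = 0), "strictly positive")
  expect_error(instability_weights(loss = -1), "non-negative")
})

test_that("phase-1 clustering matches hand-worked small cases", {
  # congruent: one MIG at objective 0
  rec <- make_rec("((a1:1,b1:1):1,c1:1);", "((A,B),C);")
  p <- cluster_initial(rec)
  expect_equal(nrow(p$migs), 1)
  expect_equal(p$objective, 0)

  # extra copy of A outside the cherry: split beats merge (cost 2 vs 1)
  rec2 <- make_rec("((a1:1,b1:1):1,a2:1);", "((A,B),C);")
  p2 <- cluster_initial(rec2)
  expect_equal(p2$objective, 1)
  expect_setequal(lapply(p2$members, sort), list(c("a1", "b1"), "a2"))

  # incongruent cherry: merging at cost theta_I = 0.5 beats splitting
  rec3 <- make_rec("((a1:1,c1:1):1,b1:1);", "((A,B),C);")
  p3 <- cluster_initial(rec3)
  expect_equal(nrow(p3$migs), 1)
  expect_equal(p3$objective, 0.5)
  expect_equal(p3$migs[, c("D", "I", "L")], data.frame(D = 0L, I = 1L, L = 0L),
               ignore_attr = TRUE)
})

test_that("phase-1 partitions attain the brute-force optimum", {
  w <- instability_weights()
  for (sim in sim_batch(40, seed0 = 2000, max_tips = 12)) {
    rec <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
    p <- cluster_initial(rec, w)
    objs <- vapply(enumerate_clade_partitions(rec), partition_objective,
                   numeric(1), rec = rec, w = w)
    expect_equal(p$objective, min(objs))
    expect_equal(partition_objective(rec, p$migs$root, w), p$objective)
  }
})

test_that("refinement attains the brute-force optimum under fixed sigma_bar", {
  w <- instability_weights()
  for (sim in sim_batch(25, seed0 = 3000, max_tips = 12)) {
    rec <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
    emb <- embed_tree(sim$gtree)
    p1 <- cluster_initial(rec, w)
    p2 <- cluster_refine(rec, p1, emb, w)
    sb <- p2$sigma_bar
    objs <- vapply(enumerate_clade_partitions(rec), partition_objective,
                   numeric(1), rec = rec, w = w, sigma_bar = sb, embedding = emb)
    expect_equal(p2$objective, min(objs), tolerance = 1e-9)
    expect_equal(partition_objective(rec, p2$migs$root, w, sb, emb),
                 p2$objective, tolerance = 1e-9)
  }
})

test_that("refinement with zero spread weight reproduces phase 1", {
  w0 <- instability_weights(spread = 0)
  for (sim in sim_batch(10, seed0 = 4000)) {
    rec <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
    emb <- embed_tree(sim$gtree)
    p1 <- cluster_initial(rec, w0)
    p2 <- cluster_refine(rec, p1, emb, w0)
    expect_equal(p2$migs$root, p1$migs$root)
  }
  # a lone congruent MIG is its own median: refinement cannot split it
  rec <- make_rec("((a1:1,b1:1):1,c1:1);", "((A,B),C);")
  emb <- embed_tree(rec$gtree)
  p1 <- cluster_initial(rec)
  p2 <- cluster_refine(rec, p1, emb)
  expect_equal(nrow(p2$migs), 1)
})

test_that("an extreme long-branch ortholog is split out only when spread counts", {
  # congruent 6-species family; f1 sits on a branch 20x longer than the rest
  nwk <- "(((a1:0.1,b1:0.1):0.1,c1:0.1):0.1,((d1:0.1,e1:0.1):0.1,f1:2.0):0.1);"
  rec <- make_rec(nwk, "(((A,B),C),((D,E),F));")
  emb <- embed_tree(rec$gtree)
  p1 <- cluster_initial(rec)
  expect_equal(nrow(p1$migs), 1)  # no events: phase 1 merges everything

  absorbed <- cluster_refine(rec, p1, emb, instability_weights(spread = 0))
  expect_equal(nrow(absorbed$migs), 1)

  w_hi <- instability_weights(spread = 50)
  split <- cluster_refine(rec, p1, emb, w_hi)
  expect_true(list("f1") %in% lapply(split$members, sort))
  # and the split partition is the brute-force optimum for that weighting
  objs <- vapply(enumerate_clade_partitions(rec), partition_objective,
                 numeric(1), rec = rec, w = w_hi,
                 sigma_bar = split$sigma_bar, embedding = emb)
  expect_equal(split$objective, min(objs), tolerance = 1e-9)
})

test_that("ties between merge and remain resolve by merging", {
  # (a1,a2) vs (A,B): merging (one duplication, cost theta_D) exactly ties
  # remaining as two singletons (surcharge theta_D); merge must win
  rec <- make_rec("(a1:1,a2:1);", "(A,B);")
  p <- cluster_initial(rec)
  expect_equal(nrow(p$migs), 1)
  expect_equal(p$objective, 1)
  expect_setequal(p$members[[1]], c("a1", "a2"))
})

test_that("final scores recompute sigma_bar and share scores within MIGs", {
  # single merged MIG with one duplication: score 1, P = 0 (lone MIG)
  rec <- make_rec("(((a1:1,a2:1):1,b1:1):1,c1:1);", "((A,B),C);")
  emb <- embed_tree(rec$gtree)
  res <- finalize_scores(rec, cluster_initial(rec), emb)
  expect_equal(nrow(res$migs), 1)
  expect_equal(res$migs$score, 1)
  expect_equal(unique(res$scores$score), 1)

  # engineered Euclidean tree: two event-free MIGs with sigma 2 and 8
  # give sigma_bar = 5 and spread-only scores -0.6 and +0.6
  g <- parse_newick("((x1:2,x2:2):1,(y1:8,y2:8):1);")
  s <- parse_newick("((X1,X2),(Y1,Y2));", topology_only = TRUE)
  amap <- c(x1 = "X1", x2 = "X2", y1 = "Y1", y2 = "Y2")
  rec2 <- reconcile(g, s, amap)
  expect_equal(sum(rec2$cum[rec2$root, ]), 0)  # congruent, event-free
  roots <- vapply(list(c("x1", "x2"), c("y1", "y2")), function(m) {
    which(vapply(seq_along(rec2$event), function(v) {
      setequal(g$tip.label[rec2$clade_tips[[v]]], m)
    }, logical(1)))
  }, integer(1))
  part <- phyloinstab:::.partition_from_roots(rec2, roots)
  emb2 <- embed_tree(g)
  res2 <- finalize_scores(rec2, part, emb2)
  expect_equal(res2$sigma_bar, 5, tolerance = 1e-9)
  expect_equal(sort(res2$migs$score), c(-0.6, 0.6), tolerance = 1e-9)

  # every member of a MIG carries the identical score
  for (sim in sim_batch(5, seed0 = 5000)) {
    rec3 <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
    p <- cluster_initial(rec3)
    emb3 <- embed_tree(sim$gtree)
    res3 <- finalize_scores(rec3, cluster_refine(rec3, p, emb3), emb3)
    per <- tapply(res3$scores$score, res3$scores$cluster, function(x) length(unique(x)))
    expect_true(all(per == 1))
    expect_setequal(res3$scores$sequence, sim$gtree$tip.label)
  }
})

test_that("scaling all weights scales scores but not partitions", {
  for (cc in c(0.5, 3)) {
    for (sim in sim_batch(6, seed0 = 6000)) {
      rec <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
      emb <- embed_tree(sim$gtree)
      w1 <- instability_weights()
      wc <- instability_weights(dup = cc, loss = cc, incongruence = 0.5 * cc,
                                spread = cc)
      r1 <- finalize_scores(rec, cluster_refine(rec, cluster_initial(rec, w1), emb, w1), emb, w1)
      rc <- finalize_scores(rec, cluster_refine(rec, cluster_initial(rec, wc), emb, wc), emb, wc)
      expect_equal(rc$migs$id, r1$migs$id)
      expect_equal(rc$migs$size, r1$migs$size)
      expect_equal(rc$migs$score, cc * r1$migs$score, tolerance = 1e-9)
    }
  }
})

test_that("partitions are always disjoint clades covering all leaves", {
  for (sim in sim_batch(12, seed0 = 7000)) {
    rec <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
    emb <- embed_tree(sim$gtree)
    p <- cluster_refine(rec, cluster_initial(rec), emb)
    all_members <- unlist(p$members)
    expect_equal(sort(all_members), sort(sim$gtree$tip.label))
    expect_equal(anyDuplicated(all_members), 0)
    expect_equal(p$migs$id, seq_len(nrow(p$migs)))
    # ids follow post-order of the MIG roots
    expect_equal(p$migs$root,
                 intersect(rec$postorder, p$migs$root))
  }
})

test_that("event-cost component is monotone in each single weight", {
  sim <- sim_batch(1, seed0 = 8000)[[1]]
  rec <- reconcile(sim$gtree, sim_stree6(), sim$assignments)
  p <- cluster_initial(rec)
  base <- instability_weights()
  cost <- function(w) {
    w$dup * p$migs$D + w$incongruence * p$migs$I + w$loss * p$migs$L
  }
  for (f in c("dup", "loss", "incongruence")) {
    w2 <- base
    w2[[f]] <- w2[[f]] + 1
    expect_true(all(cost(w2) >= cost(base)))
  }
})
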