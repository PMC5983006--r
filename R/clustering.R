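#' Event and spread weights
#'
#' The four strictly documented weights of the instability score:
#' duplication, loss, incongruence and spread. Defaults are (1, 1, 0.5, 1)
#' for duplications, loss, incongruence and spread respectively.
#'
#' @param dup Weight of a duplication event (theta_D, must be > 0).
#' @param loss Weight of a loss event (theta_L, >= 0).
#' @param incongruence Weight of an incongruence event (theta_I, >= 0).
#' @param spread Weight of the relative-spread term (theta_P, >= 0).
#' @return An `instability_weights` object.
#' @export
instability_weights <- function(dup = 1, loss = 1, incongruence = 0.5, spread = 1) {
  w <- c(dup = dup, loss = loss, incongruence = incongruence, spread = spread)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be non-negative and finite")
  if (w["dup"] <= 0) stop("the duplication weight must be strictly positive")
  structure(as.list(w), class = "instability_weights")
}

#' Instability score of one MIG
#'
#' `score = theta_D * D + theta_I * I + theta_L * L + theta_P * P`: the
#' weighted count of duplication, incongruence and loss events at or below
#' the MIG's root, plus the weighted relative spread. Interpretable as the
#' incongruence experienced by the cluster throughout its history.
#'
#' @param counts Named vector with elements D, I, L (see
#'   [clade_event_counts()]).
#' @param P Relative spread of the MIG.
#' @param weights An [instability_weights()] object.
#' @return Numeric score (may be negative for tight, event-free MIGs).
#' @export
score_mig <- function(counts, P = 0, weights = instability_weights()) {
  stopifnot(inherits(weights, "instability_weights"))
  unname(weights$dup * counts[["D"]] + weights$incongruence * counts[["I"]] +
           weights$loss * counts[["L"]] + weights$spread * P)
}

# Weighted event cost of every clade (vector over nodes).
.event_costs <- function(rec, weights) {
  rec$cum[, "D"] * weights$dup + rec$cum[, "I"] * weights$incongruence +
    rec$cum[, "L"] * weights$loss
}

# Post-order merge-vs-remain dynamic program. merge_cost is a per-node
# vector giving the cost of making that clade a single MIG; the remain
# option costs the children's optima plus one duplication weight (each
# extra MIG posits an extra ancestral locus). Ties merge.
.cluster_dp <- function(rec, merge_cost, weights) {
  ntip <- ape::Ntip(rec$gtree)
  nn <- length(rec$event)
  obj <- numeric(nn)
  merged <- logical(nn)
  for (v in rec$postorder) {
    if (v <= ntip) {
      obj[v] <- 0
      merged[v] <- TRUE
      next
    }
    ch <- rec$children[[v]]
    m <- merge_cost[v]
    r <- obj[ch[1]] + obj[ch[2]] + weights$dup
    if (m <= r) {
      obj[v] <- m
      merged[v] <- TRUE
    } else {
      obj[v] <- r
      merged[v] <- FALSE
    }
  }
  roots <- integer(0)
  stack <- rec$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (merged[v]) roots <- c(roots, v) else stack <- c(stack, rec$children[[v]])
  }
  list(objective = obj[rec$root], roots = roots)
}

# Build a mig_partition object from a set of MIG root nodes.
.partition_from_roots <- function(rec, roots, objective = NA_real_,
                                  phase = NA_integer_, sigma_bar = NA_real_) {
  pos <- match(roots, rec$postorder)
  roots <- roots[order(pos)]  # ids are consecutive in post-order of roots
  labs <- rec$gtree$tip.label
  members <- lapply(roots, function(v) labs[rec$clade_tips[[v]]])
  covered <- sort(unlist(lapply(roots, function(v) rec$clade_tips[[v]])))
  if (!identical(covered, seq_len(ape::Ntip(rec$gtree)))) {
    stop("internal error: MIGs do not partition the leaves")
  }
  counts <- t(vapply(roots, function(v) rec$cum[v, ], numeric(3)))
  migs <- data.frame(id = seq_along(roots), root = roots,
                     size = lengths(members),
                     D = as.integer(counts[, "D"]),
                     I = as.integer(counts[, "I"]),
                     L = as.integer(counts[, "L"]))
  structure(list(migs = migs, members = members, objective = objective,
                 phase = phase, sigma_bar = sigma_bar),
            class = "mig_partition")
}

#' Initial (event-parsimony) clustering into MIGs
#'
#' Phase 1 of the clustering procedure. Every node is visited in depth-first
#' post-order; at each internal node the cost of merging the whole clade
#' into one MIG (its weighted event cost) is compared with letting the
#' children's MIG patterns remain (their optima plus one duplication weight
#' for the extra inferred ancestral locus). The spread term is held at 0 in
#' this phase. The returned partition attains the global minimum of
#' `sum_MIG eventcost(MIG) + theta_D * (#MIGs - 1)` over all clade
#' partitions; ties are resolved by merging.
#'
#' @param rec A `reconciliation` object.
#' @param weights An [instability_weights()] object.
#' @return A `mig_partition`: per-MIG roots, members and event counts, plus
#'   the achieved objective value.
#' @export
cluster_initial <- function(rec, weights = instability_weights()) {
  stopifnot(inherits(rec, "reconciliation"), inherits(weights, "instability_weights"))
  dp <- .cluster_dp(rec, .event_costs(rec, weights), weights)
  .partition_from_roots(rec, dp$roots, dp$objective, phase = 1L)
}

#' Refine a MIG partition using branch-length spread
#'
#' Phase 2 repeats the merge-vs-remain dynamic program with the full score
#' function: each candidate MIG's merge cost gains `theta_P * P(clade)`,
#' where the relative spread P uses the median spread `sigma_bar` computed
#' once from the phase-1 partition and held fixed (singleton clades have
#' P = 0; if no non-singleton phase-1 MIG exists, or the median spread is
#' zero, the spread term is inert and the phase-1 partition is returned by
#' construction).
#'
#' @param rec A `reconciliation` object.
#' @param partition Phase-1 `mig_partition` from [cluster_initial()].
#' @param embedding A `tree_embedding` from [embed_tree()].
#' @param weights An [instability_weights()] object.
#' @return A refined `mig_partition` (phase 2), carrying the fixed
#'   `sigma_bar` used.
#' @export
cluster_refine <- function(rec, partition, embedding,
                           weights = instability_weights()) {
  stopifnot(inherits(rec, "reconciliation"), inherits(partition, "mig_partition"),
            inherits(embedding, "tree_embedding"))
  sig <- .clade_sigmas(rec, embedding)
  sizes <- lengths(rec$clade_tips)
  sigma_bar <- .median_sigma(sig[partition$migs$root], partition$migs$size)
  P <- rep(0, length(sig))
  if (!is.na(sigma_bar)) {
    big <- sizes >= 2L
    P[big] <- relative_spread(sig[big], sigma_bar)
  }
  dp <- .cluster_dp(rec, .event_costs(rec, weights) + weights$spread * P, weights)
  .partition_from_roots(rec, dp$roots, dp$objective, phase = 2L,
                        sigma_bar = if (is.na(sigma_bar)) NA_real_ else sigma_bar)
}

#' Final per-gene instability scores
#'
#' Recomputes the median spread from the final partition, scores every MIG
#' with the full score function and assigns each member sequence its MIG's
#' score. MIG identifiers are consecutive integers in post-order of the MIG
#' roots. Scores are not floored at zero: a tight, event-free MIG can score
#' negatively.
#'
#' @param rec A `reconciliation` object.
#' @param partition The final `mig_partition`.
#' @param embedding A `tree_embedding` from [embed_tree()].
#' @param weights An [instability_weights()] object.
#' @return An `instability_scores` object: `$scores` (data.frame sequence,
#'   species, cluster, score — one row per leaf), `$migs` (per-MIG summary:
#'   id, size, D, I, L, sigma, P, score) and `$sigma_bar`.
#' @export
finalize_scores <- function(rec, partition, embedding,
                            weights = instability_weights()) {
  stopifnot(inherits(rec, "reconciliation"), inherits(partition, "mig_partition"),
            inherits(embedding, "tree_embedding"))
  migs <- partition$migs
  sigma <- vapply(seq_len(nrow(migs)), function(i) {
    mig_sigma(embedding, partition$members[[i]])
  }, numeric(1))
  sigma_bar <- .median_sigma(sigma, migs$size)
  P <- rep(0, nrow(migs))
  if (!is.na(sigma_bar)) {
    big <- migs$size >= 2L
    P[big] <- relative_spread(sigma[big], sigma_bar)
  }
  score <- weights$dup * migs$D + weights$incongruence * migs$I +
    weights$loss * migs$L + weights$spread * P
  migs$sigma <- sigma
  migs$P <- P
  migs$score <- score
  rows <- do.call(rbind, lapply(seq_len(nrow(migs)), function(i) {
    mem <- partition$members[[i]]
    data.frame(sequence = mem, species = unname(rec$assignments[mem]),
               cluster = migs$id[i], score = score[i],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(list(scores = rows,
                 migs = migs[, c("id", "size", "D", "I", "L", "sigma", "P", "score")],
                 sigma_bar = if (is.na(sigma_bar)) NA_real_ else sigma_bar),
            class = "instability_scores")
}

#' @export
print.mig_partition <- function(x, ...) {
  cat("MIG partition (phase ", x$phase, "): ", nrow(x$migs), " MIGs over ",
      sum(x$migs$size), " sequences; objective = ",
      format(x$objective), "\n", sep = "")
  invisible(x)
}

#' @export
print.instability_scores <- function(x, ...) {
  cat("Instability scores: ", nrow(x$scores), " sequences in ",
      nrow(x$migs), " MIGs; score range [",
      format(min(x$migs$score)), ", ", format(max(x$migs$score)), "]\n", sep = "")
  invisible(x)
}
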