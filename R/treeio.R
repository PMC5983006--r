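#' Parse a Newick string into a tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Gene trees keep their
#' branch lengths; species trees are parsed with `topology_only = TRUE`,
#' which drops any branch lengths and permits polytomies.
#'
#' @param text A Newick string terminated by `;`.
#' @param topology_only Drop branch lengths after parsing (species trees
#'   carry topology only).
#' @return An [ape::phylo] object. Leaf labels are preserved verbatim;
#'   internal labels (e.g. bootstrap values) are retained in `node.label`
#'   but unused downstream. Missing branch lengths on a gene tree default
#'   to 0 with a warning.
#' @examples
#' parse_newick("((a1:0.1,b1:0.2):0.05,c1:0.3);")
#' parse_newick("((A,B,C),D);", topology_only = TRUE)
#' @export
parse_newick <- function(text, topology_only = FALSE) {
  .check_newick_text(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("failed to parse Newick string")
  if (ape::Ntip(phy) < 2L) stop("tree must have at least 2 leaves")
  labs <- phy$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label in tree")
  if (anyDuplicated(labs)) {
    stop("duplicate leaf label: ", labs[duplicated(labs)][1])
  }
  if (topology_only) {
    phy$edge.length <- NULL
  } else if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  } else {
    if (any(is.na(phy$edge.length))) {
      warning("missing branch lengths; defaulting to 0")
      phy$edge.length[is.na(phy$edge.length)] <- 0
    }
    if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  }
  phy
}

# Pre-scan for structural errors so that parse failures carry a character
# offset, which ape::read.tree does not report.
.check_newick_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty Newick string")
  if (substr(txt, nchar(txt), nchar(txt)) != ";") {
    stop("Newick string must end in ';' (offset ", nchar(txt), ")")
  }
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at offset ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(' (", depth, " unclosed) at offset ", nchar(txt))
  invisible(TRUE)
}

#' Read a gene tree from a Newick file
#'
#' @param file Path to a Newick file containing a single gene-family tree.
#' @return An [ape::phylo] gene tree (branch lengths retained).
#' @export
read_gene_tree <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = "\n"))
}

#' Read a species-information file
#'
#' The information file holds the species tree (topology only) and the
#' assignment of every sequence to one species, in two bracketed sections:
#'
#' ```
#' [species tree]
#' ((A,B),C);
#' [assignments]
#' A: a1, a2
#' B: b1
#' C: c*
#' ```
#'
#' A token ending in `*` is a prefix pattern, expanded against the gene-tree
#' leaves when the assignments are resolved (see [resolve_assignments()]).
#'
#' @param file Path to an information file (or use `text =` for a literal
#'   string).
#' @param text Optional literal file content, overriding `file`.
#' @return An object of class `species_info`: a list with `$tree` (the
#'   species tree, an [ape::phylo] without branch lengths), `$direct`
#'   (named character vector, sequence id -> species) and `$prefixes`
#'   (named character vector, prefix -> species).
#' @export
read_species_info <- function(file, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sect <- tolower(lines) == "[species tree]"
  asct <- tolower(lines) == "[assignments]"
  if (!any(sect)) stop("information file is missing a [species tree] section")
  if (!any(asct)) stop("information file is missing an [assignments] section")
  headers <- sort(c(which(sect), which(asct), length(lines) + 1L))
  section_body <- function(start) {
    stop_at <- min(headers[headers > start]) - 1L
    if (stop_at < start + 1L) character(0) else lines[seq(start + 1L, stop_at)]
  }
  tree_lines <- section_body(which(sect)[1])
  if (!length(tree_lines)) stop("no species tree found in [species tree] section")
  stree <- parse_newick(paste(tree_lines, collapse = ""), topology_only = TRUE)
  if (anyDuplicated(stree$tip.label)) stop("duplicate species label in species tree")

  asn_lines <- section_body(which(asct)[1])
  direct <- character(0)
  prefixes <- character(0)
  for (ln in asn_lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed assignment line: '", ln, "'")
    sp <- trimws(m[2])
    if (!sp %in% stree$tip.label) {
      stop("species '", sp, "' in assignments is absent from the species tree")
    }
    ids <- trimws(strsplit(m[3], ",")[[1]])
    ids <- ids[nzchar(ids)]
    for (id in ids) {
      if (endsWith(id, "*")) {
        pref <- substr(id, 1L, nchar(id) - 1L)
        if (pref %in% names(prefixes) && prefixes[pref] != sp) {
          stop("prefix '", pref, "*' assigned to both '", prefixes[pref],
               "' and '", sp, "'")
        }
        prefixes[pref] <- sp
      } else {
        if (id %in% names(direct) && direct[id] != sp) {
          stop("sequence '", id, "' assigned to both '", direct[id],
               "' and '", sp, "'")
        }
        direct[id] <- sp
      }
    }
  }
  structure(list(tree = stree, direct = direct, prefixes = prefixes),
            class = "species_info")
}

#' Resolve sequence-to-species assignments for a set of gene-tree leaves
#'
#' Expands prefix patterns against the actual leaf labels and checks that
#' every leaf receives exactly one species.
#'
#' @param info A `species_info` object from [read_species_info()].
#' @param leaves Character vector of gene-tree leaf labels.
#' @return Named character vector: leaf label -> species label.
#' @export
resolve_assignments <- function(info, leaves) {
  stopifnot(inherits(info, "species_info"))
  out <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
  for (lf in leaves) {
    hits <- character(0)
    if (lf %in% names(info$direct)) hits <- unname(info$direct[lf])
    if (length(info$prefixes)) {
      pm <- vapply(names(info$prefixes), function(p) startsWith(lf, p), logical(1))
      hits <- c(hits, unname(info$prefixes[pm]))
    }
    hits <- unique(hits)
    if (length(hits) == 0L) stop("leaf '", lf, "' has no species assignment")
    if (length(hits) > 1L) {
      stop("leaf '", lf, "' matches assignments for multiple species: ",
           paste(hits, collapse = ", "))
    }
    out[lf] <- hits
  }
  out
}

#' Write a species-information file
#'
#' Inverse of [read_species_info()] for explicit (non-pattern) assignments.
#'
#' @param stree Species tree ([ape::phylo], topology only).
#' @param assignments Named character vector: sequence id -> species label.
#' @param file Output path; if `NULL` the text is returned invisibly.
#' @return The file content, invisibly.
#' @export
write_info_file <- function(stree, assignments, file = NULL) {
  nwk <- ape::write.tree(stree)
  by_sp <- split(names(assignments), assignments)
  lines <- c("[species tree]", nwk, "[assignments]",
             vapply(names(by_sp), function(sp) {
               paste0(sp, ": ", paste(by_sp[[sp]], collapse = ", "))
             }, character(1)))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Root a gene tree by minimum reconciliation cost
#'
#' Evaluates every possible rooting of the (unrooted) gene tree and returns
#' the one minimizing the phase-1 clustering objective (event-parsimony
#' cost plus the per-group surcharge; see [cluster_initial()]). Ties are
#' broken deterministically by the lexicographically smallest sorted
#' leaf-label set of the root's first child. The split edge's length is
#' divided equally between the two child edges of the new root.
#'
#' @param gtree Gene tree (rooted or unrooted [ape::phylo], >= 3 leaves).
#' @param stree Species tree.
#' @param assignments Named character vector leaf -> species, or a
#'   `species_info` object.
#' @param weights An [instability_weights()] object.
#' @param rooted If `TRUE` and `gtree` is already binary-rooted, it is
#'   returned unchanged.
#' @return A binary rooted [ape::phylo].
#' @export
root_gene_tree <- function(gtree, stree, assignments,
                           weights = instability_weights(), rooted = FALSE) {
  if (inherits(assignments, "species_info")) {
    assignments <- resolve_assignments(assignments, gtree$tip.label)
  }
  if (rooted) {
    if (!.is_binary_rooted(gtree)) {
      stop("'rooted = TRUE' but the gene tree is not binary-rooted")
    }
    return(gtree)
  }
  if (ape::Ntip(gtree) < 3L) stop("need at least 3 leaves to root a tree")
  ut <- ape::unroot(gtree)
  tips <- .clade_tips(ut)
  best <- NULL
  best_obj <- Inf
  best_key <- NULL
  for (i in seq_len(nrow(ut$edge))) {
    side <- ut$tip.label[tips[[ut$edge[i, 2]]]]
    cand <- ape::root(ut, outgroup = side, resolve.root = TRUE)
    cand <- .rebalance_root_edges(cand)
    rec <- reconcile(cand, stree, assignments)
    obj <- cluster_initial(rec, weights)$objective
    ch1 <- .tree_children(cand)[[.tree_root(cand)]][1]
    key <- .labelset_key(cand$tip.label[.clade_tips(cand)[[ch1]]])
    if (obj < best_obj - 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && (is.null(best_key) || key < best_key))) {
      best <- cand
      best_obj <- obj
      best_key <- key
    }
  }
  best
}

# ape::root() leaves the full length of the split edge on one side of the
# new root; share it out equally.
.rebalance_root_edges <- function(phy) {
  if (is.null(phy$edge.length)) return(phy)
  root <- .tree_root(phy)
  idx <- which(phy$edge[, 1] == root)
  if (length(idx) == 2L) {
    tot <- sum(phy$edge.length[idx])
    phy$edge.length[idx] <- tot / 2
  }
  phy
}

#' Write an instability score table as CSV
#'
#' Column order is (sequence, species, cluster, score); scores are printed
#' with full (round-trip) precision. All members of one MIG share the
#' identical score field.
#'
#' @param table A score-table `data.frame` with columns `sequence`,
#'   `species`, `cluster`, `score` (one row per gene-tree leaf).
#' @param file Output path; if `NULL` the CSV text is returned.
#' @param header Write the header line `sequence,species,cluster,score`.
#' @return The CSV text, invisibly when written to a file.
#' @export
write_scores_csv <- function(table, file = NULL, header = TRUE) {
  stopifnot(is.data.frame(table),
            all(c("sequence", "species", "cluster", "score") %in% names(table)))
  rows <- paste(table$sequence, table$species, table$cluster,
                vapply(table$score, .format_score, character(1)), sep = ",")
  if (header) rows <- c("sequence,species,cluster,score", rows)
  txt <- paste(rows, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read an instability score table written by [write_scores_csv()]
#'
#' @param file Path to the CSV (with or without header).
#' @return A `data.frame` with columns sequence, species, cluster, score.
#' @export
read_scores_csv <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && lines[1] == "sequence,species,cluster,score") {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) stop("malformed score row at line ", bad[1])
  data.frame(sequence = vapply(parts, `[`, character(1), 1L),
             species = vapply(parts, `[`, character(1), 2L),
             cluster = as.integer(vapply(parts, `[`, character(1), 3L)),
             score = as.numeric(vapply(parts, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

# Shortest decimal representation that round-trips, always with a decimal
# point (so 0 prints as "0.0").
.format_score <- function(x) {
  for (d in 1:17) {
    s <- trimws(formatC(x, digits = d, format = "g"))
    if (as.numeric(s) == x) break
  }
  if (!grepl("[.e]", s)) s <- paste0(s, ".0")
  s
}
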