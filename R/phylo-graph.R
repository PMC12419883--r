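## Rooted, edge-weighted phylogenies are held as ape "phylo" objects.  All
## functions in this file impose a canonical edge enumeration (preorder from
## the root, children ordered by the lexicographically smallest tip label in
## their subtree) so that downstream eigenvector bases are reproducible.

#' Parse a rooted Newick tree
#'
#' Reads a Newick string with branch lengths into a validated `phylo`
#' object.  Tip labels must be unique, all branch lengths must be present
#' and non-negative, and the tree must be rooted.  Tip order follows the
#' input string.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:2):3,C:4);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .newick_scan(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse failure: no tree read", call. = FALSE)
  validate_tree(tr)
  tr
}

## Pre-scan for structural errors so failures can name a character offset;
## ape's parser gives no position information.
.newick_scan <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse failure: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
    if (ch == ";" && depth != 0L)
      stop("Newick parse failure: ';' inside open parenthesis at character ",
           "offset ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("Newick parse failure: ", depth, " unclosed '(' at character offset ",
         length(chars), call. = FALSE)
  if (!any(chars == ";"))
    stop("Newick parse failure: missing terminating ';' at character offset ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylogeny for use in this package
#'
#' Checks the `PhyloTree` invariants: single root, unique tip labels,
#' branch lengths present and non-negative, connected topology.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must all be present and >= 0", call. = FALSE)
  n <- length(tree$tip.label)
  nodes <- seq_len(n + tree$Nnode)
  child_counts <- tabulate(tree$edge[, 2L], nbins = max(nodes))
  roots <- setdiff(nodes, tree$edge[, 2L])
  if (length(roots) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  if (any(child_counts > 1L))
    stop("a vertex has more than one parent", call. = FALSE)
  invisible(tree)
}

#' Serialize a tree to Newick with full double precision
#'
#' @param tree A `phylo` object.
#' @return A Newick string; `parse_newick(write_newick(tree))` reproduces
#'   topology and branch lengths exactly.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  et <- edge_table(tree)
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(et)), et$parent)  # edge rows by parent node
  render <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(.escape_label(tree$tip.label[node]))
    inner <- vapply(rows, function(r) {
      paste0(render(et$child[r]), ":", sprintf("%.17g", et$length[r]))
    }, character(1L))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(render(root_node(tree)), ";")
}

.escape_label <- function(x) {
  if (grepl("[ ():,;']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' @keywords internal
root_node <- function(tree) {
  n <- length(tree$tip.label)
  setdiff(seq_len(n + tree$Nnode), tree$edge[, 2L])[1L]
}

## Lexicographically smallest tip label below each node; the child-ordering
## key of the canonical edge enumeration.
.min_tip_label <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  lab <- rep(NA_character_, nn)
  lab[seq_len(n)] <- tree$tip.label
  ## postorder over edges: ape trees are not guaranteed ordered, so iterate
  ## until fixed point (cheap for the tree sizes used here)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
      if (!is.na(lab[c]) && (is.na(lab[p]) || lab[c] < lab[p])) {
        lab[p] <- lab[c]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Canonical edge enumeration of a tree
#'
#' Enumerates edges in preorder from the root; among the children of a
#' node, subtrees are visited in order of their lexicographically smallest
#' descendant tip label.  This fixed order makes influence-matrix columns,
#' and hence eigenvector signs and order, reproducible across runs.
#'
#' @param tree A `phylo` object.
#' @return A data frame with one row per edge (columns `index`, `parent`,
#'   `child` as node numbers, `length`, and `child_label`, the tip label
#'   for terminal edges or `NA`).
#' @export
edge_table <- function(tree) {
  n <- length(tree$tip.label)
  key <- .min_tip_label(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- tree$edge.length
  edge_of_child <- integer(n + tree$Nnode)
  edge_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  ne <- nrow(tree$edge)
  ord_parent <- integer(ne); ord_child <- integer(ne); ord_len <- numeric(ne)
  pos <- 0L
  visit <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(invisible())
    kids <- kids[order(key[kids], method = "radix")]
    for (k in kids) {  # edge first, then its whole subtree (true preorder)
      pos <<- pos + 1L
      ord_parent[pos] <<- node; ord_child[pos] <<- k
      ord_len[pos] <<- elen[edge_of_child[k]]
      visit(k)
    }
  }
  visit(root_node(tree))
  data.frame(
    index = seq_along(ord_child),
    parent = ord_parent,
    child = ord_child,
    length = ord_len,
    child_label = ifelse(ord_child <= n, tree$tip.label[ord_child], NA),
    stringsAsFactors = FALSE
  )
}

#' Prune a tree to a set of tips, keeping the original root
#'
#' Removes all tips not in `keep`, suppresses internal vertices left with a
#' single child (their branch lengths are summed), but always retains the
#' original root even if it is left with one child.  Keeping the root
#' preserves root-path lengths, and hence shared path lengths, among the
#' remaining tips.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return A `phylo` object.
#' @export
prune_to_tips <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(trimws(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(keep) < 2L) stop("need at least 2 tips to keep", call. = FALSE)
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode); plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  root <- root_node(tree)
  kept_tip <- seq_len(n)[tree$tip.label %in% keep]
  ## count kept-tip descendants per node
  nk <- integer(n + tree$Nnode)
  for (t in kept_tip) {
    v <- t
    repeat {
      nk[v] <- nk[v] + 1L
      if (v == root) break
      v <- parent[v]
    }
  }
  kid_count <- integer(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    if (nk[tree$edge[i, 2L]] > 0L)
      kid_count[tree$edge[i, 1L]] <- kid_count[tree$edge[i, 1L]] + 1L
  survives <- logical(n + tree$Nnode)
  survives[kept_tip] <- TRUE
  survives[root] <- TRUE
  internal <- setdiff(which(nk > 0L), kept_tip)
  survives[internal[kid_count[internal] >= 2L]] <- TRUE
  ## render surviving structure back to Newick (lengths merged on the way up)
  lab <- .min_tip_label(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  render <- function(node) {
    if (node <= n) return(.escape_label(tree$tip.label[node]))
    kids <- children[[as.character(node)]]
    kids <- kids[nk[kids] > 0L]
    kids <- kids[order(lab[kids], method = "radix")]
    parts <- vapply(kids, function(k) {
      len <- plen[k]
      while (!survives[k]) {  # suppress single-child chain, summing lengths
        kk <- children[[as.character(k)]]
        k <- kk[nk[kk] > 0L][1L]
        len <- len + plen[k]
      }
      paste0(render(k), ":", sprintf("%.17g", len))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  parse_newick(paste0(render(root), ";"))
}

#' Influence matrix of a tree restricted to a training tip set
#'
#' Prunes the tree to the training tips (see [prune_to_tips()]) and builds
#' the binary tips-by-edges indicator matrix: entry (t, e) is 1 when edge e
#' lies on the path from the root to tip t.  Columns follow the canonical
#' preorder edge enumeration of [edge_table()].
#'
#' @param tree A `phylo` object covering at least the training tips.
#' @param training_tips Character vector of tip labels forming the training
#'   set; other tips are pruned away.
#' @return An object of class `influence_matrix`: a list with elements `I`
#'   (binary matrix, tips x edges), `edges` (canonical edge table of the
#'   pruned tree), `lengths` (per-column branch lengths) and `tree` (the
#'   pruned `phylo`).
#' @export
influence_matrix <- function(tree, training_tips = tree$tip.label) {
  if (length(training_tips) == 0L)
    stop("training tip set is empty", call. = FALSE)
  ptree <- if (setequal(training_tips, tree$tip.label)) {
    validate_tree(tree)
  } else {
    prune_to_tips(tree, training_tips)
  }
  et <- edge_table(ptree)
  n <- length(ptree$tip.label)
  parent <- integer(n + ptree$Nnode)
  parent[ptree$edge[, 2L]] <- ptree$edge[, 1L]
  root <- root_node(ptree)
  col_of_child <- integer(n + ptree$Nnode)
  col_of_child[et$child] <- et$index
  I <- matrix(0, nrow = n, ncol = nrow(et),
              dimnames = list(ptree$tip.label,
                              sprintf("e%d", et$index)))
  for (t in seq_len(n)) {
    v <- t
    while (v != root) {
      I[t, col_of_child[v]] <- 1
      v <- parent[v]
    }
  }
  structure(
    list(I = I, edges = et, lengths = et$length, tree = ptree),
    class = "influence_matrix"
  )
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat("Influence matrix:", nrow(x$I), "tips x", ncol(x$I), "edges\n")
  invisible(x)
}

#' Brute-force shared root-path length matrix
#'
#' For each pair of tips, sums the lengths of the edges shared by their
#' root-to-tip paths.  The diagonal holds tip depths.  Under Brownian
#' motion with unit rate this is the trait covariance matrix, which makes
#' this function the independent oracle for the influence-matrix algebra:
#' `I diag(phi) t(I)` must equal it exactly.
#'
#' @param tree A `phylo` object.
#' @param tips Tip labels to include (default all).
#' @return A symmetric positive semi-definite matrix with tip-label
#'   dimnames.
#' @export
path_length_matrix <- function(tree, tips = tree$tip.label) {
  validate_tree(tree)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode); plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  root <- root_node(tree)
  idx <- match(tips, tree$tip.label)
  paths <- lapply(idx, function(t) {
    v <- t; nodes <- integer(0)
    while (v != root) { nodes <- c(nodes, v); v <- parent[v] }
    nodes  # path encoded by child-end node numbers
  })
  m <- length(idx)
  out <- matrix(0, m, m, dimnames = list(tips, tips))
  for (i in seq_len(m)) {
    for (j in i:m) {
      shared <- intersect(paths[[i]], paths[[j]])
      out[i, j] <- out[j, i] <- sum(plen[shared])
    }
  }
  out
}

#' Locate held-out tips relative to a training tree
#'
#' For every tip of `full_tree` absent from `training_tips`, finds where
#' its lineage attaches to the pruned training tree: the attachment edge
#' (canonical index), the length already traversed along that edge from its
#' parent end, and the pendant length from the attachment point out to the
#' held-out tip.  The pendant length is recorded for completeness but plays
#' no role in point prediction.
#'
#' @param full_tree A `phylo` object containing training and target tips.
#' @param training_tips Character vector of training tip labels.
#' @return A list of `tip_location` objects (fields `label`, `edge`,
#'   `traversed`, `pendant`), one per held-out tip, in `full_tree` tip
#'   order.
#' @export
locate_targets <- function(full_tree, training_tips) {
  validate_tree(full_tree)
  training_tips <- trimws(training_tips)
  unknown <- setdiff(training_tips, full_tree$tip.label)
  if (length(unknown))
    stop("unknown training tip(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  targets <- setdiff(full_tree$tip.label, training_tips)
  if (!length(targets)) return(list())
  ptree <- prune_to_tips(full_tree, training_tips)
  et <- edge_table(ptree)

  n <- length(full_tree$tip.label)
  parent <- integer(n + full_tree$Nnode); plen <- numeric(n + full_tree$Nnode)
  parent[full_tree$edge[, 2L]] <- full_tree$edge[, 1L]
  plen[full_tree$edge[, 2L]] <- full_tree$edge.length
  root <- root_node(full_tree)
  kept_tip <- which(full_tree$tip.label %in% training_tips)
  nk <- integer(n + full_tree$Nnode)
  for (t in kept_tip) {
    v <- t
    repeat { nk[v] <- nk[v] + 1L; if (v == root) break; v <- parent[v] }
  }
  kid_count <- integer(n + full_tree$Nnode)
  for (i in seq_len(nrow(full_tree$edge)))
    if (nk[full_tree$edge[i, 2L]] > 0L)
      kid_count[full_tree$edge[i, 1L]] <-
        kid_count[full_tree$edge[i, 1L]] + 1L
  survives <- logical(n + full_tree$Nnode)
  survives[kept_tip] <- TRUE; survives[root] <- TRUE
  internal <- setdiff(which(nk > 0L), kept_tip)
  survives[internal[kid_count[internal] >= 2L]] <- TRUE
  children <- split(full_tree$edge[, 2L], full_tree$edge[, 1L])

  ## map surviving full-tree nodes to training-tree nodes via the set of
  ## training tips below each
  tipset_key <- function(tr) {
    nn <- length(tr$tip.label) + tr$Nnode
    sets <- vector("list", nn)
    for (t in seq_along(tr$tip.label)) sets[[t]] <- tr$tip.label[t]
    pr <- integer(nn); pr[tr$edge[, 2L]] <- tr$edge[, 1L]
    rt <- root_node(tr)
    for (t in seq_along(tr$tip.label)) {
      v <- t
      while (v != rt) {
        v <- pr[v]
        sets[[v]] <- c(sets[[v]], tr$tip.label[t])
      }
    }
    vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1L))
  }
  full_key <- local({
    nn <- n + full_tree$Nnode
    sets <- vector("list", nn)
    for (t in kept_tip) {
      v <- t
      repeat {
        sets[[v]] <- c(sets[[v]], full_tree$tip.label[t])
        if (v == root) break
        v <- parent[v]
      }
    }
    vapply(sets, function(s)
      if (is.null(s)) NA_character_ else paste(sort(s), collapse = "\r"),
      character(1L))
  })
  train_key <- tipset_key(ptree)
  train_root <- root_node(ptree)
  edge_ending_at <- integer(length(train_key))
  edge_ending_at[et$child] <- et$index
  train_node_of <- function(v) match(full_key[v], train_key)

  locate_one <- function(lab) {
    f <- match(lab, full_tree$tip.label)
    pendant <- 0; v <- f
    repeat {
      pendant <- pendant + plen[v]
      v <- parent[v]
      if (nk[v] > 0L) break
      if (v == root) break
    }
    X <- v
    if (survives[X]) {
      tn <- train_node_of(X)
      if (is.na(tn)) tn <- train_root  # X above MRCA chain: treat as root
      if (tn == train_root) {
        return(structure(list(label = lab, edge = 1L, traversed = 0,
                              pendant = pendant), class = "tip_location"))
      }
      e <- edge_ending_at[tn]
      return(structure(list(label = lab, edge = e,
                            traversed = et$length[e], pendant = pendant),
                       class = "tip_location"))
    }
    ## X is a suppressed degree-2 point: find surviving ancestor A and the
    ## surviving node D below X, then measure A -> X along the full tree
    A <- parent[X]
    while (!survives[A]) A <- parent[A]
    traversed <- 0; v <- X
    while (v != A) { traversed <- traversed + plen[v]; v <- parent[v] }
    D <- X
    repeat {
      kids <- children[[as.character(D)]]
      D <- kids[nk[kids] > 0L][1L]
      if (survives[D]) break
    }
    e <- edge_ending_at[train_node_of(D)]
    if (traversed > et$length[e] + 1e-9)
      stop("internal error: traversed length exceeds attachment edge",
           call. = FALSE)
    structure(list(label = lab, edge = e, traversed = traversed,
                   pendant = pendant), class = "tip_location")
  }
  locs <- lapply(targets, locate_one)
  names(locs) <- targets
  locs
}

#' @export
print.tip_location <- function(x, ...) {
  cat(sprintf("tip '%s': edge %d, traversed %.6g, pendant %.6g\n",
              x$label, x$edge, x$traversed, x$pendant))
  invisible(x)
}
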