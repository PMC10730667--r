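#' Polytomy-capable phylogenetic trees
#'
#' Trees produced by the joining engines are conceptually unrooted; the
#' final join node doubles as the serialization root. Nodes are plain
#' nested lists with fields `label` (non-empty for leaves only), `children`
#' (ordered list, possibly more than two: polytomies are first-class) and
#' `length` (branch to the parent; `NA` for the root). All topology
#' comparisons go through unrooted splits, never through the rooted shape.
#'
#' @param root root node as built by [tree_node()].
#' @return an object of class `mfnj_tree`.
#' @seealso [to_newick()], [tree_splits()], [root_at_longest_branch()]
#' @export
phylo_tree <- function(root) {
  tips <- collect_leaves(root)
  if (anyDuplicated(tips)) {
    stop_validation("duplicate leaf labels in tree")
  }
  structure(list(root = root, tip_labels = tips), class = "mfnj_tree")
}

#' Construct a tree node
#'
#' @param label taxon label; non-empty exactly for leaves.
#' @param children list of child nodes (empty for leaves).
#' @param length branch length to the parent (`NA` for a root).
#' @return a node (plain list).
#' @export
tree_node <- function(label = "", children = list(), length = NA_real_) {
  if (length(children) == 0 && !nzchar(label)) {
    stop("a leaf node needs a non-empty label")
  }
  list(label = label, children = children, length = as.numeric(length))
}

collect_leaves <- function(node) {
  if (length(node$children) == 0) return(node$label)
  unlist(lapply(node$children, collect_leaves), use.names = FALSE)
}

#' @export
print.mfnj_tree <- function(x, ...) {
  cat(sprintf("Phylogenetic tree with %d leaves\n", length(x$tip_labels)))
  cat(to_newick(x), "\n")
  invisible(x)
}

# Newick-quote a label when it contains structural characters.
newick_label <- function(label) {
  if (grepl("[][(){},:;='\"` \t]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

#' Serialize a tree to Newick
#'
#' Children are written in creation order, so identical runs give
#' byte-identical output. Branch lengths use significant digits (not fixed
#' decimals) so tiny lengths survive; negative lengths, if kept by the
#' engine's policy, are written as-is.
#'
#' @param tree a [phylo_tree()].
#' @param precision significant digits for branch lengths.
#' @return a single Newick string terminated by `";"`.
#' @examples
#' tr <- phylo_tree(tree_node(children = list(
#'   tree_node("A", length = 1), tree_node("B", length = 2),
#'   tree_node("C", length = 3))))
#' to_newick(tr)  # "(A:1,B:2,C:3);"
#' @export
to_newick <- function(tree, precision = 6) {
  fmt <- function(x) sprintf("%.*g", precision, x)
  rec <- function(node) {
    core <- if (length(node$children) == 0) {
      newick_label(node$label)
    } else {
      paste0("(", paste(vapply(node$children, rec, character(1)),
                        collapse = ","), ")",
             if (nzchar(node$label)) newick_label(node$label) else "")
    }
    if (is.na(node$length)) core else paste0(core, ":", fmt(node$length))
  }
  paste0(rec(tree$root), ";")
}

#' Parse a Newick string
#'
#' Thin wrapper over [ape::read.tree()], provided for round-trip tests and
#' for loading reference trees.
#'
#' @param text Newick string.
#' @return a [phylo_tree()].
#' @export
read_newick <- function(text) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop_parse("could not parse Newick input")
  as_phylo_tree(phy)
}

#' Convert between `mfnj_tree` and `ape::phylo`
#'
#' @param x tree to convert.
#' @param ... unused.
#' @return `as.phylo()` gives an [ape] `phylo`; `as_phylo_tree()` the
#'   package-native nested representation.
#' @export
as.phylo.mfnj_tree <- function(x, ...) {
  tips <- x$tip_labels
  n <- length(tips)
  n_internal <- count_internal(x$root)
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  next_internal <- n + 1L
  rec <- function(node, parent_id) {
    if (length(node$children) == 0) {
      id <- match(node$label, tips)
    } else {
      id <- next_internal
      next_internal <<- next_internal + 1L
    }
    if (!is.na(parent_id)) {
      parent <<- c(parent, parent_id)
      child <<- c(child, id)
      elen <<- c(elen, node$length)
    }
    for (ch in node$children) rec(ch, id)
    id
  }
  rec(x$root, NA_integer_)
  structure(list(edge = cbind(parent, child, deparse.level = 0),
                 edge.length = elen, tip.label = tips,
                 Nnode = n_internal),
            class = "phylo", order = "cladewise")
}

#' @rdname as.phylo.mfnj_tree
#' @export
as_phylo_tree <- function(x) {
  stopifnot(inherits(x, "phylo"))
  # ape keeps Newick quoting in labels; undo it
  unquote <- function(s) {
    q <- grepl("^'.*'$", s)
    s[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", s[q]))
    s
  }
  x$tip.label <- unquote(x$tip.label)
  n <- length(x$tip.label)
  root_id <- n + 1L
  edge <- x$edge
  elen <- x$edge.length
  if (is.null(elen)) elen <- rep(NA_real_, nrow(edge))
  rec <- function(id, len) {
    rows <- which(edge[, 1] == id)
    if (length(rows) == 0) {
      tree_node(x$tip.label[id], length = len)
    } else {
      tree_node(children = lapply(rows, function(r) rec(edge[r, 2], elen[r])),
                length = len)
    }
  }
  phylo_tree(rec(root_id, NA_real_))
}

count_internal <- function(node) {
  if (length(node$children) == 0) return(0L)
  1L + sum(vapply(node$children, count_internal, integer(1)))
}

# --- unrooted view ---------------------------------------------------------
# Flatten a rooted tree into an undirected edge list over numbered vertices.
# A degree-2 serialization root (2-taxon final edge, or a tree re-rooted for
# display) is suppressed: its two incident edges merge into one whose length
# is their sum, so the unrooted topology is independent of rooting.
unrooted_graph <- function(tree) {
  vlabel <- character(0)
  e_a <- integer(0); e_b <- integer(0); e_len <- numeric(0)
  e_childset <- list()  # leaf labels below the child end, in the rooted sense
  new_vertex <- function(label) {
    vlabel[length(vlabel) + 1L] <<- label
    length(vlabel)
  }
  rec <- function(node, parent_v) {
    v <- new_vertex(node$label)
    leaves <- character(0)
    for (ch in node$children) leaves <- c(leaves, rec(ch, v))
    if (length(node$children) == 0) leaves <- node$label
    if (!is.na(parent_v)) {
      e_a[length(e_a) + 1L] <<- parent_v
      e_b[length(e_b) + 1L] <<- v
      e_len[length(e_len) + 1L] <<- node$length
      e_childset[[length(e_childset) + 1L]] <<- leaves
    }
    leaves
  }
  rec(tree$root, NA_integer_)
  root_edges <- which(e_a == 1L)
  if (length(tree$root$children) == 2 && length(root_edges) == 2) {
    i <- root_edges[1]; j <- root_edges[2]
    e_a[i] <- e_b[j]            # join the two children directly
    e_len[i] <- e_len[i] + e_len[j]
    keep <- setdiff(seq_along(e_a), j)
    e_a <- e_a[keep]; e_b <- e_b[keep]; e_len <- e_len[keep]
    e_childset <- e_childset[keep]
  }
  list(vlabel = vlabel,
       edges = data.frame(a = e_a, b = e_b, len = e_len),
       childset = e_childset)
}

#' Unrooted splits of a tree
#'
#' The set of non-trivial bipartitions of the leaf set induced by internal
#' edges of the unrooted tree. Each split is represented canonically as the
#' sorted, `"|"`-joined side that does not contain the lexicographically
#' smallest leaf label; degree-2 serialization roots are suppressed first.
#' A fully binary tree on N leaves has N-3 splits; a star has none.
#'
#' @param tree a [phylo_tree()].
#' @return character vector of canonical split representations (sorted).
#' @export
tree_splits <- function(tree) {
  g <- unrooted_graph(tree)
  all_leaves <- sort(tree$tip_labels)
  n <- length(all_leaves)
  anchor <- all_leaves[1]
  out <- character(0)
  for (k in seq_len(nrow(g$edges))) {
    side <- g$childset[[k]]
    if (anchor %in% side) side <- setdiff(all_leaves, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

#' Compare two trees as unrooted topologies
#'
#' @param t1,t2 [phylo_tree()] objects over the same leaf set.
#' @return `TRUE` iff the unrooted split sets are equal.
#' @export
same_unrooted_topology <- function(t1, t2) {
  if (!setequal(t1$tip_labels, t2$tip_labels)) {
    stop_input("trees have different leaf sets")
  }
  setequal(tree_splits(t1), tree_splits(t2))
}

#' Re-root a tree at its longest branch
#'
#' Display helper mirroring the common convention of placing the longest
#' branch at the root: the single longest branch is split at its midpoint
#' by a new degree-2 root. Ties are broken toward the branch whose child
#' subtree contains the lexicographically smallest leaf. The unrooted split
#' set and total branch length are unchanged.
#'
#' @param tree a [phylo_tree()] with at least 2 leaves.
#' @return a re-rooted [phylo_tree()].
#' @export
root_at_longest_branch <- function(tree) {
  if (length(tree$tip_labels) <= 2) return(tree)
  g <- unrooted_graph(tree)
  len <- g$edges$len
  if (anyNA(len)) stop_input("tree has missing branch lengths")
  cand <- which(len == max(len))
  if (length(cand) > 1) {
    mins <- vapply(g$childset[cand], min, character(1))
    cand <- cand[order(mins)][1]
  }
  k <- cand[1]
  half <- len[k] / 2
  r <- length(g$vlabel) + 1L
  edges <- g$edges[-k, , drop = FALSE]
  edges <- rbind(edges,
                 data.frame(a = r, b = g$edges$b[k], len = half),
                 data.frame(a = r, b = g$edges$a[k], len = half))
  # rebuild a rooted tree from the new root over the undirected edge set
  adj <- vector("list", r)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    adj[[a]] <- rbind(adj[[a]], c(b, edges$len[i]))
    adj[[b]] <- rbind(adj[[b]], c(a, edges$len[i]))
  }
  build <- function(v, from, len) {
    nbr <- adj[[v]]
    kids <- if (is.null(nbr)) {
      matrix(numeric(0), 0, 2)
    } else if (is.na(from)) {
      nbr
    } else {
      nbr[nbr[, 1] != from, , drop = FALSE]
    }
    if (NROW(kids) == 0) {
      tree_node(g$vlabel[v], length = len)
    } else {
      tree_node(children = lapply(seq_len(nrow(kids)), function(i) {
        build(as.integer(kids[i, 1]), v, kids[i, 2])
      }), length = len)
    }
  }
  phylo_tree(build(r, NA_integer_, NA_real_))
}

#' Branch lengths of the unrooted tree
#'
#' Lengths of the edges of the unrooted view of the tree, with a degree-2
#' serialization root suppressed (its two incident half-edges merge into
#' one). This is the right multiset for comparing trees that may have been
#' rooted differently: a rooted representation splits one unrooted edge in
#' two at the root.
#'
#' @param tree a [phylo_tree()].
#' @return sorted numeric vector of unrooted edge lengths.
#' @export
unrooted_edge_lengths <- function(tree) {
  sort(unrooted_graph(tree)$edges$len)
}

#' Total branch length of a tree
#'
#' @param tree a [phylo_tree()].
#' @return sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  rec <- function(node) {
    sum(vapply(node$children, rec, numeric(1)),
        if (is.na(node$length)) 0 else node$length)
  }
  rec(tree$root)
}

# clamp negative branch lengths to zero (display policy; applied after the
# whole agglomeration so the trajectory is unaffected)
clamp_tree_lengths <- function(tree) {
  rec <- function(node) {
    if (!is.na(node$length) && node$length < 0) node$length <- 0
    node$children <- lapply(node$children, rec)
    node
  }
  phylo_tree(rec(tree$root))
}
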