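#' Algorithm configuration
#'
#' Tunables for the joining engines. The selection criterion is computed in
#' floating point, so "equal" S values are detected with a tolerance:
#' a pair is tied with the minimum when
#' `S <= S_min + tie_atol + tie_rtol * |S_min|`. The defaults are far below
#' the S differences that genuinely distinct pairs produce on typical
#' distance matrices (e.g. percentage differences with one decimal), and
#' far above double-precision summation noise.
#'
#' @param tie_rtol relative tie tolerance (dimensionless).
#' @param tie_atol absolute tie tolerance (same units as S).
#' @param negative_branch `"keep"` writes negative branch lengths as
#'   computed (faithful to the original arithmetic); `"clamp_to_zero"`
#'   clamps them for display after the agglomeration has finished, so the
#'   algorithm's trajectory is unaffected.
#' @param nj_tie_break classic-NJ tie policy; `"first_scan"` picks the tied
#'   pair that comes first by (smaller index, larger index) in the current
#'   matrix order — deterministic and input-order-sensitive by design,
#'   which is exactly the phenomenon the multifurcating variant removes.
#' @param enum_cap maximum number of distinct trees the tie-break
#'   enumerator returns before flagging truncation.
#' @param precision significant digits for Newick branch lengths.
#' @return a list of class `mfnj_config`.
#' @export
mfnj_config <- function(tie_rtol = 1e-9, tie_atol = 1e-12,
                        negative_branch = c("keep", "clamp_to_zero"),
                        nj_tie_break = "first_scan",
                        enum_cap = 64, precision = 6) {
  stopifnot(tie_rtol >= 0, tie_atol >= 0, enum_cap >= 1)
  structure(list(tie_rtol = tie_rtol, tie_atol = tie_atol,
                 negative_branch = match.arg(negative_branch),
                 nj_tie_break = match.arg(nj_tie_break),
                 enum_cap = as.integer(enum_cap),
                 precision = as.integer(precision)),
            class = "mfnj_config")
}

#' Selection criterion state
#'
#' Computes, for the current matrix of N active OTUs, the row sums
#' `R_i = sum_k D_ik`, the Studier–Keppler criterion
#' `S_ij = (N - 2) D_ij - R_i - R_j`, and its minimum over unordered
#' pairs. Minimizing S is equivalent to minimizing the total branch length
#' of the tree obtained by joining i and j.
#'
#' @param dm a [dist_matrix()] (or plain labeled symmetric matrix) with at
#'   least 3 active OTUs.
#' @return list with `row_sums`, `s_values` (diagonal `Inf`, off-diagonal
#'   symmetric), and `s_min`.
#' @export
s_state <- function(dm) {
  n <- nrow(dm)
  stopifnot(n >= 3)
  r <- rowSums(dm)
  s <- (n - 2) * unclass(dm) - outer(r, r, "+")
  diag(s) <- Inf
  list(row_sums = r, s_values = s, s_min = min(s))
}

#' Tied minimal pairs
#'
#' Every unordered pair whose S value lies within tolerance of the minimum;
#' contains at least one pair and is independent of scan order.
#'
#' @param state result of [s_state()].
#' @param cfg an [mfnj_config()].
#' @return two-column integer matrix of pairs (row index < column index).
#' @export
tied_min_pairs <- function(state, cfg = mfnj_config()) {
  thr <- state$s_min + cfg$tie_atol + cfg$tie_rtol * abs(state$s_min)
  idx <- which(state$s_values <= thr, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  idx
}

#' Group tied pairs into join sets
#'
#' Tie groups are the connected components of the graph whose vertices are
#' the OTUs appearing in tied pairs and whose edges are the pairs; two
#' pairs sharing an OTU merge into one group, so chains of ties join any
#' number of OTUs at once. Components are listed in order of their smallest
#' member index, members sorted, and are pairwise disjoint.
#'
#' @param pairs two-column integer matrix as from [tied_min_pairs()].
#' @return list of integer vectors, each of size >= 2.
#' @export
tie_groups <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  verts <- sort(unique(as.vector(pairs)))
  # tiny union-find over the pair graph
  id <- seq_along(verts)
  root_of <- function(i) { while (id[i] != i) i <- id[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- root_of(match(pairs[k, 1], verts))
    b <- root_of(match(pairs[k, 2], verts))
    if (a != b) id[b] <- a
  }
  roots <- vapply(seq_along(verts), root_of, integer(1))
  groups <- unname(split(verts, roots))
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  groups[order(vapply(groups, min, integer(1)))]
}

# --- generalized distance updates ------------------------------------------

# sum of distances among all unordered pairs within group
r_within <- function(dm, group) sum(dm[group, group]) / 2

#' Distance from a new internal node to an outside OTU
#'
#' Generalization of the classic pair update
#' `D_uk = (D_{i1 k} + D_{i2 k})/2 - D_{i1 i2}/2` to a join set I of any
#' size: `D_uk = R_Ik / |I| - R_II / (|I| (|I| - 1))`, where `R_Ik` is the
#' total distance from members of I to k and `R_II` the total within-I
#' distance. For |I| = 2 this reduces exactly to the pair formula.
#'
#' @param dm active distance matrix.
#' @param group integer indices of the join set I (size >= 2).
#' @param k index of an OTU outside the group.
#' @return the updated distance, a scalar.
#' @export
node_otu_distance <- function(dm, group, k) {
  stopifnot(length(group) >= 2, !(k %in% group))
  p <- length(group)
  sum(dm[group, k]) / p - r_within(dm, group) / (p * (p - 1))
}

#' Distance between two new internal nodes created in the same iteration
#'
#' When two disjoint join sets I and J are collapsed simultaneously, the
#' distance between their new nodes u and v is
#' `D_uv = R_IJ / (|I||J|) - R_II / (|I|(|I|-1)) - R_JJ / (|J|(|J|-1))`,
#' the average of `D_ij - L_iu - L_jv` over all cross pairs under the
#' star-tree branch-length identity.
#'
#' @param dm active distance matrix.
#' @param group_i,group_j disjoint integer index sets, each of size >= 2.
#' @return the updated distance, a scalar.
#' @export
node_node_distance <- function(dm, group_i, group_j) {
  stopifnot(length(group_i) >= 2, length(group_j) >= 2,
            length(intersect(group_i, group_j)) == 0)
  p <- length(group_i); q <- length(group_j)
  sum(dm[group_i, group_j]) / (p * q) -
    r_within(dm, group_i) / (p * (p - 1)) -
    r_within(dm, group_j) / (q * (q - 1))
}

#' Branch lengths for a join whose complement is non-empty
#'
#' For each member i of the join set I (with at least one active OTU left
#' outside I, including members of sibling join sets of the same
#' iteration):
#' `L_iu = R_II / (|I|(|I|-1)) + R_iC / (N - |I|) - R_IC / (|I|(N - |I|))`,
#' where C is the complement of I among the N active OTUs. For |I| = 2 this
#' is exactly the classic pair branch-length formula. The lengths satisfy
#' the star-tree conservation identity `sum_i L_iu = R_II / (|I| - 1)`.
#'
#' @param dm active distance matrix (all N active OTUs).
#' @param group integer indices of the join set I, 2 <= |I| < N.
#' @return named numeric vector of branch lengths, one per member.
#' @export
branch_lengths_join <- function(dm, group) {
  n <- nrow(dm)
  p <- length(group)
  stopifnot(p >= 2, p < n)
  comp <- setdiff(seq_len(n), group)
  r_ii <- r_within(dm, group)
  r_ic_each <- rowSums(dm[group, comp, drop = FALSE])
  r_ic <- sum(r_ic_each)
  len <- r_ii / (p * (p - 1)) + r_ic_each / (n - p) - r_ic / (p * (n - p))
  stats::setNames(as.numeric(len), rownames(dm)[group])
}

#' Branch lengths for the final join (empty complement)
#'
#' When the join set I contains all remaining active OTUs the update above
#' is undefined; instead
#' `L_iu = R_iI / (|I| - 2) - R_II / ((|I| - 1)(|I| - 2))`, which for
#' |I| = 3 is the familiar three-point formula
#' `L_1 = (D_12 + D_13 - D_23) / 2`. The conservation identity
#' `sum_i L_iu = R_II / (|I| - 1)` holds here too.
#'
#' @param dm active distance matrix restricted to the group (|I| >= 3).
#' @param group integer indices; must cover all rows of `dm`.
#' @return named numeric vector of branch lengths.
#' @export
branch_lengths_star <- function(dm, group = seq_len(nrow(dm))) {
  p <- length(group)
  stopifnot(p >= 3, p == nrow(dm[group, group, drop = FALSE]))
  sub <- dm[group, group, drop = FALSE]
  r_i <- rowSums(sub)
  r_ii <- sum(sub) / 2
  len <- r_i / (p - 2) - r_ii / ((p - 1) * (p - 2))
  stats::setNames(as.numeric(len), rownames(dm)[group])
}

# --- driver ----------------------------------------------------------------

# internal label for a new node, guaranteed unique among active labels
fresh_label <- function(counter, taxa) {
  lab <- sprintf("node_%d", counter)
  while (lab %in% taxa) lab <- paste0(lab, "_")
  lab
}

# join the given index groups simultaneously; returns updated state + event
apply_join <- function(D, nodes, iteration, groups, node_counter, taxa) {
  n <- nrow(D)
  labels <- rownames(D)
  members <- unlist(groups)
  survivors <- setdiff(seq_len(n), members)
  g_count <- length(groups)
  new_nodes <- vector("list", g_count)
  new_labels <- character(g_count)
  event_groups <- vector("list", g_count)
  for (g in seq_len(g_count)) {
    grp <- groups[[g]]
    len <- branch_lengths_join(D, grp)
    node_counter <- node_counter + 1L
    new_labels[g] <- fresh_label(node_counter, taxa)
    new_nodes[[g]] <- tree_node(children = Map(function(nd, l) {
      nd$length <- l; nd
    }, nodes[grp], as.list(unname(len))))
    event_groups[[g]] <- list(node = new_labels[g],
                              members = labels[grp],
                              lengths = unname(len))
  }
  m <- length(survivors) + g_count
  newD <- matrix(0, m, m)
  newD[seq_along(survivors), seq_along(survivors)] <-
    D[survivors, survivors]
  for (g in seq_len(g_count)) {
    gi <- length(survivors) + g
    for (s in seq_along(survivors)) {
      d <- node_otu_distance(D, groups[[g]], survivors[s])
      newD[gi, s] <- newD[s, gi] <- d
    }
    if (g > 1) for (h in seq_len(g - 1)) {
      d <- node_node_distance(D, groups[[g]], groups[[h]])
      hi <- length(survivors) + h
      newD[gi, hi] <- newD[hi, gi] <- d
    }
  }
  rownames(newD) <- colnames(newD) <- c(labels[survivors], new_labels)
  list(D = newD,
       nodes = c(nodes[survivors], new_nodes),
       node_counter = node_counter,
       event = list(iteration = iteration, groups = event_groups,
                    n_before = n, n_after = m))
}

# final joins: N == 2 single edge, or a star over all remaining OTUs
finalize <- function(D, nodes, iteration) {
  n <- nrow(D)
  labels <- rownames(D)
  if (n == 2) {
    half <- D[1, 2] / 2
    root <- tree_node(children = Map(function(nd, l) { nd$length <- l; nd },
                                     nodes, list(half, half)))
    lens <- c(half, half)
  } else {
    len <- branch_lengths_star(D)
    root <- tree_node(children = Map(function(nd, l) { nd$length <- l; nd },
                                     nodes, as.list(unname(len))))
    lens <- unname(len)
  }
  list(root = root,
       event = list(iteration = iteration,
                    groups = list(list(node = "root", members = labels,
                                       lengths = lens)),
                    n_before = n, n_after = 1L))
}

run_engine <- function(dm, cfg, multifurcating) {
  if (!inherits(dm, "mfnj_dist")) dm <- dist_matrix(as.matrix(dm))
  if (nrow(dm) < 2) stop_input("need at least 2 taxa")
  D <- unclass(dm)
  taxa <- rownames(D)
  nodes <- lapply(taxa, tree_node)
  log <- list()
  node_counter <- 0L
  iteration <- 0L
  repeat {
    iteration <- iteration + 1L
    n <- nrow(D)
    if (n <= 3) {
      fin <- finalize(D, nodes, iteration)
      log[[length(log) + 1L]] <- fin$event
      root <- fin$root
      break
    }
    st <- s_state(D)
    pairs <- tied_min_pairs(st, cfg)
    if (multifurcating) {
      groups <- tie_groups(pairs)
    } else {
      groups <- list(as.integer(pairs[1, ]))  # first_scan tie-break
    }
    if (length(groups) == 1 && length(groups[[1]]) == n) {
      fin <- finalize(D, nodes, iteration)
      log[[length(log) + 1L]] <- fin$event
      root <- fin$root
      break
    }
    step <- apply_join(D, nodes, iteration, groups, node_counter, taxa)
    D <- step$D; nodes <- step$nodes; node_counter <- step$node_counter
    log[[length(log) + 1L]] <- step$event
  }
  tree <- phylo_tree(root)
  if (cfg$negative_branch == "clamp_to_zero") tree <- clamp_tree_lengths(tree)
  structure(list(tree = tree, log = log,
                 method = if (multifurcating) "mfnj" else "nj"),
            class = "mfnj_result")
}

#' Multifurcating neighbor joining
#'
#' Agglomerates a distance matrix into a phylogenetic tree like classic
#' neighbor joining, but when several pairs of OTUs tie for the minimal
#' selection criterion it joins the whole tied group(s) at once, creating a
#' polytomy per group. The output tree is therefore unique and independent
#' of the input order of taxa; when no iteration has a tie it is identical
#' to the classic NJ tree.
#'
#' @param dm a [dist_matrix()] (a plain labeled symmetric matrix is
#'   accepted and validated).
#' @param cfg an [mfnj_config()].
#' @return an `mfnj_result`: list with `tree` (a [phylo_tree()]) and `log`,
#'   the per-iteration join log (1-based iteration index, groups joined
#'   with their new node ids and branch lengths, matrix size before/after).
#' @examples
#' res <- run_mfnj(bear_matrix())
#' to_newick(res$tree)
#' @export
run_mfnj <- function(dm, cfg = mfnj_config()) run_engine(dm, cfg, TRUE)

#' Classic neighbor joining
#'
#' One pair of OTUs is joined per iteration; when several pairs tie for the
#' minimal criterion the `first_scan` policy keeps the pair that comes
#' first by (smaller index, larger index) in the current matrix order, so
#' the result can depend on the input order of taxa (use
#' [enumerate_nj()] to see every outcome, or [run_mfnj()] for the unique
#' polytomic resolution).
#'
#' @inheritParams run_mfnj
#' @return an `mfnj_result`, as for [run_mfnj()].
#' @export
run_nj <- function(dm, cfg = mfnj_config()) run_engine(dm, cfg, FALSE)

#' @export
print.mfnj_result <- function(x, ...) {
  cat(sprintf("%s tree, %d leaves, %d iterations\n",
              toupper(x$method), length(x$tree$tip_labels),
              length(x$log)))
  cat(to_newick(x$tree), "\n")
  invisible(x)
}

#' Write a join log as JSON lines
#'
#' One JSON object per iteration: iteration index, groups joined (new node
#' id, member labels, branch lengths), and active OTU counts before and
#' after.
#'
#' @param log the `log` element of an `mfnj_result`.
#' @param sink file path or connection.
#' @return the JSON lines, invisibly.
#' @export
write_join_log <- function(log, sink = NULL) {
  lines <- vapply(log, function(ev) {
    jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA)
  }, character(1))
  if (!is.null(sink)) writeLines(lines, sink)
  invisible(lines)
}
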