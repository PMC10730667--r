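# Naive reference implementation used as an independent oracle.
#
# Deliberately different computational route from the engine:
#   * R and S recomputed with explicit scalar loops (no vectorization),
#   * tie groups found by boolean-matrix transitive closure (engine: union-find),
#   * distance updates through the averaging forms
#       D_uk = mean_i (D_ik - L_iu)
#       D_uv = mean_{i,j} (D_ij - L_iu - L_jv)
#     (engine: the closed-form R_Ik / R_IJ expressions),
#   * branch lengths as literal loop translations of the formulas.

oracle_branch_nonfinal <- function(D, grp) {
  n <- nrow(D)
  p <- length(grp)
  comp <- setdiff(seq_len(n), grp)
  r_ii <- 0
  for (i in grp) for (j in grp) if (j > i) r_ii <- r_ii + D[i, j]
  r_iic <- 0
  for (i in grp) for (k in comp) r_iic <- r_iic + D[i, k]
  vapply(grp, function(i) {
    r_ic <- 0
    for (k in comp) r_ic <- r_ic + D[i, k]
    r_ii / (p * (p - 1)) + r_ic / (n - p) - r_iic / (p * (n - p))
  }, numeric(1))
}

oracle_branch_final <- function(D) {
  n <- nrow(D)
  r_ii <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) r_ii <- r_ii + D[i, j]
  vapply(seq_len(n), function(i) {
    r_i <- 0
    for (j in seq_len(n)) if (j != i) r_i <- r_i + D[i, j]
    r_i / (n - 2) - r_ii / ((n - 1) * (n - 2))
  }, numeric(1))
}

oracle_tied_pairs <- function(D, rtol = 1e-9, atol = 1e-12) {
  n <- nrow(D)
  R <- numeric(n)
  for (i in seq_len(n)) for (k in seq_len(n)) R[i] <- R[i] + D[i, k]
  smin <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- (n - 2) * D[i, j] - R[i] - R[j]
    if (s < smin) smin <- s
  }
  thr <- smin + atol + rtol * abs(smin)
  pairs <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- (n - 2) * D[i, j] - R[i] - R[j]
    if (s <= thr) pairs <- rbind(pairs, c(i, j))
  }
  list(s_min = smin, pairs = pairs)
}

# connected components of the tied-pair graph via transitive closure
oracle_components <- function(pairs, n) {
  A <- diag(n) > 0
  for (k in seq_len(nrow(pairs))) {
    A[pairs[k, 1], pairs[k, 2]] <- TRUE
    A[pairs[k, 2], pairs[k, 1]] <- TRUE
  }
  for (r in seq_len(ceiling(log2(n)) + 1)) A <- (A %*% A) > 0
  involved <- sort(unique(as.vector(pairs)))
  comps <- unique(lapply(involved, function(v) which(A[v, ])))
  comps[order(vapply(comps, min, integer(1)))]
}

oracle_run <- function(D, multifurcating = TRUE, rtol = 1e-9, atol = 1e-12) {
  D <- unclass(D)
  nodes <- lapply(rownames(D), tree_node)
  log <- list()
  counter <- 0L
  iteration <- 0L
  attach_kids <- function(kids, lens) {
    Map(function(nd, l) { nd$length <- l; nd }, kids, as.list(lens))
  }
  repeat {
    iteration <- iteration + 1L
    n <- nrow(D)
    if (n == 2) {
      lens <- c(D[1, 2] / 2, D[1, 2] / 2)
      root <- tree_node(children = attach_kids(nodes, lens))
      log[[iteration]] <- list(iteration = iteration, groups = list(
        list(node = "root", members = rownames(D), lengths = lens)))
      break
    }
    if (n == 3) {
      lens <- oracle_branch_final(D)
      root <- tree_node(children = attach_kids(nodes, lens))
      log[[iteration]] <- list(iteration = iteration, groups = list(
        list(node = "root", members = rownames(D), lengths = lens)))
      break
    }
    tied <- oracle_tied_pairs(D, rtol, atol)
    groups <- if (multifurcating) {
      oracle_components(tied$pairs, n)
    } else {
      list(tied$pairs[1, ])
    }
    if (length(groups) == 1 && length(groups[[1]]) == n) {
      lens <- oracle_branch_final(D)
      root <- tree_node(children = attach_kids(nodes, lens))
      log[[iteration]] <- list(iteration = iteration, groups = list(
        list(node = "root", members = rownames(D), lengths = lens)))
      break
    }
    lens_by_group <- lapply(groups, function(g) oracle_branch_nonfinal(D, g))
    survivors <- setdiff(seq_len(n), unlist(groups))
    g_count <- length(groups)
    m <- length(survivors) + g_count
    newD <- matrix(0, m, m)
    newD[seq_along(survivors), seq_along(survivors)] <-
      D[survivors, survivors]
    new_labels <- character(g_count)
    new_nodes <- vector("list", g_count)
    ev_groups <- vector("list", g_count)
    for (g in seq_len(g_count)) {
      counter <- counter + 1L
      new_labels[g] <- sprintf("oracle_%d", counter)
      grp <- groups[[g]]
      L <- lens_by_group[[g]]
      gi <- length(survivors) + g
      for (s in seq_along(survivors)) {
        k <- survivors[s]
        acc <- 0
        for (t in seq_along(grp)) acc <- acc + D[grp[t], k] - L[t]
        newD[gi, s] <- newD[s, gi] <- acc / length(grp)
      }
      if (g > 1) for (h in seq_len(g - 1)) {
        grp2 <- groups[[h]]; L2 <- lens_by_group[[h]]
        acc <- 0
        for (t in seq_along(grp)) for (t2 in seq_along(grp2)) {
          acc <- acc + D[grp[t], grp2[t2]] - L[t] - L2[t2]
        }
        hi <- length(survivors) + h
        newD[gi, hi] <- newD[hi, gi] <- acc / (length(grp) * length(grp2))
      }
      new_nodes[[g]] <- tree_node(children = attach_kids(nodes[grp], L))
      ev_groups[[g]] <- list(node = new_labels[g],
                             members = rownames(D)[grp], lengths = L)
    }
    rownames(newD) <- colnames(newD) <- c(rownames(D)[survivors], new_labels)
    log[[iteration]] <- list(iteration = iteration, groups = ev_groups)
    nodes <- c(nodes[survivors], new_nodes)
    D <- newD
  }
  list(tree = phylo_tree(root), log = log)
}

# exhaustive enumeration over every tied-pair choice sequence (oracle for
# enumerate_nj at small n); returns the set of split-set signatures
oracle_enumerate_sigs <- function(D) {
  D <- unclass(D)
  sigs <- character(0)
  rec <- function(D, nodes) {
    n <- nrow(D)
    if (n <= 3) {
      lens <- if (n == 2) rep(D[1, 2] / 2, 2) else oracle_branch_final(D)
      root <- tree_node(children = Map(function(nd, l) {
        nd$length <- l; nd
      }, nodes, as.list(lens)))
      sigs <<- union(sigs, paste(tree_splits(phylo_tree(root)),
                                 collapse = ";"))
      return(invisible(NULL))
    }
    tied <- oracle_tied_pairs(D)
    for (k in seq_len(nrow(tied$pairs))) {
      grp <- tied$pairs[k, ]
      L <- oracle_branch_nonfinal(D, grp)
      survivors <- setdiff(seq_len(n), grp)
      m <- length(survivors) + 1L
      newD <- matrix(0, m, m)
      newD[seq_along(survivors), seq_along(survivors)] <-
        D[survivors, survivors]
      for (s in seq_along(survivors)) {
        kk <- survivors[s]
        newD[m, s] <- newD[s, m] <-
          (D[grp[1], kk] - L[1] + D[grp[2], kk] - L[2]) / 2
      }
      rownames(newD) <- colnames(newD) <-
        c(rownames(D)[survivors], paste0("e", n, "_", k))
      u <- tree_node(children = Map(function(nd, l) { nd$length <- l; nd },
                                    nodes[grp], as.list(L)))
      rec(newD, c(nodes[survivors], list(u)))
    }
    invisible(NULL)
  }
  rec(D, lapply(rownames(D), tree_node))
  sigs
}

# canonical per-iteration join signature: each joined group as the sorted
# leaf sets of its members, so engine and oracle logs compare despite
# different internal node naming
log_leaf_signature <- function(log, taxa) {
  leafset <- as.list(stats::setNames(taxa, taxa))
  out <- vector("list", length(log))
  for (e in seq_along(log)) {
    ev <- log[[e]]
    sigs <- vapply(ev$groups, function(g) {
      member_sets <- vapply(g$members, function(m) {
        paste(sort(leafset[[m]]), collapse = ",")
      }, character(1))
      whole <- sort(unlist(lapply(g$members, function(m) leafset[[m]])))
      leafset[[g$node]] <<- whole
      paste(sort(member_sets), collapse = " + ")
    }, character(1))
    out[[e]] <- sort(sigs)
  }
  out
}

all_branch_lengths <- function(tree) {
  rec <- function(node) {
    c(if (!is.na(node$length)) node$length,
      unlist(lapply(node$children, rec)))
  }
  out <- rec(tree$root)
  if (is.null(out)) numeric(0) else out
}
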