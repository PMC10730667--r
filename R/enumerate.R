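#' Enumerate every classic-NJ tie-break outcome
#'
#' Depth-first exploration of every choice of tied minimal pair at every
#' iteration of classic neighbor joining. The resulting trees are
#' deduplicated by their unrooted split sets and reported in order of first
#' discovery (the exploration is lexicographic in the choice sequence, so
#' the order is deterministic). On a tie-free matrix this returns exactly
#' the single [run_nj()] tree; on the nine-bear matrix it returns the two
#' alternative dichotomous trees that motivate the multifurcating variant.
#'
#' @inheritParams run_mfnj
#' @return an `mfnj_enum`: list with `trees` (list of [phylo_tree()]),
#'   `truncated` (`TRUE` if `cfg$enum_cap` distinct trees — or an internal
#'   path budget — was hit before the search finished) and `n_paths`, the
#'   number of complete choice sequences explored.
#' @export
enumerate_nj <- function(dm, cfg = mfnj_config()) {
  if (!inherits(dm, "mfnj_dist")) dm <- dist_matrix(as.matrix(dm))
  if (nrow(dm) < 3) stop_input("enumeration needs at least 3 taxa")
  taxa <- rownames(dm)
  acc <- new.env(parent = emptyenv())
  acc$trees <- list()
  acc$sigs <- character(0)
  acc$truncated <- FALSE
  acc$paths <- 0L
  max_paths <- 100000L  # safety valve for pathological all-tied matrices
  rec <- function(D, nodes, counter) {
    if (acc$truncated) return(invisible(NULL))
    n <- nrow(D)
    if (n <= 3) {
      acc$paths <- acc$paths + 1L
      if (acc$paths > max_paths) {
        acc$truncated <- TRUE
        return(invisible(NULL))
      }
      tree <- phylo_tree(finalize(D, nodes, 0L)$root)
      if (cfg$negative_branch == "clamp_to_zero") {
        tree <- clamp_tree_lengths(tree)
      }
      sig <- paste(tree_splits(tree), collapse = ";")
      if (!(sig %in% acc$sigs)) {
        if (length(acc$trees) >= cfg$enum_cap) {
          acc$truncated <- TRUE
          return(invisible(NULL))
        }
        acc$sigs <- c(acc$sigs, sig)
        acc$trees[[length(acc$trees) + 1L]] <- tree
      }
      return(invisible(NULL))
    }
    pairs <- tied_min_pairs(s_state(D), cfg)
    for (k in seq_len(nrow(pairs))) {
      if (acc$truncated) break
      step <- apply_join(D, nodes, 0L, list(as.integer(pairs[k, ])),
                         counter, taxa)
      rec(step$D, step$nodes, step$node_counter)
    }
    invisible(NULL)
  }
  rec(unclass(dm), lapply(taxa, tree_node), 0L)
  structure(list(trees = acc$trees, truncated = acc$truncated,
                 n_paths = acc$paths),
            class = "mfnj_enum")
}

#' @export
print.mfnj_enum <- function(x, ...) {
  cat(sprintf("%d distinct unrooted topolog%s (%d tie-break paths%s)\n",
              length(x$trees), if (length(x$trees) == 1) "y" else "ies",
              x$n_paths, if (x$truncated) ", truncated" else ""))
  for (tr in x$trees) cat(to_newick(tr), "\n")
  invisible(x)
}
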