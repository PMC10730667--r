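#' Specification for the random-tree generator
#'
#' Describes the ground-truth trees used in the test suite: random
#' coalescent-style labeled trees with branch lengths drawn from
#' `length_dist` (default uniform on \[0.5, 5\], a generic choice that makes
#' selection-criterion ties measure-zero), optional multifurcations
#' generated at construction time (not by collapsing short edges, so
#' polytomy ground truth is exact), and optional symmetric Gaussian noise
#' on the pairwise distances.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param polytomy_prob probability that a coalescence event merges more
#'   than two lineages.
#' @param length_dist function of `n` returning `n` branch lengths.
#' @param noise_sd standard deviation of additive Gaussian perturbation
#'   applied per unordered pair by [perturb()].
#' @param seed optional random seed; generation is fully reproducible from
#'   `(spec, seed)`.
#' @return a list of class `mfnj_genspec`.
#' @export
generator_spec <- function(n_leaves, polytomy_prob = 0,
                           length_dist = function(n) stats::runif(n, 0.5, 5),
                           noise_sd = 0, seed = NULL) {
  stopifnot(n_leaves >= 2, polytomy_prob >= 0, polytomy_prob <= 1,
            noise_sd >= 0, is.function(length_dist))
  structure(list(n_leaves = as.integer(n_leaves),
                 polytomy_prob = polytomy_prob,
                 length_dist = length_dist,
                 noise_sd = noise_sd, seed = seed),
            class = "mfnj_genspec")
}

#' Random labeled tree with known branch lengths
#'
#' Coalescent-style construction: start from `n_leaves` lineages labeled
#' `t1..tn`; repeatedly merge a random set of lineages (size 2, or 3+ with
#' probability `polytomy_prob`) into a new internal node, drawing one
#' branch length per merged lineage, until one lineage remains.
#'
#' @param spec a [generator_spec()].
#' @return a [phylo_tree()].
#' @export
random_tree <- function(spec) {
  stopifnot(inherits(spec, "mfnj_genspec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_leaves
  lineages <- lapply(paste0("t", seq_len(n)), tree_node)
  if (n == 2) {
    len <- spec$length_dist(2)
    root <- tree_node(children = Map(function(nd, l) { nd$length <- l; nd },
                                     lineages, as.list(len)))
    return(phylo_tree(root))
  }
  while (length(lineages) > 1) {
    m <- length(lineages)
    k <- if (m >= 3 && stats::runif(1) < spec$polytomy_prob) {
      sample(3:m, 1)
    } else {
      2L
    }
    k <- min(k, m)
    pick <- sample.int(m, k)
    len <- spec$length_dist(k)
    merged <- tree_node(children = Map(function(nd, l) { nd$length <- l; nd },
                                       lineages[pick], as.list(len)))
    lineages <- c(lineages[-pick], list(merged))
  }
  phylo_tree(lineages[[1]])
}

#' Additive distance matrix of a tree
#'
#' `D_ij` is the sum of branch lengths on the path between leaves i and j,
#' so the matrix is an additive (tree) metric by construction; on such
#' matrices neighbor joining provably recovers the generating tree.
#'
#' @param tree a [phylo_tree()] with non-negative branch lengths.
#' @return a [dist_matrix()] over the tree's leaves, in tip-label order.
#' @export
additive_matrix <- function(tree) {
  g <- unrooted_graph(tree)
  if (anyNA(g$edges$len)) stop_input("tree has missing branch lengths")
  if (any(g$edges$len < 0)) stop_input("tree has negative branch lengths")
  nv <- length(g$vlabel)
  adj <- vector("list", nv)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$a[i]; b <- g$edges$b[i]; l <- g$edges$len[i]
    adj[[a]] <- rbind(adj[[a]], c(b, l))
    adj[[b]] <- rbind(adj[[b]], c(a, l))
  }
  labels <- tree$tip_labels
  leaf_v <- match(labels, g$vlabel)
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (s in seq_len(n)) {
    # single-source path lengths over the (acyclic) edge set
    dist <- rep(NA_real_, nv)
    from <- rep(NA_integer_, nv)
    v0 <- leaf_v[s]
    dist[v0] <- 0
    queue <- v0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nbr <- adj[[v]]
      for (r in seq_len(NROW(nbr))) {
        w <- as.integer(nbr[r, 1])
        if (!is.na(from[v]) && w == from[v]) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + nbr[r, 2]
          from[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist[leaf_v]
  }
  dist_matrix((D + t(D)) / 2, labels)
}

#' Star-tree distance matrix
#'
#' `D_ij = l_i + l_j`: the additive matrix of a star tree in which every
#' taxon hangs off one central node at distance `l_i`. On such a matrix
#' every pair ties for the minimal selection criterion, so multifurcating
#' neighbor joining collapses the whole matrix into a single polytomy in
#' one iteration, recovering the `l_i` exactly.
#'
#' @param lengths positive branch lengths, at least 3.
#' @param labels taxon labels (default `t1..tn`).
#' @return a [dist_matrix()].
#' @export
star_matrix <- function(lengths, labels = paste0("t", seq_along(lengths))) {
  if (length(lengths) < 3) stop_input("a star matrix needs at least 3 taxa")
  stopifnot(all(lengths > 0))
  D <- outer(lengths, lengths, "+")
  diag(D) <- 0
  dist_matrix(D, labels)
}

#' Perturb a distance matrix with symmetric Gaussian noise
#'
#' One Gaussian draw per unordered pair is added to both mirror entries, so
#' symmetry holds by construction; the diagonal is untouched and results
#' below a small positive floor (1e-6) are clamped to it. Useful to make a
#' matrix tie-free: after generic perturbation, classic and multifurcating
#' neighbor joining agree.
#'
#' @param dm a [dist_matrix()].
#' @param noise_sd standard deviation of the noise; 0 returns `dm`.
#' @param seed optional seed for reproducibility.
#' @return a [dist_matrix()].
#' @export
perturb <- function(dm, noise_sd, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(dm)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dm)
  out <- unclass(dm)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- out[i, j] + stats::rnorm(1, sd = noise_sd)
      out[i, j] <- out[j, i] <- max(v, 1e-6)
    }
  }
  dist_matrix(out, rownames(dm))
}
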