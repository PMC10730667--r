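test_that("s_state matches brute-force evaluation of the selection criterion", {
  # equilateral 3-taxon: every pair forced equal
  eq3 <- dist_matrix(matrix(2, 3, 3) - diag(2, 3), c("A", "B", "C"))
  st <- s_state(eq3)
  expect_equal(unname(st$row_sums), c(4, 4, 4))
  expect_equal(st$s_min, -6)
  expect_true(all(abs(st$s_values[upper.tri(st$s_values)] + 6) < 1e-12))

  # bear matrix, iteration 1: exhaustive independent scan
  bears <- bear_matrix()
  st <- s_state(bears)
  tied <- oracle_tied_pairs(unclass(bears))
  expect_equal(st$s_min, tied$s_min, tolerance = 1e-12)
  expect_equal(st$s_min, -57.7)  # frozen from exact-rational evaluation
  pairs <- tied_min_pairs(st)
  expect_identical(nrow(pairs), nrow(tied$pairs))
  expect_identical(rownames(bears)[pairs[1, ]], c("Kodiak", "Captive-3"))

  # star-tree additive matrix: all pairs tie at S = -2 * sum(l)
  l <- c(1, 2, 3, 4)
  st <- s_state(star_matrix(l))
  expect_true(all(abs(st$s_values[upper.tri(st$s_values)] + 2 * sum(l)) <
                    1e-12))
  expect_equal(nrow(tied_min_pairs(st)), 6)

  # random matrices: engine S minimum equals the loop oracle
  for (seed in 1:10) {
    D <- random_dist(4 + (seed %% 7), seed = seed)
    expect_equal(s_state(D)$s_min, oracle_tied_pairs(unclass(D))$s_min,
                 tolerance = 1e-12)
  }
})

test_that("tied pair detection respects tolerances and scan-order freedom", {
  st <- list(s_values = matrix(c(Inf, -6, -6, -6, Inf, -6, -6, -6, Inf), 3),
             s_min = -6)
  expect_equal(nrow(tied_min_pairs(st)), 3)

  st <- list(s_values = matrix(c(Inf, -10, -5, -10, Inf, -2, -5, -2, Inf), 3),
             s_min = -10)
  expect_identical(tied_min_pairs(st), matrix(c(1L, 2L), 1))
})

test_that("tie groups are connected components, ordered and disjoint", {
  expect_identical(tie_groups(rbind(c(1L, 2L), c(2L, 3L))), list(1:3))
  expect_identical(tie_groups(rbind(c(1L, 2L), c(3L, 4L))),
                   list(c(1L, 2L), c(3L, 4L)))
  expect_identical(tie_groups(matrix(c(4L, 7L), 1)), list(c(4L, 7L)))
  # chains merge transitively and match the closure oracle
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:12, 1)
    k <- sample(1:6, 1)
    pairs <- unique(t(replicate(k, sort(sample.int(n, 2)))))
    got <- tie_groups(pairs)
    want <- oracle_components(pairs, n)
    expect_identical(got, lapply(want, as.integer))
    expect_identical(anyDuplicated(unlist(got)), 0L)
  }
})

test_that("node-OTU distance generalizes the classic pair update", {
  D <- dist_matrix(matrix(c(0, 4, 5,
                            4, 0, 7,
                            5, 7, 0), 3, 3), c("i1", "i2", "k"))
  expect_equal(node_otu_distance(D, 1:2, 3), 4)  # (5+7)/2 - 4/2

  sym <- matrix(2, 4, 4) - diag(2, 4)
  sym[4, 1:3] <- sym[1:3, 4] <- 10; sym[4, 4] <- 0
  expect_equal(node_otu_distance(dist_matrix(sym, c("a", "b", "c", "k")),
                                 1:3, 4), 9)

  # star matrix: new node sits at the center, D_uk = l_k
  l <- c(1, 2, 3, 4, 5)
  sm <- star_matrix(l)
  for (sz in 2:4) {
    expect_equal(node_otu_distance(sm, seq_len(sz), 5), l[5],
                 tolerance = 1e-12)
  }

  # |I| = 2 reduces to the pair formula on random matrices
  for (seed in 1:40) {
    D <- random_dist(4 + (seed %% 6), seed = 100 + seed)
    n <- nrow(D)
    ij <- sort(sample.int(n, 2))
    k <- sample(setdiff(seq_len(n), ij), 1)
    eq3 <- (D[ij[1], k] + D[ij[2], k]) / 2 - D[ij[1], ij[2]] / 2
    expect_equal(node_otu_distance(D, ij, k), eq3, tolerance = 1e-12)
  }
  expect_error(node_otu_distance(sm, 1:2, 2))
})

test_that("node-node distance matches the averaging-form oracle", {
  D <- matrix(10, 4, 4) - diag(10, 4)
  D[1, 2] <- D[2, 1] <- 2
  D[3, 4] <- D[4, 3] <- 4
  dm <- dist_matrix(D, paste0("t", 1:4))
  expect_equal(node_node_distance(dm, 1:2, 3:4), 7)  # 40/4 - 1 - 2

  l <- c(1, 2, 3, 4, 5, 6)
  sm <- star_matrix(l)
  expect_equal(node_node_distance(sm, 1:3, 4:6), 0, tolerance = 1e-12)
  expect_equal(node_node_distance(sm, c(1, 4), c(2, 5, 6)), 0,
               tolerance = 1e-12)

  # equality with the mean of (D_ij - L_iu - L_jv) on random matrices
  for (seed in 1:40) {
    D <- random_dist(5 + (seed %% 5), seed = 200 + seed)
    n <- nrow(D)
    gi <- 1:2
    gj <- 3:min(5, n - 0)
    li <- branch_lengths_join(D, gi)
    lj <- branch_lengths_join(D, gj)
    acc <- 0
    for (a in seq_along(gi)) for (b in seq_along(gj)) {
      acc <- acc + D[gi[a], gj[b]] - li[[a]] - lj[[b]]
    }
    expect_equal(node_node_distance(D, gi, gj),
                 acc / (length(gi) * length(gj)), tolerance = 1e-9)
  }
  expect_error(node_node_distance(dm, 1:2, 2:3))
})

test_that("branch lengths: additive recovery, conservation, reductions", {
  # exact recovery on the 4-taxon additive matrix
  L <- branch_lengths_join(tree4_matrix(), 1:2)
  expect_equal(unname(L), c(1, 2), tolerance = 1e-12)

  # three-point final formula
  D3 <- dist_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), c("a", "b", "c"))
  expect_equal(unname(branch_lengths_star(D3)), c(1, 2, 3), tolerance = 1e-12)
  eq3 <- dist_matrix(matrix(2, 3, 3) - diag(2, 3), c("A", "B", "C"))
  expect_equal(unname(branch_lengths_star(eq3)), c(1, 1, 1))

  # star matrix over all N: exact leaf lengths
  l <- c(1, 2, 3, 4, 5)
  expect_equal(unname(branch_lengths_star(star_matrix(l))), l,
               tolerance = 1e-12)

  # bear first join equals the classic pair formula evaluated directly
  bears <- unclass(bear_matrix())
  got <- branch_lengths_join(bear_matrix(), c(3, 4))  # Kodiak, Captive-3
  expect_equal(unname(got), c(0.35, 0.35), tolerance = 1e-12)

  expect_error(branch_lengths_join(tree4_matrix(), 1:4))
  expect_error(branch_lengths_star(D3, 1:2))
})

test_that("conservation and reduction identities hold on random matrices", {
  # acceptance-scale property suite: 1000 random matrices
  set.seed(42)
  max_red <- 0
  max_cons <- 0
  for (rep in 1:1000) {
    n <- sample(4:9, 1)
    D <- random_dist(n)
    ij <- sort(sample.int(n, 2))
    k <- sample(setdiff(seq_len(n), ij), 1)

    # |I| = 2 node-OTU update vs classic pair update
    eq3 <- (D[ij[1], k] + D[ij[2], k]) / 2 - D[ij[1], ij[2]] / 2
    max_red <- max(max_red, abs(node_otu_distance(D, ij, k) - eq3))

    # |I| = 2 branch lengths vs classic pair branch lengths
    comp <- setdiff(seq_len(n), ij)
    ric <- sum(D[ij[1], comp]); rIc <- sum(D[ij, comp])
    eq4 <- D[ij[1], ij[2]] / 2 + ric / (n - 2) - rIc / (2 * (n - 2))
    L2 <- branch_lengths_join(D, ij)
    max_red <- max(max_red, abs(L2[1] - eq4),
                   abs(L2[2] - (D[ij[1], ij[2]] - eq4)))

    # |I| = 3 final star vs three-point formula
    tri <- sort(sample.int(n, 3))
    sub <- D[tri, tri]
    eq7 <- (sub[1, 2] + sub[1, 3] - sub[2, 3]) / 2
    L3 <- branch_lengths_star(dist_matrix(sub, paste0("x", 1:3)))
    max_red <- max(max_red, abs(L3[1] - eq7))

    # conservation: sum of branch lengths = R_II / (|I| - 1)
    p <- sample(2:(n - 1), 1)
    grp <- sort(sample.int(n, p))
    Lg <- branch_lengths_join(D, grp)
    r_ii <- sum(D[grp, grp]) / 2
    target <- r_ii / (p - 1)
    max_cons <- max(max_cons, abs(sum(Lg) - target) / max(1, abs(target)))
  }
  expect_lt(max_red, 1e-12)
  expect_lt(max_cons, 1e-9)
})

test_that("classic NJ: terminal star, additive recovery, ape agreement", {
  D3 <- dist_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3), c("A", "B", "C"))
  res <- run_nj(D3)
  expect_identical(to_newick(res$tree), "(A:1,B:2,C:3);")

  res4 <- run_nj(tree4_matrix())
  truth <- read_newick(tree4_newick)
  expect_true(same_unrooted_topology(res4$tree, truth))
  lab <- rownames(tree4_matrix())
  expect_lt(max(abs(additive_matrix(res4$tree)[lab, lab] - tree4_matrix())),
            1e-9)

  # tie-free random matrices: agreement with ape's independent NJ
  for (seed in 1:10) {
    D <- perturb(random_dist(5 + (seed %% 6), seed = seed), 0.01,
                 seed = seed + 1000)
    ours <- run_nj(D)$tree
    apes <- as_phylo_tree(ape::root(ape::nj(stats::as.dist(unclass(D))),
                                    rownames(D)[1], resolve.root = TRUE))
    expect_true(same_unrooted_topology(ours, apes))
  }

  expect_error(run_nj(dist_matrix(matrix(0, 1, 1), "A")),
               class = "mfnj_validation_error")
})

test_that("MFNJ equals NJ on tie-free input and resolves stars in one step", {
  for (seed in 1:10) {
    D <- perturb(random_dist(5 + (seed %% 8), seed = 300 + seed), 0.01,
                 seed = seed)
    a <- run_mfnj(D)
    b <- run_nj(D)
    expect_true(same_unrooted_topology(a$tree, b$tree))
    # compare unrooted edge lengths: when MFNJ reaches exactly 4 OTUs the
    # selection criterion structurally ties a pair with its complement, so
    # MFNJ finishes 4 -> 2 -> 1 and roots on a degree-2 node while NJ ends
    # in a 3-star; the unrooted trees coincide
    expect_equal(unrooted_edge_lengths(a$tree),
                 unrooted_edge_lengths(b$tree), tolerance = 1e-9)
  }

  l <- c(1.5, 2.25, 3, 4.5, 5.25, 6)
  res <- run_mfnj(star_matrix(l))
  expect_length(res$log, 1)                      # single iteration
  expect_length(res$tree$root$children, 6)       # one degree-6 polytomy
  expect_length(tree_splits(res$tree), 0)
  got <- vapply(res$tree$root$children, function(k) k$length, numeric(1))
  labs <- vapply(res$tree$root$children, function(k) k$label, character(1))
  expect_equal(got[order(labs)], l[order(paste0("t", 1:6))],
               tolerance = 1e-9)
})

test_that("simultaneous disjoint joins produce two nodes and a midpoint edge", {
  D <- matrix(10, 4, 4) - diag(10, 4)
  D[1, 2] <- D[2, 1] <- 2
  D[3, 4] <- D[4, 3] <- 4
  res <- run_mfnj(dist_matrix(D, c("a", "b", "c", "d")))
  expect_length(res$log, 2)
  expect_length(res$log[[1]]$groups, 2)          # both pairs tie, joined at once
  expect_identical(res$log[[1]]$n_after, 2L)
  lab <- c("a", "b", "c", "d")
  expect_lt(max(abs(additive_matrix(res$tree)[lab, lab] - D)), 1e-9)
  expect_identical(tree_splits(res$tree), "c|d")
})

test_that("negative-branch policy clamps only the serialized tree", {
  D <- bear_matrix()
  keep <- run_mfnj(D)
  clamp <- run_mfnj(D, mfnj_config(negative_branch = "clamp_to_zero"))
  expect_lt(min(all_branch_lengths(keep$tree)), 0)
  expect_gte(min(all_branch_lengths(clamp$tree)), 0)
  expect_true(same_unrooted_topology(keep$tree, clamp$tree))
  expect_identical(log_leaf_signature(keep$log, rownames(D)),
                   log_leaf_signature(clamp$log, rownames(D)))
})

test_that("engine agrees with the naive reference implementation", {
  taxa_of <- function(D) rownames(D)
  for (seed in 1:60) {
    D <- random_dist(4 + (seed %% 9), seed = 400 + seed)
    eng <- run_mfnj(D)
    ora <- oracle_run(unclass(D), multifurcating = TRUE)
    expect_true(same_unrooted_topology(eng$tree, ora$tree))
    expect_equal(sort(all_branch_lengths(eng$tree)),
                 sort(all_branch_lengths(ora$tree)), tolerance = 1e-9)
    expect_identical(log_leaf_signature(eng$log, taxa_of(D)),
                     log_leaf_signature(ora$log, taxa_of(D)))
  }
  # tie-rich inputs exercise the grouping path
  for (l_seed in 1:5) {
    set.seed(500 + l_seed)
    l <- sample(1:5, 7, replace = TRUE) / 2
    sm <- star_matrix(l)
    eng <- run_mfnj(sm)
    ora <- oracle_run(unclass(sm), multifurcating = TRUE)
    expect_true(same_unrooted_topology(eng$tree, ora$tree))
    expect_equal(sort(all_branch_lengths(eng$tree)),
                 sort(all_branch_lengths(ora$tree)), tolerance = 1e-9)
  }
  bears <- bear_matrix()
  eng <- run_mfnj(bears)
  ora <- oracle_run(unclass(bears))
  expect_identical(log_leaf_signature(eng$log, rownames(bears)),
                   log_leaf_signature(ora$log, rownames(bears)))
  expect_equal(sort(all_branch_lengths(eng$tree)),
               sort(all_branch_lengths(ora$tree)), tolerance = 1e-9)
})

test_that("active matrix stays symmetric with zero diagonal along the run", {
  # replay the engine's own updates via public ops on a tie-rich matrix
  D <- unclass(star_matrix(c(1, 1, 2, 2, 3)))
  res <- run_mfnj(dist_matrix(D, rownames(D)))
  for (ev in res$log) {
    expect_true(ev$n_after < ev$n_before)
    expect_identical(ev$n_after,
                     ev$n_before - sum(lengths(lapply(ev$groups,
                                                      `[[`, "members")) - 1L))
  }
})
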