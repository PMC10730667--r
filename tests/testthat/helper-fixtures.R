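# shared fixtures, all built in code

# random labeled symmetric matrix with uniform off-diagonal distances
random_dist <- function(n, seed = NULL, lo = 1, hi = 10) {
  if (!is.null(seed)) set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, lo, hi)
  D <- D + t(D)
  dist_matrix(D, paste0("t", seq_len(n)))
}

# the 4-taxon caterpillar ((A:1,B:2):1,(C:3,D:4)); path-sum distances entered
# by hand: D_AB=3, D_AC=5, D_AD=6, D_BC=6, D_BD=7, D_CD=7
tree4_newick <- "((A:1,B:2):1,(C:3,D:4):0);"
tree4_matrix <- function() {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, byrow = TRUE)
  dist_matrix(D, c("A", "B", "C", "D"))
}
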