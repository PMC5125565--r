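# Brute-force enumeration oracles for the nonparametric tests, and a greedy
# centroid-matching helper shared by the detection tests. These are kept
# deliberately independent of the package implementations.

# Wilcoxon signed-rank: enumerate all 2^n sign assignments of the rank
# vector; two-sided p doubles the smaller tail of W+.
wsr_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(wall <= wobs), mean(wall >= wobs)))
}

# Mann-Whitney U: enumerate all choose(nA+nB, nA) group labelings; doubled
# smaller tail of U_A.
mwu_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uobs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  uall <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(uall <= uobs), mean(uall >= uobs)))
}

# Single-linkage clustering oracle: transitive closure of the adjacency
# relation dist <= r_link via repeated boolean matrix products.
single_linkage_oracle <- function(x, y, r_link) {
  n <- length(x)
  adj <- as.matrix(dist(cbind(x, y))) <= r_link
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# Greedy nearest matching of detections to ground truth within a tolerance.
match_centroids <- function(det_x, det_y, truth_x, truth_y, tol_um) {
  used <- rep(FALSE, length(truth_x))
  hits <- integer(0)   # truth index matched by each accepted detection
  det_hit <- rep(NA_integer_, length(det_x))
  for (i in seq_along(det_x)) {
    d2 <- (truth_x - det_x[i])^2 + (truth_y - det_y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol_um^2) {
      used[j] <- TRUE
      det_hit[i] <- j
      hits <- c(hits, j)
    }
  }
  list(n_matched = length(hits),
       precision = if (length(det_x)) length(hits) / length(det_x) else 0,
       recall = if (length(truth_x)) length(hits) / length(truth_x) else 0,
       det_hit = det_hit)
}
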