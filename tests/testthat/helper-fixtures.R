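# Shared fixtures: small phantoms and simple tensor fields built in code.

# Compact phantom (32 x 32 x 16) for fast module tests.
small_phantom_spec <- function(noise = "none", seed = 1L, ...) {
  phantom_spec(shape = c(32L, 32L, 16L), proj_offset = 4L, assoc_offset = 9L,
               extent = c(3L, 3L, 3L), noise = noise, seed = seed, ...)
}

# Uniform diagonal tensor field as a tensor_volume.
uniform_field <- function(d = c(1e-3, 1e-3, 1e-3), shape = c(8L, 8L, 4L),
                          voxel = c(1, 1, 1)) {
  alpscog:::tensor_volume_from_diag(array(d[1], shape), array(d[2], shape),
                                    array(d[3], shape), voxel)
}

# One-voxel DWI volume with noise-free signal from a full symmetric tensor.
single_voxel_dwi <- function(D, bval = 1000, s0 = 1000,
                             dirs = gradient_table_64()) {
  sig <- c(s0, vapply(seq_len(ncol(dirs)), function(j) {
    g <- dirs[, j]
    s0 * exp(-bval * drop(t(g) %*% D %*% g))
  }, numeric(1)))
  dwi_volume(array(sig, c(1, 1, 1, length(sig))), c(2, 2, 2),
             c(0, rep(bval, ncol(dirs))), cbind(c(0, 0, 0), dirs))
}

# Independent connected-component oracle: graph components over pairwise
# Chebyshev-adjacent foreground voxels (26-connectivity).
count_components_oracle <- function(mask) {
  vox <- which(mask, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- i != j && max(abs(vox[i, ] - vox[j, ])) <= 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Explicit pairwise AUC oracle with half-credit for ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
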