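# Shared in-code fixtures: no files on disk, everything generated.

# A noiseless two-intensity phantom slice (bright ellipse on dark ground).
two_level_phantom <- function(shape = c(48L, 48L), seed = 3L) {
  generate_phantom(phantom_spec(shape = shape, noise_sd = 0,
                                bias_amplitude = 0, seed = seed))
}

# NAQSS state with uniform amplitudes and the first r states marked;
# bypasses intensity quantization so the textbook Grover identities apply.
uniform_state <- function(N, r) {
  n <- as.integer(log2(N))
  stopifnot(2^n == N, r >= 1, r <= N)
  structure(list(theta = rep(1 / sqrt(N), N),
                 label = c(rep(TRUE, r), rep(FALSE, N - r)),
                 a = rep(pi / 4, N), level = rep(2L, N), M = 2L,
                 n_qubits = n, dims = N, bits = n, map = seq_len(N)),
            class = "naqss_state")
}

# Small random superpixel graph with k nodes (seeded, fully connected).
random_graph <- function(k, seed = 1L) {
  set.seed(seed)
  means <- runif(k, 0, 100)
  dmat <- abs(outer(means, means, `-`))
  sigma <- max(stats::sd(dmat[upper.tri(dmat)]), 1e-6)
  W <- stats::dnorm(dmat, sd = sigma)
  diag(W) <- 0
  structure(list(membership = array(seq_len(k), c(k, 1)), means = means,
                 sizes = rep(1L, k), weights = W, sigma = sigma,
                 dims = c(k, 1L)),
            class = "superpixel_graph")
}

# Exhaustive minimum of the graph energy over labelings {-1,0,1}^k
# (excluding all-zero); independent of the eigen route.
brute_force_energy_min <- function(graph, seeds, lambda = 1) {
  k <- length(graph$means)
  ys <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), k)))
  best <- Inf
  for (i in seq_len(nrow(ys))) {
    y <- ys[i, ]
    if (sum(y^2) == 0) next
    e <- qcuts_energy(y, graph, seeds, lambda)
    if (e < best) best <- e
  }
  best
}

# Brute-force directed/undirected Hausdorff over explicit point sets.
brute_hausdorff <- function(px, py) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  dir <- function(A, B) max(apply(A, 1, function(p)
    min(apply(B, 1, function(q) d(p, q)))))
  max(dir(px, py), dir(py, px))
}
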