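test_that("superpixel graph: partition covers voxels once, Gaussian weights", {
  ph <- two_level_phantom()
  g <- build_superpixels(ph$image, 40)
  expect_identical(dim(g$membership), dim(ph$image$data))
  expect_true(all(g$membership >= 1 & g$membership <= length(g$means)))
  expect_identical(sum(g$sizes), length(ph$image$data))
  expect_true(all(g$sizes > 0))
  expect_equal(g$weights, t(g$weights))
  expect_true(all(diag(g$weights) == 0))
  expect_true(all(g$weights >= 0))

  # constant image: every off-diagonal weight is the Gaussian peak
  gc <- build_superpixels(array(3, c(8, 8)), 4, sigma = 2)
  off <- gc$weights[upper.tri(gc$weights)]
  expect_true(all(abs(off - 1 / (2 * sqrt(2 * pi))) < 1e-12))

  # sigma = 1, |S_i - S_j| = 1 gives the printed density value
  expect_equal(stats::dnorm(1, sd = 1), exp(-0.5) / sqrt(2 * pi))
  expect_error(build_superpixels(ph$image, 1), "n must be")
})

test_that("energy: smooth-labeling zero, two-node expansion, error cases", {
  gc <- build_superpixels(array(3, c(8, 8)), 4, sigma = 2)
  e_uniform <- qcuts_energy(rep(1, 4), gc, seeds = integer(0), lambda = 1)
  expect_equal(e_uniform, 0)   # z_j^2 - z_i z_j = 0 when all labels equal

  g2 <- random_graph(2, seed = 4)
  w12 <- g2$weights[1, 2]
  e <- qcuts_energy(c(1, -1), g2, seeds = integer(0), lambda = 1)
  expect_equal(e, 2 * w12)     # ordered pairs: 4 w12 / sum(z^2)

  expect_error(qcuts_energy(c(0, 0), g2, seeds = 1, lambda = 1), "degenerate")
  expect_error(qcuts_energy(c(2, 1), g2, seeds = 1, lambda = 1), "-1, 0, 1")
})

test_that("eigen relaxation: Rayleigh bound and reported gap vs brute force", {
  for (s in 1:4) {
    k <- sample(5:8, 1)
    g <- random_graph(k, seed = s)
    sol <- qcuts_solve(g, n_seeds = 2)
    brute <- brute_force_energy_min(g, sol$seeds, lambda = 1)
    # the continuous minimizer can never exceed the discrete optimum
    expect_lte(sol$rayleigh, brute + 1e-9)
    # the thresholded labeling's energy is reported; gap is non-negative
    expect_true(is.finite(sol$energy))
    expect_gte(sol$energy - brute, -1e-9)
  }
})

test_that("two well-separated clusters split along the intensity gap", {
  make_two_cluster <- function(gap, seed = 1) {
    set.seed(seed)
    means <- c(rnorm(5, 10, 0.5), rnorm(5, 10 + gap, 0.5))
    dmat <- abs(outer(means, means, `-`))
    W <- stats::dnorm(dmat, sd = 2); diag(W) <- 0
    structure(list(membership = array(seq_along(means), c(10, 1)),
                   means = means, sizes = rep(1L, 10), weights = W,
                   sigma = 2, dims = c(10L, 1L)),
              class = "superpixel_graph")
  }
  g <- make_two_cluster(30)
  sol <- qcuts_solve(g, n_seeds = 3, invert_seeds = TRUE)  # seeds in bright cluster
  fg <- which(sol$y == sol$foreground)
  expect_setequal(fg, 6:10)

  # monotone contrast: achieved Dice never decreases with the cluster gap
  dices <- vapply(c(8, 15, 30), function(gap) {
    sg <- make_two_cluster(gap)
    so <- qcuts_solve(sg, n_seeds = 3, invert_seeds = TRUE)
    pred <- so$y == so$foreground
    truth <- c(rep(FALSE, 5), rep(TRUE, 5))
    2 * sum(pred & truth) / (sum(pred) + sum(truth))
  }, numeric(1))
  expect_true(all(diff(dices) >= 0))
})

test_that("lambda = 0 leaves a solution pinned by the seeds alone", {
  g <- random_graph(7, seed = 2)
  sol <- qcuts_solve(g, n_seeds = 2, lambda = 0)
  # only the unary term remains: the minimizer carries no amplitude on seeds
  expect_true(all(abs(sol$z[sol$seeds]) < 1e-8))
})

test_that("solver determinism and node-permutation equivariance", {
  g <- random_graph(8, seed = 5)
  a <- qcuts_solve(g, n_seeds = 2)
  b <- qcuts_solve(g, n_seeds = 2)
  expect_identical(a$y, b$y)

  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  gp <- g
  gp$means <- g$means[perm]
  gp$weights <- g$weights[perm, perm]
  sp <- qcuts_solve(gp, n_seeds = 2)
  expect_identical(sp$y, a$y[perm])
  expect_identical(sp$foreground, a$foreground)
})

test_that("full pipeline recovers a bright organ when seeds are oriented to it", {
  ph <- two_level_phantom()
  res <- qcuts_segment(ph$image, n_superpixels = 64, n_seeds = 16,
                       invert_seeds = TRUE)
  expect_gte(dice(res$mask, ph$truth), 0.9)
  expect_identical(length(res$solution$z), length(res$graph$means))

  lab <- qontour:::label_components(res$mask$data, full = TRUE)
  expect_lte(max(lab), 1L)
})
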