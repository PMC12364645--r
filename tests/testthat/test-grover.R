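test_that("NAQSS encoding: endpoint angles, normalization, hand-worked 2x2", {
  img <- matrix(c(0, 1, 1, 1), 2, 2)
  st <- naqss_encode(img, M = 2)
  expect_identical(sort(unique(st$a)), c(0, pi / 2))
  expect_equal(sum(st$theta^2), 1, tolerance = 1e-9)
  # a = (0, pi/2, pi/2, pi/2) normalizes to (0, 1, 1, 1)/sqrt(3)
  expect_equal(sort(st$theta), c(0, 1, 1, 1) / sqrt(3), tolerance = 1e-12)

  set.seed(3)
  st2 <- naqss_encode(array(runif(5 * 7), c(5, 7)), M = 16)
  expect_equal(sum(st2$theta^2), 1, tolerance = 1e-9)
  expect_identical(length(st2$theta), 8L * 8L)   # padded to powers of two
  expect_true(all(st2$theta[is.na(st2$map)] == 0))
  expect_true(all(!st2$label[is.na(st2$map)]))

  expect_error(naqss_encode(matrix(5, 3, 3), M = 4), "degenerate")
})

test_that("location index and coordinate bits round-trip bijectively", {
  bits <- c(3L, 2L)
  N <- 2^sum(bits)
  i <- 0:(N - 1)
  coords <- naqss_index_to_coords(i, bits)
  expect_identical(naqss_coords_to_index(coords, bits), as.integer(i))
  expect_identical(anyDuplicated(coords), 0L)
  expect_true(all(coords[, 1] < 8 & coords[, 2] < 4))

  bits3 <- c(2L, 2L, 1L)
  i3 <- 0:(2^5 - 1)
  expect_identical(
    naqss_coords_to_index(naqss_index_to_coords(i3, bits3), bits3),
    as.integer(i3))
})

test_that("Grover plan: textbook counts, r = N short-circuit, errors", {
  st <- uniform_state(4, 1)
  pl <- grover_plan(st)
  expect_equal(pl$omega, pi / 3, tolerance = 1e-12)
  expect_equal(pl$phi, pi / 6, tolerance = 1e-12)
  expect_identical(pl$t, 1L)

  big <- uniform_state(1024, 1)
  expect_identical(grover_plan(big)$t, 25L)      # = floor((pi/4) sqrt(N))

  all_marked <- uniform_state(8, 8)
  expect_identical(grover_plan(all_marked)$t, 0L)

  none <- uniform_state(8, 1); none$label[] <- FALSE
  expect_error(grover_plan(none), "no marked")
})

test_that("oracle + diffusion: k = 0 identity, exact N=4 amplification, unitarity", {
  st <- uniform_state(4, 1)
  expect_identical(grover_iterate(st, 0)$theta, st$theta)

  one <- grover_iterate(st, 1)
  expect_equal(one$theta, c(1, 0, 0, 0), tolerance = 1e-12)

  set.seed(6)
  rnd <- uniform_state(64, 5)
  rnd$theta <- rnorm(64); rnd$theta <- rnd$theta / sqrt(sum(rnd$theta^2))
  after <- grover_iterate(rnd, 7)
  expect_equal(sum(after$theta^2), 1, tolerance = 1e-9)
})

test_that("success probability matches the analytic rotation and the gate oracle", {
  # sin^2((2k+1) alpha) across the full grid, 1e-9 tolerance
  worst <- 0
  for (N in c(4, 8, 16, 64)) {
    for (r in seq_len(N / 2)) {
      st <- uniform_state(N, r)
      alpha <- asin(sqrt(r / N))
      t_opt <- grover_plan(st)$t
      for (k in unique(pmin(0:3, 2 * t_opt))) {
        p_sim <- grover_success_probability(st, k)
        worst <- max(worst, abs(p_sim - sin((2 * k + 1) * alpha)^2))
      }
      # t maximizes over the neighbouring iteration counts
      ks <- max(0, t_opt - 1):(t_opt + 1)
      ps <- vapply(ks, function(k) grover_success_probability(st, k), numeric(1))
      expect_gte(grover_success_probability(st, t_opt), max(ps) - 1e-12)
    }
  }
  expect_lt(worst, 1e-9)

  expect_equal(grover_success_probability(uniform_state(16, 4), 0), 4 / 16)
  expect_equal(grover_success_probability(uniform_state(16, 4), 1), 1,
               tolerance = 1e-12)

  # independent gate-built statevector agrees with the amplitude path
  for (n in 2:5) {
    N <- 2^n
    r <- max(1, N %/% 8)
    st <- uniform_state(N, r)
    for (k in 0:2)
      expect_equal(grover_success_probability(st, k),
                   qontour:::grover_statevector_reference(n, seq_len(r), k),
                   tolerance = 1e-9)
  }
})

test_that("probability increases monotonically up to the planned optimum", {
  st <- uniform_state(256, 3)
  t_opt <- grover_plan(st)$t
  ps <- vapply(0:t_opt, function(k) grover_success_probability(st, k),
               numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("segmentation: oracle marker recovered exactly, island removed, noisy bound", {
  ph <- two_level_phantom()
  res <- grover_segment(ph$image, ph$truth)
  expect_equal(dice(res$raw, ph$truth), 1)

  # detached one-voxel island in the marker disappears after post-processing
  island <- ph$truth$data; island[2, 2] <- TRUE
  res2 <- grover_segment(ph$image, binary_mask(island))
  expect_false(res2$mask$data[2, 2])
  lab <- qontour:::label_components(res2$mask$data, full = TRUE)
  expect_identical(max(lab), 1L)

  phn <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sd = 12, seed = 7))
  mk <- make_marker(phn$truth, marker_spec("noisy", 0.1, seed = 2))
  res3 <- grover_segment(phn$image, mk)
  expect_gte(dice(res3$mask, phn$truth), dice(mk, phn$truth) - 0.02)

  expect_error(grover_segment(ph$image, binary_mask(array(FALSE, dim(ph$truth$data)))),
               "empty marker")
})

test_that("superpixel-level search broadcasts labels back to voxels", {
  ph <- two_level_phantom()
  sp <- build_superpixels(ph$image, 32)
  res <- grover_segment(ph$image, ph$truth, superpixels = sp)
  expect_s3_class(res$plan, "grover_plan")
  expect_lte(res$plan$N, 32 * 2)       # padded superpixel count, not voxels
  expect_gte(dice(res$mask, ph$truth), 0.85)
})
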