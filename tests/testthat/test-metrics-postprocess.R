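test_that("Dice: identity, disjoint, half-overlap, empty convention, symmetry", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE      # |X|=|Y|=4, overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)
  d <- matrix(FALSE, 4, 4); d[4, 4] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)

  set.seed(8)
  for (i in 1:5) {
    x <- array(runif(64) > 0.5, c(4, 4, 4))
    y <- array(runif(64) > 0.5, c(4, 4, 4))
    expect_equal(dice(x, y), dice(y, x))
  }
})

test_that("Hausdorff: zero on equality, 3-4-5 points, empty flag, symmetry", {
  a <- matrix(FALSE, 8, 8); a[3:5, 3:5] <- TRUE
  expect_equal(hausdorff(a, a), 0)

  p <- matrix(FALSE, 8, 8); p[1, 1] <- TRUE
  q <- matrix(FALSE, 8, 8); q[4, 5] <- TRUE
  expect_equal(hausdorff(p, q), 5)

  expect_identical(hausdorff(a, matrix(FALSE, 8, 8)), Inf)
  expect_equal(hausdorff(p, q, spacing = c(2, 2)), 10)

  set.seed(9)
  for (i in 1:5) {
    x <- array(runif(125) > 0.6, c(5, 5, 5)); x[1, 1, 1] <- TRUE
    y <- array(runif(125) > 0.6, c(5, 5, 5)); y[5, 5, 5] <- TRUE
    expect_equal(hausdorff(x, y), hausdorff(y, x))
  }
})

test_that("Hausdorff matches brute-force pairwise distances on nested squares", {
  outer_sq <- matrix(FALSE, 12, 12); outer_sq[3:10, 3:10] <- TRUE
  inner_sq <- matrix(FALSE, 12, 12); inner_sq[5:8, 5:8] <- TRUE
  px <- arrayInd(which(qontour:::boundary_voxels(outer_sq, "inner")), c(12, 12))
  py <- arrayInd(which(qontour:::boundary_voxels(inner_sq, "inner")), c(12, 12))
  expect_equal(hausdorff(outer_sq, inner_sq), brute_hausdorff(px, py))
  expect_equal(hausdorff(outer_sq, inner_sq), 2 * sqrt(2))
})

test_that("largest connected component: size rule and stated tie-break", {
  m <- matrix(FALSE, 10, 10)
  m[1:2, 1:5] <- TRUE                 # size 10
  m[8:10, 9] <- TRUE                  # size 3
  out <- largest_connected_component(m)
  expect_identical(sum(out), 10L)
  expect_true(all(out[1:2, 1:5]))

  single <- matrix(FALSE, 5, 5); single[2:3, 2:3] <- TRUE
  expect_identical(largest_connected_component(single), single)

  # equal sizes: keep the component containing the smallest linear index
  tie <- matrix(FALSE, 9, 9); tie[2:3, 2:3] <- TRUE; tie[6:7, 6:7] <- TRUE
  kept <- largest_connected_component(tie)
  expect_true(all(kept[2:3, 2:3]) && !any(kept[6:7, 6:7]))

  # diagonal touch is connected in 2D (8-connectivity)
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(sum(largest_connected_component(diag2)), 2L)
})

test_that("hole filling: ring fills, solid unchanged, open C-shape untouched", {
  ring <- matrix(FALSE, 7, 7); ring[2:6, 2:6] <- TRUE; ring[3:5, 3:5] <- FALSE
  filled <- fill_holes(ring)
  solid <- matrix(FALSE, 7, 7); solid[2:6, 2:6] <- TRUE
  expect_identical(filled, solid)
  expect_identical(fill_holes(solid), solid)

  cshape <- ring; cshape[4, 2] <- FALSE   # cut the ring open to the border
  # brute-force flood fill from the border (4-connectivity oracle)
  reach <- !cshape & col(cshape) %in% c(1, 7) | !cshape & row(cshape) %in% c(1, 7)
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-7, ]
    grown[-7, ] <- grown[-7, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -7]
    grown[, -7] <- grown[, -7] | reach[, -1]
    grown <- grown & !cshape
    if (identical(grown, reach)) break
    reach <- grown
  }
  expect_identical(fill_holes(cshape), cshape | (!cshape & !reach))
})

test_that("post-processing operators are idempotent and single-component", {
  set.seed(4)
  for (i in 1:4) {
    m <- array(runif(18^3) > 0.72, c(18, 18, 18))
    pp <- postprocess_mask(m)
    expect_identical(postprocess_mask(pp), pp)
    expect_identical(fill_holes(fill_holes(m)), fill_holes(m))
    lab <- qontour:::label_components(pp, full = TRUE)
    expect_lte(max(lab), 1L)
  }
})

test_that("multi-level Otsu: separated clusters, two-value split, shift invariance", {
  set.seed(12)
  v <- c(rnorm(200, 0, 0.05), rnorm(200, 1, 0.05),
         rnorm(200, 2, 0.05), rnorm(200, 3, 0.05))
  thr <- multi_otsu_highest(v, levels = 4)
  expect_gt(thr, max(v[v < 2.5]))
  expect_lt(thr, min(v[v > 2.5]))

  two <- c(rep(0, 50), rep(1, 50))
  t2 <- multi_otsu_highest(two, levels = 2)
  expect_gt(t2, 0); expect_lte(t2, 1)

  expect_equal(multi_otsu_highest(v + 10, levels = 4) - 10, thr,
               tolerance = (max(v) - min(v)) / 256)

  expect_error(multi_otsu_highest(rep(c(0, 1, 2), 10), levels = 4),
               "distinct")
})

test_that("eval_record assembles a tidy one-row record", {
  ph <- two_level_phantom(c(24L, 24L))
  rec <- eval_record("oracle", ph$truth, ph$truth, params = list(nu = 0.03),
                     case_id = "c1")
  expect_s3_class(rec, "tbl_df")
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$dice, 1)
  expect_equal(rec$hausdorff, 0)
  expect_identical(rec$params[[1]]$nu, 0.03)
})
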