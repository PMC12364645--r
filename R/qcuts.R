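#' Build a superpixel graph
#'
#' Partitions the image into approximately `n` compact regions by Lloyd
#' k-means over `(intensity, compactness-scaled coordinates)` with
#' deterministic regular-grid initial centres, then connects every pair of
#' superpixels with the Gaussian similarity of their mean intensities,
#' `w_ij = 1 / (sigma sqrt(2 pi)) * exp(-|S_i - S_j|^2 / (2 sigma^2))`,
#' where `S_i` is the mean intensity of the voxels belonging to superpixel
#' `i`. The graph is fully connected (no self-edges; `w_ii = 0`).
#'
#' @param img An [image_volume()] or array.
#' @param n Target superpixel count (`2 <= n <=` voxel count).
#' @param sigma Gaussian bandwidth; by default the standard deviation of the
#'   pairwise `|S_i - S_j|` values (falling back to 1 when that is 0).
#' @param compactness Relative weight of the spatial coordinates against the
#'   `[0, 1]`-scaled intensity in the clustering feature space.
#' @return A `superpixel_graph` list: `membership` (per-voxel id array),
#'   `means`, `sizes`, `weights` (symmetric matrix), `sigma`, `dims`.
#' @export
build_superpixels <- function(img, n, sigma = NULL, compactness = 0.5) {
  arr <- as_vol_array(img)
  nv <- length(arr)
  if (n < 2L) stop("build_superpixels: n must be >= 2", call. = FALSE)
  if (n > nv) stop("build_superpixels: n exceeds voxel count", call. = FALSE)
  d <- dim(arr)
  coords <- arrayInd(seq_len(nv), d)
  feat <- cbind(minmax01(arr)[seq_len(nv)],
                compactness * sweep(coords, 2L, d, `/`))
  # deterministic regular-sample initial centres
  pick <- unique(round(seq(1, nv, length.out = n)))
  km <- suppressWarnings(
    kmeans(feat, centers = feat[pick, , drop = FALSE],
           iter.max = 30L, algorithm = "Lloyd"))
  memb <- km$cluster
  # compact ids in case Lloyd emptied a cluster
  keep <- sort(unique(memb))
  memb <- match(memb, keep)
  means <- as.numeric(tapply(as.numeric(arr), memb, mean))
  sizes <- tabulate(memb)
  k <- length(means)
  dmat <- abs(outer(means, means, `-`))
  if (is.null(sigma)) {
    sigma <- sd(dmat[upper.tri(dmat)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  W <- dnorm(dmat, sd = sigma)
  diag(W) <- 0
  structure(list(membership = array(memb, d), means = means, sizes = sizes,
                 weights = W, sigma = sigma, dims = d),
            class = "superpixel_graph")
}

#' @export
print.superpixel_graph <- function(x, ...) {
  cat("<superpixel_graph> ", length(x$means), " superpixels over ",
      paste(x$dims, collapse = " x "), " voxels | sigma = ",
      format(x$sigma), "\n", sep = "")
  invisible(x)
}

#' Graph energy of a labeling
#'
#' `E(y) = E_unary(y) + lambda * E_binary(y)` with
#' `E_unary = sum_{i in seeds} y_i^2 / sum_i y_i^2` (the seed indicator as a
#' quadratic form) and
#' `E_binary = sum_{i != j} w_ij (y_j^2 - y_i y_j) / sum_i y_i^2` (ordered
#' pairs). For any `y` this equals the Rayleigh quotient of
#' `U + lambda (D - W)` at `y`, which is what the eigen-solver minimizes.
#'
#' @param y Label vector with entries in `{-1, 0, 1}` (at least one nonzero).
#' @param graph A [superpixel_graph()].
#' @param seeds Integer vector of seed superpixel ids.
#' @param lambda Weight of the binary (smoothness) term.
#' @return The energy (a finite number).
#' @export
qcuts_energy <- function(y, graph, seeds, lambda = 1) {
  stopifnot(inherits(graph, "superpixel_graph"))
  if (!all(y %in% c(-1, 0, 1)))
    stop("qcuts_energy: y entries must be in {-1, 0, 1}", call. = FALSE)
  ss <- sum(y^2)
  if (ss == 0)
    stop("qcuts_energy: all-zero labeling is degenerate", call. = FALSE)
  W <- graph$weights
  unary <- sum(y[seeds]^2) / ss
  degs <- colSums(W)
  binary <- (sum(degs * y^2) - drop(y %*% W %*% y)) / ss
  unary + lambda * binary
}

#' Minimize the graph energy by eigen-decomposition
#'
#' Assembles the symmetric matrix `A = U + lambda (D - W)` whose Rayleigh
#' quotient is the energy of [qcuts_energy()], takes the eigenvector `z` of
#' its smallest eigenvalue (the classical stand-in for annealing to the
#' ground state), orients it so the mean seed component is non-negative, and
#' maps `y = z o z` to labels: components with `|z| < 1e-12` get 0, the rest
#' get `+1` where `z^2` exceeds the highest 4-level Otsu split of `z^2`
#' (largest-gap midpoint when `z^2` has fewer than 4 distinct values) and
#' `-1` otherwise. Because the unary term penalizes amplitude on the seeds,
#' the minimizer concentrates `z` away from them: the seed side of the cut
#' is the low-`z^2` class.
#'
#' @param graph A [superpixel_graph()].
#' @param n_seeds Number of seeds (default `max(1, 5%)` of superpixels).
#' @param lambda Binary-term weight (default 1).
#' @param invert_seeds If `FALSE` (the published rule) seeds are the
#'   superpixels with the lowest mean intensity, suited to dark targets; if
#'   `TRUE`, the highest, suited to bright organs.
#' @param seeds Optional explicit seed ids (overrides the intensity rule).
#' @return A `qcuts_solution` list: `z`, `y`, `foreground` (label value of
#'   the seed-majority class), `energy`, `rayleigh`, `lambda`, `seeds`.
#' @export
qcuts_solve <- function(graph, n_seeds = NULL, lambda = 1,
                        invert_seeds = FALSE, seeds = NULL) {
  stopifnot(inherits(graph, "superpixel_graph"))
  k <- length(graph$means)
  if (is.null(seeds)) {
    if (is.null(n_seeds)) n_seeds <- max(1L, round(0.05 * k))
    if (n_seeds < 1L || n_seeds >= k)
      stop("qcuts_solve: need 1 <= n_seeds < superpixel count", call. = FALSE)
    ord <- order(graph$means, decreasing = invert_seeds)
    seeds <- ord[seq_len(n_seeds)]
  }
  u <- numeric(k); u[seeds] <- 1
  W <- graph$weights
  A <- diag(u) + lambda * (diag(colSums(W)) - W)
  es <- tryCatch(eigen(A, symmetric = TRUE),
                 error = function(e)
                   stop("qcuts_solve: eigensolver failure (condition ",
                        format(kappa(A)), "): ", conditionMessage(e),
                        call. = FALSE))
  z <- es$vectors[, k]
  if (sum(z[seeds]) < 0) z <- -z
  zz <- z^2
  y <- integer(k)
  nonzero <- abs(z) >= 1e-12
  if (any(nonzero)) {
    vals <- zz[nonzero]
    thr <- if (length(unique(vals)) >= 4L)
      multi_otsu_highest(vals, levels = 4L)
    else {
      sv <- sort(unique(vals))
      if (length(sv) == 1L) sv[1] - 1e-15
      else { g <- which.max(diff(sv)); (sv[g] + sv[g + 1]) / 2 }
    }
    y[nonzero] <- ifelse(vals >= thr, 1L, -1L)
  }
  fg <- as.integer(names(which.max(table(y[seeds]))))
  energy <- tryCatch(qcuts_energy(y, graph, seeds, lambda),
                     error = function(e) NA_real_)
  structure(list(z = z, y = y, foreground = fg,
                 energy = energy,
                 rayleigh = drop(z %*% A %*% z) / sum(z^2),
                 lambda = lambda, seeds = seeds, n_seeds = length(seeds)),
            class = "qcuts_solution")
}

#' @export
print.qcuts_solution <- function(x, ...) {
  cat("<qcuts_solution> ", length(x$y), " nodes | foreground label ",
      x$foreground, " (", sum(x$y == x$foreground), " nodes) | energy ",
      format(x$energy), "\n", sep = "")
  invisible(x)
}

#' QCuts segmentation
#'
#' Builds a superpixel graph, minimizes the two-term energy by
#' eigen-decomposition, broadcasts the seed-majority (foreground) label back
#' to voxels, and applies the standard post-processing.
#'
#' @param img An [image_volume()] or array.
#' @param n_superpixels Superpixel count (default 256).
#' @param n_seeds,lambda,invert_seeds Passed to [qcuts_solve()].
#' @param sigma,compactness Passed to [build_superpixels()].
#' @return A list: `mask` ([binary_mask()]), `solution` (the
#'   [qcuts_solve()] result), `graph`.
#' @export
qcuts_segment <- function(img, n_superpixels = 256L, n_seeds = NULL,
                          lambda = 1, invert_seeds = FALSE, sigma = NULL,
                          compactness = 0.5) {
  graph <- build_superpixels(img, n_superpixels, sigma = sigma,
                             compactness = compactness)
  sol <- qcuts_solve(graph, n_seeds = n_seeds, lambda = lambda,
                     invert_seeds = invert_seeds)
  fg_ids <- which(sol$y == sol$foreground)
  raw <- array(graph$membership %in% fg_ids, graph$dims)
  out <- if (any(raw)) postprocess_mask(raw) else raw
  list(mask = rewrap_mask(out, wrap_like(img, out)), solution = sol,
       graph = graph)
}
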