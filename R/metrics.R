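#' Sorensen-Dice coefficient
#'
#' `DSC = 2|X n Y| / (|X| + |Y|)`. Two empty masks are defined to agree
#' perfectly (DSC = 1).
#'
#' @param x,y Congruent [binary_mask()]s or logical arrays.
#' @return A number in `[0, 1]`.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
#' dice(a, b)
#' @export
dice <- function(x, y) {
  ax <- as_vol_array(x); ay <- as_vol_array(y)
  check_congruent(ax, ay)
  nx <- sum(ax); ny <- sum(ay)
  if (nx + ny == 0) return(1)
  2 * sum(ax & ay) / (nx + ny)
}

#' Hausdorff distance between mask boundaries
#'
#' The maximum of the two directed Hausdorff distances between the boundary
#' voxel sets of `x` and `y`, under the Euclidean metric. Distances are in
#' voxel units unless `spacing` is supplied, in which case coordinates are
#' scaled per axis (mm). If either mask is empty the distance is `Inf`.
#'
#' @param x,y Congruent [binary_mask()]s or logical arrays.
#' @param spacing Optional positive numeric vector, one entry per axis.
#' @return A non-negative number, possibly `Inf`.
#' @export
hausdorff <- function(x, y, spacing = NULL) {
  ax <- as_vol_array(x); ay <- as_vol_array(y)
  check_congruent(ax, ay)
  if (!any(ax) || !any(ay)) return(Inf)
  px <- arrayInd(which(boundary_voxels(ax, side = "inner")), dim(ax))
  py <- arrayInd(which(boundary_voxels(ay, side = "inner")), dim(ay))
  if (!is.null(spacing)) {
    px <- sweep(px, 2L, spacing, `*`)
    py <- sweep(py, 2L, spacing, `*`)
  }
  max(directed_hausdorff(px, py), directed_hausdorff(py, px))
}

# max over rows of `a` of min distance to rows of `b`; chunked so the
# pairwise distance matrix never exceeds ~2e6 entries.
directed_hausdorff <- function(a, b, chunk = 2048L) {
  worst <- 0
  bt <- t(b)
  b2 <- colSums(bt^2)
  for (start in seq(1L, nrow(a), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(a))
    ac <- a[rows, , drop = FALSE]
    d2 <- outer(rowSums(ac^2), b2, `+`) - 2 * ac %*% bt
    worst <- max(worst, max(apply(d2, 1L, min)))
  }
  sqrt(max(worst, 0))
}

#' Highest threshold of a multi-level Otsu split
#'
#' Computes `levels - 1` thresholds on a 256-bin histogram by exact
#' maximization of the between-class variance (dynamic programming over all
#' bin partitions, equivalent to exhaustive search) and returns the highest
#' threshold on the data scale. The result is invariant, up to bin
#' resolution, to adding a constant to all values.
#'
#' @param x Numeric array or vector with at least `levels` distinct values.
#' @param levels Number of classes (default 4, so 3 thresholds).
#' @param bins Histogram resolution.
#' @return The highest threshold (a single number).
#' @export
multi_otsu_highest <- function(x, levels = 4L, bins = 256L) {
  v <- as.numeric(as_vol_array_or_vector(x))
  u <- unique(v)
  if (length(u) < levels)
    stop("multi_otsu_highest: need at least ", levels,
         " distinct values (degenerate input)", call. = FALSE)
  r <- range(v)
  # bin values onto 1..bins
  b <- pmin(bins, 1L + floor((v - r[1]) / (r[2] - r[1]) * bins))
  cnt <- tabulate(b, bins)
  w <- cnt / sum(cnt)
  # class score for bins a..b: w_ab * mu_ab^2 (the total-mean term is constant)
  cw <- cumsum(w)
  cm <- cumsum(w * seq_len(bins))
  seg <- function(a, b) {  # vectorized over `a`; `b` scalar
    lo_w <- ifelse(a > 1L, cw[pmax(a - 1L, 1L)], 0)
    lo_m <- ifelse(a > 1L, cm[pmax(a - 1L, 1L)], 0)
    ww <- cw[b] - lo_w
    mm <- cm[b] - lo_m
    ifelse(ww > 0, mm^2 / ww, -Inf)
  }
  nthr <- levels - 1L
  # f[k, j]: best score of splitting bins 1..j into k classes; arg tracks cuts
  f <- matrix(-Inf, nthr + 1L, bins)
  arg <- matrix(0L, nthr + 1L, bins)
  f[1L, ] <- vapply(seq_len(bins), function(j) seg(1L, j), numeric(1))
  for (k in 2L:(nthr + 1L)) {
    for (j in k:bins) {
      t_prev <- (k - 1L):(j - 1L)
      cand <- f[k - 1L, t_prev] + seg(t_prev + 1L, j)
      best <- which.max(cand)
      f[k, j] <- cand[best]
      arg[k, j] <- t_prev[best]
    }
  }
  # backtrack the highest cut
  cuts <- integer(nthr)
  j <- bins
  for (k in (nthr + 1L):2L) {
    cuts[k - 1L] <- arg[k, j]
    j <- arg[k, j]
  }
  top <- max(cuts)
  # threshold = upper edge of bin `top` on the data scale
  r[1] + top / bins * (r[2] - r[1])
}

as_vol_array_or_vector <- function(x) {
  if (inherits(x, "image_volume") || inherits(x, "binary_mask")) x$data else x
}

#' Per-case evaluation record
#'
#' One row of the Table-2-style evaluation: method tag, Dice, Hausdorff
#' distance, hyperparameters and case identifier.
#'
#' @param method Character method tag.
#' @param pred,truth Congruent masks.
#' @param params Named list of hyperparameters (stored as a list-column).
#' @param case_id Fixture identifier.
#' @param spacing Optional spacing passed to [hausdorff()].
#' @return A one-row [tibble::tibble()] with class `eval_record`.
#' @export
eval_record <- function(method, pred, truth, params = list(),
                        case_id = NA_character_, spacing = NULL) {
  out <- tibble::tibble(
    case_id = as.character(case_id),
    method = method,
    dice = dice(pred, truth),
    hausdorff = hausdorff(pred, truth, spacing = spacing),
    params = list(params)
  )
  class(out) <- c("eval_record", class(out))
  out
}
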