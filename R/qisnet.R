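#' Multi-class gray-level transition table
#'
#' The eleven published 8-level transition rows plus, as row 12 (tag
#' `"best"`), the row reported to give the highest Dice in practice
#' (`0, 0.04, 0.28, ...`). Each row starts at 0, ends at 1, is
#' non-decreasing, and is scaled by `pi/2` when translated into qutrit
#' angles.
#'
#' @return A 12 x 8 numeric matrix.
#' @export
qisnet_transition_table <- function() {
  rows <- rbind(
    c(0, 0.15, 0.30, 0.46, 0.61, 0.76, 0.91, 1.0),
    c(0, 0.14, 0.28, 0.42, 0.56, 0.70, 0.90, 1.0),
    c(0, 0.13, 0.26, 0.39, 0.52, 0.75, 0.91, 1.0),
    c(0, 0.18, 0.36, 0.54, 0.72, 0.90, 0.97, 1.0),
    c(0, 0.17, 0.34, 0.51, 0.68, 0.85, 0.95, 1.0),
    c(0, 0.15, 0.29, 0.43, 0.57, 0.71, 0.85, 1.0),
    c(0, 0.15, 0.30, 0.46, 0.61, 0.76, 0.91, 1.0),
    c(0, 0.62, 0.71, 0.80, 0.83, 0.93, 0.98, 1.0),
    c(0, 0.60, 0.72, 0.82, 0.94, 0.96, 0.98, 1.0),
    c(0, 0.63, 0.74, 0.79, 0.82, 0.88, 0.97, 1.0),
    c(0, 0.70, 0.74, 0.79, 0.82, 0.88, 0.98, 1.0),
    c(0, 0.04, 0.28, 0.42, 0.56, 0.70, 0.90, 1.0)
  )
  rownames(rows) <- c(paste0("row", 1:11), "best")
  rows
}

#' QIS-Net parameters
#'
#' @param nu Steepness factor of the quantum sigmoid (> 0).
#' @param beta Activation factor (midpoint of the sigmoid on the `[0, 1]`
#'   intensity scale; default 0.5).
#' @param transition_table_index Row of [qisnet_transition_table()] to use
#'   (1-12; 12 = the `"best"` row, the default).
#' @param max_iters Iteration cap.
#' @param tol Convergence tolerance on the mean absolute state change.
#' @return A `qisnet_params` list.
#' @export
qisnet_params <- function(nu = 0.04, beta = 0.5, transition_table_index = 12L,
                          max_iters = 50L, tol = 1e-4) {
  if (nu <= 0) stop("qisnet_params: nu must be > 0", call. = FALSE)
  tti <- as.integer(transition_table_index)
  if (tti < 1L || tti > 12L)
    stop("qisnet_params: transition_table_index must be in 1..12", call. = FALSE)
  if (max_iters < 1L) stop("qisnet_params: max_iters must be >= 1", call. = FALSE)
  if (tol <= 0) stop("qisnet_params: tol must be > 0", call. = FALSE)
  structure(list(nu = nu, beta = beta, transition_table_index = tti,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "qisnet_params")
}

#' Quantum sigmoidal activation
#'
#' `sigma(x) = 1 / (lambda_omega + exp(-nu * (x - beta)))`: strictly
#' increasing in `x`, with range `(0, 1 / lambda_omega)`. `lambda_omega` is
#' the per-pixel gray-scale intensity index; `nu` and `beta` come from
#' [qisnet_params()]. The exponent saturates instead of overflowing.
#'
#' @param x Numeric input (vectorized).
#' @param params A [qisnet_params()].
#' @param lambda_omega Positive gray-scale intensity index (vectorized).
#' @return Numeric, same length as `x`.
#' @examples
#' quantum_sigmoid(0.5, qisnet_params(nu = 1, beta = 0.5), 1)  # 0.5
#' @export
quantum_sigmoid <- function(x, params, lambda_omega) {
  stopifnot(all(lambda_omega > 0))
  e <- -params$nu * (x - params$beta)
  e[e > 700] <- 700
  e[e < -700] <- -700
  1 / (lambda_omega + exp(e))
}

# 8-neighborhood offsets for a 2D slice
qisnet_offsets <- function() {
  o <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  o[rowSums(o != 0) > 0, , drop = FALSE]
}

#' Per-pixel qutrit features of a 2D slice
#'
#' Computes, for every pixel of a `[0, 1]`-scaled slice (padded by edge
#' replication so border pixels have eight neighbors):
#'
#' * the qutrit translation `a = (pi/2) * F[level(mu)]`, quantizing intensity
#'   into the 8 levels of the chosen transition row;
#' * membership angles `alpha_j = pi/2 - (a_center - a_j)` toward each of the
#'   eight neighbors, the edge-sensitive term;
#' * the threshold angle `gamma = 2 * pi * sum_j a_j`;
#' * the cardinality `B` (3x3 sum of translated values) and its amplitude
#'   `A = 2 * pi * B`;
#' * the frequency `omega = 2 * pi * (2 * pi - sum_j (a_j - a_center))`;
#' * the aggregated input `x = sum_j a_j * cos(omega - A)`;
#' * the gray-level index `lambda_omega`: the transition-row interval width
#'   selected by the quantization bin of the 8-neighbor sum, rescaled onto
#'   `(0, 1]` by the row's largest interval and floored at `1e-6`.
#'
#' @param img A 2D [image_volume()] or matrix with intensities in `[0, 1]`.
#' @param params A [qisnet_params()].
#' @return A `qutrit_field` list of per-pixel matrices (`state` initialized
#'   to the scaled intensities).
#' @export
neighborhood_features <- function(img, params = qisnet_params()) {
  mu <- as_vol_array(img)
  if (length(dim(mu)) != 2L)
    stop("neighborhood_features: input must be a 2D slice", call. = FALSE)
  if (min(mu) < 0 || max(mu) > 1)
    stop("neighborhood_features: intensities must lie in [0, 1]", call. = FALSE)
  F_row <- qisnet_transition_table()[params$transition_table_index, ]
  # translate intensity -> transition level -> angle in [0, pi/2]
  lvl <- pmin(8L, 1L + floor(mu * 8))
  a <- (pi / 2) * array(F_row[lvl], dim(mu))
  offs <- qisnet_offsets()
  nb <- lapply(seq_len(nrow(offs)), function(r)
    shift_replicate(a, offs[r, ]))
  nb_sum <- Reduce(`+`, nb)                     # sum_j a_j over 8 neighbors
  B <- nb_sum + a                               # 3x3 cardinality
  gamma <- 2 * pi * nb_sum
  omega <- 2 * pi * (2 * pi - (nb_sum - 8 * a))
  A <- 2 * pi * B
  x <- nb_sum * cos(omega - A)                  # sum_j a_j cos(omega - A)
  alpha <- lapply(nb, function(aj) pi / 2 - (a - aj))
  # lambda_omega from the 8-neighbor raw-intensity sum S_N
  S_N <- Reduce(`+`, lapply(seq_len(nrow(offs)), function(r)
    shift_replicate(mu, offs[r, ])))
  widths <- diff(F_row)
  bin <- pmin(7L, 1L + floor((S_N / 8) * 7))
  lambda_omega <- pmax(1e-6, array(widths[bin], dim(mu)) / max(widths))
  structure(list(state = mu, a = a, alpha = alpha, gamma = gamma,
                 omega = omega, A = A, B = B, x = x, S_N = S_N,
                 lambda_omega = lambda_omega, dim = dim(mu)),
            class = "qutrit_field")
}

# edge-replicated shift (every pixel gets 8 neighbors)
shift_replicate <- function(a, off) {
  d <- dim(a)
  ri <- pmin(d[1], pmax(1L, seq_len(d[1]) + off[1]))
  ci <- pmin(d[2], pmax(1L, seq_len(d[2]) + off[2]))
  a[ri, ci, drop = FALSE]
}

#' Coupling of the two rotation layers
#'
#' The single auditable reading of the printed input-output relation: the
#' forward layer rotates each neighbor's interconnection unit vector by its
#' membership angle (`R(theta)`), the backward layer undoes the rotation
#' (`R(-theta)`) while picking up the phase of the previous state, so the
#' output neuron is
#' `z_t = sigma(x_t) * (1/8) * sum_j cos(alpha_tj - gamma_t) * exp(i s_j)`,
#' with `s_j` the neighbor's previous population. The measured population is
#' `|z_t|^2`, clamped to `[0, 1]`.
#'
#' @param field A `qutrit_field`.
#' @param params A [qisnet_params()].
#' @return Complex matrix of output neurons `z_t`.
#' @keywords internal
qisnet_coupling <- function(field, params) {
  offs <- qisnet_offsets()
  s_nb <- lapply(seq_len(nrow(offs)), function(r)
    shift_replicate(field$state, offs[r, ]))
  acc <- 0 + 0i
  for (j in seq_len(nrow(offs)))
    acc <- acc + cos(field$alpha[[j]] - field$gamma) * exp(1i * s_nb[[j]])
  sig <- quantum_sigmoid(field$x, params, field$lambda_omega)
  sig * acc / 8
}

#' One forward/backward iteration of the network
#'
#' Applies the rotation pair, measures the population, clamps to `[0, 1]`,
#' and reports the mean absolute state change. Deterministic.
#'
#' @param field A `qutrit_field` from [neighborhood_features()].
#' @param params A [qisnet_params()].
#' @return The updated field, with attribute `"delta"` = mean absolute change.
#' @export
qisnet_iterate <- function(field, params = qisnet_params()) {
  z <- qisnet_coupling(field, params)
  pop <- Mod(z)^2
  pop[pop > 1] <- 1
  delta <- mean(abs(pop - field$state))
  field$state <- pop
  attr(field, "delta") <- delta
  field
}

qisnet_run_slice <- function(mu, params) {
  field <- neighborhood_features(mu, params)
  for (it in seq_len(params$max_iters)) {
    field <- qisnet_iterate(field, params)
    if (attr(field, "delta") < params$tol) break
  }
  field$state
}

#' QIS-Net segmentation
#'
#' Min-max scales each 2D slice to `[0, 1]` (3D volumes are processed
#' slice-wise and restacked), iterates the network to convergence or
#' `max_iters`, binarizes the converged population map at the highest of a
#' 4-level Otsu threshold, then keeps the largest connected component and
#' fills holes (on the full volume for 3D input). If the thresholded mask is
#' empty, an empty mask is returned with attribute `warning = "empty"`.
#'
#' @param img An [image_volume()] (2D slice or 3D volume) or array.
#' @param params A [qisnet_params()].
#' @return A [binary_mask()] (attribute `"warning"` set to `"empty"` when no
#'   voxel survives thresholding).
#' @export
qisnet_segment <- function(img, params = qisnet_params()) {
  arr <- as_vol_array(img)
  nd <- length(dim(arr))
  seg_slice <- function(sl) {
    mu <- minmax01(sl)
    pop <- qisnet_run_slice(mu, params)
    thr <- tryCatch(multi_otsu_highest(pop, levels = 4L),
                    error = function(e) NA_real_)
    if (is.na(thr)) return(array(FALSE, dim(sl)))
    pop > thr
  }
  raw <- if (nd == 2L) seg_slice(arr) else {
    out <- array(FALSE, dim(arr))
    for (k in seq_len(dim(arr)[3])) out[, , k] <- seg_slice(arr[, , k])
    out
  }
  if (!any(raw)) {
    res <- rewrap_mask(raw, wrap_like(img, raw))
    attr(res, "warning") <- "empty"
    return(res)
  }
  rewrap_mask(postprocess_mask(raw), wrap_like(img, raw))
}

wrap_like <- function(img, arr) {
  if (inherits(img, "image_volume") || inherits(img, "binary_mask"))
    binary_mask(array(FALSE, dim(as_vol_array(img))), spacing = img$spacing,
                origin = img$origin, direction = img$direction)
  else arr
}

#' Sweep the steepness factor and keep the best mask by Dice
#'
#' Mirrors the published per-patient optimization: [qisnet_segment()] is run
#' for every `nu` in the sweep (default `0.02, 0.03, 0.04, 0.05`) and the
#' mask with the highest Dice against `truth` is returned together with an
#' evaluation record holding the winning `nu`.
#'
#' @param img An [image_volume()] or array.
#' @param truth Ground-truth [binary_mask()] of the same shape.
#' @param nus Numeric vector of steepness factors (nonempty).
#' @param params Base [qisnet_params()] (its `nu` is overridden).
#' @param case_id Identifier recorded in the evaluation record.
#' @return A list with `mask` (the best [binary_mask()]), `record` (an
#'   [eval_record()] with the winning `nu`), and `sweep` (a tibble of the
#'   Dice per `nu`).
#' @export
qisnet_sweep <- function(img, truth, nus = c(0.02, 0.03, 0.04, 0.05),
                         params = qisnet_params(), case_id = NA_character_) {
  if (!length(nus)) stop("qisnet_sweep: nus must be nonempty", call. = FALSE)
  check_congruent(img, truth, "image and truth")
  fits <- lapply(nus, function(nu) {
    p <- params; p$nu <- nu
    qisnet_segment(img, p)
  })
  dices <- vapply(fits, function(m) dice(m, truth), numeric(1))
  best <- which.max(dices)
  rec <- eval_record("qisnet", fits[[best]], truth,
                     params = list(nu = nus[best],
                                   transition_table_index =
                                     params$transition_table_index),
                     case_id = case_id)
  list(mask = fits[[best]], record = rec,
       sweep = tibble::tibble(nu = nus, dice = dices))
}
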