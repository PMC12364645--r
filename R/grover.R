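#' NAQSS encoding of an image or superpixel array
#'
#' Quantizes each element to one of `M` intensity levels by uniform binning
#' of the min-max range, maps level `i` to the color angle
#' `a_i = (pi/2) (i - 1) / (M - 1)`, and normalizes the angles into
#' amplitudes `theta_i = a_i / sqrt(sum a^2)` over `N = 2^n` location basis
#' states (`|i> = |x_m>|y_k>`: each axis is padded to the next power of two
#' and the coordinate bits concatenated, most significant axis first).
#' Padded states carry amplitude 0 and label 0. Labels (the per-state
#' foreground qubit `chi_i`) are copied from the marker.
#'
#' @param x An [image_volume()], array, or numeric vector (e.g. superpixel
#'   means).
#' @param M Number of intensity levels (>= 2; default 256).
#' @param marker A congruent [binary_mask()]/logical array/logical vector of
#'   foreground labels, or `NULL` for all-background.
#' @return A `naqss_state` list: `theta`, `label`, `a`, `level`, `M`,
#'   `n_qubits` (location qubits), `dims`, `bits` (bits per axis), `map`
#'   (original linear index of each basis state, `NA` for padding).
#' @examples
#' st <- naqss_encode(matrix(c(0, 1, 1, 1), 2, 2), M = 2,
#'                    marker = matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
#' st$theta
#' @export
naqss_encode <- function(x, M = 256L, marker = NULL) {
  if (M < 2L) stop("naqss_encode: M must be >= 2", call. = FALSE)
  vals <- if (is.numeric(x) && is.null(dim(x))) as.numeric(x)
          else as_vol_array(x)
  dims <- if (is.null(dim(vals))) length(vals) else dim(vals)
  u <- minmax01(if (is.null(dim(vals))) array(vals, length(vals)) else vals)
  lvl <- pmin(as.integer(M), 1L + as.integer(floor(u * M)))
  a <- (pi / 2) * (lvl - 1) / (M - 1)
  if (all(a == 0))
    stop("naqss_encode: degenerate encoding, all elements at minimum ",
         "intensity (unnormalizable)", call. = FALSE)
  lab <- if (is.null(marker)) rep(FALSE, length(vals)) else {
    m <- if (is.logical(marker) && is.null(dim(marker))) marker
         else as_vol_array(marker)
    if (length(m) != length(vals))
      stop("naqss_encode: marker not congruent with input", call. = FALSE)
    as.logical(m)
  }
  bits <- vapply(dims, function(d) ceiling(log2(max(d, 1))), numeric(1))
  bits <- as.integer(bits)
  n_qubits <- sum(bits)
  N <- 2L^n_qubits
  # basis order: coordinate bits concatenated, first axis most significant
  idx0 <- 0:(N - 1L)
  coords <- naqss_index_to_coords(idx0, bits)
  inside <- rep(TRUE, N)
  for (k in seq_along(dims)) inside <- inside & coords[, k] < dims[k]
  map <- rep(NA_integer_, N)
  strides <- cumprod(c(1, dims[-length(dims)]))
  map[inside] <- as.integer(coords[inside, , drop = FALSE] %*% strides) + 1L
  theta <- numeric(N); av <- numeric(N); lv <- integer(N); lb <- rep(FALSE, N)
  theta[inside] <- a[map[inside]]
  av[inside] <- a[map[inside]]
  lv[inside] <- lvl[map[inside]]
  lb[inside] <- lab[map[inside]]
  theta <- theta / sqrt(sum(theta^2))
  structure(list(theta = theta, label = lb, a = av, level = lv, M = M,
                 n_qubits = n_qubits, dims = dims, bits = bits, map = map),
            class = "naqss_state")
}

#' @export
print.naqss_state <- function(x, ...) {
  cat("<naqss_state> N = ", length(x$theta), " (", x$n_qubits,
      " location qubits + 1 label qubit) | marked: ", sum(x$label),
      " | levels M = ", x$M, "\n", sep = "")
  invisible(x)
}

#' Location-index / coordinate-bit round trip
#'
#' `|i> = |x_m>|y_k>(|z..>)`: the 0-based location index is the
#' concatenation of the per-axis coordinate bits, first axis most
#' significant. These two helpers are exact inverses for all `i < 2^sum(bits)`.
#'
#' @param i 0-based integer index (vectorized).
#' @param bits Integer vector of bits per axis.
#' @return `naqss_index_to_coords`: a matrix of 0-based coordinates, one row
#'   per index; `naqss_coords_to_index`: an integer vector of indices.
#' @export
naqss_index_to_coords <- function(i, bits) {
  nd <- length(bits)
  out <- matrix(0L, length(i), nd)
  rem <- as.numeric(i)
  for (k in nd:1) {
    out[, k] <- as.integer(rem %% 2^bits[k])
    rem <- rem %/% 2^bits[k]
  }
  out
}

#' @rdname naqss_index_to_coords
#' @param coords Matrix of 0-based coordinates (one row per index).
#' @export
naqss_coords_to_index <- function(coords, bits) {
  coords <- rbind(coords)
  nd <- length(bits)
  i <- numeric(nrow(coords))
  for (k in seq_len(nd)) i <- i * 2^bits[k] + coords[, k]
  as.integer(i)
}

#' Plan the optimal number of Grover iterations
#'
#' `t = round((pi/2 - phi) / omega)` (half-up, floored at 0), with
#' `omega = acos(1 - 2 r / N)` and `phi = atan((A0 / L0) sqrt(r / (N - r)))`,
#' where `A0` / `L0` are the average amplitudes of the marked / unmarked
#' states. For uniform amplitudes this reduces to the textbook rotation with
#' `omega = 2 asin(sqrt(r / N))` and `t ~ (pi/4) sqrt(N / r)`. `r = N`
#' short-circuits to `t = 0`; `r = 0` is an error.
#'
#' @param state A `naqss_state` from [naqss_encode()].
#' @return A `grover_plan` list: `N`, `r`, `A0`, `L0`, `omega`, `phi`, `t`.
#' @export
grover_plan <- function(state) {
  stopifnot(inherits(state, "naqss_state"))
  N <- length(state$theta)
  r <- sum(state$label)
  if (r == 0L)
    stop("grover_plan: no marked states", call. = FALSE)
  if (r == N) {
    return(structure(list(N = N, r = r, A0 = mean(state$theta), L0 = NA_real_,
                          omega = pi, phi = pi / 2, t = 0L),
                     class = "grover_plan"))
  }
  A0 <- mean(state$theta[state$label])
  L0 <- mean(state$theta[!state$label])
  omega <- acos(1 - 2 * r / N)
  phi <- if (L0 <= 0) pi / 2 else atan((A0 / L0) * sqrt(r / (N - r)))
  t <- max(0, floor((pi / 2 - phi) / omega + 0.5))
  structure(list(N = N, r = r, A0 = A0, L0 = L0, omega = omega, phi = phi,
                 t = as.integer(t)),
            class = "grover_plan")
}

#' @export
print.grover_plan <- function(x, ...) {
  cat("<grover_plan> N = ", x$N, ", r = ", x$r,
      " | omega = ", format(x$omega), ", phi = ", format(x$phi),
      " -> t = ", x$t, "\n", sep = "")
  invisible(x)
}

#' Apply k rounds of oracle + diffusion
#'
#' Each round phase-flips the marked amplitudes (the oracle's Z gate) and
#' reflects all amplitudes about their mean (the diffusion operator). Both
#' reflections are unitary, so the norm is conserved; the whole operation is
#' deterministic.
#'
#' @param state A `naqss_state`.
#' @param k Number of Grover rounds (>= 0).
#' @return The state with updated `theta`.
#' @export
grover_iterate <- function(state, k) {
  stopifnot(inherits(state, "naqss_state"), k >= 0)
  theta <- state$theta
  marked <- state$label
  for (step in seq_len(k)) {
    theta[marked] <- -theta[marked]
    theta <- 2 * mean(theta) - theta
  }
  state$theta <- theta
  state
}

#' Success probability of measuring a marked state
#'
#' The summed squared amplitude over marked states after `k` Grover rounds,
#' `Pr(psi_g) = sum_{i in A} theta_i^2`. For uniform initial amplitudes this
#' equals `sin^2((2k + 1) asin(sqrt(r / N)))`.
#'
#' @param state A `naqss_state`.
#' @param k Number of rounds (>= 0).
#' @return A probability in `[0, 1]`.
#' @export
grover_success_probability <- function(state, k) {
  st <- grover_iterate(state, k)
  sum(st$theta[st$label]^2)
}

# Independent test oracle: full complex statevector built from gate
# constructions (Hadamard tensor powers, Z-oracle as a diagonal, diffusion
# as H^{(x)n} (2|0><0| - I) H^{(x)n}), for n <= 12 qubits. Used only to
# cross-check the reflect-about-mean path on uniform starts.
grover_statevector_reference <- function(n_qubits, marked_idx, k) {
  N <- 2L^n_qubits
  stopifnot(n_qubits <= 12L, all(marked_idx >= 1L), all(marked_idx <= N))
  H1 <- matrix(1 / sqrt(2) * c(1, 1, 1, -1), 2, 2)
  Hn <- Reduce(kronecker, rep(list(H1), n_qubits))
  psi <- Hn %*% c(1, rep(0, N - 1))           # |0..0> through Hadamards
  oracle <- rep(1, N); oracle[marked_idx] <- -1
  refl0 <- 2 * outer(c(1, rep(0, N - 1)), c(1, rep(0, N - 1))) - diag(N)
  diffusion <- Hn %*% refl0 %*% Hn
  for (step in seq_len(k)) psi <- diffusion %*% (oracle * psi)
  sum(Mod(psi[marked_idx])^2)
}

#' Grover-search segmentation with externally marked states
#'
#' Encodes the image (or, when a [superpixel_graph()] is supplied, the
#' superpixel mean intensities) into an NAQSS state whose labels come from
#' the marker, runs the planned number of Grover rounds, recovers the
#' amplified set by thresholding squared amplitudes above the uniform level
#' `1/N`, broadcasts superpixel labels back to voxels, and applies the
#' standard post-processing (largest connected component + hole filling).
#'
#' @param img An [image_volume()] or array.
#' @param marker A nonempty congruent [binary_mask()] designating candidate
#'   foreground (the marked states).
#' @param superpixels Optional [superpixel_graph()] built on `img`.
#' @param M Number of intensity levels for the encoding.
#' @return A list: `mask` (post-processed [binary_mask()]), `raw` (the
#'   recovered mask before post-processing), `plan` (the [grover_plan()]).
#' @export
grover_segment <- function(img, marker, superpixels = NULL, M = 256L) {
  arr <- as_vol_array(img)
  mk <- as_vol_array(marker)
  check_congruent(arr, mk, "image and marker")
  if (!any(mk)) stop("grover_segment: empty marker (no marked states)",
                     call. = FALSE)
  if (is.null(superpixels)) {
    st <- naqss_encode(arr, M = M, marker = mk)
  } else {
    stopifnot(inherits(superpixels, "superpixel_graph"))
    sp_label <- vapply(seq_along(superpixels$means), function(i)
      mean(mk[superpixels$membership == i]) > 0.5, logical(1))
    if (!any(sp_label))
      stop("grover_segment: marker covers no superpixel majority",
           call. = FALSE)
    st <- naqss_encode(superpixels$means, M = M, marker = sp_label)
  }
  plan <- grover_plan(st)
  amplified <- grover_iterate(st, plan$t)
  # measuring the label qubit projects onto the marked subspace; the
  # amplitude threshold then recovers the amplified states within it
  hit <- amplified$label & amplified$theta^2 > 1 / length(amplified$theta)
  raw <- array(FALSE, dim(arr))
  keep <- !is.na(st$map) & hit
  if (is.null(superpixels)) {
    raw[st$map[keep]] <- TRUE
  } else {
    sp_hit <- st$map[keep]                     # superpixel ids
    raw[superpixels$membership %in% sp_hit] <- TRUE
  }
  out <- if (any(raw)) postprocess_mask(raw) else raw
  list(mask = rewrap_mask(out, wrap_like(img, out)),
       raw = rewrap_mask(raw, wrap_like(img, raw)),
       plan = plan)
}
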