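#' Specification of a synthetic abdominal phantom
#'
#' Describes a single-channel 2D/3D volume containing one bright ellipsoidal
#' organ ("liver") over darker background tissue, with optional additive
#' Gaussian noise, a smooth multiplicative bias field, an optional dark
#' distractor sphere, and a contrast "phase" that rescales the organ
#' intensity. These phantoms emulate the statistical structure of
#' contrast-phase abdominal MR (bright organ, smooth shading, noise); they
#' make no claim about MR physics.
#'
#' Phase multipliers applied to the organ mean: pre-contrast 1.0,
#' arterial 1.3, venous 1.15.
#'
#' @param shape Integer vector of 2 or 3 grid dimensions.
#' @param liver_center Ellipsoid centre in voxels (defaults to grid centre).
#' @param liver_axes Ellipsoid semi-axes in voxels (defaults to 30% of shape).
#' @param liver_intensity,background_intensity Mean levels (arbitrary units).
#' @param distractor_intensity Mean level of the optional distractor sphere;
#'   `NULL` for none.
#' @param distractor_center,distractor_radius Distractor geometry (voxels).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param bias_amplitude Peak relative deviation of the multiplicative bias
#'   field, in `[0, 1)`.
#' @param phase One of `"pre-contrast"`, `"arterial"`, `"venous"`.
#' @param seed Integer RNG seed; identical specs give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         liver_center = NULL, liver_axes = NULL,
                         liver_intensity = 200, background_intensity = 80,
                         distractor_intensity = NULL,
                         distractor_center = NULL, distractor_radius = NULL,
                         noise_sd = 0, bias_amplitude = 0,
                         phase = c("pre-contrast", "arterial", "venous"),
                         seed = 1L) {
  phase <- match.arg(phase)
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L) || any(shape < 4L))
    stop("phantom_spec: shape must have 2 or 3 axes, each >= 4", call. = FALSE)
  if (is.null(liver_center)) liver_center <- (shape + 1) / 2
  if (is.null(liver_axes)) liver_axes <- pmax(2, 0.3 * shape)
  if (length(liver_center) != nd || length(liver_axes) != nd)
    stop("phantom_spec: liver_center/liver_axes must match shape length",
         call. = FALSE)
  if (any(liver_axes <= 0))
    stop("phantom_spec: liver_axes must be positive", call. = FALSE)
  if (any(liver_center - liver_axes < 1) || any(liver_center + liver_axes > shape))
    stop("phantom_spec: ellipsoid does not fit inside the grid", call. = FALSE)
  if (min(liver_intensity, background_intensity) < 0 || noise_sd < 0)
    stop("phantom_spec: intensities and noise_sd must be >= 0", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("phantom_spec: bias_amplitude must lie in [0, 1)", call. = FALSE)
  if (!is.null(distractor_intensity)) {
    if (is.null(distractor_center))
      distractor_center <- pmax(3, round(shape * 0.15))
    if (is.null(distractor_radius))
      distractor_radius <- max(2, round(min(shape) * 0.08))
    if (distractor_intensity < 0)
      stop("phantom_spec: distractor_intensity must be >= 0", call. = FALSE)
  }
  structure(list(shape = shape, liver_center = liver_center,
                 liver_axes = liver_axes,
                 liver_intensity = liver_intensity,
                 background_intensity = background_intensity,
                 distractor_intensity = distractor_intensity,
                 distractor_center = distractor_center,
                 distractor_radius = distractor_radius,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 phase = phase, seed = as.integer(seed)),
            class = "phantom_spec")
}

phase_multiplier <- function(phase) {
  switch(phase, "pre-contrast" = 1.0, "arterial" = 1.3, "venous" = 1.15)
}

# coordinate grids as a list of arrays, one per axis
coord_grids <- function(shape) {
  nd <- length(shape)
  lapply(seq_len(nd), function(k) {
    perm <- seq_len(nd)
    v <- seq_len(shape[k])
    a <- array(rep(v, times = prod(shape[-k]) / 1), dim = c(shape[k], shape[-k]))
    aperm(a, order(c(k, seq_len(nd)[-k])))
  })
}

ellipsoid_mask <- function(shape, center, axes) {
  g <- coord_grids(shape)
  q <- 0
  for (k in seq_along(shape)) q <- q + ((g[[k]] - center[k]) / axes[k])^2
  q <= 1
}

#' Generate a phantom volume with its ground-truth mask
#'
#' The mask is the exact analytic ellipsoid interior. The image is the
#' phase-scaled piecewise-constant mean map, multiplied by a smooth bias
#' field (a product of half-period cosines per axis scaled to
#' `1 +/- bias_amplitude`), plus seeded additive Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([image_volume()]), `truth`
#'   ([binary_mask()]) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32), noise_sd = 0))
#' sort(unique(as.vector(ph$image$data)))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  truth <- ellipsoid_mask(shape, spec$liver_center, spec$liver_axes)
  means <- array(spec$background_intensity, shape)
  means[truth] <- spec$liver_intensity * phase_multiplier(spec$phase)
  if (!is.null(spec$distractor_intensity)) {
    ds <- ellipsoid_mask(shape, spec$distractor_center,
                         rep(spec$distractor_radius, length(shape)))
    means[ds & !truth] <- spec$distractor_intensity
  }
  img <- means
  if (spec$bias_amplitude > 0) {
    g <- coord_grids(shape)
    b <- 1
    for (k in seq_along(shape))
      b <- b * cos(pi * ((g[[k]] - 1) / (shape[k] - 1) - 0.5))
    img <- img * (1 + spec$bias_amplitude * (2 * b - 1))
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(spec$seed)
    img <- img + array(rnorm(length(img), sd = spec$noise_sd), shape)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  list(image = image_volume(img), truth = binary_mask(truth), spec = spec)
}

#' Specification of a corrupted marker mask
#'
#' Markers stand in for an external (e.g. AI) prediction that designates
#' Grover's marked states. `oracle` returns the truth unchanged; `eroded` /
#' `dilated` apply one pass of the 3x3(x3) box structuring element; `noisy`
#' flips exactly `round(error_rate * n_boundary)` boundary voxels, where the
#' boundary is the set of voxels differing from a face neighbor on either
#' side of the truth surface.
#'
#' @param mode One of `"oracle"`, `"eroded"`, `"dilated"`, `"noisy"`.
#' @param error_rate Fraction of boundary voxels flipped in `[0, 0.5]`.
#' @param seed Integer RNG seed for the noisy mode.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(mode = c("oracle", "eroded", "dilated", "noisy"),
                        error_rate = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (error_rate < 0 || error_rate > 0.5)
    stop("marker_spec: error_rate must lie in [0, 0.5]", call. = FALSE)
  structure(list(mode = mode, error_rate = error_rate, seed = as.integer(seed)),
            class = "marker_spec")
}

#' Corrupt a ground-truth mask into a marker
#'
#' Noisy flips are nested: the seeded permutation of boundary voxels is drawn
#' once and the first `round(error_rate * n_boundary)` entries are flipped,
#' so the marker's Dice against truth is non-increasing in `error_rate`.
#'
#' @param truth A [binary_mask()] (nonempty unless `mode = "oracle"`).
#' @param spec A [marker_spec()].
#' @return A [binary_mask()].
#' @export
make_marker <- function(truth, spec) {
  stopifnot(inherits(spec, "marker_spec"))
  arr <- as_vol_array(truth)
  if (spec$mode != "oracle" && !any(arr))
    stop("make_marker: truth is empty", call. = FALSE)
  out <- switch(spec$mode,
    oracle = arr,
    eroded = binary_erode(arr, full = TRUE),
    dilated = binary_dilate(arr, full = TRUE),
    noisy = {
      bnd <- which(boundary_voxels(arr, side = "both"))
      k <- round(spec$error_rate * length(bnd))
      flipped <- arr
      if (k > 0) {
        old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
        set.seed(spec$seed)
        perm <- sample(bnd)
        if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
        flipped[perm[seq_len(k)]] <- !flipped[perm[seq_len(k)]]
      }
      flipped
    })
  rewrap_mask(out, truth)
}
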