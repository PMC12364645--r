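#' NAQSS qubit count for a grid
#'
#' An image with `prod(dims)` elements needs `n = ceiling(log2(prod(dims)))`
#' location qubits and one extra intensity/label qubit, so `n + 1` in total.
#' A 1024 x 1024 x 72 volume needs 28 qubits.
#'
#' @param dims Integer vector of grid dimensions (each >= 1, nonempty).
#' @return A list with `location_qubits` and `total_qubits`.
#' @examples
#' naqss_qubits(c(1024, 1024, 72))$total_qubits  # 28
#' @export
naqss_qubits <- function(dims) {
  if (!length(dims)) stop("naqss_qubits: dims must be nonempty", call. = FALSE)
  if (any(dims < 1)) stop("naqss_qubits: every dim must be >= 1", call. = FALSE)
  loc <- as.integer(ceiling(log2(prod(as.numeric(dims)))))
  loc <- max(loc, 0L)
  list(location_qubits = loc, total_qubits = loc + 1L)
}

#' Classical storage of a grid
#'
#' `bits = prod(dims) * bit_depth`; megabytes use the decimal convention
#' (`8e6` bits per MB), matching the usual "2.42 Gigabits / about 300 MB"
#' arithmetic for a 32-bit 1024 x 1024 x 72 volume.
#'
#' @param dims Integer vector of grid dimensions.
#' @param bit_depth Bits per element: 8, 16, 32 or 64.
#' @return A list with `bits` and `megabytes`.
#' @examples
#' classical_storage(c(1024, 1024, 72), 32)
#' @export
classical_storage <- function(dims, bit_depth) {
  if (!bit_depth %in% c(8, 16, 32, 64))
    stop("classical_storage: bit_depth must be 8, 16, 32 or 64", call. = FALSE)
  bits <- prod(as.numeric(dims)) * bit_depth
  list(bits = bits, megabytes = bits / 8e6)
}

#' Logical qubit count of the annealing formulation
#'
#' One binary variable per graph node: an image preprocessed into `n`
#' superpixels needs `n` logical qubits on an annealer.
#'
#' @param n_superpixels Node count (>= 1).
#' @return `n_superpixels`, as an integer.
#' @export
annealer_logical_qubits <- function(n_superpixels) {
  if (n_superpixels < 1) stop("annealer_logical_qubits: n must be >= 1",
                              call. = FALSE)
  as.integer(n_superpixels)
}

#' Full quantum-resource report for a grid
#'
#' @param dims Grid dimensions.
#' @param bit_depth Bits per element for the classical-storage comparison.
#' @param n_superpixels Optional superpixel count for the annealer estimate.
#' @return A one-row [tibble::tibble()] with `n_pixels`, `location_qubits`,
#'   `total_qubits`, `storage_bits`, `storage_megabytes`, and (if requested)
#'   `annealer_logical_qubits`.
#' @export
resource_report <- function(dims, bit_depth = 32, n_superpixels = NULL) {
  q <- naqss_qubits(dims)
  s <- classical_storage(dims, bit_depth)
  out <- tibble::tibble(
    n_pixels = prod(as.numeric(dims)),
    location_qubits = q$location_qubits,
    total_qubits = q$total_qubits,
    storage_bits = s$bits,
    storage_megabytes = s$megabytes
  )
  if (!is.null(n_superpixels))
    out$annealer_logical_qubits <- annealer_logical_qubits(n_superpixels)
  out
}
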