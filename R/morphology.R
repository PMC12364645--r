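# Shift-based binary morphology on plain 2D/3D arrays.
#
# Connectivity convention (complementary pair): foreground components use
# 8-connectivity in 2D / 26 in 3D; background operations (hole filling) use
# 4 / 6, so that a foreground curve and the background it separates are
# never both "connected" across the same diagonal.

# All integer offset vectors with entries in {-1,0,1}, excluding the origin.
# full = TRUE gives the 8/26-neighborhood, FALSE the 4/6 face neighborhood.
neighbor_offsets <- function(nd, full = TRUE) {
  grid <- do.call(expand.grid, rep(list(-1:1), nd))
  grid <- as.matrix(grid)
  keep <- rowSums(grid != 0) > 0
  if (!full) keep <- keep & rowSums(abs(grid)) == 1
  grid[keep, , drop = FALSE]
}

# Value of the neighbor at `off` for every cell: out[i] = a[i + off],
# with `fill` where i + off leaves the array.
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o); src[[k]] <- seq_len(d[k] - o) + o }
    else        { dst[[k]] <- seq_len(d[k] + o) - o; src[[k]] <- seq_len(d[k] + o) }
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src)))))
}

# Label connected foreground components; returns integer array, 0 = background.
# Components are relabelled so that component 1 contains the smallest linear
# index among foreground voxels, component 2 the next-smallest new index, etc.
label_components <- function(mask, full = TRUE) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  node_of <- integer(length(mask))
  node_of[idx] <- seq_along(idx)
  offs <- neighbor_offsets(length(d), full)
  # keep one offset per +/- pair: edges are undirected
  offs <- offs[apply(offs, 1L, function(o) {
    nz <- o[o != 0]; nz[1] > 0
  }), , drop = FALSE]
  strides <- cumprod(c(1L, d[-length(d)]))
  coords <- arrayInd(idx, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- sweep(coords, 2L, off, `+`)
    ok <- rep(TRUE, nrow(nb))
    for (k in seq_along(d)) ok <- ok & nb[, k] >= 1L & nb[, k] <= d[k]
    if (!any(ok)) next
    nb_lin <- as.integer((nb[ok, , drop = FALSE] - 1L) %*% strides) + 1L
    hit <- mask[nb_lin]
    if (!any(hit)) next
    edges[[r]] <- cbind(node_of[idx[ok][hit]], node_of[nb_lin[hit]])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    comp <- seq_along(idx)  # all isolated voxels
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(idx)]
  }
  # stable relabelling by first (smallest) linear index in each component
  first_seen <- !duplicated(comp)
  new_id <- integer(max(comp))
  new_id[comp[first_seen]] <- seq_len(sum(first_seen))
  lab[idx] <- new_id[comp]
  lab
}

#' Keep only the largest connected component
#'
#' Foreground connectivity is 8 in 2D and 26 in 3D. Size ties are broken in
#' favour of the component containing the smallest linear index. An empty
#' mask is returned unchanged.
#'
#' @param mask A [binary_mask()] or logical array.
#' @return Same type as the input.
#' @export
largest_connected_component <- function(mask) {
  arr <- as_vol_array(mask)
  lab <- label_components(arr, full = TRUE)
  if (!any(lab > 0L)) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)  # ties -> lowest id = smallest first linear index
  out <- lab == best
  rewrap_mask(out, mask)
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connectivity in 2D, 6 in 3D) that do not touch the
#' array border are flipped to foreground.
#'
#' @param mask A [binary_mask()] or logical array.
#' @return Same type as the input.
#' @export
fill_holes <- function(mask) {
  arr <- as_vol_array(mask)
  bg <- !arr
  lab <- label_components(bg, full = FALSE)
  if (!any(lab > 0L)) return(mask)
  border <- border_indices(dim(arr))
  open_ids <- unique(lab[border])
  open_ids <- open_ids[open_ids > 0L]
  holes <- bg & !(lab %in% open_ids)
  rewrap_mask(arr | holes, mask)
}

border_indices <- function(d) {
  idx <- array(FALSE, d)
  for (k in seq_along(d)) {
    ix <- rep(list(quote(expr = )), length(d))
    ix[[k]] <- c(1L, d[k])
    idx <- do.call(`[<-`, c(list(idx), ix, list(TRUE)))
  }
  which(idx)
}

rewrap_mask <- function(arr, template) {
  arr <- array(as.logical(arr), dim(as_vol_array(template)))
  if (inherits(template, "binary_mask"))
    binary_mask(arr, spacing = template$spacing, origin = template$origin,
                direction = template$direction)
  else arr
}

# Erosion / dilation with the 3x3(x3) box structuring element.
binary_erode <- function(arr, full = TRUE) {
  out <- arr
  for (r in seq_len(nrow(offs <- neighbor_offsets(length(dim(arr)), full))))
    out <- out & shift_array(arr, offs[r, ], FALSE)
  out
}

binary_dilate <- function(arr, full = TRUE) {
  out <- arr
  for (r in seq_len(nrow(offs <- neighbor_offsets(length(dim(arr)), full))))
    out <- out | shift_array(arr, offs[r, ], FALSE)
  out
}

# Voxels whose value differs from at least one face neighbor (array border
# counts as background); symmetric boundary = inner | outer shell.
boundary_voxels <- function(arr, side = c("both", "inner")) {
  side <- match.arg(side)
  inner <- arr & !binary_erode(arr, full = FALSE)
  if (side == "inner") return(inner)
  outer <- !arr & binary_dilate(arr, full = FALSE)
  inner | outer
}

#' Standard post-processing: largest component, then hole filling
#'
#' The shared clean-up applied to every method's raw binary prediction.
#'
#' @param mask A [binary_mask()] or logical array.
#' @return Same type as the input.
#' @export
postprocess_mask <- function(mask) {
  fill_holes(largest_connected_component(mask))
}
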