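# Independent brute-force oracles used to cross-check the metrology stage.
# These deliberately use naive per-voxel scans (and igraph for connected
# components) rather than the package's own code paths.

# AP extent between first and last supra-threshold voxel centers on slice k,
# by scanning every voxel.
oracle_slice_extent_y <- function(volume, threshold, k) {
  ys <- grid_coords(volume$grid, 2)
  found <- c()
  for (j in seq_len(volume$grid$dim[2]))
    for (i in seq_len(volume$grid$dim[1]))
      if (volume$voxels[i, j, k] >= threshold) found <- c(found, j)
  if (!length(found)) return(NA_real_)
  ys[max(found)] - ys[min(found)]
}

# Largest 6-connected component volume via igraph, scanning voxel pairs.
oracle_contour_volume_cc <- function(volume, lo, hi) {
  mask <- volume$voxels >= lo & volume$voxels <= hi
  idx <- which(mask)
  if (!length(idx)) return(0)
  dims <- dim(mask)
  id <- array(0L, dims)
  id[idx] <- seq_along(idx)
  edges <- c()
  co <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    for (ax in 1:3) {
      q <- p
      q[ax] <- q[ax] + 1L
      if (q[ax] <= dims[ax] && mask[q[1], q[2], q[3]])
        edges <- c(edges, id[p[1], p[2], p[3]], id[q[1], q[2], q[3]])
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  max(igraph::components(g)$csize) * voxel_volume_cc(volume$grid)
}
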