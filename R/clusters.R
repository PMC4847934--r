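#' Threshold a group t-map into clusters
#'
#' Voxelwise familywise-error control by Bonferroni correction over in-mask
#' voxels: the one-sided threshold is `qt(1 - alpha_fwe / n_in_mask, dof)`.
#' Suprathreshold voxels are grouped into connected components
#' (26-neighbourhood by default) and components with more than `k_min`
#' voxels are retained, sorted by peak t descending.
#'
#' @param statmap A `stat_map` from [group_ttest()].
#' @param alpha_fwe Familywise error rate (default 0.05).
#' @param k_min Cluster extent threshold: clusters must have `size_k > k_min`
#'   voxels (default 20).
#' @param connectivity 6, 18 or 26 (face, edge, corner neighbours).
#' @return List of clusters, each `list(peak_voxel, peak_t, size_k, voxels)`.
#' @export
threshold_clusters <- function(statmap, alpha_fwe = 0.05, k_min = 20L,
                               connectivity = 26L) {
  stopifnot(inherits(statmap, "stat_map"))
  if (statmap$n_in_mask == 0L) stop("empty analysis mask")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  thr <- stats::qt(1 - alpha_fwe / statmap$n_in_mask, statmap$dof)
  supra <- statmap$mask & !is.na(statmap$tmap) & statmap$tmap > thr
  comps <- connected_components(supra, connectivity)
  out <- lapply(comps, function(vox) {
    tv <- statmap$tmap[vox]
    peak <- which.max(tv)
    list(peak_voxel = as.integer(vox[peak, ]), peak_t = tv[peak],
         size_k = nrow(vox), voxels = vox)
  })
  out <- Filter(function(cl) cl$size_k > k_min, out)
  out[order(vapply(out, `[[`, numeric(1), "peak_t"), decreasing = TRUE)]
}

# Label connected components of a logical 3D array; returns a list of
# n x 3 voxel-index matrices.
connected_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  labels <- array(0L, dims)
  comp <- list()
  next_label <- 0L
  coords <- arrayInd(idx, dims)
  for (k in seq_along(idx)) {
    if (labels[idx[k]] != 0L) next
    next_label <- next_label + 1L
    queue <- matrix(coords[k, ], 1)
    labels[idx[k]] <- next_label
    members <- queue
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      new <- mask[lin] & labels[lin] == 0L
      if (any(new)) {
        labels[lin[new]] <- next_label
        queue <- rbind(queue, nb[new, , drop = FALSE])
        members <- rbind(members, nb[new, , drop = FALSE])
      }
    }
    colnames(members) <- c("x", "y", "z")
    comp[[next_label]] <- members
  }
  comp
}

#' Cluster table in reporting form
#'
#' @param clusters Output of [threshold_clusters()].
#' @return data.frame with columns peak_x, peak_y, peak_z, size_k, peak_t.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(peak_x = integer(), peak_y = integer(),
                      peak_z = integer(), size_k = integer(),
                      peak_t = numeric()))
  data.frame(
    peak_x = vapply(clusters, function(cl) cl$peak_voxel[1], integer(1)),
    peak_y = vapply(clusters, function(cl) cl$peak_voxel[2], integer(1)),
    peak_z = vapply(clusters, function(cl) cl$peak_voxel[3], integer(1)),
    size_k = vapply(clusters, function(cl) cl$size_k, integer(1)),
    peak_t = vapply(clusters, function(cl) cl$peak_t, numeric(1)))
}
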