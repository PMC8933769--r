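# Cluster-extent thresholding of Z maps and five-region positivity calls.
# Testing is one-sided in the positive direction only: amyloid accumulation
# is an increase, so negative Z never drives a call.

conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  lim <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3,
                stop("connectivity must be 6, 18 or 26"))
  g[rowSums(abs(g)) <= lim, , drop = FALSE]
}

#' Threshold a Z map into suprathreshold clusters
#'
#' Connected components of \{Z >= z_threshold\} inside the analysis mask,
#' under 6/18/26 connectivity; components smaller than `min_voxels` are
#' discarded. The defaults (Z >= 2.6, i.e. one-sided p < 0.01 on the normal
#' tail, with a minimum extent of 300 voxels = 2.4 cc on the 2 mm grid) are
#' the false-positive control used for regional positivity.
#'
#' @param zm An `aq_zmap`.
#' @param z_threshold Positive Z threshold (default 2.6).
#' @param min_voxels Minimum cluster extent in voxels (default 300).
#' @param connectivity 6, 18 (default) or 26.
#' @return An `aq_clusters`: a list with `clusters` (each holding `voxels`
#'   as linear indices, `size`, `peak_z`, `centroid_mm`), the thresholds, and
#'   the grid. Clusters are sorted by size descending, ties by peak Z then
#'   lexicographic centroid. May be empty.
#' @export
threshold_clusters <- function(zm, z_threshold = 2.6, min_voxels = 300,
                               connectivity = 18) {
  stopifnot(z_threshold > 0, min_voxels > 0)
  g <- zm$z$grid
  d <- g$dims
  supra <- which(zm$z$data >= z_threshold & zm$mask$data == 1L)
  clusters <- list()
  if (length(supra) > 0) {
    off <- conn_offsets(connectivity)
    in_set <- array(FALSE, d); in_set[supra] <- TRUE
    visited <- array(FALSE, d)
    # linear index -> 0-based coords
    to_coord <- function(lin) {
      lin0 <- lin - 1
      i <- lin0 %% d[1]
      j <- (lin0 %/% d[1]) %% d[2]
      k <- lin0 %/% (d[1] * d[2])
      cbind(i, j, k)
    }
    for (seed in supra) {
      if (visited[seed]) next
      members <- integer(0)
      frontier <- seed
      visited[seed] <- TRUE
      while (length(frontier)) {
        members <- c(members, frontier)
        co <- to_coord(frontier)
        nb <- co[rep(seq_len(nrow(co)), each = nrow(off)), , drop = FALSE] +
          off[rep(seq_len(nrow(off)), nrow(co)), , drop = FALSE]
        ok <- nb[, 1] >= 0 & nb[, 1] < d[1] &
              nb[, 2] >= 0 & nb[, 2] < d[2] &
              nb[, 3] >= 0 & nb[, 3] < d[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- unique(nb[, 1] + d[1] * (nb[, 2] + d[2] * nb[, 3]) + 1)
        lin <- lin[in_set[lin] & !visited[lin]]
        visited[lin] <- TRUE
        frontier <- lin
      }
      if (length(members) >= min_voxels) {
        zv <- zm$z$data[members]
        cen <- colMeans(voxel_to_world(g, to_coord(members)))
        clusters[[length(clusters) + 1]] <- list(
          voxels = sort(members), size = length(members),
          peak_z = max(zv), centroid_mm = cen)
      }
    }
    if (length(clusters) > 1) {
      key <- order(-vapply(clusters, `[[`, 0, "size"),
                   -vapply(clusters, `[[`, 0, "peak_z"),
                   vapply(clusters, function(cl) cl$centroid_mm[1], 0),
                   vapply(clusters, function(cl) cl$centroid_mm[2], 0),
                   vapply(clusters, function(cl) cl$centroid_mm[3], 0))
      clusters <- clusters[key]
    }
  }
  structure(list(clusters = clusters, z_threshold = z_threshold,
                 min_voxels = min_voxels, connectivity = connectivity,
                 grid = g), class = "aq_clusters")
}

#' @export
print.aq_clusters <- function(x, ...) {
  cat(sprintf("<aq_clusters> %d cluster(s) at Z >= %g, >= %d voxels, conn %d\n",
              length(x$clusters), x$z_threshold, x$min_voxels, x$connectivity))
  if (length(x$clusters)) print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy aq_clusters
#' @export
tidy.aq_clusters <- function(x, ...) {
  if (!length(x$clusters)) {
    return(tibble::tibble(cluster = integer(0), size = integer(0),
                          volume_cc = numeric(0), peak_z = numeric(0),
                          centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
                          centroid_z_mm = numeric(0)))
  }
  cc <- voxel_volume_cc(x$grid)
  tibble::tibble(
    cluster = seq_along(x$clusters),
    size = vapply(x$clusters, `[[`, 0, "size"),
    volume_cc = vapply(x$clusters, `[[`, 0, "size") * cc,
    peak_z = vapply(x$clusters, `[[`, 0, "peak_z"),
    centroid_x_mm = vapply(x$clusters, function(cl) cl$centroid_mm[1], 0),
    centroid_y_mm = vapply(x$clusters, function(cl) cl$centroid_mm[2], 0),
    centroid_z_mm = vapply(x$clusters, function(cl) cl$centroid_mm[3], 0))
}

#' Regional positivity calls from surviving clusters
#'
#' A region is called positive iff at least one voxel of at least one
#' surviving cluster lies inside its mask; per-region overlap voxel counts
#' are reported.
#'
#' @param cs An `aq_clusters`.
#' @param vs An `aq_voiset` on the same grid.
#' @return An `aq_calls` tibble with `region`, `overlap_voxels`, `positive`.
#' @export
regional_positivity <- function(cs, vs) {
  stop_if_grid_mismatch(cs$grid, vs$grid, "clusters and VOI set")
  all_vox <- unlist(lapply(cs$clusters, `[[`, "voxels"))
  out <- tibble::tibble(
    region = REGION_NAMES,
    overlap_voxels = vapply(REGION_NAMES, function(nm) {
      if (!length(all_vox)) return(0L)
      sum(vs$region_masks[[nm]]$data[all_vox] == 1L)
    }, 0L)
  )
  out$positive <- out$overlap_voxels >= 1
  class(out) <- c("aq_calls", class(out))
  out
}
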