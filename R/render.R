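# Orthogonal-slice PNG export of Z maps over anatomy, with the target-region
# contour. Replaces interactive display: one PNG per requested slice per
# orientation (axial, coronal, sagittal).

hot_colormap <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  cbind(pmin(3 * t, 1), pmin(pmax(3 * t - 1, 0), 1), pmin(pmax(3 * t - 2, 0), 1))
}

# in-plane 4-neighbour boundary of a binary slice
slice_contour <- function(m) {
  if (!any(m)) return(m)
  er <- m
  er[-1, ] <- er[-1, ] & m[-nrow(m), ]
  er[-nrow(m), ] <- er[-nrow(m), ] & m[-1, ]
  er[, -1] <- er[, -1] & m[, -ncol(m)]
  er[, -ncol(m)] <- er[, -ncol(m)] & m[, -1]
  m & !er
}

#' Render orthogonal slice overlays of a Z map
#'
#' Writes axial, coronal and sagittal PNG slices: grayscale anatomy, a
#' hot-colour Z overlay scaled between `z_low` and `z_high` (only voxels with
#' Z >= `z_low` inside the analysis mask are painted), and the target-VOI
#' contour in white. Optionally restricts the overlay to voxels belonging to
#' clusters surviving `min_voxels`.
#'
#' @param zm An `aq_zmap`.
#' @param anatomy Background `aq_vol` on the same grid (e.g. standardized MRI
#'   or the PET itself).
#' @param vs An `aq_voiset` (target contour source).
#' @param opts List: `z_low` (default 2.6), `z_high` (default 7), `min_voxels`
#'   (default 0 = no cluster filtering), `slices` (slice count per
#'   orientation, default 6), `connectivity` (default 18), `out_dir`
#'   (default `tempdir()`), `prefix`.
#' @return Character vector of written PNG paths (3 x slices), invisibly.
#' @export
render_overlay <- function(zm, anatomy, vs, opts = list()) {
  o <- utils::modifyList(list(z_low = 2.6, z_high = 7, min_voxels = 0,
                              slices = 6, connectivity = 18,
                              out_dir = tempdir(), prefix = "zmap"), opts)
  if (o$z_low >= o$z_high) stop("z_low must be below z_high")
  stop_if_grid_mismatch(zm$z$grid, anatomy$grid, "Z map and anatomy")
  if (!dir.exists(o$out_dir)) dir.create(o$out_dir, recursive = TRUE)
  z <- zm$z$data
  show <- z >= o$z_low & zm$mask$data == 1L
  if (o$min_voxels > 0) {
    cs <- threshold_clusters(zm, o$z_low, o$min_voxels, o$connectivity)
    keep <- array(FALSE, zm$z$grid$dims)
    keep[unlist(lapply(cs$clusters, `[[`, "voxels"))] <- TRUE
    show <- show & keep
  }
  an <- anatomy$data
  rngd <- range(an)
  an <- if (diff(rngd) > 0) (an - rngd[1]) / diff(rngd) else an * 0
  d <- zm$z$grid$dims
  contour3 <- vs$target_mask$data == 1L
  files <- character(0)
  planes <- list(axial = 3L, coronal = 2L, sagittal = 1L)
  for (pn in names(planes)) {
    ax <- planes[[pn]]
    ks <- unique(round(seq(0.2, 0.8, length.out = o$slices) * (d[ax] - 1))) + 1
    for (s in ks) {
      slc <- switch(ax, an[s, , ], an[, s, ], an[, , s])
      zsl <- switch(ax, z[s, , ], z[, s, ], z[, , s])
      shs <- switch(ax, show[s, , ], show[, s, ], show[, , s])
      cts <- slice_contour(switch(ax, contour3[s, , ], contour3[, s, ], contour3[, , s]))
      img <- array(rep(slc, 3), dim = c(dim(slc), 3))
      if (any(shs)) {
        t <- (zsl[shs] - o$z_low) / (o$z_high - o$z_low)
        col <- hot_colormap(t)
        for (ch in 1:3) {
          pl <- img[, , ch]; pl[shs] <- col[, ch]; img[, , ch] <- pl
        }
      }
      if (any(cts)) for (ch in 1:3) {
        pl <- img[, , ch]; pl[cts] <- 1; img[, , ch] <- pl
      }
      # flip rows so superior/anterior is up in the PNG
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      img <- aperm(img, c(2, 1, 3))
      f <- file.path(o$out_dir, sprintf("%s_%s_%03d.png", o$prefix, pn, s - 1))
      png::writePNG(img, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
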