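#' Plot geometry
#'
#' Describes the rectangular census plot: its extents in metres and the base
#' resolution of the elevation survey (10 m between adjacent survey nodes,
#' the standard for forest-dynamics plots).
#'
#' @param x_extent,y_extent plot dimensions in metres (default 500 x 300,
#'   a 15-ha plot).
#' @param base_resolution spacing of elevation nodes in metres (default 10).
#' @return an object of class `plot_geometry`.
#' @export
plot_geometry <- function(x_extent = 500, y_extent = 300, base_resolution = 10) {
  if (x_extent <= 0 || y_extent <= 0 || base_resolution <= 0)
    stop("extents and base_resolution must be positive")
  if (x_extent %% base_resolution != 0 || y_extent %% base_resolution != 0)
    stop("extents must be multiples of base_resolution")
  structure(list(x_extent = x_extent, y_extent = y_extent,
                 base_resolution = base_resolution),
            class = "plot_geometry")
}

#' Largest sub-extent divisible by a sampling grain
#'
#' When the plot extent is not a multiple of the grain, the far (east/north)
#' margin is discarded and the analysis uses the largest origin-anchored
#' rectangle whose sides are multiples of the grain.  For a 500 x 300 m plot
#' this gives 480 x 300 at 30 m, 480 x 280 at 40 m and 480 x 300 at 60 m.
#'
#' @param geometry a [plot_geometry()].
#' @param grain quadrat side length in metres.
#' @return named numeric vector `c(sub_x, sub_y)`.
#' @export
sub_extent_for_grain <- function(geometry, grain) {
  stopifnot(inherits(geometry, "plot_geometry"))
  if (grain <= 0) stop("grain must be positive")
  if (grain > min(geometry$x_extent, geometry$y_extent))
    stop("grain ", grain, " exceeds the smallest plot extent")
  c(sub_x = floor(geometry$x_extent / grain) * grain,
    sub_y = floor(geometry$y_extent / grain) * grain)
}

#' Quadrat centroids at a sampling grain
#'
#' Centroid of cell (ix, iy) is ((ix + 0.5) g, (iy + 0.5) g).  Cells are
#' ordered by ix then iy, the site order used by every module in the package.
#'
#' @inheritParams sub_extent_for_grain
#' @return data.frame with columns `site`, `ix`, `iy`, `cx`, `cy`.
#' @export
cell_centroids <- function(geometry, grain) {
  se <- sub_extent_for_grain(geometry, grain)
  nx <- se[["sub_x"]] / grain
  ny <- se[["sub_y"]] / grain
  g <- expand.grid(iy = seq_len(ny) - 1L, ix = seq_len(nx) - 1L)
  g <- g[, c("ix", "iy")]
  g <- g[order(g$ix, g$iy), , drop = FALSE]
  data.frame(site = site_id(g$ix, g$iy),
             ix = g$ix, iy = g$iy,
             cx = (g$ix + 0.5) * grain,
             cy = (g$iy + 0.5) * grain,
             row.names = NULL)
}

site_id <- function(ix, iy) sprintf("x%03d_y%03d", ix, iy)
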