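# Per-quadrat topographic variables from the 10-m elevation node grid.
#
# Conventions (fixed here because field studies usually defer to cited
# methods without spelling them out):
#  * ELE at grain g is the mean over the constituent base-resolution subcells
#    of their 4-corner-node means.  This is a weighted node mean (interior
#    nodes weight 4, edge nodes 2, corner nodes 1) and makes coarse-grain ELE
#    nest exactly: grain-20 ELE is the mean of its four grain-10 ELEs.
#  * SLO is the mean slope in degrees of the four planes through three of the
#    cell's four corner nodes (the CTFS forest-plot convention).
#  * Aspect is the direction of steepest ascent of the least-squares plane
#    through the four corners, measured clockwise from north, reported as
#    SIN and COS.  Cells with negligible gradient are flagged flat and get
#    SIN = COS = 0.
#  * CON (convexity) is focal-cell ELE minus the mean ELE of the up-to-8
#    neighbouring cells; edge cells use the cell-centre elevation (bilinear
#    from the node grid) minus the cell's own corner mean.
#  * TWI and ACH are simplified D8-based stand-ins (see [twi_ach()]); field
#    supplied columns can override them.

# --- internal dem accessors -------------------------------------------------

# corner z values of every grain cell: list of four matrices (nx x ny)
# z00 = SW, z10 = SE, z01 = NW, z11 = NE.  When the grain is not a multiple
# of the node spacing (e.g. 25 m on a 10-m grid) corners are bilinearly
# interpolated from the node lattice.
.cell_corners <- function(dem, grain, nx, ny) {
  k <- grain / dem$resolution
  if (k == round(k)) {
    xs0 <- seq(1, by = k, length.out = nx)
    ys0 <- seq(1, by = k, length.out = ny)
    return(list(z00 = dem$elev[xs0,     ys0,     drop = FALSE],
                z10 = dem$elev[xs0 + k, ys0,     drop = FALSE],
                z01 = dem$elev[xs0,     ys0 + k, drop = FALSE],
                z11 = dem$elev[xs0 + k, ys0 + k, drop = FALSE]))
  }
  cx <- (seq_len(nx) - 1) * grain
  cy <- (seq_len(ny) - 1) * grain
  at <- function(xoff, yoff) matrix(
    .dem_at(dem, outer(cx + xoff, rep(1, ny)), outer(rep(1, nx), cy + yoff)),
    nx, ny)
  list(z00 = at(0, 0), z10 = at(grain, 0),
       z01 = at(0, grain), z11 = at(grain, grain))
}

# base-resolution cell elevations (corner means), nx0 x ny0
.base_cell_ele <- function(dem) {
  e <- dem$elev
  (e[-nrow(e), -ncol(e)] + e[-1, -ncol(e)] + e[-nrow(e), -1] + e[-1, -1]) / 4
}

# cell ELE matrix at grain over the origin-anchored sub-extent.  For grains
# that are node-grid multiples this is the mean of the constituent
# base-resolution subcell elevations (exact nesting); otherwise the mean of
# the four bilinearly interpolated cell corners.
.cell_ele <- function(dem, grain, nx, ny) {
  k <- grain / dem$resolution
  if (k == round(k)) {
    e0 <- .base_cell_ele(dem)
    return(block_mean(e0[seq_len(nx * k), seq_len(ny * k), drop = FALSE],
                      as.integer(k)))
  }
  co <- .cell_corners(dem, grain, nx, ny)
  (co$z00 + co$z10 + co$z01 + co$z11) / 4
}

# bilinear sample of the node grid at arbitrary coordinates
.dem_at <- function(dem, x, y) {
  r <- dem$resolution
  fx <- as.vector(x) / r; fy <- as.vector(y) / r
  i0 <- pmin(floor(fx), nrow(dem$elev) - 2L); i1 <- i0 + 1L
  j0 <- pmin(floor(fy), ncol(dem$elev) - 2L); j1 <- j0 + 1L
  tx <- fx - i0; ty <- fy - j0
  idx <- function(i, j) dem$elev[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i1, j0) +
    (1 - tx) * ty * idx(i0, j1) + tx * ty * idx(i1, j1)
}

# slope (degrees) per cell: mean of the four 3-corner planes
.cell_slope <- function(corners, grain) {
  g <- grain
  with(corners, {
    sl <- function(b1, b2) atan(sqrt(b1^2 + b2^2)) * 180 / pi
    s1 <- sl((z10 - z00) / g, (z01 - z00) / g)  # omit NE
    s2 <- sl((z11 - z01) / g, (z11 - z10) / g)  # omit SW
    s3 <- sl((z11 - z01) / g, (z01 - z00) / g)  # omit SE
    s4 <- sl((z10 - z00) / g, (z11 - z10) / g)  # omit NW
    (s1 + s2 + s3 + s4) / 4
  })
}

# least-squares-plane gradient (b1 east, b2 north) per cell
.cell_gradient <- function(corners, grain) {
  with(corners, list(b1 = (z10 + z11 - z00 - z01) / (2 * grain),
                     b2 = (z01 + z11 - z00 - z10) / (2 * grain)))
}

#' Cell convexity from a cell-elevation matrix
#'
#' Convexity of a quadrat is its elevation minus the mean elevation of its
#' (up to 8) neighbouring quadrats.  For edge quadrats, which lack a full
#' neighbourhood, the convention is the elevation at the quadrat centre minus
#' the quadrat's own corner-mean elevation; supply those centre elevations
#' via `center_ele` (edge cells are `NA` when it is missing).
#'
#' @param ele matrix of per-cell elevations (x index in rows).
#' @param center_ele optional matrix of cell-centre elevations, same shape.
#' @return matrix of convexities, same shape as `ele`.
#' @export
cell_convexity <- function(ele, center_ele = NULL) {
  nx <- nrow(ele); ny <- ncol(ele)
  pad <- matrix(NA_real_, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- ele
  nb_sum <- matrix(0, nx, ny)
  nb_n <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- pad[(2:(nx + 1)) + dx, (2:(ny + 1)) + dy, drop = FALSE]
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_n <- nb_n + ok
  }
  con <- ele - nb_sum / nb_n
  edge <- nb_n < 8L
  if (any(edge)) {
    if (is.null(center_ele)) {
      con[edge] <- NA_real_
    } else {
      con[edge] <- center_ele[edge] - ele[edge]
    }
  }
  con
}

# --- exported operations ----------------------------------------------------

#' Topographic wetness index and altitude above channels (D8)
#'
#' Simplified drainage model on the grain-level cell-elevation grid: D8 flow
#' directions (steepest descent; ties broken in the fixed order E, N, W, S,
#' NE, NW, SW, SE), flow accumulation as the count of upslope cells including
#' the cell itself, `TWI = ln(a * grain / tan(max(SLO, 0.1 deg)))`, channel
#' cells are those with accumulation at or above `channel_threshold`, and
#' `ACH` is the focal cell's elevation minus that of the nearest channel cell
#' (zero for channel cells).  Field-measured TWI/ACH columns, when available,
#' should be preferred via the `overrides` argument of [topo_variables()].
#'
#' @param dem an `elevation_grid` from [generate_dem()] or [read_dem()].
#' @param geometry a [plot_geometry()].
#' @param grain quadrat side in metres (multiple of the dem resolution).
#' @param channel_threshold accumulation (cells) from which a cell counts as
#'   channel; default `max(2, ceiling(0.05 * n_cells))`, i.e. cells draining
#'   at least about 5% of the grid.
#' @return data.frame with columns `site`, `TWI`, `ACH`, `accumulation`,
#'   `channel`, in standard site order.
#' @export
twi_ach <- function(dem, geometry, grain, channel_threshold = NULL) {
  se <- sub_extent_for_grain(geometry, grain)
  nx <- se[["sub_x"]] / grain; ny <- se[["sub_y"]] / grain
  ele <- .cell_ele(dem, grain, nx, ny)
  corners <- .cell_corners(dem, grain, nx, ny)
  slo <- .cell_slope(corners, grain)
  n_cells <- nx * ny
  if (is.null(channel_threshold))
    channel_threshold <- max(2, ceiling(0.05 * n_cells))

  # D8 receivers; fixed direction order breaks gradient ties
  ddx <- c(1L, 0L, -1L, 0L, 1L, -1L, -1L, 1L)
  ddy <- c(0L, 1L, 0L, -1L, 1L, 1L, -1L, -1L)
  dd <- grain * c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  recv <- matrix(NA_integer_, nx, ny)  # linear index of receiver
  lin <- function(i, j) (j - 1L) * nx + i
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    best <- 0; best_k <- NA_integer_
    for (k in 1:8) {
      i2 <- i + ddx[k]; j2 <- j + ddy[k]
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > ny) next
      drop_k <- (ele[i, j] - ele[i2, j2]) / dd[k]
      if (drop_k > best + 1e-12) { best <- drop_k; best_k <- k }
    }
    if (!is.na(best_k)) recv[i, j] <- lin(i + ddx[best_k], j + ddy[best_k])
  }
  acc <- rep(1, n_cells)
  ord <- order(as.vector(ele), seq_len(n_cells), decreasing = TRUE)
  for (c0 in ord) {
    r <- recv[c0]
    if (!is.na(r)) acc[r] <- acc[r] + acc[c0]
  }
  acc <- matrix(acc, nx, ny)
  twi <- log(acc * grain / tan(pmax(slo, 0.1) * pi / 180))

  channel <- acc >= channel_threshold
  if (!any(channel))
    stop("no cell reaches channel_threshold = ", channel_threshold,
         "; ACH undefined -- lower channel_threshold")
  cc <- which(channel, arr.ind = TRUE)
  ach <- matrix(0, nx, ny)
  all_ij <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny)))
  d2 <- outer(all_ij[, 1], cc[, 1], "-")^2 + outer(all_ij[, 2], cc[, 2], "-")^2
  nearest <- cc[max.col(-d2, ties.method = "first"), , drop = FALSE]
  ach[all_ij] <- ele[all_ij] - ele[nearest]

  cen <- cell_centroids(geometry, grain)
  idx <- cbind(cen$ix + 1L, cen$iy + 1L)
  data.frame(site = cen$site, TWI = twi[idx], ACH = ach[idx],
             accumulation = acc[idx], channel = channel[idx])
}

#' Per-quadrat topographic variables
#'
#' Computes the eight standard forest-plot topographic variables at a given
#' sampling grain from the 10-m elevation node grid: elevation (ELE), slope
#' (SLO, degrees), convexity (CON), the sine and cosine of aspect (SIN, COS),
#' topographic wetness index (TWI), altitude above channels (ACH), and --
#' when a rock-bareness field is supplied -- the rock-bareness rate (RBR).
#' See the file header of `R/topography.R` for the exact conventions.
#'
#' @inheritParams twi_ach
#' @param rbr optional rock-bareness on the base-resolution cell grid
#'   (matrix, values in 0..1), averaged into grain cells; or `NULL`.
#' @param compute_twi_ach set `FALSE` to skip the drainage model (TWI/ACH
#'   columns become `NA`); a failed drainage model downgrades to `NA` with a
#'   warning rather than failing the whole table.
#' @param overrides optional data.frame/list of per-site columns (`TWI`,
#'   `ACH`, `RBR`) replacing the internally computed ones, in site order.
#' @return data.frame (one row per quadrat, standard site order) with the
#'   variable columns plus `site`, `ix`, `iy`, `cx`, `cy` and a logical
#'   `flat` flag; attributes `grain`, `sub_x`, `sub_y`.
#' @export
topo_variables <- function(dem, geometry, grain, rbr = NULL,
                           channel_threshold = NULL, compute_twi_ach = TRUE,
                           overrides = NULL) {
  stopifnot(inherits(geometry, "plot_geometry"))
  se <- sub_extent_for_grain(geometry, grain)
  if (se[["sub_x"]] > dem$x_extent || se[["sub_y"]] > dem$y_extent)
    stop("dem does not cover the sub-extent for grain ", grain)
  nx <- se[["sub_x"]] / grain; ny <- se[["sub_y"]] / grain

  ele <- .cell_ele(dem, grain, nx, ny)
  corners <- .cell_corners(dem, grain, nx, ny)
  slo <- .cell_slope(corners, grain)
  gr <- .cell_gradient(corners, grain)
  gmag <- sqrt(gr$b1^2 + gr$b2^2)
  flat <- slo < 1e-6 | gmag < 1e-12
  sin_a <- ifelse(flat, 0, gr$b1 / gmag)
  cos_a <- ifelse(flat, 0, gr$b2 / gmag)

  cen <- cell_centroids(geometry, grain)
  center_ele <- matrix(.dem_at(dem, (row(ele) - 0.5) * grain,
                               (col(ele) - 0.5) * grain), nx, ny)
  con <- cell_convexity(ele, center_ele)

  idx <- cbind(cen$ix + 1L, cen$iy + 1L)
  out <- cbind(cen, data.frame(
    ELE = ele[idx], SLO = slo[idx], CON = con[idx],
    SIN = sin_a[idx], COS = cos_a[idx], flat = flat[idx]))

  if (compute_twi_ach) {
    ta <- tryCatch(twi_ach(dem, geometry, grain, channel_threshold),
                   error = function(e) {
                     warning("TWI/ACH unavailable: ", conditionMessage(e))
                     NULL
                   })
    if (is.null(ta)) {
      out$TWI <- NA_real_; out$ACH <- NA_real_
    } else {
      stopifnot(identical(ta$site, out$site))
      out$TWI <- ta$TWI; out$ACH <- ta$ACH
    }
  } else {
    out$TWI <- NA_real_; out$ACH <- NA_real_
  }

  if (!is.null(rbr)) {
    k <- grain / dem$resolution
    if (k == round(k)) {
      rb <- block_mean(rbr[seq_len(nx * k), seq_len(ny * k), drop = FALSE],
                       as.integer(k))
    } else {
      # assign base cells to grain cells by their centres
      bix <- floor(((seq_len(nrow(rbr)) - 0.5) * dem$resolution) / grain)
      biy <- floor(((seq_len(ncol(rbr)) - 0.5) * dem$resolution) / grain)
      rb <- matrix(NA_real_, nx, ny)
      for (a in seq_len(nx)) for (b in seq_len(ny))
        rb[a, b] <- mean(rbr[bix == a - 1L, biy == b - 1L])
    }
    out$RBR <- rb[idx]
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (length(overrides[[nm]]) != nrow(out))
        stop("override column ", nm, " has wrong length")
      out[[nm]] <- overrides[[nm]]
    }
  }
  attr(out, "grain") <- grain
  attr(out, "sub_x") <- se[["sub_x"]]
  attr(out, "sub_y") <- se[["sub_y"]]
  out
}

#' Third-degree polynomial expansion of the topographic variables
#'
#' Emits, for each of ELE, SLO, CON, TWI, ACH and RBR, the centred variable
#' and its square and cube (18 columns), then appends SIN and COS: exactly 20
#' reconstructed predictors for variation partitioning.  A constant input
#' column yields zero columns (with a warning) so the 20-column contract is
#' kept.
#'
#' @param env an EnvTable as returned by [topo_variables()] (must contain the
#'   six polynomial variables plus SIN and COS).
#' @return numeric matrix, sites x 20, rownames = site ids.
#' @export
polynomial_expand <- function(env) {
  poly_vars <- c("ELE", "SLO", "CON", "TWI", "ACH", "RBR")
  need <- c(poly_vars, "SIN", "COS")
  miss <- setdiff(need, names(env))
  if (length(miss))
    stop("EnvTable lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(env[need]))
    stop("EnvTable contains NA in required columns")
  cols <- list()
  for (v in poly_vars) {
    x <- env[[v]] - mean(env[[v]])
    if (isTRUE(all.equal(stats::sd(env[[v]]), 0)) || all(x == 0)) {
      warning("constant column ", v, ": polynomial terms emitted as zeros")
      x <- rep(0, length(x))
    }
    cols[[v]] <- x
    cols[[paste0(v, ".2")]] <- x^2
    cols[[paste0(v, ".3")]] <- x^3
  }
  cols[["SIN"]] <- env$SIN
  cols[["COS"]] <- env$COS
  m <- do.call(cbind, cols)
  rownames(m) <- env$site
  stopifnot(ncol(m) == 20L)
  m
}

#' Standardised Euclidean environmental distance
#'
#' Z-scores each variable across sites (n-1 denominator) and returns the
#' pairwise Euclidean distance matrix.  Single-variable mode supports the
#' per-driver Mantel batteries.
#'
#' @param env EnvTable (data.frame) or a numeric matrix of predictors.
#' @param vars which columns to use; default: all of ELE, SLO, CON, TWI,
#'   ACH, RBR, SIN, COS that are present.
#' @return a `stats::dist` object labelled by site id.
#' @export
env_distance <- function(env, vars = NULL) {
  if (is.matrix(env)) {
    X <- env
  } else {
    if (is.null(vars))
      vars <- intersect(c("ELE", "SLO", "CON", "TWI", "ACH", "RBR",
                          "SIN", "COS"), names(env))
    X <- as.matrix(env[, vars, drop = FALSE])
    rownames(X) <- env$site
  }
  if (nrow(X) < 2) stop("need at least two sites")
  if (anyNA(X)) stop("environmental columns contain NA")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s) excluded: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0) stop("no variable with positive variance")
    sds <- sds[sds > 0]
  }
  Xz <- scale(X)  # n-1 denominator
  stats::dist(Xz)
}
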