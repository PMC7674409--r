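#' Render a colony snapshot to a raster PNG
#'
#' Nearest-node rasterization of the occupied lattice, colored by strain
#' (producer/reducer-1 blue, consumer/reducer-2 green, paper-figure style)
#' or by lineage (pseudo-color palette cycling over founder ids). Obstacles
#' are drawn dark gray, empty domain white. Requires the `png` package.
#'
#' @param run A `colony_run`, or a `colony_state` (then `lattice` must be
#'   given).
#' @param path Output PNG path.
#' @param color_by "strain" or "lineage".
#' @param px_per_um Raster resolution (default 0.2, i.e. 1 px per 5 um).
#' @param lattice Optional `hex_lattice` when `run` is a bare state.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(run, path, color_by = c("strain", "lineage"),
                            px_per_um = 0.2, lattice = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("render_snapshot requires the 'png' package", call. = FALSE)
  color_by <- match.arg(color_by)
  if (inherits(run, "colony_run")) {
    state <- run$state; lattice <- run$lattice
  } else state <- run
  stopifnot(inherits(state, "colony_state"), inherits(lattice, "hex_lattice"))

  w <- max(16L, as.integer(ceiling(2 * lattice$radius * px_per_um)))
  gx <- seq(-lattice$radius, lattice$radius, length.out = w)

  # pixel coordinates in image-array (column-major) order, y down the rows
  px <- rep(gx, each = w)
  py <- rep(rev(gx), times = w)
  qf <- (px / lattice$pitch) - (py / (lattice$pitch * sqrt(3)))
  rf <- 2 * py / (lattice$pitch * sqrt(3))
  cube <- axial_round(qf, rf)
  qoff <- lattice$q - min(lattice$q); roff <- lattice$r - min(lattice$r)
  nq <- max(qoff) + 1L
  key <- qoff + nq * roff
  nk <- (cube$q - min(lattice$q)) + nq * (cube$r - min(lattice$r))
  nk[cube$q < min(lattice$q) | cube$r < min(lattice$r)] <- -1L
  node <- match(nk, key)

  pal_strain <- rbind(c(0.2, 0.4, 0.9), c(0.2, 0.8, 0.3))
  ok <- !is.na(node)
  nd <- pmax(node, 1L)
  col <- matrix(1, nrow = length(node), ncol = 3)  # white background
  obs_px <- ok & lattice$is_obstacle[nd]
  col[obs_px, ] <- 0.25
  occ <- ok & !lattice$is_obstacle[nd] & state$strain[nd] > 0L
  if (any(occ)) {
    if (color_by == "strain") {
      col[occ, ] <- pal_strain[state$strain[node[occ]], , drop = FALSE]
    } else {
      hue <- (state$lineage[node[occ]] * 0.6180339887) %% 1
      col[occ, ] <- t(grDevices::col2rgb(grDevices::hsv(hue, 0.8, 0.9)) / 255)
    }
  }
  png::writePNG(array(col, dim = c(w, w, 3)), path)
  invisible(path)
}

# cube-rounding of fractional axial coordinates to the nearest hex
axial_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}
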