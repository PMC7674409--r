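#' Build a circular hexagonal-lattice domain
#'
#' Constructs the immutable lattice geometry used as the backbone for
#' nutrient diffusion and colony occupancy: hexagon centers on a triangular
#' (pointy-top axial) grid, clipped to a disc of the given radius.
#'
#' The center-to-center pitch between adjacent nodes is `side * sqrt(3)`
#' (~34.64 um for the default 20 um hexagon side). Nodes on the outer rim
#' (incomplete 6-neighbor ring) are flagged as boundary nodes; these act as
#' the nitrate source in the simulation.
#'
#' @param radius Domain radius in micrometers (must exceed `side`).
#' @param side Hexagon side length in micrometers (default 20).
#' @return An object of class `hex_lattice`: a list with `n` (node count),
#'   `q`,`r` (axial coordinates), `x`,`y` (positions, um), `nbr` (n x 6
#'   integer matrix of neighbor node ids, 0 where absent), `degree`,
#'   `is_boundary`, `is_obstacle`, `side`, `pitch` and `radius`.
#' @examples
#' lat <- hex_lattice(radius = 34.7, side = 20)  # central node + 6-ring
#' lat$n
#' @export
hex_lattice <- function(radius, side = 20) {
  stopifnot(is.numeric(radius), length(radius) == 1L,
            is.numeric(side), length(side) == 1L)
  if (!is.finite(radius) || !is.finite(side) || side <= 0 || radius <= side)
    stop("invalid geometry: need radius > side > 0", call. = FALSE)
  pitch <- side * sqrt(3)

  # enumerate axial coordinates generously, then clip to the disc
  rmax <- ceiling(radius / (pitch * sqrt(3) / 2)) + 1L
  qmax <- ceiling(radius / pitch + rmax / 2) + 1L
  grid <- expand.grid(q = seq(-qmax, qmax), r = seq(-rmax, rmax))
  x <- pitch * (grid$q + grid$r / 2)
  y <- pitch * (sqrt(3) / 2) * grid$r
  keep <- x * x + y * y <= radius * radius
  q <- grid$q[keep]; r <- grid$r[keep]; x <- x[keep]; y <- y[keep]
  ord <- order(r, q)
  q <- q[ord]; r <- r[ord]; x <- x[ord]; y <- y[ord]
  n <- length(q)

  # adjacency via axial key lookup
  qoff <- q - min(q); roff <- r - min(r)
  nq <- max(qoff) + 1L
  key <- qoff + nq * roff
  dirs <- cbind(q = c(1L, -1L, 0L, 0L, 1L, -1L),
                r = c(0L, 0L, 1L, -1L, -1L, 1L))
  nbr <- matrix(0L, nrow = n, ncol = 6L)
  for (d in seq_len(6L)) {
    nk <- (qoff + dirs[d, 1L]) + nq * (roff + dirs[d, 2L])
    hit <- match(nk, key)
    # guard against key aliasing at the enumeration edge
    bad <- !is.na(hit) &
      (q[hit] != q + dirs[d, 1L] | r[hit] != r + dirs[d, 2L])
    hit[bad] <- NA_integer_
    nbr[, d] <- ifelse(is.na(hit), 0L, hit)
  }
  degree <- rowSums(nbr > 0L)

  structure(list(
    n = n, q = q, r = r, x = x, y = y,
    nbr = nbr, degree = degree,
    is_boundary = degree < 6L,
    is_obstacle = rep(FALSE, n),
    side = side, pitch = pitch, radius = radius
  ), class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf(
    "hex_lattice: %d nodes, radius %g um, side %g um (pitch %.2f um)\n",
    x$n, x$radius, x$side, x$pitch))
  cat(sprintf("  boundary nodes: %d, obstacle nodes: %d\n",
              sum(x$is_boundary), sum(x$is_obstacle)))
  invisible(x)
}

#' Specify a solid-obstacle layout
#'
#' Obstacles emulate solid impenetrable grains in a structured (porous)
#' habitat. `regular` mode places equal-diameter discs on a square grid of
#' the given spacing; `stochastic` mode draws each disc's diameter from a
#' normal distribution.
#'
#' The paper-style structured habitats use 100 um diameter discs at 500, 400
#' and 300 um spacing (coarse/medium/fine). The stochastic spread of "20 um
#' variance" is interpreted as a standard deviation of 20 um by default;
#' set `spread_is_sd = FALSE` to read it literally as a variance
#' (sigma = sqrt(20) um).
#'
#' @param mode One of "none", "regular", "stochastic".
#' @param diameter Mean obstacle diameter, um.
#' @param spacing Center-to-center obstacle spacing, um (square grid).
#' @param spread Diameter spread parameter, um (stochastic mode).
#' @param spread_is_sd Interpret `spread` as a standard deviation (default)
#'   rather than a variance.
#' @param seed Optional integer seed making stochastic layouts reproducible
#'   independently of the surrounding RNG state.
#' @return An object of class `obstacle_spec`.
#' @export
obstacle_spec <- function(mode = c("none", "regular", "stochastic"),
                          diameter = 100, spacing = 500,
                          spread = 20, spread_is_sd = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  if (mode != "none") {
    stopifnot(is.numeric(diameter), is.numeric(spacing))
    if (!(spacing > diameter && diameter > 0))
      stop("obstacle_spec: need spacing > diameter > 0", call. = FALSE)
  }
  structure(list(mode = mode, diameter = diameter, spacing = spacing,
                 spread = spread, spread_is_sd = spread_is_sd, seed = seed),
            class = "obstacle_spec")
}

# run code with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Apply a solid-obstacle layout to a lattice
#'
#' Flags nodes whose centers fall inside any obstacle disc as obstacles.
#' Obstacle nodes are excluded from diffusion, occupancy and path traversal.
#' Obstacle centers are laid on a square grid of the requested spacing;
#' centers inside the protected central disc (`clear_radius`, normally the
#' inoculation radius) are dropped, and no node inside that disc is ever
#' flagged, so the inoculum region stays obstacle-free. Discs may overlap the
#' domain rim and are clipped to it.
#'
#' @param lattice A `hex_lattice`.
#' @param spec An `obstacle_spec`.
#' @param clear_radius Radius (um) of the central disc kept obstacle-free.
#' @return The lattice with `is_obstacle` updated.
#' @export
apply_obstacles <- function(lattice, spec, clear_radius = 0) {
  stopifnot(inherits(lattice, "hex_lattice"), inherits(spec, "obstacle_spec"))
  if (spec$mode == "none") return(lattice)

  s <- spec$spacing
  k <- ceiling((lattice$radius + spec$diameter) / s)
  centers <- expand.grid(cx = s * seq(-k, k), cy = s * seq(-k, k))
  cr <- sqrt(centers$cx^2 + centers$cy^2)
  keep <- (clear_radius <= 0 | cr > clear_radius) &
    cr <= lattice$radius + spec$diameter / 2
  centers <- centers[keep, , drop = FALSE]
  m <- nrow(centers)
  if (m == 0L) return(lattice)

  diam <- if (spec$mode == "regular") {
    rep(spec$diameter, m)
  } else {
    sd <- if (isTRUE(spec$spread_is_sd)) spec$spread else sqrt(spec$spread)
    with_seed(spec$seed, pmax(0, stats::rnorm(m, spec$diameter, sd)))
  }

  obs <- lattice$is_obstacle
  protected <- lattice$x^2 + lattice$y^2 <= clear_radius^2
  for (i in seq_len(m)) {
    if (diam[i] <= 0) next
    d2 <- (lattice$x - centers$cx[i])^2 + (lattice$y - centers$cy[i])^2
    obs <- obs | (d2 <= (diam[i] / 2)^2 & !protected)
  }
  if (all(obs[lattice$is_boundary]))
    stop("obstacle layout covers the entire boundary rim", call. = FALSE)
  lattice$is_obstacle <- obs
  lattice
}

# logical: nodes that are empty (unoccupied, non-obstacle)
vacant_nodes <- function(lattice, occupancy) {
  occ <- as_occupied(lattice, occupancy)
  !occ & !lattice$is_obstacle
}

as_occupied <- function(lattice, occupancy) {
  if (inherits(occupancy, "colony_state")) occupancy <- occupancy$strain
  stopifnot(length(occupancy) == lattice$n)
  if (is.logical(occupancy)) occupancy else occupancy > 0L
}

# for every node, whether it has >= 1 vacant (empty, non-obstacle) neighbor
has_vacant_neighbor <- function(lattice, occupancy) {
  vac <- vacant_nodes(lattice, occupancy)
  padded <- c(FALSE, vac)              # nbr id 0 -> index 1 -> FALSE
  hits <- padded[lattice$nbr + 1L]
  dim(hits) <- dim(lattice$nbr)
  rowSums(hits) > 0L
}

#' Colony periphery
#'
#' The periphery is the set of occupied nodes adjacent to at least one
#' unoccupied, non-obstacle node — the actively expanding colony edge.
#'
#' @param lattice A `hex_lattice`.
#' @param occupancy A logical or integer vector of length `lattice$n`
#'   (0 / `FALSE` = empty), or a `colony_state`.
#' @return Integer vector of periphery node ids (possibly empty).
#' @export
periphery <- function(lattice, occupancy) {
  occ <- as_occupied(lattice, occupancy)
  which(occ & !lattice$is_obstacle & has_vacant_neighbor(lattice, occupancy))
}

#' Shortest path from an occupied node to the colony periphery
#'
#' Breadth-first search through occupied, non-obstacle nodes from `origin` to
#' the nearest periphery node. Among targets at equal graph distance, one is
#' chosen uniformly at random (simulation RNG), and the path is traced back
#' choosing uniformly among shortest-path predecessors; this is the
#' random tie-break used by the shoving algorithm.
#'
#' @inheritParams periphery
#' @param origin Occupied node id to start from.
#' @param max_depth Maximum path length in edges (default unlimited). Used by
#'   the shoving rule, which only relocates cells within 5 cells (<100 um) of
#'   the periphery.
#' @return Integer vector of node ids from `origin` to a periphery node
#'   (inclusive), or `NULL` if no periphery is reachable within `max_depth`.
#' @export
shortest_path_to_periphery <- function(lattice, occupancy, origin,
                                       max_depth = Inf) {
  occ <- as_occupied(lattice, occupancy)
  if (!occ[origin] || lattice$is_obstacle[origin])
    stop("origin must be an occupied, non-obstacle node", call. = FALSE)
  is_periph <- has_vacant_neighbor(lattice, occupancy)
  if (is_periph[origin]) return(origin)

  dist <- rep(-1L, lattice$n)
  dist[origin] <- 0L
  frontier <- origin
  depth <- 0L
  repeat {
    if (depth >= max_depth || length(frontier) == 0L) return(NULL)
    depth <- depth + 1L
    nb <- lattice$nbr[frontier, , drop = FALSE]
    nb <- nb[nb > 0L]
    nb <- unique(nb[occ[nb] & !lattice$is_obstacle[nb] & dist[nb] < 0L])
    if (length(nb) == 0L) return(NULL)
    dist[nb] <- depth
    hits <- nb[is_periph[nb]]
    if (length(hits) > 0L) {
      target <- if (length(hits) == 1L) hits else sample(hits, 1L)
      # trace back, choosing uniformly among shortest-path predecessors
      path <- integer(depth + 1L)
      path[depth + 1L] <- target
      cur <- target
      for (d in seq(depth - 1L, 0L)) {
        pre <- lattice$nbr[cur, ]
        pre <- pre[pre > 0L]
        pre <- pre[dist[pre] == d & occ[pre] & !lattice$is_obstacle[pre]]
        cur <- if (length(pre) == 1L) pre else sample(pre, 1L)
        path[d + 1L] <- cur
      }
      return(path)
    }
    frontier <- nb
  }
}

#' Export a lattice as a per-node table
#'
#' @param lattice A `hex_lattice`.
#' @return A data.frame with columns `node`, `x`, `y`, `boundary`, `obstacle`.
#' @export
lattice_table <- function(lattice) {
  data.frame(node = seq_len(lattice$n), x = lattice$x, y = lattice$y,
             boundary = lattice$is_boundary, obstacle = lattice$is_obstacle)
}

#' Write a lattice node table to a delimited text file
#'
#' @param lattice A `hex_lattice`.
#' @param path Output file path (tab-separated).
#' @export
write_lattice <- function(lattice, path) {
  utils::write.table(lattice_table(lattice), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
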