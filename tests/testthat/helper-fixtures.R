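# Fixtures are built in code: tiny lattices, closed two-node systems and
# hand-laid colony states used across the module tests.

# disc of `rings` complete hexagonal rings around the center (side 20 um)
ring_lattice <- function(rings, side = 20) {
  pitch <- side * sqrt(3)
  hex_lattice(radius = rings * pitch + 1, side = side)
}

# a closed two-compartment system: a 7-node disc with all but one adjacent
# pair masked as obstacles
two_node_system <- function() {
  lat <- hex_lattice(34.7, 20)
  keep <- c(1L, lat$nbr[1L, 1L])
  lat$is_obstacle <- !(seq_len(lat$n) %in% keep)
  list(lattice = lat, a = keep[1L], b = keep[2L])
}

# colony state with the given nodes occupied; strains/lineages recycled
manual_state <- function(lattice, nodes, strain = 1L,
                         lineage = seq_along(nodes), mass = 1,
                         scenario = "competition") {
  st <- hexcolony:::new_colony_state(lattice, scenario)
  st$strain[nodes] <- rep_len(as.integer(strain), length(nodes))
  st$lineage[nodes] <- rep_len(as.integer(lineage), length(nodes))
  st$mass[nodes] <- rep_len(mass, length(nodes))
  st$founders <- data.frame(
    lineage = st$lineage[nodes], node = nodes, strain = st$strain[nodes],
    radial = sqrt(lattice$x[nodes]^2 + lattice$y[nodes]^2))
  st$inoculation_radius <- if (nrow(st$founders)) max(st$founders$radial) else 0
  st
}

# nodes of the filled disc of graph radius `rings` around the center node
disc_nodes <- function(lattice, rings) {
  center <- which.min(lattice$x^2 + lattice$y^2)
  d <- bfs_distances(lattice, center)
  which(d >= 0 & d <= rings)
}

# plain breadth-first distances on the lattice graph (independent oracle
# helper; ignores occupancy, optionally restricted to `allowed` nodes)
bfs_distances <- function(lattice, from, allowed = NULL) {
  ok <- if (is.null(allowed)) rep(TRUE, lattice$n) else
    seq_len(lattice$n) %in% allowed
  dist <- rep(-1L, lattice$n)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nb <- lattice$nbr[frontier, , drop = FALSE]
    nb <- unique(nb[nb > 0L])
    nb <- nb[ok[nb] & dist[nb] < 0L]
    dist[nb] <- dist[frontier[1L]] + 1L
    frontier <- nb
  }
  dist
}

mini_config <- function(scenario = "competition", seed = 1,
                        total_time = 14400, ...) {
  scenario_config(scenario = scenario, radius = 400,
                  inoculation_radius = 160, total_time = total_time,
                  seed = seed, ...)
}
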