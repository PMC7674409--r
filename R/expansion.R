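SCENARIOS <- c("competition", "weak_mutualism", "strong_mutualism")

#' Roles of the two strain labels under a trophic scenario
#'
#' Competition uses two complete reducers (labels 1 and 2 differ only in
#' their fluorescent tag); both mutualistic scenarios use one producer
#' (label 1) and one consumer (label 2).
#'
#' @param scenario One of "competition", "weak_mutualism", "strong_mutualism".
#' @return Character vector of length 2: role of strain label 1 and 2.
#' @export
strain_roles <- function(scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (scenario == "competition") c("complete_reducer", "complete_reducer")
  else c("producer", "consumer")
}

#' Colony-expansion parameters
#'
#' @param division_mass Critical super-agent mass for division, kg. The
#'   default 1e-10 kg corresponds to a super-agent of roughly 3e5 cells of
#'   ~3e-16 kg dry mass; it sets the biomass scale coupling growth to
#'   nutrient consumption and hence the growth-layer thickness and the
#'   colony expansion speed.
#' @param shove_radius Maximum shortest-path distance to the periphery, in
#'   grid cells (edges), within which a trapped divider shoves the chain of
#'   cells outward (default 5, i.e. < 100 um).
#' @param shoving_enabled Disable to let only peripheral cells contribute to
#'   lateral expansion (interior divisions stack vertically).
#' @param inoculation_radius Radius of the central inoculated disc, um.
#' @param inoculum_frac Range of the initial mass as a fraction of
#'   `division_mass` (uniform draw; default `c(0.1, 1)`).
#' @param encasement Optionally overwrite the outermost inoculated ring with
#'   one strain ("consumer_ring"/"producer_ring") after random assignment.
#' @return An object of class `expansion_params`.
#' @export
expansion_params <- function(division_mass = 1e-10, shove_radius = 5L,
                             shoving_enabled = TRUE,
                             inoculation_radius = 2000,
                             inoculum_frac = c(0.1, 1),
                             encasement = c("none", "consumer_ring",
                                            "producer_ring")) {
  encasement <- match.arg(encasement)
  stopifnot(division_mass > 0, shove_radius >= 0, inoculation_radius > 0,
            length(inoculum_frac) == 2L)
  if (any(inoculum_frac <= 0) || any(inoculum_frac > 1) ||
      inoculum_frac[1] > inoculum_frac[2])
    stop("inoculum_frac must be an increasing interval within (0, 1]",
         call. = FALSE)
  structure(list(division_mass = division_mass,
                 shove_radius = as.integer(shove_radius),
                 shoving_enabled = isTRUE(shoving_enabled),
                 inoculation_radius = inoculation_radius,
                 inoculum_frac = inoculum_frac, encasement = encasement),
            class = "expansion_params")
}

new_colony_state <- function(lattice, scenario) {
  structure(list(
    strain = integer(lattice$n), lineage = integer(lattice$n),
    mass = numeric(lattice$n), stacked = numeric(lattice$n),
    scenario = scenario, founders = NULL, inoculation_radius = NA_real_
  ), class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  occ <- sum(x$strain > 0L)
  cat(sprintf("colony_state (%s): %d occupied nodes, %d founders, %.3g kg biomass\n",
              x$scenario, occ,
              if (is.null(x$founders)) 0L else nrow(x$founders),
              sum(x$mass) + sum(x$stacked)))
  invisible(x)
}

#' Inoculate the colony
#'
#' Every non-obstacle node within the inoculation radius receives one
#' super-agent: strain label drawn uniformly (1:1 mix), initial mass drawn
#' uniformly from `inoculum_frac * division_mass`, and a unique founder
#' lineage id. Encasement modes then overwrite the strain of the outermost
#' occupied ring (lineage ids kept). Uses the current RNG stream.
#'
#' @param lattice A `hex_lattice`.
#' @param params An `expansion_params`.
#' @param scenario Trophic scenario (see [strain_roles()]).
#' @return A `colony_state` with a `founders` data.frame (columns `lineage`,
#'   `node`, `strain`, `radial`, the founder's distance from the colony
#'   center in um).
#' @export
inoculate <- function(lattice, params, scenario = "competition") {
  scenario <- match.arg(scenario, SCENARIOS)
  stopifnot(inherits(params, "expansion_params"))
  r2 <- lattice$x^2 + lattice$y^2
  inside <- r2 <= params$inoculation_radius^2
  if (any(inside & lattice$is_obstacle))
    stop("obstacle inside the inoculation disc", call. = FALSE)
  nodes <- which(inside)
  if (length(nodes) == 0L)
    stop("inoculation radius contains no lattice nodes", call. = FALSE)

  st <- new_colony_state(lattice, scenario)
  n <- length(nodes)
  st$strain[nodes] <- sample(c(1L, 2L), n, replace = TRUE)
  st$lineage[nodes] <- seq_len(n)
  st$mass[nodes] <- stats::runif(n, params$inoculum_frac[1],
                                 params$inoculum_frac[2]) * params$division_mass
  st$inoculation_radius <- params$inoculation_radius

  if (params$encasement != "none") {
    ring <- periphery(lattice, st$strain)
    st$strain[ring] <- if (params$encasement == "consumer_ring") 2L else 1L
  }
  st$founders <- data.frame(lineage = st$lineage[nodes], node = nodes,
                            strain = st$strain[nodes],
                            radial = sqrt(r2[nodes]))
  st
}

#' Shove a chain of cells toward the periphery
#'
#' The periphery-end agent of `path` moves to a uniformly random vacant
#' (unoccupied, non-obstacle) neighbor; every other agent on the path
#' advances one position toward the periphery, vacating the origin node.
#' Strain, lineage, mass and stacked mass move with each agent.
#'
#' @param state A `colony_state`.
#' @param lattice A `hex_lattice`.
#' @param path Integer node ids from the dividing cell to a periphery cell,
#'   all occupied.
#' @return The updated `colony_state` with the origin node vacant, or `NULL`
#'   if the periphery-end agent has no vacant neighbor (caller falls back to
#'   stacking).
#' @export
shove <- function(state, lattice, path) {
  stopifnot(length(path) >= 1L, all(state$strain[path] > 0L))
  tip <- path[length(path)]
  nb <- lattice$nbr[tip, ]
  nb <- nb[nb > 0L]
  nb <- nb[state$strain[nb] == 0L & !lattice$is_obstacle[nb]]
  if (length(nb) == 0L) return(NULL)
  dest <- if (length(nb) == 1L) nb else sample(nb, 1L)
  chain <- c(path, dest)
  for (f in c("strain", "lineage", "mass", "stacked")) {
    v <- state[[f]]
    v[chain[-1L]] <- v[chain[-length(chain)]]
    v[chain[1L]] <- if (is.integer(v)) 0L else 0
    state[[f]] <- v
  }
  state
}

place_daughter <- function(state, node, strain, lineage, mass) {
  state$strain[node] <- strain
  state$lineage[node] <- lineage
  state$mass[node] <- mass
  state$stacked[node] <- 0
  state
}

#' Divide one super-agent
#'
#' The agent's mass is halved between two daughters sharing its strain and
#' lineage. Placement priority: (a) a uniformly random vacant neighbor;
#' (b) if none and shoving is enabled and the shortest path to the periphery
#' is within `shove_radius` edges, shove the chain outward and place the
#' daughter on the vacated origin; (c) otherwise the daughter mass is added
#' to the stacked (pseudo-3D) layer at the node.
#'
#' @param state A `colony_state`.
#' @param lattice A `hex_lattice`.
#' @param node Node id of the dividing agent (mass >= `division_mass`).
#' @param params An `expansion_params`.
#' @return The updated `colony_state`; attribute `"placement"` records the
#'   branch taken ("vacancy", "shove" or "stack").
#' @export
divide_agent <- function(state, lattice, node, params) {
  if (state$strain[node] == 0L)
    stop("node is not occupied", call. = FALSE)
  if (state$mass[node] < params$division_mass)
    stop("agent below division mass", call. = FALSE)
  half <- state$mass[node] / 2
  strain <- state$strain[node]; lineage <- state$lineage[node]

  nb <- lattice$nbr[node, ]
  nb <- nb[nb > 0L]
  nb <- nb[state$strain[nb] == 0L & !lattice$is_obstacle[nb]]
  if (length(nb) > 0L) {
    dest <- if (length(nb) == 1L) nb else sample(nb, 1L)
    state$mass[node] <- half
    state <- place_daughter(state, dest, strain, lineage, half)
    attr(state, "placement") <- "vacancy"
    return(state)
  }
  if (params$shoving_enabled) {
    path <- shortest_path_to_periphery(lattice, state$strain, node,
                                       max_depth = params$shove_radius)
    if (!is.null(path)) {
      shoved <- shove(state, lattice, path)
      if (!is.null(shoved)) {
        shoved <- place_daughter(shoved, node, strain, lineage, half)
        # the parent moved one step along the path; its mass halves there
        parent_at <- path[2L]
        shoved$mass[parent_at] <- half
        attr(shoved, "placement") <- "shove"
        return(shoved)
      }
    }
  }
  state$mass[node] <- half
  state$stacked[node] <- state$stacked[node] + half
  attr(state, "placement") <- "stack"
  state
}

# one division sweep over a macro step: agents at or above the division mass
# divide once, in uniformly shuffled order
division_sweep <- function(state, lattice, params) {
  ready <- which(state$mass >= params$division_mass)
  if (length(ready) == 0L) return(state)
  if (length(ready) > 1L) ready <- sample(ready)
  for (node in ready) {
    # a shove may have moved this agent; its mass moved with it
    if (state$strain[node] == 0L || state$mass[node] < params$division_mass)
      next
    state <- divide_agent(state, lattice, node, params)
  }
  attr(state, "placement") <- NULL
  state
}

#' Occupancy snapshot as a per-node table
#'
#' @param state A `colony_state`.
#' @return data.frame with columns `node`, `strain`, `lineage`, `mass`,
#'   `stacked` for occupied nodes.
#' @export
occupancy_table <- function(state) {
  occ <- which(state$strain > 0L)
  data.frame(node = occ, strain = state$strain[occ],
             lineage = state$lineage[occ], mass = state$mass[occ],
             stacked = state$stacked[occ])
}

#' Write an occupancy snapshot to a delimited text file
#'
#' @param state A `colony_state`.
#' @param path Output file path (tab-separated).
#' @export
write_snapshot <- function(state, path) {
  utils::write.table(occupancy_table(state), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
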