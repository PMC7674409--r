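#' Unique lineages at the colony periphery
#'
#' @param state A `colony_state`.
#' @param lattice A `hex_lattice`.
#' @return A list with `by_strain` (named list of sorted lineage-id vectors,
#'   one per strain label present) and `all` (union).
#' @export
peripheral_lineages <- function(state, lattice) {
  p <- periphery(lattice, state$strain)
  by_strain <- lapply(split(state$lineage[p], state$strain[p]),
                      function(v) sort(unique(v)))
  list(by_strain = by_strain, all = sort(unique(state$lineage[p])))
}

#' Count interspecies boundaries along the colony periphery
#'
#' Periphery agents are ordered by angular position around the centroid of
#' the occupied nodes (ties broken by radius) and strain transitions are
#' counted along the resulting cyclic sequence — the standard
#' operationalization of counting visible sector boundaries.
#'
#' @inheritParams peripheral_lineages
#' @return Integer transition count (0 for a monoclonal periphery).
#' @export
interspecies_boundaries <- function(state, lattice) {
  p <- periphery(lattice, state$strain)
  if (length(p) == 0L) stop("empty periphery", call. = FALSE)
  occ <- state$strain > 0L
  cx <- mean(lattice$x[occ]); cy <- mean(lattice$y[occ])
  dx <- lattice$x[p] - cx; dy <- lattice$y[p] - cy
  ang <- atan2(dy, dx)
  ord <- order(ang, dx^2 + dy^2)
  s <- state$strain[p][ord]
  if (length(s) == 1L) return(0L)
  sum(s != c(s[-1L], s[1L]))
}

# connected components of same-strain occupied nodes (6-neighbor adjacency)
strain_components <- function(state, lattice, strain) {
  nodes <- which(state$strain == strain)
  if (length(nodes) == 0L)
    return(list(membership = integer(0), nodes = integer(0), n = 0L))
  idx <- integer(lattice$n); idx[nodes] <- seq_along(nodes)
  jj <- as.vector(lattice$nbr[nodes, , drop = FALSE])
  ii <- rep(nodes, times = 6L)
  keep <- jj > 0L & state$strain[pmax(jj, 1L)] == strain
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[ii[keep]], idx[jj[keep]]))
  comp <- igraph::components(g)
  list(membership = comp$membership, nodes = nodes, n = comp$no)
}

#' Consumer branches intersecting the periphery
#'
#' A branch is a connected component of consumer-occupied nodes that reaches
#' the colony periphery. Returns the branch count together with the number
#' of unique peripheral consumer lineages and their ratio (the paper-style
#' lineage-to-branch ratio; monoclonal branches give 1).
#'
#' @inheritParams peripheral_lineages
#' @param consumer_strain Strain label of the consumer (default 2).
#' @return List with `branches`, `peripheral_lineages` and `ratio`
#'   (`NA` when there are no branches).
#' @export
consumer_branches <- function(state, lattice, consumer_strain = 2L) {
  comp <- strain_components(state, lattice, consumer_strain)
  p <- periphery(lattice, state$strain)
  on_p <- comp$nodes %in% p
  branches <- length(unique(comp$membership[on_p]))
  lin <- length(unique(state$lineage[comp$nodes[on_p]]))
  list(branches = branches, peripheral_lineages = lin,
       ratio = if (branches > 0L) lin / branches else NA_real_)
}

#' Founder-lineage loss during range expansion
#'
#' Fraction of founder lineages with no descendant on the final colony
#' periphery, reported (a) over founders that started within the actively
#' growing layer (within `growth_layer_depth` of the inoculum edge) and
#' (b) over all founders including the colony center.
#'
#' @inheritParams peripheral_lineages
#' @param growth_layer_depth Depth of the initial growth layer, um
#'   (default 100, the nitrate penetration proxy matching the shoving
#'   radius of 5 cells).
#' @return Named numeric vector, percentages:
#'   `c(growth_layer = ..., all = ...)`.
#' @export
lineage_loss <- function(state, lattice, growth_layer_depth = 100) {
  stopifnot(!is.null(state$founders))
  surv <- peripheral_lineages(state, lattice)$all
  f <- state$founders
  in_layer <- f$radial >= state$inoculation_radius - growth_layer_depth
  c(growth_layer = 100 * mean(!(f$lineage[in_layer] %in% surv)),
    all = 100 * mean(!(f$lineage %in% surv)))
}

#' Final biomass per founder lineage
#'
#' Living mass including stacked layers, summed by lineage; founders with no
#' surviving biomass appear with 0.
#'
#' @param state A `colony_state`.
#' @return Named numeric vector (names = lineage ids), kg.
#' @export
lineage_biomass <- function(state) {
  stopifnot(!is.null(state$founders))
  occ <- state$strain > 0L
  tot <- state$mass[occ] + state$stacked[occ]
  by_lin <- tapply(tot, state$lineage[occ], sum)
  out <- stats::setNames(numeric(nrow(state$founders)),
                         as.character(state$founders$lineage))
  out[names(by_lin)] <- as.numeric(by_lin)
  out
}

#' Lucky-founder fraction
#'
#' Smallest percentage of founders whose lineages jointly hold more than
#' half of the final colony biomass: lineages are ranked by final biomass
#' and the minimal head count whose cumulative biomass exceeds 50% of the
#' total is expressed as a percentage of the founder count.
#'
#' @param biomass Numeric vector of per-lineage final biomass (e.g. from
#'   [lineage_biomass()]), or a `colony_state`.
#' @return Percentage in (0, 100].
#' @export
lucky_fraction <- function(biomass) {
  if (inherits(biomass, "colony_state")) biomass <- lineage_biomass(biomass)
  stopifnot(length(biomass) > 0L, all(biomass >= 0), sum(biomass) > 0)
  srt <- sort(biomass, decreasing = TRUE)
  k <- unname(which(cumsum(srt) > sum(srt) / 2)[1L])
  100 * k / length(biomass)
}

#' Compare a metric between two groups of replicate runs
#'
#' Welch two-sample t-test on replicate-level metric values.
#'
#' @param a,b Numeric vectors of per-replicate metric values (>= 2 each).
#' @return List with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_runs <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two replicates per group", call. = FALSE)
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Final lineage table for a run
#'
#' @param state A `colony_state`.
#' @param lattice A `hex_lattice`.
#' @return data.frame: `lineage`, `strain`, `founder_node`, `final_biomass`
#'   (kg), `survived_to_periphery`.
#' @export
lineage_table <- function(state, lattice) {
  stopifnot(!is.null(state$founders))
  bio <- lineage_biomass(state)
  surv <- peripheral_lineages(state, lattice)$all
  f <- state$founders
  data.frame(lineage = f$lineage, strain = f$strain, founder_node = f$node,
             final_biomass = as.numeric(bio[as.character(f$lineage)]),
             survived_to_periphery = f$lineage %in% surv)
}
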