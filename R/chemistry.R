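# Units: lattice geometry in um; diffusion coefficients in m^2/s;
# concentrations in mM (= mol/m^3); amounts in mol; node volumes in m^3.

hex_area_m2 <- function(side_um) 3 * sqrt(3) / 2 * (side_um * 1e-6)^2

# per-bond exchange rate [1/s]: k = D * A_bond / (pitch * V_node)
# with A_bond = side * depth and V_node = hex_area * depth (depth cancels).
# On the triangular lattice of hexagon centers this finite-volume conductance
# reproduces the continuum diffusivity exactly (1.5 * side * pitch = hex_area).
bond_rate <- function(lattice, d_coef) {
  d_coef * (lattice$side * 1e-6) /
    ((lattice$pitch * 1e-6) * hex_area_m2(lattice$side))
}

#' Per-node nitrate/nitrite concentration field
#'
#' @param lattice A `hex_lattice`.
#' @param depth Diffusion-layer depth in meters (default 1e-3, a 1 mm
#'   nutrient-bearing slab). Together with the hexagon area this sets the
#'   node volume, which couples concentrations to molar amounts.
#' @param no3,no2 Initial concentrations in mM, recycled over nodes.
#' @return An object of class `chemical_field`: list with numeric vectors
#'   `no3`, `no2` (mM), `node_volume` (m^3) and `depth` (m).
#' @export
chemical_field <- function(lattice, depth = 1e-3, no3 = 0, no2 = 0) {
  stopifnot(inherits(lattice, "hex_lattice"), depth > 0)
  if (any(no3 < 0) || any(no2 < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(
    no3 = rep_len(as.numeric(no3), lattice$n),
    no2 = rep_len(as.numeric(no2), lattice$n),
    node_volume = hex_area_m2(lattice$side) * depth,
    depth = depth
  ), class = "chemical_field")
}

#' Diffusion parameters
#'
#' @param d_no3,d_no2 Diffusion coefficients, m^2/s (default 1.7e-9 for both).
#' @param boundary_no3 Nitrate concentration imposed on boundary (rim) nodes
#'   before each diffusion step, mM.
#' @param macro_dt Macro time step, s (default 60).
#' @param substeps Number of explicit sub-steps per macro step; `NULL` picks
#'   `ceiling(macro_dt / (0.5 * dt_stable))` automatically (explicit scheme)
#'   or 1 (implicit scheme).
#' @param scheme "explicit" (forward-Euler pairwise flux, reference scheme)
#'   or "implicit" (backward-Euler, sparse Cholesky; unconditionally stable,
#'   used by the simulation presets).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(d_no3 = 1.7e-9, d_no2 = 1.7e-9,
                             boundary_no3 = 1, macro_dt = 60,
                             substeps = NULL,
                             scheme = c("explicit", "implicit")) {
  scheme <- match.arg(scheme)
  stopifnot(d_no3 > 0, d_no2 > 0, boundary_no3 >= 0, macro_dt > 0)
  if (!is.null(substeps)) stopifnot(substeps >= 1)
  structure(list(d_no3 = d_no3, d_no2 = d_no2, boundary_no3 = boundary_no3,
                 macro_dt = macro_dt, substeps = substeps, scheme = scheme),
            class = "diffusion_params")
}

#' Largest stable explicit sub-step
#'
#' Positivity/stability bound for the explicit pairwise-flux scheme:
#' `1 / (max_degree * k)` where `k` is the per-bond exchange rate of the
#' fastest-diffusing species and `max_degree` the largest number of
#' non-obstacle neighbors of any non-obstacle node.
#'
#' @param lattice A `hex_lattice`.
#' @param params A `diffusion_params`.
#' @return Maximum stable sub-step, s.
#' @export
max_stable_dt <- function(lattice, params) {
  k <- bond_rate(lattice, max(params$d_no3, params$d_no2))
  deg <- diffusion_degree(lattice)
  maxdeg <- max(deg[!lattice$is_obstacle], 1L)
  1 / (maxdeg * k)
}

# neighbor count excluding obstacle edges
diffusion_degree <- function(lattice) {
  ok <- c(FALSE, !lattice$is_obstacle)[lattice$nbr + 1L]
  dim(ok) <- dim(lattice$nbr)
  d <- rowSums(ok)
  d[lattice$is_obstacle] <- 0L
  as.integer(d)
}

n_substeps <- function(lattice, params) {
  if (!is.null(params$substeps)) return(as.integer(params$substeps))
  if (params$scheme == "implicit") return(1L)
  as.integer(ceiling(params$macro_dt / (0.5 * max_stable_dt(lattice, params))))
}

#' Precompute the diffusion operator for a lattice
#'
#' For the explicit scheme this caches per-direction neighbor index vectors;
#' for the implicit scheme it factorizes the backward-Euler system matrix
#' `I + dt_sub * L` (sparse Cholesky) once per distinct diffusion
#' coefficient. Reusing the operator across steps is what makes long runs
#' affordable.
#'
#' @inheritParams max_stable_dt
#' @return An opaque list consumed by [diffusion_step()].
#' @export
diffusion_operator <- function(lattice, params) {
  sub <- n_substeps(lattice, params)
  dt_sub <- params$macro_dt / sub
  if (params$scheme == "explicit") {
    dt_max <- max_stable_dt(lattice, params)
    if (dt_sub > dt_max * (1 + 1e-12))
      stop(sprintf(
        "explicit sub-step %.4g s exceeds the stability bound %.4g s; use at least %d substeps",
        dt_sub, dt_max, ceiling(params$macro_dt / dt_max)), call. = FALSE)
    live <- !lattice$is_obstacle
    dirs <- lapply(seq_len(6L), function(d) {
      j <- lattice$nbr[, d]
      i <- which(j > 0L & live & live[pmax(j, 1L)])
      list(i = i, j = j[i])
    })
    deg <- diffusion_degree(lattice)
    list(scheme = "explicit", substeps = sub, dt_sub = dt_sub,
         dirs = dirs, deg = deg,
         k_no3 = bond_rate(lattice, params$d_no3),
         k_no2 = bond_rate(lattice, params$d_no2))
  } else {
    live <- !lattice$is_obstacle
    jj <- as.vector(lattice$nbr)
    ii <- rep(seq_len(lattice$n), times = 6L)
    keep <- jj > 0L & live[ii] & live[pmax(jj, 1L)]
    ii <- ii[keep]; jj <- jj[keep]
    deg <- diffusion_degree(lattice)
    make_solver <- function(d_coef) {
      k <- bond_rate(lattice, d_coef)
      lap <- Matrix::sparseMatrix(
        i = c(ii, seq_len(lattice$n)), j = c(jj, seq_len(lattice$n)),
        x = c(rep(-k, length(ii)), deg * k + 0),
        dims = c(lattice$n, lattice$n))
      a <- Matrix::Diagonal(lattice$n) + dt_sub * lap
      Matrix::Cholesky(Matrix::forceSymmetric(a), LDL = FALSE)
    }
    ch_no3 <- make_solver(params$d_no3)
    ch_no2 <- if (params$d_no2 == params$d_no3) ch_no3 else
      make_solver(params$d_no2)
    list(scheme = "implicit", substeps = sub, dt_sub = dt_sub,
         ch_no3 = ch_no3, ch_no2 = ch_no2)
  }
}

explicit_substep <- function(conc, op, k) {
  s <- numeric(length(conc))
  for (d in op$dirs) s[d$i] <- s[d$i] + conc[d$j]
  conc + (k * op$dt_sub) * (s - op$deg * conc)
}

#' Advance concentrations by one macro diffusion step
#'
#' Fickian exchange along lattice bonds over `macro_dt`, split into substeps.
#' No flux crosses obstacle edges; in a closed system total mass is conserved
#' to floating-point accuracy by both schemes.
#'
#' @param field A `chemical_field`.
#' @inheritParams max_stable_dt
#' @param operator Optional precomputed [diffusion_operator()] (built on the
#'   fly when omitted).
#' @param species Which species to advance (default both).
#' @return The advanced `chemical_field`.
#' @export
diffusion_step <- function(field, lattice, params, operator = NULL,
                           species = c("no3", "no2")) {
  stopifnot(inherits(field, "chemical_field"))
  if (is.null(operator)) operator <- diffusion_operator(lattice, params)
  for (sp in species) {
    conc <- field[[sp]]
    if (operator$scheme == "explicit") {
      k <- if (sp == "no3") operator$k_no3 else operator$k_no2
      for (it in seq_len(operator$substeps))
        conc <- explicit_substep(conc, operator, k)
    } else {
      ch <- if (sp == "no3") operator$ch_no3 else operator$ch_no2
      for (it in seq_len(operator$substeps))
        conc <- as.numeric(Matrix::solve(ch, conc, system = "A"))
    }
    field[[sp]] <- conc
  }
  field
}

#' Impose the boundary nitrate source
#'
#' Sets the nitrate concentration on every non-obstacle boundary (rim) node
#' to `params$boundary_no3`, emulating the constant peripheral nutrient
#' reservoir. Applied before the diffusion step each macro step. Nitrite is
#' untouched (it is produced only by metabolism and the rim is closed to it).
#'
#' @inheritParams diffusion_step
#' @return The updated `chemical_field`.
#' @export
apply_boundary_source <- function(field, lattice, params) {
  idx <- lattice$is_boundary & !lattice$is_obstacle
  if (!any(idx)) stop("lattice has no boundary nodes", call. = FALSE)
  field$no3[idx] <- params$boundary_no3
  field
}

#' Apply biological sink/source terms to the field
#'
#' Per node, the concentration change is `(source - sink) * dt / node_volume`.
#' Consumption is clipped so no concentration goes negative; the realized
#' (possibly reduced) molar uptake is returned so the growth step can stay
#' stoichiometric with what was actually consumed.
#'
#' @param field A `chemical_field`.
#' @param lattice A `hex_lattice`.
#' @param sinks_no3,sinks_no2 Per-node consumption rates, mol/s (>= 0).
#' @param sources_no2 Per-node nitrite production rates, mol/s (>= 0).
#' @param dt Time step, s.
#' @return A list: `field` (updated), `no3_consumed`, `no2_consumed`
#'   (realized per-node molar uptake over the step).
#' @export
apply_reactions <- function(field, lattice, sinks_no3 = 0, sinks_no2 = 0,
                            sources_no2 = 0, dt) {
  stopifnot(inherits(field, "chemical_field"), dt > 0)
  sinks_no3 <- rep_len(sinks_no3, lattice$n)
  sinks_no2 <- rep_len(sinks_no2, lattice$n)
  sources_no2 <- rep_len(sources_no2, lattice$n)
  if (any(sinks_no3 < 0) || any(sinks_no2 < 0) || any(sources_no2 < 0))
    stop("reaction rates must be non-negative", call. = FALSE)
  v <- field$node_volume
  take3 <- pmin(sinks_no3 * dt, field$no3 * v)
  take2 <- pmin(sinks_no2 * dt, field$no2 * v)
  field$no3 <- field$no3 - take3 / v
  field$no2 <- field$no2 - take2 / v + sources_no2 * dt / v
  list(field = field, no3_consumed = take3, no2_consumed = take2)
}

#' Total molar amounts in the field
#'
#' Sums concentration times node volume over non-obstacle nodes. Used for
#' mass-conservation audits.
#'
#' @inheritParams apply_boundary_source
#' @return Named numeric vector `c(no3 = ..., no2 = ...)`, mol.
#' @export
total_mass <- function(field, lattice) {
  live <- !lattice$is_obstacle
  c(no3 = sum(field$no3[live]) * field$node_volume,
    no2 = sum(field$no2[live]) * field$node_volume)
}

#' Write a field snapshot as a per-node delimited table
#'
#' @inheritParams apply_boundary_source
#' @param path Output file path (tab-separated columns node, no3, no2).
#' @export
write_field <- function(field, lattice, path) {
  utils::write.table(
    data.frame(node = seq_len(lattice$n), no3 = field$no3, no2 = field$no2),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
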