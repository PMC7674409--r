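#' Full scenario configuration
#'
#' Bundles geometry, obstacle layout, diffusion, kinetics and expansion
#' parameters with run control (total time, seed, replicates, output
#' cadence) into a validated configuration object.
#'
#' Nitrite toxicity is tied to the scenario: `strong_mutualism` switches the
#' yield inhibition on (pH 6.5 regime), the other scenarios leave it off.
#'
#' @param scenario "competition", "weak_mutualism" or "strong_mutualism".
#' @param radius Domain radius, um.
#' @param side Hexagon side, um.
#' @param inoculation_radius Inoculated central disc radius, um.
#' @param obstacles An [obstacle_spec()].
#' @param diffusion A [diffusion_params()] (macro time step lives here).
#' @param kinetics A [kinetic_params()]; `NULL` uses defaults with toxicity
#'   set from the scenario.
#' @param expansion An [expansion_params()]; its inoculation radius is
#'   overridden by `inoculation_radius`.
#' @param depth Diffusion-layer depth, m.
#' @param initial_no3 Initial nitrate everywhere, mM (`NULL` = boundary
#'   value; the agar is pre-amended with the same nitrate as the rim source).
#' @param total_time Total simulated time, s (default 259200 = 72 h); must
#'   be a multiple of the macro step.
#' @param seed Integer seed; every stochastic element of a run (inoculation,
#'   placement, shoving tie-breaks, stochastic obstacles) draws from the
#'   stream this seeds.
#' @param replicates Default replicate count for [run_replicates()].
#' @param metrics_every Metric-recording cadence in macro steps.
#' @param snapshot_every Snapshot cadence in macro steps (`NULL` = none).
#' @param log_mu Record per-agent growth rates at the metrics cadence.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("competition", "weak_mutualism",
                                         "strong_mutualism"),
                            radius = 5000, side = 20,
                            inoculation_radius = 2000,
                            obstacles = obstacle_spec("none"),
                            diffusion = diffusion_params(scheme = "implicit"),
                            kinetics = NULL,
                            expansion = expansion_params(),
                            depth = 1e-3, initial_no3 = NULL,
                            total_time = 259200, seed = 1L,
                            replicates = 6L, metrics_every = 60L,
                            snapshot_every = NULL, log_mu = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(kinetics))
    kinetics <- kinetic_params(toxicity_on = scenario == "strong_mutualism")
  kinetics$toxicity_on <- scenario == "strong_mutualism"
  expansion$inoculation_radius <- inoculation_radius
  if (is.null(initial_no3)) initial_no3 <- diffusion$boundary_no3
  cfg <- structure(list(
    scenario = scenario, radius = radius, side = side,
    inoculation_radius = inoculation_radius,
    obstacles = obstacles, diffusion = diffusion, kinetics = kinetics,
    expansion = expansion, depth = depth, initial_no3 = initial_no3,
    total_time = total_time, seed = as.integer(seed),
    replicates = as.integer(replicates),
    metrics_every = as.integer(metrics_every),
    snapshot_every = snapshot_every, log_mu = isTRUE(log_mu)
  ), class = "scenario_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$radius <= cfg$side) stop("radius must exceed side", call. = FALSE)
  if (cfg$inoculation_radius >= cfg$radius)
    stop("inoculation radius must be smaller than the domain radius",
         call. = FALSE)
  dt <- cfg$diffusion$macro_dt
  if (abs(cfg$total_time / dt - round(cfg$total_time / dt)) > 1e-9)
    stop("total_time must be a multiple of the macro time step",
         call. = FALSE)
  if (cfg$replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (cfg$initial_no3 < 0) stop("initial_no3 must be >= 0", call. = FALSE)
  if (any(cfg$expansion$inoculum_frac <= 0))
    stop("inoculum masses must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: %s, domain %g um (side %g um), inoculum %g um\n",
              x$scenario, x$radius, x$side, x$inoculation_radius))
  cat(sprintf("  obstacles: %s; total time %g h at %g s steps; seed %d\n",
              x$obstacles$mode, x$total_time / 3600, x$diffusion$macro_dt,
              x$seed))
  invisible(x)
}

PRESET_NAMES <- c(
  as.vector(outer(c("competition", "weak", "strong"),
                  c("homogeneous", "coarse", "medium", "fine", "stochastic"),
                  paste, sep = "_")),
  "weak_noshove", "weak_consumer_ring", "weak_producer_ring")

#' Named scenario presets
#'
#' Paper-faithful configurations for the study's named experiments:
#' `{competition, weak, strong}_{homogeneous, coarse, medium, fine,
#' stochastic}` plus `weak_noshove`, `weak_consumer_ring` and
#' `weak_producer_ring`. Obstacle spacings are 500/400/300 um
#' (coarse/medium/fine) with 100 um discs; the stochastic habitat uses the
#' medium spacing with diameters N(100, sd 20) um. The bare scenario name
#' (e.g. `"weak"`) is shorthand for its homogeneous habitat.
#'
#' @param name Preset name (see above).
#' @param scale "full" (5 mm domain, 2 mm inoculum — the paper geometry),
#'   "reduced" (1 mm / 0.4 mm — the desk-scale geometry used for the
#'   statistics in the package's tests) or "mini" (0.4 mm / 0.16 mm, 12 h —
#'   a smoke-test scale). Temporal conditions (72 h at 60 s) are kept at
#'   full and reduced scale; see the methods vignette.
#' @param seed Integer seed stored in the config.
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name, scale = c("full", "reduced", "mini"),
                            seed = 1L) {
  scale <- match.arg(scale)
  if (name %in% c("competition", "weak", "strong"))
    name <- paste0(name, "_homogeneous")
  if (!name %in% PRESET_NAMES)
    stop("unknown preset: ", name, call. = FALSE)

  parts <- strsplit(name, "_")[[1L]]
  base <- parts[1L]; variant <- parts[2L]
  scenario <- switch(base, competition = "competition",
                     weak = "weak_mutualism", strong = "strong_mutualism")

  obstacles <- switch(variant,
    homogeneous = , noshove = , consumer = , producer = obstacle_spec("none"),
    coarse = obstacle_spec("regular", spacing = 500),
    medium = obstacle_spec("regular", spacing = 400),
    fine = obstacle_spec("regular", spacing = 300),
    stochastic = obstacle_spec("stochastic", spacing = 400))

  geom <- switch(scale,
    full = list(radius = 5000, inoc = 2000, time = 259200),
    reduced = list(radius = 1000, inoc = 400, time = 259200),
    mini = list(radius = 400, inoc = 160, time = 43200))

  expansion <- expansion_params(
    shoving_enabled = variant != "noshove",
    encasement = switch(variant, consumer = "consumer_ring",
                        producer = "producer_ring", "none"))

  scenario_config(scenario = scenario, radius = geom$radius,
                  inoculation_radius = geom$inoc, obstacles = obstacles,
                  expansion = expansion, total_time = geom$time, seed = seed)
}

#' Run one range-expansion simulation
#'
#' Executes the full macro-step loop: boundary nitrate source, diffusion,
#' growth-rate evaluation on post-diffusion concentrations, biomass update
#' with stoichiometric nutrient consumption (clipped at local availability)
#' and nitrite release by producers, then division with vacancy placement,
#' shoving or vertical stacking. Fully deterministic given the config seed.
#'
#' @param config A `scenario_config`.
#' @param out_dir Optional directory; when given, the metrics time series
#'   (`metrics.tsv`), the final occupancy snapshot (`final_state.tsv`) and
#'   the lineage table (`lineages.tsv`) are written there, plus periodic
#'   snapshots if `snapshot_every` is set.
#' @param quiet Suppress progress messages.
#' @return An object of class `colony_run`: list with `state`, `lattice`,
#'   `field`, `metrics` (data.frame), `config`, `audit` (stoichiometric
#'   bookkeeping) and `provenance`.
#' @export
simulate_colony <- function(config, out_dir = NULL, quiet = TRUE) {
  validate_config(config)
  set.seed(config$seed)

  lattice <- hex_lattice(config$radius, config$side)
  lattice <- apply_obstacles(lattice, config$obstacles,
                             clear_radius = config$inoculation_radius)
  state <- inoculate(lattice, config$expansion, config$scenario)
  field <- chemical_field(lattice, depth = config$depth,
                          no3 = config$initial_no3, no2 = 0)
  op <- diffusion_operator(lattice, config$diffusion)
  kin <- config$kinetics
  roles <- strain_roles(config$scenario)
  track_no2 <- "producer" %in% roles
  dt <- config$diffusion$macro_dt
  nsteps <- as.integer(round(config$total_time / dt))
  species <- if (track_no2) c("no3", "no2") else "no3"

  initial_biomass <- sum(state$mass) + sum(state$stacked)
  cum_gain <- 0
  clip_events <- 0L
  metrics <- vector("list", nsteps %/% config$metrics_every + 1L)
  mi <- 0L
  mu_log <- if (config$log_mu) list() else NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  for (t in seq_len(nsteps)) {
    field <- apply_boundary_source(field, lattice, config$diffusion)
    field <- diffusion_step(field, lattice, config$diffusion, op, species)

    occ <- which(state$strain > 0L)
    role_v <- roles[state$strain[occ]]
    mu <- growth_rate(role_v, field$no3[occ], field$no2[occ], kin)
    yy <- yield_coefficient(field$no2[occ], kin)
    mtot <- state$mass[occ] + state$stacked[occ]
    demand <- consumption(mtot, mu, yy, dt) / dt   # mol/s

    is_cons <- role_v == "consumer"
    sinks3 <- numeric(lattice$n); sinks2 <- numeric(lattice$n)
    sinks3[occ[!is_cons]] <- demand[!is_cons]
    sinks2[occ[is_cons]] <- demand[is_cons]
    rx <- apply_reactions(field, lattice, sinks3, sinks2, 0, dt)
    field <- rx$field
    realized <- rx$no3_consumed[occ] + rx$no2_consumed[occ]
    clip_events <- clip_events + sum(realized < demand * dt * (1 - 1e-12))

    if (track_no2) {
      # producers release nitrite 1:1 with their realized nitrate uptake
      src2 <- numeric(lattice$n)
      prod_nodes <- occ[role_v == "producer"]
      src2[prod_nodes] <- rx$no3_consumed[prod_nodes] / dt
      field <- apply_reactions(field, lattice, 0, 0, src2, dt)$field
    }

    gain <- yy * realized
    cum_gain <- cum_gain + sum(gain)
    fac <- 1 + ifelse(mtot > 0, gain / mtot, 0)
    state$mass[occ] <- state$mass[occ] * fac
    state$stacked[occ] <- state$stacked[occ] * fac

    state <- division_sweep(state, lattice, config$expansion)

    if (t %% config$metrics_every == 0L || t == nsteps) {
      mi <- mi + 1L
      metrics[[mi]] <- metric_row(state, lattice, field, t * dt, roles, mu, occ)
      if (config$log_mu)
        mu_log[[mi]] <- data.frame(time = t * dt, node = occ,
                                   strain = state$strain[occ], mu = mu)
      if (!quiet)
        message(sprintf("t = %5.1f h: %d occupied, biomass %.3g kg",
                        t * dt / 3600, sum(state$strain > 0L),
                        sum(state$mass) + sum(state$stacked)))
      if (!is.null(out_dir) && !is.null(config$snapshot_every) &&
          t %% config$snapshot_every == 0L)
        write_snapshot(state, file.path(out_dir,
                                        sprintf("snapshot_%07d.tsv", t)))
    }
  }

  metrics <- do.call(rbind, metrics[seq_len(mi)])
  final_biomass <- sum(state$mass) + sum(state$stacked)
  run <- structure(list(
    state = state, lattice = lattice, field = field, metrics = metrics,
    config = config,
    audit = list(initial_biomass = initial_biomass,
                 final_biomass = final_biomass,
                 yield_weighted_consumption = cum_gain,
                 clip_events = clip_events),
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      package_version = as.character(
                        utils::packageVersion("hexcolony")),
                      r_version = R.version.string),
    mu_log = if (config$log_mu) do.call(rbind, mu_log) else NULL
  ), class = "colony_run")

  if (!is.null(out_dir)) {
    write_metrics(run, file.path(out_dir, "metrics.tsv"))
    write_snapshot(state, file.path(out_dir, "final_state.tsv"))
    utils::write.table(lineage_table(state, lattice),
                       file.path(out_dir, "lineages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run
}

metric_row <- function(state, lattice, field, time, roles, mu, occ) {
  p <- periphery(lattice, state$strain)
  br <- if ("consumer" %in% roles) consumer_branches(state, lattice)
        else list(branches = NA_integer_, ratio = NA_real_)
  lin <- peripheral_lineages(state, lattice)$by_strain
  n1 <- length(lin[["1"]]); n2 <- length(lin[["2"]])
  r_occ <- sqrt(lattice$x[occ]^2 + lattice$y[occ]^2)
  data.frame(
    time = time,
    n_occupied = length(occ),
    colony_radius = if (length(occ)) max(r_occ) else 0,
    total_biomass = sum(state$mass) + sum(state$stacked),
    boundaries = if (length(p)) interspecies_boundaries(state, lattice)
                 else NA_integer_,
    periph_lineages_1 = n1, periph_lineages_2 = n2,
    consumer_branches = br$branches, branch_ratio = br$ratio,
    mean_mu_1 = if (any(state$strain[occ] == 1L))
      mean(mu[state$strain[occ] == 1L]) else NA_real_,
    mean_mu_2 = if (any(state$strain[occ] == 2L))
      mean(mu[state$strain[occ] == 2L]) else NA_real_)
}

#' @export
print.colony_run <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("colony_run (%s, seed %d): %d steps recorded\n",
              x$config$scenario, x$config$seed, nrow(x$metrics)))
  cat(sprintf("  final: %d occupied nodes, radius %.0f um, biomass %.3g kg\n",
              m$n_occupied, m$colony_radius, m$total_biomass))
  cat(sprintf("  peripheral lineages: %d + %d; boundaries: %s\n",
              m$periph_lineages_1, m$periph_lineages_2,
              format(m$boundaries)))
  invisible(x)
}

#' Summary statistics of a finished run
#'
#' @param run A `colony_run`.
#' @param growth_layer_depth Growth-layer depth for [lineage_loss()], um.
#' @return Named list of end-time metrics: lineage-loss percentages, lucky
#'   fraction, boundary and branch counts, biomass and radius.
#' @export
run_statistics <- function(run, growth_layer_depth = 100) {
  loss <- lineage_loss(run$state, run$lattice, growth_layer_depth)
  br <- consumer_branches(run$state, run$lattice)
  m <- run$metrics[nrow(run$metrics), ]
  list(loss_growth_layer = unname(loss["growth_layer"]),
       loss_all = unname(loss["all"]),
       lucky_fraction = lucky_fraction(run$state),
       boundaries = m$boundaries,
       consumer_branches = br$branches,
       branch_ratio = br$ratio,
       periph_lineages_1 = m$periph_lineages_1,
       periph_lineages_2 = m$periph_lineages_2,
       total_biomass = m$total_biomass,
       colony_radius = m$colony_radius,
       n_founders = nrow(run$state$founders))
}

#' Run a batch of replicate simulations
#'
#' Replicates differ only in their seed, derived from the base seed by the
#' fixed rule `seed + i` (i = 1..n). Stochastic obstacle fields are redrawn
#' per replicate.
#'
#' @param config A `scenario_config`.
#' @param n Number of replicates (default `config$replicates`).
#' @param growth_layer_depth Passed to [run_statistics()].
#' @return List with `runs` (list of `colony_run`), `stats` (per-replicate
#'   data.frame) and `summary` (mean and sd per metric).
#' @export
run_replicates <- function(config, n = config$replicates,
                           growth_layer_depth = 100) {
  stopifnot(n >= 1L)
  runs <- vector("list", n)
  stats_l <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + i
    runs[[i]] <- simulate_colony(cfg)
    s <- run_statistics(runs[[i]], growth_layer_depth)
    stats_l[[i]] <- data.frame(replicate = i, seed = cfg$seed,
                               as.data.frame(s))
  }
  stats <- do.call(rbind, stats_l)
  num <- vapply(stats, is.numeric, logical(1)) &
    !names(stats) %in% c("replicate", "seed")
  summary <- data.frame(
    metric = names(stats)[num],
    mean = vapply(stats[num], function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(stats[num], function(v) stats::sd(v, na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  list(runs = runs, stats = stats, summary = summary)
}

#' Write the metrics time series of a run
#'
#' Deterministic tab-separated output (identical bytes for identical
#' config and seed).
#'
#' @param run A `colony_run`.
#' @param path Output file path.
#' @export
write_metrics <- function(run, path) {
  utils::write.table(run$metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Recompute colony metrics from a written snapshot
#'
#' @param snapshot_path Path to a snapshot written by [write_snapshot()].
#' @param lattice The `hex_lattice` the snapshot refers to.
#' @return One-row data.frame of occupancy metrics.
#' @export
metrics_from_snapshot <- function(snapshot_path, lattice) {
  tab <- utils::read.table(snapshot_path, header = TRUE, sep = "\t")
  st <- new_colony_state(lattice, "competition")
  st$strain[tab$node] <- tab$strain
  st$lineage[tab$node] <- tab$lineage
  st$mass[tab$node] <- tab$mass
  st$stacked[tab$node] <- tab$stacked
  p <- periphery(lattice, st$strain)
  data.frame(
    n_occupied = nrow(tab),
    total_biomass = sum(tab$mass) + sum(tab$stacked),
    boundaries = if (length(p)) interspecies_boundaries(st, lattice)
                 else NA_integer_,
    periph_lineages = length(unique(st$lineage[p])))
}
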