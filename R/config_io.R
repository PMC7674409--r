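#' Write a scenario configuration to a YAML file
#'
#' All kinetic, diffusion, expansion and obstacle parameters are serialized
#' as plain key-value YAML and can be edited by hand; [read_config()]
#' rebuilds and revalidates the configuration.
#'
#' @param config A `scenario_config`.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  plain <- list(
    scenario = config$scenario,
    geometry = list(radius = config$radius, side = config$side,
                    inoculation_radius = config$inoculation_radius,
                    depth = config$depth),
    obstacles = unclass(config$obstacles),
    diffusion = unclass(config$diffusion),
    kinetics = unclass(config$kinetics),
    expansion = unclass(config$expansion)[
      setdiff(names(config$expansion), "inoculation_radius")],
    run = list(initial_no3 = config$initial_no3,
               total_time = config$total_time, seed = config$seed,
               replicates = config$replicates,
               metrics_every = config$metrics_every,
               snapshot_every = config$snapshot_every,
               log_mu = config$log_mu))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' @param path Path to a file written by [write_config()] (or hand-edited in
#'   the same layout).
#' @return A validated `scenario_config`.
#' @export
read_config <- function(path) {
  p <- yaml::read_yaml(path)
  scenario_config(
    scenario = p$scenario,
    radius = p$geometry$radius, side = p$geometry$side,
    inoculation_radius = p$geometry$inoculation_radius,
    depth = p$geometry$depth,
    obstacles = do.call(obstacle_spec, p$obstacles),
    diffusion = do.call(diffusion_params, p$diffusion),
    kinetics = do.call(kinetic_params, p$kinetics),
    expansion = do.call(expansion_params,
                        c(p$expansion,
                          list(inoculation_radius =
                                 p$geometry$inoculation_radius))),
    initial_no3 = p$run$initial_no3,
    total_time = p$run$total_time, seed = p$run$seed,
    replicates = p$run$replicates, metrics_every = p$run$metrics_every,
    snapshot_every = p$run$snapshot_every, log_mu = p$run$log_mu)
}
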