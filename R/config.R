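# YAML run configuration. The schema mirrors sim_params() field-for-field
# under `simulation:`; bead index ranges are written [from, to].

#' Read a pipeline run configuration
#'
#' @param path YAML file, or a list already in config shape.
#' @return validated config list with elements `simulation`
#'   (a [sim_params()]), `n_cells`, `seed`, `dna_channel`, `thresholds`,
#'   `min_volume`, `relative_min`, `contact_mode`, `report`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  sim <- cfg$simulation %||% list()
  chans <- sim$channels
  if (!is.null(chans)) {
    chans <- lapply(chans, function(ch) {
      utils::modifyList(default_channels()[[1]], ch)
    })
  }
  rng2seq <- function(r) if (is.null(r)) NULL else seq(r[[1]], r[[2]])
  bp <- sim$band_probes
  if (!is.null(bp)) {
    bp <- list(channel = bp$channel, cen = rng2seq(bp$cen),
               mid = rng2seq(bp$mid), tel = rng2seq(bp$tel))
  }
  args <- list(
    nucleus_radii = sim$nucleus_radii, voxel_spacing = sim$voxel_spacing,
    grid_dim = sim$grid_dim, channels = chans,
    confinement = sim$confinement, pairing_prob = sim$pairing_prob,
    translocation = sim$translocation, band_probes = bp,
    psf_sigma = sim$psf_sigma, photon_scale = sim$photon_scale,
    read_noise_sd = sim$read_noise_sd, background = sim$background,
    shot_noise = sim$shot_noise, seed = sim$seed
  )
  args <- args[!vapply(args, is.null, TRUE)]
  params <- do.call(sim_params, args)
  list(
    simulation = params,
    n_cells = cfg$n_cells %||% 20L,
    seed = cfg$seed %||% params$seed,
    dna_channel = cfg$dna_channel %||% "dna",
    channels = cfg$channels %||% vapply(params$channels, `[[`, "", "name"),
    thresholds = cfg$thresholds,
    min_volume = cfg$min_volume %||% 0.05,
    relative_min = cfg$relative_min %||% 0.1,
    contact_mode = cfg$contact_mode %||% "adjacency",
    report = cfg$report %||% list(plots = FALSE)
  )
}
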