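#' Default model configuration
#'
#' Bundles the parameter objects of every stage of the pipeline: the Vim rate
#' network and its DBS synapse, the M1 population and its three input
#' synapse classes, the motoneuron pool, the tremor background, the MUAP/EMG
#' stage, the spectral system output and the PID controller. `dt` is the
#' shared simulation step (ms) of all spiking/current stages.
#'
#' @return A named list of class `dbs_config`.
#' @export
dbs_config <- function() {
  structure(list(
    dt = 0.1,
    vim_network = vim_network_params(),
    m1 = m1_params(),
    m1_synapses = m1_synapse_defaults(),
    motoneuron = motoneuron_params(),
    tremor = tremor_params(),
    muap = muap_params(),
    spectral = spectral_params(),
    control = pid_gains()
  ), class = "dbs_config")
}

#' Scale the population sizes of a configuration
#'
#' Convenience for fast, scaled-down runs (tests, demos): smaller M1 and
#' motoneuron populations with proportionate fan-in. Dynamics parameters are
#' untouched.
#'
#' @param config A [dbs_config()] list.
#' @param N_c,N_m,fan_in New population sizes and fan-in.
#' @return The modified configuration.
#' @export
scale_config <- function(config, N_c = 30, N_m = 24, fan_in = 14) {
  config$m1$N_c <- N_c
  config$motoneuron$N_m <- N_m
  config$motoneuron$fan_in <- fan_in
  config
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.matrix(x)) {
    apply(x, 1, as.numeric, simplify = FALSE)
  } else x
}

#' Write / read a configuration as YAML
#'
#' @param config A [dbs_config()] list.
#' @param path File path.
#' @return `read_config` returns a reconstructed `dbs_config`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_classes(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tm <- function(x) do.call(tm_params, x)
  vn <- raw$vim_network
  vn$weights <- do.call(rbind, vn$weights)
  vn$dbs_synapse <- tm(vn$dbs_synapse)
  for (f in c("tau_rate", "act_max", "act_theta", "act_slope",
              "baseline_drive", "dbs_coupling"))
    vn[[f]] <- as.numeric(vn[[f]])
  mn <- raw$motoneuron
  mn$Vth_range <- as.numeric(mn$Vth_range)
  sp <- raw$spectral
  sp$band <- as.numeric(sp$band)
  structure(list(
    dt = raw$dt,
    vim_network = do.call(vim_network_params, vn),
    m1 = do.call(m1_params, raw$m1),
    m1_synapses = lapply(raw$m1_synapses, tm),
    motoneuron = do.call(motoneuron_params, mn),
    tremor = do.call(tremor_params, raw$tremor),
    muap = do.call(muap_params, raw$muap),
    spectral = do.call(spectral_params, sp),
    control = do.call(pid_gains, raw$control)
  ), class = "dbs_config")
}
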