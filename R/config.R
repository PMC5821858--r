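#' Pipeline configuration
#'
#' All tunable parameters of the analysis with their study defaults: 200 Hz
#' sampling, 1-second epochs, 300 epochs per session, 1-70 Hz broadband with
#' a 60 Hz notch, 8 histogram bins, 1000 surrogates at alpha 0.05 with
#' threshold-style correction, 100 random references, 5 hubs, top-30% edge
#' plotting, 80% outcome cutoff and a 10 events/day frequency cutoff.
#'
#' @param ... overrides for any default field.
#' @return validated named list of class `ccnet_config`.
#' @export
ccnet_config <- function(...) {
  cfg <- list(
    fs = 200, epoch_seconds = 1, n_epochs = 300,
    broadband = c(1, 70), notch = 60,
    n_bins = 8, n_surrogates = 1000, alpha = 0.05,
    correction = "threshold", surrogates = "pooled",
    n_random = 100, hub_k = 5, plot_fraction = 0.30,
    freq_cutoff = 10, outcome_cutoff = 80,
    base_strength = 0.25, reject_z = 6,
    n_per_group = c(I_HighGood = 6, II_LowGood = 11,
                    III_HighBad = 6, IV_LowBad = 7),
    signal_format = "csv", master_seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_arg("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "ccnet_config")
}

validate_config <- function(cfg) {
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_arg("alpha must be in (0, 1)")
  if (cfg$outcome_cutoff > 100 || cfg$outcome_cutoff < -100) {
    stop_arg("outcome_cutoff must be in [-100, 100]")
  }
  if (cfg$n_epochs <= 0 || cfg$n_surrogates <= 0 || cfg$n_random <= 0) {
    stop_arg("counts must be positive")
  }
  if (!cfg$correction %in% c("threshold", "subtract")) {
    stop_arg("correction must be 'threshold' or 'subtract'")
  }
  if (!cfg$signal_format %in% c("csv", "edf")) {
    stop_arg("signal_format must be 'csv' or 'edf'")
  }
  if (cfg$broadband[2] >= cfg$fs / 2) {
    stop_arg("broadband upper edge must be below fs/2")
  }
  invisible(cfg)
}

#' @rdname ccnet_config
#' @param path YAML file of key-value overrides.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ccnet_config, vals)
}

#' @rdname ccnet_config
#' @param cfg a `ccnet_config`.
#' @export
config_hash <- function(cfg) fnv1a_hash(cfg[order(names(cfg))])

# Provenance lines stamped into every pipeline output directory.
provenance_lines <- function(cfg) {
  c(sprintf("# ccnet %s | R %s | config %s",
            as.character(packageVersion("ccnet")),
            paste(R.version$major, R.version$minor, sep = "."),
            config_hash(cfg)),
    sprintf("# %s = %s", names(cfg),
            vapply(cfg, function(v) paste(format(v), collapse = ","), "")))
}
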