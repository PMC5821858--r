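# Directory layout written by run_simulate and consumed by run_connect:
#   out_dir/metadata.csv                       one row per patient
#   out_dir/provenance.txt                     config + versions + hash
#   out_dir/signals/<patient>_<session>.csv    channels x samples (or .edf)
# Real recordings drop into the same tree: metadata.csv plus one signal file
# per patient-session.

signal_path <- function(dir, patient_id, session, format) {
  file.path(dir, "signals", sprintf("%s_%s.%s", patient_id, session, format))
}

write_signal_csv <- function(mat, path) {
  df <- data.frame(channel = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
}

read_signal_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Simulate a cohort and write it to disk
#'
#' Generates the synthetic cohort defined by `config` and writes the
#' directory tree documented in the package: clinical metadata CSV plus one
#' signal matrix per patient-session, with epochs concatenated in time so
#' the files look like continuous recordings.
#'
#' @param config a [ccnet_config()].
#' @param out_dir output directory (created).
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config = ccnet_config(), out_dir) {
  validate_config(config)
  dir.create(file.path(out_dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(
    n_per_group = config$n_per_group, seed = config$master_seed,
    n_epochs = config$n_epochs,
    n_samples = round(config$fs * config$epoch_seconds), fs = config$fs,
    base_strength = config$base_strength, freq_cutoff = config$freq_cutoff)
  meta <- cohort_metadata(cohort)
  write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  for (p in cohort$patients) {
    for (s in session_labels()) {
      d <- p$sessions[[s]]$data
      flat <- matrix(aperm(d, c(2, 3, 1)), nrow = dim(d)[2])
      rownames(flat) <- cohort$montage$channel
      pth <- signal_path(out_dir, p$patient_id, s, config$signal_format)
      if (config$signal_format == "edf") {
        write_edf(flat, pth, fs = config$fs, patient_id = p$patient_id)
      } else {
        write_signal_csv(flat, pth)
      }
    }
  }
  writeLines(provenance_lines(config), file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

read_signal_any <- function(path, montage) {
  m <- if (grepl("\\.edf$", path)) read_edf(path)$data else read_signal_csv(path)
  m[match_channels(rownames(m), montage), , drop = FALSE]
}

#' Build adjacency matrices from a cohort directory
#'
#' Reads each patient-session recording, re-references it to the common
#' average, segments it into 1-second epochs, and writes the
#' surrogate-corrected MI adjacency matrix as both CSV and Pajek .net.
#' Existing outputs are skipped unless `force = TRUE` (resumable runs).
#'
#' @param in_dir cohort directory (see [run_simulate()]).
#' @param out_dir output directory for `adjacency/` files.
#' @param config a [ccnet_config()].
#' @param force recompute existing outputs.
#' @param filter apply the broadband filter before epoching (default FALSE:
#'   the synthetic generator emits in-band signals; set TRUE for real
#'   recordings).
#' @return invisibly, the adjacency output directory.
#' @export
run_connect <- function(in_dir, out_dir, config = ccnet_config(),
                        force = FALSE, filter = FALSE) {
  validate_config(config)
  meta <- read.csv(file.path(in_dir, "metadata.csv"),
                   stringsAsFactors = FALSE)
  adir <- file.path(out_dir, "adjacency")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  mont <- montage_1020()
  for (pi in seq_len(nrow(meta))) {
    pid <- meta$patient_id[pi]
    for (si in seq_along(session_labels())) {
      s <- session_labels()[si]
      dest <- file.path(adir, sprintf("%s_%s.csv", pid, s))
      if (file.exists(dest) && !force) next
      src <- signal_path(in_dir, pid, s, config$signal_format)
      if (!file.exists(src)) stop_arg("missing signal file: ", src)
      raw <- read_signal_any(src, mont)
      if (filter) raw <- broadband_filter(raw, fs = config$fs,
                                          low = config$broadband[1],
                                          high = config$broadband[2],
                                          notch = config$notch)
      raw <- average_rereference(raw)
      n_avail <- floor(ncol(raw) / round(config$fs * config$epoch_seconds))
      eps <- segment_and_select(raw, fs = config$fs,
                                n_epochs = min(config$n_epochs, n_avail),
                                reject_z = config$reject_z,
                                seed = fan_seed(config$master_seed, pi, si, 1),
                                epoch_seconds = config$epoch_seconds,
                                montage = mont)
      adj <- epoch_adjacency(eps, n_surrogates = config$n_surrogates,
                             alpha = config$alpha, n_bins = config$n_bins,
                             seed = fan_seed(config$master_seed, pi, si, 2),
                             surrogates = config$surrogates,
                             mode = config$correction, session = s)
      write_adjacency_csv(adj, dest)
      write_pajek(adj, sub("\\.csv$", ".net", dest), montage = mont)
    }
  }
  writeLines(provenance_lines(config), file.path(out_dir, "provenance.txt"))
  invisible(adir)
}

#' Compute tidy metrics from stored adjacency matrices
#'
#' @param in_dir directory containing `adjacency/` (from [run_connect()])
#'   and the cohort `metadata.csv` directory via `meta_dir`.
#' @param meta_dir directory holding `metadata.csv` (defaults to `in_dir`).
#' @param out_dir output directory for `metrics_global.csv`,
#'   `metrics_nodes.csv` and `hubs.csv`.
#' @param config a [ccnet_config()].
#' @return invisibly, the output directory.
#' @export
run_metrics <- function(in_dir, out_dir, config = ccnet_config(),
                        meta_dir = in_dir) {
  validate_config(config)
  meta <- read.csv(file.path(meta_dir, "metadata.csv"),
                   stringsAsFactors = FALSE)
  adir <- file.path(in_dir, "adjacency")
  if (!dir.exists(adir) || !length(list.files(adir, pattern = "\\.csv$"))) {
    stop_arg("no adjacency matrices found under ", adir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta$group <- assign_group(meta$preop_seizure_freq, meta$reduction_y2,
                             config$freq_cutoff, config$outcome_cutoff)
  gl <- list(); nd <- list(); hb <- list()
  mont <- montage_1020()
  for (pi in seq_len(nrow(meta))) {
    pid <- meta$patient_id[pi]
    for (si in seq_along(session_labels())) {
      s <- session_labels()[si]
      a <- read_adjacency_csv(file.path(adir, sprintf("%s_%s.csv", pid, s)),
                              session = s)
      bc <- weighted_betweenness(a)
      lcc <- local_clustering(a)
      gm <- suppressWarnings(global_metrics(
        a, n_random = config$n_random,
        seed = fan_seed(config$master_seed, pi, si, 3)))
      hubs <- extract_hubs(bc, k = config$hub_k)
      gl[[length(gl) + 1]] <- data.frame(
        patient_id = pid, group = meta$group[pi], session = s,
        bc_mean = mean(bc), lcc_mean = mean(lcc), cpl_raw = gm$cpl_raw,
        gcc_raw = gm$gcc_raw, cpl_norm = gm$cpl_norm,
        gcc_norm = gm$gcc_norm, small_worldness = gm$small_worldness,
        stringsAsFactors = FALSE)
      nd[[length(nd) + 1]] <- data.frame(
        patient_id = pid, group = meta$group[pi], session = s,
        channel = names(bc), bc = as.numeric(bc), lcc = as.numeric(lcc),
        stringsAsFactors = FALSE)
      hb[[length(hb) + 1]] <- data.frame(
        patient_id = pid, group = meta$group[pi], session = s,
        rank = seq_along(hubs), channel = as.character(hubs),
        x = mont$x[match(as.character(hubs), mont$channel)],
        y = mont$y[match(as.character(hubs), mont$channel)],
        region = mont$region[match(as.character(hubs), mont$channel)],
        stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, gl), file.path(out_dir, "metrics_global.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, nd), file.path(out_dir, "metrics_nodes.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, hb), file.path(out_dir, "hubs.csv"),
            row.names = FALSE)
  writeLines(provenance_lines(config), file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' Run the statistical battery over stored metrics
#'
#' @param in_dir directory holding `metrics_global.csv` / `metrics_nodes.csv`.
#' @param out_dir output directory for `report_*.csv` and `report.txt`.
#' @param config a [ccnet_config()].
#' @return the [longitudinal_report()] object, invisibly.
#' @export
run_report <- function(in_dir, out_dir, config = ccnet_config()) {
  validate_config(config)
  gpath <- file.path(in_dir, "metrics_global.csv")
  if (!file.exists(gpath)) stop_arg("no metrics found under ", in_dir)
  metrics <- list(global = read.csv(gpath, stringsAsFactors = FALSE),
                  nodes = read.csv(file.path(in_dir, "metrics_nodes.csv"),
                                   stringsAsFactors = FALSE))
  rep <- longitudinal_report(metrics, alpha = config$alpha)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(rep$trajectories, file.path(out_dir, "report_trajectories.csv"),
            row.names = FALSE)
  write.csv(rep$anova, file.path(out_dir, "report_anova.csv"),
            row.names = FALSE)
  write.csv(rep$levene, file.path(out_dir, "report_levene.csv"),
            row.names = FALSE)
  txt <- c(provenance_lines(config), "",
           utils::capture.output(print(rep)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(rep)
}
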