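#' Coupling model for synthetic multichannel signals
#'
#' A first-order multivariate autoregressive signal model: channel `i` at time
#' `t` is `ar_coeffs[i] * x_i(t-1) + coupling_scale * sum_j C[i,j] x_j(t-1) +`
#' Gaussian innovation. Pairwise dependence grows monotonically with the
#' coupling entry. Coupling entries live in `[0, 1)`; `coupling_scale`
#' (default 0.5) maps them into the transition matrix so that even the
#' strongest supported single-pair coupling of 0.8 remains a stable system.
#'
#' @param coupling symmetric nonnegative matrix, zero diagonal, entries < 1.
#' @param noise_sd innovation standard deviation (signal units, default 1).
#' @param ar_coeffs per-channel AR(1) coefficients (default 0.5).
#' @param condition_tag `"preop"`, `"postop_good"` or `"postop_bad"` (or
#'   `"custom"`).
#' @param coupling_scale factor applied to `coupling` in the AR transition
#'   matrix (default 0.5).
#' @return object of class `coupling_model`.
#' @export
coupling_model <- function(coupling, noise_sd = 1,
                           ar_coeffs = rep(0.5, nrow(coupling)),
                           condition_tag = "custom", coupling_scale = 0.5) {
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != ncol(coupling)) stop_arg("coupling must be square")
  if (max(abs(coupling - t(coupling))) > 1e-12) stop_arg("coupling must be symmetric")
  if (any(diag(coupling) != 0)) stop_arg("coupling diagonal must be zero")
  if (any(coupling < 0) || any(coupling >= 1)) stop_arg("coupling entries must be in [0, 1)")
  structure(list(coupling = coupling, noise_sd = noise_sd,
                 ar_coeffs = ar_coeffs, condition_tag = condition_tag,
                 coupling_scale = coupling_scale),
            class = "coupling_model")
}

ar_transition <- function(model) {
  diag(model$ar_coeffs) + model$coupling_scale * model$coupling
}

#' @rdname coupling_model
#' @param model a `coupling_model`.
#' @export
is_stable <- function(model) {
  max(Mod(eigen(ar_transition(model), only.values = TRUE)$values)) < 1
}

# Edge sets of the planted scalp topology, as channel-name pairs.
planted_edges <- function() {
  list(
    # first 8 backbone edges touch the midline (star spokes), last 4 are the
    # parasagittal chains
    backbone = rbind(c("Fz", "Cz"), c("Cz", "Pz"), c("Fz", "F3"), c("Fz", "F4"),
                     c("Cz", "C3"), c("Cz", "C4"), c("Pz", "P3"), c("Pz", "P4"),
                     c("F3", "C3"), c("C3", "P3"), c("F4", "C4"), c("C4", "P4")),
    attach = rbind(c("Fp1", "F3"), c("Fp2", "F4"), c("F7", "F3"), c("F8", "F4"),
                   c("T3", "C3"), c("T4", "C4"), c("T5", "P3"), c("T6", "P4"),
                   c("O1", "P3"), c("O2", "P4")),
    homologous = homologous_lateral_pairs(),
    lateral_chain = rbind(c("Fp1", "F7"), c("F7", "T3"), c("T3", "T5"),
                          c("T5", "O1"), c("Fp2", "F8"), c("F8", "T4"),
                          c("T4", "T6"), c("T6", "O2"))
  )
}

set_edges <- function(C, pairs, value, montage) {
  i <- match(pairs[, 1], montage$channel)
  j <- match(pairs[, 2], montage$channel)
  C[cbind(i, j)] <- value
  C[cbind(j, i)] <- value
  C
}

#' Condition-specific coupling models
#'
#' Builds the planted 19-channel coupling structure for one study condition.
#' Pre-operative coupling is concentrated on a paramedian backbone (midline +
#' parasagittal chains) with lateral channels attached through weaker links
#' and only faint interhemispheric or intra-lateral connections — so
#' paramedian channels carry the network's shortest paths. The good-outcome
#' post-operative model weakens the paramedian backbone, strengthens the
#' homologous interhemispheric lateral pairs and the lateral chains, and
#' flattens the weight distribution toward a homogeneous network. The
#' bad-outcome model keeps the mean paramedian coupling essentially unchanged
#' but concentrates it star-like onto the midline spokes (mirroring the
#' midline-bound hubs of bad outcomes), with the faint lateral couplings
#' further reduced — a less clustered, less integrated reorganization.
#'
#' @param condition `"preop"`, `"postop_good"` or `"postop_bad"`.
#' @param base_strength backbone coupling strength, in (0, 0.9); default 0.25.
#' @param seed optional seed for small per-edge lognormal jitter; `NULL`
#'   (default) gives the deterministic template.
#' @param jitter_sd lognormal sd of the per-edge jitter when `seed` is given
#'   (default 0.05).
#' @return a [coupling_model()].
#' @export
make_condition_coupling <- function(condition = c("preop", "postop_good", "postop_bad"),
                                    base_strength = 0.25, seed = NULL,
                                    jitter_sd = 0.05) {
  condition <- match.arg(condition)
  if (base_strength <= 0 || base_strength >= 0.9) {
    stop_arg("base_strength must be in (0, 0.9)")
  }
  mont <- montage_1020()
  ed <- planted_edges()
  C <- matrix(0, 19, 19, dimnames = list(mont$channel, mont$channel))
  b <- base_strength
  C <- switch(condition,
    preop = {
      C <- set_edges(C, ed$backbone, b, mont)
      C <- set_edges(C, ed$attach, 0.45 * b, mont)
      C <- set_edges(C, ed$homologous, 0.10 * b, mont)
      set_edges(C, ed$lateral_chain, 0.10 * b, mont)
    },
    postop_good = {
      C <- set_edges(C, ed$backbone, 0.45 * b, mont)
      C <- set_edges(C, ed$attach, 0.45 * b, mont)
      C <- set_edges(C, ed$homologous, 0.55 * b, mont)
      set_edges(C, ed$lateral_chain, 0.45 * b, mont)
    },
    postop_bad = {
      C <- set_edges(C, ed$backbone[1:8, ], 1.30 * b, mont)  # midline spokes up
      C <- set_edges(C, ed$backbone[9:12, ], 0.50 * b, mont) # chains down
      C <- set_edges(C, ed$attach, 0.40 * b, mont)
      C <- set_edges(C, ed$homologous, 0.02 * b, mont)
      set_edges(C, ed$lateral_chain, 0.02 * b, mont)
    })
  if (!is.null(seed)) {
    C <- with_seed(seed, {
      jit <- matrix(exp(rnorm(19 * 19, 0, jitter_sd)), 19, 19)
      jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
      pmin(C * jit, 0.999)
    })
  }
  m <- coupling_model(C, condition_tag = condition)
  if (!is_stable(m)) stop_arg("condition coupling model is unstable")
  m
}

#' Generate coupled multichannel epochs
#'
#' Simulates independent stationary epochs of the multivariate AR process
#' defined by `model`. Each epoch starts from white noise and discards a
#' burn-in before recording, so epochs are exchangeable and stationary.
#' Identical `(model, seed)` reproduce bit-identical output.
#'
#' @param model a [coupling_model()]; must be stable.
#' @param n_epochs number of epochs (> 0).
#' @param n_samples samples per epoch (default 200 = 1 s at 200 Hz).
#' @param fs sampling frequency carried on the result (default 200).
#' @param seed RNG seed.
#' @param burn_in discarded initial samples per epoch (default 300).
#' @param montage montage for the result (channel count must match).
#' @return an [epoch_set()].
#' @export
generate_coupled_epochs <- function(model, n_epochs, n_samples = 200, fs = 200,
                                    seed = 1, burn_in = 300,
                                    montage = montage_1020()) {
  if (!inherits(model, "coupling_model")) stop_arg("model must be a coupling_model")
  if (n_epochs <= 0) stop_arg("n_epochs must be positive")
  if (!is_stable(model)) {
    stop_arg("unstable coupling model (spectral radius >= 1); ",
             "reduce coupling or coupling_scale")
  }
  nc <- nrow(model$coupling)
  if (nc != nrow(montage)) stop_arg("model/montage channel mismatch")
  A <- ar_transition(model)
  with_seed(seed, {
    X <- matrix(rnorm(n_epochs * nc, sd = model$noise_sd), n_epochs, nc)
    for (t in seq_len(burn_in)) {
      X <- X %*% A + matrix(rnorm(n_epochs * nc, sd = model$noise_sd),
                            n_epochs, nc)
    }
    out <- array(0, dim = c(n_epochs, nc, n_samples))
    for (t in seq_len(n_samples)) {
      X <- X %*% A + matrix(rnorm(n_epochs * nc, sd = model$noise_sd),
                            n_epochs, nc)
      out[, , t] <- X
    }
    epoch_set(out, fs = fs, montage = montage)
  })
}

cohort_groups <- function() {
  c("I_HighGood", "II_LowGood", "III_HighBad", "IV_LowBad")
}

session_labels <- function() c("preop", "m3", "y1", "y2")

#' Generate a synthetic four-group, four-session cohort
#'
#' Emulates the study design: patients split 2x2 by high/low pre-operative
#' daily seizure frequency and good/bad two-year outcome, each recorded at
#' four sessions (pre-op, 3 months, 1 year, 2 years). Good-outcome patients'
#' coupling interpolates linearly from the pre-operative to the good
#' post-operative structure across the follow-ups; bad-outcome patients
#' switch to the bad post-operative structure (retained paramedian core) from
#' 3 months on. Seizure frequencies straddle `freq_cutoff` and two-year
#' reductions straddle the 80% outcome cutoff consistently with the planted
#' group labels. Default group sizes (6, 11, 6, 7) mirror the study's
#' repeated-measures degrees of freedom.
#'
#' @param n_per_group named counts for `I_HighGood`, `II_LowGood`,
#'   `III_HighBad`, `IV_LowBad`.
#' @param seed master seed; every patient/session stream is fanned out from it.
#' @param n_epochs epochs per session (study value 300).
#' @param n_samples,fs epoch length and sampling rate.
#' @param base_strength backbone coupling strength.
#' @param freq_cutoff high/low seizure-frequency cutoff in events/day
#'   (default 10).
#' @param jitter_sd per-patient coupling jitter (lognormal sd).
#' @return object of class `cc_cohort`: list with `patients` (each carrying
#'   `patient_id`, `group`, `preop_seizure_freq`, `reductions`, `sessions`),
#'   `montage` and the generating `config`.
#' @export
generate_cohort <- function(n_per_group = c(I_HighGood = 6, II_LowGood = 11,
                                            III_HighBad = 6, IV_LowBad = 7),
                            seed = 1, n_epochs = 300, n_samples = 200,
                            fs = 200, base_strength = 0.25, freq_cutoff = 10,
                            jitter_sd = 0.05) {
  if (!all(cohort_groups() %in% names(n_per_group))) {
    stop_arg("n_per_group must name all four groups")
  }
  if (any(n_per_group <= 0)) stop_arg("group counts must be positive")
  mont <- montage_1020()
  patients <- list()
  pid <- 0L
  for (g in cohort_groups()) {
    high <- grepl("High", g)
    good <- grepl("Good", g)
    for (k in seq_len(n_per_group[[g]])) {
      pid <- pid + 1L
      pseed <- fan_seed(seed, pid)
      clin <- with_seed(pseed, {
        freq <- if (high) freq_cutoff * exp(runif(1, 0.2, 1.6)) else
          freq_cutoff * exp(-runif(1, 0.2, 1.6))
        red <- if (good) {
          c(m3 = runif(1, 50, 100), y1 = runif(1, 70, 100),
            y2 = runif(1, 85, 100))
        } else {
          c(m3 = runif(1, 0, 80), y1 = runif(1, 0, 80),
            y2 = runif(1, 0, 80))
        }
        list(freq = freq, red = red)
      })
      pre <- make_condition_coupling("preop", base_strength,
                                     seed = fan_seed(pseed, 101),
                                     jitter_sd = jitter_sd)
      target <- make_condition_coupling(
        if (good) "postop_good" else "postop_bad", base_strength,
        seed = fan_seed(pseed, 102), jitter_sd = jitter_sd)
      frac <- if (good) c(preop = 0, m3 = 1 / 3, y1 = 2 / 3, y2 = 1) else
        c(preop = 0, m3 = 1, y1 = 1, y2 = 1)
      sessions <- list()
      for (si in seq_along(session_labels())) {
        s <- session_labels()[si]
        C <- (1 - frac[[s]]) * pre$coupling + frac[[s]] * target$coupling
        m <- coupling_model(C, condition_tag =
                              if (s == "preop") "preop" else target$condition_tag)
        sessions[[s]] <- generate_coupled_epochs(
          m, n_epochs = n_epochs, n_samples = n_samples, fs = fs,
          seed = fan_seed(pseed, 200 + si), montage = mont)
      }
      patients[[pid]] <- list(
        patient_id = sprintf("P%02d", pid), group = g,
        preop_seizure_freq = clin$freq, reductions = clin$red,
        sessions = sessions)
    }
  }
  structure(list(patients = patients, montage = mont,
                 config = list(n_per_group = n_per_group, seed = seed,
                               n_epochs = n_epochs, n_samples = n_samples,
                               fs = fs, base_strength = base_strength,
                               freq_cutoff = freq_cutoff,
                               jitter_sd = jitter_sd)),
            class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("<cc_cohort> %d patients x %d sessions (%d epochs each)\n",
              length(x$patients), length(session_labels()),
              x$config$n_epochs))
  print(table(vapply(x$patients, `[[`, character(1), "group")))
  invisible(x)
}

#' Cohort clinical metadata table
#'
#' @param cohort a `cc_cohort`.
#' @return data.frame with one row per patient: id, group, pre-operative
#'   seizure frequency and percent reductions at each follow-up.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, group = p$group,
               preop_seizure_freq = p$preop_seizure_freq,
               reduction_m3 = p$reductions[["m3"]],
               reduction_y1 = p$reductions[["y1"]],
               reduction_y2 = p$reductions[["y2"]],
               stringsAsFactors = FALSE)
  }))
}
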