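#' Compute adjacency matrices for every patient-session
#'
#' Runs [epoch_adjacency()] over a cohort with seeds fanned out per
#' patient-session from `seed`, so any patient can be recomputed in
#' isolation and bit-identically.
#'
#' @param cohort a `cc_cohort`.
#' @param n_surrogates,alpha,n_bins,mode passed to [epoch_adjacency()].
#' @param seed master seed.
#' @return nested list `adj[[patient_id]][[session]]` of adjacency matrices.
#' @export
cohort_adjacency <- function(cohort, n_surrogates = 1000, alpha = 0.05,
                             n_bins = 8, seed = 1, mode = "threshold") {
  out <- list()
  for (pi in seq_along(cohort$patients)) {
    p <- cohort$patients[[pi]]
    out[[p$patient_id]] <- lapply(seq_along(session_labels()), function(si) {
      s <- session_labels()[si]
      epoch_adjacency(p$sessions[[s]], n_surrogates = n_surrogates,
                      alpha = alpha, n_bins = n_bins,
                      seed = fan_seed(seed, pi, si), mode = mode,
                      session = s)
    })
    names(out[[p$patient_id]]) <- session_labels()
  }
  out
}

#' Tidy network metrics for a cohort
#'
#' Per patient-session: node-level betweenness and local clustering, their
#' channel means, and the null-normalized global metrics (CPL, GCC,
#' small-worldness).
#'
#' @param cohort a `cc_cohort` (for group/clinical metadata).
#' @param adj output of [cohort_adjacency()].
#' @param n_random random-reference ensemble size per network.
#' @param seed master seed for the reference ensembles.
#' @return list with `global` (one row per patient-session) and `nodes`
#'   (one row per patient-session-channel) data.frames.
#' @export
cohort_metrics <- function(cohort, adj, n_random = 100, seed = 1) {
  gl <- list(); nd <- list()
  for (pi in seq_along(cohort$patients)) {
    p <- cohort$patients[[pi]]
    for (si in seq_along(session_labels())) {
      s <- session_labels()[si]
      a <- adj[[p$patient_id]][[s]]
      bc <- weighted_betweenness(a)
      lcc <- local_clustering(a)
      gm <- suppressWarnings(
        global_metrics(a, n_random = n_random, seed = fan_seed(seed, pi, si)))
      gl[[length(gl) + 1]] <- data.frame(
        patient_id = p$patient_id, group = p$group, session = s,
        bc_mean = mean(bc), lcc_mean = mean(lcc),
        cpl_raw = gm$cpl_raw, gcc_raw = gm$gcc_raw,
        cpl_norm = gm$cpl_norm, gcc_norm = gm$gcc_norm,
        small_worldness = gm$small_worldness, stringsAsFactors = FALSE)
      nd[[length(nd) + 1]] <- data.frame(
        patient_id = p$patient_id, group = p$group, session = s,
        channel = names(bc), bc = as.numeric(bc), lcc = as.numeric(lcc),
        stringsAsFactors = FALSE)
    }
  }
  list(global = do.call(rbind, gl), nodes = do.call(rbind, nd))
}

#' Group-average adjacency for one session
#'
#' @param adj output of [cohort_adjacency()].
#' @param cohort the cohort.
#' @param groups group labels to pool (e.g. the combined good groups).
#' @param session session label.
#' @return group-level [adjacency_matrix()].
#' @export
group_session_adjacency <- function(adj, cohort, groups, session) {
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  grp <- vapply(cohort$patients, `[[`, character(1), "group")
  keep <- ids[grp %in% groups]
  if (!length(keep)) stop_arg("no patients in groups: ",
                              paste(groups, collapse = ", "))
  group_adjacency(lapply(keep, function(id) adj[[id]][[session]]))
}

#' Longitudinal outcome-group report
#'
#' The statistical battery over a cohort's metric table: per group and metric,
#' session means with standard errors and a repeated-measures ANOVA with
#' Bonferroni post-hocs; small-worldness additionally tested on the combined
#' good-outcome groups (I + II); and Levene homogeneity tests comparing the
#' channel-wise dispersion of the node metrics between pre-operation and
#' three months post-operation per group.
#'
#' @param metrics output of [cohort_metrics()].
#' @param alpha significance level (default 0.05).
#' @param metric_cols global metric columns to analyse.
#' @return list of class `cc_report`: `trajectories`, `anova`, `levene`
#'   data.frames and `combined_good_sw` (an `rm_anova`).
#' @export
longitudinal_report <- function(metrics, alpha = 0.05,
                                metric_cols = c("bc_mean", "lcc_mean",
                                                "cpl_norm", "gcc_norm",
                                                "small_worldness")) {
  gdf <- metrics$global
  sessions <- session_labels()
  traj <- list(); anov <- list()
  for (g in cohort_groups()) {
    sub <- gdf[gdf$group == g, , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty group omitted from report: ", g)
      next
    }
    for (m in metric_cols) {
      for (s in sessions) {
        v <- sub[sub$session == s, m]
        traj[[length(traj) + 1]] <- data.frame(
          group = g, metric = m, session = s, mean = mean(v),
          se = sd(v) / sqrt(length(v)), n = length(v),
          stringsAsFactors = FALSE)
      }
      wide <- vapply(sessions, function(s) sub[sub$session == s, m],
                     numeric(length(unique(sub$patient_id))))
      wide <- matrix(wide, ncol = length(sessions),
                     dimnames = list(NULL, sessions))
      if (nrow(wide) < 2) {
        warning("group ", g, " has a single patient: ANOVA skipped")
        anov[[length(anov) + 1]] <- data.frame(
          group = g, metric = m, F = NA_real_, df_num = NA_integer_,
          df_den = NA_integer_, p = NA_real_, significant_pairs = "",
          stringsAsFactors = FALSE)
        next
      }
      res <- rm_anova(wide, alpha = alpha)
      anov[[length(anov) + 1]] <- data.frame(
        group = g, metric = m, F = res$F, df_num = res$df_num,
        df_den = res$df_den, p = res$p,
        significant_pairs = if (is.null(res$posthoc)) "" else
          paste(res$posthoc$pair[res$posthoc$p_corrected < alpha],
                collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  good <- gdf[gdf$group %in% c("I_HighGood", "II_LowGood"), ]
  combined <- if (length(unique(good$patient_id)) >= 2) {
    rm_anova(sapply(sessions,
                    function(s) good[good$session == s, "small_worldness"]),
             alpha = alpha)
  } else NULL

  lev <- list()
  ndf <- metrics$nodes
  for (g in intersect(cohort_groups(), unique(ndf$group))) {
    for (m in c("bc", "lcc")) {
      # channel-wise group means at each state: dispersion across the scalp
      pre <- tapply(ndf[ndf$group == g & ndf$session == "preop", m],
                    ndf$channel[ndf$group == g & ndf$session == "preop"], mean)
      m3 <- tapply(ndf[ndf$group == g & ndf$session == "m3", m],
                   ndf$channel[ndf$group == g & ndf$session == "m3"], mean)
      lt <- suppressWarnings(levene_test(as.numeric(pre), as.numeric(m3)))
      lev[[length(lev) + 1]] <- data.frame(
        group = g, metric = m, W = lt$W, p = lt$p, stringsAsFactors = FALSE)
    }
  }
  structure(list(trajectories = do.call(rbind, traj),
                 anova = do.call(rbind, anov),
                 levene = do.call(rbind, lev),
                 combined_good_sw = combined, alpha = alpha),
            class = "cc_report")
}

#' @export
print.cc_report <- function(x, ...) {
  cat("<cc_report>\n")
  cat("Repeated-measures ANOVA by group and metric:\n")
  print(x$anova, row.names = FALSE, digits = 4)
  if (!is.null(x$combined_good_sw)) {
    cat("\nCombined good groups (I+II), small-worldness:\n")
    print(x$combined_good_sw)
  }
  cat("\nLevene homogeneity (preop vs m3, channel-wise):\n")
  print(x$levene, row.names = FALSE, digits = 4)
  invisible(x)
}
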