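#' Run the full psychometric analysis pipeline
#'
#' Exclusions -> imputation -> participant scoring -> permutation split-half
#' reliabilities -> observed and disattenuated correlation matrix (whole
#' sample and per ability cluster) -> k-means ability clustering -> group
#' descriptives -> one-sample tests of pointing against the 90-degree
#' chance level and of efficiency against the learned-route efficiency.
#'
#' @param pointing_I,pointing_II Pointing trial tables for the two phases
#'   (`pointing_II` may be `NULL`).
#' @param shortcut Shortcutting trial table.
#' @param learned_route_eff Imputation/reference constant (> 1), e.g. 2.54
#'   or a maze-derived [learned_route_efficiency()].
#' @param n_permutations Permutations per reliability estimate.
#' @param seed Seed for reliability permutations and clustering.
#' @param participant_fail_max,trial_fail_max Exclusion thresholds, see
#'   [apply_exclusions()].
#' @param k_candidates Candidate cluster counts.
#' @param matching_pairs_only Restrict pointing trials to pairs shared with
#'   the shortcutting task (see [score_participants()]).
#' @return A list of class `study_report`: `exclusions`, `scores`,
#'   `reliability` (named estimates), `correlations` (matrix + reports),
#'   `clusters`, `group_correlations` (per-group matrices),
#'   `group_descriptives`, `tests` (one-sample results), `flags`
#'   (disattenuated values beyond 1), `config` echo.
#' @export
analyze_study <- function(pointing_I, pointing_II = NULL, shortcut,
                          learned_route_eff,
                          n_permutations = 1000, seed = 1L,
                          participant_fail_max = 0.30, trial_fail_max = 0.30,
                          k_candidates = 2:6, matching_pairs_only = FALSE) {
  pointing <- rbind(pointing_I, pointing_II)
  excl <- apply_exclusions(pointing, shortcut,
                           participant_fail_max, trial_fail_max)
  eff_trials <- impute_failed(excl$shortcut, learned_route_eff)
  scores <- score_participants(excl$pointing, eff_trials,
                               matching_pairs_only = matching_pairs_only)

  mats <- list(
    pointing_error_I = trial_matrix(excl$pointing, "pointing", phase = "I"),
    efficiency = trial_matrix(eff_trials, "efficiency")
  )
  if (any(excl$pointing$phase == "II")) {
    mats$pointing_error_II <- trial_matrix(excl$pointing, "pointing", phase = "II")
  }
  rel <- lapply(names(mats), function(nm) {
    permutation_split_half(mats[[nm]], n_permutations, seed = seed, measure = nm)
  })
  names(rel) <- names(mats)
  rel_vec <- vapply(rel, `[[`, numeric(1), "estimate")

  measures <- intersect(c("efficiency", "pointing_error_I", "pointing_error_II"),
                        names(rel_vec))
  cors <- tryCatch(
    correlation_matrix(scores[measures], rel_vec[measures]),
    error = function(e) {
      warning("correlations skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })

  clusters <- tryCatch(
    cluster_participants(scores, k_candidates = k_candidates, seed = seed),
    error = function(e) {
      warning("clustering skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })

  group_cors <- NULL
  group_desc <- NULL
  try_test <- function(values, mu0) {
    tryCatch(one_sample_test(values = values[is.finite(values)], mu0 = mu0),
             error = function(e) {
               warning("one-sample test skipped: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  }
  tests <- list(
    pointing_I_vs_chance = try_test(scores$pointing_error_I, 90),
    efficiency_vs_learned_route = try_test(scores$efficiency, learned_route_eff)
  )
  if (!is.null(clusters)) {
    grp <- stats::setNames(clusters$assignment$group,
                           clusters$assignment$participant_id)
    group_cors <- list()
    for (g in unique(grp)) {
      ids <- names(grp)[grp == g]
      gm <- lapply(mats, function(m) m[rownames(m) %in% ids, , drop = FALSE])
      grel <- vapply(names(gm), function(nm) {
        if (nrow(gm[[nm]]) < 5) return(NA_real_)
        permutation_split_half(gm[[nm]], n_permutations, seed = seed,
                               measure = nm)$estimate
      }, numeric(1))
      gs <- scores[scores$participant_id %in% ids, , drop = FALSE]
      group_cors[[g]] <- tryCatch(
        correlation_matrix(gs[measures], grel[measures]),
        error = function(e) NULL)
      tests[[paste0(g, "_pointing_I_vs_chance")]] <-
        try_test(gs$pointing_error_I, 90)
      tests[[paste0(g, "_efficiency_vs_learned_route")]] <-
        try_test(gs$efficiency, learned_route_eff)
    }
    group_desc <- suppressWarnings(
      group_descriptives(scores, clusters$assignment, mats,
                         n_permutations = n_permutations, seed = seed))
  }

  flags <- if (is.null(cors)) character(0) else {
    names(Filter(function(r) isTRUE(r$flagged), attr(cors, "reports")))
  }

  structure(list(
    exclusions = excl$log,
    scores = scores,
    reliability = rel,
    correlations = cors,
    clusters = clusters,
    group_correlations = group_cors,
    group_descriptives = group_desc,
    tests = tests,
    flags = flags,
    config = list(learned_route_eff = learned_route_eff,
                  n_permutations = n_permutations, seed = seed,
                  participant_fail_max = participant_fail_max,
                  trial_fail_max = trial_fail_max,
                  matching_pairs_only = matching_pairs_only)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d participants scored, %d exclusions\n",
              nrow(x$scores), nrow(x$exclusions)))
  cat("reliabilities:",
      paste(sprintf("%s = %.2f", names(x$reliability),
                    vapply(x$reliability, `[[`, numeric(1), "estimate")),
            collapse = ", "), "\n")
  if (!is.null(x$clusters)) {
    cat(sprintf("clusters: k = %d\n", x$clusters$chosen_k))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV tables (scores, exclusions, correlation matrices, group
#' descriptives, cluster assignment) plus a JSON summary of reliabilities,
#' tests, flags and configuration.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(report$correlations)) {
    utils::write.csv(as.data.frame(report$correlations),
                     file.path(dir, "correlation_matrix.csv"))
  }
  if (!is.null(report$group_descriptives)) {
    utils::write.csv(report$group_descriptives,
                     file.path(dir, "group_descriptives.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$clusters)) {
    utils::write.csv(report$clusters$assignment,
                     file.path(dir, "cluster_assignment.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    reliability = lapply(report$reliability, unclass),
    tests = lapply(report$tests, unclass),
    flags = report$flags,
    config = report$config
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Recompute inferential statistics from printed summary tables
#'
#' Replays published summary statistics without raw data: rows with
#' `(label, mean, sd, n, mu0)` are run through [one_sample_test()]; rows
#' with `(label, r_obs, r_xx, r_yy)` through [disattenuate()] (and, when an
#' `n` column is present, [correlation_test()]).
#'
#' @param moments Data.frame with columns `label`, `mean`, `sd`, `n`,
#'   `mu0`, or `NULL`.
#' @param correlations Data.frame with columns `label`, `r_obs`, `r_xx`,
#'   `r_yy` (optionally `n`), or `NULL`.
#' @return A data.frame with one row per input row: the recomputed `t`,
#'   `df`, `p`, `cohen_d`, `ci_lo`, `ci_hi` or `r_disattenuated`.
#' @export
replay_printed <- function(moments = NULL, correlations = NULL) {
  out <- list()
  if (!is.null(moments) && nrow(moments)) {
    check_cols(moments, c("label", "mean", "sd", "n", "mu0"), "moments")
    for (i in seq_len(nrow(moments))) {
      r <- tryCatch(
        one_sample_test(mean = moments$mean[i], sd = moments$sd[i],
                        n = moments$n[i], mu0 = moments$mu0[i]),
        error = function(e) stop("moments row ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        label = moments$label[i], kind = "one_sample",
        t = r$t, df = r$df, p = r$p, cohen_d = r$cohen_d,
        ci_lo = r$ci95[1], ci_hi = r$ci95[2],
        r_disattenuated = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(correlations) && nrow(correlations)) {
    check_cols(correlations, c("label", "r_obs", "r_xx", "r_yy"),
               "correlations")
    for (i in seq_len(nrow(correlations))) {
      rd <- tryCatch(
        suppressWarnings(disattenuate(correlations$r_obs[i],
                                      correlations$r_xx[i],
                                      correlations$r_yy[i])),
        error = function(e) stop("correlations row ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
      row <- data.frame(
        label = correlations$label[i], kind = "disattenuation",
        t = NA_real_, df = NA_real_, p = NA_real_, cohen_d = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_,
        r_disattenuated = as.numeric(rd), stringsAsFactors = FALSE)
      if ("n" %in% names(correlations) && is.finite(correlations$n[i])) {
        ct <- correlation_test(correlations$r_obs[i], correlations$n[i])
        row$t <- ct$t; row$df <- ct$df; row$p <- ct$p
        row$ci_lo <- ct$ci95[1]; row$ci_hi <- ct$ci95[2]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    return(data.frame(label = character(0), kind = character(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      cohen_d = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), r_disattenuated = numeric(0)))
  }
  do.call(rbind, out)
}
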