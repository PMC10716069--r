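#' Cluster participants into ability groups
#'
#' k-means on the three participant-level measures (travel efficiency and
#' Phase I / Phase II pointing errors), z-scored per measure so the
#' incommensurate scales (ratio vs. degrees) carry equal weight. Each
#' candidate number of clusters is fit with the best of `n_init` random
#' initializations; the chosen k maximizes the mean silhouette width, and
#' the within-cluster sum of squares (inertia) curve is reported for elbow
#' inspection. Clusters whose mean Phase I pointing error is above the
#' grand mean of cluster centers are labeled `"low"` (spatial ability),
#' the rest `"high"`; ties are broken by efficiency.
#'
#' @param scores Participant scores (see [score_participants()]); rows with
#'   a missing measure are not clustered.
#' @param k_candidates Candidate cluster counts (default 2:6).
#' @param seed Optional seed; fixes the initializations.
#' @param n_init Random initializations per candidate k (default 50).
#' @return An object of class `group_assignment`: `assignment` (data.frame
#'   `participant_id`, `cluster`, `group`), `chosen_k`, `inertia` and
#'   `silhouette` (named by k), `centers` (on the original scale), `seed`.
#' @export
cluster_participants <- function(scores, k_candidates = 2:6, seed = NULL,
                                 n_init = 50) {
  feats <- c("efficiency", "pointing_error_I", "pointing_error_II")
  stopifnot(all(feats %in% names(scores)))
  ok <- stats::complete.cases(scores[feats])
  x <- scores[ok, , drop = FALSE]
  k_candidates <- k_candidates[k_candidates >= 2 & k_candidates <= nrow(x) - 1]
  if (!length(k_candidates) || nrow(x) < 3) {
    stop("too few fully-scored participants to cluster", call. = FALSE)
  }
  z <- scale(as.matrix(x[feats]))
  if (!is.null(seed)) set.seed(seed)

  d <- stats::dist(z)
  fits <- list(); inertia <- sil <- numeric(0)
  for (k in k_candidates) {
    km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
    fits[[as.character(k)]] <- km
    inertia[as.character(k)] <- km$tot.withinss
    sil[as.character(k)] <-
      mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  chosen_k <- k_candidates[which.max(sil)]
  km <- fits[[as.character(chosen_k)]]

  # de-standardize centers for reporting
  centers <- sweep(sweep(km$centers, 2, attr(z, "scaled:scale"), "*"),
                   2, attr(z, "scaled:center"), "+")
  mean_err <- centers[, "pointing_error_I"]
  thr <- mean(mean_err)
  low <- mean_err > thr | (mean_err == thr & centers[, "efficiency"] > mean(centers[, "efficiency"]))
  group <- ifelse(low[km$cluster], "low", "high")

  structure(list(
    assignment = data.frame(participant_id = x$participant_id,
                            cluster = km$cluster, group = group,
                            stringsAsFactors = FALSE),
    chosen_k = chosen_k,
    inertia = inertia,
    silhouette = sil,
    centers = centers,
    seed = seed
  ), class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment: k = %d (silhouette %.3f); %s\n",
              x$chosen_k, max(x$silhouette),
              paste(sprintf("%s: %d", names(table(x$assignment$group)),
                            table(x$assignment$group)), collapse = ", ")))
  invisible(x)
}

#' Descriptive statistics and internal consistency per group
#'
#' For each group and measure: mean, SD (n-1), min, max, adjusted
#' Fisher-Pearson sample skewness, excess kurtosis, trial count, and the
#' permutation split-half reliability computed on that group's rows of the
#' trial matrix. Skewness and kurtosis are reported absent for constant
#' scores; reliability is omitted (with a warning) for groups smaller
#' than 5.
#'
#' @param scores Participant scores.
#' @param groups Named character vector or data.frame (`participant_id`,
#'   `group`) assigning each participant to a group.
#' @param trial_matrices Named list of trial matrices (participant rownames)
#'   keyed by measure name; measure names must match columns of `scores`.
#' @param n_permutations,seed Passed to [permutation_split_half()].
#' @return A data.frame, one row per group x measure.
#' @export
group_descriptives <- function(scores, groups, trial_matrices,
                               n_permutations = 5000, seed = NULL) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$participant_id)
  }
  measures <- names(trial_matrices)
  stopifnot(all(measures %in% names(scores)))
  out <- list()
  for (g in unique(groups)) {
    ids <- names(groups)[groups == g]
    if (!length(ids)) stop("empty group '", g, "'", call. = FALSE)
    for (mname in measures) {
      v <- scores[[mname]][match(ids, scores$participant_id)]
      v <- v[is.finite(v)]
      m <- trial_matrices[[mname]]
      m <- m[rownames(m) %in% ids, , drop = FALSE]
      rel <- NA_real_
      if (nrow(m) < 5) {
        warning("group '", g, "' too small for a reliability estimate of ",
                mname, call. = FALSE)
      } else {
        rel <- permutation_split_half(m, n_permutations, seed = seed,
                                      measure = mname)$estimate
      }
      const <- stats::sd(v) == 0
      out[[length(out) + 1L]] <- data.frame(
        group = g, measure = mname, n = length(v),
        mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
        skewness = if (const) NA_real_ else e1071::skewness(v, type = 2),
        kurtosis = if (const) NA_real_ else e1071::kurtosis(v, type = 2),
        n_trials = ncol(m), reliability = rel,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' One-sample t test with effect size
#'
#' Tests a sample mean against a reference value `mu0`:
#' `t = (mean - mu0) / (sd / sqrt(n))` on `n - 1` df, two-sided, with
#' Cohen's `d = (mean - mu0) / sd` and the t-based 95% CI of the mean.
#' Accepts either raw values or summary statistics, so printed tables can
#' be replayed without the underlying data; both routes agree exactly.
#'
#' @param values Numeric vector of raw observations (or `NULL` when using
#'   summaries).
#' @param mean,sd,n Summary statistics, used when `values` is `NULL`.
#' @param mu0 Reference value: 90 (degrees) for chance-level pointing,
#'   or the learned-route efficiency for the shortcutting measure.
#' @param conf.level Confidence level of the CI (default 0.95).
#' @return An object of class `one_sample_result`: `t`, `df`, `p`,
#'   `cohen_d`, `ci95`, `mean`, `sd`, `n`, `mu0`.
#' @examples
#' one_sample_test(mean = 73.71, sd = 23.22, n = 57, mu0 = 90)
#' @export
one_sample_test <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                            mu0, conf.level = 0.95) {
  if (!is.null(values)) {
    stopifnot(all(is.finite(values)), length(values) >= 2)
    n <- length(values)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n), n >= 2)
  if (sd <= 0) stop("one-sample test undefined for sd = 0", call. = FALSE)
  se <- sd / sqrt(n)
  t <- (mean - mu0) / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  tc <- stats::qt(1 - (1 - conf.level) / 2, df)
  structure(list(
    t = t, df = df, p = p,
    cohen_d = (mean - mu0) / sd,
    ci95 = c(mean - tc * se, mean + tc * se),
    mean = mean, sd = sd, n = as.integer(n), mu0 = mu0
  ), class = "one_sample_result")
}

#' @export
print.one_sample_result <- function(x, ...) {
  cat(sprintf("one-sample t(%d) = %.2f, p = %.3g, d = %.2f, 95%% CI [%.2f, %.2f] (mean %.2f vs %.2f)\n",
              x$df, x$t, x$p, x$cohen_d, x$ci95[1], x$ci95[2], x$mean, x$mu0))
  invisible(x)
}
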