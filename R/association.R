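#' Sample Pearson correlation with input checks
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, each with
#'   nonzero variance.
#' @return The sample Pearson correlation.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a zero-variance vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correction for attenuation
#'
#' Estimates the correlation between true scores from an observed
#' correlation and the two measures' reliabilities:
#' `r_disattenuated = r_observed / sqrt(r_xx * r_yy)`.
#' With imperfect reliabilities the observed correlation understates the
#' latent one; dividing by the geometric mean of the reliabilities undoes
#' that attenuation. Values with magnitude above 1 — possible when sampling
#' error or underestimated reliabilities push the ratio past the admissible
#' range — are returned unclamped with a warning and a `flagged` attribute,
#' so estimator pathology stays visible.
#'
#' @param r_observed Observed correlation between the two measures.
#' @param r_xx,r_yy Reliabilities (internal consistencies) of the two
#'   measures; must be positive.
#' @return The disattenuated correlation (attribute `flagged` if `|.| > 1`).
#' @examples
#' disattenuate(0.71, 0.83, 0.72) # ~0.92
#' @export
disattenuate <- function(r_observed, r_xx, r_yy) {
  stopifnot(is.finite(r_observed), abs(r_observed) <= 1)
  if (!is.finite(r_xx) || !is.finite(r_yy) || r_xx <= 0 || r_yy <= 0) {
    stop("reliabilities must be positive", call. = FALSE)
  }
  out <- r_observed / sqrt(r_xx * r_yy)
  if (abs(out) > 1) {
    warning(sprintf("disattenuated correlation %.3f exceeds 1 in magnitude", out),
            call. = FALSE)
    attr(out, "flagged") <- TRUE
  }
  out
}

#' Inference for a single Pearson correlation
#'
#' t test of `H0: rho = 0` (`t = r sqrt((n-2)/(1-r^2))` on `n - 2` df,
#' two-sided) and a confidence interval from the Fisher z transform,
#' `tanh(atanh(r) +/- z_{1-alpha/2} / sqrt(n-3))`.
#'
#' @param r Observed correlation.
#' @param n Number of participants (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list: `r`, `n`, `t`, `df`, `p`, `ci95` (length-2). `|r| = 1`
#'   yields infinite `t` and `p = 0`.
#' @export
correlation_test <- function(r, n, alpha = 0.05) {
  stopifnot(is.finite(r), abs(r) <= 1, n >= 4)
  df <- n - 2
  if (abs(r) == 1) {
    t <- sign(r) * Inf; p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  zc <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) + c(-1, 1) * zc / sqrt(n - 3))
  list(r = r, n = n, t = t, df = df, p = p, ci95 = ci)
}

shrink_r <- function(r, limit = 0.999) {
  if (abs(r) >= 1) {
    warning(sprintf("correlation %.3f shrunk to %s for Fisher-z machinery",
                    r, sign(r) * limit), call. = FALSE)
    r <- sign(r) * limit
  }
  r
}

#' Compare two independent correlations
#'
#' Fisher z test,
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided, and
#' Zou's confidence interval for `r1 - r2` assembled from the two individual
#' Fisher-z intervals: with `(l_i, u_i)` the interval for `r_i`,
#' `L = r1 - r2 - sqrt((r1 - l1)^2 + (u2 - r2)^2)` and
#' `U = r1 - r2 + sqrt((u1 - r1)^2 + (r2 - l2)^2)`.
#' Inputs at or beyond |r| = 1 (disattenuated estimates can exceed 1) are
#' shrunk to +/-0.999 with a warning before transformation.
#'
#' @param r1,n1 Correlation and sample size of group 1.
#' @param r2,n2 Correlation and sample size of group 2.
#' @param alpha Two-sided level (default 0.05).
#' @return An object of class `correlation_comparison`: `r1`, `n1`, `r2`,
#'   `n2`, `fisher_z`, `p`, `zou_ci95`.
#' @export
compare_correlations <- function(r1, n1, r2, n2, alpha = 0.05) {
  stopifnot(n1 >= 4, n2 >= 4)
  r1 <- shrink_r(r1); r2 <- shrink_r(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  p <- 2 * stats::pnorm(-abs(z))
  ci1 <- correlation_test(r1, n1, alpha)$ci95
  ci2 <- correlation_test(r2, n2, alpha)$ci95
  L <- r1 - r2 - sqrt((r1 - ci1[1])^2 + (ci2[2] - r2)^2)
  U <- r1 - r2 + sqrt((ci1[2] - r1)^2 + (r2 - ci2[1])^2)
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 fisher_z = z, p = p, zou_ci95 = c(L, U)),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): Fisher z = %.2f, p = %.3g, Zou 95%% CI [%.2f, %.2f]\n",
              x$r1, x$n1, x$r2, x$n2, x$fisher_z, x$p,
              x$zou_ci95[1], x$zou_ci95[2]))
  invisible(x)
}

#' Power of the two-sided Pearson correlation test
#'
#' Fisher-z normal approximation: with `m = sqrt(n - 3) atanh(rho)` the
#' power is `P(|Z| > z_{1-alpha/2})` for `Z ~ N(m, 1)`, i.e.
#' `Phi(m - z) + Phi(-m - z)`. At `rho = 0` this reduces to `alpha`.
#'
#' @param n Sample size (>= 4).
#' @param rho Population correlation, `|rho| < 1`.
#' @param alpha Two-sided level (default 0.05).
#' @return Power in [0, 1].
#' @examples
#' power_correlation(48, 0.4) # about 0.81
#' @export
power_correlation <- function(n, rho, alpha = 0.05) {
  stopifnot(n >= 4, abs(rho) < 1)
  zc <- stats::qnorm(1 - alpha / 2)
  m <- sqrt(n - 3) * atanh(rho)
  stats::pnorm(m - zc) + stats::pnorm(-m - zc)
}

#' Full correlation report for a pair of measures
#'
#' Observed Pearson correlation with its t test and Fisher-z interval, plus
#' the disattenuated correlation given the two measures' reliabilities.
#'
#' @param x,y Participant-level score vectors (pairwise-complete rows are
#'   used).
#' @param r_xx,r_yy Reliabilities of the two measures.
#' @param names Length-2 character vector naming the measures.
#' @param alpha Two-sided level.
#' @return An object of class `correlation_report`.
#' @export
correlation_report <- function(x, y, r_xx, r_yy,
                               names = c("x", "y"), alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  r <- pearson_r(x, y)
  test <- correlation_test(r, length(x), alpha)
  # a non-positive reliability estimate leaves no admissible correction
  rd <- if (is.finite(r_xx) && is.finite(r_yy) && r_xx > 0 && r_yy > 0) {
    suppressWarnings(disattenuate(r, r_xx, r_yy))
  } else {
    structure(NA_real_, flagged = TRUE)
  }
  structure(list(
    measures = names, r_observed = r, n = length(x),
    t = test$t, df = test$df, p = test$p, ci95 = test$ci95,
    r_xx = r_xx, r_yy = r_yy,
    r_disattenuated = as.numeric(rd),
    flagged = isTRUE(attr(rd, "flagged"))
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("%s ~ %s: r(%d) = %.2f, t = %.2f, p = %.3g, 95%% CI [%.2f, %.2f]; r_xx = %.2f, r_yy = %.2f, disattenuated r = %.2f%s\n",
              x$measures[1], x$measures[2], x$df, x$r_observed, x$t, x$p,
              x$ci95[1], x$ci95[2], x$r_xx, x$r_yy, x$r_disattenuated,
              if (x$flagged) " [>1, flagged]" else ""))
  invisible(x)
}

#' Observed/disattenuated correlation matrix over several measures
#'
#' Square matrix with observed correlations below the diagonal and
#' disattenuated correlations above it — the conventional compact layout
#' for reporting both at once.
#'
#' @param scores Data.frame of participant-level scores (one column per
#'   measure).
#' @param reliabilities Named numeric vector of reliabilities, one per
#'   column of `scores`.
#' @return A numeric matrix with `NA` diagonal and attribute `reports`, the
#'   list of pairwise [correlation_report()] objects.
#' @export
correlation_matrix <- function(scores, reliabilities) {
  stopifnot(is.data.frame(scores), ncol(scores) >= 2,
            all(names(scores) %in% names(reliabilities)))
  p <- ncol(scores)
  out <- matrix(NA_real_, p, p, dimnames = list(names(scores), names(scores)))
  reports <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ni <- names(scores)[i]; nj <- names(scores)[j]
    rep_ij <- correlation_report(scores[[i]], scores[[j]],
                                 reliabilities[[ni]], reliabilities[[nj]],
                                 names = c(ni, nj))
    out[j, i] <- rep_ij$r_observed      # below diagonal: observed
    out[i, j] <- rep_ij$r_disattenuated # above diagonal: disattenuated
    reports[[paste(ni, nj, sep = "~")]] <- rep_ij
  }
  attr(out, "reports") <- reports
  out
}
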