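#' Spearman-Brown step-up correction
#'
#' Projects a half-test correlation to full test length:
#' `2 r / (1 + r)`. Strictly increasing on (-1, 1].
#'
#' @param r_half Correlation between two test halves, in (-1, 1].
#' @return Corrected correlation. Vectorized.
#' @export
spearman_brown <- function(r_half) {
  stopifnot(all(is.finite(r_half)), all(r_half <= 1))
  if (any(r_half == -1)) {
    stop("Spearman-Brown correction is undefined at r = -1", call. = FALSE)
  }
  2 * r_half / (1 + r_half)
}

check_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2) stop("trial matrix needs at least 2 columns", call. = FALSE)
  m
}

#' Split-half correlation for one explicit partition
#'
#' Splits the trial columns into the two given halves, averages each
#' participant's observed cells within each half, correlates the two
#' half-means across participants (Pearson) and applies the Spearman-Brown
#' correction. Participants with no observed cell in either half are dropped
#' for this split.
#'
#' @param m Trial matrix (participants x trials; `NA` = missing cell).
#' @param half1,half2 Column indices forming a disjoint cover of the columns
#'   with sizes differing by at most 1.
#' @return Corrected correlation, with attribute `n_dropped` (participants
#'   without cells in some half).
#' @export
split_half_once <- function(m, half1, half2) {
  check_matrix(m)
  half1 <- as.integer(half1); half2 <- as.integer(half2)
  k <- ncol(m)
  if (length(intersect(half1, half2)) ||
      !setequal(c(half1, half2), seq_len(k)) ||
      abs(length(half1) - length(half2)) > 1) {
    stop("halves must disjointly cover all columns with sizes differing by <= 1",
         call. = FALSE)
  }
  m1 <- rowMeans(m[, half1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(m[, half2, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(m1) & is.finite(m2)
  r <- stats::cor(m1[ok], m2[ok])
  out <- spearman_brown(r)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

# All B random half-partitions at once, complete-data fast path:
# half means are X %*% W for 0/1 weight matrices, correlations column-wise.
split_half_batch <- function(m, B, rng = NULL) {
  n <- nrow(m); k <- ncol(m)
  h <- k %/% 2L
  W1 <- matrix(0, k, B); W2 <- matrix(0, k, B)
  for (b in seq_len(B)) {
    perm <- sample.int(k)
    size1 <- if (k %% 2L == 0L) h else h + sample.int(2L, 1L) - 1L
    W1[perm[seq_len(size1)], b] <- 1 / size1
    W2[perm[(size1 + 1L):k], b] <- 1 / (k - size1)
  }
  M1 <- m %*% W1
  M2 <- m %*% W2
  C1 <- sweep(M1, 2, colMeans(M1))
  C2 <- sweep(M2, 2, colMeans(M2))
  colSums(C1 * C2) / sqrt(colSums(C1^2) * colSums(C2^2))
}

#' Permutation-based split-half internal consistency
#'
#' Estimates a measure's internal consistency by repeatedly splitting its
#' trials into two random halves, correlating participants' half-means and
#' applying the Spearman-Brown correction; the estimate is the arithmetic
#' mean of the corrected correlations over permutations. For an odd number
#' of trials the larger half falls on either side uniformly at random each
#' permutation. Individual split correlations are not clamped; an estimate
#' outside [0, 1] is reported as-is and flagged.
#'
#' @param m Trial matrix (participants x trials), e.g. from
#'   [trial_matrix()]. At least 4 columns and 5 rows are required for a
#'   stable estimate.
#' @param n_permutations Number of random half-partitions (default 5000).
#' @param seed Optional integer seed for reproducibility.
#' @param measure Label carried into the result.
#' @return An object of class `reliability_estimate`: `measure`, `estimate`,
#'   `n_permutations`, `perm_mean`, `perm_sd`, `perm_ci` (2.5/97.5
#'   percentiles of the corrected split correlations), `n_participants`,
#'   `n_trials`, `seed`, `flagged`.
#' @export
permutation_split_half <- function(m, n_permutations = 5000, seed = NULL,
                                   measure = "measure") {
  check_matrix(m)
  stopifnot(n_permutations >= 1)
  if (ncol(m) < 4 || nrow(m) < 5) {
    warning("trial matrix smaller than 5 participants x 4 trials; estimate is unstable",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(n_permutations)
  k <- ncol(m)

  if (!anyNA(m)) {
    r_half <- split_half_batch(m, B)
    rs <- rep(NA_real_, B)
    ok <- is.finite(r_half) & r_half > -1
    rs[ok] <- spearman_brown(r_half[ok])
  } else {
    h <- k %/% 2L
    rs <- vapply(seq_len(B), function(b) {
      perm <- sample.int(k)
      size1 <- if (k %% 2L == 0L) h else h + sample.int(2L, 1L) - 1L
      tryCatch(
        as.numeric(split_half_once(m, perm[seq_len(size1)],
                                   perm[(size1 + 1L):k])),
        error = function(e) NA_real_)
    }, numeric(1))
  }

  n_invalid <- sum(!is.finite(rs))
  if (n_invalid > 0) {
    warning(n_invalid, " of ", B,
            " splits produced no valid correlation and were dropped",
            call. = FALSE)
  }
  est <- if (all(!is.finite(rs))) NA_real_ else mean(rs[is.finite(rs)])
  structure(list(
    measure = measure,
    estimate = est,
    n_permutations = B,
    n_invalid_splits = n_invalid,
    perm_mean = est,
    perm_sd = stats::sd(rs[is.finite(rs)]),
    perm_ci = if (any(is.finite(rs))) {
      unname(stats::quantile(rs[is.finite(rs)], c(0.025, 0.975)))
    } else c(NA_real_, NA_real_),
    n_participants = nrow(m),
    n_trials = k,
    seed = seed,
    flagged = !is.na(est) && (est < 0 || est > 1)
  ), class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("split-half reliability [%s]: %.3f (%d permutations, %d x %d matrix)%s\n",
              x$measure, x$estimate, x$n_permutations, x$n_participants,
              x$n_trials, if (isTRUE(x$flagged)) " [outside 0..1]" else ""))
  invisible(x)
}

#' Read a wide-format trial matrix / write a reliability estimate
#'
#' The wide CSV format has a `participant_id` column followed by one column
#' per trial. The JSON emission mirrors the `reliability_estimate` fields.
#'
#' @param path File path.
#' @return `read_trial_matrix`: a numeric matrix with participant rownames.
#' @export
read_trial_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"participant_id" %in% names(df)) {
    stop("wide trial CSV must have a participant_id column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "participant_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$participant_id)
  m
}

#' @rdname read_trial_matrix
#' @param x A `reliability_estimate`.
#' @export
write_reliability <- function(x, path) {
  stopifnot(inherits(x, "reliability_estimate"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
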