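# Inference chain: Pearson family with Bonferroni-adjusted alpha, skipped
# (robust) Pearson correlation with percentile-bootstrap inference, and
# leave-one-out cross-validation with a permutation null.

check_finite_vector <- function(x, name, min_n = 3L) {
  if (!is.numeric(x) || length(x) < min_n || !all(is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric with at least %d values",
                 name, min_n))
  }
  invisible(x)
}

#' Pearson correlations of several predictors against one outcome
#'
#' Computes, for each named predictor, the Pearson correlation with `y`, its
#' two-tailed t-based p value and Fisher-z confidence interval, and tests it
#' against a Bonferroni-adjusted alpha of `alpha / m` where `m` is the number
#' of predictors (0.05 / 4 = 0.0125 in the canonical four-predictor screen).
#'
#' @param x_by_name Named list of numeric predictor vectors.
#' @param y Numeric outcome vector, same length.
#' @param alpha Family-wise alpha before adjustment (default 0.05).
#' @param conf Confidence level for the per-correlation CI (default 0.95).
#' @return A `data.frame` with one row per predictor: `predictor`, `n`, `r`,
#'   `p`, `ci_lo`, `ci_hi`, `alpha_adjusted`, `significant`.
#' @examples
#' pearson_family(list(a = c(1, 2, 3, 4, 5)), c(2, 1, 4, 3, 5))
#' @export
pearson_family <- function(x_by_name, y, alpha = 0.05, conf = 0.95) {
  if (!is.list(x_by_name) || is.null(names(x_by_name)) ||
      any(names(x_by_name) == "")) {
    stop("x_by_name must be a named list of numeric vectors")
  }
  check_finite_vector(y, "y")
  m <- length(x_by_name)
  alpha_adj <- alpha / m
  rows <- lapply(names(x_by_name), function(nm) {
    x <- x_by_name[[nm]]
    check_finite_vector(x, nm)
    if (length(x) != length(y)) stop(sprintf("'%s' and y differ in length", nm))
    if (stats::var(x) == 0) {
      stop(sprintf("correlation undefined: '%s' has zero variance", nm))
    }
    if (stats::var(y) == 0) {
      stop("correlation undefined: 'y' has zero variance")
    }
    ct <- stats::cor.test(x, y, conf.level = conf)
    data.frame(predictor = nm, n = length(x), r = unname(ct$estimate),
               p = ct$p.value,
               ci_lo = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
               ci_hi = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
               alpha_adjusted = alpha_adj,
               significant = ct$p.value < alpha_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Projection-based bivariate outlier flags (skipped-correlation rule)
#'
#' Finds a robust bivariate center via the minimum covariance determinant
#' (MCD), then, for every data point, projects all points onto the direction
#' from the center to that point and flags points whose projected coordinate
#' violates the MAD-median rule with cutoff `sqrt(qchisq(0.975, 2))`. The
#' outlier set is the union over all projections.
#'
#' @param x,y Numeric vectors (n >= 10).
#' @return Integer vector of flagged indices (possibly empty).
#' @export
skipped_outliers <- function(x, y) {
  check_finite_vector(x, "x", 10L)
  check_finite_vector(y, "y", 10L)
  stopifnot(length(x) == length(y))
  n <- length(x)
  pts <- cbind(x, y)
  # the MCD is undefined on (near-)collinear clouds; fall back to the
  # coordinate-wise median, which is all the projection step needs
  center <- tryCatch(MASS::cov.rob(pts, method = "mcd")$center,
                     error = function(e) apply(pts, 2, stats::median))
  cutoff <- sqrt(stats::qchisq(0.975, df = 2))
  centered <- sweep(pts, 2, center)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    d <- centered[i, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) next
    s <- as.numeric(centered %*% (d / nd))
    med <- stats::median(s)
    madn <- stats::mad(s)   # scaled by 1.4826 (consistent for the Gaussian)
    if (madn == 0) next
    flagged <- flagged | (abs(s - med) / madn > cutoff)
  }
  which(flagged)
}

skipped_r_point <- function(x, y) {
  out <- skipped_outliers(x, y)
  keep <- setdiff(seq_along(x), out)
  if (length(keep) < 3L) stop("degenerate sample: too few points after skipping")
  if (stats::var(x[keep]) == 0 || stats::var(y[keep]) == 0) {
    stop("degenerate sample: zero variance after skipping")
  }
  list(r = stats::cor(x[keep], y[keep]), outliers = out)
}

#' Skipped (robust) Pearson correlation with percentile-bootstrap inference
#'
#' Removes projection-flagged bivariate outliers ([skipped_outliers()]: MCD
#' center, MAD-median rule, union over projections) and computes Pearson's r
#' on the remaining points. Significance and the confidence interval come
#' from a percentile bootstrap of the entire procedure over resampled subject
#' pairs: `ci` holds the empirical `conf` quantiles of the bootstrap r, and
#' `p = 2 * min(frac(r_boot <= 0), frac(r_boot >= 0))` (two-sided tail
#' proportion). Deterministic for a fixed seed; the MCD subsampling is
#' exhaustive (hence deterministic) for the cohort sizes this package
#' targets.
#'
#' @param x,y Numeric vectors (n >= 10).
#' @param n_boot Bootstrap resamples (default 2000, the toolbox convention).
#'   `n_boot = 0` skips the bootstrap: `ci` and `p` are NA and only the point
#'   estimate and outlier set are returned.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level of the percentile CI (default 0.95).
#' @return An object of class `correlation_result`: list with `r`, `n`,
#'   `n_kept`, `outlier_indices`, `p`, `ci`, `n_boot`, `n_boot_ok`, `seed`.
#' @examples
#' set.seed(8)
#' x <- rnorm(20); y <- 0.7 * x + rnorm(20) * 0.5
#' skipped_pearson(x, y, n_boot = 50, seed = 1)$r
#' @export
skipped_pearson <- function(x, y, n_boot = 2000L, seed = 1L, conf = 0.95) {
  point <- skipped_r_point(x, y)
  n <- length(x)
  res <- structure(list(
    r = point$r, n = n, n_kept = n - length(point$outliers),
    outlier_indices = point$outliers, p = NA_real_,
    ci = c(NA_real_, NA_real_), n_boot = as.integer(n_boot),
    n_boot_ok = 0L, seed = as.integer(seed)
  ), class = "correlation_result")
  if (n_boot <= 0L) return(res)

  r_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(skipped_r_point(x[idx], y[idx])$r,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- r_boot[is.finite(r_boot)]
  if (length(ok) == 0L) stop("bootstrap degenerate on every resample")
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  res$ci <- unname(stats::quantile(ok, probs))
  res$p <- min(1, 2 * min(mean(ok <= 0), mean(ok >= 0)))
  res$n_boot_ok <- length(ok)
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Skipped Pearson r(%d) = %.3f (%d of %d kept)\n", x$n_kept - 2L, x$r,
    x$n_kept, x$n))
  if (!is.na(x$p)) {
    cat(sprintf("  percentile bootstrap (%d resamples): p = %.4g, CI [%.3f, %.3f]\n",
                x$n_boot, x$p, x$ci[1], x$ci[2]))
  }
  if (length(x$outlier_indices)) {
    cat("  flagged outliers:", paste(x$outlier_indices, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leave-one-out cross-validated linear predictions
#'
#' For each subject i, an ordinary least-squares regression of `y` on `x` is
#' fit on the other n - 1 subjects and evaluated at `x[i]`. Implemented with
#' the exact leave-one-out identity `pred_i = y_i - e_i / (1 - h_i)` (e:
#' full-fit residual, h: leverage), which is algebraically identical to
#' refitting per fold. The correlation between predicted and observed values
#' summarizes out-of-sample predictive power.
#'
#' @param x,y Numeric vectors, n >= 4; `x` must have nonzero variance in
#'   every leave-one-out fold.
#' @return List with `predictions` and `r_pred_obs`.
#' @examples
#' x <- c(0, 1, 2, 3); y <- 2 * x + 1
#' loocv_predict(x, y)$r_pred_obs  # 1: noiseless linear data
#' @export
loocv_predict <- function(x, y) {
  check_finite_vector(x, "x", 4L)
  check_finite_vector(y, "y", 4L)
  stopifnot(length(x) == length(y))
  n <- length(x)
  for (i in seq_len(n)) {
    if (stats::var(x[-i]) == 0) {
      stop(sprintf("zero variance in x when fold %d is left out", i))
    }
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  h <- 1 / n + xc^2 / sxx
  b <- sum(xc * (y - mean(y))) / sxx
  e <- (y - mean(y)) - b * xc
  pred <- y - e / (1 - h)
  if (stats::var(pred) == 0 || stats::var(y) == 0) {
    stop("predictions or outcome have zero variance")
  }
  list(predictions = pred, r_pred_obs = stats::cor(pred, y))
}

# Correlation between LOO predictions and observed values for every column of
# a matrix of (permuted) outcomes, sharing the leverage structure of x.
loocv_r_matrix <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  h <- 1 / n + xc^2 / sxx
  Yc <- sweep(Y, 2, colMeans(Y))
  B <- as.numeric(crossprod(xc, Yc)) / sxx
  E <- Yc - outer(xc, B)
  Pred <- Y - E / (1 - h)
  Pc <- sweep(Pred, 2, colMeans(Pred))
  num <- colSums(Pc * Yc)
  den <- sqrt(colSums(Pc^2) * colSums(Yc^2))
  num / den
}

#' Permutation test for the cross-validated prediction correlation
#'
#' Computes the observed correlation between leave-one-out predicted and
#' observed outcomes ([loocv_predict()]), then builds a null distribution by
#' shuffling the outcome `n_perm` times and rerunning the whole prediction
#' pipeline on each shuffle. Because the folds of a leave-one-out analysis
#' are not independent, the parametric p value for r would be invalid.
#'
#' The null distribution of a cross-validated prediction correlation is not
#' centered at zero — shuffled outcomes yield systematically *negative*
#' predicted-observed correlations — so a two-tailed p cannot be computed by
#' folding the null at zero. The two-sided p doubles the smaller tail of the
#' empirical null at the observed value,
#' `p = min(1, 2 * min(P(r_null >= r_obs), P(r_null <= r_obs)))`, each tail
#' carrying the +1 correction so p is never exactly zero (the smallest
#' attainable p is `2 / (n_perm + 1)`).
#'
#' @param x,y Numeric vectors (n >= 4).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return An object of class `loocv_result`: list with `predictions`,
#'   `r_pred_obs`, `p_perm`, `n_perm`, `seed`.
#' @export
loocv_permutation_test <- function(x, y, n_perm = 5000L, seed = 1L) {
  obs <- loocv_predict(x, y)
  n <- length(y)
  r_null <- with_seed(seed, {
    P <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
    loocv_r_matrix(x, matrix(y[P], nrow = n))
  })
  # a degenerate shuffle (constant predictions) counts against the observed
  # effect, never in its favor
  hi <- !is.finite(r_null) | r_null >= obs$r_pred_obs
  lo <- !is.finite(r_null) | r_null <= obs$r_pred_obs
  p_hi <- (1 + sum(hi)) / (n_perm + 1)
  p_lo <- (1 + sum(lo)) / (n_perm + 1)
  structure(list(predictions = obs$predictions,
                 r_pred_obs = obs$r_pred_obs,
                 p_perm = min(1, 2 * min(p_hi, p_lo)),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "LOO-CV predicted-vs-observed r(%d) = %.3f; permutation p = %.4g (%d shuffles)\n",
    length(x$predictions) - 2L, x$r_pred_obs, x$p_perm, x$n_perm))
  invisible(x)
}
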