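#' Parametric (Gaussian) reference interval
#'
#' The central 95% range under a normal model: mean ± 1.96 SD. For analytes
#' that cannot be negative a sub-zero lower bound is clamped to 0 (and
#' flagged), as guideline practice prints it.
#'
#' @param values Numeric vector, no NAs, n >= 3 (a warning is issued below the
#'   guideline minimum of 40).
#' @param nonnegative Clamp the lower bound at 0.
#' @return List: `lower`, `upper`, `clamped_at_zero`.
#' @export
parametric_ri <- function(values, nonnegative = FALSE) {
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  if (n < 3) stop("parametric reference interval needs n >= 3, got ", n)
  if (n < 40) warning("n = ", n, " is below the guideline minimum of 40 ",
                      "for a parametric reference interval")
  m <- mean(values); s <- stats::sd(values)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  clamped <- FALSE
  if (nonnegative && lower < 0) {
    lower <- 0
    clamped <- TRUE
  }
  list(lower = lower, upper = upper, clamped_at_zero = clamped)
}

#' Box-Cox transformed parametric reference interval
#'
#' For right-skewed analytes: estimate the maximum-likelihood Box-Cox
#' exponent, take mean ± 1.96 SD on the transformed scale, and back-transform
#' the bounds. Values are shifted to be strictly positive first when needed
#' (the shift is removed from the bounds).
#'
#' @param values Numeric vector, no NAs, n >= 3, non-constant.
#' @return List: `lower`, `upper`, `lambda`, `shift`.
#' @export
boxcox_parametric_ri <- function(values) {
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  if (n < 3) stop("reference interval needs n >= 3, got ", n)
  if (diff(range(values)) == 0) stop("constant vector; transform undefined")
  ps <- positive_shift(values)
  lam <- boxcox_lambda(ps$x)
  y <- boxcox_transform(ps$x, lam)
  m <- mean(y); s <- stats::sd(y)
  lower <- boxcox_inverse(m - 1.96 * s, lam) - ps$shift
  upper <- boxcox_inverse(m + 1.96 * s, lam) - ps$shift
  list(lower = unname(lower), upper = unname(upper), lambda = lam,
       shift = ps$shift)
}

#' Nonparametric (percentile) reference interval
#'
#' Empirical 2.5th and 97.5th percentiles with linear interpolation between
#' order statistics. The guideline exact method wants n >= 120; below that a
#' warning is issued and the percentiles are still returned.
#'
#' @param values Numeric vector, no NAs, n >= 3.
#' @return List: `lower`, `upper`.
#' @export
nonparametric_ri <- function(values) {
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  if (n < 3) stop("nonparametric reference interval needs n >= 3, got ", n)
  if (n < 120) warning("n = ", n, " is below the guideline minimum of 120 ",
                       "for a nonparametric reference interval")
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2])
}

ri_bounds <- function(values, method, nonnegative = FALSE) {
  switch(method,
         parametric = parametric_ri(values, nonnegative),
         parametric_boxcox = boxcox_parametric_ri(values),
         nonparametric = nonparametric_ri(values),
         stop("unknown reference-interval method: ", method))
}

#' Bootstrap confidence intervals for reference-interval bounds
#'
#' Percentile bootstrap of each bound: resample the values with replacement B
#' times, recompute the interval each time, and take the (1-level)/2 and
#' 1-(1-level)/2 percentiles of each bound's bootstrap distribution.
#' Deterministic given the seed.
#'
#' @param values Numeric vector, no NAs.
#' @param method `"parametric"`, `"parametric_boxcox"`, or `"nonparametric"`.
#' @param level Confidence level for each bound (default 0.90).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param nonnegative Passed through to the parametric method.
#' @return List: `lower_ci` and `upper_ci`, each `c(lo, hi)`.
#' @export
bootstrap_bound_ci <- function(values, method = "parametric", level = 0.90,
                               B = 1000, seed = 1L, nonnegative = FALSE) {
  stopifnot(is.numeric(values), !anyNA(values), B >= 1,
            level > 0, level < 1)
  n <- length(values)
  with_seed(seed, {
    lo <- numeric(B); hi <- numeric(B)
    for (b in seq_len(B)) {
      res <- suppressWarnings(
        ri_bounds(values[sample.int(n, n, replace = TRUE)], method,
                  nonnegative))
      lo[b] <- res$lower; hi[b] <- res$upper
    }
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    list(lower_ci = unname(stats::quantile(lo, probs, names = FALSE)),
         upper_ci = unname(stats::quantile(hi, probs, names = FALSE)))
  })
}

#' Assemble the full reference-interval table
#'
#' Routes every analyte through the decision made upstream: analytes typed
#' population-based get a reference interval (parametric when the screening
#' stage called the distribution normal, otherwise the configured non-normal
#' method, Box-Cox parametric by default) plus bootstrap confidence bounds;
#' analytes typed subject-based get descriptive statistics and carry their
#' reference change value instead of population bounds. Analytes with no
#' usable values are skipped with a warning. Analytes absent from the
#' variance-component table (no repeat-sampled animals) default to
#' population-based.
#'
#' @param data A `cp_dataset` (pre-inclusion; screening is applied here).
#' @param components Output of [variance_components()], or `NULL` to compute.
#' @param screening Output of [screen_dataset()], or `NULL` to compute.
#' @param nonnormal_method RI method for non-normal population analytes:
#'   `"parametric_boxcox"` (default), `"parametric"`, or `"nonparametric"`.
#' @param level,B,seed Bootstrap settings, see [bootstrap_bound_ci()].
#' @param outlier_method,alpha Screening settings when `screening` is NULL.
#' @return Data frame, one row per analyte, mirroring a published
#'   reference-interval table: n, mean, sd, median, min, max, distribution,
#'   bounds and their CIs, method, rcv, ri_type.
#' @export
build_intervals <- function(data, components = NULL, screening = NULL,
                            nonnormal_method = "parametric_boxcox",
                            level = 0.90, B = 1000, seed = 1L,
                            outlier_method = "horn", alpha = 0.05) {
  stopifnot(inherits(data, "cp_dataset"))
  if (is.null(screening)) {
    screening <- screen_dataset(data, method = outlier_method, alpha = alpha)
  }
  if (is.null(components)) {
    components <- suppressWarnings(variance_components(apply_inclusion(data)))
  }
  rows <- list()
  for (i in seq_len(nrow(data$analytes))) {
    a <- data$analytes$analyte[i]
    v <- unname(screening$retained[[a]])
    if (!length(v)) {
      warning("analyte '", a, "' has no usable values; skipped")
      next
    }
    rep_row <- screening$report[screening$report$analyte == a, ]
    comp <- if (!is.null(components) && a %in% components$analyte) {
      components[components$analyte == a, ]
    } else NULL
    ri_type <- if (is.null(comp)) "population" else comp$ri_type
    dist <- rep_row$normality
    base <- data.frame(
      analyte = a, ri_type = ri_type, n = length(v), mean = mean(v),
      sd = stats::sd(v), median = stats::median(v), min = min(v),
      max = max(v), distribution = dist, stringsAsFactors = FALSE
    )
    if (ri_type == "population") {
      method <- if (dist == "normal") "parametric" else nonnormal_method
      nonneg <- isTRUE(data$analytes$nonnegative[i])
      b <- suppressWarnings(ri_bounds(v, method, nonneg))
      ci <- bootstrap_bound_ci(v, method, level = level, B = B, seed = seed,
                               nonnegative = nonneg)
      lower <- b$lower; clamped <- isTRUE(b$clamped_at_zero)
      if (nonneg && lower < 0) { lower <- 0; clamped <- TRUE }
      ci_l <- ci$lower_ci; ci_u <- ci$upper_ci
      if (nonneg) ci_l <- pmax(ci_l, 0)
      row <- cbind(base, data.frame(
        method = method, lower = lower, upper = b$upper,
        lower_ci_lo = ci_l[1], lower_ci_hi = ci_l[2],
        upper_ci_lo = ci_u[1], upper_ci_hi = ci_u[2],
        clamped_at_zero = clamped,
        lambda = if (!is.null(b$lambda)) b$lambda else NA_real_,
        rcv_combined = NA_real_, index = NA_real_,
        stringsAsFactors = FALSE
      ))
    } else {
      row <- cbind(base, data.frame(
        method = "subject_based", lower = NA_real_, upper = NA_real_,
        lower_ci_lo = NA_real_, lower_ci_hi = NA_real_,
        upper_ci_lo = NA_real_, upper_ci_hi = NA_real_,
        clamped_at_zero = FALSE, lambda = NA_real_,
        rcv_combined = comp$rcv_combined, index = comp$index_without_cva,
        stringsAsFactors = FALSE
      ))
    }
    rows[[a]] <- row
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
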