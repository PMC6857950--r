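#' Apply the health-based inclusion rules
#'
#' Drops whole samples whose physical exam showed clinically significant
#' abnormalities or whose sample quality was compromised (clotting, hemolysis,
#' lymph contamination). Per-analyte missing values are handled downstream;
#' sample order is preserved.
#'
#' @param data A `cp_dataset`.
#' @return The filtered `cp_dataset` (possibly with zero rows).
#' @export
apply_inclusion <- function(data) {
  stopifnot(inherits(data, "cp_dataset"))
  keep <- !(data$samples$exam_abnormal | data$samples$sample_quality_poor)
  out <- data
  out$samples <- data$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

# Profile log-likelihood maximum-likelihood Box-Cox exponent for x > 0.
# For a location/scale model the profile reduces to
#   ll(lambda) = -n/2 * log(var_ml(y_lambda)) + (lambda - 1) * sum(log x).
boxcox_lambda <- function(x, interval = c(-3, 3)) {
  stopifnot(all(x > 0))
  n <- length(x)
  slx <- sum(log(x))
  ll <- function(lam) {
    y <- boxcox_transform(x, lam)
    v <- sum((y - mean(y))^2) / n
    if (v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slx
  }
  stats::optimize(ll, interval, maximum = TRUE, tol = 1e-4)$maximum
}

boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

boxcox_inverse <- function(y, lambda) {
  if (abs(lambda) < 1e-8) return(exp(y))
  z <- lambda * y + 1
  # outside the image of the transform (can happen for extrapolated bounds)
  out <- ifelse(z > 0, z^(1 / lambda), if (lambda < 0) Inf else 0)
  out
}

# Shift a vector to be strictly positive for Box-Cox; returns list(x, shift).
positive_shift <- function(x) {
  m <- min(x)
  if (m > 0) return(list(x = x, shift = 0))
  rng <- diff(range(x))
  eps <- if (rng > 0) 0.001 * rng else 1
  shift <- -m + eps
  list(x = x + shift, shift = shift)
}

#' Flag statistical outliers in one analyte's values
#'
#' Default is Horn's method, the de-facto standard pre-screen for reference
#' interval work: a maximum-likelihood Box-Cox transform toward symmetry
#' (values shifted to be strictly positive first if needed) followed by Tukey
#' fences at Q1 - 1.5 IQR and Q3 + 1.5 IQR on the transformed scale.
#' `tukey_raw` applies the same fences without transformation; `none` flags
#' nothing. A single pass only — flagged indexes are returned, not removed.
#'
#' @param values Numeric vector (no NAs).
#' @param method `"horn"` (default), `"tukey_raw"`, or `"none"`.
#' @return Integer vector of flagged positions (possibly empty).
#' @export
detect_outliers <- function(values, method = c("horn", "tukey_raw", "none")) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), !anyNA(values))
  if (method == "none") return(integer(0))
  if (length(values) < 20) {
    warning("fewer than 20 values; skipping outlier detection")
    return(integer(0))
  }
  y <- values
  if (method == "horn") {
    ps <- positive_shift(values)
    if (diff(range(ps$x)) == 0) return(integer(0))
    lam <- boxcox_lambda(ps$x)
    y <- boxcox_transform(ps$x, lam)
  }
  q <- stats::quantile(y, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(integer(0))
  which(y < q[1] - 1.5 * iqr | y > q[2] + 1.5 * iqr)
}

#' Classify a sample as normal or non-normal
#'
#' Shapiro-Wilk at the given alpha decides the call; sample skewness and
#' excess kurtosis are reported as diagnostics but do not override the test.
#' Constant vectors (Shapiro-Wilk undefined) are classified non-normal with a
#' warning rather than failing the pipeline.
#'
#' @param values Numeric vector, 3 <= n <= 5000, no NAs.
#' @param alpha Significance level (default 0.05).
#' @return List with `normality` (`"normal"`/`"non-normal"`), `shapiro_p`,
#'   `skewness`, `excess_kurtosis`, `n`.
#' @export
assess_normality <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  if (n < 3 || n > 5000) stop("assess_normality needs 3 <= n <= 5000, got ", n)
  sk <- e1071::skewness(values)
  ku <- e1071::kurtosis(values)
  if (diff(range(values)) == 0) {
    warning("constant vector; classifying as non-normal")
    return(list(normality = "non-normal", shapiro_p = NA_real_,
                skewness = sk, excess_kurtosis = ku, n = n))
  }
  p <- stats::shapiro.test(values)$p.value
  list(normality = if (p > alpha) "normal" else "non-normal",
       shapiro_p = p, skewness = sk, excess_kurtosis = ku, n = n)
}

#' Screen every analyte of a dataset
#'
#' Runs the full gatekeeping stage that precedes reference-interval
#' construction: sample-level inclusion rules, per-analyte missing-value
#' accounting, one pass of outlier flagging, and a normality call on the
#' retained values.
#'
#' @param data A `cp_dataset`.
#' @param method Outlier method, see [detect_outliers()].
#' @param alpha Normality alpha.
#' @return List with `report` (one row per analyte: counts, normality call,
#'   diagnostics), `retained` (named list of per-analyte numeric vectors that
#'   survived screening, named by animal_id), and `outlier_ids` (named list of
#'   flagged sample animal_ids).
#' @export
screen_dataset <- function(data, method = "horn", alpha = 0.05) {
  stopifnot(inherits(data, "cp_dataset"))
  n_input <- nrow(data$samples)
  n_exam <- sum(data$samples$exam_abnormal)
  n_quality <- sum(data$samples$sample_quality_poor & !data$samples$exam_abnormal)
  included <- apply_inclusion(data)

  report <- list(); retained <- list(); outlier_ids <- list()
  for (a in data$analytes$analyte) {
    v <- included$samples[[a]]
    ids <- included$samples$animal_id
    miss <- is.na(v)
    vv <- v[!miss]; vids <- ids[!miss]
    out_idx <- if (length(vv)) detect_outliers(vv, method) else integer(0)
    keep <- if (length(out_idx)) vv[-out_idx] else vv
    keep_ids <- if (length(out_idx)) vids[-out_idx] else vids
    norm <- if (length(keep) >= 3 && length(keep) <= 5000) {
      assess_normality(keep, alpha)
    } else {
      list(normality = "non-normal", shapiro_p = NA_real_,
           skewness = NA_real_, excess_kurtosis = NA_real_)
    }
    report[[a]] <- data.frame(
      analyte = a, n_input = n_input, n_excluded_exam = n_exam,
      n_excluded_quality = n_quality, n_missing = sum(miss),
      n_outliers = length(out_idx), n_retained = length(keep),
      normality = norm$normality, shapiro_p = norm$shapiro_p,
      skewness = norm$skewness, excess_kurtosis = norm$excess_kurtosis,
      stringsAsFactors = FALSE
    )
    retained[[a]] <- stats::setNames(keep, keep_ids)
    outlier_ids[[a]] <- vids[out_idx]
  }
  list(report = do.call(rbind, c(report, list(make.row.names = FALSE))),
       retained = retained, outlier_ids = outlier_ids)
}
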