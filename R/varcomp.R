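#' Within- and between-animal coefficients of variation
#'
#' One-way random-effects decomposition of an analyte over the longitudinally
#' sampled animals (animals with at least two non-missing values; singletons
#' carry no information about within-animal variation and are excluded).
#' The within-animal variance is the pooled within-animal variance
#' \deqn{s_w^2 = \sum_a \sum_j (x_{aj} - \bar x_a)^2 / \sum_a (n_a - 1),}
#' and the between-animal variance comes from the unbalanced method of
#' moments, \eqn{s_b^2 = \max(0, (MS_{between} - s_w^2)/n_0)} with
#' \eqn{n_0 = (N - \sum_a n_a^2 / N)/(k - 1)}. CVs are the square roots
#' divided by the grand mean of the repeat-sampled subset.
#'
#' @param data A `cp_dataset`.
#' @param analyte Analyte name.
#' @return List: `cv_i`, `cv_g`, `s_w`, `s_b`, `grand_mean`, `n_animals`,
#'   `n_samples`.
#' @export
estimate_cvs <- function(data, analyte) {
  v <- analyte_values(data, analyte)
  by_animal <- split(unname(v), names(v))
  by_animal <- by_animal[lengths(by_animal) >= 2]
  k <- length(by_animal)
  if (k < 2) {
    stop("analyte '", analyte, "' has ", k,
         " repeat-sampled animal(s); need at least 2")
  }
  n_a <- lengths(by_animal)
  N <- sum(n_a)
  means <- vapply(by_animal, mean, numeric(1))
  grand <- sum(n_a * means) / N
  if (grand <= 0) stop("grand mean of '", analyte, "' is not positive; ",
                       "CVs are undefined")
  ss_within <- sum(vapply(by_animal, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  s_w2 <- ss_within / sum(n_a - 1)
  ms_between <- sum(n_a * (means - grand)^2) / (k - 1)
  n0 <- (N - sum(n_a^2) / N) / (k - 1)
  s_b2 <- max(0, (ms_between - s_w2) / n0)
  list(cv_i = sqrt(s_w2) / grand, cv_g = sqrt(s_b2) / grand,
       s_w = sqrt(s_w2), s_b = sqrt(s_b2), grand_mean = grand,
       n_animals = k, n_samples = N)
}

#' Index of individuality
#'
#' Compares within-animal (plus, optionally, analytical) variation to
#' between-animal variation. A low index (< 0.6) means individuals hug their
#' own setpoints far from one another, so a population-based reference
#' interval is insensitive and interpretation should be subject-based.
#' Both the CVa-inclusive variant \eqn{(CV_i + CV_a)/CV_g} and the plain
#' \eqn{CV_i/CV_g} are returned.
#'
#' @param cv_i Within-animal CV (proportion, >= 0).
#' @param cv_g Between-animal CV (proportion, > 0).
#' @param cv_a Analytical CV (proportion) or `NA`/`NULL` when unknown.
#' @return List: `index_with_cva`, `index_without_cva`.
#' @export
index_of_individuality <- function(cv_i, cv_g, cv_a = NA_real_) {
  stopifnot(cv_i >= 0)
  if (is.null(cv_a)) cv_a <- NA_real_
  if (cv_g <= 0) stop("index of individuality undefined for cv_g = 0")
  without <- cv_i / cv_g
  with <- if (is.na(cv_a)) without else (cv_i + cv_a) / cv_g
  list(index_with_cva = with, index_without_cva = without)
}

#' Reference change value
#'
#' The smallest relative difference between two serial results in one animal
#' that exceeds expected within-animal (plus analytical) noise at 95%
#' confidence. `rcv_stated` is the within-animal-only form
#' \eqn{1.96 \sqrt{2}\, CV_i}; `rcv_combined` folds in the analytical CV,
#' \eqn{1.96 \sqrt{2} \sqrt{CV_a^2 + CV_i^2}} (equal to the stated form when
#' no CVa is available).
#'
#' @param cv_i Within-animal CV (proportion, >= 0).
#' @param cv_a Analytical CV or `NA`/`NULL`.
#' @return List: `rcv_stated`, `rcv_combined` (proportions).
#' @export
reference_change_value <- function(cv_i, cv_a = NA_real_) {
  stopifnot(cv_i >= 0)
  if (is.null(cv_a) || is.na(cv_a)) cv_a <- 0
  z <- 1.96 * sqrt(2)
  list(rcv_stated = z * cv_i, rcv_combined = z * sqrt(cv_a^2 + cv_i^2))
}

#' Decide subject- vs population-based reference interval
#'
#' Subject-based when the index of individuality falls below the threshold
#' (default 0.6, the conventional decision point); an index exactly at the
#' threshold is treated as population-based, the more general object.
#'
#' @param index Index of individuality (>= 0).
#' @param threshold Decision threshold (default 0.6).
#' @return `"subject"` or `"population"`.
#' @export
decide_ri_type <- function(index, threshold = 0.6) {
  stopifnot(index >= 0)
  if (index < threshold) "subject" else "population"
}

#' Variance-component table for every estimable analyte
#'
#' Runs [estimate_cvs()], [index_of_individuality()],
#' [reference_change_value()] and [decide_ri_type()] across the panel.
#' Analytes without at least two repeat-sampled animals are skipped with a
#' warning.
#'
#' @param data A `cp_dataset` (already screened if desired).
#' @param index_variant Which index decides the RI type:
#'   `"without_cva"` (default; matches how printed decisions behave) or
#'   `"with_cva"` (the CVa-inclusive formula).
#' @param threshold Index decision threshold.
#' @return Data frame with one row per analyte: CVs, both index variants,
#'   both RCV variants, and `ri_type`.
#' @export
variance_components <- function(data, index_variant = c("without_cva",
                                                        "with_cva"),
                                threshold = 0.6) {
  stopifnot(inherits(data, "cp_dataset"))
  index_variant <- match.arg(index_variant)
  rows <- list()
  for (i in seq_len(nrow(data$analytes))) {
    a <- data$analytes$analyte[i]
    cva <- data$analytes$cva[i]
    est <- tryCatch(estimate_cvs(data, a), error = function(e) e)
    if (inherits(est, "error")) {
      warning("skipping '", a, "': ", conditionMessage(est))
      next
    }
    idx <- if (est$cv_g > 0) {
      index_of_individuality(est$cv_i, est$cv_g, cva)
    } else {
      warning("cv_g = 0 for '", a, "'; index undefined, typing as subject")
      list(index_with_cva = NA_real_, index_without_cva = NA_real_)
    }
    rcv <- reference_change_value(est$cv_i, cva)
    dec <- if (index_variant == "without_cva") idx$index_without_cva
           else idx$index_with_cva
    rows[[a]] <- data.frame(
      analyte = a, cv_i = est$cv_i, cv_g = est$cv_g, cv_a = cva,
      n_animals = est$n_animals, n_samples = est$n_samples,
      index_with_cva = idx$index_with_cva,
      index_without_cva = idx$index_without_cva,
      rcv_stated = rcv$rcv_stated, rcv_combined = rcv$rcv_combined,
      ri_type = if (is.na(dec)) "subject" else decide_ri_type(dec, threshold),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
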