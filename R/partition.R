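partition_factors <- function() c("age_class", "sex", "month", "year", "site")

# Per-level usable (value, level) pairs for one analyte; levels with fewer
# than 2 samples are dropped with a warning (this is what excludes a
# single-sample month from monthly comparisons).
usable_levels <- function(data, analyte, factor) {
  if (!factor %in% partition_factors()) stop("unknown factor: ", factor)
  lev <- as.character(data$samples[[factor]])
  v <- data$samples[[analyte]]
  ok <- !is.na(v) & !is.na(lev)
  v <- v[ok]; lev <- lev[ok]
  counts <- table(lev)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping level(s) with n < 2 for ", factor, ": ",
            paste(small, collapse = ", "))
    keep <- !(lev %in% small)
    v <- v[keep]; lev <- lev[keep]
  }
  split(v, lev)
}

#' Per-level descriptive summaries
#'
#' For each level of a demographic factor: n, then a center and spread chosen
#' by that level's own normality call — mean with a t-based 95% CI when the
#' values pass Shapiro-Wilk, otherwise median with the 10th/90th percentiles
#' — plus min and max always. Mirrors the reporting convention of wildlife
#' clinical-pathology partition tables.
#'
#' @param data A `cp_dataset`.
#' @param analyte Analyte name.
#' @param factor One of `age_class`, `sex`, `month`, `year`, `site`.
#' @param alpha Normality alpha.
#' @return Data frame, one row per retained level.
#' @export
summarize_groups <- function(data, analyte, factor, alpha = 0.05) {
  stopifnot(inherits(data, "cp_dataset"))
  groups <- usable_levels(data, analyte, factor)
  rows <- lapply(names(groups), function(lv) {
    x <- groups[[lv]]
    n <- length(x)
    norm <- if (n >= 3 && diff(range(x)) > 0) {
      assess_normality(x, alpha)$normality == "normal"
    } else FALSE
    if (norm) {
      m <- mean(x)
      half <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
      center <- m; lo <- m - half; hi <- m + half
    } else {
      center <- stats::median(x)
      q <- stats::quantile(x, c(0.10, 0.90), names = FALSE)
      lo <- q[1]; hi <- q[2]
    }
    data.frame(analyte = analyte, factor = factor, level = lv, n = n,
               center = center, spread_low = lo, spread_high = hi,
               min = min(x), max = max(x), normal = norm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

two_sample_test <- function(x, y, parametric) {
  if (parametric) {
    t <- stats::t.test(x, y, var.equal = FALSE)
    list(test = "t", statistic = unname(t$statistic), p = t$p.value)
  } else {
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(test = "mann_whitney", statistic = unname(w$statistic), p = w$p.value)
  }
}

#' Compare analyte levels across a demographic factor
#'
#' Normality-gated test dispatch: every level must pass Shapiro-Wilk for the
#' parametric branch. Two levels give a t-test (Welch) or Mann-Whitney U;
#' more give one-way ANOVA or Kruskal-Wallis. When the omnibus test is
#' significant at `alpha` and the factor has more than two levels, all
#' pairwise comparisons are run with the matching two-sample test. For `sex`,
#' pairwise reporting is restricted to female vs male (the `unknown` level
#' stays in the omnibus test).
#'
#' @inheritParams summarize_groups
#' @param alpha Significance level for the omnibus gate (default 0.05).
#' @param correction Multiple-testing correction applied to the pairwise
#'   p-values: `"none"` (default, raw p-values as the field reports them) or
#'   `"holm"`.
#' @return List: `analyte`, `factor`, `test`, `statistic`, `p`, `parametric`,
#'   `pairwise` (data frame or NULL).
#' @export
compare_groups <- function(data, analyte, factor, alpha = 0.05,
                           correction = c("none", "holm")) {
  correction <- match.arg(correction)
  stopifnot(inherits(data, "cp_dataset"))
  groups <- usable_levels(data, analyte, factor)
  if (length(groups) < 2) stop("fewer than 2 usable levels for ", factor)
  parametric <- all(vapply(groups, function(x) {
    length(x) >= 3 && diff(range(x)) > 0 &&
      assess_normality(x, alpha)$normality == "normal"
  }, logical(1)))

  lv <- names(groups)
  if (length(groups) == 2) {
    res <- two_sample_test(groups[[1]], groups[[2]], parametric)
    test <- res$test; statistic <- res$statistic; p <- res$p
  } else if (parametric) {
    vals <- unlist(groups, use.names = FALSE)
    g <- factor(rep(lv, lengths(groups)))
    fit <- stats::aov(vals ~ g)
    s <- summary(fit)[[1]]
    test <- "anova"; statistic <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  } else {
    kw <- stats::kruskal.test(groups)
    test <- "kruskal_wallis"; statistic <- unname(kw$statistic); p <- kw$p.value
  }

  pairwise <- NULL
  if (length(groups) > 2 && !is.na(p) && p < alpha) {
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    if (factor == "sex") {
      pairs <- Filter(function(pr) setequal(pr, c("female", "male")), pairs)
    }
    pairwise <- do.call(rbind, lapply(pairs, function(pr) {
      r <- two_sample_test(groups[[pr[1]]], groups[[pr[2]]], parametric)
      data.frame(level_a = pr[1], level_b = pr[2], p = r$p,
                 stringsAsFactors = FALSE)
    }))
    if (correction == "holm") pairwise$p <- stats::p.adjust(pairwise$p, "holm")
  }
  list(analyte = analyte, factor = factor, test = test,
       statistic = statistic, p = p, parametric = parametric,
       pairwise = pairwise)
}

# First chronological sample per animal: the default de-duplication for
# linear modeling, so repeat-sampled animals do not pseudo-replicate.
dedup_first_capture <- function(data) {
  s <- data$samples
  ord <- order(s$animal_id, s$date)
  s <- s[ord, , drop = FALSE]
  s <- s[!duplicated(s$animal_id), , drop = FALSE]
  out <- data
  out$samples <- s[order(as.integer(rownames(s))), , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

model_frame <- function(data, analyte, dedup = c("first", "all")) {
  dedup <- match.arg(dedup)
  d <- if (dedup == "first") dedup_first_capture(data) else data
  s <- d$samples
  df <- data.frame(value = s[[analyte]],
                   age_class = factor(s$age_class), sex = factor(s$sex),
                   month = factor(s$month), year = factor(s$year),
                   site = factor(s$site))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  droplevels(df)
}

#' Ordinary least squares for one analyte on demographic terms
#'
#' Fits the analyte on the requested main effects / two-way interactions by
#' OLS with reference-level dummy coding, dropping aliased columns with a
#' warning when the design is rank-deficient. `k` counts estimated
#' coefficients plus one for the residual variance (the AICc convention).
#'
#' @param data A `cp_dataset`.
#' @param analyte Analyte name.
#' @param terms Character vector of model terms, e.g.
#'   `c("site", "sex", "site:sex")`; empty for intercept-only.
#' @param dedup `"first"` (default, one sample per animal) or `"all"`.
#' @return List: `coefficients`, `rss`, `k`, `n`, `terms`, `fit`.
#' @export
fit_linear_model <- function(data, analyte, terms = character(0),
                             dedup = "first") {
  df <- model_frame(data, analyte, dedup)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    warning("rank-deficient design for '", analyte,
            "'; dropped aliased column(s): ",
            paste(names(co)[is.na(co)], collapse = ", "))
  }
  rss <- sum(stats::residuals(fit)^2)
  list(coefficients = co, rss = rss, k = sum(!is.na(co)) + 1L,
       n = nrow(df), terms = terms, fit = fit)
}

aicc <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Default candidate model set
#'
#' The global model (all five demographic main effects plus all two-way
#' interactions) together with every main-effects-only subset, including the
#' intercept-only model.
#'
#' @param factors Main-effect names.
#' @return List of character vectors of terms.
#' @export
default_candidates <- function(factors = partition_factors()) {
  subsets <- list(character(0))
  for (f in factors) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))
  }
  global <- c(factors, utils::combn(factors, 2, paste, collapse = ":"))
  c(subsets, list(global))
}

#' Rank candidate models by AICc
#'
#' Fits each candidate by OLS and ranks by small-sample AIC,
#' \deqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1),}
#' with Akaike weights over the fitted set. Candidates whose parameter count
#' exhausts the sample (`n - k - 1 <= 0`) are skipped with a warning.
#'
#' @param data A `cp_dataset`.
#' @param analyte Analyte name.
#' @param candidates List of term vectors; default [default_candidates()].
#' @param dedup Passed to [fit_linear_model()].
#' @return Data frame ranked by AICc: `model`, `k`, `n`, `aicc`,
#'   `delta_aicc`, `weight`.
#' @export
select_model <- function(data, analyte, candidates = default_candidates(),
                         dedup = "first") {
  rows <- list()
  for (i in seq_along(candidates)) {
    terms <- candidates[[i]]
    fit <- tryCatch(
      suppressWarnings(fit_linear_model(data, analyte, terms, dedup)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate '", paste(terms, collapse = " + "),
              "' skipped: ", conditionMessage(fit))
      next
    }
    a <- aicc(fit$rss, fit$n, fit$k)
    if (is.na(a)) {
      warning("candidate '", paste(terms, collapse = " + "),
              "' skipped: too many parameters for n = ", fit$n)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      analyte = analyte,
      model = if (length(terms)) paste(terms, collapse = " + ") else "1",
      k = fit$k, n = fit$n, aicc = a, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no candidate model could be fit for ", analyte)
  out <- do.call(rbind, rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$weight <- exp(-out$delta_aicc / 2) / sum(exp(-out$delta_aicc / 2))
  out[order(out$aicc), , drop = FALSE]
}
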