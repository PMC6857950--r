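test_that("group summaries report n, center, spread, and range per level", {
  d <- grouped_dataset(list(A = 1:5), factor = "site")
  s <- suppressWarnings(summarize_groups(d, "pcv", "site"))
  expect_equal(s$n, 5)
  expect_equal(s$center, 3)
  expect_equal(s$min, 1); expect_equal(s$max, 5)

  # constant level: degenerate spread handled without error
  d2 <- grouped_dataset(list(A = c(2, 2, 2), B = rnorm(30, 5)), factor = "site")
  s2 <- suppressWarnings(summarize_groups(d2, "pcv", "site"))
  a <- s2[s2$level == "A", ]
  expect_equal(a$center, 2)
  expect_equal(a$spread_low, a$spread_high)

  expect_error(summarize_groups(d, "pcv", "habitat"), "unknown factor")
})

test_that("a configured age-class shift shows up in the summaries", {
  d <- apply_inclusion(simulate_dataset(default_study_config(seed = 2)))
  s <- suppressWarnings(summarize_groups(d, "calcium", "age_class"))
  expect_gt(s$center[s$level == "adult"], s$center[s$level == "juvenile"])
})

test_that("levels with n < 2 are dropped from partition analyses", {
  d <- simulate_dataset(default_study_config(seed = 1))
  d <- apply_inclusion(d)
  expect_equal(sum(d$samples$month == "August"), 1L)
  expect_warning(s <- summarize_groups(d, "pcv", "month"), "August")
  expect_setequal(s$level, c("May", "June", "July"))
})

test_that("test dispatch follows the normality gate", {
  set.seed(30)
  norm1 <- rnorm(60, 10); norm2 <- rnorm(60, 10); norm3 <- rnorm(60, 10)
  skew <- rexp(60)

  # two normal levels -> t-test
  cmp <- compare_groups(grouped_dataset(list(A = norm1, B = norm2)),
                        "pcv", "site")
  expect_equal(cmp$test, "t"); expect_true(cmp$parametric)

  # one skewed level poisons the gate -> Mann-Whitney
  cmp2 <- compare_groups(grouped_dataset(list(A = norm1, B = skew)),
                         "pcv", "site")
  expect_equal(cmp2$test, "mann_whitney"); expect_false(cmp2$parametric)

  # three normal levels -> ANOVA; with a skewed one -> Kruskal-Wallis
  cmp3 <- compare_groups(grouped_dataset(list(A = norm1, B = norm2, C = norm3)),
                         "pcv", "site")
  expect_equal(cmp3$test, "anova")
  cmp4 <- compare_groups(grouped_dataset(list(A = norm1, B = norm2, C = skew)),
                         "pcv", "site")
  expect_equal(cmp4$test, "kruskal_wallis")
})

test_that("comparisons behave at the null and under a large effect", {
  set.seed(31)
  g <- rnorm(40, 10)
  same <- compare_groups(grouped_dataset(list(A = g, B = g)), "pcv", "site")
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  set.seed(32)
  big <- compare_groups(
    grouped_dataset(list(A = rnorm(50), B = rnorm(50, 5))), "pcv", "site")
  expect_lt(big$p, 1e-6)
})

test_that("pairwise follow-ups appear only after a significant omnibus, and sex reports female vs male", {
  set.seed(33)
  d <- grouped_dataset(list(adult = rnorm(50, 10), subadult = rnorm(50, 10),
                            juvenile = rnorm(50, 14)), factor = "age_class")
  cmp <- compare_groups(d, "pcv", "age_class")
  expect_lt(cmp$p, 0.05)
  expect_equal(nrow(cmp$pairwise), 3)

  null3 <- grouped_dataset(list(adult = rnorm(50, 10), subadult = rnorm(50, 10),
                                juvenile = rnorm(50, 10)), factor = "age_class")
  cmp0 <- compare_groups(null3, "pcv", "age_class")
  if (cmp0$p >= 0.05) expect_null(cmp0$pairwise)

  dsex <- grouped_dataset(list(female = rnorm(60, 10), male = rnorm(60, 13),
                               unknown = rnorm(20, 10)), factor = "sex")
  cmps <- compare_groups(dsex, "pcv", "sex")
  expect_equal(nrow(cmps$pairwise), 1)
  expect_setequal(unlist(cmps$pairwise[, c("level_a", "level_b")]),
                  c("female", "male"))

  # Holm correction only ever raises pairwise p-values
  raw <- compare_groups(d, "pcv", "age_class")
  adj <- compare_groups(d, "pcv", "age_class", correction = "holm")
  expect_true(all(adj$pairwise$p >= raw$pairwise$p - 1e-15))
})

test_that("OLS fits match closed forms and a brute-force residual oracle", {
  d <- apply_inclusion(simulate_dataset(default_study_config(seed = 4)))

  f0 <- fit_linear_model(d, "pcv", character(0))
  v <- f0$fit$model$value
  expect_equal(unname(f0$coefficients[1]), mean(v), tolerance = 1e-10)
  expect_equal(f0$rss, sum((v - mean(v))^2), tolerance = 1e-8)

  f1 <- fit_linear_model(d, "pcv", "site")
  mf <- f1$fit$model
  diff_means <- mean(mf$value[mf$site == "SBCP"]) -
    mean(mf$value[mf$site == "IBSP"])
  expect_equal(abs(unname(f1$coefficients[2])), abs(diff_means),
               tolerance = 1e-10)

  # brute-force normal equations on the model matrix
  f2 <- fit_linear_model(d, "calcium", c("site", "sex", "site:sex"))
  X <- model.matrix(f2$fit)
  y <- f2$fit$model$value
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(f2$rss, sum((y - X %*% beta)^2), tolerance = 1e-8)
})

test_that("AICc selection is parsimonious under the null and finds a real effect", {
  # no true effect: intercept-only usually beats the site model
  wins <- 0
  for (s in 1:50) {
    d <- simulate_dataset(gaussian_config(mean = 50, sd_between = 5,
                                          sd_within = 5, n_single = 80L,
                                          repeat_groups = integer(0),
                                          seed = 100 + s))
    m <- select_model(d, "ast", list(character(0), "site"))
    if (m$model[1] == "1") wins <- wins + 1
  }
  expect_gt(wins / 50, 0.5)

  # strong site effect: the best model includes site
  eff <- data.frame(analyte = "ast", factor = "site", level = "IBSP",
                    shift = 20, stringsAsFactors = FALSE)
  d <- simulate_dataset(gaussian_config(mean = 50, sd_between = 5,
                                        sd_within = 5, n_single = 120L,
                                        repeat_groups = integer(0),
                                        effects = eff, seed = 77))
  m <- suppressWarnings(select_model(d, "ast"))
  expect_match(m$model[1], "site")

  # weights are a proper distribution and duplicates tie exactly
  m2 <- select_model(d, "ast", list("site", "site", character(0)))
  expect_equal(sum(m2$weight), 1, tolerance = 1e-9)
  expect_equal(m2$aicc[1], m2$aicc[2], tolerance = 1e-12)
  expect_equal(m2$delta_aicc[1], 0)
  # candidate order does not change the weights
  m3 <- select_model(d, "ast", list(character(0), "site", "site"))
  expect_equal(sort(m3$weight), sort(m2$weight), tolerance = 1e-12)
})

test_that("overparameterized candidates are skipped with a warning", {
  d <- simulate_dataset(gaussian_config(mean = 50, sd_between = 5,
                                        sd_within = 5, n_single = 8L,
                                        repeat_groups = integer(0), seed = 9))
  expect_warning(
    m <- select_model(d, "ast",
                      list(character(0),
                           c("site", "sex", "age_class", "month",
                             "site:sex", "site:age_class", "sex:age_class",
                             "site:month", "sex:month", "age_class:month"))),
    "skipped")
  expect_equal(m$model, "1")
})
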