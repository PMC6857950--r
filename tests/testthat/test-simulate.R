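test_that("zero variance collapses every draw to the configured mean plus shifts", {
  eff <- data.frame(analyte = "ast", factor = "site", level = "IBSP",
                    shift = 5, stringsAsFactors = FALSE)
  cfg <- gaussian_config(mean = 50, sd_between = 0, sd_within = 0,
                         n_single = 20L, repeat_groups = integer(0),
                         effects = eff, seed = 4)
  d <- simulate_dataset(cfg)
  expected <- ifelse(d$samples$site == "IBSP", 55, 50)
  expect_equal(d$samples$ast, expected)

  # log-normal degenerate case lands exactly on the raw-scale mean
  cfg_ln <- gaussian_config(mean = 50, sd_between = 0, sd_within = 0,
                            n_single = 20L, repeat_groups = integer(0),
                            family = "lognormal", seed = 4)
  expect_equal(simulate_dataset(cfg_ln)$samples$ast, rep(50, 20))
})

test_that("quantitation floor left-censors: sub-floor draws are reported at the floor", {
  cfg <- gaussian_config(mean = 0.5, sd_between = 0.05, sd_within = 0.05,
                         n_single = 50L, repeat_groups = integer(0),
                         nonnegative = TRUE, floor = 0.8, seed = 2)
  d <- simulate_dataset(cfg)
  expect_true(all(d$samples$ast == 0.8))

  # higher mean: floored values sit at the floor, none below, some above
  cfg2 <- gaussian_config(mean = 1.0, sd_between = 0.3, sd_within = 0.3,
                          n_single = 200L, repeat_groups = integer(0),
                          nonnegative = TRUE, floor = 0.8, seed = 2)
  v <- simulate_dataset(cfg2)$samples$ast
  expect_true(all(v >= 0.8))
  expect_true(any(v == 0.8) && any(v > 0.8))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- default_study_config(seed = 1)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(default_study_config(seed = 1))
  expect_identical(d1, d2)
  d3 <- simulate_dataset(default_study_config(seed = 2))
  expect_equal(dim(d3$samples), dim(d1$samples))
  expect_false(isTRUE(all.equal(d1$samples$pcv, d3$samples$pcv)))
})

test_that("the default study config reproduces the field-study shape", {
  d <- simulate_dataset(default_study_config(seed = 1))
  s <- d$samples
  expect_equal(nrow(s), 393L)
  expect_equal(length(unique(s$animal_id)), 227L)
  expect_equal(sum(table(s$animal_id) >= 2), 70L)
  expect_equal(as.integer(table(s$month)[c("May", "June", "July", "August")]),
               c(134L, 160L, 98L, 1L))
  expect_setequal(unique(s$site), c("SBCP", "IBSP"))
  expect_setequal(unique(s$year), c(2017L, 2018L))
  # demographics constant within animal
  for (f in c("site", "sex", "age_class")) {
    expect_true(all(tapply(s[[f]], s$animal_id,
                           function(x) length(unique(x))) == 1L))
  }
  # all 16 panel analytes present with plausible missingness
  expect_equal(nrow(d$analytes), 16L)
  expect_lt(sum(is.na(s$bile_acids)), 393 * 0.25)
})

test_that("simulated moments recover the configured parameters", {
  # law of large numbers on the grand mean
  cfg <- gaussian_config(mean = 100, sd_between = 20, sd_within = 10,
                         n_single = 100000L, repeat_groups = integer(0),
                         seed = 8)
  v <- simulate_dataset(cfg)$samples$ast
  expect_lt(abs(mean(v) - 100) / 100, 0.01)

  # pooled within-animal SD estimates sigma_within (floors off)
  cfg2 <- gaussian_config(mean = 100, sd_between = 20, sd_within = 10,
                          n_single = 0L, repeat_groups = c(`5` = 500L),
                          seed = 9)
  d2 <- simulate_dataset(cfg2)
  by_animal <- split(d2$samples$ast, d2$samples$animal_id)
  s_w <- sqrt(mean(vapply(by_animal, var, numeric(1))))
  expect_lt(abs(s_w - 10) / 10, 0.10)
})

test_that("invalid simulation configs are rejected", {
  an <- data.frame(analyte = "a", mean = 1, sd_between = -1, sd_within = 1,
                   family = "gaussian", stringsAsFactors = FALSE)
  dg <- list(site = c(A = 1), sex = c(f = 1), age_class = c(adult = 1),
             month = c(May = 1), year = c(`2017` = 1))
  expect_error(simulation_config(an, 5, integer(0), dg), "SDs")
  an$sd_between <- 1
  expect_error(simulation_config(an, 5, c(`1` = 3), dg), "repeat")
  dg_bad <- dg; dg_bad$site <- c(A = 0.6, B = 0.6)
  expect_error(simulation_config(an, 5, integer(0), dg_bad), "summing to 1")
  an2 <- an; an2$family <- "weibull"
  expect_error(simulation_config(an2, 5, integer(0), dg), "family")
})
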