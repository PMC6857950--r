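varcomp_dataset <- function(values, animals) {
  new_dataset(data.frame(animal_id = animals, date = "2017-06-01",
                         pcv = values, stringsAsFactors = FALSE),
              rbind(analyte_definition("pcv", "%", nonnegative = FALSE)))
}

test_that("variance decomposition separates pure between- and pure within-animal spread", {
  d <- varcomp_dataset(c(10, 10, 20, 20), c("a", "a", "b", "b"))
  est <- estimate_cvs(d, "pcv")
  expect_equal(est$cv_i, 0)
  expect_gt(est$cv_g, 0)

  d2 <- varcomp_dataset(c(10, 20, 10, 20), c("a", "a", "b", "b"))
  est2 <- estimate_cvs(d2, "pcv")
  expect_equal(est2$cv_g, 0)  # truncated at zero
  expect_gt(est2$cv_i, 0)

  expect_error(estimate_cvs(varcomp_dataset(c(1, 2), c("a", "a")), "pcv"),
               "at least 2")
  expect_error(estimate_cvs(
    varcomp_dataset(c(-5, -5, 5, 5), c("a", "a", "b", "b")), "pcv"),
    "not positive")
})

test_that("balanced designs match the one-way ANOVA oracle to 1e-10", {
  cases <- list(
    list(v = c(4, 6, 9, 11, 14, 16), a = rep(c("a", "b", "c"), each = 2)),
    list(v = c(1, 2, 3, 5, 8, 13, 21, 34), a = rep(c("a", "b", "c", "d"),
                                                   each = 2)),
    list(v = c(10, 12, 11, 9, 30, 28, 31, 29, 20, 21, 19, 22),
         a = rep(c("a", "b", "c"), each = 4))
  )
  for (cs in cases) {
    est <- estimate_cvs(varcomp_dataset(cs$v, cs$a), "pcv")
    av <- anova(lm(cs$v ~ factor(cs$a)))
    msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
    n_per <- length(cs$v) / length(unique(cs$a))
    sb2 <- max(0, (msb - msw) / n_per)
    expect_equal(est$cv_i, sqrt(msw) / mean(cs$v), tolerance = 1e-10)
    expect_equal(est$cv_g, sqrt(sb2) / mean(cs$v), tolerance = 1e-10)
  }
})

test_that("index of individuality reproduces published biological-variation arithmetic", {
  # printed CV pairs and their printed indexes (2 dp)
  expect_equal(round(index_of_individuality(0.78, 1.37)$index_without_cva, 2),
               0.57)
  expect_equal(round(index_of_individuality(0.66, 1.14)$index_without_cva, 2),
               0.58)
  # the CVa-inclusive variant is larger when a CVa exists
  idx <- index_of_individuality(0.78, 1.37, 0.082)
  expect_equal(idx$index_with_cva, (0.78 + 0.082) / 1.37)
  expect_gt(idx$index_with_cva, idx$index_without_cva)
  # degenerate inputs
  expect_equal(index_of_individuality(0, 1.0)$index_without_cva, 0)
  expect_error(index_of_individuality(0.5, 0), "cv_g = 0")
})

test_that("reference change values reproduce published arithmetic and are monotone", {
  expect_equal(round(100 * reference_change_value(0.78, 0.082)$rcv_combined),
               217)
  expect_equal(round(100 * reference_change_value(0.66)$rcv_stated), 183)
  expect_equal(reference_change_value(0)$rcv_combined, 0)
  # combined >= stated, with equality when no CVa
  r <- reference_change_value(0.5, 0.1)
  expect_gt(r$rcv_combined, r$rcv_stated)
  r0 <- reference_change_value(0.5)
  expect_equal(r0$rcv_combined, r0$rcv_stated)
  # monotone nondecreasing in both arguments
  grid <- expand.grid(cvi = c(0, 0.2, 0.5, 1), cva = c(0, 0.05, 0.2))
  vals <- mapply(function(i, a) reference_change_value(i, a)$rcv_combined,
                 grid$cvi, grid$cva)
  for (j in seq_len(nrow(grid))) {
    for (l in seq_len(nrow(grid))) {
      if (grid$cvi[j] >= grid$cvi[l] && grid$cva[j] >= grid$cva[l]) {
        expect_gte(vals[j], vals[l])
      }
    }
  }
})

test_that("the 0.6 rule types reference intervals with a population boundary", {
  expect_equal(decide_ri_type(0.57), "subject")
  expect_equal(decide_ri_type(0.60), "population")
  expect_equal(decide_ri_type(10), "population")
  expect_error(decide_ri_type(-0.1))
})

test_that("a Gaussian repeat-sampling design recovers its generating CVs", {
  # AST-like truth: mean 64.7, CVi 33%, CVg 56%; 70 animals x 4 samples
  cfg <- gaussian_config(mean = 64.7, sd_between = 0.56 * 64.7,
                         sd_within = 0.33 * 64.7, n_single = 0L,
                         repeat_groups = c(`4` = 70L), seed = 21)
  est <- estimate_cvs(simulate_dataset(cfg), "ast")
  expect_lt(abs(est$cv_i - 0.33) / 0.33, 0.15)
  expect_equal(est$n_animals, 70)
  expect_equal(est$n_samples, 280)
})

test_that("the panel-wide table wires CVa, both index variants, and typing together", {
  d <- simulate_dataset(default_study_config(seed = 3))
  vc <- suppressWarnings(variance_components(apply_inclusion(d)))
  expect_true(all(vc$cv_i >= 0) && all(vc$cv_g >= 0))
  expect_true(all(vc$ri_type %in% c("subject", "population")))
  expect_true(all(vc$rcv_combined >= vc$rcv_stated))
  # CVa flows in from the panel for leukocyte analytes only
  expect_equal(vc$cv_a[vc$analyte == "wbc"], 0.082)
  expect_true(is.na(vc$cv_a[vc$analyte == "ast"]))
  # without a CVa the two index variants agree
  noa <- is.na(vc$cv_a)
  expect_equal(vc$index_with_cva[noa], vc$index_without_cva[noa])
})
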