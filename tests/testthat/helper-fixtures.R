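# Small hand-built sample table used across datamodel/screening tests.
tiny_samples <- function() {
  data.frame(
    animal_id = c("t1", "t1", "t2"),
    date = c("2017-05-10", "2017-06-20", "2018-07-01"),
    site = c("SBCP", "SBCP", "IBSP"),
    sex = c("female", "female", "male"),
    age_class = c("adult", "adult", "juvenile"),
    exam_abnormal = c(FALSE, FALSE, FALSE),
    sample_quality_poor = c(FALSE, FALSE, FALSE),
    pcv = c(18, 20, 15),
    ast = c(60, NA, 80),
    stringsAsFactors = FALSE
  )
}

tiny_panel <- function() {
  rbind(analyte_definition("pcv", "%"),
        analyte_definition("ast", "U/L"))
}

# One-analyte Gaussian simulation config with explicit variance structure.
gaussian_config <- function(mean = 64.7, sd_between = 36.2, sd_within = 21.4,
                            n_single = 0L, repeat_groups = c(`3` = 70L),
                            nonnegative = FALSE, floor = NA_real_,
                            effects = NULL, seed = 1L,
                            family = "gaussian") {
  simulation_config(
    analytes = data.frame(analyte = "ast", mean = mean,
                          sd_between = sd_between, sd_within = sd_within,
                          family = family, nonnegative = nonnegative,
                          floor = floor, missing_rate = 0,
                          stringsAsFactors = FALSE),
    n_single = n_single,
    repeat_groups = repeat_groups,
    demographics = list(
      site = c(SBCP = 0.5, IBSP = 0.5),
      sex = c(female = 0.5, male = 0.5),
      age_class = c(adult = 0.6, subadult = 0.2, juvenile = 0.2),
      month = c(May = 0.4, June = 0.4, July = 0.2),
      year = c(`2017` = 0.5, `2018` = 0.5)
    ),
    effects = effects,
    seed = seed
  )
}

# Build a dataset directly from per-group value vectors (one factor).
grouped_dataset <- function(groups, factor = "site", analyte = "pcv") {
  n <- sum(lengths(groups))
  df <- data.frame(
    animal_id = sprintf("g%04d", seq_len(n)),
    date = "2017-06-01",
    site = "S", sex = "female", age_class = "adult",
    stringsAsFactors = FALSE
  )
  df[[factor]] <- rep(names(groups), lengths(groups))
  df[[analyte]] <- unlist(groups, use.names = FALSE)
  new_dataset(df, rbind(analyte_definition(analyte, nonnegative = FALSE)))
}
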