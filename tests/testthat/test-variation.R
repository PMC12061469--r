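test_that("cv_percent matches hand computation and rejects degenerates", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(10, 12, 14)), 100 * 2 / 12)  # 16.667%
  expect_error(cv_percent(c(3)), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "mean is zero")
})

test_that("classification uses the printed thresholds and boundaries", {
  expect_equal(classify_cv(0.8), "static")
  expect_equal(classify_cv(10.4), "intermediate")
  expect_equal(classify_cv(5.0), "intermediate")
  expect_equal(classify_cv(12.0), "intermediate")
  expect_equal(classify_cv(12.000001), "dynamic")
  expect_equal(classify_cv(4.999999), "static")
  expect_error(classify_cv(-1), "non-negative")

  # partition property: every non-negative value gets exactly one label
  set.seed(1)
  for (cv in c(0, runif(50, 0, 30))) {
    lab <- classify_cv(cv)
    expect_true(lab %in% c("static", "intermediate", "dynamic"))
    expect_equal(lab, if (cv < 5) "static" else if (cv <= 12)
      "intermediate" else "dynamic")
  }
})

test_that("multilevel_cv equals the brute-force oracle on the tiny table", {
  tab <- tiny_table()
  got <- multilevel_cv(tab)$p
  want <- oracle_multilevel(tab, "p")
  expect_equal(unname(got$cv_i), unname(want$cv_i))
  expect_equal(sort(unname(got$cv_p)), sort(unname(want$cv_p)))
  expect_equal(sort(unname(got$cv_g)), sort(unname(want$cv_g)))
  expect_equal(got$cv_o, want$cv_o)
})

test_that("multilevel_cv handles identical calls and degenerate units", {
  tab <- tiny_table()
  # identical within individuals, distinct across: cv_i = 0, cv_o > 0
  tab$value <- rep(c(10, 14, 20, 26, 30, 38, 44, 50), each = 2)
  got <- multilevel_cv(tab)$p
  expect_true(all(got$cv_i == 0))
  expect_gt(got$cv_o, 0)

  # a locality with one individual: its CV is NA, with warning
  tab2 <- tiny_table()
  tab2 <- tab2[tab2$individual_id != "a2", ]
  expect_warning(got2 <- multilevel_cv(tab2)$p, "locality")
  expect_true(is.na(got2$cv_p["A"]))
  expect_false(anyNA(got2$cv_g))
})

test_that("every CV level and ratio is scale invariant", {
  tab <- tiny_table()
  g1 <- multilevel_cv(tab)$p
  tab2 <- tab; tab2$value <- tab$value * 37.3
  g2 <- multilevel_cv(tab2)$p
  expect_equal(g1$cv_i, g2$cv_i)
  expect_equal(g1$cv_p, g2$cv_p)
  expect_equal(g1$cv_g, g2$cv_g)
  expect_equal(g1$cv_o, g2$cv_o)
  r1 <- discriminability_ratio(g1$cv_o, mean(g1$cv_i), mean(g1$cv_g))
  r2 <- discriminability_ratio(g2$cv_o, mean(g2$cv_i), mean(g2$cv_g))
  expect_equal(r1, r2)
})

test_that("discriminability ratios divide the right quantities", {
  r <- discriminability_ratio(20, 5, 10)
  expect_equal(r$ratio_o_over_i, 4)
  expect_equal(r$ratio_o_over_g, 2)
  expect_warning(r0 <- discriminability_ratio(20, 0, 10), "denominator")
  expect_true(is.na(r0$ratio_o_over_i))
})

test_that("model2_anova matches hand sums of squares and stats::aov", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  got <- model2_anova(v, g)
  expect_equal(got$F, 13.5)
  expect_equal(got$eta_squared, 13.5 / 17.5)
  want <- oracle_anova(v, g)
  expect_equal(got$p, want$p)

  # against R's own ANOVA on an unbalanced random case
  set.seed(21)
  v2 <- rnorm(20); g2 <- sample(c("a", "b", "c"), 20, replace = TRUE)
  got2 <- model2_anova(v2, g2)
  ref <- anova(lm(v2 ~ g2))
  expect_equal(got2$F, ref$`F value`[1])
  expect_equal(got2$p, ref$`Pr(>F)`[1])

  # identical groups degenerate to eta^2 = 0, p = 1
  expect_warning(gz <- model2_anova(rep(2, 6), g), "zero total variance")
  expect_equal(gz$eta_squared, 0)
  expect_equal(gz$p, 1)

  expect_error(model2_anova(1:4, c("a", "a", "a", "b")), ">= 2 individuals")
})

test_that("two-group eta^2 equals squared point-biserial correlation", {
  set.seed(5)
  for (i in 1:5) {
    v <- rnorm(24, mean = rep(c(0, 0.8), each = 12))
    g <- rep(c("a", "b"), each = 12)
    e <- model2_anova(v, g)$eta_squared
    expect_equal(e, cor(v, as.numeric(factor(g)))^2)
  }
})

test_that("variation_summary reproduces all pieces coherently", {
  tab <- tiny_table()
  vs <- variation_summary(tab)
  expect_equal(nrow(vs), 1)
  want <- oracle_multilevel(tab, "p")
  expect_equal(vs$cv_i_mean, mean(want$cv_i))
  expect_equal(vs$cv_o, want$cv_o)
  expect_equal(vs$ratio_o_over_i, want$cv_o / mean(want$cv_i))
  expect_equal(vs$ratio_o_over_g, want$cv_o / mean(want$cv_g))
  im <- sapply(split(tab$value, tab$individual_id), mean)
  an <- oracle_anova(im, rep(c("G1", "G2"), each = 4))
  expect_equal(vs$eta_squared, an$eta_squared)
  expect_equal(vs$anova_p, an$p)
  expect_equal(vs$classification, classify_cv(vs$cv_i_mean))
})

test_that("synthetic tables recover configured variance components", {
  # 200 individuals in one locality pool: CV_i ~ 0.8%, CV_o ~ 15.1%
  loc <- data.frame(group = c("NE", "SW"), locality = c("L1", "L2"),
                    longitude = c(110, 109.5), latitude = c(19.9, 18.5),
                    temperature_c = c(27.6, 27.6), n_males = c(100L, 100L))
  pars <- data.frame(parameter = "dominant_frequency_hz",
                     mean_ne = 3416, mean_sw = 3416,
                     sd_locality = 0, sd_individual = 0.151 * 3416,
                     sd_within = 0.008 * 3416, slope_b = 0, exempt = FALSE)
  cfg <- population_config(loc, pars, calls_per_individual = 5, seed = 42)
  sim <- generate_parameter_table(cfg)
  ml <- multilevel_cv(sim$table)$dominant_frequency_hz
  expect_lt(abs(mean(ml$cv_i) - 0.8) / 0.8, 0.10)
  expect_lt(abs(ml$cv_o - 15.1) / 15.1, 0.10)
})
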