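# Scoring engine: measurement scoring, fish averaging, module grades,
# categories, calibration.

test_that("scoring a measurement composes interval resolution and weight lookup", {
  cfg <- tiny_config()
  p <- cfg$parameters$w_temp
  set.seed(3)
  for (v in runif(50, 6, 40)) {
    s <- score_measurement(v, p)
    iv <- p$intervals[p$intervals$index == oracle_scan_interval(p, v), ]
    expect_equal(s$effective_PS, iv$PS)
    expect_equal(s$effective_SW, iv$SW)
    expect_equal(s$PW, p$PW)
  }
  # an all-healthy organ finding sits in the optimal interval
  fi <- default_model_config()$parameters$fi_heart
  s <- score_measurement(0, fi)
  expect_equal(s$effective_PS, 0)
  expect_equal(s$effective_SW, 1)
  # missing values yield the missing-marker, not a score
  expect_null(score_measurement(NA, p))
  expect_null(score_measurement("NA", p))
})

test_that("per-fish scores average arithmetically", {
  rows <- scored_df(rep("fe_gills", 5), "FE", PS = rep(-0.5, 5),
                    SW = rep(2, 5), PW = 3)
  avg <- average_fish_scores(rows)
  expect_equal(avg$effective_PS, -0.5)
  expect_equal(avg$n_fish_averaged, 5L)

  two <- scored_df(c("fe_gills", "fe_gills"), "FE", PS = c(0, -1),
                   SW = c(1, 5), PW = 3)
  expect_warning(avg2 <- average_fish_scores(two), "fewer than three")
  expect_equal(avg2$effective_PS, -0.5)
  expect_equal(avg2$effective_SW, 3)

  set.seed(8)
  for (rep_i in 1:20) {
    n <- sample(3:10, 1)
    ps <- -runif(n); sw <- sample(1:5, n, TRUE)
    got <- average_fish_scores(scored_df(rep("p", n), "FE", ps, sw, 4))
    expect_equal(got$effective_PS, sum(ps) / n)
    expect_equal(got$effective_SW, sum(sw) / n)
  }
  expect_error(average_fish_scores(random_scored(3)[0, ]), "empty")
})

test_that("module grade hits its exact boundary values", {
  mod <- module_def("W", "water")
  all_good <- scored_df(letters[1:6], "W", PS = rep(0, 6),
                        SW = sample(1:5, 6, TRUE), PW = sample(1:5, 6, TRUE))
  expect_identical(module_grade(all_good, mod)$grade, 1)
  all_bad <- scored_df(letters[1:6], "W", PS = rep(-1, 6),
                       SW = sample(1:5, 6, TRUE), PW = sample(1:5, 6, TRUE))
  expect_identical(module_grade(all_bad, mod)$grade, 0)
  expect_error(module_grade(all_bad[0, ], mod), "no measured parameters")
})

test_that("module grade equals the direct equation oracle on 500 random sets", {
  set.seed(123)
  for (i in 1:500) {
    n <- sample(1:25, 1)
    sc <- random_scored(n)
    swe <- runif(1, 0, 2.5); pwe <- runif(1, 0, 2.5)
    mod <- module_def("W", "water", SWE = swe, PWE = pwe)
    got <- module_grade(sc, mod)$grade
    want <- oracle_module_grade(sc$effective_PS, sc$effective_SW, sc$PW,
                                swe, pwe)
    expect_true(abs(got - want) <= 1e-12 * max(1, abs(want)))
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("grades are invariant to duplication and to missing-parameter removal", {
  set.seed(21)
  mod <- module_def("FG", "behaviour")
  for (i in 1:25) {
    sc <- random_scored(sample(2:15, 1), "FG")
    g <- module_grade(sc, mod)$grade
    expect_equal(module_grade(rbind(sc, sc), mod)$grade, g)
    # adding a parameter whose (1 + PS) equals the grade leaves it unchanged
    neutral <- scored_df("neutral", "FG", PS = g - 1,
                         SW = sample(1:5, 1), PW = sample(1:5, 1))
    expect_equal(module_grade(rbind(sc, neutral), mod)$grade, g)
  }
})

test_that("management module grades ignore score weights (SWE = 0)", {
  set.seed(5)
  mod_m <- module_def("M", "management")
  expect_equal(mod_m$SWE, 0)
  for (i in 1:25) {
    sc <- random_scored(sample(2:18, 1), "M")
    g1 <- module_grade(sc, mod_m)$grade
    sc$effective_SW <- sample(1:5, nrow(sc), TRUE)
    expect_equal(module_grade(sc, mod_m)$grade, g1)
  }
})

test_that("degrading a parameter lowers the grade in the provable regimes", {
  # With severity-increasing score weights, a weighted mean is strictly
  # monotone when either the weight is unchanged or the degraded score
  # does not exceed the mean of the remaining parameters.
  set.seed(77)
  mod <- module_def("W", "water")
  for (i in 1:200) {
    sc <- random_scored(sample(2:20, 1))
    j <- sample(nrow(sc), 1)
    g0 <- module_grade(sc, mod)$grade
    others <- sc[-j, , drop = FALSE]
    w_o <- others$effective_SW^mod$SWE * others$PW^mod$PWE
    mean_others <- sum(others$effective_PS * w_o) / sum(w_o)
    old_ps <- sc$effective_PS[j]
    if (i %% 2 == 0) {
      # same weight, strictly lower score
      sc$effective_PS[j] <- max(-1, old_ps - runif(1, 0.01, 0.3))
    } else {
      # heavier weight, score dropped to or below the rest's mean
      sc$effective_PS[j] <- max(-1, min(old_ps - 0.01,
                                        mean_others - runif(1, 0.01, 0.2)))
      sc$effective_SW[j] <- 5
    }
    if (sc$effective_PS[j] >= old_ps) next  # was already at the floor
    expect_lt(module_grade(sc, mod)$grade, g0)
  }
})

test_that("grade categories follow the published bracket boundaries", {
  expect_equal(categorize(0.31), "poor")
  expect_equal(categorize(c(0, 0.2499)), c("critical", "critical"))
  expect_equal(categorize(0.25), "poor")
  expect_equal(categorize(0.5), "acceptable")
  expect_equal(categorize(0.7499999), "acceptable")
  expect_equal(categorize(0.75), "good")
  expect_equal(categorize(1), "good")
  expect_error(categorize(1.2), "\\[0, 1\\]")
  expect_error(categorize(-0.01), "\\[0, 1\\]")
})

test_that("assessing a farm grades modules independently and honours NA", {
  cfg <- default_model_config()
  g <- assess(load_farm_fixture(2), cfg)
  expect_equal(g$FI$grade_rounded, 1)
  expect_equal(g$FI$category, "good")
  expect_equal(g$M$n_missing, 1L)  # predator protection indoors

  # only module W measured -> exactly one result
  a <- assessment(data.frame(parameter_id = "w_temperature", value = "12"))
  g1 <- assess(a, cfg)
  expect_named(g1, "W")

  # per-fish replicates average to the same grade as their mean score
  fish <- assessment(data.frame(
    parameter_id = rep("fi_gill_lamellae", 5), value = c(0, 0, 1, 1, 2),
    fish_index = 1:5))
  g2 <- assess(fish, cfg)
  p <- cfg$parameters$fi_gill_lamellae
  mean_ps <- mean(p$intervals$PS[match(c(0, 0, 1, 1, 2),
                                       p$intervals$index)])
  expect_equal(g2$FI$grade, 1 + mean_ps)
  expect_equal(g2$FI$scored$n_fish_averaged, 5L)

  expect_error(assess(assessment(data.frame(parameter_id = "bogus",
                                            value = "1")), cfg),
               "unknown")
})

test_that("exponent calibration recovers the published value on boundary sets", {
  grid <- seq(1.0, 2.5, by = 0.1)
  # needs-critical set turns critical only for exponents above ~1.65;
  # needs-poor set stays poor only for exponents below ~1.75: only 1.7 fits
  sets <- list(boundary_dataset(1.65, "critical"),
               boundary_dataset(1.75, "poor"))
  fit <- calibrate_exponents(sets, grid)
  expect_equal(fit$exponent, 1.7)
  expect_equal(fit$misclassified, 0L)

  # a dataset satisfied everywhere ties -> smallest grid value wins
  easy <- list(list(scored = scored_df("a", "CAL", PS = 0, SW = 1, PW = 3),
                    target = "good"))
  expect_equal(calibrate_exponents(easy, grid)$exponent, 1)

  # winner does not depend on grid order
  fit2 <- calibrate_exponents(sets, sample(grid))
  expect_equal(fit2$exponent, fit$exponent)
  expect_error(calibrate_exponents(list(), grid), "empty")
})
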