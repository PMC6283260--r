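make_brain_fixture <- function(n = 400, seed = 22) {
  set.seed(seed)
  cov <- data.frame(age = rnorm(n, 75, 7), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 16, 3), icv = rnorm(n, 1500, 100))
  m <- cbind(
    thick_icv = cov$icv / 100 + rnorm(n),        # thickness tracking ICV
    vol_age = 2 * cov$age + rnorm(n),            # volume driven by age
    area_noise = rnorm(n))
  rownames(m) <- sprintf("S%03d", seq_len(n))
  ft <- feature_table(m, c("brain_thickness", "brain_volume", "brain_area"))
  list(ft = ft, cov = cov)
}

test_that("residualization removes fitted covariates exactly", {
  fx <- make_brain_fixture()
  res <- residualize(fx$ft, fx$cov)
  r <- ft_data(res)
  expect_lt(abs(cor(r[, "vol_age"], fx$cov$age)), 1e-10)
  # area/volume are ICV-adjusted, thickness is not
  expect_lt(abs(cor(r[, "area_noise"], fx$cov$icv)), 1e-10)
  expect_gt(abs(cor(r[, "thick_icv"], fx$cov$icv)), 0.5)
  # pure-noise feature keeps its scale
  expect_equal(sd(r[, "area_noise"]), sd(ft_data(fx$ft)[, "area_noise"]),
               tolerance = 0.05)
})

test_that("residualization is idempotent and refuses missing covariates", {
  fx <- make_brain_fixture(seed = 23)
  res1 <- residualize(fx$ft, fx$cov)
  res2 <- residualize(res1, fx$cov)
  expect_lt(max(abs(ft_data(res2) - ft_data(res1))), 1e-8)
  expect_error(residualize(fx$ft, fx$cov[, c("age", "sex", "education")]),
               "icv")
  expect_error(residualize(fx$ft, transform(fx$cov, age = replace(age, 1, NA))),
               "missing values")
})

test_that("stored coefficients reproduce the residuals on new subjects", {
  fx <- make_brain_fixture(seed = 24)
  res <- residualize(fx$ft, fx$cov)
  res_applied <- residualize(fx$ft, fx$cov,
                             coefficients = attr(res, "coefficients"))
  expect_equal(ft_data(res_applied), ft_data(res), tolerance = 1e-12)
})

test_that("the cognitive composite follows the stated sign and anchoring rules", {
  # 3 subjects; subject 2 sits exactly at every baseline mean
  mmse <- data.frame(baseline = c(28, 29, 30), followup = c(28, 29, 30))
  adas <- data.frame(baseline = c(10, 20, 30), followup = c(10, 20, 30))
  cdr <- data.frame(baseline = c(0, 2, 4), followup = c(0, 2, 4))
  comp <- cognitive_composite(mmse, adas, cdr)
  expect_equal(comp$baseline_z[2], 0, tolerance = 1e-12)
  expect_equal(comp$delta, rep(0, 3), tolerance = 1e-12)      # follow-up == baseline
  expect_equal(mean(comp$baseline_z), 0, tolerance = 1e-9)
  expect_equal(sd(comp$baseline_z), 1, tolerance = 1e-9)
  # a raw ADAS increase (worsening) lowers the composite
  adas2 <- data.frame(baseline = adas$baseline,
                      followup = adas$followup + c(0, 8, 0))
  comp2 <- cognitive_composite(mmse, adas2, cdr)
  expect_lt(comp2$delta[2], 0)
  expect_equal(comp2$delta[c(1, 3)], c(0, 0), tolerance = 1e-12)
})

test_that("the composite is invariant to affine rescaling of one test", {
  set.seed(25)
  mmse <- data.frame(baseline = rnorm(50, 27, 2), followup = rnorm(50, 26, 2))
  adas <- data.frame(baseline = rnorm(50, 18, 6), followup = rnorm(50, 20, 6))
  cdr <- data.frame(baseline = rnorm(50, 2, 1), followup = rnorm(50, 2.5, 1))
  base <- cognitive_composite(mmse, adas, cdr)
  resc <- cognitive_composite(mmse, adas * 3.7 + 11, cdr)
  expect_equal(resc$baseline_z, base$baseline_z, tolerance = 1e-9)
  expect_equal(resc$delta, base$delta, tolerance = 1e-9)
})

test_that("degenerate composite inputs raise errors", {
  flat <- data.frame(baseline = rep(5, 4), followup = 1:4)
  ok <- data.frame(baseline = c(1, 2, 3, 4), followup = c(1, 2, 3, 4))
  expect_error(cognitive_composite(flat, ok, ok), "zero baseline SD")
  expect_error(cognitive_composite(ok[1:3, ], ok, ok), "same subjects")
})

test_that("trajectory groups follow the stated rules", {
  visits <- rbind(
    data.frame(subject = "p1", visit_month = c(0, 6, 12), diagnosis = c("MCI", "MCI", "AD")),
    data.frame(subject = "p2", visit_month = c(0, 6, 12), diagnosis = c("MCI", "CN", "MCI")),
    data.frame(subject = "p3", visit_month = c(0, 6, 12), diagnosis = c("CN", "CN", "CN")),
    data.frame(subject = "p4", visit_month = c(0, 6), diagnosis = c("CN", "CN")),
    data.frame(subject = "p5", visit_month = 0, diagnosis = "AD"),
    data.frame(subject = "p6", visit_month = c(0, 6, 18), diagnosis = c("CN", "CN", "AD")))
  g <- assign_groups(diagnostic_ledger(visits))
  got <- setNames(g$group, g$subject)
  expect_identical(got[["p1"]], "MCI-p")
  expect_identical(got[["p2"]], "excluded-reverter")
  expect_identical(got[["p3"]], "CN-s")
  expect_identical(got[["p4"]], "excluded-short")   # < 12 months, no progression
  expect_identical(got[["p5"]], "AD-baseline")
  expect_identical(got[["p6"]], "CN-p")
  # the assignment is a partition: exactly one group per subject
  expect_identical(nrow(g), 6L)
  # contrasts: reverters drop from 1-2; everyone enters 3 by AD-ever status
  y1 <- contrast_outcome(g, 1)
  expect_setequal(names(y1), c("p1", "p3", "p6"))
  expect_identical(unname(y1[c("p3", "p1", "p6")]), c(0L, 1L, 1L))
  y2 <- contrast_outcome(g, 2)
  expect_false("p2" %in% names(y2))
  y3 <- contrast_outcome(g, 3)
  expect_identical(length(y3), 6L)
  expect_identical(unname(y3[c("p1", "p2", "p5", "p4")]), c(1L, 0L, 1L, 0L))
  expect_error(diagnostic_ledger(data.frame(subject = "a", visit_month = 0,
                                            diagnosis = "XX")), "unknown diagnosis")
})

test_that("prevalence arithmetic reproduces the worked example", {
  g <- data.frame(group = rep(c("CN-p", "MCI-p", "CN-s", "MCI-s"),
                              c(22, 211, 165, 147)),
                  followup_months = 52.5)
  out <- prevalence_stats(g)
  expect_identical(unname(out["prevalence_pct"]), 42.8)
  expect_identical(unname(out["annual_conversion_pct"]), 9.8)
  # zero progressors
  g0 <- data.frame(group = rep(c("CN-s", "MCI-s"), c(5, 5)), followup_months = 24)
  expect_identical(unname(prevalence_stats(g0)), c(0, 0))
  expect_error(prevalence_stats(data.frame(group = "AD-baseline",
                                           followup_months = 12)), "no stable")
})
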