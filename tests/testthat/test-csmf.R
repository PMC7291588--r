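test_that("weighted CSMF reproduces hand-computed weighted proportions", {
  rs <- make_iid_recordset(c("sepsis", "sepsis", "sepsis", "pneumonia"),
                           rep("community", 4))
  v <- weighted_csmf(rs)
  expect_equal(v[["sepsis"]], 0.75)
  expect_equal(v[["pneumonia"]], 0.25)
  expect_equal(sum(v), 1)
  expect_equal(as.numeric(v[!names(v) %in% c("sepsis", "pneumonia")]),
               rep(0, 8))

  rs2 <- make_iid_recordset(c("malaria", "malaria", "diarrhea"),
                            rep("facility", 3), age_group = "child",
                            weight = c(1, 1, 2))
  v2 <- weighted_csmf(rs2, "facility")
  expect_equal(v2[["malaria"]], 0.5)
  expect_equal(v2[["diarrhea"]], 0.5)
  expect_error(weighted_csmf(rs2, "community"), "empty subset")
})

test_that("weighted CSMF is invariant to rescaling all weights", {
  rs <- generate_study(divergent_scenario(300), seed = 8)
  v1 <- weighted_csmf(rs, "facility")
  rs$weight <- rs$weight * 13.7
  v2 <- weighted_csmf(rs, "facility")
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
})

test_that("large-sample CSMF estimates recover the preset generative fractions", {
  cfg <- preset_scenario("cameroon", "neonate", "eava", n_deaths = 20000)
  rs <- generate_study(cfg, seed = 10)
  pop <- weighted_csmf(rs)
  # population CSMF targets the printed proportions; BA/BI 0.372
  expect_equal(pop[["birth_asphyxia_injury"]],
               cfg$population_csmf[["birth_asphyxia_injury"]],
               tolerance = 0.035)
  tq <- true_quantities(cfg)
  expect_lt(sum(abs(as.numeric(weighted_csmf(rs, "facility")) -
                      as.numeric(tq$facility_csmf))), 0.06)
})

test_that("CSMF accuracy matches its closed form, bounds and monotonicity", {
  u <- rep(0.1, 10)
  expect_identical(csmf_accuracy(u, u), 1)
  ref <- c(0.5, 0.3, 0.2)
  expect_identical(csmf_accuracy(c(0, 0, 1), ref), 0)
  expect_equal(csmf_accuracy(c(0.6, 0.2, 0.2), ref), 0.875, tolerance = 1e-12)
  # accuracy 1 iff identical
  set.seed(42)
  for (i in 1:20) {
    p <- as.numeric(stats::rmultinom(1, 50, rep(1, 6))) / 50
    q <- as.numeric(stats::rmultinom(1, 50, rep(1, 6))) / 50
    a <- csmf_accuracy(p, q)
    expect_true(a >= 0 && a <= 1)
    if (max(abs(p - q)) > 1e-12) expect_lt(a, 1) else expect_equal(a, 1)
  }
  # non-increasing along a ray moving away from ref
  dir <- c(0.3, -0.1, -0.2)
  accs <- vapply(seq(0, 1, 0.1), function(t)
    csmf_accuracy(ref + t * dir, ref), numeric(1))
  expect_true(all(diff(accs) <= 1e-12))
  expect_error(csmf_accuracy(c(0.5, 0.5), ref), "lengths differ")
})

test_that("PSU bootstrap is seed-reproducible and respects the statistic's range", {
  rs <- generate_study(divergent_scenario(400), seed = 5)
  b1 <- csmf_accuracy_ci(rs, n_boot = 50, seed = 99)
  b2 <- csmf_accuracy_ci(rs, n_boot = 50, seed = 99)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(c(b1$lower, b1$upper), c(b2$lower, b2$upper))
  expect_lte(b1$lower, b1$upper)
  expect_true(all(b1$replicates >= 0 & b1$replicates <= 1))

  # constant statistic collapses the interval
  cb <- psu_bootstrap(rs, function(r) 0.5, n_boot = 20, seed = 1)
  expect_equal(c(cb$lower, cb$estimate, cb$upper), c(0.5, 0.5, 0.5))

  # single-PSU stratum is a design error naming the stratum
  rs_bad <- rs
  rs_bad$psu_id[rs_bad$stratum_id == "s01"] <- "s01_p01"
  rs_bad <- va_recordset(as.data.frame(rs_bad), "neonate", "weighted_clustered")
  expect_error(psu_bootstrap(rs_bad, function(r) 1, n_boot = 5, seed = 1),
               "s01")
})

test_that("facility CSMF accuracy has sensible extremes", {
  # identical cause laws, large n: accuracy near 1
  rs <- generate_study(null_scenario(4000), seed = 6)
  est <- csmf_accuracy_ci(rs, n_boot = 50, seed = 2)
  expect_gt(est$estimate, 0.9)
  expect_gte(est$upper, est$estimate - 1e-12)

  # all facility deaths on a community minimum-fraction (zero) cause:
  # disjoint support attains the statistic's lower bound
  causes <- c(rep("sepsis", 30), rep("pneumonia", 20), rep("tetanus", 10))
  places <- c(rep("community", 50), rep("facility", 10))
  rs2 <- make_iid_recordset(causes, places)
  expect_equal(csmf_accuracy(weighted_csmf(rs2, "facility"),
                             weighted_csmf(rs2, "community")), 0)
})
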