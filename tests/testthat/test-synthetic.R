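test_that("study generation is deterministic given a seed and obeys the place model", {
  cfg <- null_scenario(200)
  r1 <- generate_study(cfg, seed = 42)
  r2 <- generate_study(cfg, seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- generate_study(cfg, seed = 43)
  expect_false(identical(r1$cause, r3$cause))

  all_fac <- scenario_config("neonate", n_deaths = 100,
                             cause_baseline_facility = rep(0.1, 10),
                             cause_baseline_community = rep(0.1, 10),
                             place_intercept = 30)
  rs <- generate_study(all_fac, seed = 1)
  expect_true(all(rs$place_class == "facility"))
  expect_true(all(rs$raw_place == "hospital"))
})

test_that("generated record sets pass validation and re-validate cleanly", {
  cfg <- preset_scenario("nigeria", "child", "pcva", n_deaths = 300)
  rs <- generate_study(cfg, seed = 2)
  expect_s3_class(rs, "va_recordset")
  rs2 <- va_recordset(as.data.frame(rs)[, record_columns_for_tests()],
                      "child", "weighted_clustered")
  expect_equal(rs2$place_class, rs$place_class)
  expect_true(all(rs$weight >= 0.2 & rs$weight <= 5))
})

test_that("invalid scenario configurations are rejected with itemized problems", {
  expect_error(scenario_config("neonate", n_deaths = 10,
                               cause_baseline_facility = rep(0.1, 10),
                               cause_baseline_community = c(0.5, 0.6, rep(0, 8))),
               "community baseline")
  expect_error(scenario_config("neonate", n_deaths = -5,
                               cause_baseline_facility = rep(0.1, 10),
                               cause_baseline_community = rep(0.1, 10)),
               "n_deaths")
  expect_error(scenario_config("neonate", n_deaths = 10,
                               cause_baseline_facility = rep(0.1, 10),
                               cause_baseline_community = rep(0.1, 10),
                               place_coefs = list(household_size = c(a = 1))),
               "unknown covariate")
})

test_that("true_quantities matches closed forms and the mixture identity", {
  # no covariate effects: true facility CSMF equals its baseline
  f <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05, 0.04, 0.03, 0.03)
  cm <- rep(0.1, 10)
  cfg <- scenario_config("neonate", n_deaths = 10,
                         cause_baseline_facility = f,
                         cause_baseline_community = cm,
                         place_intercept = 0)
  tq <- true_quantities(cfg)
  expect_equal(as.numeric(tq$facility_csmf), f, tolerance = 1e-12)
  expect_equal(as.numeric(tq$community_csmf), cm, tolerance = 1e-12)
  # intercept-only odds 1: p_facility = 0.5
  expect_equal(tq$p_facility, 0.5, tolerance = 1e-12)

  # mixture identity under covariate-dependent place and cause models
  cfg2 <- birthplace_scenario(10)
  tq2 <- true_quantities(cfg2)
  mix <- tq2$p_facility * as.numeric(tq2$facility_csmf) +
    (1 - tq2$p_facility) * as.numeric(tq2$community_csmf)
  expect_equal(as.numeric(tq2$population_csmf), mix, tolerance = 1e-9)
})

test_that("empirical weighted CSMFs converge to the enumerated truth", {
  cfg <- birthplace_scenario(100000)
  rs <- generate_study(cfg, seed = 3)
  tq <- true_quantities(cfg)
  expect_lt(sum(abs(as.numeric(weighted_csmf(rs, "community")) -
                      as.numeric(tq$community_csmf))), 0.02)
  expect_lt(sum(abs(as.numeric(weighted_csmf(rs, "facility")) -
                      as.numeric(tq$facility_csmf))), 0.02)
  expect_lt(abs(facility_share(rs) - tq$p_facility), 0.01)
})

test_that("country presets hit their published population CSMFs and facility shares", {
  for (country in c("cameroon", "malawi", "niger", "nigeria")) {
    cfg <- preset_scenario(country, "neonate", "eava")
    tq <- true_quantities(cfg)
    expect_equal(tq$p_facility, cfg$target_facility_share, tolerance = 1e-6,
                 info = country)
    expect_equal(as.numeric(tq$population_csmf),
                 as.numeric(cfg$population_csmf), tolerance = 1e-9,
                 info = country)
    expect_s3_class(cfg$cause_baseline_facility, "csmf")
    expect_s3_class(cfg$cause_baseline_community, "csmf")
  }
  niger <- preset_scenario("niger", "neonate", "eava")
  expect_lt(abs(true_quantities(niger)$p_facility - 0.19), 0.02)
  cam <- preset_scenario("cameroon", "neonate", "eava")
  expect_equal(cam$population_csmf[["birth_asphyxia_injury"]], 0.372,
               tolerance = 2e-3)
  expect_equal(attr(cam, "class"), "scenario_config")
  expect_identical(cam$design_mode, "unweighted")
  # child presets validate too
  for (country in c("cameroon", "malawi", "niger", "nigeria")) {
    cfgc <- preset_scenario(country, "child", "pcva")
    expect_s3_class(cfgc$cause_baseline_community, "csmf")
  }
})

test_that("removing all covariate effects makes place-specific cause laws identical", {
  v <- c(0.04, 0.05, 0.20, 0.06, 0.07, 0.18, 0.20, 0.06, 0.06, 0.08)
  cfg <- scenario_config("neonate", n_deaths = 30000,
                         cause_baseline_facility = v,
                         cause_baseline_community = v,
                         place_intercept = -0.5)
  rs <- generate_study(cfg, seed = 8)
  acc <- csmf_accuracy(weighted_csmf(rs, "facility"),
                       weighted_csmf(rs, "community"))
  expect_gt(acc, 0.95)
})
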