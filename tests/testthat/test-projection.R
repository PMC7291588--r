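test_that("projection A substitutes the facility distribution and scores it correctly", {
  # identical facility and community CSMFs: accuracy 1
  causes <- rep(c("sepsis", "pneumonia"), times = c(30, 10))
  rs <- make_iid_recordset(c(causes, causes),
                           rep(c("community", "facility"), each = 40))
  pa <- project_csmf(rs, "A", n_boot = 0)
  expect_equal(pa$accuracy, 1)
  expect_equal(as.numeric(pa$predicted_community_csmf),
               as.numeric(pa$facility_csmf))

  # closed form on generative vectors, large n
  cfg <- divergent_scenario(20000)
  rs2 <- generate_study(cfg, seed = 21)
  tq <- true_quantities(cfg)
  f <- as.numeric(tq$facility_csmf); cm <- as.numeric(tq$community_csmf)
  w <- tq$p_facility
  m <- w * f + (1 - w) * cm
  closed <- 1 - (1 - w) * sum(abs(f - cm)) / (2 * (1 - min(m)))
  pa2 <- project_csmf(rs2, "A", n_boot = 0)
  expect_equal(pa2$accuracy, closed, tolerance = 0.02)
})

test_that("the projection result satisfies the mixture identity", {
  rs <- generate_study(birthplace_scenario(700), seed = 9)
  for (id in c("A", "B", "E")) {
    pr <- suppressMessages(project_csmf(rs, id, n_boot = 0, seed = 4))
    mix <- pr$p_facility * as.numeric(pr$facility_csmf) +
      (1 - pr$p_facility) * as.numeric(pr$predicted_community_csmf)
    expect_equal(as.numeric(pr$predicted_population_csmf), mix,
                 tolerance = 1e-9, info = id)
    expect_equal(sum(pr$predicted_community_csmf), 1, tolerance = 1e-9)
  }
})

test_that("cause models degenerate gracefully and are deterministic given a seed", {
  rs <- make_iid_recordset(rep("sepsis", 30), rep("facility", 30))
  spec <- projection_spec("B", "neonate")
  expect_warning(mod <- fit_cause_model(rs, spec), "single-cause")
  P <- predict(mod, rs)
  expect_true(all(P[, "sepsis"] == 1))
  v <- predict_community_csmf(mod, rs)
  expect_equal(v[["sepsis"]], 1)

  rs2 <- generate_study(birthplace_scenario(600), seed = 14)
  fac <- rs2[rs2$place_class == "facility", ]
  fac_rs <- va_recordset(as.data.frame(fac)[, record_columns_for_tests()],
                         "neonate")
  spec_e <- projection_spec("E", "neonate", seed = 7)
  m1 <- fit_cause_model(fac_rs, spec_e)
  m2 <- fit_cause_model(fac_rs, spec_e)
  expect_identical(predict(m1, rs2), predict(m2, rs2))
})

test_that("model fitting and projection are invariant to record order", {
  rs <- generate_study(birthplace_scenario(500), seed = 30)
  perm <- sample(seq_len(nrow(rs)))
  rs_perm <- va_recordset(as.data.frame(rs)[perm, record_columns_for_tests()],
                          "neonate")
  for (id in c("B", "E")) {
    p1 <- suppressMessages(project_csmf(rs, id, n_boot = 0, seed = 5))
    p2 <- suppressMessages(project_csmf(rs_perm, id, n_boot = 0, seed = 5))
    expect_equal(as.numeric(p1$predicted_community_csmf),
                 as.numeric(p2$predicted_community_csmf),
                 tolerance = 1e-8, info = id)
  }
})

test_that("with covariates independent of cause, model predictions shrink to the facility CSMF", {
  cfg <- null_scenario(6000)
  rs <- generate_study(cfg, seed = 17)
  fac_csmf <- as.numeric(weighted_csmf(rs, "facility"))
  for (id in c("B", "D")) {
    pr <- suppressMessages(project_csmf(rs, id, n_boot = 0, seed = 2))
    expect_lt(sum(abs(as.numeric(pr$predicted_community_csmf) - fac_csmf)),
              0.06, label = paste("projection", id, "L1 to facility CSMF"))
  }
})

test_that("soft and hard aggregation both give valid CSMFs; hard picks modal causes", {
  rs <- generate_study(birthplace_scenario(800), seed = 19)
  fac_rs <- va_recordset(as.data.frame(rs[rs$place_class == "facility", ])[
    , record_columns_for_tests()], "neonate")
  comm_rs <- va_recordset(as.data.frame(rs[rs$place_class == "community", ])[
    , record_columns_for_tests()], "neonate")
  mod <- fit_cause_model(fac_rs, projection_spec("B", "neonate"))
  soft <- predict_community_csmf(mod, comm_rs, "soft")
  hard <- predict_community_csmf(mod, comm_rs, "hard")
  expect_equal(sum(soft), 1, tolerance = 1e-9)
  expect_equal(sum(hard), 1, tolerance = 1e-9)
  # hard assignment concentrates on the high-probability causes
  expect_gte(max(hard), max(soft) - 1e-9)
})

test_that("facility-fraction sweep obeys its algebraic identities", {
  set.seed(55)
  for (i in 1:10) {
    f <- as.numeric(stats::rmultinom(1, 200, rep(1, 8))) / 200
    cm <- as.numeric(stats::rmultinom(1, 200, rep(1, 8))) / 200
    grid <- seq(0, 1, 0.1)
    sw <- facility_fraction_sweep(cm, f, grid)
    expect_equal(sw$accuracy[sw$w == 1], 1, tolerance = 1e-12)
    # numerator linearity: sum|f - m(w)| = (1-w) sum|f - c|
    for (w in grid) {
      m <- w * f + (1 - w) * cm
      expect_equal(sum(abs(f - m)), (1 - w) * sum(abs(f - cm)),
                   tolerance = 1e-12)
    }
  }
  # community = facility: flat at 1
  v <- rep(1 / 8, 8)
  expect_equal(facility_fraction_sweep(v, v)$accuracy,
               rep(1, length(seq(0, 1, 0.05))))
})
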