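test_that("Fisher exact test matches hand-worked examples and conventions", {
  expect_equal(fisher_exact_test(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_test(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_message(p0 <- fisher_exact_test(matrix(c(0, 3, 0, 4), 2)),
                 "zero margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Fisher exact test agrees with exhaustive enumeration for all tables with total <= 20", {
  worst <- 0
  for (n in 0:20) {
    for (a_plus_b in 0:n) for (a in 0:a_plus_b) {
      cd <- n - a_plus_b
      for (cc in 0:cd) {
        m <- matrix(c(a, cc, a_plus_b - a, cd - cc), 2)
        p_pkg <- suppressMessages(fisher_exact_test(m))
        p_oracle <- fisher_enumeration_p(m)
        worst <- max(worst, abs(p_pkg - p_oracle))
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("Rao-Scott statistic reduces to the Pearson chi-square under an iid design", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    causes <- sample(c("sepsis", "pneumonia", "preterm"), n, replace = TRUE,
                     prob = c(0.45, 0.35, 0.2))
    places <- sample(c("community", "facility"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    rs <- make_iid_recordset(causes, places)
    rt <- rao_scott_test(rs, "sepsis", p_reference = "chisq")
    ct <- suppressWarnings(stats::chisq.test(
      table(rs$cause == "sepsis", rs$place_class), correct = FALSE))
    expect_equal(rt$statistic, unname(ct$statistic), tolerance = 1e-8)
    expect_equal(rt$p_value, ct$p.value, tolerance = 1e-8)
    expect_equal(rt$design_effect, 1, tolerance = 1e-10)
  }
})

test_that("Rao-Scott test is invariant to weight rescaling and flat for balanced tables", {
  rs <- make_table_recordset(10, 10, 10, 10)
  rt <- rao_scott_test(rs, "sepsis", p_reference = "chisq")
  expect_equal(rt$statistic, 0, tolerance = 1e-12)
  expect_equal(rt$p_value, 1)

  rs2 <- generate_study(divergent_scenario(400), seed = 12)
  r1 <- rao_scott_test(rs2, "sepsis")
  rs2$weight <- rs2$weight * 2
  r2 <- rao_scott_test(rs2, "sepsis")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)

  expect_error(rao_scott_test(rs2, "measles"), "unknown cause")
})

test_that("Rao-Scott p-values are approximately uniform under the null", {
  set.seed(77)
  n <- 300
  ps <- vapply(1:500, function(i) {
    causes <- ifelse(stats::runif(n) < 0.3, "sepsis", "pneumonia")
    places <- ifelse(stats::runif(n) < 0.4, "facility", "community")
    rs <- make_iid_recordset(causes, places)
    rao_scott_test(rs, "sepsis")$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_all_causes returns one row per cause with the documented test routing", {
  rs <- generate_study(preset_scenario("malawi", "neonate", "eava",
                                       n_deaths = 600), seed = 3)
  cmp <- suppressMessages(compare_all_causes(rs, n_boot = 50, seed = 1))
  expect_equal(cmp$cause, cause_scheme("neonate")$causes)
  expect_equal(nrow(cmp), 10)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$community_mf >= 0 & cmp$community_mf <= 100))
  expect_equal(sum(cmp$community_mf), 100, tolerance = 1e-9)
  expect_equal(sum(cmp$facility_mf), 100, tolerance = 1e-9)
  expect_true(all(cmp$test_used %in% c("rao_scott", "fisher")))
  # CIs bracket the point estimates
  expect_true(all(cmp$community_lower <= cmp$community_mf + 1e-9))
  expect_true(all(cmp$community_upper >= cmp$community_mf - 1e-9))

  # a cause with a zero cell in one group must route to Fisher
  causes <- c(rep("sepsis", 40), rep("diarrhea", 5), rep("sepsis", 18),
              rep("pneumonia", 12))
  places <- c(rep("community", 45), rep("facility", 30))
  rs0 <- make_iid_recordset(causes, places)
  cmp0 <- suppressMessages(compare_all_causes(rs0, ci = FALSE))
  expect_equal(cmp0$test_used[cmp0$cause == "diarrhea"], "fisher")
  expect_equal(cmp0$test_used[cmp0$cause == "pneumonia"], "fisher")
})
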