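# Fixtures built in code: small record sets and scenario configurations
# with known generative truth, shared across test files.

# build a levels x causes log-odds offset matrix from a named list of
# named vectors (unnamed causes default to 0)
offset_matrix <- function(rows) {
  causes <- unique(unlist(lapply(rows, names)))
  m <- matrix(0, length(rows), length(causes),
              dimnames = list(names(rows), causes))
  for (lv in names(rows)) m[lv, names(rows[[lv]])] <- rows[[lv]]
  m
}

record_columns_for_tests <- function() {
  c("record_id", "age_group", "cause", "raw_place",
    "provider_seen_at_facility", "age_band", "mother_education",
    "anc_formal", "sex", "born_in_facility", "wealth_quintile",
    "stratum_id", "psu_id", "weight")
}

# iid record set: each record its own PSU, equal weights, one stratum.
make_iid_recordset <- function(causes, places, age_group = "neonate",
                               design_mode = "weighted_clustered",
                               weight = 1) {
  n <- length(causes)
  stopifnot(length(places) == n)
  df <- data.frame(
    record_id = sprintf("r%04d", seq_len(n)),
    age_group = age_group,
    cause = causes,
    raw_place = ifelse(places == "facility", "hospital", "home"),
    provider_seen_at_facility = "not_applicable",
    age_band = if (age_group == "neonate") "days_0_6" else "m1_11",
    mother_education = "none",
    anc_formal = 1, sex = "male", born_in_facility = 0, wealth_quintile = 3,
    stratum_id = "s1",
    psu_id = sprintf("p%04d", seq_len(n)),
    weight = rep_len(weight, n),
    stringsAsFactors = FALSE)
  va_recordset(df, age_group, design_mode)
}

# iid record set realizing a given 2x2 table of place x (cause, other).
make_table_recordset <- function(cause_counts_comm, other_comm,
                                 cause_counts_fac, other_fac,
                                 cause = "sepsis", other = "pneumonia") {
  causes <- c(rep(cause, cause_counts_comm), rep(other, other_comm),
              rep(cause, cause_counts_fac), rep(other, other_fac))
  places <- c(rep("community", cause_counts_comm + other_comm),
              rep("facility", cause_counts_fac + other_fac))
  make_iid_recordset(causes, places)
}

# Null scenario: identical cause laws in both places, no covariate effects.
# Cell sizes chosen so the per-cause comparison mostly exercises the
# Rao-Scott route (expected counts >= 5 at n = 800).
null_scenario <- function(n = 800, seed = 1L) {
  v <- c(0.04, 0.05, 0.20, 0.06, 0.07, 0.18, 0.20, 0.06, 0.06, 0.08)
  scenario_config("neonate", n_deaths = n,
                  cause_baseline_facility = v,
                  cause_baseline_community = v,
                  place_intercept = log(0.35 / 0.65),
                  n_strata = 10, psus_per_stratum = 6,
                  seed = seed)
}

# Scenario with known divergence between place-specific cause laws and no
# null causes (every cause differs between places), for bootstrap
# coverage: the accuracy estimator is then nearly unbiased and the
# percentile interval meaningful.
divergent_scenario <- function(n = 1200, seed = 1L) {
  m <- c(0.05, 0.05, 0.20, 0.05, 0.07, 0.18, 0.20, 0.07, 0.06, 0.07)
  tilt <- c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5, 0.5, -0.5, 0.5, -0.5)
  w <- 0.40
  f <- m * exp(tilt); f <- f / sum(f)
  cm <- (m - w * f) / (1 - w); cm <- cm / sum(cm)
  scenario_config("neonate", n_deaths = n,
                  cause_baseline_facility = f,
                  cause_baseline_community = cm,
                  place_intercept = log(w / (1 - w)),
                  n_strata = 10, psus_per_stratum = 6,
                  seed = seed)
}

# Transportable scenario: the cause-given-covariates law is shared by both
# places (equal baselines + shared offsets); places differ only through
# covariate shift. Unweighted census mode isolates parameter recovery
# from weight noise; the cause law is concentrated on a few causes as in
# the neonatal studies.
transportable_scenario <- function(n = 5000, seed = 1L) {
  base <- c(0.01, 0.01, 0.45, 0.015, 0.015, 0.25, 0.20, 0.015, 0.02, 0.015)
  off <- list(
    age_band = offset_matrix(list(
      days_0_6 = c(birth_asphyxia_injury = 0.7, preterm = 0.5, sepsis = -0.5),
      days_7_27 = c(sepsis = 0.4, meningitis = 0.3))),
    mother_education = offset_matrix(list(
      none = c(tetanus = 0.5, unspecified = 0.3),
      secondary_plus = c(pneumonia = 0.3))),
    anc_formal = offset_matrix(list("1" = c(birth_asphyxia_injury = 0.2))))
  scenario_config("neonate", n_deaths = n,
                  cause_baseline_facility = base,
                  cause_baseline_community = base,
                  place_intercept = -0.5,
                  place_coefs = list(age_band = c(days_0_6 = 0.7),
                                     mother_education = c(none = -0.8,
                                                          secondary_plus = 0.5),
                                     anc_formal = c("1" = 0.4)),
                  cause_offsets = off,
                  design_mode = "unweighted",
                  seed = seed)
}

# Birthplace-linked scenario: facility birth raises intrapartum-cause risk
# and strongly raises the odds of dying in a facility; transportable, so
# projections using birthplace can recover the community distribution
# while those without it cannot.
birthplace_scenario <- function(n = 1200, seed = 1L) {
  base <- c(0.02, 0.02, 0.22, 0.04, 0.05, 0.20, 0.25, 0.05, 0.08, 0.07)
  off <- list(
    born_in_facility = offset_matrix(list(
      "1" = c(birth_asphyxia_injury = 1.0, preterm = 0.8, sepsis = -0.5))),
    age_band = offset_matrix(list(
      days_0_6 = c(birth_asphyxia_injury = 0.5, sepsis = -0.3))))
  scenario_config("neonate", n_deaths = n,
                  cause_baseline_facility = base,
                  cause_baseline_community = base,
                  place_intercept = -1.3,
                  place_coefs = list(born_in_facility = c("1" = 2.2),
                                     age_band = c(days_0_6 = 0.6),
                                     mother_education = c(secondary_plus = 0.4)),
                  cause_offsets = off,
                  seed = seed)
}

# Exhaustive two-sided Fisher p by direct enumeration over the
# hypergeometric support (independent oracle; mirrors the convention of
# summing all tables with fixed margins whose probability does not exceed
# the observed one, with the customary 1e-7 relative slack).
fisher_enumeration_p <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  a <- m[1, 1]
  mrow <- sum(m[1, ]); mcol <- sum(m[, 1]); n <- sum(m)
  support <- max(0, mcol - (n - mrow)):min(mrow, mcol)
  probs <- stats::dhyper(support, mrow, n - mrow, mcol)
  pobs <- stats::dhyper(a, mrow, n - mrow, mcol)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}
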