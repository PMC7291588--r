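#' Configure a synthetic VASA-like study
#'
#' Defines the full generative truth of a synthetic verbal/social autopsy
#' study: the survey design (strata, PSUs, weight dispersion), the
#' population covariate laws, a logistic place-of-death model (log-odds of
#' dying in a facility as a sum of per-covariate-level effects), and a
#' multinomial cause-of-death model (per-place baseline CSMF plus optional
#' per-covariate-level log-odds offsets shared by both places, so that
#' non-zero offsets make the cause-given-covariates law transportable
#' across places).
#'
#' @param age_group `"neonate"` or `"child"`.
#' @param n_deaths Number of deaths to generate.
#' @param cause_baseline_facility,cause_baseline_community Baseline CSMF
#'   vectors (full scheme, scheme order or named).
#' @param place_intercept Intercept of the facility log-odds.
#' @param place_coefs Named list `covariate -> named numeric` of
#'   log-odds-of-facility offsets per covariate level (unlisted levels = 0).
#' @param cause_offsets Named list `covariate -> matrix` (rows = covariate
#'   levels, columns = causes) of multinomial log-odds offsets, or `NULL`.
#' @param covariate_marginals Named list of named probability vectors; the
#'   default gives DHS-like marginals for the age group, with small
#'   missingness for `anc_formal`, `born_in_facility` and
#'   `wealth_quintile`.
#' @param n_strata,psus_per_stratum Survey design size (all strata have the
#'   same PSU count; every stratum has at least 2 PSUs).
#' @param weight_sd,weight_range Log-normal sd of the (unit-mean) sampling
#'   weights and the clamp range.
#' @param design_mode `"weighted_clustered"` or `"unweighted"` (census).
#' @param seed Default seed used by [generate_study()].
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(age_group = c("neonate", "child"),
                            n_deaths = 1000,
                            cause_baseline_facility,
                            cause_baseline_community,
                            place_intercept = 0,
                            place_coefs = list(),
                            cause_offsets = NULL,
                            covariate_marginals = default_marginals(match.arg(age_group)),
                            n_strata = 10, psus_per_stratum = 6,
                            weight_sd = 0.3, weight_range = c(0.2, 5),
                            design_mode = c("weighted_clustered", "unweighted"),
                            seed = 1L) {
  age_group <- match.arg(age_group)
  design_mode <- match.arg(design_mode)
  scheme <- cause_scheme(age_group)
  problems <- character(0)
  fb <- tryCatch(csmf_vector(cause_baseline_facility, scheme),
                 error = function(e) {problems <<- c(problems,
                   paste("facility baseline:", conditionMessage(e))); NULL})
  cb <- tryCatch(csmf_vector(cause_baseline_community, scheme),
                 error = function(e) {problems <<- c(problems,
                   paste("community baseline:", conditionMessage(e))); NULL})
  if (n_deaths < 1) problems <- c(problems, "n_deaths must be positive")
  if (psus_per_stratum < 2) problems <- c(problems, "every stratum needs >= 2 PSUs")
  if (n_strata < 1) problems <- c(problems, "n_strata must be positive")
  bad_cov <- names(place_coefs)[!names(place_coefs) %in% names(covariate_marginals)]
  if (length(bad_cov))
    problems <- c(problems, paste("place_coefs for unknown covariate(s):",
                                  paste(bad_cov, collapse = ", ")))
  if (!is.null(cause_offsets)) {
    bad_off <- names(cause_offsets)[!names(cause_offsets) %in% names(covariate_marginals)]
    if (length(bad_off))
      problems <- c(problems, paste("cause_offsets for unknown covariate(s):",
                                    paste(bad_off, collapse = ", ")))
    for (cv in intersect(names(cause_offsets), names(covariate_marginals)))
      if (!all(colnames(cause_offsets[[cv]]) %in% scheme$causes))
        problems <- c(problems, paste("cause_offsets columns for", cv,
                                      "must be scheme causes"))
  }
  for (cv in names(covariate_marginals)) {
    p <- covariate_marginals[[cv]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      problems <- c(problems, paste("marginal for", cv, "is not a probability vector"))
  }
  if (length(problems))
    stop("invalid scenario config:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(age_group = age_group, scheme = scheme, n_deaths = n_deaths,
                 cause_baseline_facility = fb, cause_baseline_community = cb,
                 place_intercept = place_intercept, place_coefs = place_coefs,
                 cause_offsets = cause_offsets,
                 covariate_marginals = covariate_marginals,
                 n_strata = n_strata, psus_per_stratum = psus_per_stratum,
                 weight_sd = weight_sd, weight_range = weight_range,
                 design_mode = design_mode, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @keywords internal
default_marginals <- function(age_group) {
  m <- list(
    mother_education = c(none = 0.40, primary = 0.38, secondary_plus = 0.22),
    sex = c(male = 0.53, female = 0.47),
    born_in_facility = c("0" = 0.63, "1" = 0.35, missing = 0.02),
    wealth_quintile = c("1" = 0.24, "2" = 0.21, "3" = 0.195, "4" = 0.185,
                        "5" = 0.16, missing = 0.01))
  if (age_group == "neonate") {
    m$age_band <- c(days_0_6 = 0.68, days_7_27 = 0.32)
    m$anc_formal <- c("0" = 0.30, "1" = 0.68, missing = 0.02)
  } else {
    m$age_band <- c(m1_11 = 0.45, m12_23 = 0.25, m24_59 = 0.30)
  }
  m
}

# facility log-odds for a data frame / grid of covariate levels (characters)
place_logodds <- function(config, covs) {
  eta <- rep(config$place_intercept, nrow(covs))
  for (cv in names(config$place_coefs)) {
    co <- config$place_coefs[[cv]]
    v <- covs[[cv]]
    hit <- v %in% names(co)
    eta[hit] <- eta[hit] + co[v[hit]]
  }
  eta
}

# cause probability matrix (rows of covs x causes) for one place
cause_probs <- function(config, covs, place) {
  base <- if (place == "facility") config$cause_baseline_facility
          else config$cause_baseline_community
  eta <- matrix(log(as.numeric(base)), nrow(covs), length(base), byrow = TRUE)
  if (!is.null(config$cause_offsets)) {
    for (cv in names(config$cause_offsets)) {
      off <- config$cause_offsets[[cv]]
      v <- covs[[cv]]
      hit <- v %in% rownames(off)
      if (any(hit)) {
        cols <- match(colnames(off), config$scheme$causes)
        eta[hit, cols] <- eta[hit, cols] + off[v[hit], , drop = FALSE]
      }
    }
  }
  p <- exp(eta - apply(eta, 1, max))
  p[is.na(p)] <- 0  # exp(-Inf - -Inf) guards; zero-baseline causes stay zero
  p / rowSums(p)
}

#' Generate a synthetic study from a scenario configuration
#'
#' Draws covariates from their marginals (independently), place of death
#' from the logistic place model, cause of death from the place- and
#' covariate-conditional multinomial, assigns strata and PSUs uniformly,
#' and draws unit-mean log-normal sampling weights (clamped to the
#' configured range; weights are 1 in unweighted mode). `raw_place` is
#' back-filled consistently with the generated place class (facility
#' deaths in hospital, community deaths at home). Deterministic given the
#' seed.
#'
#' @param config A [scenario_config()].
#' @param seed Seed (defaults to the config's).
#' @return A [va_recordset()].
#' @export
generate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_deaths
  with_seed(seed, {
    covs <- as.data.frame(lapply(config$covariate_marginals, function(p)
      sample(names(p), n, replace = TRUE, prob = p)),
      stringsAsFactors = FALSE)
    p_fac <- stats::plogis(place_logodds(config, covs))
    place <- ifelse(stats::runif(n) < p_fac, "facility", "community")
    causes <- character(n)
    for (pl in c("facility", "community")) {
      i <- which(place == pl)
      if (!length(i)) next
      P <- cause_probs(config, covs[i, , drop = FALSE], pl)
      u <- stats::runif(length(i))
      cum <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
      pick <- rowSums(u > cum) + 1L
      causes[i] <- config$scheme$causes[pick]
    }
    stratum <- sample.int(config$n_strata, n, replace = TRUE)
    psu <- sample.int(config$psus_per_stratum, n, replace = TRUE)
    weight <- if (config$design_mode == "unweighted") rep(1, n) else {
      w <- stats::rlnorm(n, meanlog = -config$weight_sd^2 / 2,
                         sdlog = config$weight_sd)
      pmin(pmax(w, config$weight_range[1]), config$weight_range[2])
    }
    num_or_na <- function(v) suppressWarnings(as.numeric(ifelse(v == "missing", NA, v)))
    df <- data.frame(
      record_id = sprintf("d%06d", seq_len(n)),
      age_group = config$age_group,
      cause = causes,
      raw_place = ifelse(place == "facility", "hospital", "home"),
      provider_seen_at_facility = "not_applicable",
      age_band = covs$age_band,
      mother_education = covs$mother_education,
      anc_formal = if ("anc_formal" %in% names(covs)) num_or_na(covs$anc_formal) else NA_real_,
      sex = covs$sex,
      born_in_facility = num_or_na(covs$born_in_facility),
      wealth_quintile = num_or_na(covs$wealth_quintile),
      stratum_id = sprintf("s%02d", stratum),
      psu_id = sprintf("s%02d_p%02d", stratum, psu),
      weight = weight,
      stringsAsFactors = FALSE)
    va_recordset(df, config$age_group, config$design_mode)
  })
}

#' Exact generative truth of a scenario by covariate-grid enumeration
#'
#' Marginalizes the place and cause models over the full (finite)
#' covariate grid with exact cell probabilities -- no sampling -- giving
#' the true community, facility and population CSMFs and the true facility
#' share of deaths. The population CSMF satisfies
#' `population = p_facility * facility + (1 - p_facility) * community`
#' by construction.
#'
#' @param config A [scenario_config()].
#' @return List of class `generative_truth` with elements
#'   `community_csmf`, `facility_csmf`, `population_csmf` (each a
#'   [csmf_vector()]) and `p_facility`.
#' @export
true_quantities <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- expand.grid(lapply(config$covariate_marginals, names),
                      stringsAsFactors = FALSE)
  cellp <- Reduce(`*`, lapply(names(config$covariate_marginals), function(cv)
    config$covariate_marginals[[cv]][grid[[cv]]]))
  cellp <- as.numeric(cellp)
  pf <- stats::plogis(place_logodds(config, grid))
  Pf <- cause_probs(config, grid, "facility")
  Pc <- cause_probs(config, grid, "community")
  p_facility <- sum(cellp * pf)
  fac <- colSums(cellp * pf * Pf) / p_facility
  comm <- colSums(cellp * (1 - pf) * Pc) / (1 - p_facility)
  pop <- p_facility * fac + (1 - p_facility) * comm
  scheme <- config$scheme
  nm <- function(x) stats::setNames(x, scheme$causes)
  structure(list(community_csmf = csmf_vector(nm(comm / sum(comm)), scheme),
                 facility_csmf = csmf_vector(nm(fac / sum(fac)), scheme),
                 population_csmf = csmf_vector(nm(pop / sum(pop)), scheme),
                 p_facility = p_facility),
            class = "generative_truth")
}

# Table of study-country population CSMFs (percent, renormalized on use)
# and observed facility shares of deaths, used by preset_scenario().
preset_tables <- function() {
  neo <- list(
    cameroon = list(eava = c(1.2, 3.0, 37.2, 1.2, 0.6, 18.9, 25.0, 1.2, 5.5, 6.1),
                    pcva = c(0.0, 0.0, 26.2, 7.3, 0.6, 16.5, 17.7, 3.7, 17.1, 11.0)),
    malawi = list(eava = c(1.4, 0.3, 15.2, 0.9, 1.7, 30.9, 23.3, 2.9, 7.5, 15.8),
                  pcva = c(0.0, 0.0, 16.1, 3.5, 0.3, 41.3, 13.6, 0.0, 17.6, 7.6)),
    niger = list(eava = c(4.0, 2.7, 19.9, 4.2, 5.7, 11.6, 37.4, 2.6, 2.7, 9.2),
                 pcva = c(0.4, 0.2, 20.2, 6.7, 0.5, 18.5, 39.2, 6.1, 2.2, 6.0)),
    nigeria = list(eava = c(1.2, 0.9, 22.3, 1.2, 2.9, 19.9, 31.5, 4.8, 1.9, 13.4),
                   pcva = c(0.4, 1.1, 20.3, 4.0, 2.3, 30.1, 17.9, 8.2, 3.8, 11.9)))
  chi <- list(
    cameroon = list(eava = c(4.1, 3.3, 2.7, 0.3, 16.5, 4.3, 21.9, 1.3, 20.8, 19.1, 1.1, 4.7),
                    pcva = c(3.6, 6.0, 8.0, 0.8, 16.4, 3.6, 6.6, 6.5, 16.9, 22.5, 5.8, 3.3)),
    malawi = list(eava = c(2.7, 0.6, 1.6, 1.3, 10.3, 3.2, 18.4, 1.0, 25.5, 24.7, 1.6, 9.1),
                  pcva = c(2.7, 13.0, 7.8, 0.8, 4.3, 2.7, 12.4, 1.5, 29.2, 18.7, 1.9, 5.0)),
    niger = list(eava = c(0.9, 2.8, 2.3, 1.4, 18.3, 6.3, 19.5, 0.3, 11.8, 28.9, 3.0, 4.5),
                 pcva = c(0.8, 0.2, 0.4, 3.0, 34.1, 0.1, 2.2, 8.4, 16.1, 30.4, 1.9, 2.4)),
    nigeria = list(eava = c(2.8, 0.6, 0.6, 2.0, 5.7, 3.7, 22.3, 0.6, 16.4, 36.3, 3.0, 5.9),
                   pcva = c(2.8, 0.1, 4.1, 4.4, 9.0, 3.4, 23.1, 5.0, 19.6, 23.7, 2.2, 2.6)))
  list(
    csmf = list(neonate = neo, child = chi),
    facility_share = list(
      neonate = c(cameroon = 0.335, malawi = 0.550, niger = 0.188, nigeria = 0.274),
      child = c(cameroon = 0.287, malawi = 0.505, niger = 0.186, nigeria = 0.216)),
    n_deaths = list(
      neonate = c(cameroon = 164, malawi = 320, niger = 453, nigeria = 722),
      child = c(cameroon = 635, malawi = 691, niger = 619, nigeria = 2055)))
}

# default facility-vs-community cause tilts (log-odds): direction follows
# the significant community/facility differences in the study countries
# (facility deaths tilted toward intrapartum causes and pneumonia in
# neonates, meningitis/malaria in children; community deaths toward sepsis
# and ill-defined causes); magnitudes are free scenario parameters.
default_place_tilt <- function(age_group) {
  if (age_group == "neonate")
    c(tetanus = 0, congenital = 0, birth_asphyxia_injury = 0.45,
      meningitis = 0, diarrhea = 0, pneumonia = 0.25, sepsis = -0.30,
      other = -0.45, preterm = 0.45, unspecified = -0.30)
  else
    c(injury = -0.40, aids = -0.30, malnutrition = -0.40, measles = 0,
      meningitis = 0.30, dysentery = 0, diarrhea = 0.10, pertussis = 0,
      pneumonia = 0.10, malaria = 0.30, other = 0, unspecified = -0.20)
}

#' Preset scenarios emulating the four VASA study countries
#'
#' Builds a [scenario_config()] whose generative truth matches the
#' published study conditions: the population CSMF equals the country's
#' printed cause-specific proportions (renormalized to sum to 1), the true
#' facility share of deaths equals the observed share (the place-model
#' intercept is solved by root finding over the enumerated covariate
#' grid), and the covariate effects on place of death reproduce the
#' direction of the observed demographic imbalance (facility deaths
#' younger, more often facility-born, with wealthier and more educated
#' mothers). Place-specific CSMFs are derived from the population CSMF by
#' a configurable facility log-odds tilt: `facility ~ pop * exp(tilt)`
#' (normalized), with the community CSMF solving the exact mixture
#' identity. Cameroon uses unweighted census mode.
#'
#' @param country `"cameroon"`, `"malawi"`, `"niger"` or `"nigeria"`.
#' @param age_group `"neonate"` or `"child"`.
#' @param method `"eava"` or `"pcva"`.
#' @param n_deaths Number of deaths (default: the study's sample size).
#' @param place_tilt Named log-odds tilt vector (default
#'   direction-matched, see above).
#' @param seed Default generation seed.
#' @return A `scenario_config`.
#' @export
preset_scenario <- function(country = c("cameroon", "malawi", "niger", "nigeria"),
                            age_group = c("neonate", "child"),
                            method = c("eava", "pcva"),
                            n_deaths = NULL,
                            place_tilt = default_place_tilt(match.arg(age_group)),
                            seed = 1L) {
  country <- match.arg(country)
  age_group <- match.arg(age_group)
  method <- match.arg(method)
  tabs <- preset_tables()
  scheme <- cause_scheme(age_group)
  pct <- tabs$csmf[[age_group]][[country]][[method]]
  m <- pct / sum(pct)
  names(m) <- scheme$causes
  w <- tabs$facility_share[[age_group]][[country]]
  if (is.null(n_deaths)) n_deaths <- tabs$n_deaths[[age_group]][[country]]

  tilt <- rep(0, length(m)); names(tilt) <- scheme$causes
  tilt[names(place_tilt)] <- place_tilt
  f <- m * exp(tilt); f <- f / sum(f)
  cm <- (m - w * f) / (1 - w)
  if (any(cm < -1e-12))
    stop("place tilt too large: community CSMF would be negative for ",
         paste(scheme$causes[cm < 0], collapse = ", "))
  cm <- pmax(cm, 0); cm <- cm / sum(cm)

  place_coefs <- list(
    born_in_facility = c("1" = 2.2),
    mother_education = c(none = -0.45, secondary_plus = 0.40),
    wealth_quintile = c("1" = -0.30, "5" = 0.60))
  if (age_group == "neonate") {
    place_coefs$age_band <- c(days_0_6 = 0.55)
    place_coefs$anc_formal <- c("1" = 0.40)
  }
  design_mode <- if (country == "cameroon") "unweighted" else "weighted_clustered"

  cfg <- scenario_config(age_group = age_group, n_deaths = n_deaths,
                         cause_baseline_facility = f,
                         cause_baseline_community = cm,
                         place_intercept = 0, place_coefs = place_coefs,
                         design_mode = design_mode, seed = seed)
  # solve the intercept so the true facility share hits the observed one
  g <- function(b) {
    cfg$place_intercept <- b
    true_quantities(cfg)$p_facility - w
  }
  cfg$place_intercept <- stats::uniroot(g, c(-8, 8), tol = 1e-10)$root
  cfg$country <- country
  cfg$method <- method
  cfg$population_csmf <- csmf_vector(m, scheme)
  cfg$target_facility_share <- w
  cfg
}
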