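#' Project the population cause distribution from facility deaths
#'
#' The central estimator: predicts the population cause-specific mortality
#' fractions as if community causes had not been measured, using only the
#' causes of facility deaths (plus, for model-based projections, covariates
#' of the community deaths). Projection A substitutes the observed facility
#' CSMF for the community; projections B-E predict the community CSMF from
#' a cause model fitted among facility deaths ([fit_cause_model()]). The
#' population prediction is the mixture
#' \eqn{p_{fac} \cdot CSMF_{fac} + (1 - p_{fac}) \cdot \widehat{CSMF}_{comm}}
#' with \eqn{p_{fac}} the weighted share of deaths in facilities, and is
#' scored by [csmf_accuracy()] against the observed population CSMF (the
#' observed population distribution is the reference). The confidence
#' interval comes from [psu_bootstrap()], refitting the model on every
#' replicate.
#'
#' @param rs A [va_recordset()] with both place classes present.
#' @param projection `"A"`-`"E"`, or a [projection_spec()].
#' @param n_boot Bootstrap replicates for the accuracy CI (0 = no CI;
#'   default 200, model refits make replicates expensive).
#' @param seed Integer seed (model fits and bootstrap).
#' @param aggregation `"soft"` or `"hard"` prediction aggregation.
#' @param weighted Use survey weights as observation weights in model fits.
#' @return Object of class `csmf_projection`: list with the four CSMF
#'   vectors (`facility_csmf`, `predicted_community_csmf`,
#'   `predicted_population_csmf`, `observed_population_csmf`),
#'   `p_facility`, `accuracy` (an `interval_estimate` when `n_boot > 0`),
#'   `unprojectable` causes, the fitted `model` and the `spec`.
#' @examples
#' cfg <- preset_scenario("niger", "neonate", "eava", n_deaths = 400)
#' rs <- generate_study(cfg, seed = 7)
#' project_csmf(rs, "A", n_boot = 0)
#' @export
project_csmf <- function(rs, projection = "A", n_boot = 200, seed = 1L,
                         aggregation = c("soft", "hard"), weighted = TRUE) {
  stopifnot(inherits(rs, "va_recordset"))
  aggregation <- match.arg(aggregation)
  spec <- if (inherits(projection, "projection_spec")) projection
          else projection_spec(projection, rs_age_group(rs),
                               aggregation = aggregation, seed = seed)
  if (!any(rs$place_class == "facility"))
    stop("projection requires at least one facility death")
  if (!any(rs$place_class == "community"))
    stop("projection requires at least one community death")

  point <- project_once(rs, spec, weighted)
  acc <- point$accuracy
  if (n_boot > 0) {
    acc <- psu_bootstrap(rs, function(r) project_once(r, spec, weighted)$accuracy,
                         n_boot = n_boot, seed = seed)
  }
  structure(c(point[c("facility_csmf", "predicted_community_csmf",
                      "predicted_population_csmf", "observed_population_csmf",
                      "p_facility", "unprojectable", "model")],
              list(accuracy = acc, spec = spec)),
            class = "csmf_projection")
}

# One pass of the projection pipeline (used for the point estimate and for
# every bootstrap replicate).
#' @keywords internal
project_once <- function(rs, spec, weighted) {
  scheme <- rs_scheme(rs)
  fac_csmf <- weighted_csmf(rs, "facility")
  obs_pop <- weighted_csmf(rs)
  p_fac <- facility_share(rs)
  if (spec$model_kind == "none") {
    pred_comm <- fac_csmf
    model <- NULL
  } else {
    fac_rs <- rs_subset(rs, which(rs$place_class == "facility"))
    comm_rs <- rs_subset(rs, which(rs$place_class == "community"))
    model <- suppressWarnings(fit_cause_model(fac_rs, spec, weighted = weighted))
    pred_comm <- predict_community_csmf(model, comm_rs)
  }
  pred_pop <- csmf_vector(p_fac * unclass(fac_csmf) +
                            (1 - p_fac) * unclass(pred_comm), scheme)
  unprojectable <- scheme$causes[as.numeric(fac_csmf) == 0]
  list(facility_csmf = fac_csmf,
       predicted_community_csmf = pred_comm,
       predicted_population_csmf = pred_pop,
       observed_population_csmf = obs_pop,
       p_facility = p_fac,
       unprojectable = unprojectable,
       model = model,
       accuracy = csmf_accuracy(pred_pop, obs_pop))
}

#' @export
print.csmf_projection <- function(x, digits = 3, ...) {
  cat(sprintf("CSMF projection %s (%s)\n", x$spec$projection_id,
              x$spec$model_kind))
  cat(sprintf("  facility share of deaths: %.1f%%\n", 100 * x$p_facility))
  if (inherits(x$accuracy, "interval_estimate")) {
    cat("  CSMF accuracy vs observed population: ")
    print(x$accuracy, digits = digits)
  } else {
    cat(sprintf("  CSMF accuracy vs observed population: %.*f\n",
                digits, x$accuracy))
  }
  if (length(x$unprojectable))
    cat("  unprojectable causes (no facility deaths): ",
        paste(x$unprojectable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.csmf_projection <- function(object, ...) {
  tab <- data.frame(
    cause = names(object$facility_csmf),
    facility = as.numeric(object$facility_csmf),
    predicted_community = as.numeric(object$predicted_community_csmf),
    predicted_population = as.numeric(object$predicted_population_csmf),
    observed_population = as.numeric(object$observed_population_csmf))
  structure(list(spec = object$spec, p_facility = object$p_facility,
                 accuracy = object$accuracy, table = tab),
            class = "summary.csmf_projection")
}

#' @export
print.summary.csmf_projection <- function(x, digits = 3, ...) {
  cat(sprintf("CSMF projection %s; facility share %.1f%%\n",
              x$spec$projection_id, 100 * x$p_facility))
  df <- x$table
  df[-1] <- lapply(df[-1], round, digits)
  print.data.frame(df, row.names = FALSE)
  if (inherits(x$accuracy, "interval_estimate")) print(x$accuracy, digits)
  else cat(sprintf("CSMF accuracy: %.*f\n", digits, x$accuracy))
  invisible(x)
}

#' @export
coef.csmf_projection <- function(object, ...) {
  stats::setNames(as.numeric(object$predicted_population_csmf),
                  names(object$predicted_population_csmf))
}

#' CSMF accuracy as a function of the facility share of deaths
#'
#' Holds the community and facility cause distributions fixed and varies
#' the facility share `w`: the population CSMF is
#' `m(w) = w * facility + (1 - w) * community`, and the facility CSMF is
#' scored against `m(w)` as reference. At `w = 1` the population is the
#' facility distribution and accuracy is exactly 1; the absolute-error
#' numerator shrinks linearly, `sum |facility - m(w)| = (1 - w) * sum
#' |facility - community|`.
#'
#' @param community_csmf,facility_csmf CSMF vectors on a shared scheme.
#' @param grid Facility shares in `[0, 1]` (default 0 to 1 by 0.05).
#' @return Data frame with columns `w` and `accuracy`.
#' @export
facility_fraction_sweep <- function(community_csmf, facility_csmf,
                                    grid = seq(0, 1, by = 0.05)) {
  f <- as.numeric_csmf(facility_csmf)
  cvec <- as.numeric_csmf(community_csmf)
  if (length(f) != length(cvec))
    stop("community and facility CSMFs must share a scheme")
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  acc <- vapply(grid, function(w) {
    m <- w * f + (1 - w) * cvec
    csmf_accuracy(f, m)
  }, numeric(1))
  data.frame(w = grid, accuracy = acc)
}
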