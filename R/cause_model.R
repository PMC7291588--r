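#' Covariate sets and model kinds for projections A-E
#'
#' Projection A substitutes the observed facility cause distribution for
#' the community. B fits a multinomial logistic regression on age at death
#' and mother's education (plus any formal antenatal care for neonates).
#' C fits a random forest on age at death, mother's education, child sex,
#' facility birth, and wealth quintile (plus antenatal care for neonates).
#' D is a random forest restricted to B's covariates, and E is D plus
#' facility birth.
#'
#' @param projection_id `"A"`, `"B"`, `"C"`, `"D"` or `"E"`.
#' @param age_group `"neonate"` or `"child"`.
#' @param aggregation `"soft"` (average predicted probabilities; default)
#'   or `"hard"` (single best cause per record, scheme-order tie-break).
#' @param seed Integer seed used by stochastic model fits.
#' @return List of class `projection_spec` with `projection_id`,
#'   `model_kind`, `covariates`, `aggregation`, `seed`.
#' @export
projection_spec <- function(projection_id = c("A", "B", "C", "D", "E"),
                            age_group = c("neonate", "child"),
                            aggregation = c("soft", "hard"), seed = 1L) {
  projection_id <- match.arg(projection_id)
  age_group <- match.arg(age_group)
  aggregation <- match.arg(aggregation)
  anc <- if (age_group == "neonate") "anc_formal" else NULL
  base_covs <- c("age_band", "mother_education", anc)
  spec <- switch(projection_id,
    A = list(model_kind = "none", covariates = character(0)),
    B = list(model_kind = "multinomial_logit", covariates = base_covs),
    C = list(model_kind = "random_forest",
             covariates = c("age_band", "mother_education", "sex",
                            "born_in_facility", "wealth_quintile", anc)),
    D = list(model_kind = "random_forest", covariates = base_covs),
    E = list(model_kind = "random_forest",
             covariates = c(base_covs, "born_in_facility")))
  structure(c(list(projection_id = projection_id, age_group = age_group,
                   aggregation = aggregation, seed = as.integer(seed)), spec),
            class = "projection_spec")
}

# Encode covariates as factors with an explicit "missing" level; at
# prediction time, levels unseen in training are mapped to "missing".
#' @keywords internal
encode_covariates <- function(df, covariates, levels_map = NULL) {
  out <- list()
  for (cv in covariates) {
    v <- as.character(df[[cv]])
    v[is.na(v)] <- "missing"
    if (is.null(levels_map)) {
      lev <- unique(c(sort(unique(v)), "missing"))
    } else {
      lev <- levels_map[[cv]]
      unseen <- !v %in% lev
      if (any(unseen)) {
        message("encode_covariates: ", sum(unseen), " value(s) of '", cv,
                "' unseen in training mapped to 'missing'")
        v[unseen] <- "missing"
      }
    }
    out[[cv]] <- factor(v, levels = lev)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Fit a cause-of-death model on facility deaths
#'
#' Fits the projection's model kind to cause of death against the spec's
#' covariates among facility deaths. The multinomial logit is fitted by
#' weight-adjusted maximum likelihood with a small ridge penalty
#' (`decay`, default `1e-4`) that absorbs separation; the random forest is
#' a probability forest of 500 trees with minimum node size 1 and
#' `floor(sqrt(p))` candidate features per split. Survey weights enter as
#' observation weights unless `weighted = FALSE`. Records are ordered by
#' `record_id` before fitting so results do not depend on input row order.
#' Causes absent from the training data are outside the model's support
#' and always receive predicted probability 0.
#'
#' @param facility_rs A [va_recordset()] (normally the facility subset).
#' @param spec A [projection_spec()] with `model_kind != "none"`.
#' @param weighted Use survey weights as observation weights (default TRUE).
#' @param decay Ridge penalty for the multinomial logit.
#' @return Object of class `va_cause_model` with a [predict][predict.va_cause_model]
#'   method.
#' @export
fit_cause_model <- function(facility_rs, spec, weighted = TRUE, decay = 1e-4) {
  stopifnot(inherits(facility_rs, "va_recordset"),
            inherits(spec, "projection_spec"))
  if (spec$model_kind == "none")
    stop("projection A has no model to fit; use project_csmf")
  scheme <- rs_scheme(facility_rs)
  ord <- order(as.character(facility_rs$record_id))
  rs <- rs_subset(facility_rs, ord)
  support <- scheme$causes[scheme$causes %in% unique(rs$cause)]
  if (length(support) < 1) stop("no causes present in training data")
  w <- if (weighted) effective_weights(rs) else rep(1, nrow(rs))
  w <- w / mean(w)

  X <- encode_covariates(rs, spec$covariates)
  levels_map <- lapply(X, levels)
  y <- factor(rs$cause, levels = support)

  if (length(support) == 1) {
    warning("single-cause training data: degenerate model predicting '",
            support, "' with probability 1")
    fit <- NULL
    kind <- "degenerate"
  } else if (spec$model_kind == "multinomial_logit") {
    dat <- cbind(.cause = y, X)
    fit <- nnet::multinom(.cause ~ ., data = dat, weights = w,
                          decay = decay, trace = FALSE, maxit = 500,
                          MaxNWts = 5000)
    kind <- "multinomial_logit"
  } else {
    dat <- cbind(.cause = y, X)
    fit <- ranger::ranger(
      dependent.variable.name = ".cause", data = dat,
      num.trees = 500, mtry = max(1, floor(sqrt(ncol(X)))),
      min.node.size = 1, probability = TRUE,
      case.weights = w, seed = spec$seed, num.threads = 1,
      respect.unordered.factors = "partition")
    kind <- "random_forest"
  }
  structure(list(model_kind = kind, fit = fit, spec = spec,
                 scheme = scheme, support = support,
                 levels_map = levels_map),
            class = "va_cause_model")
}

#' Predicted cause probabilities for new death records
#'
#' @param object A `va_cause_model`.
#' @param newdata A `va_recordset` or data frame with the model's
#'   covariates.
#' @param ... Unused.
#' @return Matrix (rows = records, columns = full cause scheme in order)
#'   of predicted probabilities; each row sums to 1 and causes outside the
#'   training support have probability 0.
#' @export
predict.va_cause_model <- function(object, newdata, ...) {
  X <- encode_covariates(as.data.frame(newdata), object$spec$covariates,
                         object$levels_map)
  full <- matrix(0, nrow = nrow(newdata),
                 ncol = length(object$scheme$causes),
                 dimnames = list(NULL, object$scheme$causes))
  if (object$model_kind == "degenerate") {
    full[, object$support] <- 1
    return(full)
  }
  if (object$model_kind == "multinomial_logit") {
    p <- stats::predict(object$fit, newdata = X, type = "probs")
    if (is.null(dim(p))) {
      # two-class multinom returns a vector of P(second level)
      if (length(object$support) == 2) {
        p <- cbind(1 - p, p)
        colnames(p) <- object$support
      } else p <- matrix(p, nrow = 1, dimnames = list(NULL, object$support))
    }
  } else {
    p <- stats::predict(object$fit, data = X, num.threads = 1)$predictions
  }
  full[, colnames(p)] <- p
  full
}

#' Predict the community cause distribution from a fitted model
#'
#' Soft aggregation (default) averages the per-record predicted
#' probability vectors with the survey weights; hard aggregation assigns
#' each record its highest-probability cause (scheme-order tie-break) and
#' takes weighted class proportions.
#'
#' @param model A [fit_cause_model()] result.
#' @param community_rs Non-empty `va_recordset` of community deaths.
#' @param aggregation `"soft"` or `"hard"` (defaults to the model spec's).
#' @return A [csmf_vector()] over the full cause scheme.
#' @export
predict_community_csmf <- function(model, community_rs,
                                   aggregation = NULL) {
  stopifnot(inherits(model, "va_cause_model"), nrow(community_rs) > 0)
  if (is.null(aggregation)) aggregation <- model$spec$aggregation
  aggregation <- match.arg(aggregation, c("soft", "hard"))
  P <- predict(model, community_rs)
  w <- effective_weights(community_rs)
  if (aggregation == "soft") {
    fr <- colSums(P * w) / sum(w)
  } else {
    pick <- max.col(P, ties.method = "first")  # columns already in scheme order
    cz <- factor(model$scheme$causes[pick], levels = model$scheme$causes)
    fr <- tapply(w, cz, sum, default = 0) / sum(w)
  }
  csmf_vector(fr / sum(fr), model$scheme)
}
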