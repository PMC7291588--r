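#' Survey-weighted CSMF estimate
#'
#' Estimates the cause-specific mortality fractions as weighted cause
#' proportions: fraction for cause j = (sum of weights of selected records
#' with cause j) / (sum of weights of selected records). In unweighted
#' (census) mode all weights are treated as 1. Causes absent from the
#' selection get fraction 0 so vectors stay conformable across subsets.
#'
#' @param rs A [va_recordset()].
#' @param subset `NULL` for all records, or `"facility"` / `"community"` to
#'   restrict to one place class.
#' @return A [csmf_vector()] over the record set's full cause scheme.
#' @export
weighted_csmf <- function(rs, subset = NULL) {
  stopifnot(inherits(rs, "va_recordset"))
  if (!is.null(subset)) {
    subset <- match.arg(subset, c("facility", "community"))
    keep <- rs$place_class == subset
  } else keep <- rep(TRUE, nrow(rs))
  if (!any(keep)) stop("empty subset: no records selected")
  w <- effective_weights(rs)[keep]
  cz <- factor(rs$cause[keep], levels = rs_scheme(rs)$causes)
  tot <- tapply(w, cz, sum, default = 0)
  csmf_vector(tot / sum(w), rs_scheme(rs))
}

effective_weights <- function(rs) {
  if (rs_design_mode(rs) == "unweighted") rep(1, nrow(rs)) else rs$weight
}

#' Weighted share of deaths occurring in health facilities
#'
#' @param rs A [va_recordset()].
#' @return Proportion in `[0, 1]`.
#' @export
facility_share <- function(rs) {
  stopifnot(inherits(rs, "va_recordset"))
  w <- effective_weights(rs)
  sum(w[rs$place_class == "facility"]) / sum(w)
}

#' Percentile bootstrap resampling primary sampling units
#'
#' Each replicate redraws, independently within each stratum, the original
#' number of PSUs with replacement, and assembles all records of each drawn
#' PSU (a PSU drawn k times contributes its records k times). Weights are
#' not rescaled after resampling. The confidence interval is the 2.5th and
#' 97.5th percentile of the replicate statistics; the point estimate is the
#' statistic on the original data. In unweighted (census) mode each record
#' is its own resampling unit. Replicates on which the statistic is
#' undefined (error or `NA`) are dropped; more than 10% dropped is an error.
#'
#' @param rs A [va_recordset()].
#' @param statistic Function `va_recordset -> single number`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the result is reproducible given the seed and
#'   the global RNG state is restored afterwards.
#' @param level Confidence level (default 0.95).
#' @return An object of class `interval_estimate`: list with `estimate`,
#'   `lower`, `upper`, `n_boot`, `seed`, `n_dropped` and the replicate
#'   values in `replicates`.
#' @export
psu_bootstrap <- function(rs, statistic, n_boot = 1000, seed, level = 0.95) {
  stopifnot(inherits(rs, "va_recordset"), n_boot >= 1)
  if (missing(seed) || !is.finite(seed))
    stop("a seed is required for the bootstrap")
  est <- statistic(rs)

  clustered <- rs_design_mode(rs) == "weighted_clustered"
  if (clustered) {
    psu_key <- paste(rs$stratum_id, rs$psu_id, sep = "\r")
    idx_by_psu <- split(seq_len(nrow(rs)), psu_key)
    psu_stratum <- vapply(idx_by_psu, function(i) as.character(rs$stratum_id[i[1]]), "")
    psus_by_stratum <- split(seq_along(idx_by_psu), psu_stratum)
    m_h <- lengths(psus_by_stratum)
    if (any(m_h < 2))
      stop("bootstrap requires >= 2 PSUs in every stratum; stratum ",
           paste(names(m_h)[m_h < 2], collapse = ", "), " has 1")
  }

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- if (clustered) {
        drawn <- unlist(lapply(psus_by_stratum, function(p)
          p[sample.int(length(p), length(p), replace = TRUE)]), use.names = FALSE)
        unlist(idx_by_psu[drawn], use.names = FALSE)
      } else {
        sample.int(nrow(rs), nrow(rs), replace = TRUE)
      }
      tryCatch(as.numeric(statistic(rs_subset(rs, idx))),
               error = function(e) NA_real_)
    }, numeric(1))
  })

  n_dropped <- sum(is.na(reps))
  if (n_dropped > 0)
    message(sprintf("psu_bootstrap: %d of %d replicates dropped (statistic undefined)",
                    n_dropped, n_boot))
  if (n_dropped > 0.1 * n_boot)
    stop("more than 10% of bootstrap replicates dropped")
  ok <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(estimate = est, lower = qs[1], upper = qs[2],
                 n_boot = n_boot, seed = seed, n_dropped = n_dropped,
                 replicates = reps),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f (95%% CI %.*f, %.*f)  [%d bootstrap replicates, seed %s]\n",
              digits, x$estimate, digits, x$lower, digits, x$upper,
              x$n_boot, format(x$seed)))
  invisible(x)
}

#' CSMF accuracy between two place classes, with a bootstrap CI
#'
#' Computes the CSMF accuracy of the weighted cause distribution of one
#' place class (or of the whole population) against another, with a
#' percentile confidence interval from [psu_bootstrap()] in which both
#' CSMFs are recomputed on every replicate. By convention, when comparing
#' facility to community deaths the community distribution is the
#' reference; the reference role is an explicit argument.
#'
#' @param rs A [va_recordset()] containing both roles.
#' @param pred_role,ref_role `"facility"`, `"community"` or `"population"`.
#' @param n_boot,seed,level Passed to [psu_bootstrap()].
#' @return An `interval_estimate`.
#' @export
csmf_accuracy_ci <- function(rs, pred_role = "facility", ref_role = "community",
                             n_boot = 1000, seed, level = 0.95) {
  role_csmf <- function(r, role) {
    if (role == "population") weighted_csmf(r) else weighted_csmf(r, role)
  }
  statistic <- function(r) csmf_accuracy(role_csmf(r, pred_role),
                                         role_csmf(r, ref_role))
  psu_bootstrap(rs, statistic, n_boot = n_boot, seed = seed, level = level)
}

# Evaluate an expression under a fixed seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
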