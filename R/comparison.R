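#' Compare community and facility mortality fractions for every cause
#'
#' For each cause in scheme order, computes the weighted mortality fraction
#' (MF, in percent) among community and among facility deaths, a
#' design-corrected p-value, and flags causes differing at level `alpha`.
#' The Rao-Scott corrected chi-square is used unless any raw cell of the
#' place x (cause vs other causes) table is zero or any expected raw count
#' is below 5, in which case the Fisher exact test on the raw counts is
#' used (a message notes the approximation when weights are non-uniform).
#' No multiplicity adjustment is applied.
#'
#' @param rs A [va_recordset()] with both place classes present.
#' @param alpha Significance level for flagging (default 0.05).
#' @param ci Logical: attach percentile bootstrap CIs (from
#'   [psu_bootstrap()]) to the group MFs? Default `TRUE`.
#' @param n_boot,seed Bootstrap settings used when `ci = TRUE`.
#' @return A data frame of class `cause_comparison` with one row per cause:
#'   `cause`, `community_mf`, `facility_mf` (percent), CI bounds (if
#'   requested), `p_value`, `test_used`, `significant`.
#' @export
compare_all_causes <- function(rs, alpha = 0.05, ci = TRUE,
                               n_boot = 1000, seed = 1L) {
  stopifnot(inherits(rs, "va_recordset"))
  if (length(unique(rs$place_class)) < 2)
    stop("both place classes must be present")
  scheme <- rs_scheme(rs)
  comm <- weighted_csmf(rs, "community")
  fac <- weighted_csmf(rs, "facility")

  if (ci) {
    # one bootstrap pass for the whole CSMF vector of each group
    mat <- csmf_bootstrap_replicates(rs, n_boot = n_boot, seed = seed)
    qs <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                            na.rm = TRUE)
    q_comm <- qs(mat$community); q_fac <- qs(mat$facility)
  }

  res <- lapply(scheme$causes, function(cz) {
    in_cause <- rs$cause == cz
    raw <- rbind(community = c(sum(in_cause & rs$place_class == "community"),
                               sum(!in_cause & rs$place_class == "community")),
                 facility = c(sum(in_cause & rs$place_class == "facility"),
                              sum(!in_cause & rs$place_class == "facility")))
    expected <- outer(rowSums(raw), colSums(raw)) / sum(raw)
    use_fisher <- any(raw == 0) || any(expected < 5)
    if (use_fisher) {
      if (rs_design_mode(rs) == "weighted_clustered" &&
          stats::sd(rs$weight) > 0)
        message("compare_all_causes: Fisher fallback on raw counts for '",
                cz, "' ignores non-uniform weights")
      p <- suppressMessages(fisher_exact_test(raw))
      test <- "fisher"
    } else {
      p <- rao_scott_test(rs, cause = cz)$p_value
      test <- "rao_scott"
    }
    data.frame(cause = cz,
               community_mf = 100 * comm[[cz]],
               facility_mf = 100 * fac[[cz]],
               p_value = p, test_used = test,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (ci) {
    out$community_lower <- 100 * q_comm[1, ]
    out$community_upper <- 100 * q_comm[2, ]
    out$facility_lower <- 100 * q_fac[1, ]
    out$facility_upper <- 100 * q_fac[2, ]
    out <- out[, c("cause", "community_mf", "community_lower", "community_upper",
                   "facility_mf", "facility_lower", "facility_upper",
                   "p_value", "test_used")]
  }
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  class(out) <- c("cause_comparison", "data.frame")
  out
}

# One bootstrap pass returning replicate CSMF matrices for both place
# classes (rows = replicates, cols = causes). Shares the PSU-resampling
# scheme of psu_bootstrap.
#' @keywords internal
csmf_bootstrap_replicates <- function(rs, n_boot, seed) {
  causes <- rs_scheme(rs)$causes
  clustered <- rs_design_mode(rs) == "weighted_clustered"
  if (clustered) {
    psu_key <- paste(rs$stratum_id, rs$psu_id, sep = "\r")
    idx_by_psu <- split(seq_len(nrow(rs)), psu_key)
    psu_stratum <- vapply(idx_by_psu, function(i) as.character(rs$stratum_id[i[1]]), "")
    psus_by_stratum <- split(seq_along(idx_by_psu), psu_stratum)
  }
  w_all <- effective_weights(rs)
  cz <- factor(rs$cause, levels = causes)
  fac <- rs$place_class == "facility"
  comm_mat <- fac_mat <- matrix(NA_real_, n_boot, length(causes),
                                dimnames = list(NULL, causes))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- if (clustered) {
        drawn <- unlist(lapply(psus_by_stratum, function(p)
          p[sample.int(length(p), length(p), replace = TRUE)]), use.names = FALSE)
        unlist(idx_by_psu[drawn], use.names = FALSE)
      } else sample.int(nrow(rs), nrow(rs), replace = TRUE)
      w <- w_all[idx]; cc <- cz[idx]; ff <- fac[idx]
      if (any(!ff)) {
        t1 <- tapply(w[!ff], cc[!ff], sum, default = 0)
        comm_mat[b, ] <- t1 / sum(w[!ff])
      }
      if (any(ff)) {
        t2 <- tapply(w[ff], cc[ff], sum, default = 0)
        fac_mat[b, ] <- t2 / sum(w[ff])
      }
    }
  })
  list(community = comm_mat, facility = fac_mat)
}

#' @export
print.cause_comparison <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "p_value"
  df[num] <- lapply(df[num], round, digits)
  df$p_value <- signif(df$p_value, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Demographic composition of community versus facility deaths
#'
#' For each requested covariate, the weighted percentage of deaths at each
#' covariate level within the community and within the facility group, and
#' a design-corrected p-value for the association between the covariate and
#' the place of death (Rao-Scott chi-square on the covariate x place table;
#' ordinary Pearson chi-square in unweighted mode). Missing covariate
#' values form an explicit `"missing"` level. Percentages within a factor
#' sum to 100 over its levels.
#'
#' @param rs A [va_recordset()].
#' @param factors Character vector of record columns (e.g. `"age_band"`,
#'   `"mother_education"`, `"sex"`, `"born_in_facility"`,
#'   `"wealth_quintile"`, `"anc_formal"`).
#' @return Data frame with columns `factor`, `level`, `community_pct`,
#'   `facility_pct`, `p_value`.
#' @export
demographic_table <- function(rs, factors = c("age_band", "mother_education",
                                              "sex", "born_in_facility",
                                              "wealth_quintile")) {
  stopifnot(inherits(rs, "va_recordset"), nrow(rs) > 0)
  unknown <- setdiff(factors, names(rs))
  if (length(unknown)) stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  w <- effective_weights(rs)
  grp <- rs$place_class
  out <- lapply(factors, function(f) {
    v <- as.character(rs[[f]])
    v[is.na(v)] <- "missing"
    lv <- sort(unique(v))
    pct <- function(g) {
      wi <- w[grp == g]
      vi <- factor(v[grp == g], levels = lv)
      100 * tapply(wi, vi, sum, default = 0) / sum(wi)
    }
    p <- if (length(lv) > 1 && length(unique(grp)) == 2)
      rao_scott_test(rs, factor_name = f)$p_value else 1
    data.frame(factor = f, level = lv,
               community_pct = as.numeric(pct("community")),
               facility_pct = as.numeric(pct("facility")),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
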