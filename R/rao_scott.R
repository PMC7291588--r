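#' Rao-Scott corrected chi-square test for survey data
#'
#' Tests independence between two categorical record-level variables under
#' a stratified, clustered, weighted design. The Pearson chi-square is
#' computed on the weighted cell proportions (scaled by the raw sample
#' size) and corrected by the generalized design effect: the eigenvalues of
#' the design-effect matrix of the independence contrasts, estimated by
#' linearization over PSU totals within strata (with-replacement
#' first-stage approximation). The second-order (Satterthwaite) correction
#' divides the statistic by \eqn{\bar\lambda (1 + a^2)} where \eqn{a} is
#' the coefficient of variation of the eigenvalues; the first-order
#' correction uses \eqn{\bar\lambda} alone.
#'
#' The corrected statistic is referred to an F distribution with
#' Satterthwaite-adjusted numerator degrees of freedom and denominator
#' degrees of freedom proportional to (number of PSUs minus number of
#' strata). Under a degenerate iid design (every record its own PSU, equal
#' weights, one stratum) the design effect is exactly 1, the statistic
#' reduces to the ordinary Pearson chi-square, and the `"chisq"` reference
#' reproduces the ordinary Pearson p-value; `"chisq"` is also what the
#' unweighted (census) mode uses.
#'
#' @param rs A [va_recordset()].
#' @param cause A cause label: the test is place class x (cause vs all
#'   other causes). Alternatively use `factor_name` to test place class
#'   against an arbitrary categorical record column.
#' @param factor_name Optional name of a record column to use as the row
#'   variable instead of the cause indicator (missing values become an
#'   explicit level).
#' @param order `2` (Satterthwaite, default) or `1` (first-order
#'   correction).
#' @param p_reference `"F"` (default for clustered designs) or `"chisq"`.
#' @return List with `statistic` (the design-corrected chi-square),
#'   `p_value`, `df`, `design_effect` (mean eigenvalue) and `test`.
#' @export
rao_scott_test <- function(rs, cause = NULL, factor_name = NULL,
                           order = 2, p_reference = c("F", "chisq")) {
  stopifnot(inherits(rs, "va_recordset"))
  p_reference <- match.arg(p_reference)
  if (is.null(cause) == is.null(factor_name))
    stop("supply exactly one of 'cause' or 'factor_name'")
  if (!is.null(cause)) {
    if (!cause %in% rs_scheme(rs)$causes) stop("unknown cause: ", cause)
    y <- factor(ifelse(rs$cause == cause, cause, "other_causes"),
                levels = c(cause, "other_causes"))
    if (all(rs$cause != cause))
      stop("cause '", cause, "' absent from both groups: test undefined")
  } else {
    if (!factor_name %in% names(rs)) stop("unknown factor: ", factor_name)
    v <- as.character(rs[[factor_name]])
    v[is.na(v)] <- "missing"
    y <- factor(v)
    if (nlevels(y) < 2) stop("factor '", factor_name, "' has a single level")
  }
  g <- factor(rs$place_class, levels = c("community", "facility"))
  if (any(table(g) == 0)) stop("both place classes must be present")

  if (rs_design_mode(rs) == "unweighted") {
    ct <- suppressWarnings(stats::chisq.test(table(y, g), correct = FALSE))
    return(list(statistic = unname(ct$statistic), p_value = ct$p.value,
                df = unname(ct$parameter), design_effect = 1,
                test = "pearson_chisq"))
  }

  survey_chisq(y, g, w = rs$weight, stratum = rs$stratum_id, psu = rs$psu_id,
               order = order, p_reference = p_reference)
}

# Core Rao-Scott machinery on record-level factors y (r levels) x g (c levels).
#' @keywords internal
survey_chisq <- function(y, g, w, stratum, psu, order = 2,
                         p_reference = "F") {
  r <- nlevels(y); cc <- nlevels(g); n <- length(y)
  K <- r * cc
  cell <- (as.integer(g) - 1L) * r + as.integer(y)  # column-major r x cc
  W <- sum(w)
  p_hat <- as.numeric(tapply(w, factor(cell, levels = seq_len(K)), sum, default = 0)) / W
  P <- matrix(p_hat, r, cc)
  prow <- rowSums(P); pcol <- colSums(P)
  if (any(prow <= 0) || any(pcol <= 0))
    stop("all margins must be positive for the chi-square test")
  E <- outer(prow, pcol)
  X2 <- n * sum((P - E)^2 / E)

  # contrast derivatives H: d x K, d = (r-1)(c-1), h_jk = p_jk - prow_j pcol_k
  d <- (r - 1) * (cc - 1)
  H <- matrix(0, d, K)
  row_of <- rep(seq_len(r), times = cc)
  col_of <- rep(seq_len(cc), each = r)
  ctr <- 0
  for (k in seq_len(cc - 1)) for (j in seq_len(r - 1)) {
    ctr <- ctr + 1
    H[ctr, ] <- (row_of == j & col_of == k) -
      (row_of == j) * pcol[k] - (col_of == k) * prow[j]
  }

  # design covariance of p_hat: stratified with-replacement PSU linearization
  delta <- matrix(0, n, K)
  delta[cbind(seq_len(n), cell)] <- 1
  Z <- (w / W) * sweep(delta, 2, p_hat)      # n x K influence contributions
  psu_key <- factor(paste(stratum, psu, sep = "\r"))
  U <- rowsum(Z, psu_key, reorder = FALSE)   # PSU totals
  psu_stratum <- tapply(as.character(stratum), psu_key, function(s) s[1])
  psu_stratum <- psu_stratum[rownames(U)]
  V <- matrix(0, K, K)
  n_psu <- nrow(U); n_strata <- 0L
  for (h in unique(psu_stratum)) {
    Uh <- U[psu_stratum == h, , drop = FALSE]
    m_h <- nrow(Uh)
    n_strata <- n_strata + 1L
    if (m_h < 2) stop("design error: stratum '", h, "' has a single PSU")
    Uh <- sweep(Uh, 2, colMeans(Uh))
    V <- V + crossprod(Uh) * m_h / (m_h - 1)
  }
  nu <- n_psu - n_strata

  # multinomial (SRS) covariance at p_hat, with the matching small-sample
  # factor so the design effect is exactly 1 under an iid design
  V0 <- (diag(p_hat) - tcrossprod(p_hat)) / (n - 1)

  Vh <- H %*% V %*% t(H)
  V0h <- H %*% V0 %*% t(H)
  lambda <- Re(eigen(solve(V0h, Vh), only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)
  lbar <- mean(lambda)
  if (lbar <= 0) stop("degenerate design-effect estimate")
  a2 <- if (order == 2 && d > 1) sum((lambda - lbar)^2) / (d * lbar^2) else 0
  stat <- X2 / (lbar * (1 + a2))
  df1 <- d / (1 + a2)
  p <- if (p_reference == "F") {
    stats::pf(stat / df1, df1, df1 * max(nu, 1), lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, df = df1, design_effect = lbar,
       test = "rao_scott", ddf = df1 * max(nu, 1), eigenvalues = lambda)
}

#' Fisher exact test on a 2x2 table of raw counts
#'
#' Two-sided exact p-value summing the probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's
#' (via [stats::fisher.test()]). The test uses raw unweighted counts:
#' exactness is undefined for non-integer weighted counts. A table with a
#' zero margin has only one attainable configuration and returns p = 1 by
#' convention (with a message).
#'
#' @param raw_counts 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_test <- function(raw_counts) {
  m <- as.matrix(raw_counts)
  if (!all(dim(m) == c(2, 2))) stop("raw_counts must be a 2x2 matrix")
  if (any(m < 0) || any(m != round(m)))
    stop("raw_counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    message("fisher_exact_test: zero margin; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(m)$p.value
}
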