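#' Cause schemes for under-5 verbal autopsy analysis
#'
#' The package works with two fixed cause lists: a 10-cause scheme for
#' neonatal deaths (0-27 days) and a 12-cause scheme for child deaths
#' (1-59 months). Cause order is fixed and is used for output columns and
#' deterministic tie-breaking throughout.
#'
#' @param age_group `"neonate"` or `"child"`.
#' @return An object of class `cause_scheme`: a list with elements
#'   `age_group` and `causes` (ordered character vector).
#' @examples
#' cause_scheme("neonate")$causes
#' @export
cause_scheme <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  causes <- switch(age_group,
    neonate = c("tetanus", "congenital", "birth_asphyxia_injury", "meningitis",
                "diarrhea", "pneumonia", "sepsis", "other", "preterm",
                "unspecified"),
    child = c("injury", "aids", "malnutrition", "measles", "meningitis",
              "dysentery", "diarrhea", "pertussis", "pneumonia", "malaria",
              "other", "unspecified"))
  structure(list(age_group = age_group, causes = causes),
            class = "cause_scheme")
}

#' @export
print.cause_scheme <- function(x, ...) {
  cat(sprintf("Cause scheme (%s, %d causes): %s\n",
              x$age_group, length(x$causes), paste(x$causes, collapse = ", ")))
  invisible(x)
}

#' Construct and validate a CSMF vector
#'
#' A cause-specific mortality fraction (CSMF) vector is a probability vector
#' over the causes of a [cause_scheme()]: each fraction lies in `[0, 1]` and
#' the fractions sum to 1 (within `1e-9`).
#'
#' @param fractions Numeric vector of fractions. If named, names must match
#'   the scheme's causes (any order); if unnamed, scheme order is assumed.
#' @param scheme A `cause_scheme`, or `NULL` for a free-standing vector
#'   (names are kept as given).
#' @return A named numeric vector of class `csmf` in scheme cause order,
#'   with attribute `age_group` when a scheme is supplied.
#' @export
csmf_vector <- function(fractions, scheme = NULL) {
  if (!is.numeric(fractions)) stop("fractions must be numeric")
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "cause_scheme"))
    if (is.null(names(fractions))) {
      if (length(fractions) != length(scheme$causes))
        stop("unnamed fractions must have one entry per scheme cause")
      names(fractions) <- scheme$causes
    } else {
      if (!setequal(names(fractions), scheme$causes))
        stop("fraction names do not match the scheme's causes")
      fractions <- fractions[scheme$causes]
    }
  }
  if (any(fractions < -1e-12) || any(fractions > 1 + 1e-12))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop(sprintf("fractions must sum to 1 (got %.12f)", sum(fractions)))
  structure(pmin(pmax(fractions, 0), 1), class = "csmf",
            age_group = if (!is.null(scheme)) scheme$age_group else NULL)
}

#' @export
print.csmf <- function(x, digits = 4, ...) {
  ag <- attr(x, "age_group")
  cat(sprintf("CSMF vector%s:\n",
              if (!is.null(ag)) paste0(" (", ag, ")") else ""))
  print(round(unclass(x)[seq_along(x)], digits))
  invisible(x)
}

#' @export
as.data.frame.csmf <- function(x, ...) {
  data.frame(cause = names(x), fraction = as.numeric(x),
             stringsAsFactors = FALSE)
}

#' CSMF accuracy between two cause distributions
#'
#' The cause-specific mortality fraction accuracy of a predicted
#' distribution against a reference distribution:
#' \deqn{1 - \frac{\sum_j |ref_j - pred_j|}{2\,(1 - \min_j ref_j)}}
#' It equals 1 when the distributions are identical and 0 when all predicted
#' mass sits on the reference's minimum-fraction cause (the maximal
#' attainable divergence given the reference). The statistic is not
#' symmetric: the reference distribution sets the denominator. The result is
#' clamped to `[0, 1]`.
#'
#' @param pred Predicted CSMF (a `csmf` or plain numeric probability vector).
#' @param ref Reference CSMF on the same cause scheme.
#' @return A single number in `[0, 1]`.
#' @examples
#' csmf_accuracy(c(0.6, 0.2, 0.2), c(0.5, 0.3, 0.2))  # 0.875
#' @export
csmf_accuracy <- function(pred, ref) {
  pred <- as.numeric_csmf(pred)
  ref <- as.numeric_csmf(ref)
  if (length(pred) != length(ref))
    stop("pred and ref must share a cause scheme (lengths differ)")
  if (!is.null(names(pred)) && !is.null(names(ref))) {
    if (!setequal(names(pred), names(ref)))
      stop("pred and ref must share a cause scheme (cause labels differ)")
    pred <- pred[names(ref)]
  }
  denom <- 2 * (1 - min(ref))
  if (denom <= 0) stop("degenerate reference: min fraction is 1")
  acc <- 1 - sum(abs(ref - pred)) / denom
  min(max(acc, 0), 1)
}

as.numeric_csmf <- function(x) {
  v <- unclass(x)
  if (!is.numeric(v)) stop("CSMF must be numeric")
  if (any(v < -1e-9)) stop("CSMF fractions must be non-negative")
  if (abs(sum(v) - 1) > 1e-6)
    stop("CSMF fractions must sum to 1")
  v
}
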