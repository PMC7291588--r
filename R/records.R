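#' @keywords internal
record_columns <- function() {
  c("record_id", "age_group", "cause", "raw_place",
    "provider_seen_at_facility", "age_band", "mother_education",
    "anc_formal", "sex", "born_in_facility", "wealth_quintile",
    "stratum_id", "psu_id", "weight")
}

raw_place_levels <- function() {
  c("hospital", "other_provider_or_facility", "on_route", "home", "other")
}

# Facility sub-categories accepted in input but collapsed before
# classification: the analyses only ever use the binary facility/community
# split.
facility_subcategories <- function() {
  c("health_center", "health_post", "private_doctor_clinic")
}

age_band_levels <- function(age_group) {
  if (age_group == "neonate") c("days_0_6", "days_7_27")
  else c("m1_11", "m12_23", "m24_59")
}

#' Classify place of death as facility or community
#'
#' Deaths in a hospital are facility deaths. Deaths at an "other health
#' provider or facility" count as facility deaths only when the provider was
#' seen at a health facility (trained community health workers, nurses or
#' midwives seen elsewhere are community care). Deaths at home, on route to
#' a provider or facility, or at any other place are community deaths.
#'
#' @param raw_place One of `"hospital"`, `"other_provider_or_facility"`
#'   (or a sub-category `"health_center"`, `"health_post"`,
#'   `"private_doctor_clinic"`, which are collapsed), `"on_route"`,
#'   `"home"`, `"other"`. Vectorised.
#' @param provider_seen_at_facility `"yes"`, `"no"` or `"not_applicable"`.
#' @return Character vector, `"facility"` or `"community"`.
#' @export
classify_place <- function(raw_place, provider_seen_at_facility = "not_applicable") {
  n <- max(length(raw_place), length(provider_seen_at_facility))
  raw_place <- rep_len(as.character(raw_place), n)
  flag <- rep_len(as.character(provider_seen_at_facility), n)
  raw_place[raw_place %in% facility_subcategories()] <- "other_provider_or_facility"
  bad <- !raw_place %in% raw_place_levels()
  if (any(bad))
    stop("invalid raw_place value(s): ", paste(unique(raw_place[bad]), collapse = ", "))
  bad_flag <- !flag %in% c("yes", "no", "not_applicable")
  if (any(bad_flag))
    stop("invalid provider_seen_at_facility value(s): ",
         paste(unique(flag[bad_flag]), collapse = ", "))
  unresolved <- raw_place == "other_provider_or_facility" & flag == "not_applicable"
  if (any(unresolved))
    stop("place of death 'other_provider_or_facility' requires provider_seen_at_facility ",
         "= yes/no; unresolved in ", sum(unresolved), " record(s)")
  out <- ifelse(raw_place == "hospital" |
                  (raw_place == "other_provider_or_facility" & flag == "yes"),
                "facility", "community")
  out
}

#' Assemble a validated record set of under-5 deaths
#'
#' A record set is a data frame of death records (one row per death) sharing
#' an age group and cause scheme, together with the survey-design mode.
#' `place_class` is derived from `raw_place` and
#' `provider_seen_at_facility` via [classify_place()] and never taken from
#' the input. Missing covariates are kept as `NA`, never imputed.
#'
#' @param records Data frame with the columns of the standard record CSV
#'   (see [read_va_records()]).
#' @param age_group `"neonate"` or `"child"`.
#' @param design_mode `"weighted_clustered"` (survey weights and PSUs used)
#'   or `"unweighted"` (census-style data: all weights treated as 1 and the
#'   bootstrap resamples individual records).
#' @return A data frame of class `va_recordset` with attributes
#'   `age_group`, `scheme` and `design_mode`, and a derived `place_class`
#'   column.
#' @export
va_recordset <- function(records, age_group = c("neonate", "child"),
                         design_mode = c("weighted_clustered", "unweighted")) {
  age_group <- match.arg(age_group)
  design_mode <- match.arg(design_mode)
  scheme <- cause_scheme(age_group)
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) stop("empty input: no death records")

  bad_age <- which(records$age_group != age_group)
  if (length(bad_age))
    stop("row(s) ", paste(utils::head(bad_age, 5), collapse = ", "),
         ": age_group does not match '", age_group, "'")
  bad_cause <- which(!records$cause %in% scheme$causes)
  if (length(bad_cause))
    stop("row(s) ", paste(utils::head(bad_cause, 5), collapse = ", "),
         ": cause not in the ", age_group, " scheme (",
         paste(unique(records$cause[bad_cause]), collapse = ", "), ")")
  w <- suppressWarnings(as.numeric(records$weight))
  bad_w <- which(is.na(w) | w <= 0)
  if (length(bad_w))
    stop("row(s) ", paste(utils::head(bad_w, 5), collapse = ", "),
         ": weight must be a positive number")
  records$weight <- w

  bad_band <- which(!records$age_band %in% age_band_levels(age_group))
  if (length(bad_band))
    stop("row(s) ", paste(utils::head(bad_band, 5), collapse = ", "),
         ": invalid age_band for ", age_group)
  bad_edu <- which(!(is.na(records$mother_education) |
                       records$mother_education %in% c("none", "primary", "secondary_plus")))
  if (length(bad_edu))
    stop("row(s) ", paste(utils::head(bad_edu, 5), collapse = ", "),
         ": invalid mother_education")
  for (col in c("anc_formal", "born_in_facility")) {
    v <- records[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad))
      stop("row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           ": ", col, " must be 0/1 or missing")
  }
  wq <- records$wealth_quintile
  bad_wq <- which(!(is.na(wq) | wq %in% 1:5))
  if (length(bad_wq))
    stop("row(s) ", paste(utils::head(bad_wq, 5), collapse = ", "),
         ": wealth_quintile must be 1-5 or missing")

  # one stratum per PSU
  psu_strata <- tapply(records$stratum_id, records$psu_id,
                       function(s) length(unique(s)))
  if (any(psu_strata > 1))
    stop("psu_id must nest within stratum_id; PSU(s) in multiple strata: ",
         paste(utils::head(names(psu_strata)[psu_strata > 1], 5), collapse = ", "))
  if (design_mode == "weighted_clustered" &&
      length(unique(records$psu_id)) < 2L)
    stop("weighted_clustered mode requires at least 2 PSUs")

  records$place_class <- classify_place(records$raw_place,
                                        records$provider_seen_at_facility)
  rownames(records) <- NULL
  structure(records, age_group = age_group, scheme = scheme,
            design_mode = design_mode,
            class = c("va_recordset", "data.frame"))
}

rs_scheme <- function(rs) attr(rs, "scheme")
rs_age_group <- function(rs) attr(rs, "age_group")
rs_design_mode <- function(rs) attr(rs, "design_mode")

#' Subset a record set keeping its design attributes
#' @keywords internal
rs_subset <- function(rs, idx) {
  out <- as.data.frame(rs)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, age_group = rs_age_group(rs), scheme = rs_scheme(rs),
            design_mode = rs_design_mode(rs),
            class = c("va_recordset", "data.frame"))
}

#' @export
print.va_recordset <- function(x, ...) {
  tab <- table(factor(x$place_class, c("community", "facility")))
  cat(sprintf("VA record set: %d %s deaths (%d community, %d facility), %s design\n",
              nrow(x), rs_age_group(x), tab[["community"]], tab[["facility"]],
              rs_design_mode(x)))
  invisible(x)
}

#' Read death records from the standard CSV layout
#'
#' The file is comma-delimited UTF-8 with a header row naming the columns
#' `record_id, age_group, cause, raw_place, provider_seen_at_facility,
#' age_band, mother_education, anc_formal, sex, born_in_facility,
#' wealth_quintile, stratum_id, psu_id, weight`. Booleans are encoded 0/1
#' and missing values as empty fields.
#'
#' @param path Path to the CSV file.
#' @param age_group `"neonate"` or `"child"`.
#' @param design_mode Passed to [va_recordset()].
#' @return A `va_recordset`.
#' @export
read_va_records <- function(path, age_group = c("neonate", "child"),
                            design_mode = c("weighted_clustered", "unweighted")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty input: ", path)
  for (col in c("anc_formal", "born_in_facility", "wealth_quintile", "weight"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  va_recordset(df, age_group = match.arg(age_group),
               design_mode = match.arg(design_mode))
}

#' Write death records to the standard CSV layout
#'
#' Inverse of [read_va_records()]: `read_va_records(write_va_records(rs, f))`
#' reproduces `rs` field for field. The derived `place_class` column is not
#' written.
#'
#' @param rs A `va_recordset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_va_records <- function(rs, path) {
  df <- as.data.frame(rs)[, record_columns()]
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
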