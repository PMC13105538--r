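## Study-drug exposure cohorts: generic + brand name matching, the
## primary-suspect restriction, indication filtering, and descriptive
## summaries of the resulting report sets.

#' Default trailing-token stop list for drug-name normalization
#'
#' Salt, ester and formulation tokens stripped from the end of verbatim
#' drug names before dictionary matching.
#' @return character vector of tokens.
#' @export
default_stop_tokens <- function() {
  c("MESYLATE", "MESILATE", "HYDROCHLORIDE", "HCL", "DIHYDROCHLORIDE",
    "MALEATE", "DIMALEATE", "FUMARATE", "DIFUMARATE", "TOSYLATE",
    "PHOSPHATE", "SULFATE", "SODIUM", "TABLET", "TABLETS", "CAPSULE",
    "CAPSULES", "ORAL", "FILM-COATED", "MG")
}

#' Normalize a verbatim drug name
#'
#' Uppercases, trims, collapses internal whitespace and repeatedly removes
#' trailing tokens found in the stop list (salts, formulations), so that
#' e.g. `"  Osimertinib Mesylate "` matches the dictionary entry
#' `"OSIMERTINIB"`.
#'
#' @param verbatim character vector of names.
#' @param stop_tokens tokens stripped from the end; see
#'   [default_stop_tokens()].
#' @return normalized character vector.
#' @export
normalize_name <- function(verbatim, stop_tokens = default_stop_tokens()) {
  x <- toupper(trimws(as.character(verbatim)))
  x <- gsub("[[:space:]]+", " ", x)
  repeat {
    toks <- sub("^.*[ ]", "", x)                 # last token
    strip <- grepl(" ", x, fixed = TRUE) & toks %in% stop_tokens
    if (!any(strip, na.rm = TRUE)) break
    x[strip] <- sub("[ ][^ ]+$", "", x[strip])
  }
  x[is.na(verbatim)] <- NA_character_
  x
}

#' Construct a drug dictionary
#'
#' A dictionary maps canonical drug identifiers to their synonyms (generic
#' names, salts, brand names) and to a molecular target class. Matching is
#' exact on normalized strings, so every synonym must be unique across
#' drugs after normalization.
#'
#' @param entries a data.frame with columns `drug_id`, `class`, `synonym`.
#' @param stop_tokens passed to [normalize_name()].
#' @return a `drug_dictionary` object.
#' @seealso [default_drug_dictionary()], [match_drug()]
#' @export
drug_dictionary <- function(entries, stop_tokens = default_stop_tokens()) {
  dt <- data.table::as.data.table(entries)
  stopifnot(all(c("drug_id", "class", "synonym") %in% names(dt)))
  dt[, norm_synonym := normalize_name(synonym, stop_tokens)]
  dup <- dt[, .(n = data.table::uniqueN(drug_id)), by = norm_synonym][n > 1]
  if (nrow(dup)) {
    stop("synonym(s) shared by multiple drugs after normalization: ",
         paste(dup$norm_synonym, collapse = ", "), call. = FALSE)
  }
  cls <- dt[, .(n = data.table::uniqueN(class)), by = drug_id][n > 1]
  if (nrow(cls)) {
    stop("drug(s) assigned more than one class: ",
         paste(cls$drug_id, collapse = ", "), call. = FALSE)
  }
  structure(dt, class = c("drug_dictionary", class(dt)),
            stop_tokens = stop_tokens)
}

#' Default dictionary: 14 targeted agents used in NSCLC
#'
#' Generic and principal brand names for the five EGFR-TKIs (gefitinib,
#' erlotinib, afatinib, dacomitinib, osimertinib), five ALK-TKIs
#' (crizotinib, ceritinib, alectinib, brigatinib, lorlatinib), the ROS1-TKI
#' repotrectinib, the RET-TKIs pralsetinib and selpercatinib, and the
#' KRAS-G12C inhibitor adagrasib. Fully overrideable via
#' [drug_dictionary()].
#'
#' @return a `drug_dictionary`.
#' @export
default_drug_dictionary <- function() {
  syn <- list(
    gefitinib    = list("EGFR",      c("GEFITINIB", "IRESSA")),
    erlotinib    = list("EGFR",      c("ERLOTINIB", "TARCEVA")),
    afatinib     = list("EGFR",      c("AFATINIB", "GILOTRIF", "GIOTRIF")),
    dacomitinib  = list("EGFR",      c("DACOMITINIB", "VIZIMPRO")),
    osimertinib  = list("EGFR",      c("OSIMERTINIB", "TAGRISSO")),
    crizotinib   = list("ALK",       c("CRIZOTINIB", "XALKORI")),
    ceritinib    = list("ALK",       c("CERITINIB", "ZYKADIA")),
    alectinib    = list("ALK",       c("ALECTINIB", "ALECENSA")),
    brigatinib   = list("ALK",       c("BRIGATINIB", "ALUNBRIG")),
    lorlatinib   = list("ALK",       c("LORLATINIB", "LORBRENA",
                                       "LORVIQUA")),
    repotrectinib = list("ROS1",     c("REPOTRECTINIB", "AUGTYRO")),
    pralsetinib  = list("RET",       c("PRALSETINIB", "GAVRETO")),
    selpercatinib = list("RET",     c("SELPERCATINIB", "RETEVMO",
                                      "RETSEVMO")),
    adagrasib    = list("KRAS-G12C", c("ADAGRASIB", "KRAZATI")))
  entries <- data.table::rbindlist(lapply(names(syn), function(id) {
    data.table::data.table(drug_id = id, class = syn[[id]][[1L]],
                           synonym = syn[[id]][[2L]])
  }))
  drug_dictionary(entries)
}

#' Match verbatim drug names against a dictionary
#'
#' Exact lookup of the normalized verbatim name among normalized synonyms.
#'
#' @param verbatim character vector of names as reported.
#' @param dict a [drug_dictionary()].
#' @return character vector of canonical drug ids, `NA` where unmatched.
#' @export
match_drug <- function(verbatim, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  norm <- normalize_name(verbatim, attr(dict, "stop_tokens"))
  dict$drug_id[match(norm, dict$norm_synonym)]
}

#' Annotate a store's drug mentions with canonical drug ids
#'
#' Matching checks both `DRUG.drugname` (where brand names live) and
#' `DRUG.prod_ai` (active ingredients); the drugname match wins when both
#' resolve.
#'
#' @param store a `faers_store`.
#' @param dict a [drug_dictionary()].
#' @return the store with `drugs$matched_drug_id` filled in.
#' @export
match_store_drugs <- function(store, dict) {
  stopifnot(inherits(store, "faers_store"))
  drugs <- data.table::copy(store$drugs)
  by_name <- match_drug(drugs$verbatim_name, dict)
  by_ai <- match_drug(drugs$prod_ai, dict)
  drugs[, matched_drug_id := data.table::fifelse(is.na(by_name), by_ai,
                                                 by_name)]
  store$drugs <- drugs
  store
}

#' Indication term sets
#'
#' The set of indication strings that defines the study population;
#' matching is exact on normalized (uppercased, whitespace-collapsed)
#' strings. The default ships common FAERS codings of non-small cell lung
#' cancer and is fully overrideable.
#'
#' @param terms character vector of indication terms.
#' @return a normalized, unique character vector of class
#'   `indication_terms`.
#' @export
indication_terms <- function(terms) {
  terms <- unique(gsub("[[:space:]]+", " ", toupper(trimws(terms))))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("indication term set is empty", call. = FALSE)
  structure(terms, class = "indication_terms")
}

#' @rdname indication_terms
#' @export
default_indication_terms <- function() {
  indication_terms(c(
    "NON-SMALL CELL LUNG CANCER",
    "NON-SMALL CELL LUNG CANCER METASTATIC",
    "NON-SMALL CELL LUNG CANCER RECURRENT",
    "NON-SMALL CELL LUNG CANCER STAGE IIIB",
    "NON-SMALL CELL LUNG CANCER STAGE IV",
    "LUNG ADENOCARCINOMA",
    "LUNG ADENOCARCINOMA METASTATIC",
    "LUNG SQUAMOUS CELL CARCINOMA",
    "LUNG SQUAMOUS CELL CARCINOMA METASTATIC",
    "LUNG LARGE CELL CARCINOMA"))
}

#' Build the exposure cohort for one study drug
#'
#' Selects de-duplicated reports in which the drug appears with role
#' primary suspect (PS). With `require_indication = TRUE`, the report must
#' additionally carry a qualifying indication term; by default the
#' indication must attach to the matched PS mention's `drug_seq`
#' (`indication_linkage = "drug_seq"`), with a report-level fallback
#' (`"report"`: any qualifying INDI row) available.
#'
#' @param store a de-duplicated `faers_store` (drug mentions are matched
#'   against `dict` on the fly if not already annotated).
#' @param drug_id canonical drug id present in `dict`.
#' @param dict a [drug_dictionary()].
#' @param indications an [indication_terms()] set.
#' @param require_indication logical; filter on indication?
#' @param indication_linkage `"drug_seq"` or `"report"`.
#' @return a `faers_cohort`: list with `drug_id`, `class`, `primaryids`,
#'   `n`.
#' @export
build_cohort <- function(store, drug_id, dict = default_drug_dictionary(),
                         indications = default_indication_terms(),
                         require_indication = FALSE,
                         indication_linkage = c("drug_seq", "report")) {
  stopifnot(inherits(store, "faers_store"))
  indication_linkage <- match.arg(indication_linkage)
  if (!drug_id %in% dict$drug_id) {
    stop("unknown drug_id: ", drug_id, call. = FALSE)
  }
  if (all(is.na(store$drugs$matched_drug_id))) {
    store <- match_store_drugs(store, dict)
  }
  the_id <- drug_id
  ps <- store$drugs[role == "PS" & matched_drug_id == the_id &
                      !is.na(matched_drug_id)]
  if (require_indication && nrow(ps)) {
    ind <- store$indications[
      gsub("[[:space:]]+", " ",
           toupper(trimws(indi_pt))) %in% unclass(indications)]
    if (indication_linkage == "drug_seq") {
      hit <- ps[ind, on = c(primaryid = "primaryid",
                            drug_seq = "indi_drug_seq"),
                nomatch = NULL]
      ps <- ps[primaryid %in% unique(hit$primaryid)]
    } else {
      ps <- ps[primaryid %in% unique(ind$primaryid)]
    }
  }
  pids <- .pv_sort(unique(ps$primaryid))
  structure(list(drug_id = drug_id,
                 class = dict$class[match(drug_id, dict$drug_id)],
                 primaryids = pids, n = length(pids)),
            class = "faers_cohort")
}

#' Build cohorts for every drug in a dictionary
#'
#' @inheritParams build_cohort
#' @param ... passed to [build_cohort()].
#' @return named list of `faers_cohort` objects, one per dictionary drug.
#' @export
build_all_cohorts <- function(store, dict = default_drug_dictionary(),
                              ...) {
  store <- match_store_drugs(store, dict)
  ids <- .pv_sort(unique(dict$drug_id))
  stats::setNames(lapply(ids, function(id) {
    build_cohort(store, id, dict, ...)
  }), ids)
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("<faers_cohort> ", x$drug_id, " (", x$class, "): ", x$n,
      " primary-suspect reports\n", sep = "")
  invisible(x)
}

.cohort_demo <- function(cohort, store) {
  store$demo[primaryid %in% cohort$primaryids]
}

.cat_block <- function(vals, labels, variable) {
  n <- length(vals)
  counts <- vapply(labels, function(l) sum(vals == l, na.rm = TRUE),
                   integer(1))
  miss <- sum(is.na(vals))
  dt <- data.table::data.table(
    variable = variable, level = c(labels, "missing"),
    count = c(counts, miss))
  dt[, pct := if (n > 0) 100 * count / n else NA_real_]
  dt
}

#' Descriptive summary of a cohort
#'
#' Counts and percentages by sex, reporter type and outcome category
#' (multi-outcome reports count in each category); mean/SD and
#' median/Q1-Q3 for age and weight; binned age (<18, 18-64.9, 65-85, >85
#' years) and weight (<50, 50-100, >100 kg). Missing values are counted
#' separately and never imputed.
#'
#' @param cohort a `faers_cohort`.
#' @param store the `faers_store` the cohort was drawn from.
#' @return list of data.tables: `categorical`, `continuous`, `binned`.
#' @export
descriptive_summary <- function(cohort, store) {
  demo <- .cohort_demo(cohort, store)
  n <- nrow(demo)
  cat_tabs <- list(
    .cat_block(data.table::fifelse(demo$sex == "unknown", NA_character_,
                                   demo$sex), c("F", "M"), "sex"),
    .cat_block(demo$reporter_type,
               unname(.faers_reporter_map), "reporter_type"))
  outc <- store$outcomes[primaryid %in% cohort$primaryids]
  outc_counts <- vapply(.faers_outcome_codes, function(cd) {
    sum(outc$outc_cod == cd)
  }, integer(1))
  outc_dt <- data.table::data.table(
    variable = "outcome", level = .faers_outcome_codes,
    count = outc_counts,
    pct = if (n > 0) 100 * outc_counts / n else NA_real_)
  categorical <- data.table::rbindlist(c(cat_tabs, list(outc_dt)))

  cont_row <- function(x, variable) {
    ok <- x[!is.na(x)]
    data.table::data.table(
      variable = variable, n = length(ok), n_missing = sum(is.na(x)),
      mean = if (length(ok)) mean(ok) else NA_real_,
      sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
      median = if (length(ok)) stats::median(ok) else NA_real_,
      q1 = if (length(ok)) unname(stats::quantile(ok, 0.25)) else NA_real_,
      q3 = if (length(ok)) unname(stats::quantile(ok, 0.75)) else NA_real_)
  }
  continuous <- rbind(cont_row(demo$age_years, "age_years"),
                      cont_row(demo$weight_kg, "weight_kg"))

  age_bin <- cut(demo$age_years, c(-Inf, 18, 65, 85, Inf), right = FALSE,
                 labels = c("<18", "18-64.9", "65-85", ">85"))
  wt_bin <- cut(demo$weight_kg, c(-Inf, 50, 100, Inf), right = TRUE,
                labels = c("<50", "50-100", ">100"))
  binned <- rbind(.cat_block(as.character(age_bin),
                             c("<18", "18-64.9", "65-85", ">85"),
                             "age_group"),
                  .cat_block(as.character(wt_bin),
                             c("<50", "50-100", ">100"), "weight_group"))
  out <- list(categorical = categorical, continuous = continuous,
              binned = binned, n = n)
  if (n == 0L) attr(out, "empty_cohort") <- TRUE
  out
}

#' Yearly report counts for a cohort
#'
#' Counts by calendar year of `FDA_DT`; reports with a missing date are
#' returned as a separate `NA`-year bucket.
#'
#' @inheritParams descriptive_summary
#' @return data.table with columns `year`, `count`.
#' @export
yearly_counts <- function(cohort, store) {
  demo <- .cohort_demo(cohort, store)
  if (nrow(demo) == 0L) {
    return(data.table::data.table(year = integer(), count = integer()))
  }
  yr <- demo$fda_dt %/% 10000L
  out <- data.table::data.table(year = yr)[, .(count = .N), by = year]
  data.table::setorder(out, year, na.last = TRUE)
  out
}

#' Per-field missingness profile
#'
#' Fraction of cohort reports with a missing value for each demographic
#' field (the descriptive counterpart of an imputation step; nothing is
#' imputed here).
#'
#' @inheritParams descriptive_summary
#' @return data.table with `field`, `n_missing`, `frac_missing`; fractions
#'   are `NA` (flagged via the `empty_cohort` attribute) for an empty
#'   cohort.
#' @export
missingness_profile <- function(cohort, store) {
  demo <- .cohort_demo(cohort, store)
  n <- nrow(demo)
  fields <- list(sex = demo$sex == "unknown",
                 age_years = is.na(demo$age_years),
                 weight_kg = is.na(demo$weight_kg),
                 fda_dt = is.na(demo$fda_dt),
                 reporter_country = is.na(demo$reporter_country),
                 reporter_type = is.na(demo$reporter_type))
  out <- data.table::data.table(
    field = names(fields),
    n_missing = vapply(fields, sum, integer(1)),
    frac_missing = if (n > 0) {
      vapply(fields, function(m) sum(m) / n, numeric(1))
    } else NA_real_)
  if (n == 0L) attr(out, "empty_cohort") <- TRUE
  out
}
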