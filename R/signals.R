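## 2x2 contingency construction and the four disproportionality methods:
## PRR/chi-square, ROR with 95% CI, BCPNN information component, and
## MGPS EBGM/EB05 (see mgps.R), plus concordance key-signal calling.

#' Construct a 2x2 contingency table for a drug-event pair
#'
#' Cells follow the standard pharmacovigilance layout: `a` = reports with
#' drug and event, `b` = drug without event, `c` = event without drug,
#' `d` = neither. `N = a+b+c+d` and the expected count under independence
#' `E = (a+b)(a+c)/N` are derived. All arguments are vectorized.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return a `contingency` data.table with columns `a,b,c,d,N,E`.
#' @export
contingency_table <- function(a, b, c, d) {
  dt <- data.table::data.table(a = as.numeric(a), b = as.numeric(b),
                               c = as.numeric(c), d = as.numeric(d))
  if (any(dt < 0, na.rm = TRUE)) stop("negative cell count", call. = FALSE)
  dt[, N := a + b + c + d]
  if (any(dt$N <= 0)) stop("empty contingency table (N = 0)",
                           call. = FALSE)
  dt[, E := (a + b) * (a + c) / N]
  data.table::setattr(dt, "class", c("contingency", class(dt)))
  dt
}

#' Build the 2x2 table for one cohort and one event term
#'
#' The counting unit is the de-duplicated report; a PT reported twice in
#' one report counts once. The comparator is the full ingested universe
#' (every de-duplicated report, cohort included).
#'
#' @param store the de-duplicated `faers_store` universe.
#' @param cohort a `faers_cohort` (must be a subset of the universe).
#' @param pt event term.
#' @return a one-row `contingency` table.
#' @export
build_contingency <- function(store, cohort, pt) {
  stopifnot(inherits(store, "faers_store"), inherits(cohort, "faers_cohort"))
  all_ids <- store$demo$primaryid
  if (!all(cohort$primaryids %in% all_ids)) {
    stop("cohort is not a subset of the universe", call. = FALSE)
  }
  the_pt <- pt
  with_pt <- unique(store$events[pt == the_pt]$primaryid)
  n <- length(all_ids)
  n_drug <- cohort$n
  n_pt <- length(with_pt)
  a <- sum(with_pt %in% cohort$primaryids)
  contingency_table(a, n_drug - a, n_pt - a, n - n_drug - n_pt + a)
}

#' Proportional reporting ratio and chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-square statistic is
#' `N(|ad-bc| - y)^2 / [(a+b)(c+d)(a+c)(b+d)]` with `y = 0` (Pearson) or
#' `y = N/2` (Yates continuity correction, the default in the FAERS
#' disproportionality literature; the numerator base is floored at 0).
#' A zero row or column margin makes the statistic undefined (`NA`),
#' never an error.
#'
#' @param tab a `contingency` table (any number of rows).
#' @param correction `"yates"` or `"pearson"`.
#' @return data.table with columns `prr`, `chi2`.
#' @export
prr_stats <- function(tab, correction = c("yates", "pearson")) {
  correction <- match.arg(correction)
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  cc <- as.numeric(tab$c); d <- as.numeric(tab$d)
  n <- a + b + cc + d
  prr <- (a / (a + b)) / (cc / (cc + d))
  prr[(a + b) == 0 | (cc + d) == 0 | cc == 0] <- NA_real_
  y <- if (correction == "yates") n / 2 else 0
  base <- pmax(abs(a * d - b * cc) - y, 0)
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- n * base^2 / denom
  chi2[denom == 0] <- NA_real_
  data.table::data.table(prr = prr, chi2 = chi2)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/(bc)`; the Wald interval is
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the estimate undefined (`NA`), carried as a soft failure.
#'
#' @param tab a `contingency` table.
#' @return data.table with columns `ror`, `ror_lo`, `ror_hi` (`ror_lo` is
#'   the ROR025 signal bound).
#' @export
ror_stats <- function(tab) {
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  cc <- as.numeric(tab$c); d <- as.numeric(tab$d)
  bad <- a == 0 | b == 0 | cc == 0 | d == 0
  ror <- a * d / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  ror[bad] <- NA_real_; lo[bad] <- NA_real_; hi[bad] <- NA_real_
  data.table::data.table(ror = ror, ror_lo = lo, ror_hi = hi)
}

#' BCPNN information component with credible lower bound
#'
#' Gamma-posterior shrinkage formulation of the information component: the
#' relative reporting rate has posterior `Gamma(a + 1/2, E + 1/2)` (shape,
#' rate), so `IC = log2[(a + 1/2)/(E + 1/2)]` and `IC025` is the log2 of
#' the exact 2.5th posterior percentile. The add-1/2 shrinkage makes every
#' table defined. A `"two_sigma"` approximation
#' (`IC - 2 * posterior SD of log2(rate)`) is available for compatibility
#' with normal-approximation implementations.
#'
#' @param tab a `contingency` table.
#' @param method `"posterior"` (exact quantile, default) or `"two_sigma"`.
#' @return data.table with columns `ic`, `ic025` (log2 scale).
#' @export
bcpnn_stats <- function(tab, method = c("posterior", "two_sigma")) {
  method <- match.arg(method)
  a <- tab$a; E <- tab$E
  shape <- a + 0.5
  rate <- E + 0.5
  ic <- log2(shape / rate)
  ic025 <- if (method == "posterior") {
    log2(stats::qgamma(0.025, shape = shape, rate = rate))
  } else {
    ic - 2 * sqrt(trigamma(shape)) / log(2)
  }
  data.table::data.table(ic = ic, ic025 = ic025)
}

#' Signal-calling thresholds
#'
#' Defaults follow standard pharmacovigilance practice: PRR >= 2 with
#' chi-square >= 4 and at least 3 reports; ROR025 > 1; IC025 > 0;
#' EB05 >= 2.
#'
#' @param prr,chi2,min_reports,ror_lo,ic025,eb05 threshold values.
#' @return a named list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(prr = 2, chi2 = 4, min_reports = 3,
                              ror_lo = 1, ic025 = 0, eb05 = 2) {
  structure(list(prr = prr, chi2 = chi2, min_reports = min_reports,
                 ror_lo = ror_lo, ic025 = ic025, eb05 = eb05),
            class = "signal_thresholds")
}

#' Call key signals by four-method concordance
#'
#' Sets the per-method flags (`prr_flag = PRR >= 2 & chi2 >= 4 & a >= 3`,
#' `ror_flag = ROR025 > 1`, `ic_flag = IC025 > 0`, `ebgm_flag = EB05 >= 2`
#' at the default thresholds) and the concordance flag
#' `key = prr_flag & ror_flag & ic_flag & ebgm_flag`. An undefined
#' statistic (NA) yields a `FALSE` flag, so sparse tables never crash a
#' pipeline -- they simply cannot signal.
#'
#' @param scores data.table carrying columns `a`, `prr`, `chi2`, `ror_lo`,
#'   `ic025`, `eb05` (as produced by [signal_scan()] or by binding the
#'   per-method statistics).
#' @param thresholds a [signal_thresholds()] object.
#' @return `scores` with logical columns `prr_flag`, `ror_flag`,
#'   `ic_flag`, `ebgm_flag`, `key` added.
#' @export
call_signal <- function(scores, thresholds = signal_thresholds()) {
  dt <- data.table::as.data.table(scores)
  flag <- function(x) !is.na(x) & x
  dt[, prr_flag := flag(prr >= thresholds$prr & chi2 >= thresholds$chi2 &
                          a >= thresholds$min_reports)]
  dt[, ror_flag := flag(ror_lo > thresholds$ror_lo)]
  dt[, ic_flag := flag(ic025 > thresholds$ic025)]
  dt[, ebgm_flag := flag(eb05 >= thresholds$eb05)]
  dt[, key := prr_flag & ror_flag & ic_flag & ebgm_flag]
  dt[]
}

## All (drug, PT) 2x2 cells for a set of cohorts against the universe,
## for PTs with a >= min_count in the cohort.
.contingency_grid <- function(store, cohorts, min_count = 1L) {
  n <- nrow(store$demo)
  pt_tot <- store$events[, .(n_pt = .N), by = pt]
  grids <- lapply(cohorts, function(co) {
    ev <- store$events[primaryid %in% co$primaryids]
    if (nrow(ev) == 0L) return(NULL)
    cnt <- ev[, .(a = .N), by = pt][a >= min_count]
    if (nrow(cnt) == 0L) return(NULL)
    cnt[, drug := co$drug_id]
    cnt[, class := co$class]
    cnt[pt_tot, on = "pt", n_pt := i.n_pt]
    cnt[, a := as.numeric(a)]
    cnt[, b := co$n - a]
    cnt[, c := n_pt - a]
    cnt[, d := n - co$n - n_pt + a]
    cnt[, n_pt := NULL]
    cnt
  })
  grid <- data.table::rbindlist(grids[!vapply(grids, is.null, logical(1))])
  if (nrow(grid) == 0L) {
    stop("no drug-event pairs to evaluate", call. = FALSE)
  }
  grid[, N := a + b + c + d]
  grid[, E := (a + b) * (a + c) / N]
  data.table::setorder(grid, drug, pt)
  grid[]
}

#' Four-method disproportionality scan over drug-event pairs
#'
#' Builds the 2x2 table for every (cohort drug, PT) pair with at least
#' `min_count` co-reports, computes PRR/chi-square, ROR with CI, the BCPNN
#' information component, fits (or reuses) the MGPS gamma-mixture prior
#' over all pairs in scope, scores EBGM/EB05, and calls key signals by
#' four-method concordance.
#'
#' @param store the de-duplicated `faers_store` universe.
#' @param cohorts a list of `faers_cohort` objects (see
#'   [build_all_cohorts()]).
#' @param min_count minimum `a` for a pair to enter the scan (and the MGPS
#'   likelihood), default 1.
#' @param thresholds a [signal_thresholds()] object.
#' @param chi2_correction `"yates"` (default) or `"pearson"`.
#' @param bcpnn_method `"posterior"` or `"two_sigma"`.
#' @param prior an [fit_mgps_prior()] result to reuse; fitted here when
#'   `NULL`.
#' @return a `signal_table` data.table, one row per (drug, pt): cells,
#'   all statistics, the four flags and `key`. The fitted prior is carried
#'   in the `mgps_prior` attribute.
#' @export
signal_scan <- function(store, cohorts, min_count = 1L,
                        thresholds = signal_thresholds(),
                        chi2_correction = c("yates", "pearson"),
                        bcpnn_method = c("posterior", "two_sigma"),
                        prior = NULL) {
  chi2_correction <- match.arg(chi2_correction)
  bcpnn_method <- match.arg(bcpnn_method)
  grid <- .contingency_grid(store, cohorts, min_count)
  grid <- cbind(grid, prr_stats(grid, chi2_correction), ror_stats(grid),
                bcpnn_stats(grid, bcpnn_method))
  if (is.null(prior)) prior <- fit_mgps_prior(grid$a, grid$E)
  grid <- cbind(grid, mgps_score(grid$a, grid$E, prior))
  grid <- call_signal(grid, thresholds)
  data.table::setattr(grid, "class", c("signal_table", class(grid)))
  data.table::setattr(grid, "mgps_prior", prior)
  data.table::setattr(grid, "thresholds", thresholds)
  grid
}

#' Rank key signals
#'
#' Descending sort among `key = TRUE` rows by report count `a`
#' (`by = "count"`) or by `ebgm`; ties broken by the other field
#' descending, then PT lexicographic. Returns at most `k` rows (fewer when
#' fewer key signals exist).
#'
#' @param scores a `signal_table` (optionally pre-filtered to one drug).
#' @param by `"count"` or `"ebgm"`.
#' @param k maximum number of rows.
#' @param drug optional drug id to restrict to.
#' @return the top rows of `scores`, ordered.
#' @export
rank_signals <- function(scores, by = c("count", "ebgm"), k = 10L,
                         drug = NULL) {
  by <- match.arg(by)
  dt <- data.table::as.data.table(scores)[key == TRUE]
  if (!is.null(drug)) {
    the_drug <- drug
    dt <- dt[drug == the_drug]
  }
  if (nrow(dt) == 0L) return(dt)
  primary <- if (by == "count") dt$a else dt$ebgm
  secondary <- if (by == "count") dt$ebgm else dt$a
  ord <- order(-primary, -secondary, dt$pt, method = "radix")
  dt[ord][seq_len(min(k, nrow(dt)))]
}

#' Binary drug x PT key-signal matrix
#'
#' Rows are drugs (every scanned drug is retained, including drugs with no
#' key signals, as all-`FALSE` rows); columns are the union of key-signal
#' PTs across drugs.
#'
#' @param scores a `signal_table` from [signal_scan()].
#' @param drugs optional character vector fixing the row set and order
#'   (defaults to the drugs present in `scores`).
#' @return a logical matrix of class `signal_matrix` with a `classes`
#'   attribute (target class per drug, where available).
#' @export
signal_matrix <- function(scores, drugs = NULL) {
  dt <- data.table::as.data.table(scores)
  if (is.null(drugs)) drugs <- .pv_sort(unique(dt$drug))
  keys <- dt[key == TRUE]
  pts <- .pv_sort(unique(keys$pt))
  m <- matrix(FALSE, nrow = length(drugs), ncol = length(pts),
              dimnames = list(drugs, pts))
  if (nrow(keys)) m[cbind(keys$drug, keys$pt)] <- TRUE
  classes <- if ("class" %in% names(dt)) {
    cls <- unique(dt[, .(drug, class)])
    stats::setNames(cls$class, cls$drug)[drugs]
  } else stats::setNames(rep(NA_character_, length(drugs)), drugs)
  structure(m, class = c("signal_matrix", "matrix", "array"),
            classes = classes)
}

#' Per-drug key-signal set sizes
#'
#' @param sm a [signal_matrix()].
#' @return named integer vector of row sums (signal-set size per drug).
#' @export
signal_set_sizes <- function(sm) {
  rowSums(unclass(sm))
}
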