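## Mapping key-signal PTs to System Organ Classes: the drug-SOC-PT atlas,
## marker-organ concordance bookkeeping, and cross-drug shared-PT tables.

#' Load a PT to primary-SOC mapping
#'
#' MedDRA content is licensed, so the mapping is supplied by the user as a
#' two-column tab-separated file (`pt`, `soc`, header row). MedDRA's
#' multiaxiality is deliberately collapsed to a single primary SOC per PT;
#' duplicate identical rows are de-duplicated, duplicate PTs with
#' conflicting SOCs are an error. Looking up an unmapped PT yields the
#' sentinel SOC `"UNMAPPED"`.
#'
#' @param file path to the mapping file.
#' @return a `pt_soc_map` data.table with columns `pt`, `soc`.
#' @export
load_pt_soc_map <- function(file) {
  dt <- data.table::fread(file, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (nrow(dt) == 0L) stop("empty PT-SOC mapping file", call. = FALSE)
  data.table::setnames(dt, tolower(names(dt)))
  stopifnot(all(c("pt", "soc") %in% names(dt)))
  dt <- unique(dt[, .(pt, soc)])
  conf <- dt[, .N, by = pt][N > 1]
  if (nrow(conf)) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(conf$pt, collapse = ", "), call. = FALSE)
  }
  pt_soc_map(dt)
}

#' @rdname load_pt_soc_map
#' @param map a data.frame with columns `pt`, `soc` (one row per PT).
#' @export
pt_soc_map <- function(map) {
  dt <- unique(data.table::as.data.table(map)[, .(pt, soc)])
  if (anyDuplicated(dt$pt)) {
    stop("each PT must map to exactly one primary SOC", call. = FALSE)
  }
  structure(dt, class = c("pt_soc_map", class(dt)))
}

#' Look up the primary SOC of event terms
#'
#' @param map a [pt_soc_map()].
#' @param pts character vector of PTs.
#' @return character vector of SOCs, `"UNMAPPED"` where absent.
#' @export
soc_of <- function(map, pts) {
  out <- map$soc[match(pts, map$pt)]
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' Build the drug-SOC-PT atlas
#'
#' Takes every key signal (with its report count `a`), maps each PT to its
#' primary SOC, and groups signals per drug by SOC. Per-drug SOC
#' histograms and marker-organ concordance flags are derived: a drug shows
#' marker-organ concordance with an organ SOC when the `Investigations`
#' SOC (laboratory/diagnostic abnormalities) and that organ SOC are
#' jointly enriched -- both holding at least `min_pt` signal PTs. The
#' quantitative rule (`min_pt`) is a package convention, configurable.
#'
#' @param scores a `signal_table` from [signal_scan()].
#' @param map a [pt_soc_map()].
#' @param investigations_soc name of the laboratory-abnormality SOC.
#' @param min_pt minimum signal-PT count per SOC for joint enrichment.
#' @return a `soc_atlas`: list with `atlas` (drug, soc, pt, a),
#'   `soc_histogram` (drug, soc, n_pt, total_a) and `concordance`
#'   (drug, organ soc, concordant flag).
#' @export
build_atlas <- function(scores, map, investigations_soc = "Investigations",
                        min_pt = 2L) {
  dt <- data.table::as.data.table(scores)[key == TRUE]
  all_drugs <- .pv_sort(unique(data.table::as.data.table(scores)$drug))
  atlas <- dt[, .(drug, pt, a)]
  atlas[, soc := soc_of(map, pt)]
  data.table::setcolorder(atlas, c("drug", "soc", "pt", "a"))
  data.table::setorder(atlas, drug, soc, pt)
  hist <- atlas[, .(n_pt = .N, total_a = sum(a)), by = .(drug, soc)]
  data.table::setorder(hist, drug, soc)
  inv <- hist[soc == investigations_soc, .(drug, inv_n = n_pt)]
  organs <- hist[soc != investigations_soc & soc != "UNMAPPED"]
  conc <- organs[, .(drug, organ_soc = soc, n_pt_organ = n_pt)]
  conc[inv, on = "drug", n_pt_investigations := i.inv_n]
  conc[is.na(conc$n_pt_investigations), n_pt_investigations := 0L]
  conc[, concordant := n_pt_investigations >= min_pt &
         n_pt_organ >= min_pt]
  structure(list(atlas = atlas, soc_histogram = hist, concordance = conc,
                 drugs = all_drugs),
            class = "soc_atlas")
}

utils::globalVariables(c("n_pt_organ", "n_pt_investigations", "concordant",
                         "i.inv_n", "organ_soc", "level", "variable"))

#' Cross-drug shared-PT analysis
#'
#' For each key-signal PT, counts the drugs whose signal set contains it;
#' reports the PTs at each sharing level `k >= 2`, the maximum sharing
#' count, and the all-drug intersection (empty exactly when no PT reaches
#' every drug).
#'
#' @param sm a [signal_matrix()].
#' @return list with `per_pt` (pt, n_drugs, drugs), `sharing_levels`
#'   (k, n_pts, pts), `max_sharing`, `all_drug_intersection`.
#' @export
shared_pt_counts <- function(sm) {
  m <- unclass(sm)
  n_drugs <- colSums(m)
  per_pt <- data.table::data.table(
    pt = as.character(colnames(m)), n_drugs = as.integer(n_drugs),
    drugs = vapply(seq_len(ncol(m)), function(j) {
      paste(.pv_sort(rownames(m)[m[, j]]), collapse = ";")
    }, character(1)))
  data.table::setorder(per_pt, -n_drugs, pt)
  ks <- .pv_sort(unique(n_drugs[n_drugs >= 2]))
  sharing <- data.table::data.table(
    k = as.integer(ks),
    n_pts = vapply(ks, function(k) sum(n_drugs == k), numeric(1)),
    pts = vapply(ks, function(k) {
      paste(.pv_sort(colnames(m)[n_drugs == k]), collapse = ";")
    }, character(1)))
  inter <- colnames(m)[n_drugs == nrow(m)]
  list(per_pt = per_pt, sharing_levels = sharing,
       max_sharing = if (length(n_drugs)) as.integer(max(n_drugs)) else 0L,
       all_drug_intersection = inter)
}
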