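## FAERS-shaped synthetic corpora with known ground truth: planted
## drug-event disproportionality signals, class-structured signatures,
## duplicate case versions, and configurable missingness. The generator
## emits exactly the seven-table "$"-delimited dialect the parser reads,
## plus a truth table and a mock PT-to-SOC map.

#' Default synthetic drug panel
#'
#' The 14-agent panel across five target classes, with per-drug exposure
#' probabilities (the probability that a report's primary-suspect drug is
#' this agent) between 0.015 and 0.03 -- report volumes in spontaneous
#' databases differ several-fold between agents, and these rates give
#' per-drug cohorts of roughly 750-1500 reports at the default corpus
#' size.
#'
#' @return data.table with `drug_id`, `class`, `exposure_prob`.
#' @export
default_drug_panel <- function() {
  dict <- default_drug_dictionary()
  ids <- c("gefitinib", "erlotinib", "afatinib", "dacomitinib",
           "osimertinib", "crizotinib", "ceritinib", "alectinib",
           "brigatinib", "lorlatinib", "repotrectinib", "pralsetinib",
           "selpercatinib", "adagrasib")
  p <- c(0.025, 0.03, 0.02, 0.015, 0.03, 0.02, 0.015, 0.02, 0.015, 0.015,
         0.015, 0.015, 0.015, 0.015)
  data.table::data.table(drug_id = ids,
                         class = dict$class[match(ids, dict$drug_id)],
                         exposure_prob = p)
}

#' Default synthetic PT vocabulary
#'
#' `n_pt` mock preferred terms spread round-robin over ten SOCs (one of
#' which is `Investigations`, so marker-organ bookkeeping is exercised),
#' with background reporting probabilities cycling over
#' \{0.002, 0.004, 0.006, 0.008, 0.012\} -- about 1.3 events per report in
#' expectation.
#'
#' @param n_pt vocabulary size.
#' @return data.table with `pt`, `soc`, `p_background`.
#' @export
default_pt_vocabulary <- function(n_pt = 200L) {
  socs <- c("Investigations",
            "Skin and subcutaneous tissue disorders",
            "Gastrointestinal disorders",
            "Hepatobiliary disorders",
            "Cardiac disorders",
            "Nervous system disorders",
            "Eye disorders",
            "Respiratory disorders",
            "Musculoskeletal disorders",
            "Metabolism and nutrition disorders")
  data.table::data.table(
    pt = sprintf("PT%03d", seq_len(n_pt)),
    soc = socs[(seq_len(n_pt) - 1L) %% length(socs) + 1L],
    p_background = rep(c(0.002, 0.004, 0.006, 0.008, 0.012),
                       length.out = n_pt))
}

#' Default planted signal set
#'
#' The class-signature layout: each target class gets `n_shared` PTs
#' planted (at rate multiplier `rho`) for every drug of the class, and
#' each drug additionally gets `n_unique` drug-specific PTs. Blocks are
#' pairwise disjoint and drawn from vocabulary terms with background
#' probability >= 0.006, so at the default corpus size every planted pair
#' has expected co-report count >= 20.
#'
#' @param panel a [default_drug_panel()]-shaped table.
#' @param vocab a [default_pt_vocabulary()]-shaped table.
#' @param rho reporting-rate multiplier (>= 1) for planted pairs.
#' @param n_shared,n_unique block sizes.
#' @return data.table with `drug_id`, `pt`, `rho`.
#' @export
default_planted_signals <- function(panel = default_drug_panel(),
                                    vocab = default_pt_vocabulary(),
                                    rho = 5, n_shared = 5L,
                                    n_unique = 3L) {
  eligible <- vocab$pt[vocab$p_background >= 0.006]
  classes <- unique(panel$class)
  need <- length(classes) * n_shared + nrow(panel) * n_unique
  if (length(eligible) < need) {
    stop("vocabulary too small for the requested planted blocks",
         call. = FALSE)
  }
  pos <- 0L
  out <- list()
  for (cl in classes) {
    block <- eligible[pos + seq_len(n_shared)]
    pos <- pos + n_shared
    for (id in panel$drug_id[panel$class == cl]) {
      out[[length(out) + 1L]] <- data.table::data.table(
        drug_id = id, pt = block, rho = rho)
    }
  }
  for (id in panel$drug_id) {
    block <- eligible[pos + seq_len(n_unique)]
    pos <- pos + n_unique
    out[[length(out) + 1L]] <- data.table::data.table(
      drug_id = id, pt = block, rho = rho)
  }
  data.table::rbindlist(out)
}

#' Synthetic corpus configuration
#'
#' Bundles and validates everything [generate_corpus()] needs. The
#' defaults define the package's reference study conditions: 50 000
#' reports, the 14-drug panel, a 200-term vocabulary, class-shared plus
#' drug-unique planted signals at `rho = 5`, a 5% duplicate-version
#' fraction, and realistic per-field missingness.
#'
#' @param n_reports number of distinct cases.
#' @param panel drug panel table (`drug_id`, `class`, `exposure_prob`).
#' @param vocab PT vocabulary (`pt`, `soc`, `p_background`).
#' @param planted planted signals (`drug_id`, `pt`, `rho`).
#' @param duplicate_fraction fraction of cases re-emitted as a later
#'   version (same caseid, larger primaryid, later date), in \[0, 1).
#' @param missingness named list of per-field missingness probabilities
#'   (`sex`, `age`, `weight`, `reporter_country`, `reporter_type`,
#'   `fda_dt`).
#' @param n_background_drugs number of non-panel drugs absorbing the
#'   remaining exposure probability.
#' @param indication_terms qualifying indication(s) attached to every
#'   panel-drug report.
#' @param seed integer seed; the seed and config fully determine every
#'   emitted byte.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_reports = 50000L,
                         panel = default_drug_panel(),
                         vocab = default_pt_vocabulary(),
                         planted = default_planted_signals(panel, vocab),
                         duplicate_fraction = 0.05,
                         missingness = list(sex = 0.03, age = 0.15,
                                            weight = 0.30,
                                            reporter_country = 0.20,
                                            reporter_type = 0.10,
                                            fda_dt = 0),
                         n_background_drugs = 30L,
                         indication_terms = "NON-SMALL CELL LUNG CANCER",
                         seed = 1L) {
  panel <- data.table::as.data.table(panel)
  vocab <- data.table::as.data.table(vocab)
  planted <- data.table::as.data.table(planted)
  stopifnot(n_reports >= 1,
            all(panel$exposure_prob > 0 & panel$exposure_prob < 1),
            sum(panel$exposure_prob) < 1,
            all(vocab$p_background > 0 & vocab$p_background < 1),
            duplicate_fraction >= 0, duplicate_fraction < 1)
  if (any(planted$rho < 1)) stop("planted rho must be >= 1", call. = FALSE)
  if (anyDuplicated(planted[, .(drug_id, pt)])) {
    stop("a (drug, PT) pair may be planted at most once", call. = FALSE)
  }
  if (!all(planted$drug_id %in% panel$drug_id) ||
      !all(planted$pt %in% vocab$pt)) {
    stop("planted pairs must reference panel drugs and vocabulary PTs",
         call. = FALSE)
  }
  pj <- merge(planted, vocab[, .(pt, p_background)], by = "pt")
  if (any(pj$rho * pj$p_background >= 1)) {
    warning("some planted rates rho * p >= 1; capped at 0.99",
            call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports), panel = panel,
                 vocab = vocab, planted = planted,
                 duplicate_fraction = duplicate_fraction,
                 missingness = missingness,
                 n_background_drugs = as.integer(n_background_drugs),
                 indication_terms = toupper(indication_terms),
                 seed = as.integer(seed)),
            class = "synth_config")
}

.blank_where <- function(x, miss) {
  x[miss] <- ""
  x
}

#' Generate a FAERS-dialect synthetic corpus with ground truth
#'
#' Each report draws one primary-suspect drug by exposure probability
#' (panel agent or anonymous background drug), then each vocabulary PT
#' independently with its background probability -- multiplied by `rho`
#' (capped at 0.99) for planted (drug, PT) pairs. Demographics are drawn
#' from fixed distributions with unit-code variety (ages partly reported
#' in months/decades, weights partly in pounds), per-field missingness is
#' applied, and a configured fraction of cases is re-emitted as a later
#' version (same caseid, larger primaryid, later date) to exercise the
#' de-duplication rule. The same seed yields byte-identical output.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return list with `dir`, `files` (named paths of the seven tables),
#'   `truth` (planted pairs with expected and realized counts, also
#'   written to `truth.tsv`), `pt_soc_map` (path of the mock mapping) and
#'   the `config`.
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_reports
  panel <- config$panel
  vocab <- config$vocab
  npt <- nrow(vocab)
  dict <- default_drug_dictionary()

  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  days <- seq(as.Date("2004-01-01"), as.Date("2025-06-30"), by = "day")
  date0 <- days[sample.int(length(days), n, replace = TRUE)]
  fda_dt <- format(date0, "%Y%m%d")

  bg_ids <- sprintf("BACKGROUND DRUG %02d", seq_len(config$n_background_drugs))
  bg_p <- (1 - sum(panel$exposure_prob)) / config$n_background_drugs
  all_ids <- c(panel$drug_id, bg_ids)
  probs <- c(panel$exposure_prob, rep(bg_p, config$n_background_drugs))
  assign_drug <- sample(all_ids, n, replace = TRUE, prob = probs)

  ## events: per-drug Bernoulli draws against the (possibly boosted)
  ## per-PT probability vector
  ev_list <- vector("list", length(all_ids))
  for (g in seq_along(all_ids)) {
    id <- all_ids[g]
    idx <- which(assign_drug == id)
    if (!length(idx)) next
    pvec <- vocab$p_background
    pl <- config$planted[drug_id == id]
    if (nrow(pl)) {
      j <- match(pl$pt, vocab$pt)
      pvec[j] <- pmin(pl$rho * pvec[j], 0.99)
    }
    m <- length(idx)
    u <- matrix(stats::runif(m * npt), nrow = m)
    hit <- which(u < matrix(pvec, nrow = m, ncol = npt, byrow = TRUE),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      ev_list[[g]] <- data.table::data.table(
        row = idx[hit[, 1L]], pt = vocab$pt[hit[, 2L]])
    }
  }
  events <- data.table::rbindlist(ev_list[!vapply(ev_list, is.null,
                                                  logical(1))])
  data.table::setorder(events, row, pt)

  ## realized truth counts on the base (pre-duplication) corpus
  truth <- merge(config$planted, vocab[, .(pt, p_background)], by = "pt")
  truth[, expected_a := n * panel$exposure_prob[
    match(drug_id, panel$drug_id)] * pmin(rho * p_background, 0.99)]
  ev_drug <- events[, .(row, pt)]
  ev_drug[, drug_id := assign_drug[row]]
  realized <- ev_drug[, .(realized_a = .N), by = .(drug_id, pt)]
  truth <- merge(truth, realized, by = c("drug_id", "pt"), all.x = TRUE)
  truth[is.na(realized_a), realized_a := 0L]
  data.table::setcolorder(truth, c("drug_id", "pt", "rho", "p_background",
                                   "expected_a", "realized_a"))
  data.table::setorder(truth, drug_id, pt)

  ## demographics
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  age_yr <- pmin(pmax(round(stats::rnorm(n, 65, 12), 1), 18), 95)
  age_cod <- sample(c("YR", "MON", "DEC"), n, replace = TRUE,
                    prob = c(0.90, 0.06, 0.04))
  age_val <- data.table::fcase(age_cod == "YR", as.character(age_yr),
                               age_cod == "MON",
                               as.character(round(age_yr * 12)),
                               age_cod == "DEC",
                               as.character(round(age_yr / 10, 1)))
  wt_kg <- pmin(pmax(round(stats::rnorm(n, 68, 15), 1), 35), 180)
  wt_cod <- sample(c("KG", "LBS"), n, replace = TRUE, prob = c(0.8, 0.2))
  wt_val <- data.table::fifelse(
    wt_cod == "KG", as.character(wt_kg),
    as.character(round(wt_kg / 0.453592, 1)))
  occp <- sample(c("MD", "CN", "PH", "HP", "OT"), n, replace = TRUE,
                 prob = c(0.40, 0.25, 0.08, 0.07, 0.20))
  country <- sample(c("US", "JP", "CN", "GB", "DE", "FR", "CA", "AU"), n,
                    replace = TRUE,
                    prob = c(0.45, 0.15, 0.12, 0.08, 0.06, 0.05, 0.05,
                             0.04))

  ms <- config$missingness
  miss_of <- function(p) stats::runif(n) < (if (is.null(p)) 0 else p)
  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = .blank_where(fda_dt, miss_of(ms$fda_dt)),
    sex = .blank_where(sex, miss_of(ms$sex)),
    age = age_val, age_cod = age_cod,
    wt = wt_val, wt_cod = wt_cod,
    occp_cod = .blank_where(occp, miss_of(ms$reporter_type)),
    reporter_country = .blank_where(country, miss_of(ms$reporter_country)))
  age_miss <- miss_of(ms$age)
  demo[age_miss, `:=`(age = "", age_cod = "")]
  wt_miss <- miss_of(ms$weight)
  demo[wt_miss, `:=`(wt = "", wt_cod = "")]

  ## drug mentions: the PS drug plus 0-2 background concomitants
  is_panel <- assign_drug %in% panel$drug_id
  ps_name <- assign_drug
  if (any(is_panel)) {
    pick_brand <- stats::runif(n) < 0.4
    syn_brand <- vapply(assign_drug[is_panel], function(id) {
      syns <- dict$synonym[dict$drug_id == id]
      if (length(syns) > 1L) syns[2L] else syns[1L]
    }, character(1))
    ps_name[is_panel] <- ifelse(pick_brand[is_panel], syn_brand,
                                toupper(assign_drug[is_panel]))
  }
  ps_ai <- ifelse(is_panel, toupper(assign_drug), assign_drug)
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  con_rows <- rep(seq_len(n), n_con)
  con_seq <- unlist(lapply(n_con[n_con > 0], function(k) 1L + seq_len(k)),
                    use.names = FALSE)
  con_name <- sample(bg_ids, length(con_rows), replace = TRUE)
  drug_tab <- rbind(
    data.table::data.table(primaryid = primaryid, drug_seq = "1",
                           role_cod = "PS", drugname = ps_name,
                           prod_ai = ps_ai),
    data.table::data.table(primaryid = primaryid[con_rows],
                           drug_seq = as.character(con_seq),
                           role_cod = "C", drugname = con_name,
                           prod_ai = con_name))
  data.table::setorder(drug_tab, primaryid, drug_seq)

  reac_tab <- data.table::data.table(primaryid = primaryid[events$row],
                                     pt = events$pt)

  ## indications: every panel report qualifies on the PS drug_seq;
  ## background reports carry unrelated indications
  other_ind <- c("HYPERTENSION", "DIABETES MELLITUS", "BREAST CANCER",
                 "RHEUMATOID ARTHRITIS", "ASTHMA")
  ind_panel <- data.table::data.table(
    primaryid = primaryid[is_panel], indi_drug_seq = "1",
    indi_pt = sample(config$indication_terms, sum(is_panel),
                     replace = TRUE))
  bg_has_ind <- !is_panel & stats::runif(n) < 0.7
  ind_bg <- data.table::data.table(
    primaryid = primaryid[bg_has_ind], indi_drug_seq = "1",
    indi_pt = sample(other_ind, sum(bg_has_ind), replace = TRUE))
  indi_tab <- rbind(ind_panel, ind_bg)
  data.table::setorder(indi_tab, primaryid)

  outc_probs <- c(DE = 0.12, HO = 0.18, LT = 0.03, DS = 0.01, OT = 0.45)
  outc_list <- lapply(names(outc_probs), function(cd) {
    hit <- stats::runif(n) < outc_probs[[cd]]
    data.table::data.table(primaryid = primaryid[hit], outc_cod = cd)
  })
  outc_tab <- data.table::rbindlist(outc_list)
  data.table::setorder(outc_tab, primaryid, outc_cod)

  ther_tab <- data.table::data.table(
    primaryid = primaryid, dsg_drug_seq = "1",
    start_dt = format(date0 - sample(30:400, n, replace = TRUE), "%Y%m%d"),
    end_dt = "")
  rpsr_tab <- data.table::data.table(
    primaryid = primaryid,
    rpsr_cod = sample(c("FGN", "HP", "CSM", "LIT", "DT"), n,
                      replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.1, 0.05)))

  ## duplicate case versions: same caseid, larger primaryid, later date
  n_dup <- floor(config$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_idx <- .pv_sort(sample.int(n, n_dup))
    old_pid <- primaryid[dup_idx]
    new_pid <- paste0(caseid[dup_idx], "2")
    dup_date <- format(date0[dup_idx] +
                         sample(7:180, n_dup, replace = TRUE), "%Y%m%d")
    dup_demo <- data.table::copy(demo[dup_idx])
    dup_demo[, primaryid := new_pid]
    dup_demo[, fda_dt := data.table::fifelse(nzchar(demo$fda_dt[dup_idx]),
                                             dup_date, "")]
    demo <- rbind(demo, dup_demo)
    copy_dup <- function(dt) {
      sub <- dt[dt$primaryid %in% old_pid]
      sub <- data.table::copy(sub)
      sub[, primaryid := paste0(substr(primaryid, 1, nchar(primaryid) - 1),
                                "2")]
      rbind(dt, sub)
    }
    drug_tab <- copy_dup(drug_tab)
    reac_tab <- copy_dup(reac_tab)
    indi_tab <- copy_dup(indi_tab)
    outc_tab <- copy_dup(outc_tab)
    ther_tab <- copy_dup(ther_tab)
    rpsr_tab <- copy_dup(rpsr_tab)
  }

  tag <- "25Q2"
  files <- c(DEMO = file.path(dir, paste0("DEMO", tag, ".txt")),
             DRUG = file.path(dir, paste0("DRUG", tag, ".txt")),
             REAC = file.path(dir, paste0("REAC", tag, ".txt")),
             INDI = file.path(dir, paste0("INDI", tag, ".txt")),
             OUTC = file.path(dir, paste0("OUTC", tag, ".txt")),
             THER = file.path(dir, paste0("THER", tag, ".txt")),
             RPSR = file.path(dir, paste0("RPSR", tag, ".txt")))
  wr <- function(dt, path) {
    data.table::fwrite(dt, path, sep = "$", quote = FALSE, na = "")
  }
  wr(demo, files["DEMO"])
  wr(drug_tab, files["DRUG"])
  wr(reac_tab, files["REAC"])
  wr(indi_tab, files["INDI"])
  wr(outc_tab, files["OUTC"])
  wr(ther_tab, files["THER"])
  wr(rpsr_tab, files["RPSR"])

  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t", quote = FALSE)
  map_path <- file.path(dir, "pt_soc_map.tsv")
  data.table::fwrite(vocab[, .(pt, soc)], map_path, sep = "\t",
                     quote = FALSE)

  list(dir = dir, files = files, truth = truth, truth_path = truth_path,
       pt_soc_map = map_path, config = config)
}

utils::globalVariables(c("row", "age", "age_cod", "wt", "wt_cod",
                         "start_dt", "end_dt"))

#' Evaluate signal recovery against the planted truth
#'
#' Sensitivity is the fraction of planted pairs with expected co-report
#' count at least `min_expected` and rate multiplier at least `min_rho`
#' that are called key signals; the false-positive proportion is the
#' fraction of evaluated non-planted pairs called key. Evaluated pairs are
#' the rows of the scan (pairs with at least one co-report).
#'
#' @param truth the truth table from [generate_corpus()] (all planted
#'   pairs, whatever their rho).
#' @param scores a `signal_table` from [signal_scan()].
#' @param min_expected,min_rho inclusion bounds for the sensitivity
#'   denominator.
#' @return list with `sensitivity` (`NA` when no planted pair qualifies),
#'   `false_positive_proportion`, `n_planted_evaluated`, `n_null`.
#' @export
evaluate_recovery <- function(truth, scores, min_expected = 10,
                              min_rho = 5) {
  truth <- data.table::as.data.table(truth)
  dt <- data.table::as.data.table(scores)
  if (!any(unique(truth$drug_id) %in% unique(dt$drug))) {
    stop("truth and scores share no drug labels", call. = FALSE)
  }
  keys <- dt[key == TRUE, .(drug, pt)]
  planted_eval <- truth[expected_a >= min_expected & rho >= min_rho]
  sens <- if (nrow(planted_eval) == 0L) NA_real_ else {
    hit <- keys[planted_eval, on = c(drug = "drug_id", "pt"),
                nomatch = NULL]
    nrow(hit) / nrow(planted_eval)
  }
  nulls <- dt[!truth, on = c(drug = "drug_id", "pt")]
  fpp <- if (nrow(nulls)) mean(nulls$key) else NA_real_
  list(sensitivity = sens, false_positive_proportion = fpp,
       n_planted_evaluated = nrow(planted_eval), n_null = nrow(nulls))
}
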