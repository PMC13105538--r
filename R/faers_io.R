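## Parsing, validation and de-duplication of FAERS-dialect quarterly tables.
##
## The FAERS ASCII dialect: "$"-delimited text, one header row, files named
## DEMOyyQq.txt, DRUGyyQq.txt, REACyyQq.txt, INDIyyQq.txt, OUTCyyQq.txt,
## THERyyQq.txt, RPSRyyQq.txt.

.faers_tables <- c("DEMO", "DRUG", "REAC", "INDI", "OUTC", "THER", "RPSR")

.faers_required_cols <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod",
           "wt", "wt_cod", "occp_cod", "reporter_country"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  REAC = c("primaryid", "pt"),
  INDI = c("primaryid", "indi_drug_seq", "indi_pt"),
  OUTC = c("primaryid", "outc_cod"),
  THER = c("primaryid"),
  RPSR = c("primaryid")
)

.faers_outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

.faers_reporter_map <- c(
  CN = "consumer", HP = "health-professional", PH = "pharmacist",
  MD = "physician", OT = "other"
)

# hours per Julian year = 24 * 365.25
.age_divisors <- c(DEC = 0.1, YR = 1, MON = 12, WK = 52.1775,
                   DY = 365.25, HR = 8766)

.faers_table_type <- function(path) {
  base <- toupper(basename(path))
  hit <- .faers_tables[vapply(.faers_tables, function(t) startsWith(base, t),
                              logical(1))]
  if (length(hit) != 1L) NA_character_ else hit
}

.faers_quarter <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("[0-9]{2}[Qq][1-4]", basename(path)))
  if (length(m)) toupper(m) else NA_character_
}

## Read a "$"-delimited file with one header row. Returns the accepted rows
## as a character data.table plus row-accounting. Rows whose field count does
## not match the header are rejected (real FAERS quarters contain stray
## delimiters), never fatal.
.read_dollar_table <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) txt <- iconv(txt, from = "latin1", to = "UTF-8")
  lines <- strsplit(txt, "\r\n|\r|\n")[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty FAERS file: ", path, call. = FALSE)
  }
  header <- tolower(strsplit(lines[1L], "$", fixed = TRUE)[[1]])
  header <- trimws(header)
  body <- lines[-1L]
  ncol <- length(header)
  # sentinel so trailing empty fields are counted
  sp <- strsplit(paste0(body, "$\x01"), "$", fixed = TRUE)
  nf <- lengths(sp) - 1L
  ok <- nf == ncol
  dt <- if (any(ok)) {
    m <- matrix(unlist(sp[ok], use.names = FALSE), ncol = ncol + 1L,
                byrow = TRUE)[, seq_len(ncol), drop = FALSE]
    out <- data.table::as.data.table(m)
    data.table::setnames(out, header)
    out
  } else {
    out <- data.table::as.data.table(
      matrix(character(0), ncol = ncol, dimnames = list(NULL, header)))
    out
  }
  for (j in names(dt)) data.table::set(dt, j = j, value = trimws(dt[[j]]))
  list(dt = dt, parsed = length(body), accepted = sum(ok),
       rejected = sum(!ok))
}

.require_cols <- function(dt, cols, file) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop("FAERS schema error in ", basename(file), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Normalize a reported age to years
#'
#' FAERS stores age as a value plus a unit code (`AGE_COD`). Recognised codes
#' are `DEC` (decades), `YR` (years), `MON` (months), `WK` (weeks), `DY`
#' (days) and `HR` (hours). Any other code, an unparseable value, or a result
#' outside \[0, 150\] yields `NA` -- normalization is total and never errors.
#'
#' @param value character or numeric vector of reported ages.
#' @param code character vector of unit codes (recycled against `value`).
#' @return numeric vector of ages in years, `NA` where not interpretable.
#' @examples
#' normalize_age_years(c("67", "670", "5"), c("YR", "MON", "DEC"))
#' @export
normalize_age_years <- function(value, code) {
  v <- suppressWarnings(as.numeric(value))
  div <- .age_divisors[toupper(as.character(code))]
  out <- v / unname(div)
  out[!is.finite(out) | out < 0 | out > 150] <- NA_real_
  out
}

#' Normalize a reported weight to kilograms
#'
#' Recognised `WT_COD` codes: `KG`, `LBS` (pounds, 0.453592 kg each) and
#' `GMS` (grams). Unknown codes or values outside (0, 650\] kg yield `NA`.
#'
#' @param value character or numeric vector of reported weights.
#' @param code character vector of unit codes.
#' @return numeric vector of weights in kg, `NA` where not interpretable.
#' @examples
#' normalize_weight_kg(c("59", "154"), c("KG", "LBS"))
#' @export
normalize_weight_kg <- function(value, code) {
  v <- suppressWarnings(as.numeric(value))
  mult <- c(KG = 1, LBS = 0.453592, GMS = 0.001)[toupper(as.character(code))]
  out <- v * unname(mult)
  out[!is.finite(out) | out <= 0 | out > 650] <- NA_real_
  out
}

.new_faers_store <- function(demo, drugs, events, indications, outcomes,
                             therapy, sources, provenance,
                             deduplicated = FALSE) {
  structure(
    list(demo = demo, drugs = drugs, events = events,
         indications = indications, outcomes = outcomes, therapy = therapy,
         sources = sources, provenance = provenance),
    class = "faers_store", deduplicated = deduplicated)
}

.empty_demo <- function() {
  data.table::data.table(
    primaryid = character(), caseid = character(), fda_dt = integer(),
    sex = character(), age_years = numeric(), weight_kg = numeric(),
    reporter_country = character(), reporter_type = character())
}

#' Read FAERS quarterly ASCII tables into a normalized report store
#'
#' Parses the seven "$"-delimited FAERS tables (DEMO, DRUG, REAC, INDI,
#' OUTC, THER, RPSR), joins them on `primaryid`, normalizes demographics
#' (age to years, weight to kg, sex, reporter type, outcome codes) and
#' returns a `faers_store`: a list of relational tables keyed by report.
#'
#' One report is created per DEMO row. Rows in the other tables whose
#' `primaryid` has no DEMO row (join orphans) are counted in the provenance
#' table and dropped. Malformed rows (wrong field count, e.g. from stray
#' delimiters) are rejected per file and counted, never fatal. Event terms
#' are stored as a set: a PT reported twice in one report counts once.
#'
#' @param paths character vector of file paths and/or directories (a
#'   directory is expanded to the FAERS-named `.txt` files it contains).
#' @param schema_version currently only `"current"` (the post-2012 FAERS
#'   schema); files carrying the legacy LAERS `ISR` column are refused.
#' @return an object of class `faers_store` with elements `demo`, `drugs`,
#'   `events`, `indications`, `outcomes`, `therapy`, `sources` and a
#'   `provenance` table reconciling parsed = accepted + rejected per file.
#' @seealso [deduplicate()], [write_store()]
#' @export
read_faers_tables <- function(paths, schema_version = "current") {
  schema_version <- match.arg(schema_version)
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.(txt|TXT)$", full.names = TRUE)
    } else p
  }))
  files <- files[!is.na(vapply(files, .faers_table_type, character(1)))]
  if (length(files) == 0L) stop("no FAERS-named input files found",
                                call. = FALSE)
  types <- vapply(files, .faers_table_type, character(1))
  if (!"DEMO" %in% types) stop("no DEMO file supplied", call. = FALSE)

  parsed <- vector("list", length(files))
  prov <- vector("list", length(files))
  for (i in seq_along(files)) {
    res <- .read_dollar_table(files[i])
    if ("isr" %in% names(res$dt)) {
      stop("legacy (pre-2012) LAERS schema detected in ",
           basename(files[i]),
           ": the ISR-keyed dialect is not supported", call. = FALSE)
    }
    .require_cols(res$dt, .faers_required_cols[[types[i]]], files[i])
    parsed[[i]] <- res$dt
    prov[[i]] <- data.table::data.table(
      file = basename(files[i]), table = types[i],
      quarter = .faers_quarter(files[i]), parsed = res$parsed,
      accepted = res$accepted, rejected = res$rejected, orphans = 0L)
  }
  provenance <- data.table::rbindlist(prov)

  bind_type <- function(type) {
    idx <- which(types == type)
    if (!length(idx)) return(NULL)
    data.table::rbindlist(parsed[idx], use.names = TRUE, fill = TRUE)
  }

  demo_raw <- bind_type("DEMO")
  if (nrow(demo_raw) == 0L) stop("DEMO contains no rows", call. = FALSE)
  demo <- data.table::data.table(
    primaryid = demo_raw$primaryid,
    caseid = demo_raw$caseid,
    fda_dt = suppressWarnings(as.integer(demo_raw$fda_dt)),
    sex = data.table::fifelse(toupper(demo_raw$sex) %in% c("F", "M"),
                              toupper(demo_raw$sex), "unknown"),
    age_years = normalize_age_years(demo_raw$age, demo_raw$age_cod),
    weight_kg = normalize_weight_kg(demo_raw$wt, demo_raw$wt_cod),
    reporter_country = data.table::fifelse(nzchar(demo_raw$reporter_country),
                                           demo_raw$reporter_country,
                                           NA_character_),
    reporter_type = unname(
      .faers_reporter_map[toupper(demo_raw$occp_cod)]))
  known <- demo$primaryid

  orphan_filter <- function(dt, type) {
    if (is.null(dt) || nrow(dt) == 0L) return(dt)
    orphan <- !(dt$primaryid %in% known)
    if (any(orphan)) {
      provenance[table == type, orphans := orphans + sum(orphan)]
    }
    dt[!orphan]
  }

  drug_raw <- orphan_filter(bind_type("DRUG"), "DRUG")
  drugs <- if (is.null(drug_raw)) {
    data.table::data.table(primaryid = character(), drug_seq = integer(),
                           role = character(), verbatim_name = character(),
                           prod_ai = character(),
                           matched_drug_id = character())
  } else {
    data.table::data.table(
      primaryid = drug_raw$primaryid,
      drug_seq = suppressWarnings(as.integer(drug_raw$drug_seq)),
      role = data.table::fifelse(
        toupper(drug_raw$role_cod) %in% c("PS", "SS", "C", "I"),
        toupper(drug_raw$role_cod), NA_character_),
      verbatim_name = drug_raw$drugname,
      prod_ai = drug_raw$prod_ai,
      matched_drug_id = NA_character_)
  }

  reac_raw <- orphan_filter(bind_type("REAC"), "REAC")
  events <- if (is.null(reac_raw)) {
    data.table::data.table(primaryid = character(), pt = character())
  } else {
    unique(reac_raw[nzchar(pt), .(primaryid, pt)])
  }

  indi_raw <- orphan_filter(bind_type("INDI"), "INDI")
  indications <- if (is.null(indi_raw)) {
    data.table::data.table(primaryid = character(),
                           indi_drug_seq = integer(),
                           indi_pt = character())
  } else {
    data.table::data.table(
      primaryid = indi_raw$primaryid,
      indi_drug_seq = suppressWarnings(as.integer(indi_raw$indi_drug_seq)),
      indi_pt = indi_raw$indi_pt)
  }

  outc_raw <- orphan_filter(bind_type("OUTC"), "OUTC")
  outcomes <- if (is.null(outc_raw)) {
    data.table::data.table(primaryid = character(), outc_cod = character())
  } else {
    unique(outc_raw[toupper(outc_cod) %in% .faers_outcome_codes,
                    .(primaryid, outc_cod = toupper(outc_cod))])
  }

  ther <- orphan_filter(bind_type("THER"), "THER")
  if (is.null(ther)) ther <- data.table::data.table(primaryid = character())
  rpsr <- orphan_filter(bind_type("RPSR"), "RPSR")
  if (is.null(rpsr)) rpsr <- data.table::data.table(primaryid = character())

  .new_faers_store(demo, drugs, events, indications, outcomes, ther, rpsr,
                   provenance)
}

## numeric when parseable, else a lexicographic fallback rank offset past
## every numeric id (FAERS primaryids are numeric strings in practice)
.primaryid_rank <- function(pid) {
  num <- suppressWarnings(as.numeric(pid))
  bad <- is.na(num)
  if (any(bad)) {
    num[bad] <- max(num[!bad], 0) + as.numeric(
      factor(pid[bad], levels = .pv_sort(unique(pid[bad]))))
  }
  num
}

#' De-duplicate a FAERS report store to one report per case
#'
#' FAERS cases accumulate versions (same `CASEID`, new `PRIMARYID`).
#' Following FDA guidance, the surviving version per case is the one with
#' the most recent `FDA_DT`; among versions sharing that date, the one with
#' the numerically larger `PRIMARYID`. A missing `FDA_DT` sorts earliest,
#' so a dated version always beats an undated one. The operation is
#' idempotent and invariant to input row order, and a consistency check
#' asserts caseid uniqueness afterwards.
#'
#' @param store a `faers_store` from [read_faers_tables()].
#' @return the store restricted to surviving report versions, with the
#'   `deduplicated` attribute set.
#' @export
deduplicate <- function(store) {
  stopifnot(inherits(store, "faers_store"))
  demo <- data.table::copy(store$demo)
  dt_key <- data.table::fifelse(is.na(demo$fda_dt), -1L, demo$fda_dt)
  pid_key <- .primaryid_rank(demo$primaryid)
  ord <- order(demo$caseid, dt_key, pid_key, method = "radix")
  demo <- demo[ord]
  keep <- demo[, .I[.N], by = caseid]$V1
  demo <- demo[keep]
  data.table::setorder(demo, caseid)
  if (anyDuplicated(demo$caseid)) {
    stop("internal error: caseid not unique after de-duplication")
  }
  pids <- demo$primaryid
  sub <- function(dt) dt[dt$primaryid %in% pids]
  out <- .new_faers_store(
    demo, sub(store$drugs), sub(store$events), sub(store$indications),
    sub(store$outcomes), sub(store$therapy), sub(store$sources),
    store$provenance, deduplicated = TRUE)
  attr(out, "dedup_counts") <- c(before = nrow(store$demo),
                                 after = nrow(demo))
  out
}

#' @export
print.faers_store <- function(x, ...) {
  cat("<faers_store> ", nrow(x$demo), " reports (",
      length(unique(x$demo$caseid)), " cases)",
      if (isTRUE(attr(x, "deduplicated"))) ", de-duplicated" else "",
      "\n", sep = "")
  cat("  drug mentions: ", nrow(x$drugs), "; event terms: ", nrow(x$events),
      "; indications: ", nrow(x$indications), "\n", sep = "")
  invisible(x)
}

## exact decimal round-trip for the two normalized numeric fields
.num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write / load a normalized report store
#'
#' `write_store()` serializes a `faers_store` as tab-separated tables plus a
#' JSON provenance sidecar; `load_store()` restores it. The round trip is
#' the identity: missing values are preserved (never coerced to 0) and the
#' normalized numeric fields are written at full precision.
#'
#' @param store a `faers_store`.
#' @param path directory to write into (created if needed).
#' @return `write_store()` returns `path` invisibly; `load_store()` returns
#'   the reconstructed `faers_store`.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "faers_store"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  demo <- data.table::copy(store$demo)
  demo[, age_years := .num_to_chr(store$demo$age_years)]
  demo[, weight_kg := .num_to_chr(store$demo$weight_kg)]
  tabs <- list(demo = demo, drugs = store$drugs, events = store$events,
               indications = store$indications, outcomes = store$outcomes,
               therapy = store$therapy, sources = store$sources)
  for (nm in names(tabs)) {
    data.table::fwrite(tabs[[nm]], file.path(path, paste0(nm, ".tsv")),
                       sep = "\t", na = "", quote = FALSE)
  }
  meta <- list(deduplicated = isTRUE(attr(store, "deduplicated")),
               provenance = store$provenance)
  jsonlite::write_json(meta, file.path(path, "provenance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_store
#' @export
load_store <- function(path) {
  rd <- function(nm, classes) {
    f <- file.path(path, paste0(nm, ".tsv"))
    data.table::fread(f, sep = "\t", na.strings = "", colClasses = classes,
                      quote = "")
  }
  demo <- rd("demo", list(
    character = c("primaryid", "caseid", "sex", "reporter_country",
                  "reporter_type", "age_years", "weight_kg"),
    integer = "fda_dt"))
  demo[, age_years := as.numeric(age_years)]
  demo[, weight_kg := as.numeric(weight_kg)]
  drugs <- rd("drugs", list(
    character = c("primaryid", "role", "verbatim_name", "prod_ai",
                  "matched_drug_id"),
    integer = "drug_seq"))
  events <- rd("events", list(character = c("primaryid", "pt")))
  indications <- rd("indications", list(
    character = c("primaryid", "indi_pt"), integer = "indi_drug_seq"))
  outcomes <- rd("outcomes", list(character = c("primaryid", "outc_cod")))
  therapy <- rd("therapy", "character")
  sources <- rd("sources", "character")
  meta <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  prov <- data.table::as.data.table(meta$provenance)
  .new_faers_store(demo, drugs, events, indications, outcomes, therapy,
                   sources, prov, deduplicated = isTRUE(meta$deduplicated))
}
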