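# Small in-code FAERS fixtures and a cached reference pipeline run shared
# across test files.

.demo_defaults <- list(fda_dt = "20240101", sex = "F", age = "60",
                       age_cod = "YR", wt = "70", wt_cod = "KG",
                       occp_cod = "MD", reporter_country = "US")

# Write "$"-delimited FAERS tables from data.frames; demo columns not given
# are filled with defaults.
write_faers_fixture <- function(dir, demo, drug = NULL, reac = NULL,
                                indi = NULL, outc = NULL, tag = "24Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  for (nm in names(.demo_defaults)) {
    if (!nm %in% names(demo)) demo[[nm]] <- .demo_defaults[[nm]]
  }
  demo <- demo[c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod",
                 "wt", "wt_cod", "occp_cod", "reporter_country")]
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, INDI = indi,
               OUTC = outc)
  paths <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, tag, ".txt"))
    df <- as.data.frame(tabs[[nm]], stringsAsFactors = FALSE)
    lines <- c(paste(names(df), collapse = "$"),
               do.call(paste, c(unname(df), sep = "$")))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  paths
}

drug_row <- function(primaryid, drugname, role_cod = "PS", drug_seq = 1,
                     prod_ai = drugname) {
  data.frame(primaryid = primaryid, drug_seq = drug_seq,
             role_cod = role_cod, drugname = drugname, prod_ai = prod_ai,
             stringsAsFactors = FALSE)
}

# a parsed three-report store used by several cohort/signal tests
tiny_store <- function() {
  dir <- tempfile("tiny")
  demo <- data.frame(primaryid = c("1001", "2001", "3001"),
                     caseid = c("100", "200", "300"),
                     age = c("67", "670", "59"),
                     age_cod = c("YR", "MON", "YR"),
                     wt = c("59", "154", ""),
                     wt_cod = c("KG", "LBS", ""),
                     sex = c("F", "M", "F"))
  drug <- rbind(drug_row("1001", "TAGRISSO", prod_ai = "OSIMERTINIB"),
                drug_row("2001", "OSIMERTINIB MESYLATE"),
                drug_row("3001", "GEFITINIB", role_cod = "SS"))
  reac <- data.frame(primaryid = c("1001", "1001", "1001", "2001"),
                     pt = c("Rash", "Diarrhea", "Rash", "Rash"))
  indi <- data.frame(primaryid = c("1001", "2001"),
                     indi_drug_seq = c("1", "1"),
                     indi_pt = c("Non-small cell lung cancer",
                                 "BREAST CANCER"))
  write_faers_fixture(dir, demo, drug, reac, indi)
  read_faers_tables(dir)
}

# Reference study-conditions run (default synthetic corpus), computed once
# and shared across test files.
.pv_test_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.pv_test_cache$run)) {
    out <- file.path(tempdir(), "pvatlas-default-run")
    cfg <- synth_config(seed = 11L)
    rc <- run_config(synth = cfg, out_dir = out, seed = 11L)
    .pv_test_cache$run <- run_all(rc)
  }
  .pv_test_cache$run
}
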