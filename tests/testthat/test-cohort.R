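test_that("drug-name normalization strips salts and whitespace", {
  expect_equal(normalize_name("  Osimertinib Mesylate "), "OSIMERTINIB")
  expect_equal(normalize_name("TAGRISSO"), "TAGRISSO")
  expect_equal(normalize_name("gefitinib   tablets"), "GEFITINIB")
  expect_equal(normalize_name(""), "")
  expect_equal(normalize_name("ERLOTINIB HYDROCHLORIDE HCL"), "ERLOTINIB")
})

test_that("dictionary matching resolves generic and brand names", {
  dict <- default_drug_dictionary()
  expect_equal(match_drug("Tagrisso", dict), "osimertinib")
  expect_equal(match_drug("GEFITINIB", dict), "gefitinib")
  expect_true(is.na(match_drug("ASPIRIN", dict)))
  expect_equal(match_drug(c("XALKORI", "Lorbrena"), dict),
               c("crizotinib", "lorlatinib"))
})

test_that("a synonym shared across drugs is a configuration error", {
  bad <- data.frame(drug_id = c("a", "b"), class = c("X", "Y"),
                    synonym = c("SAMENAME", "SAMENAME"))
  expect_error(drug_dictionary(bad), "shared by multiple drugs")
  bad2 <- data.frame(drug_id = c("a", "a"), class = c("X", "Y"),
                     synonym = c("N1", "N2"))
  expect_error(drug_dictionary(bad2), "more than one class")
})

test_that("cohorts respect the primary-suspect restriction and indications", {
  store <- deduplicate(tiny_store())
  # osimertinib: PS in 1001 (brand) and 2001 (salt form); gefitinib only SS
  co_osi <- build_cohort(store, "osimertinib")
  expect_equal(co_osi$n, 2L)
  co_gef <- build_cohort(store, "gefitinib")
  expect_equal(co_gef$n, 0L)
  expect_error(build_cohort(store, "aspirin"), "unknown drug_id")
  # indication filter: only 1001 has a qualifying NSCLC term on drug_seq 1
  co_ind <- build_cohort(store, "osimertinib", require_indication = TRUE)
  expect_equal(co_ind$primaryids, "1001")
  # report-level fallback behaves the same here
  co_rep <- build_cohort(store, "osimertinib", require_indication = TRUE,
                         indication_linkage = "report")
  expect_equal(co_rep$primaryids, "1001")
})

test_that("adding reports never shrinks a cohort (monotonicity)", {
  dir <- tempfile()
  demo <- data.frame(primaryid = c("1", "2", "3"),
                     caseid = c("1", "2", "3"))
  drug <- drug_row(c("1", "2"), "GEFITINIB")
  write_faers_fixture(dir, demo, drug)
  big <- deduplicate(read_faers_tables(dir))
  dir2 <- tempfile()
  write_faers_fixture(dir2, demo[1:2, ], drug_row("1", "GEFITINIB"))
  small <- deduplicate(read_faers_tables(dir2))
  n_small <- build_cohort(small, "gefitinib")$n
  n_big <- build_cohort(big, "gefitinib")$n
  expect_gte(n_big, n_small)
})

test_that("descriptive summaries count and bin as specified", {
  dir <- tempfile()
  demo <- data.frame(primaryid = as.character(1:4),
                     caseid = as.character(1:4),
                     sex = c("F", "F", "F", "M"),
                     age = c("50", "60", "70", ""),
                     age_cod = c("YR", "YR", "YR", ""),
                     wt = c("40", "80", "120", ""),
                     wt_cod = c("KG", "KG", "KG", ""))
  drug <- drug_row(as.character(1:4), "GEFITINIB")
  outc <- data.frame(primaryid = c("1", "2", "2"),
                     outc_cod = c("DE", "DE", "HO"))
  write_faers_fixture(dir, demo, drug, outc = outc)
  store <- deduplicate(read_faers_tables(dir))
  co <- build_cohort(store, "gefitinib")
  s <- descriptive_summary(co, store)
  cat_sex <- s$categorical[s$categorical$variable == "sex"]
  expect_equal(cat_sex$count, c(3L, 1L, 0L))
  expect_equal(cat_sex$pct, c(75, 25, 0))
  # single-valued category percentages sum to 100
  expect_equal(sum(cat_sex$pct), 100)
  ages <- s$continuous[s$continuous$variable == "age_years"]
  expect_equal(ages$mean, 60)
  expect_equal(ages$median, 60)
  expect_equal(ages$n_missing, 1L)
  # multi-outcome reports count in each outcome category
  outc_tab <- s$categorical[s$categorical$variable == "outcome"]
  expect_equal(outc_tab$count[outc_tab$level == "DE"], 2L)
  expect_equal(outc_tab$count[outc_tab$level == "HO"], 1L)
  bins <- s$binned[s$binned$variable == "weight_group"]
  expect_equal(bins$count, c(1L, 1L, 1L, 1L))  # <50, 50-100, >100, missing
})

test_that("yearly counts bucket missing dates separately", {
  dir <- tempfile()
  demo <- data.frame(primaryid = as.character(1:3),
                     caseid = as.character(1:3),
                     fda_dt = c("20240101", "20240601", "20230301"))
  write_faers_fixture(dir, demo, drug_row(as.character(1:3), "GEFITINIB"))
  store <- deduplicate(read_faers_tables(dir))
  co <- build_cohort(store, "gefitinib")
  yc <- yearly_counts(co, store)
  expect_equal(yc$count[yc$year == 2024], 2L)
  expect_equal(yc$count[yc$year == 2023], 1L)
  # empty cohort -> empty series
  expect_equal(nrow(yearly_counts(build_cohort(store, "adagrasib"),
                                  store)), 0L)
})

test_that("missingness profile reports fractions in [0,1]", {
  dir <- tempfile()
  demo <- data.frame(primaryid = as.character(1:4),
                     caseid = as.character(1:4),
                     age = c("50", "60", "70", ""),
                     age_cod = c("YR", "YR", "YR", ""))
  write_faers_fixture(dir, demo, drug_row(as.character(1:4), "GEFITINIB"))
  store <- deduplicate(read_faers_tables(dir))
  co <- build_cohort(store, "gefitinib")
  mp <- missingness_profile(co, store)
  expect_equal(mp$frac_missing[mp$field == "age_years"], 0.25)
  expect_equal(mp$frac_missing[mp$field == "weight_kg"], 0)
  expect_true(all(mp$frac_missing >= 0 & mp$frac_missing <= 1))
  empty <- build_cohort(store, "adagrasib")
  mp0 <- missingness_profile(empty, store)
  expect_true(all(is.na(mp0$frac_missing)))
  expect_true(isTRUE(attr(mp0, "empty_cohort")))
})
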