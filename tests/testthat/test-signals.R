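worked <- contingency_table(5, 15, 5, 75)

test_that("contingency construction derives N and E", {
  expect_equal(worked$N, 100)
  expect_equal(worked$E, 20 * 10 / 100)
  t2 <- contingency_table(0, 20, 0, 80)
  expect_equal(t2$E, 0)
  expect_error(contingency_table(-1, 1, 1, 1), "negative")
  expect_error(contingency_table(0, 0, 0, 0), "N = 0")
})

test_that("build_contingency counts reports, not term mentions", {
  store <- deduplicate(tiny_store())
  co <- build_cohort(store, "osimertinib")
  tab <- build_contingency(store, co, "Rash")
  # Rash occurs in 1001 (twice, counted once) and 2001; universe n = 3
  expect_equal(unlist(tab[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 0, 0, 1))
  absent <- build_contingency(store, co, "Photopsia")
  expect_equal(absent$a, 0)
  expect_equal(absent$E, 0)
})

test_that("PRR, chi-square and ROR match the worked closed forms", {
  ps <- prr_stats(worked, "pearson")
  expect_equal(ps$prr, 4)
  expect_equal(ps$chi2, 6.25)
  ys <- prr_stats(worked, "yates")
  expect_equal(ys$chi2, 100 * 250^2 / 1440000)
  expect_equal(ys$chi2, 4.3403, tolerance = 1e-4)
  rs <- ror_stats(worked)
  expect_equal(rs$ror, 5)
  expect_equal(rs$ror_lo, exp(log(5) - 1.96 * sqrt(0.48)))
  expect_equal(rs$ror_lo, 1.286, tolerance = 1e-3)
  expect_equal(rs$ror_hi, 19.44, tolerance = 1e-3)
  # symmetric table: ROR 1 with a log-symmetric interval
  sym <- ror_stats(contingency_table(1, 1, 1, 1))
  expect_equal(sym$ror, 1)
  expect_equal(sym$ror_lo * sym$ror_hi, 1, tolerance = 1e-12)
})

test_that("frequentist statistics match the brute-force oracle", {
  tabs <- random_tables(1000, seed = 202)
  ct <- contingency_table(tabs$a, tabs$b, tabs$c, tabs$d)
  got_p <- prr_stats(ct, "pearson")
  got_y <- prr_stats(ct, "yates")
  got_r <- ror_stats(ct)
  for (i in seq_len(nrow(tabs))) {
    w <- as.numeric(tabs[i, ])
    expect_lt(rel_err(got_p$prr[i], do.call(oracle_prr, as.list(w))),
              1e-9)
    expect_lt(rel_err(got_p$chi2[i],
                      oracle_chi2(w[1], w[2], w[3], w[4], yates = FALSE)),
              1e-9)
    expect_lt(rel_err(got_y$chi2[i],
                      oracle_chi2(w[1], w[2], w[3], w[4], yates = TRUE)),
              1e-9)
    o <- oracle_ror(w[1], w[2], w[3], w[4])
    expect_lt(rel_err(got_r$ror[i], o["est"]), 1e-9)
    expect_lt(rel_err(got_r$ror_lo[i], o["lo"]), 1e-9)
    expect_lt(rel_err(got_r$ror_hi[i], o["hi"]), 1e-9)
  }
  # Pearson chi-square agrees with the stock test where no flooring occurs
  i <- 1
  m <- matrix(as.numeric(tabs[i, c("a", "b", "c", "d")]), 2, byrow = TRUE)
  expect_equal(got_p$chi2[i],
               unname(stats::chisq.test(m, correct = FALSE)$statistic))
})

test_that("PRR > 1 implies ROR > PRR; independence gives both = 1", {
  tabs <- random_tables(300, seed = 7)
  ct <- contingency_table(tabs$a, tabs$b, tabs$c, tabs$d)
  prr <- prr_stats(ct)$prr
  ror <- ror_stats(ct)$ror
  sel <- prr > 1
  expect_true(all(ror[sel] > prr[sel]))
  ind <- contingency_table(4, 8, 12, 24)  # ad = bc, proportional margins
  expect_equal(prr_stats(ind)$prr, 1)
  expect_equal(ror_stats(ind)$ror, 1)
})

test_that("zero margins yield soft-undefined statistics, flags false", {
  z <- contingency_table(0, 0, 10, 90)
  expect_true(is.na(prr_stats(z)$prr))
  expect_true(is.na(ror_stats(z)$ror))
  sc <- call_signal(data.frame(
    a = 0, prr = NA_real_, chi2 = NA_real_, ror_lo = NA_real_,
    ic025 = 0.5, eb05 = 2.5))
  expect_false(sc$prr_flag)
  expect_false(sc$ror_flag)
  expect_true(sc$ic_flag)
  expect_false(sc$key)
})

test_that("BCPNN information component matches its analytic forms", {
  sym <- contingency_table(25, 25, 25, 25)
  expect_equal(bcpnn_stats(sym)$ic, 0)
  bs <- bcpnn_stats(worked)
  expect_equal(bs$ic, log2(5.5 / 2.5))
  expect_equal(bs$ic, 1.1375, tolerance = 1e-4)
  # Gamma(5.5, rate 2.5) equals chi-square(11)/5: quantile identity
  expect_equal(bs$ic025, log2(stats::qchisq(0.025, 11) / 5))
  expect_equal(bs$ic025, -0.390, tolerance = 1e-3)
  # ic025 < ic everywhere; two-sigma variant is also below ic
  tabs <- random_tables(300, seed = 31)
  ct <- contingency_table(tabs$a, tabs$b, tabs$c, tabs$d)
  post <- bcpnn_stats(ct)
  expect_true(all(post$ic025 < post$ic))
  two <- bcpnn_stats(ct, method = "two_sigma")
  expect_true(all(two$ic025 < two$ic))
  # large-count limit: ic approaches the raw log2(a/E)
  big <- contingency_table(10000, 10000, 5000, 975000)
  expect_equal(bcpnn_stats(big)$ic, log2(big$a / big$E), tolerance = 1e-3)
})

test_that("key-signal calling is the four-way conjunction", {
  sc1 <- call_signal(data.table::data.table(
    a = 5, prr = 4, chi2 = 6.25, ror_lo = 1.286, ic025 = -0.390,
    eb05 = 0.683))
  expect_true(sc1$prr_flag && sc1$ror_flag)
  expect_false(sc1$ic_flag || sc1$ebgm_flag || sc1$key)
  sc2 <- call_signal(data.table::data.table(
    a = 20, prr = 5, chi2 = 40, ror_lo = 2.5, ic025 = 0.8, eb05 = 2.4))
  expect_true(sc2$key)
  # the >=3 reports rule gates via the PRR flag
  sc3 <- call_signal(data.table::data.table(
    a = 2, prr = 5, chi2 = 40, ror_lo = 2.5, ic025 = 0.8, eb05 = 2.4))
  expect_false(sc3$prr_flag)
  expect_false(sc3$key)
})

test_that("flags are monotone in each statistic", {
  base <- data.table::data.table(a = 5, prr = 2, chi2 = 4, ror_lo = 1.01,
                                 ic025 = 0.01, eb05 = 2)
  b0 <- call_signal(base)
  expect_true(b0$key)
  for (col in c("prr", "chi2", "ror_lo", "ic025", "eb05")) {
    up <- data.table::copy(base)
    up[[col]] <- up[[col]] * 2
    expect_true(call_signal(up)$key, info = col)
  }
})

test_that("ranking orders by the chosen field with deterministic ties", {
  sc <- data.table::as.data.table(data.frame(
    drug = "x", pt = c("P1", "P2", "P3", "P4"),
    a = c(10, 7, 7, 2), ebgm = c(3, 2, 5, 9),
    key = c(TRUE, TRUE, TRUE, FALSE)))
  top <- rank_signals(sc, by = "count", k = 3)
  expect_equal(top$pt, c("P1", "P3", "P2"))  # tie at a=7 broken by ebgm
  expect_equal(nrow(rank_signals(sc, by = "count", k = 10)), 3L)
  top_e <- rank_signals(sc, by = "ebgm", k = 2)
  expect_equal(top_e$pt, c("P3", "P1"))
  none <- rank_signals(sc[key == FALSE], k = 5)
  expect_equal(nrow(none), 0L)
})

test_that("signal matrix keeps all-false rows and unions PT columns", {
  sc <- data.table::as.data.table(data.frame(
    drug = c("d1", "d1", "d2", "d3"), pt = c("P1", "P2", "P2", "P9"),
    key = c(TRUE, TRUE, TRUE, FALSE)))
  sm <- signal_matrix(sc)
  expect_equal(dim(sm), c(3L, 2L))
  expect_equal(unname(signal_set_sizes(sm)), c(2, 1, 0))
  expect_setequal(colnames(sm), c("P1", "P2"))
})
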