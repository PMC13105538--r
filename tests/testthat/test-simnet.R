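mk_sm <- function(m, classes = NULL) {
  structure(m, class = c("signal_matrix", "matrix", "array"),
            classes = classes)
}

test_that("Jaccard similarity is exact set arithmetic", {
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                FALSE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, FALSE), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("P", 1:4)))
  j <- jaccard_matrix(mk_sm(m))
  expect_equal(j["A", "B"], 2 / 4)
  expect_equal(j["A", "C"], 1)          # identical non-empty sets
  expect_equal(unname(diag(unclass(j))), rep(1, 3))
  expect_true(isSymmetric(unclass(j)))
  expect_true(all(j >= 0 & j <= 1))
})

test_that("empty signal-set unions give J = 0 with a warning", {
  m <- matrix(c(TRUE, FALSE, FALSE, FALSE), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("P", 1:2)))
  expect_warning(j <- jaccard_matrix(mk_sm(m)), "empty")
  expect_equal(j["A", "B"], 0)
  expect_equal(j["B", "B"], 0)          # empty set: no unit diagonal
})

test_that("1 - J is a metric: triangle inequality on all triples", {
  run <- default_run()
  d <- dissimilarity(run$similarity)
  n <- nrow(d)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 1, n - 1)) {
      for (k in seq(j + 1, n)) {
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
        expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
        expect_lte(d[j, k], d[j, i] + d[i, k] + 1e-12)
      }
    }
  }
})

# 5 drugs whose 10 upper-triangle similarities are a fixed worked set
worked_sim <- function() {
  vals <- c(0.0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3, 0.4, 0.5, 0.6)
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  structure(m, class = c("similarity_matrix", "matrix", "array"))
}

test_that("backbone threshold is the interpolated percentile, ties kept", {
  bb <- backbone(worked_sim(), 80)
  # h = (10-1)*0.8 + 1 = 8.2 -> 0.4 + 0.2*(0.5-0.4)
  expect_equal(bb$threshold, 0.42)
  expect_equal(nrow(bb$edges), 2L)
  expect_true(all(bb$edges$weight >= bb$threshold))
  expect_error(backbone(worked_sim(), 0), "percentile")
  expect_error(backbone(worked_sim(), 100), "percentile")
  # all pairs equal: every edge survives at any percentile
  eq <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 1
  eq <- structure(eq, class = c("similarity_matrix", "matrix", "array"))
  expect_equal(nrow(backbone(eq, 90)$edges), 6L)
})

test_that("backbones nest: edges(90) within edges(80) within edges(70)", {
  run <- default_run()
  key <- function(bb) paste(bb$edges$from, bb$edges$to)
  e70 <- key(run$backbones$p70)
  e80 <- key(run$backbones$p80)
  e90 <- key(run$backbones$p90)
  expect_true(all(e90 %in% e80))
  expect_true(all(e80 %in% e70))
})

test_that("clustering places identical profiles adjacently, deterministically", {
  m <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, TRUE, FALSE,
                FALSE, FALSE, TRUE), nrow = 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), paste0("P", 1:3)))
  j <- jaccard_matrix(mk_sm(m))
  ord <- cluster_order(j)
  expect_equal(abs(diff(match(c("x", "y"), ord))), 1)
  # permutation invariance
  j2 <- jaccard_matrix(mk_sm(m[c(3, 1, 2), ]))
  expect_equal(cluster_order(j2), ord)
  # n = 2: just the two labels
  j3 <- jaccard_matrix(mk_sm(m[1:2, ]))
  expect_setequal(cluster_order(j3), c("x", "y"))
})

test_that("classical MDS reproduces exactly embeddable configurations", {
  # three points at pairwise dissimilarity 1 (equilateral)
  m <- diag(3) > 0
  dimnames(m) <- list(c("a", "b", "c"), paste0("P", 1:3))
  sim <- jaccard_matrix(mk_sm(m))          # off-diagonal J = 0, D = 1
  emb <- mds_embed(sim)
  dd <- as.matrix(stats::dist(emb$points))
  expect_equal(unname(dd[upper.tri(dd)]), rep(1, 3), tolerance = 1e-9)
  expect_equal(emb$negative_mass, 0, tolerance = 1e-9)
  # coordinates centered at the origin
  expect_equal(colSums(emb$points), c(axis1 = 0, axis2 = 0),
               tolerance = 1e-12)
  # axes ordered by descending eigenvalue
  expect_true(all(diff(emb$eig) <= 1e-9))
  expect_error(mds_embed(jaccard_matrix(mk_sm(m[1:2, ]))), "at least 3")
})

test_that("MDS matches cmdscale up to axis sign and clamps negatives", {
  run <- default_run()
  emb <- mds_embed(run$similarity)
  d <- dissimilarity(run$similarity)
  ref <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  expect_equal(abs(emb$points), abs(ref$points), tolerance = 1e-6,
               ignore_attr = TRUE)
  # sign convention: the largest-magnitude coordinate on each axis is +
  for (j in 1:2) {
    expect_gt(emb$points[which.max(abs(emb$points[, j])), j], 0)
  }
  expect_gte(emb$negative_mass, 0)
  # duplicated profiles embed at coincident points
  m <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, TRUE, FALSE,
                FALSE, FALSE, TRUE), nrow = 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), paste0("P", 1:3)))
  emb2 <- mds_embed(jaccard_matrix(mk_sm(m)))
  expect_lt(max(abs(emb2$points["x", ] - emb2$points["y", ])), 1e-6)
})

test_that("embedded distances faithfully track class-structured inputs", {
  # 3 planted classes of 3 drugs: 6 class-shared + 2 drug-unique PTs each
  m <- matrix(FALSE, 9, 3 * 6 + 9 * 2,
              dimnames = list(paste0("d", 1:9),
                              paste0("P", seq_len(3 * 6 + 9 * 2))))
  cls <- rep(c("A", "B", "C"), each = 3)
  for (i in 1:9) {
    g <- match(cls[i], c("A", "B", "C")) - 1
    m[i, g * 6 + 1:6] <- TRUE
    m[i, 18 + (i - 1) * 2 + 1:2] <- TRUE
  }
  sim <- jaccard_matrix(mk_sm(m, classes = stats::setNames(cls,
                                                           rownames(m))))
  emb <- mds_embed(sim)
  d <- dissimilarity(sim)
  dd <- as.matrix(stats::dist(emb$points))
  ut <- upper.tri(d)
  # embedded distances never exceed the input beyond the clamped
  # negative-eigenvalue contribution
  expect_lte(max(dd - d), emb$negative_mass + 1e-9)
  # linear fidelity (Jaccard block distances are heavily tied, which
  # makes rank correlations degenerate; the linear correlation is the
  # informative fidelity measure here)
  expect_gte(stats::cor(dd[ut], d[ut]), 0.9)
  # within-class pairs land closer than between-class pairs
  same <- outer(cls, cls, "==")
  expect_lt(max(dd[ut & same]), min(dd[ut & !same]))
})
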