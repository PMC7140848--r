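test_that("TPM normalization and the zero floor follow their definitions", {
  expect_equal(normalize_tpm(155, 25331960), 155 / 25331960 * 1e6)
  expect_equal(round(normalize_tpm(155, 25331960), 4), 6.1188)
  expect_equal(normalize_tpm(0, 123), 0)
  expect_equal(normalize_tpm(123, 123), 1e6)
  expect_error(normalize_tpm(1, 0), "positive")

  expect_equal(floor_zero(c(0, 0.005, 6.1188)), c(0.01, 0.005, 6.1188))
  expect_error(floor_zero(-1), "non-negative")
})

test_that("low-expression filter drops only miRNAs below 1 TPM everywhere", {
  m <- rbind(a = c(0.2, 0.5, 0.9),
             b = c(0.2, 1.0, 0.1),
             c = c(2.0, 3.0, 4.0))
  expect_identical(unname(low_expression_filter(m)), c(FALSE, TRUE, TRUE))
})

test_that("log2 fold-change matches the printed two-library ratio", {
  expect_equal(log2fc(5, 5), 0)
  expect_equal(log2fc(5, 10), 1)
  # equal effective totals reduce the TPM ratio to the raw count ratio
  expect_equal(round(log2fc(111, 26), 2), -2.09)
  expect_error(log2fc(0, 1), "positive")
})

test_that("exact-test point mass reduces to simple closed forms", {
  t00 <- ac_pvalue(0, 0, 1e6, 1e6)
  expect_equal(t00$point_mass, 0.5)
  t11 <- ac_pvalue(1, 1, 1e6, 1e6)
  expect_equal(t11$point_mass, 0.25)
})

test_that("exact test agrees with the negative-binomial oracle", {
  # p(y|x) is NB(size = x + 1, prob = 1/(1+r)) in y: check point mass and
  # both tails on a grid that includes published count pairs and totals
  grid <- expand.grid(x = c(0, 1, 5, 29, 155, 1971),
                      y = c(0, 1, 13, 47, 300, 696))
  totals <- list(c(25331960, 22632118), c(1e6, 1e6), c(19999279, 27647469))
  for (tt in totals) {
    r <- tt[2] / tt[1]
    prob <- 1 / (1 + r)
    for (k in seq_len(nrow(grid))) {
      x <- grid$x[k]; y <- grid$y[k]
      res <- ac_pvalue(x, y, tt[1], tt[2])
      expect_equal(res$point_mass, dnbinom(y, size = x + 1, prob = prob),
                   tolerance = 1e-10)
      expect_equal(res$lower_tail, pnbinom(y, size = x + 1, prob = prob),
                   tolerance = 1e-10)
      expect_equal(res$upper_tail,
                   pnbinom(y - 1, size = x + 1, prob = prob,
                           lower.tail = FALSE),
                   tolerance = 1e-10)
      # C + D double-counts exactly the point mass
      expect_equal(res$lower_tail + res$upper_tail, 1 + res$point_mass,
                   tolerance = 1e-10)
    }
  }
})

test_that("exact-test distribution normalizes and is symmetric", {
  for (x in c(0, 3, 40)) {
    res <- ac_pvalue(x, 0, 2e6, 1e6)
    ymax <- qnbinom(1 - 1e-13, size = x + 1, prob = 1 / (1 + 0.5))
    total <- ac_pvalue(x, ymax, 2e6, 1e6)$lower_tail
    expect_equal(total, 1, tolerance = 1e-10)
  }
  # with equal totals the conditional point mass is symmetric in (x, y);
  # the tail-based two-sided p is not exactly exchangeable because the test
  # conditions on x, so only the point-mass identity is asserted
  for (pair in list(c(3, 9), c(0, 5), c(120, 80))) {
    a <- ac_pvalue(pair[1], pair[2], 1e6, 1e6)$point_mass
    b <- ac_pvalue(pair[2], pair[1], 1e6, 1e6)$point_mass
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.013, 0.8, 0.04)
  ord <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[ord], bh_fdr(p[ord]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("direction calls respect both thresholds", {
  rec <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    log2fc = c(3.70, -0.5, -1.8, 2.2),
                    fdr = c(1e-4, 1e-6, 0.5, 1e-3))
  out <- call_de(rec, alpha = 0.01, lfc_threshold = 1)
  expect_identical(as.character(out$direction), c("up", "ns", "ns", "up"))
  out2 <- call_de(transform(rec, log2fc = -log2fc), alpha = 0.01)
  expect_identical(as.character(out2$direction), c("down", "ns", "ns", "down"))
})

test_that("membership labels combine per-genotype significance", {
  ht <- data.frame(mirna_id = c("m1", "m2", "m2", "m3", "m4"),
                   direction = c("up", "down", "ns", "ns", "ns"))
  hs <- data.frame(mirna_id = c("m1", "m2", "m3", "m4", "m5"),
                   direction = c("ns", "up", "ns", "down", "up"))
  lab <- membership(ht, hs)
  got <- setNames(as.character(lab$membership), lab$mirna_id)
  expect_identical(got[["m1"]], "HT-only")   # significant at one HT timepoint
  expect_identical(got[["m2"]], "both")
  expect_identical(got[["m3"]], "none")
  expect_identical(got[["m4"]], "HS-only")
  expect_identical(got[["m5"]], "HS-only")
})

test_that("run_de recovers planted fold-changes with correct direction", {
  withr::local_seed(90)
  n_null <- 150; n_up <- 60; n_down <- 60
  base <- 80
  mu1 <- rep(base, n_null + n_up + n_down)
  mu2 <- c(rep(base, n_null), rep(base * 4, n_up), rep(base / 4, n_down))
  counts <- cbind(lib1 = rpois(length(mu1), mu1),
                  lib2 = rpois(length(mu2), mu2))
  rownames(counts) <- sprintf("mir%03d", seq_len(nrow(counts)))
  totals <- c(lib1 = 1e6, lib2 = 1e6)
  res <- run_de(counts, totals,
                data.frame(name = "t", lib1 = "lib1", lib2 = "lib2"))
  truth <- rep(c("ns", "up", "down"), c(n_null, n_up, n_down))
  names(truth) <- rownames(counts)
  called <- setNames(as.character(res$direction), res$mirna_id)
  planted <- names(truth)[truth != "ns"]
  agree <- mean(called[planted] == truth[planted])
  expect_gte(agree, 0.95)
  # null false-call rate should be small under the lfc + FDR gate
  expect_lte(mean(called[names(truth)[truth == "ns"]] != "ns"), 0.02)
})

test_that("run_de floors zero counts so infinite ratios stay finite", {
  counts <- cbind(lib1 = c(50L, 0L), lib2 = c(0L, 60L))
  rownames(counts) <- c("gone", "appeared")
  res <- run_de(counts, c(lib1 = 1e5, lib2 = 1e5),
                data.frame(name = "t", lib1 = "lib1", lib2 = "lib2"))
  expect_true(all(is.finite(res$log2fc)))
  expect_identical(as.character(res$direction[res$mirna_id == "gone"]), "down")
  expect_identical(as.character(res$direction[res$mirna_id == "appeared"]), "up")
})
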