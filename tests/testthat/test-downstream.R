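revcomp_dna <- function(s) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(s, "")[[1]]),
                                        collapse = ""))

test_that("Allen penalties follow the adopted table", {
  mirna <- "UGACAGAAGAGAGUGAGCAGA" # G at position 20, A at position 10
  site <- revcomp_dna(chartr("U", "T", mirna))
  expect_equal(score_target(mirna, site)$score, 0)
  # one G:U at miRNA position 20 (outside the 2-13 core): 0.5
  w <- nchar(site)
  gu <- site
  substr(gu, w - 20 + 1, w - 20 + 1) <- "T"
  expect_equal(score_target(mirna, gu)$score, 0.5)
  # one mismatch at position 10 (inside the core): doubled to 2.0
  mm <- site
  substr(mm, w - 10 + 1, w - 10 + 1) <- "C"
  expect_equal(score_target(mirna, mm)$score, 2.0)
  # a gap outside the core costs 2.0: site missing one base
  gap <- paste0(substr(site, 1, 3), substr(site, 5, w))
  expect_equal(score_target(mirna, gap)$score, 2.0)
  expect_error(score_target(mirna, substr(site, 1, 10)), "window length")
})

test_that("alignment strings render pairs, wobbles and mismatches", {
  mirna <- "UGACAGAAGAGAGUGAGCAGA"
  site <- revcomp_dna(chartr("U", "T", mirna))
  aln <- score_target(mirna, site)$alignment
  expect_match(aln[["bars"]], "^ +\\|{21} +$")
  w <- nchar(site)
  gu <- site
  substr(gu, w - 20 + 1, w - 20 + 1) <- "T"
  expect_match(score_target(mirna, gu)$alignment[["bars"]], "o")
})

test_that("transcriptome scanning finds planted sites and respects the cutoff", {
  withr::local_seed(77)
  mirna <- "UGACAGAAGAGAGUGAGCAGA"
  site <- revcomp_dna(chartr("U", "T", mirna))
  tx <- vapply(1:3, function(i) random_dna(600), character(1))
  names(tx) <- paste0("tx", 1:3)
  planted <- list(c("tx1", 50), c("tx1", 300), c("tx2", 120), c("tx2", 480),
                  c("tx3", 10), c("tx3", 555))
  for (p in planted) {
    substr(tx[[p[1]]], as.integer(p[2]),
           as.integer(p[2]) + nchar(site) - 1) <- site
  }
  hits <- scan_targets(mirna, tx)
  # 100% recall of perfect sites by both scorers
  for (p in planted) {
    found_A <- any(hits$A$transcript_id == p[1] &
                   abs(hits$A$start - as.integer(p[2])) <= 2 &
                   hits$A$score == 0)
    found_B <- any(hits$B$transcript_id == p[1] &
                   abs(hits$B$start - as.integer(p[2])) <= 2)
    expect_true(found_A && found_B, info = paste(p, collapse = ":"))
  }
  # the bulk scanner agrees with the reference scorer on every reported site
  for (k in seq_len(nrow(hits$A))) {
    h <- hits$A[k, ]
    win <- substr(tx[[h$transcript_id]], h$start, h$end)
    expect_equal(score_target(mirna, win)$score, h$score, info = k)
  }
  # a 4.5-penalty site is invisible at cutoff 4 but scores 4.5 at cutoff 5
  bad <- site
  w <- nchar(site)
  substr(bad, w - 10 + 1, w - 10 + 1) <- "C" # core mismatch, 2.0
  substr(bad, w - 15 + 1, w - 15 + 1) <- "A" # G:A mismatch, 1.0
  substr(bad, w - 18 + 1, w - 18 + 1) <- "T" # C:U mismatch, 1.0
  substr(bad, w - 20 + 1, w - 20 + 1) <- "T" # G:U wobble, 0.5 -> total 4.5
  tx2 <- c(bg = random_dna(300))
  substr(tx2[["bg"]], 100, 100 + w - 1) <- bad
  s5 <- scan_targets(mirna, tx2, cutoff = 5)
  s4 <- scan_targets(mirna, tx2, cutoff = 4)
  hit_at <- function(h) h[h$transcript_id == "bg" &
                            abs(h$start - 100) <= 2, , drop = FALSE]
  got <- hit_at(s5$A)
  expect_identical(nrow(got), 1L)
  expect_gt(got$score, 4)
  expect_identical(nrow(hit_at(s4$A)), 0L)
})

test_that("consensus keeps only sites seen by both scorers", {
  A <- data.frame(transcript_id = c("t1", "t1", "t2"),
                  start = c(10L, 200L, 40L), end = c(30L, 220L, 60L),
                  score = c(1, 2, 0.5), energy_ratio = c(.9, .4, .95),
                  stringsAsFactors = FALSE)
  B <- data.frame(transcript_id = c("t1", "t2"),
                  start = c(18L, 40L), end = c(38L, 60L),
                  score = c(1.5, 0.5), energy_ratio = c(.9, .95),
                  stringsAsFactors = FALSE)
  cons <- consensus_targets(A, B)
  # identical site retained, A-only site dropped, 60%-overlap site merged
  expect_identical(nrow(cons), 2L)
  expect_true(any(cons$transcript_id == "t2" & cons$start == 40))
  merged <- cons[cons$transcript_id == "t1", ]
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start, 10L)
  expect_equal(merged$score_B, 1.5)
  # consensus is a subset of each scorer's hit set
  expect_true(all(paste(cons$transcript_id, cons$start) %in%
                    paste(A$transcript_id, A$start)))
})

test_that("hypergeometric tail matches the combinatorial oracle", {
  expect_equal(hypergeom_enrich(0, 5, 5, 10), 1)
  expect_equal(hypergeom_enrich(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeom_enrich(3, 3, 3, 3), 1)
  # brute-force pmf summation over an exhaustive small grid
  for (N in c(8, 15, 25)) {
    for (K in c(2, N %/% 2)) {
      for (n in c(3, N %/% 3)) {
        for (k in 0:min(n, K)) {
          brute <- sum(vapply(k:min(n, K), function(x) {
            choose(K, x) * choose(N - K, n - x) / choose(N, n)
          }, numeric(1)))
          expect_equal(hypergeom_enrich(k, n, K, N), brute,
                       tolerance = 1e-12,
                       info = paste(k, n, K, N))
        }
      }
    }
  }
  expect_error(hypergeom_enrich(6, 5, 10, 20), "inconsistent")
})

test_that("term enrichment flags planted terms and validates inputs", {
  withr::local_seed(19)
  universe <- sprintf("g%03d", 1:200)
  term_map <- do.call(rbind, lapply(1:10, function(t) {
    data.frame(gene = sample(universe, 20), term_id = sprintf("T%02d", t),
               namespace = "biological_process", stringsAsFactors = FALSE)
  }))
  # study drawn preferentially from term T01
  t1 <- term_map$gene[term_map$term_id == "T01"]
  study <- unique(c(t1[1:15], sample(setdiff(universe, t1), 10)))
  res <- enrich_terms(study, universe, term_map)
  expect_identical(res$term_id[1], "T01")
  expect_lte(res$p_adj[1], 0.05)
  expect_true(all(res$k >= 1))
  # study == universe: every p is exactly 1
  res_all <- enrich_terms(universe, universe, term_map)
  expect_true(all(res_all$p == 1))
  expect_error(enrich_terms(c("nope", universe[1]), universe, term_map),
               "nope")
})

test_that("null enrichment p-values are well calibrated", {
  withr::local_seed(404)
  universe <- sprintf("g%03d", 1:200)
  terms <- lapply(1:10, function(t) sample(universe, 20))
  M <- vapply(terms, function(g) universe %in% g, logical(200))
  n_rep <- 2000
  frac_sig <- 0
  ps <- numeric(0)
  for (r in seq_len(n_rep)) {
    idx <- sample(200, 30)
    k <- colSums(M[idx, , drop = FALSE])
    ps <- c(ps, hypergeom_enrich(k, 30, 20, 200))
  }
  expect_lte(mean(ps <= 0.05), 0.07)
})

test_that("2^-ddCt reproduces closed forms and is Ct-shift invariant", {
  mk <- function(ct_ctrl_tar, ct_trt_tar, ct_ref = 20) {
    data.frame(sample = c("s1", "s1", "s2", "s2"),
               group = c("control", "control", "treatment", "treatment"),
               gene = c("mirX", "U6", "mirX", "U6"),
               ct = c(ct_ctrl_tar, ct_ref, ct_trt_tar, ct_ref),
               stringsAsFactors = FALSE)
  }
  expect_equal(ddct(mk(24, 24))$relative_expression, 1)
  expect_equal(ddct(mk(26, 24))$relative_expression, 4)    # ddCt = -2
  expect_equal(ddct(mk(24, 25))$relative_expression, 0.5)  # ddCt = +1
  # adding a constant to every Ct leaves the result unchanged
  base <- mk(26, 24)
  shifted <- transform(base, ct = ct + 3.7)
  expect_equal(ddct(shifted)$relative_expression,
               ddct(base)$relative_expression)
  noref <- mk(26, 24)[-2, ]
  expect_error(ddct(noref), "reference")
})

test_that("qPCR/sequencing concordance matches a least-squares oracle", {
  expect_equal(corr_validation(c(1, 2, 3), c(1, 2, 3))$r_squared, 1)
  expect_equal(corr_validation(c(1, 2, 3), c(-1, -2, -3))$r, -1)
  withr::local_seed(8)
  x <- rnorm(8, sd = 2)
  y <- x + rnorm(8, sd = 0.3)
  got <- corr_validation(x, y)
  expect_equal(got$r_squared, summary(lm(y ~ x))$r.squared,
               tolerance = 1e-12)
  expect_error(corr_validation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(corr_validation(c(1, 2), c(1, 2)), "at least 3")
})
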