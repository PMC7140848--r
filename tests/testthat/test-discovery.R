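# shared fixture: one default synthetic reference
local_ref <- local({
  cfg <- sim_config(seed = 1)
  list(cfg = cfg, ref = make_reference(cfg))
})

test_that("candidate excision clips at chromosome ends and is strand-aware", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100),
                                               collapse = "")))
  hit <- list(chrom = "chr1", start = 2L, end = 24L, strand = "+")
  cands <- excise_candidates(hit, g)
  expect_true(length(cands) > 0)
  expect_true(all(vapply(cands, function(cc) cc$gstart >= 0, logical(1))))
  # a window that would start before the chromosome is clipped, not an error
  expect_true(any(vapply(cands, function(cc) cc$gstart == 0, logical(1))))
  # minus-strand candidate equals the reverse complement of the interval
  hitm <- list(chrom = "chr1", start = 100L, end = 122L, strand = "-")
  cm <- excise_candidates(hitm, g)[[1]]
  plus <- substr(as.character(g[[1]]), cm$gstart + 1, cm$gend)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(plus, "")[[1]]),
                                     collapse = ""))
  expect_identical(cm$seq, rc)
})

test_that("one excision window contains each planted novel precursor", {
  ref <- local_ref$ref
  loci <- ref$truth$planted_loci
  novel <- loci[loci$class == "novel_precursor"]
  g <- as.character(ref$genome[["chr1"]])
  for (k in seq_len(min(5, nrow(novel)))) {
    nm <- novel$name[k]
    hp <- ref$truth$hairpins[[nm]]
    mstart <- novel$start[k] + hp$mature_start - 1L # 0-based mature start
    hit <- list(chrom = "chr1", start = mstart,
                end = mstart + nchar(hp$mature), strand = "+")
    cands <- excise_candidates(hit, ref$genome)
    contained <- any(vapply(cands, function(cc) {
      grepl(hp$precursor, cc$seq, fixed = TRUE)
    }, logical(1)))
    expect_true(contained, info = nm)
  }
})

test_that("duplex statistics match designed imperfections", {
  # perfectly paired mature arm: no mismatches, no bulges
  clean <- withr::with_seed(31, mirheat:::.design_hairpin(22L, "5p", 0L, 0L))
  st <- fold_mfe(clean$precursor)
  dx <- duplex_stats(st, c(clean$mature_start, clean$mature_end))
  expect_true(dx$ok)
  expect_identical(dx$n_mismatches, 0L)
  expect_identical(dx$n_bulges, 0L)
  expect_identical(dx$mature_arm, "5p")

  # the designed pairing itself is the reference here: duplex accounting is
  # asserted on the answer-key structure, independent of how the energy
  # model renders the imperfection
  as_structure <- function(hp, mfe = -30) {
    n <- nchar(hp$precursor)
    gc <- mean(strsplit(hp$precursor, "")[[1]] %in% c("G", "C"))
    structure(list(sequence = chartr("T", "U", hp$precursor),
                   dot_bracket = render_dot_bracket(hp$designed_pairs, n),
                   pairs = hp$designed_pairs, mfe = mfe, gc_fraction = gc,
                   mfei = mfei(mfe, n, gc), length = n),
              class = "hairpin_structure")
  }

  # one designed 2-nt bulge passes the bulge rules
  bul <- withr::with_seed(37, mirheat:::.design_hairpin(22L, "5p", 0L, 2L))
  stb <- as_structure(bul)
  dxb <- duplex_stats(stb, c(bul$mature_start, bul$mature_end))
  expect_true(dxb$ok)
  expect_identical(dxb$n_bulges, 1L)
  expect_identical(dxb$max_bulge_size, 2L)
  expect_true(meyers_check(stb, dxb)$pass)

  # three designed mismatches fail the mismatch rule
  mm <- withr::with_seed(41, mirheat:::.design_hairpin(22L, "5p", 3L, 0L))
  stm <- as_structure(mm)
  dxm <- duplex_stats(stm, c(mm$mature_start, mm$mature_end))
  expect_identical(dxm$n_mismatches, 3L)
  vd <- meyers_check(stm, dxm)
  expect_false(vd$pass)
  expect_true("mismatch-count" %in% vd$reasons)
})

test_that("two separate bulges fail the bulge-count rule", {
  withr::local_seed(53)
  mature <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE,
                         prob = c(.22, .28, .28, .22)), collapse = "")
  star_v <- strsplit(chartr("ACGT", "TGCA",
                            paste(rev(strsplit(mature, "")[[1]]),
                                  collapse = "")), "")[[1]]
  star_v <- append(star_v, "A", after = 5L)
  star_v <- append(star_v, "C", after = 16L)
  prec <- paste0("AACAC", mature, "CAACACAACA",
                 paste(star_v, collapse = ""), "ACACA")
  st <- fold_mfe(prec)
  dx <- duplex_stats(st, c(6, 27))
  expect_true(dx$ok)
  expect_identical(dx$n_bulges, 2L)
  vd <- meyers_check(st, dx)
  expect_false(vd$pass)
  expect_true("bulge-count" %in% vd$reasons)
})

test_that("meyers gate rejects structures below the MFEI threshold", {
  clean <- withr::with_seed(61, mirheat:::.design_hairpin(21L, "5p", 0L, 0L))
  st <- fold_mfe(clean$precursor)
  dx <- duplex_stats(st, c(clean$mature_start, clean$mature_end))
  vd <- meyers_check(st, dx, mfei_threshold = 10)
  expect_false(vd$pass)
  expect_identical(vd$reasons, "mfei")
})

test_that("a two-hairpin candidate fails the single-loop requirement", {
  h1 <- designed_hairpin("GGCAUCGAUGCC", "CAAC")
  h2 <- designed_hairpin("GCCGGAUACGGA", "ACAA")
  st <- fold_mfe(paste0(h1, "AAA", h2))
  dx <- duplex_stats(st, c(1, 12))
  expect_false(dx$ok)
  expect_identical(dx$fail_code, "multi-loop")
  expect_false(meyers_check(st, dx)$pass)
})

test_that("star interval inverts back to the mature up to the 2-nt overhang", {
  clean <- withr::with_seed(71, mirheat:::.design_hairpin(22L, "5p", 0L, 0L))
  st <- fold_mfe(clean$precursor)
  dx <- duplex_stats(st, c(clean$mature_start, clean$mature_end))
  star_core <- c(dx$star_interval[1], dx$star_interval[2] - 2L)
  back <- duplex_stats(st, star_core)
  expect_true(back$ok)
  expect_identical(back$mature_arm, "3p")
  expect_lte(abs(back$star_interval[1] - clean$mature_start), 2L)
  expect_lte(abs((back$star_interval[2] - 2L) - clean$mature_end), 2L)
})

test_that("planted novel hairpins are recovered and known miRNAs never leak", {
  ref <- local_ref$ref
  seqs <- vapply(ref$truth$hairpins, `[[`, character(1), "mature")
  novel <- setdiff(names(ref$truth$hairpins), names(ref$known_catalog))
  tt <- data.table::data.table(sequence = unname(seqs), lib = 100L)
  calls <- discover_novel(tt, ref$genome, ref$annotation, ref$known_catalog)
  nv_seqs <- unname(seqs[novel])
  recovered <- sum(calls$pass & calls$tag_sequence %in% nv_seqs)
  expect_gte(recovered / length(nv_seqs), 0.9)
  expect_identical(sum(calls$tag_sequence %in%
                         unname(seqs[names(ref$known_catalog)])), 0L)
})

test_that("random expressed tags rarely pass at default thresholds", {
  cfg <- sim_config(seed = 11, n_novel_precursors = 0L)
  ref <- make_reference(cfg)
  g <- as.character(ref$genome[["chr1"]])
  loci <- ref$truth$planted_loci
  withr::local_seed(42)
  tags <- character(0)
  while (length(tags) < 40) {
    st <- sample(nchar(g) - 30, 1)
    L <- sample(21:24, 1)
    if (!any(loci$start < st + L - 1 & loci$end > st)) {
      tags <- c(tags, substr(g, st, st + L - 1))
    }
  }
  tt <- data.table::data.table(sequence = unique(tags), lib = 20L)
  calls <- discover_novel(tt, ref$genome, ref$annotation, ref$known_catalog)
  expect_lte(sum(calls$pass) / nrow(tt), 0.05)
})

test_that("the expression floor gates candidacy", {
  ref <- local_ref$ref
  seqs <- vapply(ref$truth$hairpins, `[[`, character(1), "mature")
  novel <- setdiff(names(ref$truth$hairpins), names(ref$known_catalog))
  tt <- data.table::data.table(sequence = unname(seqs[novel]), lib = 3L)
  calls <- discover_novel(tt, ref$genome, ref$annotation, ref$known_catalog,
                          min_reads = 5L)
  expect_identical(nrow(calls), 0L)
})
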