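test_that("exact alignment finds planted substrings on both strands", {
  withr::local_seed(101)
  g <- c(chr1 = random_dna(2000))
  tag <- substr(g[["chr1"]], 501, 524)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(tag, "")[[1]]),
                                     collapse = ""))
  hits <- align_tags(tag, g)
  expect_true(any(hits$strand == "+" & hits$start == 500 & hits$end == 524 &
                  hits$mismatches == 0))
  rhits <- align_tags(rc, g)
  expect_true(any(rhits$strand == "-" & rhits$start == 500 &
                  rhits$end == 524))
})

test_that("alignment equals the brute-force scan on random genomes", {
  withr::local_seed(555)
  g <- c(chrA = random_dna(10000), chrB = random_dna(3000))
  # exact matching, random planted and unplanted 24-nt tags
  tags <- c(substr(g[["chrA"]], 101, 124),
            substr(g[["chrB"]], 2001, 2024),
            replicate(5, random_dna(24)))
  got <- align_tags(tags, g, max_mismatches = 0L)
  want <- do.call(rbind, lapply(unique(tags), brute_align, genome = g,
                                max_mm = 0L))
  expect_identical(hit_key(got), hit_key(want))
})

test_that("mismatch-tolerant alignment equals brute force for 1-3 mismatches", {
  withr::local_seed(556)
  g <- c(chr = random_dna(3000))
  base <- substr(g[["chr"]], 1501, 1521)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- vapply(v[idx], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                        b), 1), character(1))
    paste(v, collapse = "")
  }
  for (mm in 1:3) {
    tags <- c(mutate(base, mm), random_dna(21))
    got <- align_tags(tags, g, max_mismatches = mm)
    want <- do.call(rbind, lapply(unique(tags), brute_align, genome = g,
                                  max_mm = mm))
    expect_identical(hit_key(got), hit_key(want), info = paste("mm", mm))
  }
})

test_that("category assignment follows priority and handles unmapped tags", {
  g <- c(chr1 = strrep("ACGT", 500))
  ann <- GenomicRanges::GRanges("chr1",
           IRanges::IRanges(start = c(101, 101, 301, 501),
                            end   = c(160, 124, 330, 560)),
           type = c("exon", "miRNA", "tRNA", "intron"))
  tag_mature <- substr(g[["chr1"]], 101, 124) # overlaps miRNA + exon
  tag_trna <- substr(g[["chr1"]], 305, 326)
  tag_intergenic <- substr(g[["chr1"]], 801, 822)
  # repeated 4-mer genome: all tags map somewhere; use an unmappable tag
  tag_unmapped <- strrep("A", 22)
  tags <- c(tag_mature, tag_trna, tag_intergenic, tag_unmapped)
  hits <- align_tags(tags, g)
  cats <- assign_category(tags, hits, ann)
  expect_identical(as.character(cats[[tag_unmapped]]), "Unmapped")
  expect_identical(as.character(cats[[tag_mature]]), "Mature")
  # the ACGT-repeat genome multimaps everything, so the tRNA tag also touches
  # other features; at minimum it must not be Unmapped/Intergenic
  expect_false(as.character(cats[[tag_trna]]) %in% c("Unmapped", "Intergenic"))
  expect_error(assign_category(tags, hits, ann, priority = c("Bogus")))
})

test_that("category table partitions totals and formats like the printed table", {
  tag_table <- data.table::data.table(
    sequence = c("AAAATTTTCCCCGGGAT", "ACGTACGTACGTACGTA", "TTTTAAAACCCCGGGTA"),
    libX = c(50L, 30L, 20L), libY = c(5L, 0L, 15L))
  cats <- factor(c("Mature", "Intergenic", "Unmapped"),
                 levels = CATEGORY_LEVELS)
  tab <- build_category_table(tag_table, cats)
  expect_equal(unname(tab$counts["Total", ]), c(100, 20))
  expect_equal(sum(tab$counts[-1, "libX"]), tab$counts["Total", "libX"])
  expect_equal(sum(tab$counts[-1, "libY"]), tab$counts["Total", "libY"])
  expect_equal(unname(tab$percent["Mature", "libX"]), 50)

  # printed percentage formatting, including trailing-zero trimming
  expect_identical(format_count_pct(98508, 25331960), "98,508(0.39%)")
  expect_identical(format_count_pct(1076247, 19999279), "1,076,247(5.38%)")
  expect_identical(format_count_pct(9454199, 22632118), "9,454,199(41.77%)")
  expect_identical(format_count_pct(1283163, 26275173), "1,283,163(4.88%)")
  expect_identical(format_count_pct(7884837, 22632118), "7,884,837(34.84%)")
  expect_identical(format_count_pct(939369, 27647469), "939,369(3.4%)")
  expect_identical(format_count_pct(25331960, 25331960), "25,331,960(100%)")

  all_unmapped <- build_category_table(tag_table,
    factor(rep("Unmapped", 3), levels = CATEGORY_LEVELS))
  expect_equal(unname(all_unmapped$percent["Unmapped", "libX"]), 100)
  expect_true(all(all_unmapped$counts[setdiff(rownames(all_unmapped$counts),
                                              c("Total", "Unmapped")), ] == 0))
})

test_that("known-miRNA matching applies the 3-mismatch Hamming rule", {
  catalog <- c("bra-miR0002" = "TGACAGAAGAGAGTGAGCACA",
               "bra-miR0001" = "TGACAGAAGAGAGTGAGCACA",
               "bra-miR0003" = "TTTGGATTGAAGGGAGCTCTA")
  exact <- match_known("TGACAGAAGAGAGTGAGCACA", catalog)
  expect_identical(exact$mismatches, 0L)
  # ties on equal distance break lexicographically by catalog id
  expect_identical(exact$catalog_id, "bra-miR0001")
  mm3 <- match_known("AGACAGAAGAGAGTGAGCGCG", catalog) # 3 substitutions
  expect_identical(mm3$mismatches, 3L)
  mm4 <- match_known("AGACAGAAGAGAGTGAGGGCG", catalog) # 4 substitutions
  expect_identical(nrow(mm4), 0L)
  # U in the query is read as T
  expect_identical(match_known("UGACAGAAGAGAGUGAGCACA", catalog)$mismatches, 0L)
  # length mismatch never matches
  expect_identical(nrow(match_known("TGACAGAAGAGAGTGAGCAC", catalog)), 0L)
  expect_error(match_known("ACGT", character(0)), "non-empty")
})
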