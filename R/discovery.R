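#' Excise candidate precursor windows around a genome-mapped tag
#'
#' For a uniquely mapped tag, generates candidate precursor sequences under
#' both arm hypotheses: tag on the 5p arm (extend downstream in transcript
#' orientation) and tag on the 3p arm (extend upstream), over a ladder of
#' extension lengths spanning typical plant pre-miRNA sizes. Windows are
#' clipped at chromosome ends; minus-strand candidates are
#' reverse-complemented so the mature always appears in transcript
#' orientation.
#'
#' @param hit One row of [align_tags()] output (list or single-row
#'   data.frame with `chrom`, `start`, `end`, `strand`).
#' @param genome `DNAStringSet` (or FASTA path / named character).
#' @param flanks Bases kept on the mature's outer side; both a tight and a
#'   generous flank are tried (default `c(5, 20)`).
#' @param extents Extension lengths tried on the loop side (default
#'   `c(35, 45, 55, 70, 90, 120, 180)`), short-to-long so callers can stop
#'   at the first acceptable window.
#' @return List of candidates: `seq`, `mature_start`, `mature_end` (1-based
#'   within the candidate), `arm`, `gstart`, `gend`, `strand`, `extent`.
#' @export
excise_candidates <- function(hit, genome, flanks = c(5L, 20L),
                              extents = c(35L, 45L, 55L, 70L, 90L, 120L,
                                          180L)) {
  genome <- .as_genome(genome)
  chrom <- as.character(hit$chrom)
  glen <- Biostrings::width(genome)[match(chrom, names(genome))]
  s <- hit$start; e <- hit$end # 0-based half-open
  len <- e - s
  minus <- as.character(hit$strand) == "-"
  out <- list()
  for (ext in extents) {
    for (flank in flanks) {
    for (arm in c("5p", "3p")) {
      # "downstream of the tag" in transcript orientation
      loop_right <- (arm == "5p") != minus # extension on the genomic right?
      a <- if (loop_right) max(0L, s - flank) else max(0L, s - ext)
      b <- if (loop_right) min(glen, e + ext) else min(glen, e + flank)
      if (b - a < len + 20L) next # too clipped to hold a hairpin
      seqchar <- substr(as.character(genome[[chrom]]), a + 1L, b)
      if (minus) seqchar <- .rc(seqchar)
      # mature offset inside the candidate, 1-based
      m1 <- if (!minus) s - a + 1L else b - e + 1L
      out[[length(out) + 1L]] <- list(seq = seqchar, mature_start = m1,
                                      mature_end = m1 + len - 1L, arm = arm,
                                      gstart = a, gend = b,
                                      strand = as.character(hit$strand),
                                      extent = ext)
    }
    }
  }
  out
}

#' Duplex statistics of a mature interval within a folded hairpin
#'
#' Locates the miRNA* interval from the pairing partners of the mature
#' interval (with the canonical 2-nt 3' overhang) and tallies duplex
#' imperfections: symmetric unpaired stretches (both strands) count one
#' mismatch per position, asymmetric stretches count as a single bulge whose
#' size is the larger strand's run length. G:U wobbles are pairs, not
#' mismatches.
#'
#' @param structure A `hairpin_structure` with exactly one hairpin loop.
#' @param mature_interval Length-2 vector, 1-based inclusive positions of
#'   the mature within the precursor.
#' @return List: `mature_interval`, `star_interval`, `n_mismatches`,
#'   `n_bulges`, `max_bulge_size`, `mature_arm`, `ok` (FALSE with a
#'   `fail_code` when the mature straddles the loop or is unpaired).
#' @export
duplex_stats <- function(structure, mature_interval) {
  pairs <- structure$pairs
  feats <- hairpin_features(structure)
  if (feats$n_hairpin_loops != 1L) {
    return(list(ok = FALSE, fail_code = "multi-loop",
                mature_interval = mature_interval))
  }
  # the unique innermost pair delimits the loop
  np <- NROW(pairs)
  inner <- which(vapply(seq_len(np), function(k) {
    !any(pairs[, 1] > pairs[k, 1] & pairs[, 2] < pairs[k, 2])
  }, logical(1)))
  li <- pairs[inner, 1]; lj <- pairs[inner, 2]
  m1 <- mature_interval[1]; m2 <- mature_interval[2]
  if (m1 <= li && m2 >= lj || (m1 > li && m2 < lj)) {
    return(list(ok = FALSE, fail_code = "loop-spanning",
                mature_interval = mature_interval))
  }
  arm <- if (m2 <= li) "5p" else if (m1 >= lj) "3p" else
    return(list(ok = FALSE, fail_code = "loop-spanning",
                mature_interval = mature_interval))
  partner <- rep(NA_integer_, structure$length)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  mpos <- m1:m2
  paired <- mpos[!is.na(partner[mpos])]
  if (length(paired) < 2) {
    return(list(ok = FALSE, fail_code = "unpaired-mature",
                mature_interval = mature_interval))
  }
  star_lo <- partner[max(paired)]
  star_hi <- partner[min(paired)] + 2L # canonical 2-nt 3' overhang
  star_hi <- min(star_hi, structure$length)
  # walk consecutive paired mature positions and compare gap sizes
  n_mm <- sum(mpos < min(paired)) + sum(mpos > max(paired)) # frayed ends
  n_bulge <- 0L
  max_bulge <- 0L
  pd <- sort(paired)
  for (k in seq_len(length(pd) - 1L)) {
    g_m <- pd[k + 1L] - pd[k] - 1L
    g_s <- abs(partner[pd[k]] - partner[pd[k + 1L]]) - 1L
    if (g_m == 0L && g_s == 0L) next
    if (g_m == g_s) {
      n_mm <- n_mm + g_m
    } else {
      n_mm <- n_mm + min(g_m, g_s)
      n_bulge <- n_bulge + 1L
      max_bulge <- max(max_bulge, max(g_m, g_s))
    }
  }
  list(ok = TRUE, mature_interval = c(m1, m2),
       star_interval = c(star_lo, star_hi),
       n_mismatches = as.integer(n_mm), n_bulges = n_bulge,
       max_bulge_size = as.integer(max_bulge), mature_arm = arm)
}

#' Meyers-criteria gate for a candidate miRNA hairpin
#'
#' Pass requires: a single stem-loop, at most one duplex bulge no larger
#' than two bases, fewer than three duplex mismatches, negative folding
#' energy, and MFEI at or above the threshold. The verdict carries every
#' failed criterion as a reason code.
#'
#' @param structure `hairpin_structure` of the candidate precursor.
#' @param duplex [duplex_stats()] result for the mature interval.
#' @param mfei_threshold Minimum MFEI, default 0.85.
#' @return List: `pass` (logical), `reasons` (character vector, empty on
#'   pass).
#' @export
meyers_check <- function(structure, duplex, mfei_threshold = 0.85) {
  reasons <- character(0)
  if (!isTRUE(duplex$ok)) reasons <- c(reasons, duplex$fail_code)
  feats <- hairpin_features(structure)
  if (feats$n_hairpin_loops != 1L) reasons <- c(reasons, "multi-loop")
  if (isTRUE(duplex$ok)) {
    if (duplex$n_bulges > 1L) reasons <- c(reasons, "bulge-count")
    if (duplex$max_bulge_size > 2L) reasons <- c(reasons, "bulge-size")
    if (duplex$n_mismatches >= 3L) reasons <- c(reasons, "mismatch-count")
  }
  if (structure$mfe >= 0) reasons <- c(reasons, "mfe")
  if (is.na(structure$mfei) || structure$mfei < mfei_threshold) {
    reasons <- c(reasons, "mfei")
  }
  list(pass = length(reasons) == 0L, reasons = unique(reasons))
}

#' Call novel miRNAs from unexplained expressed tags
#'
#' Implements the discovery pipeline: candidate tags (not matching the known
#' catalog, not overlapping annotated ncRNA/miRNA features, uniquely mapped,
#' expressed at or above `min_reads`) are excised under both arm hypotheses
#' over an extent ladder, folded, duplex-checked and gated by
#' [meyers_check()]; the best candidate window per tag is kept (passing
#' windows first, then highest MFEI).
#'
#' @param tag_table Tag-by-library count table ([merge_tag_sets()]).
#' @param genome,annotation,catalog Reference inputs (as in the classify
#'   module).
#' @param min_reads Expression floor summed over libraries, default 5.
#' @param mfei_threshold Passed to [meyers_check()].
#' @param strict_star Require the star sequence to be observed among the
#'   tags (default `FALSE`, matching the lenient duplex-evaluation reading).
#' @param fold_params Energy model, defaults to the package model.
#' @return data.frame, one row per evaluated tag: sequence, counts, locus,
#'   arm, MFE, MFEI, duplex stats, `star_observed`, `pass`, `reasons`.
#' @export
discover_novel <- function(tag_table, genome, annotation, catalog,
                           min_reads = 5L, mfei_threshold = 0.85,
                           strict_star = FALSE,
                           fold_params = .default_energy()) {
  genome <- .as_genome(genome)
  libs <- setdiff(names(tag_table), "sequence")
  total <- rowSums(as.matrix(tag_table[, libs, with = FALSE]))
  tags <- tag_table$sequence[total >= min_reads]
  if (!length(tags)) return(.empty_novel_calls())
  if (length(catalog)) {
    known <- match_known(tags, catalog)$tag_sequence
    tags <- setdiff(tags, known)
  }
  if (!length(tags)) return(.empty_novel_calls())
  hits <- align_tags(tags, genome, max_mismatches = 0L)
  if (nrow(hits) == 0) return(.empty_novel_calls())
  # Unique placement: one hit, or several hits confined to a single
  # precursor-sized window (a near-perfect hairpin maps its mature to both
  # arms -- one locus, not multi-mapping); genuinely dispersed tags drop out.
  keep <- integer(0)
  for (rows in split(seq_len(nrow(hits)), hits$tag_sequence)) {
    h <- hits[rows]
    one_locus <- nrow(h) == 1L ||
      (length(unique(h$chrom)) == 1L && max(h$end) - min(h$start) <= 250L)
    if (one_locus) {
      keep <- c(keep, rows[order(h$strand != "+", h$start)][1])
    }
  }
  hits <- hits[sort(keep)]
  if (nrow(hits) == 0) return(.empty_novel_calls())
  # drop tags overlapping any annotated feature (known miRNA space, ncRNA,
  # exons/introns): novel calls must come from unexplained loci
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  ov <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  hits <- hits[setdiff(seq_len(nrow(hits)), unique(S4Vectors::queryHits(ov)))]
  if (nrow(hits) == 0) return(.empty_novel_calls())
  # Inverted-repeat prefilter: a hairpin needs an approximate reverse
  # complement of the mature within precursor range. Tags without one (edit
  # distance <= 5 within +/- 200 nt) can never satisfy the duplex criteria,
  # so they skip the folding ladder entirely.
  gcache <- lapply(setNames(nm = names(genome)),
                   function(ch) as.character(genome[[ch]]))
  has_partner <- vapply(seq_len(nrow(hits)), function(k) {
    h <- hits[k]
    g <- gcache[[h$chrom]]
    a <- max(1L, h$start - 200L)
    b <- min(nchar(g), h$end + 200L)
    pat <- if (h$strand == "+") .rc(h$tag_sequence) else h$tag_sequence
    length(Biostrings::matchPattern(pat, substr(g, a, b),
                                    max.mismatch = 5,
                                    with.indels = TRUE)) > 0
  }, logical(1))
  hits <- hits[has_partner]
  if (nrow(hits) == 0) return(.empty_novel_calls())
  tagset <- tag_table$sequence
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    hit <- hits[k]
    cands <- excise_candidates(hit, genome)
    best <- NULL
    for (cand in cands) {
      st <- try(fold_mfe(cand$seq, fold_params), silent = TRUE)
      if (inherits(st, "try-error")) next
      dx <- duplex_stats(st, c(cand$mature_start, cand$mature_end))
      vd <- meyers_check(st, dx, mfei_threshold)
      score <- list(cand = cand, st = st, dx = dx, vd = vd)
      if (is.null(best) ||
          (vd$pass && !best$vd$pass) ||
          (vd$pass == best$vd$pass &&
           isTRUE(st$mfei > best$st$mfei))) {
        best <- score
      }
      # extents are ordered short-to-long: the first passing window is the
      # tightest hairpin containing the duplex, so stop there
      if (vd$pass) break
    }
    if (is.null(best)) return(NULL)
    star_obs <- FALSE
    if (isTRUE(best$dx$ok)) {
      si <- best$dx$star_interval
      star_seq <- chartr("U", "T", substr(best$cand$seq, si[1], si[2]))
      star_obs <- star_seq %in% tagset
    }
    pass <- best$vd$pass && (!strict_star || star_obs)
    reasons <- best$vd$reasons
    if (best$vd$pass && strict_star && !star_obs) reasons <- "star-unobserved"
    data.frame(tag_sequence = hit$tag_sequence,
               chrom = hit$chrom, gstart = best$cand$gstart,
               gend = best$cand$gend, strand = hit$strand,
               arm = if (isTRUE(best$dx$ok)) best$dx$mature_arm else best$cand$arm,
               precursor = chartr("U", "T", best$st$sequence),
               mfe = best$st$mfe, mfei = best$st$mfei,
               n_mismatches = if (isTRUE(best$dx$ok)) best$dx$n_mismatches else NA_integer_,
               n_bulges = if (isTRUE(best$dx$ok)) best$dx$n_bulges else NA_integer_,
               max_bulge_size = if (isTRUE(best$dx$ok)) best$dx$max_bulge_size else NA_integer_,
               star_observed = star_obs, pass = pass,
               reasons = paste(reasons, collapse = ";"),
               total_reads = total[match(hit$tag_sequence,
                                         tag_table$sequence)],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_novel_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_novel_calls <- function() {
  data.frame(tag_sequence = character(0), chrom = character(0),
             gstart = integer(0), gend = integer(0), strand = character(0),
             arm = character(0), precursor = character(0), mfe = numeric(0),
             mfei = numeric(0), n_mismatches = integer(0),
             n_bulges = integer(0), max_bulge_size = integer(0),
             star_observed = logical(0), pass = logical(0),
             reasons = character(0), total_reads = numeric(0),
             stringsAsFactors = FALSE)
}
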