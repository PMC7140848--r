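.ALLEN_MAX_GAP <- 2L

#' Score one miRNA:target duplex with Allen-rule penalties
#'
#' Gapped global alignment of the miRNA (5'->3') against the reverse of the
#' target window (the strands are antiparallel), scoring mismatch 1.0, G:U
#' wobble 0.5 and gap 2.0, each doubled at miRNA positions 2-13 from the 5'
#' end. The optimal alignment is found by dynamic programming with gaps
#' limited to 2 per strand.
#'
#' @param mirna miRNA sequence, 5'->3' (ACGU/T).
#' @param window Target site subsequence, 5'->3', with length within
#'   `length(mirna) +/- 2`.
#' @return List: `score`, `alignment` (three-line character vector: miRNA
#'   5'->3', match bars -- `|` pair, `o` wobble, space otherwise -- and
#'   target 3'->5').
#' @examples
#' score_target("UGACAGAAGAGAGUGAGCACA",
#'               as.character(Biostrings::reverseComplement(
#'                 Biostrings::DNAString("TGACAGAAGAGAGTGAGCACA"))))
#' @export
score_target <- function(mirna, window) {
  mv <- .encode_rna(mirna)
  tvq <- .encode_rna(window)
  m <- length(mv)
  w <- length(tvq)
  if (w < m - .ALLEN_MAX_GAP || w > m + .ALLEN_MAX_GAP) {
    stop("window length must be within the miRNA length +/- ", .ALLEN_MAX_GAP)
  }
  tv <- rev(tvq) # antiparallel
  wt <- function(i) ifelse(i >= 2 & i <= 13, 2, 1)
  subc <- function(mb, tb, i) {
    wc <- (mb == 0 & tb == 3) | (mb == 3 & tb == 0) |
      (mb == 1 & tb == 2) | (mb == 2 & tb == 1)
    gu <- (mb == 2 & tb == 3) | (mb == 3 & tb == 2)
    ifelse(wc, 0, ifelse(gu, 0.5, 1) * wt(i))
  }
  D <- matrix(Inf, m + 1, w + 1)
  D[1, 1] <- 0
  for (i in seq_len(m)) D[i + 1, 1] <- D[i, 1] + 2 * wt(i)
  for (j in seq_len(w)) D[1, j + 1] <- D[1, j] + 2 * wt(1)
  for (i in seq_len(m)) {
    for (j in seq_len(w)) {
      D[i + 1, j + 1] <- min(D[i, j] + subc(mv[i], tv[j], i),
                             D[i, j + 1] + 2 * wt(i),
                             D[i + 1, j] + 2 * wt(min(i + 1, m)))
    }
  }
  # traceback for the alignment strings
  i <- m; j <- w
  top <- bar <- bot <- character(0)
  letters4 <- c("A", "C", "G", "U")
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(D[i + 1, j + 1], D[i, j] + subc(mv[i], tv[j], i)))) {
      cost <- subc(mv[i], tv[j], i)
      top <- c(letters4[mv[i] + 1], top)
      bot <- c(letters4[tv[j] + 1], bot)
      bar <- c(if (cost == 0) "|" else if (cost == 0.5 * wt(i)) "o" else " ",
               bar)
      i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               isTRUE(all.equal(D[i + 1, j + 1], D[i, j + 1] + 2 * wt(i)))) {
      top <- c(letters4[mv[i] + 1], top); bot <- c("-", bot)
      bar <- c(" ", bar); i <- i - 1
    } else {
      top <- c("-", top); bot <- c(letters4[tv[j] + 1], bot)
      bar <- c(" ", bar); j <- j - 1
    }
  }
  list(score = D[m + 1, w + 1],
       alignment = c(mirna = paste0("5' ", paste(top, collapse = ""), " 3'"),
                     bars = paste0("   ", paste(bar, collapse = ""), "   "),
                     target = paste0("3' ", paste(bot, collapse = ""), " 5'")))
}

# duplex energy of an aligned site under the package stacking model: sum of
# stack terms over consecutive paired columns (WC or G:U); gaps/mismatches
# break the helix
.duplex_energy <- function(mirna, window, params = .default_energy()) {
  mv <- .encode_rna(mirna)
  tvq <- rev(.encode_rna(window))
  n <- min(length(mv), length(tvq))
  ptype <- function(a, b) {
    key <- paste0(c("A", "C", "G", "U")[a + 1], c("A", "C", "G", "U")[b + 1])
    match(key, c("AU", "UA", "GC", "CG", "GU", "UG"))
  }
  e <- 0
  prev <- NA_integer_
  for (k in seq_len(n)) {
    pt <- ptype(mv[k], tvq[k])
    if (!is.na(pt) && !is.na(prev)) e <- e + params$stack[prev, pt]
    prev <- pt
  }
  e
}

#' Scan a transcriptome for miRNA target sites with two scorers
#'
#' Scorer A reports every window whose Allen penalty is at or below
#' `cutoff`; scorer B additionally requires the site's duplex energy to
#' reach at least `energy_ratio_min` of the perfect-complement duplex energy
#' under the package's stacking model. Overlapping windows at one locus are
#' collapsed to the best-scoring one.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts Named character vector, `DNAStringSet`, or FASTA path.
#' @param cutoff Allen penalty cutoff, default 4.
#' @param energy_ratio_min Scorer B energy ratio threshold, default 0.7.
#' @param params Energy model for the duplex-energy criterion.
#' @return List of data.frames `A` and `B` with columns `transcript_id`,
#'   `start`, `end` (1-based inclusive), `score`, `energy_ratio`.
#' @export
scan_targets <- function(mirna, transcripts, cutoff = 4,
                         energy_ratio_min = 0.7,
                         params = .default_energy()) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    ts <- Biostrings::readDNAStringSet(transcripts)
    transcripts <- setNames(as.character(ts), sub("\\s.*$", "", names(ts)))
  }
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  if (!length(transcripts)) stop("transcriptome must be non-empty")
  mv <- .encode_rna(mirna)
  perfect <- .duplex_energy(mirna, .rc(chartr("U", "T", toupper(mirna))),
                            params)
  rows <- list()
  for (tid in names(transcripts)) {
    tv <- .encode_rna(transcripts[[tid]])
    hits <- .allen_scan_cpp(mv, tv, cutoff, .ALLEN_MAX_GAP)
    if (nrow(hits) == 0) next
    # collapse runs of overlapping windows to their best representative
    ord <- order(hits[, "start"])
    hits <- hits[ord, , drop = FALSE]
    ends_cm <- cummax(hits[, "end"])
    grp <- cumsum(c(TRUE, hits[-1, "start"] > utils::head(ends_cm, -1)))
    for (g in unique(grp)) {
      sub <- hits[grp == g, , drop = FALSE]
      k <- which.min(sub[, "score"])
      st <- sub[k, "start"]; en <- sub[k, "end"]
      win <- substr(transcripts[[tid]], st, en)
      er <- if (perfect < 0) .duplex_energy(mirna, win, params) / perfect else 0
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, start = unname(st), end = unname(en),
        score = unname(sub[k, "score"]), energy_ratio = er,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      energy_ratio = numeric(0), stringsAsFactors = FALSE)
  if (!length(rows)) return(list(A = empty, B = empty))
  all_hits <- do.call(rbind, rows)
  list(A = all_hits,
       B = all_hits[all_hits$energy_ratio >= energy_ratio_min, ,
                    drop = FALSE])
}

#' Intersect the hit sets of the two target scorers
#'
#' Keeps only sites reported by both scorers on the same transcript with at
#' least `min_overlap` fractional overlap (relative to the shorter site);
#' the merged record carries both scores.
#'
#' @param hitsA,hitsB Data frames from [scan_targets()].
#' @param min_overlap Fractional overlap required, default 0.5.
#' @return Data frame with `transcript_id`, `start`, `end` (scorer A's
#'   window), `score_A`, `score_B`, `scorers` (always `"A,B"`).
#' @export
consensus_targets <- function(hitsA, hitsB, min_overlap = 0.5) {
  out <- list()
  for (k in seq_len(nrow(hitsA))) {
    a <- hitsA[k, ]
    cand <- hitsB[hitsB$transcript_id == a$transcript_id, , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, a$end) - pmax(cand$start, a$start) + 1
    len <- pmin(cand$end - cand$start, a$end - a$start) + 1
    j <- which(ov / len >= min_overlap)
    if (length(j)) {
      j <- j[which.min(cand$score[j])]
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = a$transcript_id, start = a$start, end = a$end,
        score_A = a$score, score_B = cand$score[j], scorers = "A,B",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), score_A = numeric(0),
                      score_B = numeric(0), scorers = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of seeing at least
#' `k` annotated genes in a study set of size `n` drawn from a universe of
#' `N` genes of which `K` carry the term.
#'
#' @param k Study genes with the term.
#' @param n Study-set size.
#' @param K Universe genes with the term.
#' @param N Universe size.
#' @export
hypergeom_enrich <- function(k, n, K, N) {
  if (any(k > n | k > K | n > N | K > N | k < 0 | n < 0 | K < 0)) {
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a study gene set
#'
#' One upper-tail hypergeometric test per term with at least one study gene,
#' BH-adjusted; terms with adjusted p at or below `alpha` are flagged.
#'
#' @param study_genes Character vector, a subset of `universe_genes`.
#' @param universe_genes Background gene set.
#' @param term_map Data frame with columns `gene`, `term_id` and optionally
#'   `term_name`, `namespace`; rows for genes outside the universe are
#'   ignored.
#' @param alpha Corrected-p threshold for the `enriched` flag, default 0.05.
#' @return Data frame sorted by p: `term_id` (plus `term_name`/`namespace`
#'   when supplied), `k`, `n`, `K`, `N`, `p`, `p_adj`, `enriched`.
#' @export
enrich_terms <- function(study_genes, universe_genes, term_map,
                         alpha = 0.05) {
  study_genes <- unique(study_genes)
  universe_genes <- unique(universe_genes)
  missing <- setdiff(study_genes, universe_genes)
  if (length(missing)) {
    stop("study gene(s) absent from the universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  tm <- term_map[term_map$gene %in% universe_genes, , drop = FALSE]
  N <- length(universe_genes)
  n <- length(study_genes)
  terms <- split(tm, tm$term_id)
  rows <- lapply(terms, function(t) {
    genes <- unique(t$gene)
    k <- sum(study_genes %in% genes)
    if (k == 0) return(NULL)
    out <- data.frame(term_id = t$term_id[1], k = k, n = n,
                      K = length(genes), N = N,
                      p = hypergeom_enrich(k, n, length(genes), N),
                      stringsAsFactors = FALSE)
    if ("term_name" %in% names(t)) out$term_name <- t$term_name[1]
    if ("namespace" %in% names(t)) out$namespace <- t$namespace[1]
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_fdr(res$p)
  res$enriched <- res$p_adj <= alpha
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' For each target gene, delta-Ct against the reference gene is computed
#' within each sample, averaged per group, and the relative expression is
#' `2^-(dCt_treatment - dCt_control)`. An amplification efficiency of
#' exactly 2 is assumed.
#'
#' @param ct Data frame with columns `sample`, `group` (must contain
#'   `control` and `treatment`), `gene`, `ct` (as written by
#'   [simulate_qpcr()]).
#' @param reference Reference gene id, default `"U6"`.
#' @return Data frame per target gene: `gene`, `dct_control`,
#'   `dct_treatment` (means), `sem_control`, `sem_treatment`, `ddct`,
#'   `relative_expression` (= `2^-ddct`), `log2fc` (= `-ddct`).
#' @export
ddct <- function(ct, reference = "U6") {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  genes <- setdiff(unique(ct$gene), reference)
  samples <- unique(ct$sample)
  for (s in samples) {
    if (!any(ct$sample == s & ct$gene == reference)) {
      stop("reference gene ", reference, " missing in sample ", s)
    }
  }
  ref_ct <- setNames(vapply(samples, function(s) {
    mean(ct$ct[ct$sample == s & ct$gene == reference])
  }, numeric(1)), samples)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  rows <- lapply(genes, function(g) {
    d <- ct[ct$gene == g, , drop = FALSE]
    dct <- d$ct - ref_ct[d$sample]
    byg <- split(dct, d$group)
    if (!all(c("control", "treatment") %in% names(byg))) {
      stop("gene ", g, " needs both control and treatment measurements")
    }
    dc <- mean(byg$control); dt <- mean(byg$treatment)
    data.frame(gene = g, dct_control = dc, dct_treatment = dt,
               sem_control = sem(byg$control), sem_treatment = sem(byg$treatment),
               ddct = dt - dc, relative_expression = 2^-(dt - dc),
               log2fc = -(dt - dc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between qPCR and sequencing fold-changes
#'
#' @param qpcr_log2fc,seq_log2fc Equal-length (>= 3) finite vectors of per-
#'   miRNA log2 fold-changes from the two platforms.
#' @return List: `r` (Pearson), `r_squared`.
#' @export
corr_validation <- function(qpcr_log2fc, seq_log2fc) {
  if (length(qpcr_log2fc) != length(seq_log2fc) || length(qpcr_log2fc) < 3) {
    stop("need equal-length vectors of at least 3 values")
  }
  if (!all(is.finite(qpcr_log2fc)) || !all(is.finite(seq_log2fc))) {
    stop("fold-changes must be finite")
  }
  if (stats::sd(qpcr_log2fc) == 0 || stats::sd(seq_log2fc) == 0) {
    stop("zero variance in fold-changes")
  }
  r <- cor(qpcr_log2fc, seq_log2fc)
  list(r = r, r_squared = r^2)
}
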