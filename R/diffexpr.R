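#' TPM normalization for small RNA tag counts
#'
#' Normalized expression = count / total clean reads x 10^6, at full
#' precision. The denominator is the library's total clean-read count (the
#' whole cleaned library, not just miRNA-mapped reads).
#'
#' @param count Non-negative integer count(s).
#' @param total_clean_reads Positive library total(s).
#' @export
normalize_tpm <- function(count, total_clean_reads) {
  if (any(total_clean_reads <= 0)) stop("total_clean_reads must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / total_clean_reads * 1e6
}

#' Replace exact-zero TPM values by 0.01
#'
#' Only exact zeros are floored so that log fold-changes are always defined;
#' small positive values pass through unchanged.
#'
#' @param tpm Numeric vector of normalized expressions (>= 0).
#' @export
floor_zero <- function(tpm) {
  if (any(tpm < 0)) stop("tpm must be non-negative")
  ifelse(tpm == 0, 0.01, tpm)
}

#' Drop miRNAs with low expression in every library
#'
#' A miRNA is removed only when its normalized expression is below `min_tpm`
#' in all libraries; one library at or above the threshold retains it.
#'
#' @param tpm_matrix Numeric matrix, miRNAs x libraries, of (possibly floored)
#'   TPM values.
#' @param min_tpm Threshold, default 1.
#' @return Logical vector: `TRUE` for retained rows.
#' @export
low_expression_filter <- function(tpm_matrix, min_tpm = 1) {
  tpm_matrix <- as.matrix(tpm_matrix)
  apply(tpm_matrix, 1, function(x) any(x >= min_tpm))
}

#' Log2 fold-change between two normalized expressions
#' @param n1,n2 Positive (post-floor) normalized expressions; the ratio is
#'   `n2 / n1`.
#' @export
log2fc <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("normalized expressions must be positive; apply floor_zero() first")
  }
  log2(n2 / n1)
}

# log point mass log p(y | x) for the two-library exact test;
# r = N2/N1, computed with log-gamma throughout
.ac_log_pmf <- function(y, x, log_r, log1p_r) {
  y * log_r + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p_r
}

#' Audic-Claverie exact test for one tag between two libraries
#'
#' Given counts `x` (library 1) and `y` (library 2) with clean-read totals
#' `N1_total` and `N2_total`, the conditional distribution of `y` given `x`
#' has point mass
#' \deqn{p(y|x) = r^y \frac{(x+y)!}{x!\,y!} (1+r)^{-(x+y+1)}, \quad r = N_2/N_1,}
#' equivalently a negative binomial with `x + 1` successes and success
#' probability `1/(1+r)`. The lower tail `C` sums the point masses for counts
#' up to `y`, the upper tail `D` for counts at or above `y` (so `C + D`
#' exceeds 1 by exactly the point mass), and the two-sided p-value is
#' `min(1, 2 min(C, D))`. All terms are computed in log space.
#'
#' @param x,y Non-negative integer counts in library 1 and 2.
#' @param N1_total,N2_total Positive clean-read totals of the two libraries.
#' @return An `exact_test` list: `x`, `y`, `N1_total`, `N2_total`, `r`,
#'   `point_mass`, `lower_tail`, `upper_tail`, `p_two_sided`.
#' @examples
#' ac_pvalue(155, 47, 25331960, 22632118)
#' @export
ac_pvalue <- function(x, y, N1_total, N2_total) {
  if (x < 0 || y < 0 || x != round(x) || y != round(y)) {
    stop("x and y must be non-negative integers")
  }
  if (N1_total <= 0 || N2_total <= 0) stop("library totals must be positive")
  r <- N2_total / N1_total
  log_r <- log(r)
  log1p_r <- log1p(r)
  log_pm <- .ac_log_pmf(y, x, log_r, log1p_r)
  pm <- exp(log_pm)
  # The smaller tail is summed directly from the point mass outward with the
  # ratio recurrence p(y+1|x)/p(y|x) = r (x+y+1) / ((y+1)(1+r)) (terms decay
  # away from the mode, so the sum keeps full relative precision); the larger
  # tail, which is O(1), is closed through the complement identity
  # C + D = 1 + p(y|x).
  if (y <= (x + 1) * r) {
    acc <- 1; term <- 1; yy <- y
    while (yy > 0) {
      term <- term * (yy * (1 + r)) / (r * (x + yy))
      acc <- acc + term
      yy <- yy - 1L
      if (term < acc * 1e-18) break
    }
    lower <- min(1, exp(log_pm + log(acc)))
    upper <- min(1, 1 - lower + pm)
  } else {
    acc <- 1; term <- 1; yy <- y
    repeat {
      term <- term * (r * (x + yy + 1)) / ((yy + 1) * (1 + r))
      acc <- acc + term
      yy <- yy + 1L
      if (term < acc * 1e-18) break
    }
    upper <- min(1, exp(log_pm + log(acc)))
    lower <- min(1, 1 - upper + pm)
  }
  structure(list(x = x, y = y, N1_total = N1_total, N2_total = N2_total,
                 r = r, point_mass = pm, lower_tail = lower,
                 upper_tail = upper,
                 p_two_sided = min(1, 2 * min(lower, upper))),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("Audic-Claverie exact test: x=%d (N1=%g), y=%d (N2=%g)\n",
              x$x, x$N1_total, x$y, x$N2_total))
  cat(sprintf("  point mass %.4g | lower tail C %.4g | upper tail D %.4g | two-sided p %.4g\n",
              x$point_mass, x$lower_tail, x$upper_tail, x$p_two_sided))
  invisible(x)
}

# vectorized two-sided p over count pairs (shared totals)
.ac_pvalue_vec <- function(x, y, N1_total, N2_total) {
  vapply(seq_along(x), function(k) {
    ac_pvalue(x[k], y[k], N1_total, N2_total)$p_two_sided
  }, numeric(1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (delegates to [stats::p.adjust()]); results are
#' invariant to the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential expression for one contrast
#'
#' A miRNA is called `up` when `log2fc >= lfc_threshold` and `fdr <= alpha`,
#' `down` when `log2fc <= -lfc_threshold` and `fdr <= alpha`, otherwise `ns`.
#'
#' @param records Data frame with columns `mirna_id`, `log2fc`, `fdr` (and
#'   optionally anything else, passed through).
#' @param alpha FDR significance level, default 0.01.
#' @param lfc_threshold Minimum absolute log2 fold-change, default 1.
#' @return The input with a `direction` factor column.
#' @export
call_de <- function(records, alpha = 0.01, lfc_threshold = 1) {
  stopifnot(all(c("mirna_id", "log2fc", "fdr") %in% names(records)))
  dir <- rep("ns", nrow(records))
  sig <- !is.na(records$fdr) & records$fdr <= alpha
  dir[sig & records$log2fc >= lfc_threshold] <- "up"
  dir[sig & records$log2fc <= -lfc_threshold] <- "down"
  records$direction <- factor(dir, levels = c("up", "down", "ns"))
  records
}

#' Genotype-membership labels for differentially expressed miRNAs
#'
#' A miRNA is `HT-only` when it is significant (direction not `ns`) in at
#' least one heat-tolerant contrast and in no heat-sensitive contrast,
#' `HS-only` symmetrically, `both` when significant in each genotype, and
#' `none` otherwise. A miRNA significant at two timepoints of the same
#' genotype still counts once.
#'
#' @param ht_calls,hs_calls Data frames from [call_de()] (rows may repeat a
#'   miRNA across contrasts) for the heat-tolerant and heat-sensitive
#'   genotype.
#' @return Data frame with `mirna_id` and `membership` for every miRNA seen
#'   in either genotype.
#' @export
membership <- function(ht_calls, hs_calls) {
  sig_ids <- function(calls) unique(calls$mirna_id[calls$direction != "ns"])
  ht_sig <- sig_ids(ht_calls)
  hs_sig <- sig_ids(hs_calls)
  ids <- unique(c(ht_calls$mirna_id, hs_calls$mirna_id))
  lab <- ifelse(ids %in% ht_sig & ids %in% hs_sig, "both",
         ifelse(ids %in% ht_sig, "HT-only",
         ifelse(ids %in% hs_sig, "HS-only", "none")))
  data.frame(mirna_id = ids,
             membership = factor(lab, levels = c("HT-only", "HS-only",
                                                 "both", "none")),
             stringsAsFactors = FALSE)
}

#' Two-library differential expression over a set of contrasts
#'
#' Runs the full normalization-and-test procedure on a count matrix: TPM normalization with
#' the zero floor, the all-libraries low-expression filter, per-contrast
#' Audic-Claverie exact tests on raw counts with library totals, BH FDR
#' within each contrast, and direction calls.
#'
#' @param counts Integer matrix, miRNAs x libraries, with rownames (miRNA
#'   ids) and colnames (library ids).
#' @param totals Named vector of clean-read totals per library (the
#'   normalization denominators).
#' @param contrasts Data frame with columns `name`, `lib1` (baseline) and
#'   `lib2` (treatment), each a library id.
#' @param alpha,lfc_threshold Significance settings, see [call_de()].
#' @param min_tpm Low-expression threshold, see [low_expression_filter()].
#' @return Data frame with one row per retained miRNA per contrast: counts,
#'   floored TPMs, `log2fc`, `p`, `fdr`, `direction`.
#' @export
run_de <- function(counts, totals, contrasts, alpha = 0.01,
                   lfc_threshold = 1, min_tpm = 1) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry miRNA rownames and library colnames")
  }
  if (!all(colnames(counts) %in% names(totals))) {
    stop("every count column needs a clean-read total")
  }
  totals <- totals[colnames(counts)]
  tpm <- sweep(counts, 2, totals, function(c, t) normalize_tpm(c, t))
  tpm_floor <- apply(tpm, 2, floor_zero)
  keep <- low_expression_filter(tpm_floor, min_tpm)
  counts <- counts[keep, , drop = FALSE]
  tpm_floor <- tpm_floor[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(contrasts)), function(k) {
    l1 <- contrasts$lib1[k]
    l2 <- contrasts$lib2[k]
    x <- counts[, l1]
    y <- counts[, l2]
    p <- .ac_pvalue_vec(x, y, totals[[l1]], totals[[l2]])
    data.frame(mirna_id = rownames(counts), contrast = contrasts$name[k],
               count1 = unname(x), count2 = unname(y),
               tpm1 = unname(tpm_floor[, l1]), tpm2 = unname(tpm_floor[, l2]),
               log2fc = log2fc(tpm_floor[, l1], tpm_floor[, l2]),
               p = p, fdr = bh_fdr(p), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  call_de(res, alpha = alpha, lfc_threshold = lfc_threshold)
}
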