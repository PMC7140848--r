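#' Category labels in reporting order
#'
#' The eleven read categories used by the classification table, from least to
#' most specific annotation plus `Unmapped`.
#' @export
CATEGORY_LEVELS <- c("Intergenic", "Intron", "Exon", "Precursor", "Mature",
                     "Rfam_other", "rRNA", "snRNA", "snoRNA", "tRNA",
                     "Unmapped")

#' Default category priority (most specific first)
#'
#' Used to resolve tags whose hits overlap several feature types: the most
#' specific annotation wins, so reads from a mature miRNA inside its
#' precursor (which in turn may sit in an exon) count as `Mature`.
#' @export
DEFAULT_CATEGORY_PRIORITY <- c("Mature", "Precursor", "rRNA", "tRNA",
                               "snRNA", "snoRNA", "Rfam_other", "Exon",
                               "Intron")

# annotation feature type -> category
.FEATURE_CATEGORY <- c(miRNA = "Mature", miRNA_precursor = "Precursor",
                       rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA",
                       snoRNA = "snoRNA", other_sncRNA = "Rfam_other",
                       exon = "Exon", intron = "Intron")

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Map unique tags to a reference genome
#'
#' Reports every ungapped hit of each tag on both strands with at most
#' `max_mismatches` substitutions. Exact matching (the default) uses a
#' Biostrings preprocessed dictionary per tag width; mismatch-tolerant
#' matching falls back to a per-tag scan. Minus-strand hits report the plus
#' strand genomic interval that the reverse complement of the tag matches.
#' Coordinates are 0-based half-open.
#'
#' @param tags Character vector of tag sequences (ACGT).
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @param max_mismatches Maximum substitutions per hit (0-3 supported).
#' @return data.table: `tag_sequence`, `chrom`, `start`, `end`, `strand`,
#'   `mismatches`. Tags without hits simply do not appear.
#' @export
align_tags <- function(tags, genome, max_mismatches = 0L) {
  genome <- .as_genome(genome)
  tags <- unique(toupper(tags))
  res <- list()
  push <- function(tag, chrom, starts, ends, strand, mm) {
    if (!length(starts)) return()
    res[[length(res) + 1L]] <<- data.table::data.table(
      tag_sequence = tag, chrom = chrom, start = starts - 1L, end = ends,
      strand = strand, mismatches = as.integer(mm))
  }
  if (max_mismatches == 0L) {
    widths <- nchar(tags)
    for (w in unique(widths)) {
      grp <- tags[widths == w]
      fwd <- Biostrings::PDict(grp)
      rev <- Biostrings::PDict(as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(grp))))
      for (chrom in names(genome)) {
        subj <- genome[[chrom]]
        for (sd in c("+", "-")) {
          m <- Biostrings::matchPDict(if (sd == "+") fwd else rev, subj)
          cnt <- S4Vectors::elementNROWS(m)
          if (sum(cnt) == 0) next
          ir <- unlist(m, use.names = FALSE)
          res[[length(res) + 1L]] <- data.table::data.table(
            tag_sequence = rep(grp, cnt), chrom = chrom,
            start = BiocGenerics::start(ir) - 1L,
            end = BiocGenerics::end(ir), strand = sd, mismatches = 0L)
        }
      }
    }
  } else {
    for (tag in tags) {
      pat <- Biostrings::DNAString(tag)
      rpat <- Biostrings::reverseComplement(pat)
      for (chrom in names(genome)) {
        subj <- genome[[chrom]]
        for (sd in c("+", "-")) {
          pp <- if (sd == "+") pat else rpat
          m <- Biostrings::matchPattern(pp, subj,
                                        max.mismatch = max_mismatches,
                                        with.indels = FALSE)
          if (length(m)) {
            mm <- Biostrings::neditStartingAt(pp, subj,
                                              starting.at =
                                                BiocGenerics::start(m))
            push(tag, chrom, BiocGenerics::start(m), BiocGenerics::end(m),
                 sd, mm)
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(data.table::data.table(tag_sequence = character(0),
                                  chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  mismatches = integer(0)))
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, tag_sequence, chrom, start, strand)
  out
}

#' Pick one "best" hit per tag
#'
#' Fewest mismatches, then leftmost coordinate (chromosome name, then start,
#' then plus strand first): the deterministic placement rule used for
#' multi-mapping tags.
#'
#' @param hits Output of [align_tags()].
#' @return One row per tag.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  h <- data.table::copy(hits)
  data.table::setorder(h, tag_sequence, mismatches, chrom, start, strand)
  h[, .SD[1], by = "tag_sequence"]
}

#' Assign each tag to a single read category
#'
#' Unmapped tags get `Unmapped`; mapped tags take the highest-priority
#' category among the annotation features that any of their hits overlap, or
#' `Intergenic` when no hit touches a feature.
#'
#' @param tags Character vector of tag sequences (the classification
#'   universe; tags absent from `hits` are unmapped).
#' @param hits [align_tags()] output for these tags.
#' @param annotation `GRanges` with a `type` metadata column using the
#'   feature vocabulary `miRNA`, `miRNA_precursor`, `rRNA`, `tRNA`, `snRNA`,
#'   `snoRNA`, `other_sncRNA`, `exon`, `intron` (e.g. from
#'   [read_annotation()]).
#' @param priority Character vector, most specific category first.
#' @return Named factor of categories, one per tag.
#' @export
assign_category <- function(tags, hits, annotation,
                            priority = DEFAULT_CATEGORY_PRIORITY) {
  stopifnot(all(priority %in% CATEGORY_LEVELS))
  if (length(annotation) && any(GenomicRanges::start(annotation) < 1)) {
    stop("malformed annotation interval: start below 1")
  }
  cat_out <- setNames(rep("Unmapped", length(tags)), tags)
  if (nrow(hits)) {
    mapped <- unique(hits$tag_sequence)
    cat_out[mapped] <- "Intergenic"
    feat_cat <- .FEATURE_CATEGORY[as.character(annotation$type)]
    keep <- !is.na(feat_cat)
    ann <- annotation[keep]
    feat_cat <- feat_cat[keep]
    if (length(ann) && nrow(hits)) {
      gr <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$start + 1L,
                                                    hits$end))
      ov <- GenomicRanges::findOverlaps(gr, ann, ignore.strand = TRUE)
      if (length(ov)) {
        rank <- setNames(seq_along(priority), priority)
        dt <- data.table::data.table(
          tag = hits$tag_sequence[S4Vectors::queryHits(ov)],
          r = rank[feat_cat[S4Vectors::subjectHits(ov)]])
        bestr <- dt[, list(r = min(r)), by = "tag"]
        cat_out[bestr$tag] <- priority[bestr$r]
      }
    }
  }
  factor(cat_out, levels = c(CATEGORY_LEVELS))
}

#' Read-weighted classification table across libraries
#'
#' Tabulates total reads per category and library, in the standard layout:
#' a `Total` row followed by the eleven categories, with percentages of the
#' library total (full precision; see [format_count_pct()] for display).
#'
#' @param tag_table data.table from [merge_tag_sets()] (`sequence` plus one
#'   count column per library).
#' @param categories Factor from [assign_category()] aligned with
#'   `tag_table$sequence`.
#' @return List of two matrices `counts` and `percent` (rows: Total +
#'   categories; columns: libraries).
#' @export
build_category_table <- function(tag_table, categories) {
  libs <- setdiff(names(tag_table), "sequence")
  stopifnot(length(categories) == nrow(tag_table))
  counts <- vapply(libs, function(l) {
    tapply(tag_table[[l]], categories, sum, default = 0)
  }, numeric(length(CATEGORY_LEVELS)))
  counts <- rbind(Total = colSums(counts), counts)
  tot <- counts["Total", ]
  percent <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/") * 100
  stopifnot(all(abs(colSums(counts[-1, , drop = FALSE]) -
                      counts["Total", ]) < 1e-9))
  list(counts = counts, percent = percent)
}

#' Format a count with its percentage as printed in classification tables
#'
#' Renders `98508` of `25331960` as `"98,508(0.39%)"`: thousands separators,
#' percentage rounded to two decimals with trailing zeros (and a trailing
#' dot) dropped.
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @export
format_count_pct <- function(count, total) {
  pct <- round(count / total * 100, 2)
  pct_str <- sub("0+$", "", sprintf("%.2f", pct))
  pct_str <- sub("\\.$", "", pct_str)
  paste0(formatC(count, format = "d", big.mark = ","), "(", pct_str, "%)")
}

#' Match tags against a known-miRNA catalog
#'
#' A tag matches a catalog entry of identical length within a Hamming
#' distance of `max_mismatches` (default 3, the conserved-miRNA rule); the
#' entry with the fewest mismatches wins and ties break lexicographically by
#' catalog id. Tags without a match are the novel-candidate pool.
#'
#' @param tags Character vector of tag sequences.
#' @param catalog Named character vector (or FASTA path) of mature miRNA
#'   sequences; U is read as T.
#' @param max_mismatches Maximum Hamming distance, default 3.
#' @return data.table: `tag_sequence`, `catalog_id`, `mismatches`, one row
#'   per matched tag.
#' @export
match_known <- function(tags, catalog, max_mismatches = 3L) {
  if (is.character(catalog) && length(catalog) == 1 && file.exists(catalog)) {
    cs <- Biostrings::readDNAStringSet(catalog)
    catalog <- setNames(as.character(cs), sub("\\s.*$", "", names(cs)))
  }
  if (!length(catalog)) stop("catalog must be non-empty")
  catalog <- toupper(chartr("U", "T", catalog))
  ord <- order(names(catalog))
  catalog <- catalog[ord] # lexicographic id order makes ties deterministic
  tags <- toupper(chartr("U", "T", tags))
  out <- list()
  cat_len <- nchar(catalog)
  tag_len <- nchar(tags)
  for (w in intersect(unique(tag_len), unique(cat_len))) {
    tg <- unique(tags[tag_len == w])
    cg <- catalog[cat_len == w]
    tm <- do.call(rbind, strsplit(tg, ""))
    best_mm <- rep(Inf, length(tg))
    best_id <- rep(NA_character_, length(tg))
    for (j in seq_along(cg)) {
      cv <- strsplit(cg[[j]], "")[[1]]
      mm <- rowSums(tm != matrix(cv, nrow(tm), w, byrow = TRUE))
      better <- mm < best_mm
      best_mm[better] <- mm[better]
      best_id[better] <- names(cg)[j]
    }
    ok <- best_mm <= max_mismatches
    if (any(ok)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        tag_sequence = tg[ok], catalog_id = best_id[ok],
        mismatches = as.integer(best_mm[ok]))
    }
  }
  if (!length(out)) {
    return(data.table::data.table(tag_sequence = character(0),
                                  catalog_id = character(0),
                                  mismatches = integer(0)))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, tag_sequence)
  res
}

#' Import a GFF3/BED annotation as a typed GRanges
#'
#' Thin wrapper over rtracklayer that keeps the `type` column (from the GFF3
#' type field or a BED `name` column) and converts nothing else; ranges stay
#' 1-based inclusive inside `GRanges`, while tag hits are converted on
#' comparison.
#'
#' @param path GFF3 (or BED) file path.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if (is.null(gr$type) && !is.null(gr$name)) gr$type <- gr$name
  gr
}
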