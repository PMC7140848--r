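#' Read-cleaning parameters
#'
#' Bundles the adapter-trimming and filtering settings used by
#' [clean_reads()]. Defaults keep inserts of 15-30 nt, require a 3' adapter
#' match of at least `min_adapter_overlap` bases at up to
#' `adapter_error_rate` mismatches, and classify an insert as a poly-A
#' artifact when at least `polya_min_fraction` of its bases are A.
#'
#' @param adapter 3' adapter sequence (ACGT).
#' @param min_len,max_len Inclusive insert length bounds, nt.
#' @param min_adapter_overlap Minimum adapter suffix-prefix overlap, nt.
#' @param adapter_error_rate Allowed mismatch fraction within the overlap,
#'   in `[0, 0.5)`.
#' @param polya_min_fraction Fraction of A defining a poly-A artifact.
#' @param require_adapter Discard reads without a detectable adapter
#'   (default). When `FALSE`, such reads are kept untrimmed, which makes
#'   cleaning idempotent on already-clean inserts.
#' @param five_prime_adapter Optional 5' adapter; when supplied, reads whose
#'   first 8 nt match its prefix are discarded as 5'-primer contaminants.
#' @param min_mean_quality Optional mean Phred floor; `NULL` (default)
#'   disables quality filtering.
#' @export
clean_params <- function(adapter, min_len = 15L, max_len = 30L,
                         min_adapter_overlap = 6L, adapter_error_rate = 0.1,
                         polya_min_fraction = 0.9, require_adapter = TRUE,
                         five_prime_adapter = NULL, min_mean_quality = NULL) {
  adapter <- toupper(adapter)
  if (!grepl("^[ACGT]+$", adapter)) stop("adapter must be an ACGT string")
  if (min_len <= 0 || min_len > max_len) stop("need 0 < min_len <= max_len")
  if (adapter_error_rate < 0 || adapter_error_rate >= 0.5) {
    stop("adapter_error_rate must be in [0, 0.5)")
  }
  structure(list(adapter = adapter, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 adapter_error_rate = adapter_error_rate,
                 polya_min_fraction = polya_min_fraction,
                 require_adapter = isTRUE(require_adapter),
                 five_prime_adapter = five_prime_adapter,
                 min_mean_quality = min_mean_quality),
            class = "clean_params")
}

.hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

#' Trim the 3' adapter from one read
#'
#' Semi-global suffix-prefix search: every read position is considered as the
#' adapter start, comparing the overlapping bases (full adapter inside the
#' read, or a read-suffix against an adapter-prefix of at least
#' `min_adapter_overlap` nt) and allowing mismatches at
#' `adapter_error_rate` per overlap base. Among acceptable starts the one
#' with the fewest mismatches wins, ties going to the leftmost (shortest
#' insert). Returns the insert prefix, which is empty when the read starts
#' with the adapter (a no-insert artifact), or `NA_character_` when no
#' acceptable match exists.
#'
#' @param read Read sequence (ACGTN; U is accepted and read as T).
#' @param params [clean_params()].
#' @export
trim_adapter <- function(read, params) {
  read <- chartr("U", "T", toupper(read))
  if (!nzchar(read)) stop("read must be non-empty")
  if (!grepl("^[ACGTN]+$", read)) {
    stop("invalid read characters in: ", read)
  }
  n <- nchar(read)
  ad <- params$adapter
  alen <- nchar(ad)
  best_s <- NA_integer_
  best_mm <- Inf
  for (s in 0:(n - params$min_adapter_overlap)) {
    if (s < 0) break
    L <- min(n - s, alen)
    mm <- .hamming(substr(read, s + 1, s + L), substr(ad, 1, L))
    if (mm <= floor(params$adapter_error_rate * L) && mm < best_mm) {
      best_mm <- mm
      best_s <- s
      if (mm == 0) break # leftmost perfect match cannot be beaten
    }
  }
  if (is.na(best_s)) return(NA_character_)
  substr(read, 1, best_s)
}

# vectorized trimming: exact full-adapter search, then exact suffix-prefix
# overlaps, then the per-read mismatch-tolerant scan for the remainder
.trim_adapter_vec <- function(reads, params) {
  n <- length(reads)
  out <- rep(NA_character_, n)
  ad <- params$adapter
  pos <- regexpr(ad, reads, fixed = TRUE)
  hit <- pos > 0
  out[hit] <- substr(reads[hit], 1, pos[hit] - 1)
  todo <- which(!hit)
  if (length(todo)) {
    alen <- nchar(ad)
    rl <- nchar(reads[todo])
    Ls <- if (alen - 1 >= params$min_adapter_overlap) {
      seq(alen - 1, params$min_adapter_overlap)
    } else integer(0)
    for (L in Ls) {
      cand <- todo[rl >= L & is.na(out[todo])]
      if (!length(cand)) next
      sfx <- substr(reads[cand], nchar(reads[cand]) - L + 1, nchar(reads[cand]))
      ok <- sfx == substr(ad, 1, L)
      out[cand[ok]] <- substr(reads[cand[ok]], 1,
                              nchar(reads[cand[ok]]) - L)
    }
    # mismatch-tolerant fallback only for still-unmatched reads
    if (params$adapter_error_rate > 0) {
      left <- which(is.na(out))
      for (k in left) out[k] <- trim_adapter(reads[k], params)
    }
  }
  out
}

.read_fastq <- function(path) {
  nl <- length(readLines(path, warn = FALSE))
  if (nl %% 4L != 0L) {
    stop("truncated FASTQ record at record ", nl %/% 4L + 1L, " in ", path)
  }
  if (nl == 0L) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Clean a small RNA library and collapse it to unique tags
#'
#' Applies the discard rules in a fixed order -- no 3' adapter, empty insert,
#' poly-A artifact, 5'-primer contaminant (only when a 5' adapter is
#' configured), insert length bounds -- then collapses the surviving inserts
#' into unique tags with counts. The stats ledger always balances:
#' `total_raw = total_clean + sum(discarded)`.
#'
#' @param fastq Path to a FASTQ file, or a character vector of read
#'   sequences.
#' @param params [clean_params()].
#' @param library_id Library label used for the count column.
#' @return List with `tags` (data.table: `sequence`, `count`), `stats`
#'   (list: `total_raw`, `discarded` named vector, `total_clean`,
#'   `library_id`).
#' @export
clean_reads <- function(fastq, params, library_id = "lib1") {
  reads <- if (length(fastq) == 1 && !grepl("[^ACGTUNacgtun]", fastq) &&
               nchar(fastq) <= 500 && !file.exists(fastq)) {
    fastq
  } else if (length(fastq) == 1 && file.exists(fastq)) {
    .read_fastq(fastq)
  } else {
    as.character(fastq)
  }
  reads <- chartr("U", "T", toupper(reads))
  discarded <- c(no_adapter = 0L, no_insert = 0L, polya = 0L,
                 contaminant_5p = 0L, too_short = 0L, too_long = 0L,
                 low_quality = 0L)
  total_raw <- length(reads)
  inserts <- if (total_raw) .trim_adapter_vec(reads, params) else character(0)
  if (params$require_adapter) {
    drop <- is.na(inserts)
    discarded["no_adapter"] <- sum(drop)
    inserts <- inserts[!drop]
  } else {
    inserts[is.na(inserts)] <- reads[is.na(inserts)]
  }
  empty <- !nzchar(inserts)
  discarded["no_insert"] <- sum(empty)
  inserts <- inserts[!empty]
  if (length(inserts)) {
    a_frac <- nchar(gsub("[^A]", "", inserts)) / nchar(inserts)
    polya <- a_frac >= params$polya_min_fraction
    discarded["polya"] <- sum(polya)
    inserts <- inserts[!polya]
  }
  if (!is.null(params$five_prime_adapter) && length(inserts)) {
    p5 <- substr(toupper(params$five_prime_adapter), 1, 8)
    contam <- substr(inserts, 1, 8) == p5 & nchar(inserts) >= 8
    discarded["contaminant_5p"] <- sum(contam)
    inserts <- inserts[!contam]
  }
  len <- nchar(inserts)
  discarded["too_short"] <- sum(len < params$min_len)
  discarded["too_long"] <- sum(len > params$max_len)
  inserts <- inserts[len >= params$min_len & len <= params$max_len]
  tags <- data.table::data.table(sequence = inserts)[
    , list(count = .N), by = "sequence"]
  data.table::setorder(tags, sequence)
  stats <- list(total_raw = total_raw, discarded = discarded,
                total_clean = length(inserts), library_id = library_id)
  stopifnot(stats$total_raw == stats$total_clean + sum(stats$discarded))
  list(tags = tags, stats = stats)
}

#' Merge per-library tag sets into a tag-by-library count table
#'
#' @param tag_sets Named list of `clean_reads()$tags` tables (names are
#'   library ids).
#' @return data.table with `sequence` and one integer count column per
#'   library (absent tags are 0).
#' @export
merge_tag_sets <- function(tag_sets) {
  stopifnot(length(names(tag_sets)) == length(tag_sets))
  long <- data.table::rbindlist(lapply(names(tag_sets), function(id) {
    dt <- data.table::copy(tag_sets[[id]])
    dt[, "library_id" := id]
  }))
  wide <- data.table::dcast(long, sequence ~ library_id,
                            value.var = "count", fill = 0L)
  data.table::setorder(wide, sequence)
  wide
}

#' Tag length distribution of a cleaned library
#'
#' @param tags A `clean_reads()$tags` table (columns `sequence`, `count`).
#' @return data.frame with `length`, `read_fraction` (count-weighted) and
#'   `unique_fraction` (per distinct tag); both columns sum to 1. Empty
#'   input yields an empty table.
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(0), read_fraction = numeric(0),
                      unique_fraction = numeric(0)))
  }
  len <- nchar(tags$sequence)
  reads <- tapply(tags$count, len, sum)
  uniq <- table(len)
  lv <- sort(unique(len))
  data.frame(length = lv,
             read_fraction = as.numeric(reads[as.character(lv)]) /
               sum(tags$count),
             unique_fraction = as.numeric(uniq[as.character(lv)]) /
               nrow(tags))
}
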