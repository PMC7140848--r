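# Brute-force sliding-window aligner used as the oracle for align_tags()
brute_align <- function(tag, genome, max_mm = 0L) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    n <- nchar(g)
    w <- nchar(tag)
    if (w > n) next
    for (sd in c("+", "-")) {
      pat <- if (sd == "+") tag else rc(tag)
      pv <- strsplit(pat, "")[[1]]
      for (s in 0:(n - w)) {
        mm <- sum(strsplit(substr(g, s + 1, s + w), "")[[1]] != pv)
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(
            tag_sequence = tag, chrom = chrom, start = s, end = s + w,
            strand = sd, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag_sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hit_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$tag_sequence, df$chrom, df$start, df$end, df$strand,
             df$mismatches))
}
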