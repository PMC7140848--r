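#' Configuration for a synthetic small RNA heat-stress study
#'
#' Describes a fully self-contained two-genotype (heat-tolerant HT,
#' heat-sensitive HS) x three-timepoint (0/6/12 h) small RNA sequencing
#' study at desk scale: a single-chromosome genome hosting designed miRNA
#' precursors and ncRNA loci, six libraries with configurable depth,
#' negative-binomial tag counts, planted fold-changes with known direction
#' (including appear/disappear cases that exercise the TPM zero floor), and
#' artifact reads at fixed rates.
#'
#' @param seed Integer RNG seed; every derived dataset is a pure function of
#'   the config including this seed.
#' @param genome_length Chromosome length, bases.
#' @param n_known_mirnas,n_novel_precursors Planted locus counts. Known
#'   precursors have their matures in the catalog; novel precursors are
#'   intergenic and absent from it.
#' @param ncrna_fractions Named fractions of reads per contamination class
#'   (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `other_sncRNA`); must sum below 1.
#' @param depth Reads per library.
#' @param dispersion Negative-binomial dispersion of miRNA counts (variance
#'   = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param mirna_fraction Total read fraction carried by mature miRNA tags.
#' @param artifact_rates Named fractions for `polya`, `no_insert`,
#'   `oversized` artifact reads.
#' @param adapter 3' adapter appended to every insert.
#' @param read_length Instrument read length; reads are insert + adapter
#'   truncated to this many bases.
#' @param de_lfc Planted absolute log2 fold-change for ordinary DE miRNAs.
#' @return A `sim_config` list, including a `libraries` data.frame
#'   (lib_id, genotype, timepoint_h, depth) and a `de_plan` data.frame.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_known_mirnas = 24L,
                       n_novel_precursors = 12L,
                       ncrna_fractions = c(rRNA = 0.006, tRNA = 0.02,
                                           snRNA = 0.001, snoRNA = 3e-04,
                                           other_sncRNA = 3e-04),
                       depth = 1e5L,
                       dispersion = 0.01,
                       mirna_fraction = 0.18,
                       artifact_rates = c(polya = 0.02, no_insert = 0.02,
                                          oversized = 0.02),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50L,
                       de_lfc = 2) {
  stopifnot(all(ncrna_fractions >= 0), sum(ncrna_fractions) < 1,
            depth >= 0, genome_length > 0, de_lfc > 0,
            all(c("rRNA", "tRNA", "snRNA", "snoRNA", "other_sncRNA") %in%
                  names(ncrna_fractions)))
  libraries <- data.frame(
    lib_id = c("HT_0h", "HT_6h", "HT_12h", "HS_0h", "HS_6h", "HS_12h"),
    genotype = rep(c("HT", "HS"), each = 3),
    timepoint_h = rep(c(0L, 6L, 12L), 2),
    depth = as.integer(depth),
    stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_known_mirnas = as.integer(n_known_mirnas),
                 n_novel_precursors = as.integer(n_novel_precursors),
                 ncrna_fractions = ncrna_fractions,
                 libraries = libraries,
                 dispersion = dispersion,
                 mirna_fraction = mirna_fraction,
                 artifact_rates = artifact_rates,
                 adapter = toupper(adapter),
                 read_length = as.integer(read_length),
                 de_lfc = de_lfc),
            class = "sim_config")
}

.B <- c("A", "C", "G", "T")
.rand_dna <- function(n, gc = 0.5) {
  paste(sample(.B, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
.rc <- function(s) chartr("ACGT", "TGCA",
                          paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# insert length distribution of genuine small RNA fragments (modal 21 nt)
.FRAG_LEN <- c(`18` = 0.03, `19` = 0.04, `20` = 0.08, `21` = 0.32,
               `22` = 0.14, `23` = 0.13, `24` = 0.22, `25` = 0.02,
               `26` = 0.02)
.sample_frag_len <- function(n) {
  as.integer(sample(names(.FRAG_LEN), n, replace = TRUE, prob = .FRAG_LEN))
}

# Design one stem-loop precursor with an explicit answer key.
# Returns sequence pieces plus designed pairing (1-based precursor coords);
# designed mismatch positions are excluded from the pairing key and bulge
# insertions shift the star-side indices accordingly.
.design_hairpin <- function(mature_len = 21L, arm = c("5p", "3p"),
                            n_mismatch = 0L, bulge_size = 0L) {
  arm <- match.arg(arm)
  mature <- .rand_dna(mature_len, gc = 0.55)
  # loop drawn from {A, C} so it cannot pair internally: the designed stem
  # stays the unique low-energy topology and the answer key is exact. The
  # strong A bias mirrors the AU-rich loops of real plant precursors and
  # keeps precursor GC% (the MFEI denominator) in the hairpin-typical range.
  loop <- paste(sample(c("A", "C"), sample(8:12, 1), replace = TRUE,
                       prob = c(0.85, 0.15)), collapse = "")
  mat_v <- strsplit(mature, "")[[1]]
  star_v <- strsplit(.rc(mature), "")[[1]] # star_v[sp] pairs mat_v[len-sp+1]
  # designed mismatches: substitute star bases so they neither complement
  # nor wobble-pair the mature base opposite them; kept in the outer half of
  # the arm, away from any designed bulge, so the two defects cannot merge
  # into one larger loop under folding
  mm_pos <- integer(0)
  half <- mature_len %/% 2L
  if (n_mismatch > 0) {
    mm_pos <- sample(seq(3, half - 1L), n_mismatch)
    for (p in mm_pos) {
      sp <- mature_len - p + 1L
      comp <- chartr("ACGT", "TGCA", mat_v[p])
      wob <- switch(mat_v[p], G = "T", T = "G", "")
      star_v[sp] <- sample(setdiff(.B, c(comp, wob)), 1)
    }
  }
  # designed bulge: extra non-pairing (A/C) bases inserted into the star arm
  # within the loop-side half; track how pre-insertion indices shift
  shift <- rep(0L, mature_len)
  if (bulge_size > 0) {
    at <- sample(seq(4, half - 2L), 1)
    # pick a bulge base that cannot pair with the mature bases facing the
    # insertion point, so the fold cannot absorb it into a shifted register
    opp <- mature_len - at
    win <- mat_v[max(1, opp - 2):min(mature_len, opp + 2)]
    b <- if (!"T" %in% win) "A" else if (!"G" %in% win) "C" else "A"
    shift[seq_len(mature_len) > at] <- as.integer(bulge_size)
    star_v <- append(star_v, rep(b, bulge_size), after = at)
  }
  star <- paste(star_v, collapse = "")
  # flanks from {A, C} as well: they can neither pair with each other nor
  # extend the designed helix outward, so the stem ends exactly where designed
  f5 <- paste(sample(c("A", "C"), sample(5:8, 1), replace = TRUE,
                     prob = c(0.85, 0.15)), collapse = "")
  f3 <- paste(sample(c("A", "C"), sample(5:8, 1), replace = TRUE,
                     prob = c(0.85, 0.15)), collapse = "")
  ks <- setdiff(seq_len(mature_len), mm_pos)
  sp <- mature_len - ks + 1L # pre-insertion star index paired with mature ks
  if (arm == "5p") {
    precursor <- paste0(f5, mature, loop, star, f3)
    mature_off <- nchar(f5)
    star_off <- nchar(f5) + mature_len + nchar(loop)
    pairs <- cbind(mature_off + ks, star_off + sp + shift[sp])
  } else {
    precursor <- paste0(f5, star, loop, mature, f3)
    star_off <- nchar(f5)
    mature_off <- nchar(f5) + nchar(star) + nchar(loop)
    pairs <- cbind(star_off + sp + shift[sp], mature_off + ks)
  }
  stopifnot(all(pairs[, 1] < pairs[, 2]))
  list(precursor = precursor, mature = mature, star = star, arm = arm,
       mature_start = mature_off + 1L,
       mature_end = mature_off + mature_len,
       designed_pairs = pairs)
}

# split `slack` spare bases into n+1 non-negative gaps, deterministically
.random_gaps <- function(slack, n) {
  as.integer(rmultinom(1, slack, rep(1, n + 1L)))
}

#' Build the synthetic reference: genome, annotation, catalog, ground truth
#'
#' Plants designed known/novel miRNA precursors, ncRNA loci and gene models
#' into a random chromosome, with every locus recorded in a machine-readable
#' truth table, and derives the per-library expected mature-miRNA counts
#' from the differential-expression plan (ordinary effects of +/-`de_lfc`
#' log2 units at both heat timepoints of the affected genotype, plus
#' disappear/appear miRNAs whose treatment counts are exactly zero).
#'
#' @param config A [sim_config()].
#' @return List: `genome` (`DNAStringSet`), `annotation` (`GRanges` with a
#'   `type` column), `known_catalog` (named character), `truth` (list with
#'   `planted_loci`, `hairpins`, `planted_counts`, `planted_de`,
#'   `class_fractions`, `libraries`).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .make_reference_impl(config))
}

.make_reference_impl <- function(config) {
  nk <- config$n_known_mirnas
  nv <- config$n_novel_precursors
  hairpins <- list()
  loci <- list()
  add_locus <- function(name, class, seq) {
    loci[[length(loci) + 1L]] <<- list(name = name, class = class, seq = seq)
  }
  mk_name <- function(i) sprintf("bra-sim-miR%03d", i)
  nv_name <- function(i) sprintf("novel-sim-mir%02d", i)
  for (i in seq_len(nk)) {
    hp <- .design_hairpin(sample(21:24, 1),
                          arm = if (runif(1) < 0.7) "5p" else "3p",
                          n_mismatch = sample(0:2, 1, prob = c(.4, .4, .2)),
                          bulge_size = sample(0:2, 1, prob = c(.6, .25, .15)))
    hairpins[[mk_name(i)]] <- hp
    add_locus(mk_name(i), "known_precursor", hp$precursor)
  }
  for (i in seq_len(nv)) {
    hp <- .design_hairpin(sample(21:24, 1),
                          arm = if (runif(1) < 0.7) "5p" else "3p",
                          n_mismatch = sample(0:1, 1, prob = c(.6, .4)),
                          bulge_size = sample(0:1, 1, prob = c(.7, .3)))
    hairpins[[nv_name(i)]] <- hp
    add_locus(nv_name(i), "novel_precursor", hp$precursor)
  }
  for (i in 1:2) add_locus(sprintf("rRNA_%d", i), "rRNA", .rand_dna(500, .55))
  for (i in 1:3) add_locus(sprintf("tRNA_%d", i), "tRNA", .rand_dna(75, .55))
  for (i in 1:2) add_locus(sprintf("snRNA_%d", i), "snRNA", .rand_dna(120, .5))
  for (i in 1:2) add_locus(sprintf("snoRNA_%d", i), "snoRNA", .rand_dna(90, .5))
  for (i in 1:2) add_locus(sprintf("sncRNA_%d", i), "other_sncRNA",
                           .rand_dna(100, .5))
  for (g in 1:3) {
    add_locus(sprintf("gene%d_exon1", g), "exon", .rand_dna(300, .45))
    add_locus(sprintf("gene%d_intron1", g), "intron", .rand_dna(200, .4))
    add_locus(sprintf("gene%d_exon2", g), "exon", .rand_dna(300, .45))
  }
  total_span <- sum(vapply(loci, function(l) nchar(l$seq), integer(1)))
  if (total_span + 40L * length(loci) > config$genome_length) {
    stop("cannot place ", length(loci), " loci spanning ", total_span,
         " bases in genome_length ", config$genome_length,
         "; increase genome_length or reduce n_known_mirnas/",
         "n_novel_precursors")
  }
  gaps <- .random_gaps(config$genome_length - total_span, length(loci))
  gaps <- pmax(gaps, 20L) # keep loci separated so windows stay unambiguous
  pieces <- character(0)
  rows <- list()
  pos <- 0L
  for (k in seq_along(loci)) {
    gap <- .rand_dna(gaps[k], gc = 0.38)
    pieces <- c(pieces, gap, loci[[k]]$seq)
    start0 <- pos + gaps[k]              # 0-based start of locus
    end0 <- start0 + nchar(loci[[k]]$seq)
    rows[[k]] <- data.table::data.table(
      name = loci[[k]]$name, class = loci[[k]]$class, chrom = "chr1",
      start = start0, end = end0, strand = "+")
    pos <- end0
  }
  pieces <- c(pieces, .rand_dna(gaps[length(gaps)], gc = 0.38))
  genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                              "chr1"))
  planted_loci <- data.table::rbindlist(rows)

  # annotation: known precursors + matures, ncRNA classes, exons/introns;
  # novel precursors stay unannotated (they are the discovery target)
  ann_rows <- list()
  for (k in seq_len(nrow(planted_loci))) {
    cls <- planted_loci$class[k]
    nm <- planted_loci$name[k]
    s0 <- planted_loci$start[k]
    e0 <- planted_loci$end[k]
    typ <- switch(cls, known_precursor = "miRNA_precursor",
                  novel_precursor = NA_character_, cls)
    if (cls %in% c("exon", "intron")) typ <- cls
    if (!is.na(typ)) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        start1 = s0 + 1L, end1 = e0, type = typ, name = nm)
    }
    if (cls == "known_precursor") {
      hp <- hairpins[[nm]]
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        start1 = s0 + hp$mature_start, end1 = s0 + hp$mature_end,
        type = "miRNA", name = paste0(nm, "_mature"))
    }
  }
  ann_df <- do.call(rbind, ann_rows)
  annotation <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(ann_df$start1, ann_df$end1), strand = "+",
    type = ann_df$type, name = ann_df$name)

  known_catalog <- vapply(seq_len(nk), function(i) hairpins[[mk_name(i)]]$mature,
                          character(1))
  names(known_catalog) <- mk_name(seq_len(nk))

  truth <- .build_truth(config, planted_loci, hairpins, known_catalog)
  list(genome = genome, annotation = annotation,
       known_catalog = known_catalog, truth = truth)
}

# abundance ranks, DE plan and expected per-library counts
.build_truth <- function(config, planted_loci, hairpins, known_catalog) {
  kn <- names(known_catalog)
  nv <- setdiff(names(hairpins), kn)
  mirnas <- c(kn, nv)
  nm <- length(mirnas)
  # rank-skewed baseline abundances summing to mirna_fraction
  w <- 1 / (seq_len(nm) + 2)
  base_abund <- setNames(w / sum(w) * config$mirna_fraction, mirnas)

  # DE role templates (index within pool, genotype, direction, kind); roles
  # beyond the available pool are simply not planted
  kn_roles <- list(list(1, "HT", "up", "lfc"), list(2, "HT", "down", "lfc"),
                   list(3, "HT", "down", "lfc"), list(4, "HT", "down", "zero"),
                   list(5, "HS", "up", "lfc"), list(6, "HS", "down", "lfc"),
                   list(7, "HS", "down", "lfc"),
                   list(8, "HT", "up", "lfc"), list(8, "HS", "up", "lfc"),
                   list(9, "HT", "down", "lfc"), list(9, "HS", "down", "lfc"),
                   list(10, "HT", "down", "lfc"), list(10, "HS", "down", "lfc"))
  nv_roles <- list(list(1, "HT", "up", "lfc"), list(2, "HT", "down", "lfc"),
                   list(3, "HT", "down", "lfc"), list(4, "HT", "up", "zero"),
                   list(5, "HS", "up", "lfc"), list(6, "HS", "down", "lfc"),
                   list(7, "HS", "down", "lfc"),
                   list(8, "HT", "up", "lfc"), list(8, "HS", "up", "lfc"),
                   list(9, "HT", "down", "lfc"), list(9, "HS", "down", "lfc"))
  expand_roles <- function(roles, pool) {
    rows <- Filter(function(r) r[[1]] <= length(pool), roles)
    if (!length(rows)) return(NULL)
    data.frame(mirna = pool[vapply(rows, function(r) r[[1]], numeric(1))],
               genotype = vapply(rows, `[[`, character(1), 2),
               direction = vapply(rows, `[[`, character(1), 3),
               kind = vapply(rows, `[[`, character(1), 4),
               stringsAsFactors = FALSE)
  }
  de_plan <- rbind(expand_roles(kn_roles, kn), expand_roles(nv_roles, nv))
  if (is.null(de_plan)) {
    de_plan <- data.frame(mirna = character(0), genotype = character(0),
                          direction = character(0), kind = character(0),
                          stringsAsFactors = FALSE)
  }
  if (nrow(de_plan)) {
    memb <- tapply(de_plan$genotype, de_plan$mirna, function(g) {
      if (all(c("HT", "HS") %in% g)) "both"
      else if (g[1] == "HT") "HT-only" else "HS-only"
    })
    planted_de <- data.frame(
      mirna = names(memb), membership = as.character(memb),
      direction = de_plan$direction[match(names(memb), de_plan$mirna)],
      kind = de_plan$kind[match(names(memb), de_plan$mirna)],
      stringsAsFactors = FALSE)
  } else {
    planted_de <- data.frame(mirna = character(0), membership = character(0),
                             direction = character(0), kind = character(0),
                             stringsAsFactors = FALSE)
  }

  libs <- config$libraries
  mean_counts <- matrix(0, nm, nrow(libs),
                        dimnames = list(mirnas, libs$lib_id))
  for (li in seq_len(nrow(libs))) {
    g <- libs$genotype[li]; tp <- libs$timepoint_h[li]
    mult <- setNames(rep(1, nm), mirnas)
    for (r in seq_len(nrow(de_plan))) {
      m <- de_plan$mirna[r]; g0 <- de_plan$genotype[r]
      affected <- (g == g0 && tp > 0)
      if (de_plan$kind[r] == "zero") {
        if (de_plan$direction[r] == "up") {
          # heat-induced from nothing: present only in g0's stressed libraries
          mult[m] <- if (affected) 2^config$de_lfc else 0
        } else if (affected) {
          # silenced by heat in g0; baseline everywhere else
          mult[m] <- 0
        }
      } else if (affected) {
        mult[m] <- 2^(ifelse(de_plan$direction[r] == "up", 1, -1) *
                        config$de_lfc)
      }
    }
    mean_counts[, li] <- base_abund * libs$depth[li] * mult
  }

  class_fractions <- c(config$ncrna_fractions,
                       exon = 0.03, intron = 0.015, precursor = 0.004,
                       unmapped = 0.08, intergenic = NA_real_,
                       config$artifact_rates)
  class_fractions["intergenic"] <-
    1 - sum(class_fractions, na.rm = TRUE) - config$mirna_fraction
  list(planted_loci = planted_loci, hairpins = hairpins,
       planted_counts = mean_counts, planted_de = planted_de,
       de_plan = de_plan, base_abund = base_abund,
       class_fractions = class_fractions, libraries = libs,
       read_length = config$read_length, adapter = config$adapter)
}

# sample fragment reads from a set of loci (sequences given)
.frag_reads <- function(n, seqs) {
  if (n == 0 || !length(seqs)) return(character(0))
  idx <- sample(length(seqs), n, replace = TRUE)
  lens <- .sample_frag_len(n)
  vapply(seq_len(n), function(k) {
    s <- seqs[[idx[k]]]
    L <- min(lens[k], nchar(s))
    st <- sample(nchar(s) - L + 1L, 1)
    frag <- substr(s, st, st + L - 1L)
    if (runif(1) < 0.2) .rc(frag) else frag
  }, character(1))
}

#' Simulate one sequencing library as raw reads
#'
#' Draws mature-miRNA tag counts from a negative binomial around the planted
#' per-library means, adds ncRNA/exon/intron/precursor-loop fragments and
#' intergenic background at the configured class fractions, unmappable
#' random-sequence reads, and poly-A / no-insert / oversized artifacts, then
#' appends the 3' adapter and truncates to the read length. Read identifiers
#' are opaque (`<lib>_read<k>`) and the read order is shuffled.
#'
#' @param reference Output of [make_reference()].
#' @param lib_id One of the library ids in the config (e.g. `"HT_6h"`).
#' @param config The same [sim_config()] used for the reference.
#' @return Character vector of read sequences (named by read id).
#' @export
simulate_library <- function(reference, lib_id, config) {
  truth <- reference$truth
  libs <- truth$libraries
  if (!lib_id %in% libs$lib_id) stop("unknown library descriptor: ", lib_id)
  li <- match(lib_id, libs$lib_id)
  withr::with_seed(config$seed + 1000L + li, {
    depth <- libs$depth[li]
    mu <- truth$planted_counts[, lib_id]
    counts <- if (config$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else rpois(length(mu), mu)
    mature_seq <- vapply(truth$hairpins[rownames(truth$planted_counts)],
                         `[[`, character(1), "mature")
    mir_reads <- rep(mature_seq, counts)

    # class counts are drawn against the nominal non-miRNA budget so that
    # every class's expected count is depth x fraction in every library,
    # independent of how the planted DE effects move the miRNA total
    n_other <- as.integer(round(depth * (1 - config$mirna_fraction)))
    fr <- truth$class_fractions
    fr <- fr / (1 - config$mirna_fraction) # renormalize to the non-miRNA part
    classes <- names(fr)
    n_cls <- as.integer(rmultinom(1, n_other, fr))
    names(n_cls) <- classes
    loci <- truth$planted_loci
    gseq <- as.character(reference$genome[["chr1"]])
    locus_seqs <- function(cls) {
      sel <- loci[loci$class == cls]
      lapply(seq_len(nrow(sel)), function(k) {
        substr(gseq, sel$start[k] + 1L, sel$end[k])
      })
    }
    reads <- list(mir = mir_reads)
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA", "other_sncRNA")) {
      reads[[cls]] <- .frag_reads(n_cls[[cls]], locus_seqs(cls))
    }
    reads$exon <- .frag_reads(n_cls[["exon"]], locus_seqs("exon"))
    reads$intron <- .frag_reads(n_cls[["intron"]], locus_seqs("intron"))
    # precursor fragments: loop-side pieces of known precursors
    reads$precursor <- .frag_reads(n_cls[["precursor"]],
                                   locus_seqs("known_precursor"))
    # intergenic background: fragments from between-locus space
    inter <- .intergenic_intervals(loci, nchar(gseq))
    reads$intergenic <- .frag_reads(n_cls[["intergenic"]],
      lapply(seq_len(nrow(inter)), function(k) {
        substr(gseq, inter$start[k] + 1L, inter$end[k])
      }))
    # unmapped: random sequence absent from the genome
    reads$unmapped <- vapply(seq_len(n_cls[["unmapped"]]),
                             function(k) .rand_dna(.sample_frag_len(1), .5),
                             character(1))
    reads$polya <- rep(strrep("A", 22), n_cls[["polya"]])
    reads$no_insert <- rep("", n_cls[["no_insert"]])
    over <- .frag_reads(n_cls[["oversized"]],
      lapply(seq_len(nrow(inter)), function(k) {
        substr(gseq, inter$start[k] + 1L, inter$end[k])
      }))
    reads$oversized <- vapply(over, function(s) {
      # extend to 31-40 nt with random tail
      paste0(s, .rand_dna(sample(31:40, 1) - nchar(s) + 0L, .5))
    }, character(1), USE.NAMES = FALSE)

    inserts <- unlist(reads, use.names = FALSE)
    if (!length(inserts)) return(setNames(character(0), character(0)))
    full <- paste0(inserts, config$adapter)
    full <- substr(full, 1L, config$read_length)
    full <- full[sample(length(full))]
    names(full) <- sprintf("%s_read%06d", lib_id, seq_along(full))
    full
  })
}

.intergenic_intervals <- function(loci, glen, margin = 5L) {
  s <- sort(loci$start)
  e <- sort(loci$end)
  starts <- c(0L, e + margin)
  ends <- c(s - margin, glen)
  keep <- ends - starts >= 40L
  data.table::data.table(start = starts[keep], end = ends[keep])
}

#' Write reads as a FASTQ file with constant quality
#' @param reads Named character vector from [simulate_library()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (!length(reads)) { file.create(path); return(invisible(path)) }
  lines <- rbind(paste0("@", names(reads)), unname(reads), "+",
                 vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Simulate a qPCR Ct table consistent with the planted fold-changes
#'
#' For each selected miRNA, control (0 h) and treatment Ct values are
#' constructed so that the relative expression 2^-ddCt equals the planted
#' log2 fold-change plus Gaussian noise, with the U6 reference fixed across
#' samples.
#'
#' @param reference Output of [make_reference()].
#' @param mirnas miRNA names; defaults to up to 8 planted finite-effect DE
#'   miRNAs (half known, half novel).
#' @param genotype,timepoint_h The treatment library the assay mimics.
#' @param noise_sd Gaussian Ct noise, cycles (>= 0).
#' @param seed Integer seed.
#' @return data.frame: `sample`, `group` (control/treatment), `gene`
#'   (miRNA or `U6`), `ct`, plus the planted log2 fold-change per miRNA in
#'   attribute `planted_lfc`.
#' @export
simulate_qpcr <- function(reference, mirnas = NULL, genotype = "HT",
                          timepoint_h = 12L, noise_sd = 0.2, seed = 1L) {
  stopifnot(noise_sd >= 0)
  truth <- reference$truth
  if (is.null(mirnas)) {
    plan <- truth$de_plan
    cand <- plan$mirna[plan$genotype == genotype & plan$kind == "lfc"]
    kn <- intersect(names(reference$known_catalog), cand)
    nv <- setdiff(cand, kn)
    mirnas <- c(utils::head(kn, 4), utils::head(nv, 4))
  }
  ctrl_lib <- paste0(genotype, "_0h")
  trt_lib <- paste0(genotype, "_", timepoint_h, "h")
  mu0 <- truth$planted_counts[mirnas, ctrl_lib]
  mu1 <- truth$planted_counts[mirnas, trt_lib]
  if (any(mu0 == 0 | mu1 == 0)) {
    stop("qPCR simulation requires finite planted fold-changes")
  }
  lfc <- log2(mu1 / mu0)
  withr::with_seed(seed, {
    noise <- rnorm(length(mirnas), 0, noise_sd)
    ct_ref <- 20
    ct_ctrl <- 25
    ct_trt <- ct_ctrl - (lfc + noise)
    out <- rbind(
      data.frame(sample = ctrl_lib, group = "control", gene = mirnas,
                 ct = ct_ctrl, stringsAsFactors = FALSE),
      data.frame(sample = ctrl_lib, group = "control", gene = "U6",
                 ct = ct_ref, stringsAsFactors = FALSE),
      data.frame(sample = trt_lib, group = "treatment", gene = mirnas,
                 ct = ct_trt, stringsAsFactors = FALSE),
      data.frame(sample = trt_lib, group = "treatment", gene = "U6",
                 ct = ct_ref, stringsAsFactors = FALSE))
    attr(out, "planted_lfc") <- setNames(lfc, mirnas)
    out
  })
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper: reference plus all six libraries (and optionally all
#' files on disk: genome FASTA, annotation GFF3, catalog FASTA, FASTQ reads,
#' truth tables as TSV).
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, all artifacts are written
#'   there and paths are returned in the result.
#' @return List: `reference`, `libraries` (named list of read vectors), and
#'   with `outdir` a `paths` list.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  reference <- make_reference(config)
  libraries <- lapply(setNames(nm = config$libraries$lib_id),
                      function(id) simulate_library(reference, id, config))
  out <- list(reference = reference, libraries = libraries)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(outdir, "genome.fa"),
                  annotation = file.path(outdir, "annotation.gff3"),
                  catalog = file.path(outdir, "known_mirnas.fa"))
    Biostrings::writeXStringSet(reference$genome, paths$genome)
    rtracklayer::export(reference$annotation, paths$annotation,
                        format = "gff3")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(reference$known_catalog), paths$catalog)
    for (id in names(libraries)) {
      p <- file.path(outdir, paste0(id, ".fastq"))
      write_fastq(libraries[[id]], p)
      paths[[paste0("fastq_", id)]] <- p
    }
    tp <- file.path(outdir, "truth_loci.tsv")
    utils::write.table(reference$truth$planted_loci, tp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$truth_loci <- tp
    out$paths <- paths
  }
  out
}
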