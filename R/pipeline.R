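#' Assemble a pipeline configuration
#'
#' Collects every input and threshold of the end-to-end analysis. Reads may
#' be given as FASTQ paths or in-memory read vectors (one per library);
#' reference inputs may be file paths or the corresponding objects.
#'
#' @param reads Named list (library id -> FASTQ path or character vector of
#'   reads).
#' @param library_meta Data frame with `lib_id`, `genotype` (`HT`/`HS`),
#'   `timepoint_h` (0 is the control).
#' @param genome,annotation,catalog Reference genome (FASTA path /
#'   `DNAStringSet`), feature annotation (GFF3 path / `GRanges`), known
#'   mature-miRNA catalog (FASTA path / named character).
#' @param clean [clean_params()] for adapter trimming.
#' @param priority Category priority, see [assign_category()].
#' @param mfei_threshold,min_reads Novel-discovery gates
#'   (see [discover_novel()]).
#' @param alpha,lfc_threshold,min_tpm Differential-expression settings (see
#'   [run_de()]).
#' @param transcripts Optional transcriptome for target scanning.
#' @param target_cutoff,energy_ratio_min Target-scan thresholds.
#' @param term_map Optional term-to-gene table for enrichment.
#' @param qpcr Optional Ct table (path or data.frame, see [ddct()]).
#' @param qpcr_gene_seqs Optional named character mapping qPCR gene ids to
#'   mature sequences (used to line novel assays up with discovered tags).
#' @param qpcr_contrast Contrast name whose sequencing fold-changes are
#'   compared with qPCR (default `"HT_12h_vs_HT_0h"`).
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @param outdir Optional output directory for report tables.
#' @export
pipeline_config <- function(reads, library_meta, genome, annotation, catalog,
                            clean, priority = DEFAULT_CATEGORY_PRIORITY,
                            mfei_threshold = 0.85, min_reads = 5L,
                            alpha = 0.01, lfc_threshold = 1, min_tpm = 1,
                            transcripts = NULL, target_cutoff = 4,
                            energy_ratio_min = 0.7, term_map = NULL,
                            qpcr = NULL, qpcr_gene_seqs = NULL,
                            qpcr_contrast = "HT_12h_vs_HT_0h",
                            seed = 1L, outdir = NULL) {
  cfg <- list(reads = reads, library_meta = library_meta, genome = genome,
              annotation = annotation, catalog = catalog, clean = clean,
              priority = priority, mfei_threshold = mfei_threshold,
              min_reads = min_reads, alpha = alpha,
              lfc_threshold = lfc_threshold, min_tpm = min_tpm,
              transcripts = transcripts, target_cutoff = target_cutoff,
              energy_ratio_min = energy_ratio_min, term_map = term_map,
              qpcr = qpcr, qpcr_gene_seqs = qpcr_gene_seqs,
              qpcr_contrast = qpcr_contrast, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  .validate_pipeline_config(cfg)
  cfg
}

.validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$clean, "clean_params"),
            all(c("lib_id", "genotype", "timepoint_h") %in%
                  names(cfg$library_meta)))
  if (!setequal(names(cfg$reads), cfg$library_meta$lib_id)) {
    stop("validation: reads and library_meta must cover the same libraries")
  }
  for (field in c("genome", "annotation", "catalog")) {
    x <- cfg[[field]]
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      stop("validation: ", field, " path does not exist: ", x)
    }
  }
  for (id in names(cfg$reads)) {
    x <- cfg$reads[[id]]
    if (is.character(x) && length(x) == 1 && grepl("[./]", x) &&
        !file.exists(x)) {
      stop("validation: FASTQ for ", id, " does not exist: ", x)
    }
  }
  invisible(cfg)
}

#' Run the full small RNA analysis pipeline
#'
#' Stages, in order: read cleaning and tag collapsing; genome alignment and
#' category classification; known-miRNA matching; novel-miRNA discovery
#' (folding + Meyers gate); exact-test differential expression per genotype
#' with membership labels; optional target scanning, term enrichment and
#' qPCR concordance. Every stage's product is returned in the bundle, and
#' written as TSV when `outdir` is set (see [render_tables()]).
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_bundle` list: `clean_stats`, `tag_table`,
#'   `length_dist`, `categories`, `category_table`, `known_counts`,
#'   `novel_calls`, `counts`, `totals`, `de`, `membership`, `targets`,
#'   `enrichment`, `qpcr`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  .validate_pipeline_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  meta <- cfg$library_meta
  genome <- stage("inputs", .as_genome(cfg$genome))
  annotation <- stage("inputs", {
    if (is.character(cfg$annotation)) read_annotation(cfg$annotation)
    else cfg$annotation
  })
  catalog <- stage("inputs", {
    if (is.character(cfg$catalog) && length(cfg$catalog) == 1 &&
        file.exists(cfg$catalog)) {
      cs <- Biostrings::readDNAStringSet(cfg$catalog)
      setNames(as.character(cs), sub("\\s.*$", "", names(cs)))
    } else cfg$catalog
  })

  cleaned <- stage("preprocess", lapply(setNames(nm = meta$lib_id),
    function(id) clean_reads(cfg$reads[[id]], cfg$clean, id)))
  clean_stats <- lapply(cleaned, `[[`, "stats")
  tag_table <- stage("preprocess",
                     merge_tag_sets(lapply(cleaned, `[[`, "tags")))
  length_dist <- lapply(cleaned, function(x) length_distribution(x$tags))

  hits <- stage("classify", align_tags(tag_table$sequence, genome, 0L))
  categories <- stage("classify",
                      assign_category(tag_table$sequence, hits, annotation,
                                      cfg$priority))
  category_table <- stage("classify",
                          build_category_table(tag_table, categories))

  # miRNA pools: ncRNA-class tags are tabulated above but excluded here
  ncrna_cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "Rfam_other")
  pool <- tag_table$sequence[!(as.character(categories) %in% ncrna_cats)]
  km <- stage("classify", if (length(catalog)) {
    match_known(pool, catalog)
  } else data.table::data.table(tag_sequence = character(0),
                                catalog_id = character(0),
                                mismatches = integer(0)))

  libs <- meta$lib_id
  tagmat <- as.matrix(tag_table[, libs, with = FALSE])
  rownames(tagmat) <- tag_table$sequence
  known_counts <- NULL
  if (nrow(km)) {
    kc <- rowsum(tagmat[km$tag_sequence, , drop = FALSE], km$catalog_id)
    known_counts <- kc
  }

  novel_pool <- tag_table[!(tag_table$sequence %in% km$tag_sequence) &
                            !(as.character(categories) %in% ncrna_cats)]
  novel_calls <- stage("discovery",
    discover_novel(novel_pool, genome, annotation, catalog,
                   min_reads = cfg$min_reads,
                   mfei_threshold = cfg$mfei_threshold))
  novel_pass <- novel_calls[novel_calls$pass, , drop = FALSE]

  counts <- rbind(known_counts,
                  if (nrow(novel_pass)) {
                    tagmat[novel_pass$tag_sequence, , drop = FALSE]
                  } else NULL)
  totals <- setNames(vapply(clean_stats, `[[`, numeric(1), "total_clean"),
                     names(clean_stats))

  de <- NULL; memb <- NULL
  if (!is.null(counts) && nrow(counts) > 0) {
    de <- stage("diffexpr", {
      per_gt <- lapply(c("HT", "HS"), function(g) {
        m <- meta[meta$genotype == g, ]
        base <- m$lib_id[m$timepoint_h == 0]
        trts <- m$lib_id[m$timepoint_h > 0]
        if (!length(base) || !length(trts)) return(NULL)
        contrasts <- data.frame(name = paste0(trts, "_vs_", base),
                                lib1 = base, lib2 = trts,
                                stringsAsFactors = FALSE)
        cbind(genotype = g,
              run_de(counts[, m$lib_id, drop = FALSE], totals[m$lib_id],
                     contrasts, alpha = cfg$alpha,
                     lfc_threshold = cfg$lfc_threshold,
                     min_tpm = cfg$min_tpm))
      })
      do.call(rbind, per_gt)
    })
    memb <- stage("diffexpr",
                  membership(de[de$genotype == "HT", ],
                             de[de$genotype == "HS", ]))
  }

  targets <- NULL
  if (!is.null(cfg$transcripts) && !is.null(de)) {
    sig <- unique(de$mirna_id[de$direction != "ns"])
    targets <- stage("targets", {
      res <- lapply(sig, function(id) {
        seqd <- if (id %in% rownames(tagmat)) id else catalog[[id]]
        if (is.null(seqd)) return(NULL)
        h <- scan_targets(seqd, cfg$transcripts, cutoff = cfg$target_cutoff,
                          energy_ratio_min = cfg$energy_ratio_min)
        cons <- consensus_targets(h$A, h$B)
        if (nrow(cons)) cbind(mirna_id = id, cons) else NULL
      })
      res <- res[!vapply(res, is.null, logical(1))]
      if (length(res)) do.call(rbind, res) else NULL
    })
  }

  enrichment <- NULL
  if (!is.null(cfg$term_map) && !is.null(targets) && nrow(targets)) {
    enrichment <- stage("enrichment", {
      universe <- unique(cfg$term_map$gene)
      study <- intersect(unique(targets$transcript_id), universe)
      if (length(study)) enrich_terms(study, universe, cfg$term_map)
      else NULL
    })
  }

  qpcr <- NULL
  if (!is.null(cfg$qpcr) && !is.null(de)) {
    qpcr <- stage("qpcr", {
      ct <- cfg$qpcr
      if (is.character(ct)) ct <- utils::read.table(ct, header = TRUE,
                                                    sep = "\t",
                                                    stringsAsFactors = FALSE)
      dd <- ddct(ct)
      seq_de <- de[de$contrast == cfg$qpcr_contrast, ]
      ids <- vapply(dd$gene, function(g) {
        if (g %in% seq_de$mirna_id) g
        else if (!is.null(cfg$qpcr_gene_seqs) &&
                 g %in% names(cfg$qpcr_gene_seqs)) {
          s <- cfg$qpcr_gene_seqs[[g]]
          if (s %in% seq_de$mirna_id) s else NA_character_
        } else NA_character_
      }, character(1))
      dd$seq_log2fc <- seq_de$log2fc[match(ids, seq_de$mirna_id)]
      ok <- !is.na(dd$seq_log2fc)
      concord <- if (sum(ok) >= 3) {
        corr_validation(dd$log2fc[ok], dd$seq_log2fc[ok])
      } else NULL
      list(table = dd, concordance = concord)
    })
  }

  manifest <- c(seed = cfg$seed, alpha = cfg$alpha,
                lfc_threshold = cfg$lfc_threshold, min_tpm = cfg$min_tpm,
                mfei_threshold = cfg$mfei_threshold,
                min_reads = cfg$min_reads, target_cutoff = cfg$target_cutoff,
                energy_ratio_min = cfg$energy_ratio_min,
                adapter = cfg$clean$adapter, min_len = cfg$clean$min_len,
                max_len = cfg$clean$max_len,
                n_libraries = nrow(meta),
                total_raw = sum(vapply(clean_stats, `[[`, numeric(1),
                                       "total_raw")),
                total_clean = sum(totals))

  bundle <- list(clean_stats = clean_stats, tag_table = tag_table,
                 length_dist = length_dist, categories = categories,
                 category_table = category_table,
                 known_counts = known_counts, novel_calls = novel_calls,
                 counts = counts, totals = totals, de = de,
                 membership = memb, targets = targets,
                 enrichment = enrichment, qpcr = qpcr, manifest = manifest)
  class(bundle) <- "pipeline_bundle"
  if (!is.null(cfg$outdir)) render_tables(bundle, cfg$outdir)
  bundle
}

#' Write the report tables of a pipeline run
#'
#' Emits the classification table with `count(percent%)` cells, per-library
#' cleaning stats and length distributions, the novel-miRNA call table, the
#' per-contrast differential-expression tables (log2 ratios to 2 decimals,
#' p-values to 3 significant digits), the membership summary, and optional
#' target/enrichment/qPCR tables, plus a `manifest.tsv` of every parameter
#' that influenced the run.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(x, name, ...) {
    p <- file.path(outdir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       ...)
    written <<- c(written, p)
  }
  ct <- bundle$category_table
  disp <- matrix("", nrow(ct$counts), ncol(ct$counts),
                 dimnames = dimnames(ct$counts))
  for (j in seq_len(ncol(ct$counts))) {
    disp[, j] <- format_count_pct(ct$counts[, j], ct$counts["Total", j])
  }
  wr(cbind(read_type = rownames(disp), as.data.frame(disp)),
     "category_table.tsv")

  stats_df <- do.call(rbind, lapply(bundle$clean_stats, function(s) {
    data.frame(library_id = s$library_id, total_raw = s$total_raw,
               total_clean = s$total_clean, t(s$discarded))
  }))
  wr(stats_df, "clean_stats.tsv")

  ld <- do.call(rbind, lapply(names(bundle$length_dist), function(id) {
    cbind(library_id = id, bundle$length_dist[[id]])
  }))
  wr(ld, "length_distribution.tsv")
  wr(bundle$novel_calls, "novel_calls.tsv")

  if (!is.null(bundle$de)) {
    de <- bundle$de
    de_disp <- data.frame(
      miRNA_Name = de$mirna_id, genotype = de$genotype,
      contrast = de$contrast, count_control = de$count1,
      count_treatment = de$count2,
      log2_Ratio = sprintf("%.2f", de$log2fc),
      p_Value = signif(de$p, 3), FDR = signif(de$fdr, 3),
      direction = as.character(de$direction), stringsAsFactors = FALSE)
    wr(de_disp, "de_results.tsv")
    wr(bundle$membership, "membership.tsv")
    msum <- as.data.frame(table(membership = bundle$membership$membership))
    wr(msum, "membership_summary.tsv")
  }
  if (!is.null(bundle$targets)) wr(bundle$targets, "targets.tsv")
  if (!is.null(bundle$enrichment)) wr(bundle$enrichment, "enrichment.tsv")
  if (!is.null(bundle$qpcr)) {
    wr(bundle$qpcr$table, "qpcr_comparison.tsv")
    if (!is.null(bundle$qpcr$concordance)) {
      wr(data.frame(r = bundle$qpcr$concordance$r,
                    r_squared = bundle$qpcr$concordance$r_squared),
         "qpcr_concordance.tsv")
    }
  }
  wr(data.frame(parameter = names(bundle$manifest),
                value = unname(unlist(bundle$manifest))), "manifest.tsv")
  invisible(written)
}

#' Build a pipeline configuration from a synthetic study
#'
#' Generates the full synthetic study in memory and wires it into a
#' [pipeline_config()], including the qPCR Ct table and the truth-derived
#' gene-to-sequence map the qPCR stage needs for novel assays.
#'
#' @param sim A [sim_config()].
#' @param outdir Optional report directory.
#' @param ... Overrides passed to [pipeline_config()].
#' @return List: `cfg` (pipeline_config), `study` (from
#'   [simulate_study()]).
#' @export
pipeline_from_simulation <- function(sim = sim_config(), outdir = NULL,
                                     ...) {
  study <- simulate_study(sim)
  ref <- study$reference
  qp <- simulate_qpcr(ref, noise_sd = 0.2, seed = sim$seed + 77L)
  gene_seqs <- vapply(ref$truth$hairpins, `[[`, character(1), "mature")
  cfg <- pipeline_config(
    reads = study$libraries,
    library_meta = sim$libraries,
    genome = ref$genome, annotation = ref$annotation,
    catalog = ref$known_catalog,
    clean = clean_params(sim$adapter),
    qpcr = qp, qpcr_gene_seqs = gene_seqs,
    seed = sim$seed, outdir = outdir, ...)
  list(cfg = cfg, study = study)
}
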