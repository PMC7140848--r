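#' @useDynLib mirheat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PAIR_CODES <- c("AU", "UA", "GC", "CG", "GU", "UG")

# Jacobson-Stockmayer-style logarithmic extension for long loops; the whole
# model is defined at 0.01 kcal/mol resolution, so extrapolated values are
# rounded to two decimals
.extrapolate_loop <- function(tab, max_len, rt = 0.616) {
  sizes <- as.integer(names(tab))
  out <- rep(NA_real_, max_len)
  out[sizes] <- tab
  top <- max(sizes)
  idx <- seq(top + 1L, max_len)
  out[idx] <- round(tab[as.character(top)] + 1.75 * rt * log(idx / top), 2)
  out
}

#' Load the RNA energy model
#'
#' Reads the package's plain-text nearest-neighbor parameter table (stacking
#' energies for the sixteen Watson-Crick stacks plus a uniform G:U value,
#' length-indexed hairpin/bulge/internal-loop penalties with logarithmic
#' extrapolation, and affine multiloop costs). The returned list can be edited
#' before being passed to [fold_mfe()], which is how reduced models (for
#' example a pure base-pair-maximization model) are constructed.
#'
#' @param file Path to a parameter table; defaults to the table shipped in
#'   `inst/extdata/rna_energy_params.tsv`.
#' @param max_len Longest sequence the tables must cover (loop vectors are
#'   extrapolated to this length).
#' @return A list with elements `stack` (6x6 matrix, kcal/mol, pair codes
#'   AU/UA/GC/CG/GU/UG), `hairpin`, `bulge`, `internal` (numeric vectors indexed
#'   by loop size), `ml_init`, `ml_branch`, `ml_unpaired`, `pair_bonus`,
#'   `min_hairpin`, `max_loop`.
#' @export
rna_energy_params <- function(file = system.file("extdata",
                                                 "rna_energy_params.tsv",
                                                 package = "mirheat"),
                              max_len = 400L) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  st <- tab[tab$section == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  kk <- strsplit(st$key, "/", fixed = TRUE)
  for (i in seq_len(nrow(st))) {
    stack[kk[[i]][1], kk[[i]][2]] <- as.numeric(st$value[i])
  }
  if (anyNA(stack)) stop("incomplete stack table in ", file)
  pick <- function(sec) {
    x <- tab[tab$section == sec, ]
    stats::setNames(as.numeric(x$value), x$key)
  }
  ml <- pick("multiloop")
  list(stack = stack,
       hairpin = .extrapolate_loop(pick("hairpin"), max_len),
       bulge = .extrapolate_loop(pick("bulge"), max_len),
       internal = .extrapolate_loop(pick("internal"), max_len),
       ml_init = unname(ml["init"]), ml_branch = unname(ml["branch"]),
       ml_unpaired = unname(ml["unpaired"]), pair_bonus = 0,
       min_hairpin = 3L, max_loop = 30L)
}

.default_energy_env <- new.env(parent = emptyenv())
.default_energy <- function() {
  if (is.null(.default_energy_env$params)) {
    .default_energy_env$params <- rna_energy_params()
  }
  .default_energy_env$params
}

.encode_rna <- function(seq) {
  s <- chartr("acgut", "ACGUT", seq)
  s <- chartr("T", "U", s)
  v <- strsplit(s, "")[[1]]
  code <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    stop("invalid RNA alphabet: ", paste(unique(v[is.na(code)]), collapse = ""))
  }
  code
}

#' Fold a sequence to its minimum-free-energy structure
#'
#' Globally optimal nested secondary structure under the package's simplified
#' nearest-neighbor model, computed by dynamic programming. Ties in energy are
#' broken toward the structure with the most base pairs, with a deterministic
#' traceback. Allowed pairs are Watson-Crick plus G:U wobble; hairpin loops
#' have at least `params$min_hairpin` unpaired bases.
#'
#' @param seq Character scalar, ACGU/T alphabet (T is read as U); length
#'   10-400 nt.
#' @param params Energy model from [rna_energy_params()]; edit the list to run
#'   reduced models.
#' @return A `hairpin_structure` list: `sequence`, `dot_bracket`, `pairs`
#'   (two-column matrix of 1-based i < j), `mfe` (kcal/mol, <= 0),
#'   `gc_fraction`, `mfei`, `length`.
#' @examples
#' fold_mfe(paste0("GGGCGCAGGUUCAAGC", "GAAA", "GCUUGAACCUGCGCCC"))
#' @export
fold_mfe <- function(seq, params = .default_energy()) {
  code <- .encode_rna(seq)
  n <- length(code)
  if (n < 10 || n > 400) stop("sequence length must be within 10-400 nt, got ", n)
  res <- .fold_mfe_cpp(code, params$stack, params$hairpin, params$bulge,
                       params$internal, params$ml_init, params$ml_branch,
                       params$ml_unpaired, params$pair_bonus,
                       as.integer(params$min_hairpin),
                       as.integer(params$max_loop))
  pairs <- res$pairs
  gc <- mean(code == 1L | code == 2L)
  structure(list(sequence = chartr("T", "U", toupper(seq)),
                 dot_bracket = render_dot_bracket(pairs, n),
                 pairs = pairs,
                 mfe = res$mfe,
                 gc_fraction = gc,
                 mfei = if (gc > 0) mfei(res$mfe, n, gc) else NA_real_,
                 length = n),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("length %d nt | %d pairs | MFE %.1f kcal/mol | GC %.1f%% | MFEI %s\n",
              x$length, nrow(x$pairs), x$mfe, 100 * x$gc_fraction,
              ifelse(is.na(x$mfei), "NA", sprintf("%.2f", x$mfei))))
  invisible(x)
}

#' Minimal free energy index
#'
#' MFEI = (|MFE| / length * 100) / (GC fraction * 100), the standard index used
#' to separate plant pre-miRNA hairpins from other transcripts; reported as a
#' positive dimensionless value.
#'
#' @param mfe Minimum free energy, kcal/mol (<= 0).
#' @param length Sequence length, nt.
#' @param gc_fraction GC content in (0, 1].
#' @export
mfei <- function(mfe, length, gc_fraction) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(gc_fraction <= 0 | gc_fraction > 1)) {
    stop("gc_fraction must be in (0, 1]")
  }
  (abs(mfe) / length * 100) / (gc_fraction * 100)
}

#' Render a pair set as a dot-bracket string
#' @param pairs Two-column matrix of 1-based (i, j), i < j, nested.
#' @param n Sequence length.
#' @export
render_dot_bracket <- function(pairs, n) {
  v <- rep(".", n)
  if (NROW(pairs) > 0) {
    v[pairs[, 1]] <- "("
    v[pairs[, 2]] <- ")"
  }
  paste(v, collapse = "")
}

#' Parse a dot-bracket string into a pair matrix
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @return Two-column integer matrix of 1-based (i, j) with i < j, ordered by i.
#' @export
parse_dot_bracket <- function(db) {
  v <- strsplit(db, "")[[1]]
  open <- integer(0)
  out <- matrix(integer(0), 0, 2)
  for (k in seq_along(v)) {
    if (v[k] == "(") open <- c(open, k)
    else if (v[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      out <- rbind(out, c(open[length(open)], k))
      open <- open[-length(open)]
    } else if (v[k] != ".") stop("invalid dot-bracket character: ", v[k])
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  out[order(out[, 1]), , drop = FALSE]
}

#' Topological features of a folded hairpin
#'
#' Counts hairpin loops (a pair with no pair nested inside it), measures the
#' longest uninterrupted stem (run of directly stacked pairs), and classifies
#' a subsequence interval relative to the (unique) hairpin loop as lying on
#' the 5p arm, the 3p arm, the loop, or outside the paired region.
#'
#' @param structure A `hairpin_structure` from [fold_mfe()].
#' @param interval Optional length-2 integer vector (1-based, inclusive) to
#'   classify as `5p`, `3p`, `loop`, or `outside`.
#' @return List with `n_hairpin_loops`, `longest_stem`, and (when `interval`
#'   is given) `arm`.
#' @export
hairpin_features <- function(structure, interval = NULL) {
  pairs <- structure$pairs
  np <- NROW(pairs)
  res <- list(n_hairpin_loops = 0L, longest_stem = 0L)
  if (np > 0) {
    # hairpin loops: pairs (i,j) with no other pair strictly inside
    inner <- vapply(seq_len(np), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      !any(pairs[, 1] > i & pairs[, 2] < j)
    }, logical(1))
    res$n_hairpin_loops <- sum(inner)
    # longest stem: maximal run of (i,j),(i+1,j-1),...
    key <- paste(pairs[, 1], pairs[, 2])
    run <- 1L
    best <- 1L
    ord <- order(pairs[, 1])
    pr <- pairs[ord, , drop = FALSE]
    keyset <- new.env(parent = emptyenv())
    for (k in seq_len(np)) assign(paste(pr[k, 1], pr[k, 2]), TRUE, keyset)
    for (k in seq_len(np)) {
      i <- pr[k, 1]; j <- pr[k, 2]
      if (!is.null(keyset[[paste(i - 1L, j + 1L)]])) next # not a stem start
      len <- 1L
      while (!is.null(keyset[[paste(i + len, j - len)]])) len <- len + 1L
      best <- max(best, len)
    }
    res$longest_stem <- best
  }
  if (!is.null(interval)) {
    res$arm <- .classify_arm(pairs, structure$length, interval)
  }
  res
}

.classify_arm <- function(pairs, n, interval) {
  np <- NROW(pairs)
  if (np == 0) return("outside")
  inner_idx <- which(vapply(seq_len(np), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    !any(pairs[, 1] > i & pairs[, 2] < j)
  }, logical(1)))
  if (length(inner_idx) != 1) {
    stop("arm classification requires exactly one hairpin loop, found ",
         length(inner_idx))
  }
  li <- pairs[inner_idx, 1]
  lj <- pairs[inner_idx, 2]
  a <- interval[1]; b <- interval[2]
  lo <- min(pairs[, 1]); hi <- max(pairs[, 2])
  if (b < lo || a > hi) return("outside")
  if (a > li && b < lj) return("loop")
  if (b <= li) return("5p")
  if (a >= lj) return("3p")
  "loop" # straddles the loop boundary
}
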