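# Independent oracles for secondary-structure folding. These deliberately do
# NOT share code with the package: structures are enumerated exhaustively and
# scored by a loop-decomposition evaluator written directly from the model
# definition, so they can certify the dynamic program.

.orc_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# all nested pair sets for sequence `v` (character vector) with >= minloop
# unpaired bases in every hairpin; returns list of 2-column matrices
enumerate_structures <- function(v, minloop = 3L) {
  n <- length(v)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i + 1L <= minloop) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(rec(i + 1L, j), identity) # i unpaired
    ks <- if (i + minloop + 1L <= j) seq(i + minloop + 1L, j) else integer(0)
    for (k in ks) {
      if (!.orc_pairable(v[i], v[k])) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (L in left) for (R in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# energy of a given structure by loop decomposition under `params`
structure_energy <- function(pairs, v, params) {
  np <- NROW(pairs)
  if (np == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  ptype <- function(k) paste0(v[pairs[k, 1]], v[pairs[k, 2]])
  # parent of each pair = smallest strictly enclosing pair
  parent <- integer(np)
  for (k in seq_len(np)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    enc <- which(pairs[, 1] < i & pairs[, 2] > j)
    parent[k] <- if (length(enc)) enc[which.min(pairs[enc, 2] - pairs[enc, 1])] else 0L
  }
  e <- np * params$pair_bonus
  for (k in seq_len(np)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ch <- which(parent == k)
    if (length(ch) == 0) {
      e <- e + params$hairpin[j - i - 1]
    } else if (length(ch) == 1) {
      p <- pairs[ch, 1]; q <- pairs[ch, 2]
      n1 <- p - i - 1L; n2 <- j - q - 1L
      if (n1 == 0 && n2 == 0) {
        e <- e + params$stack[ptype(k), ptype(ch)]
      } else if (n1 == 0 || n2 == 0) {
        e <- e + params$bulge[n1 + n2]
      } else {
        e <- e + params$internal[n1 + n2]
      }
    } else {
      unp <- (j - i - 1L) - sum(pairs[ch, 2] - pairs[ch, 1] + 1L)
      e <- e + params$ml_init + params$ml_branch * (1L + length(ch)) +
        params$ml_unpaired * unp
    }
  }
  e
}

# brute-force minimum energy over all structures
enumerated_mfe <- function(seq, params, minloop = 3L) {
  v <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  structs <- enumerate_structures(v, minloop)
  es <- vapply(structs, structure_energy, numeric(1), v = v, params = params)
  min(0, es)
}

# classic Nussinov base-pair maximization with a minimum loop size
nussinov_max_pairs <- function(seq, minloop = 3L) {
  v <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(v)
  if (n <= minloop) return(0L)
  M <- matrix(0L, n, n)
  for (span in seq(minloop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1, j]
      if (.orc_pairable(v[i], v[j])) {
        inner <- if (j - 1 >= i + 1) M[i + 1, j - 1] else 0L
        best <- max(best, 1L + inner)
      }
      for (k in seq(i + minloop + 1L, j)) {
        if (!.orc_pairable(v[i], v[k])) next
        inner <- if (k - 1 >= i + 1) M[i + 1, k - 1] else 0L
        rest <- if (k + 1 <= j) M[k + 1, j] else 0L
        best <- max(best, 1L + inner + rest)
      }
      M[i, j] <- best
    }
  }
  M[1, n]
}

# energy model reduced to pure pair counting (Nussinov equivalence)
nussinov_params <- function() {
  p <- mirheat::rna_energy_params()
  p$stack[] <- 0
  p$hairpin[] <- 0
  p$hairpin[seq_len(min(2, length(p$hairpin)))] <- Inf
  p$bulge[] <- 0
  p$internal[] <- 0
  p$ml_init <- 0
  p$ml_branch <- 0
  p$ml_unpaired <- 0
  p$pair_bonus <- -1
  p
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a designed clean stem-loop: arm + loop + reverse complement of arm
designed_hairpin <- function(arm, loop = "GAAA") {
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(arm, "")[[1]]), collapse = ""))
  paste0(arm, loop, rc)
}
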