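# Independent oracles used to freeze expected values. These deliberately use
# naive exhaustive algorithms, not the package's implementations.

# Brute-force microhomology: test every k on both junction sides with
# explicit per-base comparisons.
mh_brute <- function(reference, s, e) {
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  n <- length(chars)
  len <- e - s
  best <- 0L
  for (k in seq_len(len)) {
    # right: deleted prefix reference[s, s+k) vs retained reference[e, e+k)
    if (e + k <= n) {
      ok <- TRUE
      for (t in seq_len(k)) if (chars[s + t] != chars[e + t]) { ok <- FALSE; break }
      if (ok && k > best) best <- k
    }
    # left: deleted suffix reference[e-k, e) vs retained reference[s-k, s)
    if (s - k >= 0) {
      ok <- TRUE
      for (t in seq_len(k)) if (chars[e - k + t] != chars[s - k + t]) { ok <- FALSE; break }
      if (ok && k > best) best <- k
    }
  }
  best
}

# Exhaustive enumeration of all global alignments of two tiny strings as op
# sequences (M = consume both, D = consume ref only, I = consume read only),
# scored with affine gaps on the complete op string. Returns the optimal
# score and all optimal (read_aln, ref_aln) pairs.
enumerate_alignments <- function(read, ref, match = 2, mismatch = -1,
                                 gap_open = 10, gap_ext = 1) {
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  fc <- strsplit(ref, "", fixed = TRUE)[[1]]
  paths <- list()
  recurse <- function(i, j, ops) {
    if (i > length(rc) && j > length(fc)) {
      paths[[length(paths) + 1L]] <<- ops
      return(invisible())
    }
    if (i <= length(rc) && j <= length(fc)) recurse(i + 1L, j + 1L, c(ops, "M"))
    if (j <= length(fc)) recurse(i, j + 1L, c(ops, "D"))
    if (i <= length(rc)) recurse(i + 1L, j, c(ops, "I"))
  }
  recurse(1L, 1L, character(0))

  score_path <- function(ops) {
    s <- 0; i <- 1L; j <- 1L; k <- 1L
    while (k <= length(ops)) {
      if (ops[k] == "M") {
        s <- s + if (rc[i] == fc[j]) match else mismatch
        i <- i + 1L; j <- j + 1L; k <- k + 1L
      } else {
        gap_type <- ops[k]; len <- 0L
        while (k <= length(ops) && ops[k] == gap_type) {
          len <- len + 1L; k <- k + 1L
          if (gap_type == "D") j <- j + 1L else i <- i + 1L
        }
        s <- s - gap_open - len * gap_ext
      }
    }
    s
  }
  scores <- vapply(paths, score_path, 0)
  best <- max(scores)
  build <- function(ops) {
    i <- 1L; j <- 1L; ra <- character(0); fa <- character(0)
    for (op in ops) {
      if (op == "M") { ra <- c(ra, rc[i]); fa <- c(fa, fc[j]); i <- i + 1L; j <- j + 1L }
      else if (op == "D") { ra <- c(ra, "-"); fa <- c(fa, fc[j]); j <- j + 1L }
      else { ra <- c(ra, rc[i]); fa <- c(fa, "-"); i <- i + 1L }
    }
    c(read_aln = paste(ra, collapse = ""), ref_aln = paste(fa, collapse = ""))
  }
  list(best_score = best,
       optimal = lapply(paths[scores == best], build))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# All placements of a deletion of the same length that produce the same
# read sequence (alignment-equivalent placements).
equivalent_placements <- function(reference, s, e) {
  len <- e - s
  n <- nchar(reference)
  target <- paste0(substring(reference, 1, s), substring(reference, e + 1, n))
  out <- list()
  for (s2 in 0:(n - len)) {
    e2 <- s2 + len
    if (paste0(substring(reference, 1, s2),
               substring(reference, e2 + 1, n)) == target) {
      out[[length(out) + 1L]] <- c(s2, e2)
    }
  }
  out
}

# A small fixed editing design shared across classifier tests.
test_design <- function(seed = 42) simulate_amplicon(seed = seed, length = 150)

# Build a read from the reference with substitutions at given 0-based
# positions (deterministic transversion).
mutate_positions <- function(sequence, positions) {
  tv <- c(A = "C", C = "A", G = "T", T = "G")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[positions + 1L] <- tv[chars[positions + 1L]]
  paste(chars, collapse = "")
}

delete_interval <- function(sequence, s, e) {
  paste0(substring(sequence, 1, s), substring(sequence, e + 1, nchar(sequence)))
}

insert_at <- function(sequence, p, ins) {
  paste0(substring(sequence, 1, p), ins, substring(sequence, p + 1, nchar(sequence)))
}
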