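#' Alignment scoring parameters
#'
#' Affine-gap scoring used by [global_align()]. A gap of length L costs
#' `gap_open + L * gap_extend`. Defaults: match +2, mismatch -1, gap open 10,
#' gap extend 1 (penalties are positive numbers). `N` in a read never scores
#' as a match.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (typically negative).
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Per-base gap extension penalty (positive).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -1, gap_open = 10, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

# Substitution matrix over A/C/G/T/N: N scores as a mismatch against
# everything, including itself, so ambiguous calls never inflate identity.
.subst_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

.check_dna <- function(x, what, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters other than ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T", call. = FALSE)
  }
}

#' Global pairwise alignment of a read against a reference
#'
#' End-to-end (Needleman-Wunsch) alignment under affine-gap scoring,
#' computed by the package's compiled dynamic-programming kernel (generic
#' aligner front-ends are far too slow for amplicon-scale read sets).
#' Identity is defined as matched columns divided by total alignment columns
#' (gap columns count); `N` never counts as a match. Traceback ties are
#' broken deterministically: match/mismatch is preferred over a gap, and a
#' gap in the read over a gap in the reference; lesion placement is
#' additionally canonicalized by [extract_lesions()], which shifts indels to
#' their leftmost equivalent position.
#'
#' @param read Read sequence (A/C/G/T/N).
#' @param reference Reference sequence (A/C/G/T).
#' @param scoring An [align_scoring()].
#' @return A list of class `pairwise_aln` with `read_aln`, `ref_aln`
#'   (gapped strings of equal length), `score`, and `identity`.
#' @examples
#' global_align("AGT", "ACGT")$identity  # 0.75
#' @export
global_align <- function(read, reference, scoring = align_scoring()) {
  res <- global_align_many(read, reference, scoring)
  res[[1L]]
}

#' Global alignment of many reads against one reference
#'
#' Vectorized form of [global_align()]; one call to the alignment engine for
#' all reads, which is how whole FASTQ samples are processed.
#'
#' @inheritParams global_align
#' @param reads Character vector of read sequences.
#' @return A list of `pairwise_aln` objects, one per read.
#' @export
global_align_many <- function(reads, reference, scoring = align_scoring()) {
  reads <- toupper(reads)
  reference <- toupper(reference)
  if (length(reference) != 1L || !nzchar(reference)) {
    stop("reference must be a single non-empty string", call. = FALSE)
  }
  if (length(reads) == 0L) return(list())
  if (any(!nzchar(reads))) stop("empty read sequence", call. = FALSE)
  .check_dna(reads, "read", allow_n = TRUE)
  .check_dna(reference, "reference", allow_n = FALSE)

  res <- .nw_affine_cpp(reads, reference, .subst_matrix(scoring),
                        scoring$gap_open, scoring$gap_extend)
  lapply(res, function(x) structure(x, class = "pairwise_aln"))
}

#' @export
print.pairwise_aln <- function(x, ...) {
  cat("Global alignment (score ", format(x$score), ", identity ",
      sprintf("%.3f", x$identity), ")\n", sep = "")
  cat(" read: ", x$read_aln, "\n  ref: ", x$ref_aln, "\n", sep = "")
  invisible(x)
}

# Shift a deletion [s, e) (0-based, half-open, on `chars` = reference as a
# character vector) to its leftmost alignment-equivalent placement.
.left_shift_del <- function(chars, s, e) {
  while (s > 0L && chars[s] == chars[e]) {  # chars[s] is ref[s-1] 0-based
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

# Shift an insertion at between-base coordinate p with inserted sequence ins
# to its leftmost equivalent placement (rotating the inserted string).
.left_shift_ins <- function(chars, p, ins) {
  iv <- strsplit(ins, "", fixed = TRUE)[[1]]
  k <- length(iv)
  while (p > 0L && chars[p] == iv[k]) {
    iv <- c(iv[k], iv[-k])
    p <- p - 1L
  }
  list(p = p, ins = paste(iv, collapse = ""))
}

#' Extract normalized lesions from an alignment
#'
#' Walks the alignment columns and reports every difference from the
#' reference as a lesion: each run of gaps becomes one deletion or insertion,
#' each mismatching column one substitution. Indels are canonicalized to
#' their leftmost alignment-equivalent placement (so a deletion inside a
#' repeat is always reported at the leftmost copy), after which touching
#' same-type deletions are merged. Deletions carry the junction microhomology
#' length computed by [microhomology_length()].
#'
#' @param aln A `pairwise_aln` from [global_align()].
#' @return A data frame with columns `kind` (`"deletion"`, `"insertion"`,
#'   `"substitution"`), `ref_start`, `ref_end` (0-based half-open; equal for
#'   insertions), `inserted_seq`, `read_base`, `mh_length` (deletions only,
#'   else 0). Zero rows for a perfect match.
#' @export
extract_lesions <- function(aln) {
  stopifnot(inherits(aln, "pairwise_aln"))
  rc <- strsplit(aln$read_aln, "", fixed = TRUE)[[1]]
  fc <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  reference <- paste(fc[fc != "-"], collapse = "")
  ref_chars <- fc[fc != "-"]

  kind <- character(0); rs <- integer(0); re <- integer(0)
  ins_seq <- character(0); read_base <- character(0)

  refpos <- 0L  # 0-based coordinate of the next reference base
  i <- 1L
  n <- length(rc)
  while (i <= n) {
    if (rc[i] == "-") {             # deletion run
      j <- i
      while (j <= n && rc[j] == "-") j <- j + 1L
      len <- j - i
      kind <- c(kind, "deletion"); rs <- c(rs, refpos); re <- c(re, refpos + len)
      ins_seq <- c(ins_seq, ""); read_base <- c(read_base, "")
      refpos <- refpos + len
      i <- j
    } else if (fc[i] == "-") {      # insertion run
      j <- i
      while (j <= n && fc[j] == "-") j <- j + 1L
      kind <- c(kind, "insertion"); rs <- c(rs, refpos); re <- c(re, refpos)
      ins_seq <- c(ins_seq, paste(rc[i:(j - 1L)], collapse = ""))
      read_base <- c(read_base, "")
      i <- j
    } else {
      if (rc[i] != fc[i]) {
        kind <- c(kind, "substitution"); rs <- c(rs, refpos); re <- c(re, refpos + 1L)
        ins_seq <- c(ins_seq, ""); read_base <- c(read_base, rc[i])
      }
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }

  les <- data.frame(kind = kind, ref_start = rs, ref_end = re,
                    inserted_seq = ins_seq, read_base = read_base,
                    stringsAsFactors = FALSE)
  if (nrow(les) == 0L) {
    les$mh_length <- integer(0)
    return(les)
  }

  # canonicalize indel placement
  for (k in seq_len(nrow(les))) {
    if (les$kind[k] == "deletion") {
      se <- .left_shift_del(ref_chars, les$ref_start[k], les$ref_end[k])
      les$ref_start[k] <- se[1]; les$ref_end[k] <- se[2]
    } else if (les$kind[k] == "insertion") {
      sh <- .left_shift_ins(ref_chars, les$ref_start[k], les$inserted_seq[k])
      les$ref_start[k] <- sh$p; les$ref_end[k] <- sh$p
      les$inserted_seq[k] <- sh$ins
    }
  }
  les <- les[order(les$ref_start, les$ref_end, les$kind), , drop = FALSE]

  # merge deletions that became adjacent after the shift
  if (nrow(les) > 1L) {
    keep <- rep(TRUE, nrow(les))
    for (k in 2:nrow(les)) {
      if (les$kind[k] == "deletion" && les$kind[k - 1L] == "deletion" &&
          keep[k - 1L] && les$ref_start[k] == les$ref_end[k - 1L]) {
        les$ref_start[k] <- les$ref_start[k - 1L]
        keep[k - 1L] <- FALSE
      }
    }
    les <- les[keep, , drop = FALSE]
  }

  les$mh_length <- 0L
  dels <- which(les$kind == "deletion")
  for (k in dels) {
    les$mh_length[k] <- microhomology_length(reference, les$ref_start[k], les$ref_end[k])
  }
  rownames(les) <- NULL
  les
}

#' Deletion-junction microhomology length
#'
#' For a deletion of `reference[del_start, del_end)` (0-based half-open),
#' returns the length of exact sequence identity between one end of the
#' deleted segment and the retained sequence at the other junction: the
#' maximum of the longest `k` with
#' `reference[del_start, del_start + k) == reference[del_end, del_end + k)`
#' and the longest `k` with
#' `reference[del_end - k, del_end) == reference[del_start - k, del_start)`,
#' with `k` capped at the deletion length and comparisons never reading
#' outside the reference. Deletions with microhomology of 2 bp or more are
#' the signature of MMEJ; the value is invariant across alignment-equivalent
#' placements of the same deletion.
#'
#' @param reference Reference sequence (string).
#' @param del_start,del_end 0-based half-open deletion interval.
#' @return Integer microhomology length (bp).
#' @examples
#' microhomology_length("AAGCTGCTAA", 3, 6)  # 2
#' microhomology_length("TTAAAAGG", 2, 3)    # 1, capped by deletion length
#' @export
microhomology_length <- function(reference, del_start, del_end) {
  n <- nchar(reference)
  del_start <- as.integer(del_start); del_end <- as.integer(del_end)
  if (is.na(del_start) || is.na(del_end) ||
      del_start < 0L || del_start >= del_end || del_end > n) {
    stop("invalid deletion interval [", del_start, ",", del_end,
         ") for reference of length ", n, call. = FALSE)
  }
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  len <- del_end - del_start

  k_right <- 0L
  while (k_right < len && del_end + k_right < n &&
         chars[del_start + k_right + 1L] == chars[del_end + k_right + 1L]) {
    k_right <- k_right + 1L
  }
  k_left <- 0L
  while (k_left < len && del_start - k_left > 0L &&
         chars[del_end - k_left] == chars[del_start - k_left]) {
    k_left <- k_left + 1L
  }
  max(k_right, k_left)
}
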