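#' Classification thresholds
#'
#' The printed analysis constants of the outcome classifier: reads must reach
#' 70% similarity to the wild-type (or donor-edited) amplicon to be retained,
#' HDR calls additionally require 95% similarity to the donor-edited
#' sequence, and deletions are attributed to MMEJ when their junction
#' microhomology is at least 2 bp. Reads with more than 10% ambiguous bases
#' are discarded outright.
#'
#' @param min_wt_similarity Minimum similarity to the better-matching of the
#'   wild-type and donor-edited sequences for a read to be retained.
#'   Default 0.70.
#' @param min_hdr_similarity Minimum similarity to the donor-edited sequence
#'   for an HDR call. Default 0.95.
#' @param mh_min Minimum junction microhomology (bp) for an MMEJ call.
#'   Default 2.
#' @param max_n_fraction Maximum tolerated fraction of `N` bases in a read.
#'   Default 0.10.
#' @return A list of class `classify_thresholds`.
#' @export
classify_thresholds <- function(min_wt_similarity = 0.70,
                                min_hdr_similarity = 0.95,
                                mh_min = 2L,
                                max_n_fraction = 0.10) {
  stopifnot(min_wt_similarity >= 0, min_wt_similarity <= 1,
            min_hdr_similarity >= 0, min_hdr_similarity <= 1,
            mh_min >= 0, max_n_fraction >= 0, max_n_fraction <= 1)
  structure(list(min_wt_similarity = min_wt_similarity,
                 min_hdr_similarity = min_hdr_similarity,
                 mh_min = as.integer(mh_min),
                 max_n_fraction = max_n_fraction),
            class = "classify_thresholds")
}

.overlaps_window <- function(lesions, win) {
  kind <- lesions$kind
  s <- lesions$ref_start; e <- lesions$ref_end
  ifelse(kind == "insertion",
         s >= win[1] & s <= win[2],          # between-base point, inclusive edges
         s < win[2] & e > win[1])            # interval overlap
}

# Classify one unique read sequence given its precomputed alignments;
# returns a one-row data frame plus the lesion table for that sequence.
.classify_one <- function(aln_wt, sim_hdr, edits, th, win) {
  out <- data.frame(category = NA_character_,
                    similarity_to_wt = NA_real_,
                    similarity_to_hdr = NA_real_,
                    n_window_del = 0L, n_window_ins = 0L,
                    edits_present = NA,
                    mh_length = 0L,
                    discard_reason = NA_character_,
                    stringsAsFactors = FALSE)

  sim_wt <- aln_wt$identity
  out$similarity_to_wt <- sim_wt
  out$similarity_to_hdr <- sim_hdr

  if (max(sim_wt, sim_hdr, na.rm = TRUE) < th$min_wt_similarity) {
    out$category <- "discarded"; out$discard_reason <- "low_similarity"
    return(list(row = out, lesions = NULL))
  }

  les <- extract_lesions(aln_wt)
  indels <- les[les$kind != "substitution", , drop = FALSE]
  win_indels <- indels[.overlaps_window(indels, win), , drop = FALSE]
  n_del <- sum(win_indels$kind == "deletion")
  n_ins <- sum(win_indels$kind == "insertion")
  out$n_window_del <- n_del
  out$n_window_ins <- n_ins

  edits_present <- FALSE
  if (!is.null(edits)) {
    subs <- les[les$kind == "substitution", , drop = FALSE]
    edits_present <- all(vapply(seq_along(edits$positions), function(i) {
      any(subs$ref_start == edits$positions[i] & subs$read_base == edits$alt[i])
    }, logical(1)))
  }
  out$edits_present <- edits_present

  has_window_indel <- nrow(win_indels) > 0L
  if (!has_window_indel) {
    if (edits_present && !is.na(sim_hdr) && sim_hdr >= th$min_hdr_similarity) {
      out$category <- "hdr"
    } else {
      # no window indel, and either no intended edit or (all edits present but
      # below the HDR similarity bar): substitutions alone are disregarded
      out$category <- "unmodified"
    }
  } else if (edits_present) {
    out$category <- "mix"
  } else {
    if (n_del == 1L && n_ins == 0L) {
      d <- win_indels[win_indels$kind == "deletion", , drop = FALSE]
      out$mh_length <- d$mh_length[1]
      out$category <- if (d$mh_length[1] >= th$mh_min) "mmej" else "nhej"
    } else {
      out$category <- "nhej"
    }
  }
  list(row = out, lesions = les)
}

#' Classify amplicon reads into repair-pathway outcomes
#'
#' Assigns each read to one of `unmodified`, `hdr`, `nhej`, `mmej`, `mix`, or
#' `discarded`. The decision cascade, applied to the global alignment against
#' the wild-type amplicon (and, when a donor is given, the donor-edited
#' sequence):
#'
#' 1. discard reads with > 10% `N` or with similarity below
#'    `min_wt_similarity` to both references;
#' 2. only indels overlapping the quantification window and substitutions at
#'    intended-edit positions are considered; all other substitutions are
#'    disregarded as potential sequencing errors;
#' 3. no window indel, no intended edit: `unmodified`;
#' 4. all intended edits present, no window indel, similarity to the
#'    donor-edited sequence at least `min_hdr_similarity`: `hdr`;
#' 5. window indel and all intended edits present: `mix`;
#' 6. window indel, intended edits absent: `mmej` when the read carries
#'    exactly one window-overlapping deletion with junction microhomology of
#'    at least `mh_min` bp and no window insertion; otherwise `nhej`.
#'
#' Reads on the minus strand must be reverse-complemented beforehand; the
#' classifier assumes read and reference share an orientation.
#'
#' @param reads Character vector of read sequences (a named vector keeps the
#'   names as read ids).
#' @param amplicon An [amplicon()].
#' @param guide A [guide_spec()].
#' @param edits An [edit_spec()] or `NULL` when no donor was supplied.
#' @param thresholds A [classify_thresholds()].
#' @param scoring An [align_scoring()].
#' @return A data frame of class `outcome_calls`, one row per read, with
#'   columns `read_id`, `category`, `similarity_to_wt`, `similarity_to_hdr`,
#'   `n_window_del`, `n_window_ins`, `edits_present`, `mh_length`,
#'   `discard_reason`, and a list column `lesions` holding the per-read
#'   lesion table. Attribute `window` stores the quantification window.
#' @export
classify_reads <- function(reads, amplicon, guide, edits = NULL,
                           thresholds = classify_thresholds(),
                           scoring = align_scoring()) {
  stopifnot(inherits(amplicon, "amplicon"), inherits(guide, "guide_spec"))
  if (!is.null(edits)) stopifnot(inherits(edits, "edit_spec"))
  stopifnot(inherits(thresholds, "classify_thresholds"))
  reads <- toupper(reads)
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  win <- quant_window(guide, amplicon$length)  # errors if outside amplicon

  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))

  uniq <- unique(reads)
  n_frac <- nchar(gsub("[^N]", "", uniq)) / nchar(uniq)
  usable <- n_frac <= thresholds$max_n_fraction

  res <- vector("list", length(uniq))
  if (any(!usable)) {
    row_n <- data.frame(category = "discarded",
                        similarity_to_wt = NA_real_,
                        similarity_to_hdr = NA_real_,
                        n_window_del = 0L, n_window_ins = 0L,
                        edits_present = NA, mh_length = 0L,
                        discard_reason = "too_many_N",
                        stringsAsFactors = FALSE)
    res[!usable] <- list(list(row = row_n, lesions = NULL))
  }
  if (any(usable)) {
    aln_wt <- global_align_many(uniq[usable], amplicon$sequence, scoring)
    sim_hdr <- if (!is.null(edits)) {
      vapply(global_align_many(uniq[usable], edits$expected_hdr_sequence,
                               scoring),
             `[[`, 0, "identity")
    } else {
      rep(NA_real_, sum(usable))
    }
    res[usable] <- lapply(seq_along(aln_wt), function(i) {
      .classify_one(aln_wt[[i]], sim_hdr[i], edits, thresholds, win)
    })
  }
  rows <- do.call(rbind, lapply(res, `[[`, "row"))
  idx <- match(reads, uniq)

  calls <- rows[idx, , drop = FALSE]
  calls <- cbind(read_id = ids, calls)
  calls$lesions <- lapply(res, `[[`, "lesions")[idx]
  rownames(calls) <- NULL
  attr(calls, "window") <- win
  class(calls) <- c("outcome_calls", class(calls))
  calls
}

#' Classify a single read
#'
#' Convenience wrapper around [classify_reads()] for one sequence.
#'
#' @inheritParams classify_reads
#' @param read A single read sequence.
#' @return A one-row `outcome_calls` data frame.
#' @export
classify_read <- function(read, amplicon, guide, edits = NULL,
                          thresholds = classify_thresholds(),
                          scoring = align_scoring()) {
  classify_reads(read, amplicon, guide, edits, thresholds, scoring)
}

#' Summarize per-read calls into a sample outcome table
#'
#' Percentage shares are computed over non-discarded reads and always sum to
#' 100. Insertion and deletion shares are computed over indel-bearing reads
#' (categories `nhej`, `mmej`, `mix`): the share of such reads carrying at
#' least one window insertion (respectively deletion); a read carrying both
#' counts towards both shares.
#'
#' @param calls An `outcome_calls` data frame from [classify_reads()].
#' @return A list of class `sample_outcome` with elements `table` (category,
#'   count, percent), `insertion_share`, `deletion_share` (percent of indel
#'   reads; `NA` when there are none), `retained`, `discarded`, `total`.
#' @export
summarize_sample <- function(calls) {
  stopifnot(inherits(calls, "outcome_calls"))
  cats <- c("unmodified", "hdr", "nhej", "mmej", "mix")
  retained <- calls[calls$category != "discarded", , drop = FALSE]
  if (nrow(retained) == 0L) {
    stop("all reads were discarded; no outcome shares can be computed",
         call. = FALSE)
  }
  counts <- vapply(cats, function(ct) sum(retained$category == ct), 1L)
  tab <- data.frame(category = cats, count = as.integer(counts),
                    percent = 100 * counts / nrow(retained),
                    stringsAsFactors = FALSE)

  indel <- retained[retained$category %in% c("nhej", "mmej", "mix"), , drop = FALSE]
  if (nrow(indel) > 0L) {
    ins_share <- 100 * sum(indel$n_window_ins > 0) / nrow(indel)
    del_share <- 100 * sum(indel$n_window_del > 0) / nrow(indel)
  } else {
    ins_share <- NA_real_; del_share <- NA_real_
  }
  structure(list(table = tab,
                 insertion_share = ins_share,
                 deletion_share = del_share,
                 retained = nrow(retained),
                 discarded = nrow(calls) - nrow(retained),
                 total = nrow(calls)),
            class = "sample_outcome")
}

#' @export
print.sample_outcome <- function(x, ...) {
  cat("Sample outcome (", x$retained, " retained / ", x$discarded,
      " discarded of ", x$total, " reads)\n", sep = "")
  print(transform(x$table, percent = round(percent, 2)), row.names = FALSE)
  if (!is.na(x$insertion_share)) {
    cat(sprintf("indel reads: %.1f%% with insertion, %.1f%% with deletion\n",
                x$insertion_share, x$deletion_share))
  }
  invisible(x)
}

#' Deletion spectrum of a sample
#'
#' Summarizes all deletions seen in retained reads: per-position deletion
#' coverage along the amplicon, the deletion-length histogram, and the
#' junction-microhomology histogram. Shifts in these spectra (e.g. towards
#' longer, microhomology-flanked deletions) reveal drug-induced changes in
#' deletion shape patterns.
#'
#' @param calls An `outcome_calls` data frame from [classify_reads()].
#' @param amplicon_length Reference length (bp).
#' @return A list of class `deletion_spectrum`: `position` (data frame
#'   `pos` 0-based, `count`), `length_hist`, `mh_hist` (data frames with
#'   `value`, `count`), and `n_deletion_reads`.
#' @export
deletion_spectrum <- function(calls, amplicon_length) {
  stopifnot(inherits(calls, "outcome_calls"))
  retained <- calls[calls$category != "discarded", , drop = FALSE]
  pos_count <- integer(amplicon_length)
  lens <- integer(0); mhs <- integer(0)
  n_del_reads <- 0L
  for (les in retained$lesions) {
    if (is.null(les)) next
    dels <- les[les$kind == "deletion", , drop = FALSE]
    if (nrow(dels) == 0L) next
    n_del_reads <- n_del_reads + 1L
    for (k in seq_len(nrow(dels))) {
      span <- (dels$ref_start[k] + 1L):dels$ref_end[k]  # 1-based indices
      pos_count[span] <- pos_count[span] + 1L
    }
    # one length / mh entry per read: the read's (single or combined) deletions
    lens <- c(lens, sum(dels$ref_end - dels$ref_start))
    mhs <- c(mhs, max(dels$mh_length))
  }
  hist_of <- function(v) {
    if (length(v) == 0L) return(data.frame(value = integer(0), count = integer(0)))
    t <- table(v)
    data.frame(value = as.integer(names(t)), count = as.integer(t))
  }
  structure(list(position = data.frame(pos = 0:(amplicon_length - 1L),
                                       count = pos_count),
                 length_hist = hist_of(lens),
                 mh_hist = hist_of(mhs),
                 n_deletion_reads = n_del_reads),
            class = "deletion_spectrum")
}
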