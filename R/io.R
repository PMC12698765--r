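#' Read a FASTQ file
#'
#' Reads (optionally gzip-compressed) FASTQ into a named character vector of
#' sequences. Base qualities are not used by the classifier and are dropped.
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTQ
#'
#' Writes reads with a constant quality string (the generator does not model
#' base qualities).
#'
#' @param reads Named character vector of sequences.
#' @param path Output path (`.gz` suffix compresses).
#' @param quality_char Single character used for every base quality.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  s <- Biostrings::DNAStringSet(reads)
  if (is.null(names(s))) names(s) <- sprintf("read_%d", seq_along(s))
  q <- Biostrings::BStringSet(strrep(quality_char, Biostrings::width(s)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read an experiment sheet
#'
#' The sheet maps samples to FASTQ files and editing designs. Required
#' columns: `sample_id`, `fastq_path`, `amplicon_name`, `amplicon_seq`,
#' `protospacer_start`, `protospacer_end`, `strand`, `cut_offset`,
#' `donor_edits` (comma-separated `pos:ref>alt`, 0-based; empty for no
#' donor).
#'
#' @param path Path to a tab-separated sheet.
#' @return Data frame with one row per sample.
#' @export
read_experiment_sheet <- function(path) {
  sheet <- .read_tsv(path)
  .require_columns(sheet, c("sample_id", "fastq_path", "amplicon_name",
                            "amplicon_seq", "protospacer_start",
                            "protospacer_end", "strand", "cut_offset",
                            "donor_edits"),
                   "experiment sheet")
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in experiment sheet", call. = FALSE)
  }
  sheet
}

#' Read a screen condition table
#'
#' Required columns: `drug`, `concentration_um`, `plate`, `well`, `reads`,
#' `hdr_pct`, `nhej_pct`, `mmej_pct`, `mix_pct`, `fluorescence`, `is_mock`.
#'
#' @param path Path to a tab-separated condition table.
#' @return Data frame of conditions.
#' @export
read_conditions <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("drug", "concentration_um", "plate", "well", "reads",
                         "hdr_pct", "nhej_pct", "mmej_pct", "mix_pct",
                         "fluorescence", "is_mock"),
                   "condition table")
  df$is_mock <- as.logical(df$is_mock)
  pct <- c("hdr_pct", "nhej_pct", "mmej_pct", "mix_pct")
  for (p in pct) {
    bad <- !is.na(df[[p]]) & (df[[p]] < 0 | df[[p]] > 100)
    if (any(bad)) stop(p, " outside [0, 100]", call. = FALSE)
  }
  if (any(df$reads < 0, na.rm = TRUE)) stop("negative read counts", call. = FALSE)
  df
}

#' Read a drug-to-target-class annotation table
#'
#' One row per (drug, target class) pair; required columns `drug`,
#' `target_class`.
#'
#' @param path Path to a tab-separated annotation table.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("drug", "target_class"), "annotation table")
  df
}
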