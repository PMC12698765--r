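#' Reference amplicon
#'
#' Constructs a validated wild-type target amplicon. All coordinates in this
#' package are 0-based, half-open (`[start, end)`), matching the convention of
#' BED files and most sequence tooling; this is stated on every function that
#' takes coordinates.
#'
#' @param name Identifier for the amplicon (e.g. the target gene).
#' @param sequence Reference DNA string. Only `A`, `C`, `G`, `T` are allowed
#'   (ambiguity codes may occur in reads, never in the reference).
#' @return An object of class `amplicon` with fields `name`, `sequence`,
#'   `length`.
#' @examples
#' amp <- amplicon("my_target", "ACGTACGTACGT")
#' amp$length
#' @export
amplicon <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("amplicon sequence must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("amplicon sequence may contain only A/C/G/T", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "amplicon"
  )
}

#' Guide (protospacer) specification
#'
#' Describes where the guide RNA matches the amplicon and where the nuclease
#' cuts. The predicted blunt cut for Cas9 lies 3 bp from the PAM-proximal end
#' of the protospacer (`cut_offset = -3`); Cas12a or other nucleases can be
#' accommodated by changing `cut_offset`. The quantification window used for
#' indel calling is `window_width` bp centred on the cut site.
#'
#' @param protospacer_start,protospacer_end 0-based half-open reference
#'   coordinates of the protospacer.
#' @param strand `"+"` or `"-"`; for `"-"` the PAM-proximal end is
#'   `protospacer_start`.
#' @param cut_offset Signed offset (bp) of the cut from the PAM-proximal
#'   protospacer end. Default `-3` (Cas9).
#' @param window_width Width (bp) of the quantification window centred on the
#'   cut site. Must be even and at least 2. Default 20.
#' @return An object of class `guide_spec`.
#' @export
guide_spec <- function(protospacer_start, protospacer_end, strand = "+",
                       cut_offset = -3L, window_width = 20L) {
  protospacer_start <- as.integer(protospacer_start)
  protospacer_end <- as.integer(protospacer_end)
  window_width <- as.integer(window_width)
  if (!(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (is.na(protospacer_start) || is.na(protospacer_end) ||
      protospacer_start < 0L || protospacer_start >= protospacer_end) {
    stop("need 0 <= protospacer_start < protospacer_end", call. = FALSE)
  }
  if (window_width < 2L || window_width %% 2L != 0L) {
    stop("window_width must be even and >= 2", call. = FALSE)
  }
  structure(
    list(protospacer_start = protospacer_start,
         protospacer_end = protospacer_end,
         strand = strand,
         cut_offset = as.integer(cut_offset),
         window_width = window_width),
    class = "guide_spec"
  )
}

#' Predicted cut site of a guide
#'
#' Returns the cut site as a 0-based *between-base* coordinate `c`: the
#' nuclease cuts between reference positions `c - 1` and `c`.
#'
#' @param guide A [guide_spec()].
#' @return Integer between-base coordinate.
#' @export
cut_site <- function(guide) {
  stopifnot(inherits(guide, "guide_spec"))
  if (guide$strand == "+") {
    guide$protospacer_end + guide$cut_offset
  } else {
    guide$protospacer_start - guide$cut_offset
  }
}

#' Quantification window around the cut site
#'
#' The window is `window_width` bp centred on the predicted cut site,
#' returned as a 0-based half-open interval. Indels are only counted when
#' they overlap this window; substitutions are only counted at intended-edit
#' positions.
#'
#' @param guide A [guide_spec()].
#' @param amplicon_length Length of the reference amplicon (bp).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
quant_window <- function(guide, amplicon_length) {
  cs <- cut_site(guide)
  half <- guide$window_width %/% 2L
  win <- c(cs - half, cs + half)
  if (win[1] < 0L || win[2] > amplicon_length) {
    stop("quantification window [", win[1], ",", win[2],
         ") falls outside the amplicon (length ", amplicon_length, ")",
         call. = FALSE)
  }
  win
}

#' Intended donor edits
#'
#' Describes the precise substitutions carried by the single-stranded DNA
#' donor. `expected_hdr_sequence` is the reference with all substitutions
#' applied; a read matching it closely (and carrying all intended edits with
#' no window indel) is scored as HDR.
#'
#' @param positions Integer vector of 0-based reference positions.
#' @param ref Character vector of reference bases at those positions.
#' @param alt Character vector of donor (edited) bases.
#' @param reference The wild-type amplicon sequence (string or [amplicon()]).
#' @return An object of class `edit_spec` with fields `positions`, `ref`,
#'   `alt`, `expected_hdr_sequence`.
#' @export
edit_spec <- function(positions, ref, alt, reference) {
  if (inherits(reference, "amplicon")) reference <- reference$sequence
  positions <- as.integer(positions)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(positions) == length(ref), length(ref) == length(alt))
  if (length(positions) == 0L) stop("edit_spec needs at least one edit", call. = FALSE)
  if (anyDuplicated(positions)) stop("edit positions must be unique", call. = FALSE)
  if (any(positions < 0L | positions >= nchar(reference))) {
    stop("edit position outside the reference", call. = FALSE)
  }
  have <- substring(reference, positions + 1L, positions + 1L)
  if (!all(have == ref)) {
    stop("ref base does not match the reference at position(s) ",
         paste(positions[have != ref], collapse = ", "), call. = FALSE)
  }
  if (any(ref == alt)) stop("alt base must differ from ref base", call. = FALSE)
  hdr <- strsplit(reference, "", fixed = TRUE)[[1]]
  hdr[positions + 1L] <- alt
  structure(
    list(positions = positions, ref = ref, alt = alt,
         expected_hdr_sequence = paste(hdr, collapse = "")),
    class = "edit_spec"
  )
}

#' Parse a compact donor-edit string
#'
#' Experiment sheets encode donor edits as comma-separated `pos:ref>alt`
#' tokens with 0-based positions, e.g. `"77:G>T,80:A>C"`.
#'
#' @param text The encoded edits (may be `NA`/empty for no donor).
#' @param reference Wild-type amplicon sequence.
#' @return An [edit_spec()] or `NULL` when `text` is empty.
#' @export
parse_donor_edits <- function(text, reference) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  tokens <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^\\s*(\\d+):([ACGTacgt])>([ACGTacgt])\\s*$", tokens))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed donor edit token(s): ", paste(tokens[bad], collapse = ", "),
         call. = FALSE)
  }
  edit_spec(
    positions = vapply(m, function(x) as.integer(x[2]), 1L),
    ref = vapply(m, `[`, "", 3L),
    alt = vapply(m, `[`, "", 4L),
    reference = reference
  )
}
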