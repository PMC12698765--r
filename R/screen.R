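#' Mock-relative metrics per condition
#'
#' Divides each condition's raw metric shares by the mean of the matching
#' mock (solvent-only) wells on the same plate, yielding unitless
#' fold-changes `rel_hdr`, `rel_nhej`, `rel_mmej`, `rel_mix`, and
#' `rel_survival`. Survival is computed from blank-corrected resazurin
#' fluorescence via [relative_survival()]; editing metrics are divided
#' directly. A plate with a single mock uses that well as the denominator; a
#' mock metric of zero leaves that metric `NA` for the whole plate (flagged
#' in the `undefined_metrics` attribute) so it drops out of downstream
#' quartiles.
#'
#' @param records Condition data frame as returned by [read_conditions()] or
#'   [simulate_screen()].
#' @param blanks Optional data frame `plate`, `fluorescence` of cell-free
#'   blank wells; per-plate means are subtracted before survival is formed.
#'   When `NULL`, blank fluorescence is taken as 0.
#' @return `records` with `rel_hdr`, `rel_nhej`, `rel_mmej`, `rel_mix`,
#'   `rel_survival` columns appended.
#' @export
relative_to_mock <- function(records, blanks = NULL) {
  .require_columns(records, c("drug", "plate", "hdr_pct", "nhej_pct",
                              "mmej_pct", "mix_pct", "fluorescence",
                              "is_mock"),
                   "condition table")
  plates <- unique(records$plate)
  no_mock <- plates[!plates %in% unique(records$plate[records$is_mock])]
  if (length(no_mock) > 0L) {
    stop("plate(s) without a mock condition: ",
         paste(no_mock, collapse = ", "), call. = FALSE)
  }
  blank_mean <- setNames(rep(0, length(plates)), plates)
  if (!is.null(blanks)) {
    .require_columns(blanks, c("plate", "fluorescence"), "blank table")
    bm <- tapply(blanks$fluorescence, blanks$plate, mean)
    blank_mean[names(bm)] <- bm
  }

  metric_cols <- c(rel_hdr = "hdr_pct", rel_nhej = "nhej_pct",
                   rel_mmej = "mmej_pct", rel_mix = "mix_pct")
  for (m in names(metric_cols)) records[[m]] <- NA_real_
  records$rel_survival <- NA_real_
  undefined <- character(0)

  for (pl in plates) {
    on_plate <- records$plate == pl
    mocks <- records[on_plate & records$is_mock, , drop = FALSE]
    for (m in names(metric_cols)) {
      denom <- mean(mocks[[metric_cols[[m]]]])
      if (is.na(denom) || denom <= 0) {
        undefined <- c(undefined, paste0(pl, ":", m))
        next
      }
      records[[m]][on_plate] <- records[[metric_cols[[m]]]][on_plate] / denom
    }
    mock_f <- mean(mocks$fluorescence)
    records$rel_survival[on_plate] <- relative_survival(
      records$fluorescence[on_plate], mock_f, blank_mean[[as.character(pl)]]
    )
  }
  attr(records, "undefined_metrics") <- undefined
  records
}

#' Sequencing-depth filter
#'
#' Drops conditions whose retained read count is at or below `min_reads`
#' (default 1000): a condition with exactly 1000 reads is excluded, one with
#' 1001 retained. Low-depth conditions produce unstable outcome shares and
#' would otherwise generate false hit assignments.
#'
#' @param records Condition data frame with a `reads` column.
#' @param min_reads Depth threshold; retained means `reads > min_reads`.
#' @return The retained rows; the excluded rows are kept in the `excluded`
#'   attribute as an exclusion log.
#' @export
read_depth_filter <- function(records, min_reads = 1000) {
  stopifnot(min_reads >= 0)
  .require_columns(records, "reads", "condition table")
  keep <- !is.na(records$reads) & records$reads > min_reads
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded") <- records[!keep, , drop = FALSE]
  out
}

#' First and third quartiles
#'
#' Linear-interpolation quantiles (the type-7 convention of
#' [stats::quantile()]), fixed so that category bounds are reproducible; the
#' convention is exposed for sensitivity checks.
#'
#' @param values Numeric fold-changes; non-finite entries are dropped.
#' @param type Quantile algorithm passed to [stats::quantile()]. Default 7.
#' @return Named numeric vector `c(q1, q3)`.
#' @examples
#' compute_quartiles(c(1, 2, 3, 4, 5))  # q1 = 2, q3 = 4
#' @export
compute_quartiles <- function(values, type = 7) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    stop("need at least 4 finite values to compute quartile bounds",
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' Quartile bounds for every screen metric
#'
#' Computes Q1/Q3 per metric across all retained drug (non-mock) conditions,
#' pooled over concentrations. These bounds define the directional
#' hit-category rules.
#'
#' @param metrics Data frame with the `rel_*` columns from
#'   [relative_to_mock()], typically after [read_depth_filter()].
#' @param metric_names Metrics to bound.
#' @param type Quantile convention (see [compute_quartiles()]).
#' @return A list of class `quartile_bounds`: per metric a `c(q1, q3)`
#'   vector.
#' @export
screen_quartiles <- function(metrics,
                             metric_names = c("rel_hdr", "rel_nhej",
                                              "rel_mmej", "rel_survival"),
                             type = 7) {
  .require_columns(metrics, metric_names, "metrics table")
  pop <- if ("is_mock" %in% names(metrics)) {
    metrics[!metrics$is_mock, , drop = FALSE]
  } else {
    metrics
  }
  bounds <- lapply(metric_names, function(m) compute_quartiles(pop[[m]], type))
  names(bounds) <- metric_names
  structure(bounds, class = "quartile_bounds")
}

# The seven directional category rules. Arrows: increase (> Q3), decrease
# (< Q1), remain equal or increase (>= Q1), remain equal or decrease (<= Q3).
.category_rules <- list(
  hdr_enhancer  = function(h, n, m, s, b) h > b$rel_hdr["q3"] & n <= b$rel_nhej["q3"] & m <= b$rel_mmej["q3"],
  hdr_inhibitor = function(h, n, m, s, b) h < b$rel_hdr["q1"] & n >= b$rel_nhej["q1"] & m >= b$rel_mmej["q1"],
  nhej_enhancer  = function(h, n, m, s, b) n > b$rel_nhej["q3"] & h <= b$rel_hdr["q3"] & m <= b$rel_mmej["q3"],
  nhej_inhibitor = function(h, n, m, s, b) n < b$rel_nhej["q1"] & h >= b$rel_hdr["q1"] & m >= b$rel_mmej["q1"],
  mmej_enhancer  = function(h, n, m, s, b) m > b$rel_mmej["q3"] & h <= b$rel_hdr["q3"] & n <= b$rel_nhej["q3"],
  mmej_inhibitor = function(h, n, m, s, b) m < b$rel_mmej["q1"] & h >= b$rel_hdr["q1"] & n >= b$rel_nhej["q1"],
  survival_enhancer = function(h, n, m, s, b) s > b$rel_survival["q3"]
)

#' Hit categories of a single condition
#'
#' Applies the seven directional quartile rules. A pathway enhancer must
#' raise its own metric above Q3 while the two other editing metrics stay at
#' or below Q3 (so a drug that raises everything, or rescues toxicity, is
#' not called); an inhibitor mirrors this below Q1. The survival-enhancer
#' rule uses only survival. A condition may satisfy several rules; an empty
#' result means neutral.
#'
#' @param rel_hdr,rel_nhej,rel_mmej,rel_survival Mock-relative fold-changes.
#' @param bounds A `quartile_bounds` object from [screen_quartiles()].
#' @return Character vector of category names (possibly empty).
#' @export
categorize_condition <- function(rel_hdr, rel_nhej, rel_mmej, rel_survival,
                                 bounds) {
  stopifnot(inherits(bounds, "quartile_bounds"))
  hit <- character(0)
  for (cat in names(.category_rules)) {
    needed <- if (cat == "survival_enhancer") "rel_survival" else
      c("rel_hdr", "rel_nhej", "rel_mmej")
    vals <- c(rel_hdr, rel_nhej, rel_mmej, rel_survival)[
      match(needed, c("rel_hdr", "rel_nhej", "rel_mmej", "rel_survival"))]
    if (any(is.na(vals)) || any(!needed %in% names(bounds))) {
      warning("metric missing for category ", cat, "; rule skipped",
              call. = FALSE)
      next
    }
    ok <- .category_rules[[cat]](rel_hdr, rel_nhej, rel_mmej, rel_survival,
                                 bounds)
    if (isTRUE(ok)) hit <- c(hit, cat)
  }
  hit
}

#' Hit categories for a whole metrics table
#'
#' Vectorized [categorize_condition()]; appends a `categories` column
#' (semicolon-joined, empty string for neutral conditions).
#'
#' @param metrics Metrics data frame with `rel_*` columns.
#' @param bounds A `quartile_bounds` object.
#' @return `metrics` with a `categories` character column appended.
#' @export
categorize_conditions <- function(metrics, bounds) {
  .require_columns(metrics, c("rel_hdr", "rel_nhej", "rel_mmej",
                              "rel_survival"),
                   "metrics table")
  metrics$categories <- vapply(seq_len(nrow(metrics)), function(i) {
    paste(categorize_condition(metrics$rel_hdr[i], metrics$rel_nhej[i],
                               metrics$rel_mmej[i], metrics$rel_survival[i],
                               bounds),
          collapse = ";")
  }, character(1))
  metrics
}

#' Detection-limit normalization of relative MMEJ
#'
#' Even complete genetic ablation of MMEJ leaves a residual share of
#' MMEJ-like deletions (imprecision in scoring NHEJ- vs MMEJ-derived indels
#' and low baseline MMEJ when NHEJ is active), so an observed relative MMEJ
#' of `floor` (default 0.74, the residual under MMEJ-pathway knock-out)
#' corresponds to full inhibition. Values below 1 are rescaled linearly so
#' that `floor` maps to 0 and 1 maps to 1, clamped below at 0; values of 1
#' or more (no inhibition) pass through unchanged.
#'
#' @param rel_mmej Numeric vector of mock-relative MMEJ fold-changes.
#' @param floor Detection-limit constant in (0, 1). Default 0.74.
#' @return Normalized fold-changes, same length as `rel_mmej`.
#' @examples
#' normalize_mmej_detection_limit(c(0.74, 0.87, 1, 1.6))
#' @export
normalize_mmej_detection_limit <- function(rel_mmej, floor = 0.74) {
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor >= 1) {
    stop("floor must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  ifelse(rel_mmej >= 1, rel_mmej,
         pmax(0, (rel_mmej - floor) / (1 - floor)))
}

#' Select the top drugs for one metric
#'
#' Ranks drug conditions by a mock-relative metric (descending for
#' enhancers, ascending for inhibitors), keeps each drug once at its best
#' concentration, breaks ties by drug id for determinism, and returns the
#' first `n` (default 30). Mock conditions are excluded.
#'
#' @param metrics Metrics data frame with `drug` and the requested metric.
#' @param metric Metric column name, e.g. `"rel_mmej"`.
#' @param n Number of drugs to return. Default 30.
#' @param direction `"enhancer"` (largest values first) or `"inhibitor"`
#'   (smallest first).
#' @return Data frame of the top drugs with their best metric value,
#'   ranked.
#' @export
select_top_hits <- function(metrics, metric, n = 30,
                            direction = c("enhancer", "inhibitor")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  if (!metric %in% names(metrics)) {
    stop("metric '", metric, "' not found in the metrics table", call. = FALSE)
  }
  df <- metrics
  if ("is_mock" %in% names(df)) df <- df[!df$is_mock, , drop = FALSE]
  df <- df[is.finite(df[[metric]]), , drop = FALSE]

  # best value per drug
  sgn <- if (direction == "enhancer") -1 else 1
  ord <- order(df$drug, sgn * df[[metric]], method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$drug), , drop = FALSE]

  ord <- order(sgn * df[[metric]], df$drug, method = "radix")
  df <- df[ord, , drop = FALSE]
  out <- df[seq_len(min(n, nrow(df))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Target-class enrichment of top drugs
#'
#' Compares the share of each target class among the top drugs with its
#' share in the whole library. Only classes hit by at least two different
#' top drugs are reported. Drugs missing from the annotation count as class
#' `"unannotated"`.
#'
#' @param top_drugs Character vector of top drug ids (or a data frame with a
#'   `drug` column, e.g. from [select_top_hits()]).
#' @param annotation Data frame `drug`, `target_class` (one row per pair).
#' @param library_drugs Character vector of all drug ids in the library.
#' @return Data frame of class shares: `target_class`, `n_top`, `top_share`,
#'   `library_share`, `fold_enrichment`, sorted by descending top share.
#' @export
target_class_enrichment <- function(top_drugs, annotation, library_drugs) {
  if (is.data.frame(top_drugs)) top_drugs <- top_drugs$drug
  top_drugs <- unique(as.character(top_drugs))
  library_drugs <- unique(as.character(library_drugs))
  if (length(top_drugs) == 0L) stop("empty top-drug list", call. = FALSE)
  .require_columns(annotation, c("drug", "target_class"), "annotation table")

  classes_of <- function(drug) {
    cls <- unique(annotation$target_class[annotation$drug == drug])
    if (length(cls) == 0L) "unannotated" else cls
  }
  top_pairs <- unique(do.call(rbind, lapply(top_drugs, function(d) {
    data.frame(drug = d, target_class = classes_of(d), stringsAsFactors = FALSE)
  })))
  lib_pairs <- unique(do.call(rbind, lapply(library_drugs, function(d) {
    data.frame(drug = d, target_class = classes_of(d), stringsAsFactors = FALSE)
  })))

  top_counts <- table(top_pairs$target_class)
  keep <- names(top_counts)[top_counts >= 2L]
  if (length(keep) == 0L) {
    return(data.frame(target_class = character(0), n_top = integer(0),
                      top_share = numeric(0), library_share = numeric(0),
                      fold_enrichment = numeric(0)))
  }
  lib_counts <- table(lib_pairs$target_class)
  out <- data.frame(
    target_class = keep,
    n_top = as.integer(top_counts[keep]),
    top_share = as.numeric(top_counts[keep]) / length(top_drugs),
    library_share = as.numeric(ifelse(is.na(lib_counts[keep]), 0,
                                      lib_counts[keep])) / length(library_drugs),
    stringsAsFactors = FALSE
  )
  out$fold_enrichment <- ifelse(out$library_share > 0,
                                out$top_share / out$library_share, Inf)
  out <- out[order(-out$top_share, out$target_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Principal component analysis of screen metrics
#'
#' SVD-based PCA (via [stats::prcomp()]) of the mock-relative metrics, by
#' default z-scored per metric. Rows with missing values are dropped (and
#' logged in the `dropped_rows` attribute); constant columns are dropped
#' with a warning when standardizing. Component signs are made deterministic
#' by orienting each loading vector so its largest-magnitude entry is
#' positive.
#'
#' @param metrics Metrics data frame.
#' @param metric_names Columns to enter the PCA.
#' @param standardize Z-score the columns first. Default `TRUE`.
#' @return A list of class `screen_pca`: `scores` (conditions x PCs),
#'   `loadings` (metrics x PCs), `var_pct` (percent variance per PC).
#' @export
run_pca <- function(metrics,
                    metric_names = c("rel_hdr", "rel_nhej", "rel_mmej",
                                     "rel_survival"),
                    standardize = TRUE) {
  .require_columns(metrics, metric_names, "metrics table")
  if (length(metric_names) < 2L) stop("need at least 2 metrics", call. = FALSE)
  x <- as.matrix(metrics[, metric_names, drop = FALSE])
  complete <- stats::complete.cases(x) & apply(is.finite(x), 1, all)
  dropped <- which(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 complete conditions", call. = FALSE)

  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    warning("dropping constant metric column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 non-constant metrics", call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)

  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(p$rotation))) {
    v <- p$rotation[, j]
    if (v[which.max(abs(v))] < 0) {
      p$rotation[, j] <- -v
      p$x[, j] <- -p$x[, j]
    }
  }
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, var_pct = var_pct),
            class = "screen_pca",
            dropped_rows = dropped)
}

#' @export
print.screen_pca <- function(x, ...) {
  cat("PCA of screen metrics:", nrow(x$scores), "conditions,",
      ncol(x$loadings), "components\n")
  cat("variance explained (%):",
      paste(sprintf("%.1f", x$var_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Shortlist hits per category for dose-response follow-up
#'
#' For each category, ranks its member drugs by the category's defining
#' metric (largest effect first) and extends the shortlist until it contains
#' at least `min_hits` non-toxic drugs, where non-toxic means relative cell
#' survival strictly above `nontoxic_threshold` (default 0.79, the survival
#' Q1 of the screen; a drug at exactly the threshold counts as toxic). A
#' category that cannot reach `min_hits` non-toxic members returns all its
#' members with a shortfall warning.
#'
#' @param categorized Metrics data frame with a `categories` column from
#'   [categorize_conditions()].
#' @param min_hits Minimum number of non-toxic hits per category. Default 4.
#' @param nontoxic_threshold Relative-survival cutoff (strict `>`).
#'   Default 0.79.
#' @return Named list (per category) of shortlist data frames.
#' @export
select_subset_for_dose_response <- function(categorized, min_hits = 4,
                                            nontoxic_threshold = 0.79) {
  .require_columns(categorized, c("drug", "categories", "rel_survival"),
                   "categorized table")
  defining <- c(hdr_enhancer = "rel_hdr", hdr_inhibitor = "rel_hdr",
                nhej_enhancer = "rel_nhej", nhej_inhibitor = "rel_nhej",
                mmej_enhancer = "rel_mmej", mmej_inhibitor = "rel_mmej",
                survival_enhancer = "rel_survival")
  out <- list()
  for (cat in names(defining)) {
    members <- categorized[grepl(cat, categorized$categories, fixed = TRUE), ,
                           drop = FALSE]
    if (nrow(members) == 0L) next
    metric <- defining[[cat]]
    sgn <- if (grepl("inhibitor", cat)) 1 else -1
    ord <- order(members$drug, sgn * members[[metric]], method = "radix")
    members <- members[ord, , drop = FALSE]
    members <- members[!duplicated(members$drug), , drop = FALSE]
    members <- members[order(sgn * members[[metric]], members$drug,
                             method = "radix"), , drop = FALSE]
    members$nontoxic <- members$rel_survival > nontoxic_threshold

    n_ok <- cumsum(members$nontoxic)
    if (max(n_ok) < min_hits) {
      warning("category ", cat, ": only ", max(n_ok),
              " non-toxic member(s); returning all ", nrow(members),
              call. = FALSE)
      take <- nrow(members)
    } else {
      take <- which(n_ok >= min_hits)[1]
    }
    short <- members[seq_len(take), , drop = FALSE]
    rownames(short) <- NULL
    out[[cat]] <- short
  }
  out
}

#' Dose ladder around a base concentration
#'
#' The follow-up concentrations tested around a hit's screening
#' concentration: 0.2-, 0.5-, 1-, 2-, and 5-fold, ascending.
#'
#' @param base_concentration Base concentration (µM), positive.
#' @return Numeric vector of 5 concentrations.
#' @examples
#' build_dose_ladder(1)  # 0.2 0.5 1 2 5
#' @export
build_dose_ladder <- function(base_concentration) {
  if (!is.numeric(base_concentration) || length(base_concentration) != 1L ||
      !is.finite(base_concentration) || base_concentration <= 0) {
    stop("base concentration must be a single positive number", call. = FALSE)
  }
  base_concentration * c(0.2, 0.5, 1, 2, 5)
}

#' Pearson correlation between two screen metrics
#'
#' Plain two-tailed Pearson correlation with no multiple-testing adjustment,
#' used to relate e.g. the deletion share to relative MMEJ.
#'
#' @param metrics Metrics data frame.
#' @param x,y Metric column names.
#' @return List with `r`, `p_value`, `n`; `r` is `NA` with a note when
#'   either metric has zero variance.
#' @export
metric_correlation <- function(metrics, x, y) {
  .require_columns(metrics, c(x, y), "metrics table")
  xv <- metrics[[x]]; yv <- metrics[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(xv),
                note = "zero variance; correlation undefined"))
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}
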