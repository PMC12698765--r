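.file_checksums <- function(paths) {
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p),
                        logical(1))]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

.write_manifest <- function(path, stage, params, counts, inputs = list()) {
  manifest <- list(
    tool = "repairchoice",
    version = as.character(utils::packageVersion("repairchoice")),
    stage = stage,
    parameters = params,
    input_checksums = .file_checksums(inputs),
    counts = counts,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Run the screen-analysis pipeline
#'
#' Executes the full condition-table path: mock normalization, depth filter,
#' quartile bounds, hit categorization, detection-limit-normalized MMEJ, top
#' hits and target-class enrichment, PCA, and the dose-response shortlist,
#' writing one TSV per stage plus a JSON run manifest. Outputs are sorted
#' deterministically so reruns are byte-identical.
#'
#' @param conditions Condition table: a data frame or a TSV path (see
#'   [read_conditions()]).
#' @param annotation Optional drug annotation (data frame or TSV path);
#'   enrichment is skipped when absent.
#' @param blanks Optional blank-well table (data frame or TSV path).
#' @param out_dir Output directory (created if needed).
#' @param min_reads Depth-filter threshold. Default 1000.
#' @param top_n Top-hit list size. Default 30.
#' @param mmej_floor MMEJ detection-limit constant. Default 0.74.
#' @param min_hits,nontoxic_threshold Dose-response shortlist rules (see
#'   [select_subset_for_dose_response()]).
#' @return Invisibly, a list with the per-stage objects (`metrics`,
#'   `bounds`, `categorized`, `top_hits`, `enrichment`, `pca`, `shortlist`,
#'   `manifest`).
#' @export
run_screen_pipeline <- function(conditions, annotation = NULL, blanks = NULL,
                                out_dir, min_reads = 1000, top_n = 30,
                                mmej_floor = 0.74, min_hits = 4,
                                nontoxic_threshold = 0.79) {
  inputs <- list()
  if (is.character(conditions)) {
    inputs$conditions <- conditions
    conditions <- read_conditions(conditions)
  }
  if (is.character(annotation)) {
    inputs$annotation <- annotation
    annotation <- read_annotation(annotation)
  }
  if (is.character(blanks)) {
    inputs$blanks <- blanks
    blanks <- .read_tsv(blanks)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n_in <- nrow(conditions)
  metrics <- relative_to_mock(conditions, blanks = blanks)
  retained <- read_depth_filter(metrics, min_reads = min_reads)
  excluded <- attr(retained, "excluded")

  bounds <- screen_quartiles(retained)
  categorized <- categorize_conditions(retained, bounds)
  categorized$rel_mmej_normalized <-
    normalize_mmej_detection_limit(categorized$rel_mmej, floor = mmej_floor)

  ord <- order(categorized$drug, categorized$concentration_um,
               categorized$plate, categorized$well, method = "radix")
  categorized <- categorized[ord, , drop = FALSE]

  metric_dirs <- list(
    c("rel_hdr", "enhancer"), c("rel_hdr", "inhibitor"),
    c("rel_nhej", "enhancer"), c("rel_nhej", "inhibitor"),
    c("rel_mmej", "enhancer"), c("rel_mmej", "inhibitor"),
    c("rel_survival", "enhancer")
  )
  top_hits <- lapply(metric_dirs, function(md) {
    select_top_hits(categorized, md[1], n = top_n, direction = md[2])
  })
  names(top_hits) <- vapply(metric_dirs, paste, "", collapse = "_")

  enrichment <- NULL
  if (!is.null(annotation)) {
    lib <- unique(conditions$drug[!conditions$is_mock])
    enrichment <- lapply(top_hits, function(th) {
      target_class_enrichment(th$drug, annotation, lib)
    })
  }

  pca <- tryCatch(run_pca(categorized), error = function(e) {
    message("PCA skipped: ", conditionMessage(e))
    NULL
  })
  shortlist <- select_subset_for_dose_response(
    categorized, min_hits = min_hits, nontoxic_threshold = nontoxic_threshold)

  flat <- categorized
  flat$lesions <- NULL
  .write_tsv(flat, file.path(out_dir, "metrics.tsv"))
  .write_tsv(flat[, c("drug", "concentration_um", "plate", "well",
                      "categories")],
             file.path(out_dir, "categories.tsv"))
  qdf <- data.frame(metric = names(bounds),
                    q1 = vapply(bounds, `[[`, 0, "q1"),
                    q3 = vapply(bounds, `[[`, 0, "q3"))
  .write_tsv(qdf, file.path(out_dir, "quartiles.tsv"))
  for (nm in names(top_hits)) {
    keep <- intersect(c("drug", "concentration_um", "rel_hdr", "rel_nhej",
                        "rel_mmej", "rel_survival", "rank"),
                      names(top_hits[[nm]]))
    .write_tsv(top_hits[[nm]][, keep],
               file.path(out_dir, paste0("top_", nm, ".tsv")))
  }
  if (!is.null(enrichment)) {
    enr <- do.call(rbind, lapply(names(enrichment), function(nm) {
      e <- enrichment[[nm]]
      if (nrow(e) == 0L) return(NULL)
      cbind(list_name = nm, e)
    }))
    if (!is.null(enr)) .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(pca)) {
    .write_tsv(cbind(condition = rownames(pca$scores),
                     as.data.frame(pca$scores)),
               file.path(out_dir, "pca_scores.tsv"))
    .write_tsv(cbind(metric = rownames(pca$loadings),
                     as.data.frame(pca$loadings)),
               file.path(out_dir, "pca_loadings.tsv"))
    .write_tsv(data.frame(pc = seq_along(pca$var_pct), var_pct = pca$var_pct),
               file.path(out_dir, "pca_variance.tsv"))
  }

  manifest <- .write_manifest(
    file.path(out_dir, "manifest.json"),
    stage = "screen",
    params = list(min_reads = min_reads, top_n = top_n,
                  mmej_floor = mmej_floor, min_hits = min_hits,
                  nontoxic_threshold = nontoxic_threshold),
    counts = list(conditions_in = n_in,
                  conditions_retained = nrow(retained),
                  conditions_filtered = nrow(excluded),
                  mock_conditions = sum(conditions$is_mock)),
    inputs = inputs
  )
  invisible(list(metrics = metrics, bounds = bounds,
                 categorized = categorized, top_hits = top_hits,
                 enrichment = enrichment, pca = pca, shortlist = shortlist,
                 manifest = manifest))
}

#' Classify every sample of an experiment sheet
#'
#' Runs [classify_reads()] on each sample's FASTQ and writes per-sample
#' outcome tables, per-read calls (with lesions in a compact text encoding),
#' deletion spectra, and a run manifest with read-count reconciliation.
#'
#' @param sheet Experiment sheet: a data frame or TSV path (see
#'   [read_experiment_sheet()]).
#' @param out_dir Output directory.
#' @param thresholds A [classify_thresholds()].
#' @param scoring An [align_scoring()].
#' @return Invisibly, a named list of per-sample results (`calls`,
#'   `summary`, `spectrum`).
#' @export
classify_experiment <- function(sheet, out_dir,
                                thresholds = classify_thresholds(),
                                scoring = align_scoring()) {
  inputs <- list()
  if (is.character(sheet)) {
    inputs$sheet <- sheet
    sheet <- read_experiment_sheet(sheet)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  encode_lesions <- function(les) {
    if (is.null(les) || nrow(les) == 0L) return("")
    paste(vapply(seq_len(nrow(les)), function(k) {
      switch(les$kind[k],
             deletion = sprintf("D%d-%d", les$ref_start[k], les$ref_end[k]),
             insertion = sprintf("I%d+%s", les$ref_start[k],
                                 les$inserted_seq[k]),
             substitution = sprintf("S%d%s", les$ref_start[k],
                                    les$read_base[k]))
    }, ""), collapse = ",")
  }

  results <- list()
  total_in <- 0L; total_retained <- 0L
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    amp <- amplicon(sheet$amplicon_name[i], sheet$amplicon_seq[i])
    guide <- guide_spec(sheet$protospacer_start[i], sheet$protospacer_end[i],
                        strand = sheet$strand[i],
                        cut_offset = sheet$cut_offset[i])
    edits <- parse_donor_edits(sheet$donor_edits[i], amp$sequence)
    reads <- read_fastq(sheet$fastq_path[i])
    inputs[[paste0("fastq_", sid)]] <- sheet$fastq_path[i]

    calls <- classify_reads(reads, amp, guide, edits,
                            thresholds = thresholds, scoring = scoring)
    smry <- summarize_sample(calls)
    spec <- deletion_spectrum(calls, amp$length)

    .write_tsv(smry$table, file.path(out_dir, paste0(sid, "_outcomes.tsv")))
    call_tab <- data.frame(
      read_id = calls$read_id, category = calls$category,
      similarity_to_wt = calls$similarity_to_wt,
      similarity_to_hdr = calls$similarity_to_hdr,
      mh_length = calls$mh_length,
      lesions = vapply(calls$lesions, encode_lesions, ""),
      stringsAsFactors = FALSE)
    .write_tsv(call_tab, file.path(out_dir, paste0(sid, "_calls.tsv")))
    .write_tsv(spec$position, file.path(out_dir, paste0(sid, "_spectrum.tsv")))

    total_in <- total_in + smry$total
    total_retained <- total_retained + smry$retained
    results[[sid]] <- list(calls = calls, summary = smry, spectrum = spec)
  }

  .write_manifest(
    file.path(out_dir, "manifest.json"),
    stage = "classify",
    params = unclass(thresholds),
    counts = list(samples = nrow(sheet), reads_in = total_in,
                  reads_retained = total_retained,
                  reads_discarded = total_in - total_retained),
    inputs = inputs
  )
  invisible(results)
}

#' Run the full pipeline from a configuration
#'
#' Single entry point wiring classification and screen analysis. The
#' configuration is a named list or a YAML file with (any of) the blocks:
#'
#' * `classify`: `sheet` (experiment sheet TSV) plus optional threshold
#'   overrides `min_wt_similarity`, `min_hdr_similarity`, `mh_min`;
#' * `screen`: `conditions` (TSV), optional `annotation`, `blanks`, and the
#'   parameters of [run_screen_pipeline()];
#' * `out_dir`: output directory (required).
#'
#' Configuration problems are reported with their field path before any
#' computation; stage errors propagate as R errors.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (is.null(config$classify) && is.null(config$screen)) {
    stop("config must contain a 'classify' and/or a 'screen' block",
         call. = FALSE)
  }
  out <- list()
  if (!is.null(config$classify)) {
    cc <- config$classify
    if (is.null(cc$sheet)) stop("config$classify$sheet is required",
                                call. = FALSE)
    th <- classify_thresholds(
      min_wt_similarity = cc$min_wt_similarity %||% 0.70,
      min_hdr_similarity = cc$min_hdr_similarity %||% 0.95,
      mh_min = cc$mh_min %||% 2L)
    out$classify <- classify_experiment(
      cc$sheet, file.path(config$out_dir, "classify"), thresholds = th)
  }
  if (!is.null(config$screen)) {
    sc <- config$screen
    if (is.null(sc$conditions)) stop("config$screen$conditions is required",
                                     call. = FALSE)
    out$screen <- run_screen_pipeline(
      sc$conditions, annotation = sc$annotation, blanks = sc$blanks,
      out_dir = file.path(config$out_dir, "screen"),
      min_reads = sc$min_reads %||% 1000,
      top_n = sc$top_n %||% 30,
      mmej_floor = sc$mmej_floor %||% 0.74,
      min_hits = sc$min_hits %||% 4,
      nontoxic_threshold = sc$nontoxic_threshold %||% 0.79)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
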