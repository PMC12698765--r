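.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.transversion <- c(A = "C", C = "A", G = "T", T = "G")

# Candidate MMEJ deletions: intervals [p1, p2) spanning the cut whose first
# mh_len deleted bases recur immediately after the deletion, so the junction
# carries >= mh_len bp of microhomology. Candidates are kept only when the
# canonical (left-aligned) placement still overlaps the window and is a
# single deletion with mh >= 2 -- i.e. the classifier is guaranteed to see
# an MMEJ junction.
.find_mh_deletions <- function(sequence, cut, win, mh_len = 2L,
                               max_flank = 15L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  for (p1 in max(0L, cut - max_flank):(cut - 1L)) {
    for (p2 in (cut + 1L):min(n - mh_len, cut + max_flank)) {
      if (p2 - p1 < mh_len + 1L) next  # deletion longer than the repeat
      if (all(chars[(p1 + 1L):(p1 + mh_len)] == chars[(p2 + 1L):(p2 + mh_len)])) {
        se <- .left_shift_del(chars, p1, p2)
        if (se[1] < win[2] && se[2] > win[1] &&
            microhomology_length(sequence, se[1], se[2]) >= 2L) {
          out[[length(out) + 1L]] <- c(p1, p2)
        }
      }
    }
  }
  out
}

#' Simulate a reference amplicon with guide and donor design
#'
#' Generates a random amplicon at the requested GC content, places a 20 bp
#' protospacer so that the Cas9 cut site falls at the amplicon midpoint, and
#' designs a single-substitution donor `donor_offset` bp right of the cut
#' (a transversion, so an intended edit is never confusable with the
#' reference). Sequences are re-drawn until at least one microhomology-
#' flanked deletion (>= 2 bp exact repeat) spans the cut site, so that MMEJ
#' reads can always be generated. Fully reproducible under `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param length Amplicon length (bp), at least 80. Default 150 (one MiSeq
#'   read).
#' @param gc GC fraction. Default 0.5.
#' @param donor_offset Offset (bp) of the donor substitution right of the
#'   cut. Default 4 (inside the quantification window).
#' @param window_width Quantification-window width passed to the guide.
#'   Default 20.
#' @return List with `amplicon`, `guide`, `edits`, and `mh_deletions` (the
#'   usable microhomology deletions, 0-based half-open intervals).
#' @export
simulate_amplicon <- function(seed, length = 150L, gc = 0.5,
                              donor_offset = 4L, window_width = 20L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  length <- as.integer(length)
  if (length < 80L) stop("amplicon length must be at least 80 bp", call. = FALSE)
  cut <- length %/% 2L
  proto_start <- cut + 3L - 20L  # 20 bp protospacer, PAM-proximal end at cut+3
  if (proto_start < 20L || cut + 3L > length - 20L) {
    stop("guide does not fit with 20 bp flanks", call. = FALSE)
  }
  set.seed(seed)
  for (attempt in 1:100) {
    seq <- .random_dna(length, gc)
    guide <- guide_spec(proto_start, cut + 3L, strand = "+",
                        cut_offset = -3L, window_width = window_width)
    win <- quant_window(guide, length)
    cands <- .find_mh_deletions(seq, cut, win)
    if (base::length(cands) > 0L) {
      amp <- amplicon(sprintf("sim_amplicon_%d", seed), seq)
      pos <- cut + donor_offset
      ref_base <- substring(seq, pos + 1L, pos + 1L)
      edits <- edit_spec(pos, ref_base, .transversion[[ref_base]], seq)
      return(list(amplicon = amp, guide = guide, edits = edits,
                  mh_deletions = cands))
    }
  }
  stop("could not generate an amplicon with a microhomology pair near the cut",
       call. = FALSE)
}

.apply_deletion <- function(sequence, s, e) {
  paste0(substring(sequence, 1L, s), substring(sequence, e + 1L))
}

.apply_insertion <- function(sequence, p, ins) {
  paste0(substring(sequence, 1L, p), ins, substring(sequence, p + 1L))
}

# NHEJ deletion alleles: short deletions spanning the cut whose canonical
# placement has junction microhomology < 2 (rejection sampling) and still
# overlaps the window.
.nhej_del_alleles <- function(sequence, cut, win, n_alleles = 6L,
                              max_len = 8L, max_tries = 400L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  found <- list()
  for (i in seq_len(max_tries)) {
    len <- sample.int(max_len, 1L)
    s <- cut - sample.int(len, 1L)  # spans the cut: s < cut <= s + len
    e <- s + len
    if (s < 0L || e > length(chars)) next
    se <- .left_shift_del(chars, s, e)
    if (se[1] >= win[2] || se[2] <= win[1]) next
    if (microhomology_length(sequence, se[1], se[2]) >= 2L) next
    key <- paste(se, collapse = "-")
    if (!key %in% names(found)) found[[key]] <- se
    if (length(found) >= n_alleles) break
  }
  if (length(found) == 0L) {
    stop("could not sample an NHEJ deletion with microhomology < 2",
         call. = FALSE)
  }
  unname(found)
}

#' Simulate amplicon reads with known repair-pathway labels
#'
#' Draws reads from a multinomial mixture over generative outcome kinds and
#' reports the ground truth per read:
#'
#' * `unmodified`: the reference;
#' * `hdr`: the donor-edited sequence;
#' * `nhej_ins`: a 1 bp insertion at the cut (the inserted base differs from
#'   the base left of the cut so the insertion cannot left-shift);
#' * `nhej_del`: a short deletion spanning the cut, rejection-sampled to a
#'   junction microhomology below 2 bp;
#' * `mmej_del`: a deletion between two copies of a >= 2 bp repeat flanking
#'   the cut, leaving one copy (junction microhomology >= 2 bp);
#' * `mix`: donor substitution plus a 1 bp insertion at the cut.
#'
#' Per-base substitution errors are applied last at `error_rate`. Everything
#' is reproducible under `seed`.
#'
#' @param sim A design from [simulate_amplicon()] (or a list with
#'   `amplicon`, `guide`, `edits`, `mh_deletions`).
#' @param n_reads Number of reads. Default 1000.
#' @param mixture Named probabilities over
#'   `unmodified`/`hdr`/`nhej_ins`/`nhej_del`/`mmej_del`/`mix`; must sum
#'   to 1.
#' @param error_rate Per-base substitution error rate. Default 0.
#' @param seed Integer seed (mandatory).
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame `read_id`, `generative_kind`, `category` -- the expected
#'   classifier label -- and `allele`).
#' @export
simulate_reads <- function(sim, n_reads = 1000L,
                           mixture = c(unmodified = 0.3, hdr = 0.1,
                                       nhej_ins = 0.25, nhej_del = 0.2,
                                       mmej_del = 0.1, mix = 0.05),
                           error_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  kinds <- c("unmodified", "hdr", "nhej_ins", "nhej_del", "mmej_del", "mix")
  if (!setequal(names(mixture), kinds) ||
      abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    stop("mixture must be probabilities over ", paste(kinds, collapse = "/"),
         " summing to 1", call. = FALSE)
  }
  mixture <- mixture[kinds]
  stopifnot(error_rate >= 0, error_rate < 1)
  amp <- sim$amplicon; guide <- sim$guide; edits <- sim$edits
  ref <- amp$sequence
  cut <- cut_site(guide)
  win <- quant_window(guide, amp$length)

  set.seed(seed)

  # allele pool per generative kind
  left_base <- substring(ref, cut, cut)
  ins_base <- sample(setdiff(c("A", "C", "G", "T"), left_base), 1L)
  nhej_dels <- .nhej_del_alleles(ref, cut, win)
  mmej_dels <- sim$mh_deletions
  if (is.null(mmej_dels) || length(mmej_dels) == 0L) {
    mmej_dels <- .find_mh_deletions(ref, cut, win)
  }
  mmej_dels <- mmej_dels[seq_len(min(3L, length(mmej_dels)))]

  alleles <- list(
    unmodified = list(ref),
    hdr = list(edits$expected_hdr_sequence),
    nhej_ins = list(.apply_insertion(ref, cut, ins_base)),
    nhej_del = lapply(nhej_dels, function(se) .apply_deletion(ref, se[1], se[2])),
    mmej_del = lapply(mmej_dels, function(se) .apply_deletion(ref, se[1], se[2])),
    mix = list(.apply_insertion(edits$expected_hdr_sequence, cut, ins_base))
  )
  category_of <- c(unmodified = "unmodified", hdr = "hdr", nhej_ins = "nhej",
                   nhej_del = "nhej", mmej_del = "mmej", mix = "mix")

  kind_draw <- sample(kinds, n_reads, replace = TRUE, prob = mixture)
  reads <- character(n_reads)
  allele_id <- integer(n_reads)
  for (k in kinds) {
    idx <- which(kind_draw == k)
    if (length(idx) == 0L) next
    which_allele <- sample.int(length(alleles[[k]]), length(idx), replace = TRUE)
    reads[idx] <- unlist(alleles[[k]])[which_allele]
    allele_id[idx] <- which_allele
  }

  if (error_rate > 0) {
    widths <- nchar(reads)
    n_err <- stats::rbinom(n_reads, widths, error_rate)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(widths[i], n_err[i])
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      reads[i] <- paste(chars, collapse = "")
    }
  }

  ids <- sprintf("read_%06d", seq_len(n_reads))
  names(reads) <- ids
  truth <- data.frame(read_id = ids,
                      generative_kind = kind_draw,
                      category = unname(category_of[kind_draw]),
                      allele = paste0(kind_draw, "_", allele_id),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

.sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

.screen_classes <- c(
  hdr_enhancer = "cholinergic_receptor", hdr_inhibitor = "nucleoside_analog",
  nhej_enhancer = "adrenergic_receptor", nhej_inhibitor = "dna_pk_kinase",
  mmej_enhancer = "sodium_potassium_pump", mmej_inhibitor = "parp",
  survival_enhancer = "fatty_acid"
)
.other_classes <- c("topoisomerase", "gpcr", "ion_channel", "nuclear_receptor",
                    "transporter", "protease", "phosphodiesterase",
                    "histamine_receptor", "cox", "unclassified_enzyme")

#' Simulate a drug-repurposing screen with planted effects
#'
#' Generates the condition table, blank-well table, drug annotation table,
#' and ground truth for a whole screen at metric level (outcome shares are
#' drawn directly rather than via per-read simulation, which keeps large
#' screens fast; read-level data for single samples come from
#' [simulate_reads()]).
#'
#' The drug library has four strata. *Planted* drugs (`n_per_category` per
#' hit category) carry a clean `effect_fold` change of their defining
#' metric(s). *Null* drugs (fraction `frac_null`) are inert: only
#' measurement noise. The remaining *background* drugs model the real
#' heterogeneity of a bioactive library: per-metric lognormal drug effects
#' (`background_sdlog`), a `toxic_frac` subset with strong survival loss
#' (editing metrics co-reduced, read counts scaled down so deep toxicity
#' trips the depth filter). Outcome shares get multiplicative lognormal
#' measurement noise (`noise_cv`); read counts are Poisson around
#' `reads_mean` times survival; fluorescence is blank plus gain times
#' survival plus gaussian noise.
#'
#' With several `concentrations`, drug log-effects scale linearly with
#' concentration relative to the highest one.
#'
#' @param n_drugs Number of drugs. Default 200.
#' @param concentrations Concentrations (µM) at which every drug is tested.
#'   Default 10 (single-dose screen).
#' @param n_per_category Planted drugs per hit category. Default 4.
#' @param effect_fold Planted fold-change. Default 2.
#' @param frac_null Fraction of inert null drugs. Default 0.1.
#' @param background_sdlog Lognormal sd of background drug effects.
#'   Default 0.6.
#' @param toxic_frac Fraction of background drugs that are strongly toxic.
#'   Default 0.1.
#' @param noise_cv Multiplicative measurement noise CV. Default 0.1.
#' @param baseline Named baseline outcome shares (percent) for
#'   `hdr`/`nhej`/`mmej`/`mix`; the unmodified share is the remainder.
#' @param reads_mean Mean retained reads of a healthy condition.
#'   Default 15000.
#' @param wells_per_plate Drug wells per plate. Default 88.
#' @param mocks_per_plate Mock (DMSO) wells per plate. Default 4.
#' @param blanks_per_plate Cell-free blank wells per plate. Default 4.
#' @param fluor_blank,fluor_gain,fluor_sd Fluorescence model: blank level,
#'   gain per unit survival, additive gaussian noise sd.
#' @param seed Integer seed (mandatory).
#' @return List with `conditions`, `blanks`, `annotation` (data frames in
#'   the formats of [read_conditions()] / [read_annotation()]) and `truth`
#'   (list of `drugs` and `conditions` ground-truth data frames).
#' @export
simulate_screen <- function(n_drugs = 200L, concentrations = 10,
                            n_per_category = 4L, effect_fold = 2,
                            frac_null = 0.1, background_sdlog = 0.6,
                            toxic_frac = 0.1, noise_cv = 0.1,
                            baseline = c(hdr = 10, nhej = 30, mmej = 8,
                                         mix = 4),
                            reads_mean = 15000, wells_per_plate = 88L,
                            mocks_per_plate = 4L, blanks_per_plate = 4L,
                            fluor_blank = 2000, fluor_gain = 28000,
                            fluor_sd = 300, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_drugs >= 1L, all(concentrations > 0), mocks_per_plate >= 1L,
            noise_cv >= 0, sum(baseline) < 100)
  categories <- names(.screen_classes)
  n_planted <- length(categories) * n_per_category
  n_null <- round(frac_null * n_drugs)
  if (n_planted + n_null > n_drugs) {
    stop("n_drugs too small for the requested planted and null strata",
         call. = FALSE)
  }
  set.seed(seed)

  drugs <- sprintf("drug_%04d", seq_len(n_drugs))
  strata <- c(rep(categories, each = n_per_category),
              rep("null", n_null),
              rep("background", n_drugs - n_planted - n_null))
  strata <- sample(strata)  # shuffle assignment over drug ids

  eff <- matrix(1, n_drugs, 4,
                dimnames = list(drugs, c("hdr", "nhej", "mmej", "survival")))
  toxic <- rep(FALSE, n_drugs)
  for (i in seq_len(n_drugs)) {
    st <- strata[i]
    if (st == "null") next
    if (st == "background") {
      eff[i, ] <- stats::rlnorm(4, 0, background_sdlog)
      if (stats::runif(1) < toxic_frac) {
        toxic[i] <- TRUE
        surv <- stats::runif(1, 0.02, 0.5)
        eff[i, "survival"] <- surv
        eff[i, c("hdr", "nhej", "mmej")] <-
          eff[i, c("hdr", "nhej", "mmej")] * sqrt(surv)
      }
    } else {
      metric <- sub("_(enhancer|inhibitor)$", "", st)
      fold <- if (grepl("inhibitor$", st)) 1 / effect_fold else effect_fold
      eff[i, metric] <- fold
    }
  }

  truth_drugs <- data.frame(drug = drugs, truth_category = strata,
                            toxic = toxic,
                            hdr_effect = eff[, "hdr"],
                            nhej_effect = eff[, "nhej"],
                            mmej_effect = eff[, "mmej"],
                            survival_effect = eff[, "survival"],
                            stringsAsFactors = FALSE)

  # plate layout: conditions filled plate by plate, mocks/blanks per plate
  cond_grid <- expand.grid(drug = drugs, concentration_um = concentrations,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cond <- nrow(cond_grid)
  plate_of <- (seq_len(n_cond) - 1L) %/% wells_per_plate + 1L
  n_plates <- max(plate_of)
  sdlog <- .sdlog_from_cv(noise_cv)
  cmax <- max(concentrations)
  base_vec <- baseline[c("hdr", "nhej", "mmej", "mix")]

  rows <- vector("list", n_cond + n_plates * mocks_per_plate)
  truth_cond <- vector("list", n_cond)
  r <- 0L
  for (i in seq_len(n_cond)) {
    d <- cond_grid$drug[i]; conc <- cond_grid$concentration_um[i]
    scale_c <- conc / cmax
    e <- eff[d, ]^scale_c          # log-effects scale with concentration
    surv_true <- e[["survival"]]
    pct <- c(base_vec[c("hdr", "nhej", "mmej")] *
               e[c("hdr", "nhej", "mmej")], base_vec["mix"])
    pct <- pct * stats::rlnorm(4, 0, sdlog)
    if (sum(pct) > 98) pct <- pct * 98 / sum(pct)  # shares saturate
    surv_obs <- surv_true * stats::rlnorm(1, 0, sdlog)
    reads <- stats::rpois(1, reads_mean * max(0, surv_true))
    fluor <- fluor_blank + fluor_gain * surv_obs + stats::rnorm(1, 0, fluor_sd)
    r <- r + 1L
    rows[[r]] <- data.frame(
      drug = d, concentration_um = conc,
      plate = sprintf("plate_%02d", plate_of[i]),
      well = sprintf("w%03d", (i - 1L) %% wells_per_plate + 1L),
      reads = reads,
      hdr_pct = pct[[1]], nhej_pct = pct[[2]], mmej_pct = pct[[3]],
      mix_pct = pct[[4]],
      fluorescence = fluor, is_mock = FALSE, stringsAsFactors = FALSE)
    truth_cond[[i]] <- data.frame(
      drug = d, concentration_um = conc,
      truth_category = strata[match(d, drugs)],
      expected_rel_hdr = e[["hdr"]], expected_rel_nhej = e[["nhej"]],
      expected_rel_mmej = e[["mmej"]], expected_rel_survival = surv_true,
      stringsAsFactors = FALSE)
  }
  for (pl in seq_len(n_plates)) {
    for (m in seq_len(mocks_per_plate)) {
      pct <- base_vec * stats::rlnorm(4, 0, sdlog)
      surv_obs <- stats::rlnorm(1, 0, sdlog)
      r <- r + 1L
      rows[[r]] <- data.frame(
        drug = "DMSO", concentration_um = 0,
        plate = sprintf("plate_%02d", pl),
        well = sprintf("mock%02d", m),
        reads = stats::rpois(1, reads_mean),
        hdr_pct = pct[[1]], nhej_pct = pct[[2]], mmej_pct = pct[[3]],
        mix_pct = pct[[4]],
        fluorescence = fluor_blank + fluor_gain * surv_obs +
          stats::rnorm(1, 0, fluor_sd),
        is_mock = TRUE, stringsAsFactors = FALSE)
    }
  }
  conditions <- do.call(rbind, rows)
  rownames(conditions) <- NULL

  blanks <- do.call(rbind, lapply(seq_len(n_plates), function(pl) {
    data.frame(plate = sprintf("plate_%02d", pl),
               well = sprintf("blank%02d", seq_len(blanks_per_plate)),
               fluorescence = fluor_blank +
                 stats::rnorm(blanks_per_plate, 0, fluor_sd / 5),
               stringsAsFactors = FALSE)
  }))

  ann <- lapply(seq_len(n_drugs), function(i) {
    st <- strata[i]
    cls <- if (st %in% categories) {
      unique(c(.screen_classes[[st]], sample(.other_classes, 1L)))
    } else {
      sample(c(.other_classes, unname(.screen_classes)),
             sample.int(2L, 1L))
    }
    data.frame(drug = drugs[i], target_class = cls, stringsAsFactors = FALSE)
  })
  annotation <- do.call(rbind, ann)

  list(conditions = conditions, blanks = blanks, annotation = annotation,
       truth = list(drugs = truth_drugs,
                    conditions = do.call(rbind, truth_cond)))
}
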