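#' Relative survival from resazurin fluorescence
#'
#' Resorufin fluorescence reflects the number of living cells; the surviving
#' fraction of a well is its blank-corrected fluorescence divided by the
#' blank-corrected mean of the mock wells:
#' `(sample - blank) / (mock - blank)`. Values above 1 (more cells than
#' mock) are allowed; values below 0 are clamped to 0 and flagged.
#'
#' @param sample_f Sample fluorescence (vectorized).
#' @param mock_f_mean Mean fluorescence of the mock wells.
#' @param blank_f_mean Mean fluorescence of cell-free blank wells.
#' @return Surviving fractions; attribute `clamped` marks entries clamped at
#'   0.
#' @export
relative_survival <- function(sample_f, mock_f_mean, blank_f_mean = 0) {
  stopifnot(length(mock_f_mean) == 1L, length(blank_f_mean) == 1L)
  if (!is.finite(mock_f_mean) || !is.finite(blank_f_mean) ||
      mock_f_mean <= blank_f_mean) {
    stop("plate failure: mock fluorescence must exceed blank fluorescence",
         call. = FALSE)
  }
  s <- (sample_f - blank_f_mean) / (mock_f_mean - blank_f_mean)
  clamped <- is.finite(s) & s < 0
  s[clamped] <- 0
  attr(s, "clamped") <- clamped
  s
}

.s4pl <- function(conc, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the sigmoidal surviving-fraction model
#' `S(c) = bottom + (top - bottom) / (1 + (c / ec50)^h)` by
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) in log-concentration space
#' (the model is parameterized by `log(ec50)`). Five starts are taken with
#' `log(ec50)` initialized on a grid spanning the dose range, and the
#' converged fit with the smallest residual sum of squares is kept. Bounds
#' stabilize the fit: `0 <= bottom`, `top <= top_max` (default 1.5),
#' `0.2 <= h <= 10`. Data whose survival range is below `flat_tol` are
#' flagged degenerate and not fitted.
#'
#' @param dose Concentrations (µM), all positive, at least 4 distinct
#'   levels (replicates welcome).
#' @param survival Surviving fractions, same length as `dose`.
#' @param top_max Upper bound for the fitted top asymptote. Default 1.5.
#' @param flat_tol Minimal survival range for a non-degenerate fit.
#'   Default 0.05.
#' @param n_starts Number of `log(ec50)` grid starts. Default 5.
#' @return A list of class `dose_response_fit`: `top`, `bottom`, `ec50`,
#'   `hill`, `residual_sd`, `converged`, `degenerate`, `data`.
#' @export
fit_dose_response <- function(dose, survival, top_max = 1.5, flat_tol = 0.05,
                              n_starts = 5) {
  stopifnot(length(dose) == length(survival))
  ok <- is.finite(dose) & is.finite(survival)
  dose <- dose[ok]; survival <- survival[ok]
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(unique(dose)) < 4L) {
    stop("need at least 4 distinct dose levels", call. = FALSE)
  }

  base <- list(top = NA_real_, bottom = NA_real_, ec50 = NA_real_,
               hill = NA_real_, residual_sd = NA_real_, converged = FALSE,
               degenerate = FALSE,
               data = data.frame(dose = dose, survival = survival))
  if (diff(range(survival)) < flat_tol) {
    base$degenerate <- TRUE
    base$top <- mean(survival); base$bottom <- mean(survival)
    return(structure(base, class = "dose_response_fit"))
  }

  df <- data.frame(lc = log(dose), s = survival)
  starts_lec <- seq(min(df$lc), max(df$lc), length.out = n_starts)
  top0 <- max(survival); bot0 <- min(survival)

  best <- NULL; best_rss <- Inf
  for (lec in starts_lec) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        s ~ bottom + (top - bottom) / (1 + exp(hill * (lc - lec50))),
        data = df,
        start = list(top = top0, bottom = bot0, lec50 = lec, hill = 1),
        lower = c(top = 0, bottom = 0, lec50 = min(df$lc) - 10, hill = 0.2),
        upper = c(top = top_max, bottom = top_max, lec50 = max(df$lc) + 10,
                  hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) {
    stop("dose-response fit failed to converge from any start; ",
         "inspect the data (n = ", length(dose), ", survival range ",
         sprintf("%.3f-%.3f", min(survival), max(survival)), ")",
         call. = FALSE)
  }
  cf <- stats::coef(best)
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  if (bottom > top) {  # reparameterize so bottom <= top (curve is the same
    # family with negative slope; keep the conventional orientation)
    tmp <- top; top <- bottom; bottom <- tmp
    cf["hill"] <- -cf["hill"]
  }
  out <- base
  out$top <- top; out$bottom <- bottom
  out$ec50 <- exp(unname(cf["lec50"]))
  out$hill <- unname(cf["hill"])
  out$residual_sd <- sqrt(best_rss / max(1L, length(dose) - 4L))
  out$converged <- TRUE
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate dose-response (flat survival near ",
        sprintf("%.2f", x$top), ")\n", sep = "")
  } else {
    cat(sprintf("4PL fit: top %.3f, bottom %.3f, EC50 %.4g uM, hill %.2f (residual sd %.3g)\n",
                x$top, x$bottom, x$ec50, x$hill, x$residual_sd))
  }
  invisible(x)
}

#' Predicted survival from a dose-response fit
#'
#' @param fit A `dose_response_fit`.
#' @param conc Concentrations (µM).
#' @return Predicted surviving fractions.
#' @export
predict_survival <- function(fit, conc) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$degenerate) return(rep(fit$top, length(conc)))
  .s4pl(conc, fit$top, fit$bottom, fit$ec50, fit$hill)
}

#' Effective concentration for a given fraction of cell death
#'
#' Solves the fitted 4PL analytically for the concentration at which the
#' predicted surviving fraction equals `1 - death_fraction`. The EC75 of the
#' screen (`death_fraction = 0.25`) is the concentration inducing 25% cell
#' death, i.e. an absolute surviving fraction of 0.75 relative to mock --
#' not 75% of the fitted span.
#'
#' @param fit A converged `dose_response_fit`.
#' @param death_fraction Fraction of cell death, in (0, 1). Default 0.25
#'   (EC75).
#' @return Concentration (µM).
#' @examples
#' \dontrun{ec_x(fit, 0.25)  # EC75}
#' @export
ec_x <- function(fit, death_fraction = 0.25) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$degenerate || !fit$converged) {
    stop("cannot invert a degenerate or unconverged fit", call. = FALSE)
  }
  stopifnot(death_fraction > 0, death_fraction < 1)
  s_target <- 1 - death_fraction
  if (s_target <= fit$bottom || s_target >= fit$top) {
    stop(sprintf(
      "target surviving fraction %.3f is outside the fitted asymptote range (%.3f, %.3f)",
      s_target, fit$bottom, fit$top), call. = FALSE)
  }
  fit$ec50 * ((fit$top - fit$bottom) / (s_target - fit$bottom) - 1)^(1 / fit$hill)
}

#' Genotype survival contrast for synthetic-lethality calls
#'
#' Compares the survival of a repair-deficient genotype against its control
#' across a shared dose grid and flags synthetic lethality: doses where the
#' control is essentially unaffected (survival within `control_tol` of 1)
#' while the deficient genotype drops below `lethal_threshold`.
#'
#' @param control,mutant Either `dose_response_fit` objects (evaluated on
#'   `doses`) or data frames with `dose` and `survival` columns (matched on
#'   dose).
#' @param doses Dose grid (µM); required when both inputs are fits,
#'   otherwise defaults to the shared doses of the tables.
#' @param control_tol Tolerance around 1 for "control unaffected".
#'   Default 0.15.
#' @param lethal_threshold Survival ratio below which the deficient genotype
#'   is called synthetically lethal. Default 0.7.
#' @return Data frame `dose`, `control_survival`, `mutant_survival`,
#'   `ratio`, `synthetic_lethal`; the ratio is `NA` where control survival
#'   is 0. Attribute `any_lethal` summarizes the flag.
#' @export
synthetic_lethality_contrast <- function(control, mutant, doses = NULL,
                                         control_tol = 0.15,
                                         lethal_threshold = 0.7) {
  surv_at <- function(obj, d) {
    if (inherits(obj, "dose_response_fit")) return(predict_survival(obj, d))
    .require_columns(obj, c("dose", "survival"), "survival table")
    idx <- match(d, obj$dose)
    if (anyNA(idx)) stop("non-overlapping dose grids", call. = FALSE)
    obj$survival[idx]
  }
  if (is.null(doses)) {
    if (is.data.frame(control) && is.data.frame(mutant)) {
      doses <- sort(intersect(control$dose, mutant$dose))
      if (length(doses) == 0L) stop("non-overlapping dose grids", call. = FALSE)
    } else {
      stop("doses must be given when using fitted curves", call. = FALSE)
    }
  }
  cs <- surv_at(control, doses)
  ms <- surv_at(mutant, doses)
  ratio <- ifelse(cs > 0, ms / cs, NA_real_)
  flag <- !is.na(ratio) & abs(cs - 1) <= control_tol & ratio < lethal_threshold
  out <- data.frame(dose = doses, control_survival = cs, mutant_survival = ms,
                    ratio = ratio, synthetic_lethal = flag)
  attr(out, "any_lethal") <- any(flag)
  out
}
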