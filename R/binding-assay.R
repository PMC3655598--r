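#' Competition-binding dilution series
#'
#' One series = one (test peptide, HLA allele) pair: the unlabelled test
#' peptide is titrated against a biotinylated reference peptide held at a
#' fixed concentration, and the reference's binding signal (time-resolved
#' fluorescence units) is read at each test concentration. Replicate wells
#' are allowed (repeat the concentration).
#'
#' @param peptide_id,allele_id Identifiers.
#' @param concentrations Test-peptide concentrations in uM, strictly
#'   positive, at least 4 distinct levels.
#' @param signals Nonnegative signals, one per concentration entry.
#' @param reference_conc Fixed reference-peptide concentration in uM
#'   (0.1-1 uM depending on the HLA; optional metadata).
#' @return An object of class `competition_series`.
#' @export
competition_series <- function(peptide_id, allele_id, concentrations,
                               signals, reference_conc = NA_real_) {
  concentrations <- as.numeric(concentrations)
  signals <- as.numeric(signals)
  if (length(concentrations) != length(signals))
    stop("concentrations and signals must have the same length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must be strictly positive")
  if (any(!is.finite(signals)) || any(signals < 0))
    stop("signals must be nonnegative")
  if (length(unique(concentrations)) < 4L)
    stop("at least 4 distinct concentration levels are required for a fit")
  structure(list(peptide_id = as.character(peptide_id),
                 allele_id = as.character(allele_id),
                 concentrations = concentrations,
                 signals = signals,
                 reference_conc = reference_conc),
            class = "competition_series")
}

fourpl_value <- function(conc, top, bottom, hill, midpoint) {
  bottom + (top - bottom) / (1 + (conc / midpoint)^hill)
}

#' Fit a four-parameter logistic inhibition curve
#'
#' Least-squares fit of
#' `signal = bottom + (top - bottom) / (1 + (conc/midpoint)^hill)`
#' on the dilution series, with a multi-start initialization grid
#' (midpoint at every tested concentration, hill in 0.5/1/2) and the best
#' converged start kept by residual sum of squares. Replicate wells enter
#' the fit as pooled residuals. A series with essentially no signal span
#' (no inhibition) is returned as a degenerate flat fit rather than an
#' error, so that downstream censoring can classify it as a non-binder.
#'
#' @param series A [competition_series()].
#' @param control `nls.lm` control; default tightens the relative
#'   convergence tolerance to 1e-10.
#' @return An object of class `fourpl_fit` with elements `top`, `bottom`,
#'   `hill`, `midpoint`, `converged`, `flat`, `residual_sd`,
#'   `se_log_midpoint`, `n`, `conc_range`, and the underlying `model`
#'   (NULL for flat/degenerate fits).
#' @export
fit_4pl <- function(series,
                    control = minpack.lm::nls.lm.control(
                      ftol = 1e-10, ptol = 1e-10, maxiter = 200)) {
  if (!inherits(series, "competition_series"))
    stop("series must be a 'competition_series'")
  conc <- series$concentrations
  sig <- series$signals
  n <- length(sig)
  span <- diff(range(sig))
  mid_grid <- sort(unique(conc))
  hill_grid <- c(0.5, 1, 2)

  flat_fit <- function() {
    m <- mean(sig)
    structure(list(peptide_id = series$peptide_id,
                   allele_id = series$allele_id,
                   top = m, bottom = m, hill = NA_real_,
                   midpoint = NA_real_, converged = TRUE, flat = TRUE,
                   residual_sd = if (n > 1) sd(sig) else 0,
                   se_log_midpoint = NA_real_, n = n,
                   conc_range = range(conc), model = NULL),
              class = "fourpl_fit")
  }
  # no usable signal span: flat series
  if (span <= .Machine$double.eps^0.5 * max(abs(sig), 1)) return(flat_fit())

  dat <- data.frame(conc = conc, sig = sig)
  best <- NULL; best_rss <- Inf
  for (m0 in mid_grid) for (h0 in hill_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        sig ~ bottom + (top - bottom) / (1 + exp(hill * (log(conc) - lmid))),
        data = dat,
        start = list(top = max(sig), bottom = min(sig),
                     hill = h0, lmid = log(m0)),
        lower = c(top = -Inf, bottom = -Inf, hill = 1e-3,
                  lmid = log(min(conc)) - 25),
        upper = c(top = Inf, bottom = Inf, hill = 50,
                  lmid = log(max(conc)) + 25),
        control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (!is.finite(rss)) next
    if (rss < best_rss) {
      best_rss <- rss; best <- fit
    }
  }
  if (is.null(best)) {
    # non-convergence from every start: report honestly, no silent fallback
    return(structure(list(peptide_id = series$peptide_id,
                          allele_id = series$allele_id,
                          top = NA_real_, bottom = NA_real_,
                          hill = NA_real_, midpoint = NA_real_,
                          converged = FALSE, flat = FALSE,
                          residual_sd = NA_real_,
                          se_log_midpoint = NA_real_, n = n,
                          conc_range = range(conc), model = NULL),
                     class = "fourpl_fit"))
  }
  cf <- coef(best)
  se_lmid <- tryCatch(sqrt(diag(vcov(best)))[["lmid"]],
                      error = function(e) NA_real_)
  structure(list(peptide_id = series$peptide_id,
                 allele_id = series$allele_id,
                 top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 hill = unname(cf["hill"]),
                 midpoint = exp(unname(cf["lmid"])),
                 converged = TRUE, flat = FALSE,
                 residual_sd = sqrt(best_rss / max(n - 4L, 1L)),
                 se_log_midpoint = se_lmid, n = n,
                 conc_range = range(conc), model = best),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> %s / %s\n", x$peptide_id, x$allele_id))
  if (!x$converged) {
    cat("  NOT converged\n"); return(invisible(x))
  }
  if (x$flat) {
    cat(sprintf("  flat series (signal ~ %.3g); no inhibition detected\n",
                x$top))
  } else {
    cat(sprintf("  top %.3g  bottom %.3g  hill %.3g  midpoint %.3g uM  (resid sd %.3g)\n",
                x$top, x$bottom, x$hill, x$midpoint, x$residual_sd))
  }
  invisible(x)
}

#' Extract IC50 (or a censor code) from a 4PL fit
#'
#' The IC50 is the test-peptide concentration producing 50% inhibition,
#' i.e. the concentration at which the predicted signal is halfway between
#' the fitted asymptotes -- for the symmetric 4PL this is the fitted
#' midpoint. It is reported as a number only when it lies inside the tested
#' concentration range; otherwise it is censored: `"NB"` when the fitted
#' span is indistinguishable from noise (top - bottom < 3 residual SDs, no
#' detectable inhibition), `"> max"` when 50% inhibition was not reached at
#' the highest tested concentration, `"< min"` when it lies below the
#' lowest.
#'
#' @param fit A converged [fit_4pl()] result.
#' @param series The [competition_series()] that was fitted (for the tested
#'   range; defaults to the range recorded in the fit).
#' @return A list of class `ic50_estimate` with `value` (uM or NA),
#'   `censor` (`"none"`, `"nb"`, `"gt_max"`, `"lt_min"`), and a printable
#'   `label` (e.g. `"95.8"`, `"NB"`, `"> 100"`).
#' @export
ic50_from_fit <- function(fit, series = NULL) {
  if (!inherits(fit, "fourpl_fit")) stop("fit must be a 'fourpl_fit'")
  if (!fit$converged) stop("cannot extract an IC50 from a non-converged fit")
  rng <- if (!is.null(series)) range(series$concentrations) else fit$conc_range
  mk <- function(value, censor, label)
    structure(list(value = value, censor = censor, label = label),
              class = "ic50_estimate")
  span <- fit$top - fit$bottom
  if (fit$flat || !is.finite(span) || span <= 3 * fit$residual_sd)
    return(mk(NA_real_, "nb", "NB"))
  ic50 <- fit$midpoint
  if (ic50 > rng[2])
    return(mk(NA_real_, "gt_max", sprintf("> %g", rng[2])))
  if (ic50 < rng[1])
    return(mk(NA_real_, "lt_min", sprintf("< %g", rng[1])))
  mk(ic50, "none", sprintf("%.3g", ic50))
}

#' @export
print.ic50_estimate <- function(x, ...) {
  cat("<ic50_estimate>", x$label, "uM\n"); invisible(x)
}

#' Classify HLA binding affinity from an IC50
#'
#' High affinity: IC50 < 25 uM; weak: IC50 > 50 uM; the unlabeled 25-50 uM
#' band is reported as moderate; censored non-binders as `"non-binder"`.
#' Accepts numbers, [ic50_from_fit()] results, or the printed censor
#' vocabulary (`"NB"`, `"<5"`, `">50"`, ...). A censored bound that cannot
#' be resolved to a single class (e.g. `"<40"`) returns NA with a warning.
#'
#' @param ic50 Numeric vector, character vector, or a single
#'   `ic50_estimate`.
#' @param high_max,weak_min Class boundaries in uM (defaults 25 and 50).
#' @return Character vector in
#'   `c("high", "moderate", "weak", "non-binder")` (NA where unresolvable).
#' @export
classify_affinity <- function(ic50, high_max = AFFINITY_HIGH_MAX,
                              weak_min = AFFINITY_WEAK_MIN) {
  if (inherits(ic50, "ic50_estimate"))
    ic50 <- if (ic50$censor == "none") ic50$value else ic50$label
  one <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (is.numeric(x)) {
      if (x < 0) stop("IC50 must be nonnegative")
      return(if (x < high_max) "high"
             else if (x <= weak_min) "moderate" else "weak")
    }
    s <- gsub("\\s", "", toupper(as.character(x)))
    if (s %in% c("NB", "NON-BINDER", "NONBINDER")) return("non-binder")
    if (grepl("^<", s)) {
      bound <- as.numeric(sub("^<", "", s))
      if (is.na(bound) || bound < 0) stop("unparseable IC50 value: ", x)
      if (bound <= high_max) return("high")
      warning("censored value '", x, "' spans multiple affinity classes")
      return(NA_character_)
    }
    if (grepl("^>", s)) {
      bound <- as.numeric(sub("^>", "", s))
      if (is.na(bound) || bound < 0) stop("unparseable IC50 value: ", x)
      if (bound >= weak_min) return("weak")
      warning("censored value '", x, "' spans multiple affinity classes")
      return(NA_character_)
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("unparseable IC50 value: ", x)
    one(v)
  }
  vapply(ic50, one, character(1), USE.NAMES = FALSE)
}

#' Concordance between predicted and measured binding
#'
#' Cross-tabulates predicted binder status against measured affinity
#' classes: a measured binder is any class other than `"non-binder"`
#' (high, moderate, or weak).
#'
#' @param predicted_binder Logical vector of in-silico binder predictions.
#' @param measured_class Character vector of measured classes (as from
#'   [classify_affinity()]), same length.
#' @return A list with `tp`, `fp`, `tn`, `fn`, `n`, and `accuracy`
#'   (= (tp + tn) / n).
#' @export
concordance_table <- function(predicted_binder, measured_class) {
  if (length(predicted_binder) != length(measured_class))
    stop("predicted and measured vectors must have the same length")
  predicted_binder <- as.logical(predicted_binder)
  bound <- measured_class != "non-binder"
  tp <- sum(predicted_binder & bound)
  fp <- sum(predicted_binder & !bound)
  tn <- sum(!predicted_binder & !bound)
  fn <- sum(!predicted_binder & bound)
  n <- length(predicted_binder)
  list(tp = tp, fp = fp, tn = tn, fn = fn, n = n, accuracy = (tp + tn) / n)
}

#' Read competition-binding series from a long TSV
#'
#' Columns: `peptide_id`, `allele_id`, `concentration_uM`, `signal`, and
#' optionally `replicate`.
#'
#' @param path TSV path.
#' @return A list of [competition_series()], one per peptide/allele pair.
#' @export
read_competition_series <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "allele_id", "concentration_uM", "signal")
  if (!all(need %in% names(tab)))
    stop("competition table must have columns: ",
         paste(need, collapse = ", "))
  key <- paste(tab$peptide_id, tab$allele_id, sep = " / ")
  lapply(split(tab, key), function(d)
    competition_series(d$peptide_id[1], d$allele_id[1],
                       d$concentration_uM, d$signal))
}
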