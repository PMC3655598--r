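#' Spot-forming cells per million PBMC over background
#'
#' Normalizes an ELISpot triplicate to the field's standard reporting scale:
#' `(mean(test wells) - mean(background wells)) * 1e6 / cells_per_well`.
#' May be negative when the stimulus wells fall below background.
#'
#' @param spot_counts Numeric spot counts of the test wells (usually a
#'   triplicate).
#' @param cells_per_well Cells plated per well (2e5-2.5e5 in the assay
#'   protocol); must be positive.
#' @param background_mean_counts Mean spot count of the no-stimulus
#'   background wells.
#' @return Single numeric SFC per 10^6 cells over background.
#' @export
sfc_per_million <- function(spot_counts, cells_per_well,
                            background_mean_counts) {
  if (!is.numeric(cells_per_well) || length(cells_per_well) != 1L ||
      is.na(cells_per_well) || cells_per_well <= 0)
    stop("cells_per_well must be a single positive number")
  (mean(spot_counts) - background_mean_counts) * 1e6 / cells_per_well
}

#' ELISpot dual positivity criterion
#'
#' A response is positive when (1) the mean of the triplicate test wells is
#' at least twice the mean of the background wells, and (2) the response is
#' at least `sfc_min` (default 50) spots per million cells over background.
#' When only the normalized summary is available (as in published response
#' tables), criterion (2) alone decides. The threshold is applied
#' inclusively (`>= 50`): the assay methods state "at least 50" even though
#' some table legends print ">50"; no published value sits exactly at 50,
#' so the choice does not affect the packaged fixtures.
#'
#' @param sfc_over_bg SFC per 10^6 cells over background.
#' @param test_mean,background_mean Raw triplicate means; supply both to
#'   enforce the 2x-background rule.
#' @param sfc_min Positivity threshold (default 50).
#' @return Logical.
#' @export
is_positive <- function(sfc_over_bg, test_mean = NULL, background_mean = NULL,
                        sfc_min = POSITIVITY_SFC_DEFAULT) {
  crit2 <- !is.na(sfc_over_bg) & sfc_over_bg >= sfc_min
  if (is.null(test_mean) || is.null(background_mean)) return(crit2)
  crit1 <- test_mean >= 2 * background_mean
  crit1 & crit2
}

#' Tregitope suppression call for one peptide
#'
#' A response counts as suppressed when the SFC with Tregitope is strictly
#' lower than without; equal values are not suppressed.
#'
#' @param sfc_without,sfc_with SFC per 10^6 over background in the two
#'   culture arms.
#' @return Logical (NA when either value is missing -- such pairs are
#'   excluded upstream).
#' @export
is_suppressed <- function(sfc_without, sfc_with) {
  ifelse(is.na(sfc_without) | is.na(sfc_with), NA, sfc_with < sfc_without)
}

#' One-tailed t-test for suppression of a triplicate pair
#'
#' Pooled-variance two-sample Student's t-test of the without-Tregitope
#' triplicate against the with-Tregitope triplicate, one-tailed in the
#' suppression direction (mean with < mean without). When the pooled
#' variance is zero the statistic is undefined; equal means then return
#' p = 0.5 by convention (no evidence either way), and unequal means return
#' 0 or 1 according to direction.
#'
#' @param triplicate_without,triplicate_with Numeric spot counts, at least
#'   2 replicates each.
#' @return One-tailed p-value.
#' @export
suppression_significance <- function(triplicate_without, triplicate_with) {
  x <- as.numeric(triplicate_without); y <- as.numeric(triplicate_with)
  if (length(x) < 2L || length(y) < 2L)
    stop("at least 2 replicates per arm are required")
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) return(0.5)
    return(if (delta > 0) 0 else 1)
  }
  t <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  pt(t, df, lower.tail = FALSE)
}

#' Read an ELISpot table
#'
#' Accepts either the condition-long layout (one row per subject, stimulus
#' and culture arm, with raw triplicates `rep1..rep3` plus
#' `cells_per_well`, or a precomputed `sfc_over_bg`) or the pair-wide
#' layout used by the packaged fixture (`sfc_without` / `sfc_with`).
#'
#' @param path TSV path.
#' @return A data.frame in the layout found in the file.
#' @export
read_elispot <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "stimulus") %in% names(tab)))
    stop("ELISpot table must have subject_id and stimulus columns")
  pairwide <- all(c("sfc_without", "sfc_with") %in% names(tab))
  long <- "condition" %in% names(tab) &&
    (all(c("rep1", "rep2") %in% names(tab)) || "sfc_over_bg" %in% names(tab))
  if (!pairwide && !long)
    stop("ELISpot table must carry either sfc_without/sfc_with pairs or ",
         "condition rows with rep1..rep3 (or sfc_over_bg)")
  tab
}

#' Pair ELISpot records and derive per-pair calls
#'
#' Converts an ELISpot table (either layout accepted by [read_elispot()])
#' into one row per (subject, stimulus) pair with both culture arms,
#' computing normalized SFC from raw triplicates where present (using the
#' subject's no-stimulus background wells of the matching arm), the
#' baseline positivity call, the suppression call, and -- when raw
#' triplicates are available -- the one-tailed suppression p-value.
#' Pairs with a missing arm (ND) are dropped.
#'
#' @param records Data.frame from [read_elispot()] or
#'   [gen_elispot_dataset()]. Background wells in the long layout are rows
#'   with `stimulus_type == "background"`.
#' @param sfc_min Positivity threshold (default 50).
#' @param alpha Significance level used to flag `significant` when a
#'   p-value is computed (default 0.05).
#' @return Data.frame with columns `subject_id`, `cohort`, `stimulus`,
#'   `stimulus_type`, `sfc_without`, `sfc_with`, `positive_baseline`,
#'   `suppressed`, `p_value`, `significant`.
#' @export
elispot_pairs <- function(records, sfc_min = POSITIVITY_SFC_DEFAULT,
                          alpha = 0.05) {
  if (!nrow(records)) stop("no ELISpot records supplied")
  if (!"stimulus_type" %in% names(records))
    records$stimulus_type <- ifelse(
      grepl("pool", records$stimulus, ignore.case = TRUE), "pool",
      ifelse(grepl("protein", records$stimulus, ignore.case = TRUE),
             "protein", "peptide"))
  if (!"cohort" %in% names(records)) records$cohort <- NA_character_

  if (all(c("sfc_without", "sfc_with") %in% names(records))) {
    out <- records[, c("subject_id", "cohort", "stimulus", "stimulus_type",
                       "sfc_without", "sfc_with")]
    out$positive_baseline <- is_positive(out$sfc_without, sfc_min = sfc_min)
    out$suppressed <- is_suppressed(out$sfc_without, out$sfc_with)
    out$p_value <- NA_real_
    out$significant <- if ("significant" %in% names(records))
      as.logical(records$significant) else NA
    out <- out[!is.na(out$sfc_without) & !is.na(out$sfc_with), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  raw_mode <- all(c("rep1", "rep2") %in% names(records))
  rep_cols <- intersect(c("rep1", "rep2", "rep3"), names(records))
  rows <- list()
  for (sid in unique(records$subject_id)) {
    sub <- records[records$subject_id == sid, , drop = FALSE]
    bg_mean <- function(cond) {
      bg <- sub[sub$stimulus_type == "background" & sub$condition == cond, ,
                drop = FALSE]
      if (!nrow(bg)) return(NA_real_)
      mean(unlist(bg[, rep_cols]), na.rm = TRUE)
    }
    bg_wo <- if (raw_mode) bg_mean("without") else NA_real_
    bg_wi <- if (raw_mode) bg_mean("with") else NA_real_
    for (stim in unique(sub$stimulus[sub$stimulus_type != "background"])) {
      d <- sub[sub$stimulus == stim, , drop = FALSE]
      wo <- d[d$condition == "without", , drop = FALSE]
      wi <- d[d$condition == "with", , drop = FALSE]
      if (nrow(wo) != 1L || nrow(wi) != 1L) next
      arm <- function(row, bg) {
        if (raw_mode) {
          reps <- as.numeric(row[, rep_cols])
          reps <- reps[!is.na(reps)]
          if (!length(reps)) return(list(sfc = NA_real_, mean = NA_real_,
                                         reps = NULL))
          list(sfc = sfc_per_million(reps, row$cells_per_well, bg),
               mean = mean(reps), reps = reps)
        } else {
          list(sfc = row$sfc_over_bg, mean = NA_real_, reps = NULL)
        }
      }
      a_wo <- arm(wo, bg_wo); a_wi <- arm(wi, bg_wi)
      if (is.na(a_wo$sfc) || is.na(a_wi$sfc)) next
      p <- if (!is.null(a_wo$reps) && !is.null(a_wi$reps) &&
               length(a_wo$reps) >= 2 && length(a_wi$reps) >= 2)
        suppression_significance(a_wo$reps, a_wi$reps) else NA_real_
      pos <- if (raw_mode)
        is_positive(a_wo$sfc, a_wo$mean, bg_wo, sfc_min = sfc_min)
      else is_positive(a_wo$sfc, sfc_min = sfc_min)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, cohort = d$cohort[1], stimulus = stim,
        stimulus_type = d$stimulus_type[1],
        sfc_without = a_wo$sfc, sfc_with = a_wi$sfc,
        positive_baseline = pos,
        suppressed = is_suppressed(a_wo$sfc, a_wi$sfc),
        p_value = p,
        significant = if (is.na(p)) NA else p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no complete (without, with) pairs found")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize one subject's ELISpot responses
#'
#' Counts, over the subject's individual peptides (the pooled-peptide and
#' whole-protein stimuli are excluded), the peptides tested, baseline
#' positives, Tregitope-suppressed responses, and significantly suppressed
#' responses; flags a broad responder when at least half of the tested
#' peptides were positive at baseline (count >= n/2, no rounding).
#'
#' @param pairs Data.frame from [elispot_pairs()] for one subject.
#' @return One-row data.frame with columns `subject_id`, `cohort`,
#'   `n_peptides_tested`, `n_positive_baseline`, `n_suppressed`,
#'   `n_suppressed_significant`, `broad_responder`.
#' @export
summarize_subject <- function(pairs) {
  if (length(unique(pairs$subject_id)) != 1L)
    stop("summarize_subject expects pairs of exactly one subject")
  pep <- pairs[pairs$stimulus_type == "peptide", , drop = FALSE]
  if (!nrow(pep))
    stop("subject ", pairs$subject_id[1],
         " has no testable peptide pairs (all ND)")
  n <- nrow(pep)
  n_pos <- sum(pep$positive_baseline)
  n_sup <- sum(pep$suppressed)
  n_sig <- sum(pep$suppressed & !is.na(pep$significant) & pep$significant)
  data.frame(subject_id = pep$subject_id[1], cohort = pep$cohort[1],
             n_peptides_tested = n, n_positive_baseline = n_pos,
             n_suppressed = n_sup, n_suppressed_significant = n_sig,
             broad_responder = n_pos >= n / 2,
             stringsAsFactors = FALSE)
}

#' Summarize all subjects of an ELISpot experiment
#'
#' @param pairs Data.frame from [elispot_pairs()].
#' @return Data.frame with one [summarize_subject()] row per subject, in
#'   first-appearance order.
#' @export
summarize_elispot <- function(pairs) {
  ids <- unique(pairs$subject_id)
  out <- do.call(rbind, lapply(ids, function(sid)
    summarize_subject(pairs[pairs$subject_id == sid, , drop = FALSE])))
  rownames(out) <- NULL
  out
}

#' Cohort-level ELISpot report
#'
#' Per cohort: number of subjects, mean baseline-positive peptide count
#' (reported to 1 decimal), and the pooled suppression fraction
#' `sum(n_suppressed) / sum(n_peptides_tested)` as a whole percentage
#' (pooled over pairs, not averaged over per-subject percentages). Broad
#' responders are counted over all subjects.
#'
#' @param summaries Data.frame from [summarize_elispot()].
#' @return A list with one entry per cohort (each a list with `n_subjects`,
#'   `mean_positive`, `suppression_pct`) plus `broad_responders` and
#'   `n_subjects_total`.
#' @export
summarize_cohort <- function(summaries) {
  if (!nrow(summaries)) stop("empty summary table")
  out <- lapply(split(summaries, summaries$cohort), function(d) {
    list(n_subjects = nrow(d),
         mean_positive = round(mean(d$n_positive_baseline), 1),
         suppression_pct =
           round(100 * sum(d$n_suppressed) / sum(d$n_peptides_tested)))
  })
  out$broad_responders <- sum(summaries$broad_responder)
  out$n_subjects_total <- nrow(summaries)
  out
}
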