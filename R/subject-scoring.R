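#' Subject HLA-DRB1 genotype
#'
#' @param subject_id Subject identifier.
#' @param alleles Character vector of 1-2 DRB1 allele labels (a homozygous
#'   subject may list the same allele twice; alleles are deduplicated for
#'   scoring, so the score does not double-count).
#' @param cohort `"diabetic"` or `"control"`.
#' @return An object of class `subject_genotype`.
#' @export
subject_genotype <- function(subject_id, alleles,
                             cohort = c("diabetic", "control")) {
  cohort <- match.arg(cohort)
  alleles <- as.character(alleles)
  if (!length(alleles) || length(alleles) > 2L || anyNA(alleles) ||
      !all(nzchar(alleles)))
    stop("a genotype needs 1 or 2 non-empty DRB1 allele labels")
  structure(list(subject_id = as.character(subject_id),
                 alleles = unique(alleles), cohort = cohort),
            class = "subject_genotype")
}

#' Individualized T-cell epitope measure (iTEM)
#'
#' Restricts a peptide's frame scores to the subject's DRB1 alleles and
#' sums the thresholded excess over all frames:
#' `sum over subject alleles, over frames, of max(z - z_hit, 0)`.
#' The score is zero when no subject-restricted frame reaches the hit
#' threshold, symmetric in allele order, deduplicated for homozygotes, and
#' monotone nondecreasing in every frame's Z-score. The exact published
#' formula is not public; this thresholded-excess sum is this package's
#' documented reimplementation.
#'
#' @param peptide_table A `frame_score_table` for the peptide, scored for
#'   (at least) the subject's alleles.
#' @param genotype A [subject_genotype()].
#' @param z_hit Hit threshold; defaults to the table's own.
#' @return Single nonnegative numeric score.
#' @export
item_score <- function(peptide_table, genotype, z_hit = NULL) {
  if (!inherits(genotype, "subject_genotype"))
    stop("genotype must be a 'subject_genotype'")
  at <- fst_attrs(peptide_table)
  if (is.null(z_hit)) z_hit <- at$z_hit
  missing <- setdiff(genotype$alleles, unique(peptide_table$allele))
  if (length(missing))
    stop("no scores for subject allele(s): ", paste(missing, collapse = ", "))
  rows <- peptide_table[peptide_table$allele %in% genotype$alleles, ,
                        drop = FALSE]
  ex <- pmax(rows$z - z_hit, 0)
  ex[is.na(ex)] <- 0
  sum(ex)
}

#' Classify predicted responders from iTEM scores
#'
#' @param scores Numeric iTEM scores.
#' @param cutoff Responder threshold; scores at or above it predict an
#'   immune response.
#' @return Logical vector.
#' @seealso [item_cutoff_youden()] for a data-driven cutoff.
#' @export
item_responders <- function(scores, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff))
    stop("cutoff must be a single number")
  scores >= cutoff
}

#' Choose an iTEM responder cutoff by the Youden index
#'
#' Scans candidate cutoffs (midpoints between sorted distinct scores, plus
#' the extremes) and returns the one maximizing sensitivity +
#' specificity - 1 against observed responses. Ties resolve to the lowest
#' such cutoff.
#'
#' @param scores Numeric iTEM scores (calibration data).
#' @param observed Logical observed responses, same length.
#' @return Single numeric cutoff.
#' @export
item_cutoff_youden <- function(scores, observed) {
  if (length(scores) != length(observed))
    stop("scores and observed must have the same length")
  observed <- as.logical(observed)
  if (!any(observed) || all(observed))
    stop("observed responses must include both classes")
  u <- sort(unique(scores))
  cand <- unique(c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1))
  youden <- vapply(cand, function(ct) {
    pred <- scores >= ct
    sens <- sum(pred & observed) / sum(observed)
    spec <- sum(!pred & !observed) / sum(!observed)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(youden)]
}

#' Test association between predicted and observed responder status
#'
#' Builds the 2x2 contingency table of predicted responder status against
#' observed assay positivity and applies the chi-squared test (Yates
#' continuity correction by default).
#'
#' @param predicted Logical vector of predicted responders.
#' @param observed Logical vector of observed positives.
#' @param correct Apply continuity correction (default TRUE).
#' @return A list with `statistic`, `p_value`, `table`, and `method`.
#' @export
association_test <- function(predicted, observed, correct = TRUE) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have the same length")
  predicted <- factor(as.logical(predicted), levels = c(FALSE, TRUE))
  observed <- factor(as.logical(observed), levels = c(FALSE, TRUE))
  tab <- table(predicted = predicted, observed = observed)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 margin (all observations in one class); ",
         "consider Fisher's exact test or abstain")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       table = tab, method = ht$method)
}

#' Regress Tregitope-induced suppression on iTEM scores
#'
#' Ordinary least squares of the decrease in spot-forming cells
#' (`delta_sfc = SFC without Tregitope - SFC with Tregitope`, positive =
#' suppression) on the Tregitope iTEM score.
#'
#' @param item_scores Numeric iTEM scores, one per subject/peptide pair.
#' @param delta_sfc Numeric decrease in SFC per 10^6 cells, same length.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   and the fitted `model`.
#' @export
regress_suppression <- function(item_scores, delta_sfc) {
  if (length(item_scores) != length(delta_sfc))
    stop("item_scores and delta_sfc must have the same length")
  keep <- complete.cases(item_scores, delta_sfc)
  x <- item_scores[keep]; y <- delta_sfc[keep]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  if (var(x) == 0) stop("iTEM scores have zero variance; slope is undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(x), model = fit)
}

#' Read a subject genotype table
#'
#' Tab-separated columns: `subject_id`, `allele1`, `allele2` (may be empty
#' or NA for a single typed allele), `cohort`.
#'
#' @param path TSV path.
#' @return A list of [subject_genotype()] objects, named by subject.
#' @export
read_genotypes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "allele1", "cohort")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns: subject_id, allele1[, allele2], cohort")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    alleles <- c(tab$allele1[i],
                 if ("allele2" %in% names(tab)) tab$allele2[i])
    alleles <- alleles[!is.na(alleles) & nzchar(alleles)]
    subject_genotype(tab$subject_id[i], alleles, tab$cohort[i])
  })
  names(out) <- tab$subject_id
  out
}
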