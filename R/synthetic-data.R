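#' Generate a synthetic allele scoring matrix
#'
#' Coefficients are drawn i.i.d. standard normal, so the raw score of a
#' random 9-mer is a sum of nine independent draws and is close to normal;
#' after calibration the fraction of random 9-mers with Z >= 1.64 is
#' therefore about 5% by construction. Optionally a single anchor residue
#' is given a fixed high coefficient at every position, enabling designed
#' epitopes: a poly-anchor stretch scores far above the background for
#' every allele sharing that anchor.
#'
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param allele Allele label for the matrix.
#' @param anchor_residue Optional single standard residue to boost.
#' @param anchor_value Coefficient assigned to the anchor residue at every
#'   position (default 4, roughly 4 background SDs per occupied position).
#' @param calibrate Calibrate the matrix before returning (default TRUE).
#' @param n_random Background sample size for calibration.
#' @return A (calibrated) [scoring_matrix()].
#' @export
gen_matrix <- function(seed = 1L, allele = "SYN-01", anchor_residue = NULL,
                       anchor_value = 4, calibrate = TRUE, n_random = 1e5) {
  coef <- withr_seed(seed, {
    m <- matrix(rnorm(NINEMER * 20L), nrow = NINEMER,
                dimnames = list(NULL, AA_ALPHABET))
    m
  })
  if (!is.null(anchor_residue)) {
    if (!anchor_residue %in% AA_ALPHABET)
      stop("anchor_residue must be a standard amino acid")
    coef[, anchor_residue] <- anchor_value
  }
  mat <- scoring_matrix(coef, allele = allele)
  if (calibrate) mat <- calibrate_matrix(mat, n_random = n_random, seed = seed)
  mat
}

#' Generate a set of synthetic allele matrices
#'
#' @param n_alleles Number of matrices (alleles labelled `SYN-01`,
#'   `SYN-02`, ...).
#' @param seed Base seed; per-allele seeds are derived deterministically.
#' @param n_anchored How many of the alleles share the anchor residue
#'   (default: all). Anchored alleles all hit a poly-anchor planted window,
#'   so planting with `n_anchored >= 4` creates EpiBars.
#' @param anchor_residue Shared anchor (default `"W"`).
#' @inheritParams gen_matrix
#' @return Named list of calibrated [scoring_matrix()] objects.
#' @export
gen_matrix_set <- function(n_alleles = 4L, seed = 1L,
                           n_anchored = n_alleles, anchor_residue = "W",
                           anchor_value = 4, n_random = 1e5) {
  if (n_alleles < 1L) stop("n_alleles must be at least 1")
  if (n_anchored > n_alleles) stop("n_anchored cannot exceed n_alleles")
  mats <- lapply(seq_len(n_alleles), function(k) {
    gen_matrix(seed = derive_seed(seed, k),
               allele = sprintf("SYN-%02d", k),
               anchor_residue = if (k <= n_anchored) anchor_residue,
               anchor_value = anchor_value, n_random = n_random)
  })
  names(mats) <- vapply(mats, function(m) m$allele, character(1))
  mats
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Generate a protein with planted epitope clusters
#'
#' Background residues are drawn uniformly from the standard alphabet
#' excluding the anchor residue (so the planted windows are the only
#' anchor-bearing regions and the ground truth is unambiguous); each
#' planted window is filled with the anchor residue, making every fully
#' contained 9-mer frame a strong hit for all anchored alleles. Frames
#' partially overlapping a window may also score above threshold, so called
#' clusters can extend a few residues beyond the planted bounds; every
#' hit-bearing frame intersects a planted window by construction.
#'
#' @param seed Integer seed.
#' @param length Protein length in residues (default 200).
#' @param plants List of planted windows, each `list(start =, end =)` with
#'   1-based inclusive bounds, 12-25 residues, non-overlapping (or an empty
#'   list for a background-only protein).
#' @param matrices Calibrated matrices from [gen_matrix_set()] (used to
#'   verify that each plant actually reaches the hit threshold for the
#'   anchored alleles).
#' @param anchor_residue Anchor used by the matrices (default `"W"`).
#' @param z_hit Hit threshold for the feasibility check.
#' @return A list of class `synthetic_protein`: `sequence`, `truth` (a
#'   data.frame of planted `start`/`end`), `anchor_residue`, `seed`.
#' @export
gen_protein <- function(seed = 1L, length = 200L, plants = list(),
                        matrices, anchor_residue = "W",
                        z_hit = Z_HIT_DEFAULT) {
  length <- as.integer(length)
  if (length < NINEMER) stop("protein length must be at least 9")
  truth <- if (base::length(plants))
    data.frame(start = vapply(plants, function(p) as.integer(p$start), 1L),
               end = vapply(plants, function(p) as.integer(p$end), 1L))
  else data.frame(start = integer(0), end = integer(0))
  if (nrow(truth)) {
    truth <- truth[order(truth$start), , drop = FALSE]
    len <- truth$end - truth$start + 1L
    if (any(truth$start < 1L) || any(truth$end > length))
      stop("planted windows must lie within the protein")
    if (any(len < 12L) || any(len > 25L))
      stop("planted windows must be 12-25 residues long")
    if (nrow(truth) > 1L &&
        any(truth$start[-1] <= truth$end[-nrow(truth)]))
      stop("planted windows must not overlap")
  }
  bg_alphabet <- setdiff(AA_ALPHABET, anchor_residue)
  residues <- withr_seed(seed,
    sample(bg_alphabet, length, replace = TRUE))
  for (i in seq_len(nrow(truth)))
    residues[truth$start[i]:truth$end[i]] <- anchor_residue
  sequence <- paste(residues, collapse = "")

  if (nrow(truth)) {
    poly <- strrep(anchor_residue, NINEMER)
    n_ok <- sum(vapply(matrices, function(m)
      z_score(raw_score(poly, m), m) >= z_hit, logical(1)))
    if (n_ok == 0)
      stop("infeasible plant: the anchor 9-mer reaches the hit threshold ",
           "for none of the supplied matrices")
  }
  structure(list(sequence = sequence, truth = truth,
                 anchor_residue = anchor_residue, seed = as.integer(seed)),
            class = "synthetic_protein")
}

#' Generate a competition-binding dilution series with known truth
#'
#' Signals follow the four-parameter logistic model at log-spaced
#' concentrations with mean-one multiplicative lognormal noise of the
#' given coefficient of variation.
#'
#' @param seed Integer seed.
#' @param truth List with `top`, `bottom`, `hill`, `midpoint` (uM).
#' @param levels Number of concentration levels (>= 4, default 8).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.05; 0 gives noiseless data).
#' @param conc_min,conc_max Tested concentration range in uM.
#' @param replicates Wells per concentration (default 1).
#' @param peptide_id,allele_id Labels.
#' @return A [competition_series()] with the generating parameters stored
#'   in the `truth` attribute.
#' @export
gen_competition_series <- function(seed = 1L,
                                   truth = list(top = 100, bottom = 0,
                                                hill = 1, midpoint = 10),
                                   levels = 8L, cv = 0.05,
                                   conc_min = 0.1, conc_max = 100,
                                   replicates = 1L,
                                   peptide_id = "SYN-PEP",
                                   allele_id = "SYN-01") {
  if (levels < 4L) stop("at least 4 concentration levels are required")
  if (cv < 0) stop("cv must be nonnegative")
  conc <- rep(exp(seq(log(conc_min), log(conc_max), length.out = levels)),
              each = replicates)
  mu <- fourpl_value(conc, truth$top, truth$bottom, truth$hill,
                     truth$midpoint)
  sig <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    withr_seed(seed, mu * exp(rnorm(length(mu), -sdlog^2 / 2, sdlog)))
  } else mu
  out <- competition_series(peptide_id, allele_id, conc, pmax(sig, 0))
  attr(out, "truth") <- truth
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate a synthetic two-step ELISpot dataset
#'
#' Emulates the paired culture design: per subject and peptide a baseline
#' (without Tregitope) response strength in SFC per 10^6 cells is drawn
#' lognormal; the with-Tregitope strength is the baseline reduced by
#' `effect` scaled by a per-subject susceptibility drawn Beta(5, 2) (so
#' subjects differ in how strongly Tregitopes suppress them, mimicking the
#' observed spread of per-subject suppression fractions). Triplicate wells
#' are integer spot counts: per-well expected counts (background rate plus
#' stimulus contribution) get mean-one multiplicative lognormal noise with
#' the given CV and are then Poisson-sampled. No-stimulus background wells
#' are included per subject and arm.
#'
#' @param seed Integer seed.
#' @param n_diabetic,n_control Cohort sizes (default 6 and 5, the study's).
#' @param n_peptides Peptides per subject (default 14).
#' @param effect Fractional suppression in `[0, 1)` (default 0.6).
#' @param cv Coefficient of variation of the well-level noise
#'   (default 0.2).
#' @param cells_per_well Cells plated per well (default 2.5e5).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline SFC strength (defaults log(100) and 1, spanning the tens to
#'   several hundreds observed in practice).
#' @param background_rate Expected background spots per well (default 10).
#' @return Condition-long data.frame of records (columns `subject_id`,
#'   `cohort`, `stimulus`, `stimulus_type`, `condition`, `rep1..rep3`,
#'   `cells_per_well`), with the per-pair generating truth in the `truth`
#'   attribute (`mean_sfc_without`, `mean_sfc_with`, `susceptibility`).
#' @export
gen_elispot_dataset <- function(seed = 1L, n_diabetic = 6L, n_control = 5L,
                                n_peptides = 14L, effect = 0.6, cv = 0.2,
                                cells_per_well = 2.5e5,
                                baseline_meanlog = log(100),
                                baseline_sdlog = 1,
                                background_rate = 10) {
  if (n_diabetic + n_control < 1L) stop("at least one subject is required")
  if (effect < 0 || effect >= 1) stop("effect must lie in [0, 1)")
  if (cv <= 0) stop("cv must be positive")
  subjects <- c(if (n_diabetic) sprintf("D%02d", seq_len(n_diabetic)),
                if (n_control) sprintf("C%02d", seq_len(n_control)))
  cohorts <- c(rep("diabetic", n_diabetic), rep("control", n_control))
  peptides <- sprintf("PEP-%02d", seq_len(n_peptides))
  sdlog <- sqrt(log(1 + cv^2))

  withr_seed(seed, {
    recs <- list(); truths <- list()
    triplicate <- function(mean_sfc) {
      lambda <- background_rate + mean_sfc * cells_per_well / 1e6
      lambda <- pmax(lambda, 0)
      factors <- exp(rnorm(3L, -sdlog^2 / 2, sdlog))
      rpois(3L, lambda * factors)
    }
    for (i in seq_along(subjects)) {
      susc <- rbeta(1L, 5, 2)
      for (cond in c("without", "with")) {
        bg <- triplicate(0)
        recs[[length(recs) + 1L]] <- data.frame(
          subject_id = subjects[i], cohort = cohorts[i],
          stimulus = "background", stimulus_type = "background",
          condition = cond, rep1 = bg[1], rep2 = bg[2], rep3 = bg[3],
          cells_per_well = cells_per_well, stringsAsFactors = FALSE)
      }
      for (p in peptides) {
        base <- exp(rnorm(1L, baseline_meanlog, baseline_sdlog))
        treated <- base * (1 - effect * susc)
        for (cond in c("without", "with")) {
          tr <- triplicate(if (cond == "without") base else treated)
          recs[[length(recs) + 1L]] <- data.frame(
            subject_id = subjects[i], cohort = cohorts[i],
            stimulus = p, stimulus_type = "peptide", condition = cond,
            rep1 = tr[1], rep2 = tr[2], rep3 = tr[3],
            cells_per_well = cells_per_well, stringsAsFactors = FALSE)
        }
        truths[[length(truths) + 1L]] <- data.frame(
          subject_id = subjects[i], stimulus = p,
          mean_sfc_without = base, mean_sfc_with = treated,
          susceptibility = susc, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, recs)
    attr(out, "truth") <- do.call(rbind, truths)
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Write a simulation bundle to disk
#'
#' Generates a matrix set, a planted protein, a competition series, and an
#' ELISpot dataset under one seed and writes them as plain-text files
#' (matrix TSVs, FASTA, long TSVs) together with a JSON manifest echoing
#' the seed and configuration.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_alleles,protein_length,plants Passed to the generators.
#' @return Invisibly, the manifest as a list.
#' @export
write_simulation_bundle <- function(dir, seed = 1L, n_alleles = 4L,
                                    protein_length = 200L,
                                    plants = list(list(start = 90,
                                                       end = 110))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- gen_matrix_set(n_alleles = n_alleles, seed = seed)
  for (m in mats)
    write_scoring_matrix(m, file.path(dir, paste0("matrix_", gsub("[^A-Za-z0-9]", "_", m$allele), ".tsv")))
  prot <- gen_protein(seed = seed, length = protein_length, plants = plants,
                      matrices = mats)
  seqs <- Biostrings::AAStringSet(setNames(prot$sequence, "synthetic_protein"))
  Biostrings::writeXStringSet(seqs, file.path(dir, "protein.fasta"))
  series <- gen_competition_series(seed = seed)
  comp <- data.frame(peptide_id = series$peptide_id,
                     allele_id = series$allele_id,
                     concentration_uM = series$concentrations,
                     signal = series$signals)
  write.table(comp, file.path(dir, "competition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  eli <- gen_elispot_dataset(seed = seed)
  write.table(eli, file.path(dir, "elispot.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(tool = paste0("epitopetools ",
                                 as.character(packageVersion("epitopetools"))),
                   seed = as.integer(seed),
                   n_alleles = as.integer(n_alleles),
                   protein_length = as.integer(protein_length),
                   plants = lapply(seq_len(nrow(prot$truth)), function(i)
                     list(start = prot$truth$start[i],
                          end = prot$truth$end[i])),
                   files = c("matrix_*.tsv", "protein.fasta",
                             "competition.tsv", "elispot.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
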