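#' Construct a per-allele 9-mer scoring matrix
#'
#' A scoring matrix holds one real-valued binding-propensity coefficient per
#' (frame position, amino acid) cell: 9 positions by the 20 standard
#' residues. Raw 9-mer scores are the sum of the nine per-position
#' coefficients; [calibrate_matrix()] attaches the mean and standard
#' deviation of raw scores of random 9-mers so that raw scores can be
#' Z-normalized and compared across alleles.
#'
#' @param coefficients Numeric 9 x 20 matrix. Columns must be named with the
#'   standard one-letter amino-acid codes (any order); rows are frame
#'   positions 1-9.
#' @param allele Allele label, e.g. `"DRB1*0401"` or `"I-Ag7"`.
#' @param background_freqs Named numeric vector of amino-acid sampling
#'   frequencies used for background calibration. Defaults to uniform 1/20;
#'   the background peptide model is otherwise unspecified, so uniform
#'   random 9-mers are the documented default.
#' @return An object of class `scoring_matrix`.
#' @seealso [calibrate_matrix()], [raw_score()], [z_score()],
#'   [read_scoring_matrix()]
#' @export
scoring_matrix <- function(coefficients, allele,
                           background_freqs = NULL) {
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != NINEMER)
    stop("coefficients must have exactly 9 rows (frame positions), got ",
         nrow(coefficients))
  cn <- colnames(coefficients)
  if (is.null(cn) || !setequal(cn, AA_ALPHABET))
    stop("coefficients must have one column per standard amino acid (",
         paste(AA_ALPHABET, collapse = ""), ")")
  coefficients <- coefficients[, AA_ALPHABET, drop = FALSE]
  storage.mode(coefficients) <- "double"
  if (anyNA(coefficients)) stop("coefficients must not contain NA")
  if (is.null(background_freqs)) {
    background_freqs <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    if (is.null(names(background_freqs)) ||
        !setequal(names(background_freqs), AA_ALPHABET))
      stop("background_freqs must be named with the 20 standard amino acids")
    background_freqs <- background_freqs[AA_ALPHABET]
    if (any(background_freqs < 0) || sum(background_freqs) <= 0)
      stop("background_freqs must be nonnegative and sum to a positive value")
    background_freqs <- background_freqs / sum(background_freqs)
  }
  structure(
    list(allele = as.character(allele),
         coefficients = coefficients,
         background_freqs = background_freqs,
         background_mean = NA_real_,
         background_sd = NA_real_,
         calibration = NULL),
    class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("<scoring_matrix> allele:", x$allele, "\n")
  if (is_calibrated(x)) {
    cat(sprintf("  calibrated: background mean %.4f, sd %.4f (n = %d, seed = %d)\n",
                x$background_mean, x$background_sd,
                x$calibration$n_random, x$calibration$seed))
  } else {
    cat("  not calibrated\n")
  }
  cat("  coefficient range: [",
      sprintf("%.3f", min(x$coefficients)), ", ",
      sprintf("%.3f", max(x$coefficients)), "]\n", sep = "")
  invisible(x)
}

is_calibrated <- function(matrix) {
  inherits(matrix, "scoring_matrix") && !is.na(matrix$background_sd)
}

stopifnot_scoring_matrix <- function(matrix) {
  if (!inherits(matrix, "scoring_matrix"))
    stop("expected a 'scoring_matrix' object")
  invisible(matrix)
}

#' Calibrate a scoring matrix against a random-peptide background
#'
#' Draws `n_random` 9-mers i.i.d. from the matrix's background amino-acid
#' frequencies, scores them, and stores the sample mean and standard
#' deviation of the raw scores. Z-scores ([z_score()]) are then
#' `(raw - background_mean) / background_sd`, placing all alleles on a
#' common scale in which a score of 1.64 marks the top 5% of random
#' peptides and 2.32 the top 1%.
#'
#' @param matrix A [scoring_matrix()].
#' @param n_random Number of background 9-mers (>= 1000; default 1e5).
#' @param seed Integer RNG seed, recorded in the calibration metadata so the
#'   background is reproducible.
#' @return The matrix with `background_mean`/`background_sd` set and a
#'   `calibration` record (`n_random`, `seed`).
#' @export
calibrate_matrix <- function(matrix, n_random = 1e5, seed = 1L) {
  stopifnot_scoring_matrix(matrix)
  n_random <- as.integer(n_random)
  if (is.na(n_random) || n_random < 1000)
    stop("n_random must be at least 1000")
  scores <- withr_seed(seed, random_ninemer_scores(matrix, n_random))
  m <- mean(scores)
  s <- sd(scores)
  if (!is.finite(s) || s <= 0)
    stop("calibration error: raw-score standard deviation is zero ",
         "(degenerate matrix); Z-normalization is undefined")
  matrix$background_mean <- m
  matrix$background_sd <- s
  matrix$calibration <- list(n_random = n_random, seed = as.integer(seed))
  matrix
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Raw scores of n random 9-mers drawn from the background frequencies.
# Uses the current RNG stream.
random_ninemer_scores <- function(matrix, n) {
  idx <- sample.int(20L, NINEMER * n, replace = TRUE,
                    prob = matrix$background_freqs)
  dim(idx) <- c(NINEMER, n)
  colSums(matrix(matrix$coefficients[cbind(rep(seq_len(NINEMER), n),
                                           as.vector(idx))],
                 nrow = NINEMER))
}

#' Raw PSSM score of 9-mer peptides
#'
#' Sums the per-position coefficients of each residue of a 9-mer. Vectorized
#' over peptides.
#'
#' @param ninemer Character vector of 9-residue peptides.
#' @param matrix A [scoring_matrix()].
#' @return Numeric vector of raw scores.
#' @export
raw_score <- function(ninemer, matrix) {
  stopifnot_scoring_matrix(matrix)
  ninemer <- as.character(ninemer)
  if (any(nchar(ninemer) != NINEMER))
    stop("every peptide must be exactly 9 residues long")
  chars <- matrix(unlist(strsplit(ninemer, "", fixed = TRUE), use.names = FALSE),
                  nrow = NINEMER)
  col <- match(chars, AA_ALPHABET)
  if (anyNA(col)) {
    bad <- unique(chars[is.na(col)])
    stop("unknown residue(s) not in the standard alphabet: ",
         paste(bad, collapse = ", "))
  }
  dim(col) <- dim(chars)
  colSums(matrix(matrix$coefficients[cbind(rep(seq_len(NINEMER),
                                               ncol(chars)),
                                           as.vector(col))],
                 nrow = NINEMER))
}

#' Z-normalize raw scores
#'
#' Converts raw scores to the calibrated Z scale:
#' `(raw - background_mean) / background_sd`. Z-scores are directly
#' comparable across alleles; values at or above 1.64 fall in the top 5% of
#' the random-peptide background, values at or above 2.32 in the top 1%.
#'
#' @param raw Numeric vector of raw scores.
#' @param matrix A calibrated [scoring_matrix()].
#' @return Numeric vector of Z-scores.
#' @export
z_score <- function(raw, matrix) {
  stopifnot_scoring_matrix(matrix)
  if (!is_calibrated(matrix))
    stop("matrix for allele '", matrix$allele,
         "' is not calibrated; run calibrate_matrix() first")
  (raw - matrix$background_mean) / matrix$background_sd
}

#' Read and write scoring-matrix files
#'
#' The on-disk format is a tab-separated table of 9 rows (frame positions)
#' by 20 columns (standard amino acids, named in the header), preceded by
#' comment lines of the form `# key: value` carrying at least the allele
#' label and optionally the background calibration
#' (`background_mean`, `background_sd`, `calibration_n`, `calibration_seed`).
#'
#' @param path File path.
#' @return `read_scoring_matrix()` returns a [scoring_matrix()];
#'   `write_scoring_matrix()` invisibly returns `path`.
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  if (is.null(meta$allele)) stop("matrix file lacks an '# allele:' header: ", path)
  tab <- read.delim(text = lines[!grepl("^#", lines)], check.names = FALSE)
  mat <- scoring_matrix(as.matrix(tab), allele = meta$allele)
  if (!is.null(meta$background_mean) && !is.null(meta$background_sd)) {
    mat$background_mean <- as.numeric(meta$background_mean)
    mat$background_sd <- as.numeric(meta$background_sd)
    mat$calibration <- list(
      n_random = as.integer(meta$calibration_n %||% NA),
      seed = as.integer(meta$calibration_seed %||% NA))
  }
  mat
}

#' @rdname read_scoring_matrix
#' @param matrix A [scoring_matrix()].
#' @export
write_scoring_matrix <- function(matrix, path) {
  stopifnot_scoring_matrix(matrix)
  hdr <- sprintf("# allele: %s", matrix$allele)
  if (is_calibrated(matrix)) {
    hdr <- c(hdr,
             sprintf("# background_mean: %.17g", matrix$background_mean),
             sprintf("# background_sd: %.17g", matrix$background_sd),
             sprintf("# calibration_n: %d", matrix$calibration$n_random),
             sprintf("# calibration_seed: %d", matrix$calibration$seed))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(AA_ALPHABET, collapse = "\t"), con)
  write.table(matrix$coefficients, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
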