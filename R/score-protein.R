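#' Parse a protein into overlapping 9-mer frames
#'
#' Splits an amino-acid sequence into all overlapping 9-mer frames; each
#' frame overlaps the previous by eight residues, so a sequence of length L
#' yields L - 8 frames and frame i starts at residue i (1-based).
#'
#' @param sequence Single amino-acid string (or an object coercible via
#'   `as.character`, e.g. a `Biostrings::AAString`).
#' @param validate Check the sequence against the 20-residue standard
#'   alphabet (default TRUE). With `validate = FALSE` non-standard letters
#'   are carried through and handled by the caller.
#' @return A data.frame with columns `start` (1-based residue index) and
#'   `ninemer`.
#' @examples
#' nrow(parse_ninemers(paste(rep("A", 585), collapse = ""))) # 577
#' @export
parse_ninemers <- function(sequence, validate = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("sequence must be a single string")
  n <- nchar(sequence)
  if (n < NINEMER)
    stop("sequence length ", n, " is shorter than 9 residues; ",
         "no 9-mer frame can be formed")
  if (validate) {
    letters_seen <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
    bad <- setdiff(letters_seen, AA_ALPHABET)
    if (length(bad))
      stop("non-standard residue(s) in sequence: ",
           paste(bad, collapse = ", "),
           " (use on_nonstandard = \"mask\" in score_protein() to skip ",
           "affected frames)")
  }
  starts <- seq_len(n - NINEMER + 1L)
  data.frame(start = starts,
             ninemer = substring(sequence, starts, starts + NINEMER - 1L),
             stringsAsFactors = FALSE)
}

#' Score a protein against one or more allele matrices
#'
#' Produces the full frame-by-allele score table: each overlapping 9-mer
#' frame is scored against every calibrated matrix, Z-normalized, and
#' flagged as a hit (top 5% of the random background, Z >= `z_hit`) or a
#' strong hit (top 1%, Z >= `z_top1`).
#'
#' @param sequence Amino-acid string (length >= 9).
#' @param matrices A calibrated [scoring_matrix()] or list of them.
#' @param sequence_id Identifier carried into the output (default
#'   `"seq1"`).
#' @param z_hit,z_top1 Hit thresholds on the Z scale. Defaults 1.64 and
#'   2.32, the 0.95 and 0.99 standard-normal quantiles rounded to two
#'   decimals.
#' @param on_nonstandard `"error"` (default) rejects sequences containing
#'   non-standard residues (X, B, Z, U, ...); `"mask"` scores frames that
#'   contain such residues as `NA` (never a hit). Silent zero-filling is
#'   deliberately not offered because it would bias Z-scores downwards.
#' @return A `frame_score_table`: a data.frame with columns `sequence_id`,
#'   `start`, `ninemer`, `allele`, `raw`, `z`, `hit`, `top1`, ordered by
#'   frame then allele, with the thresholds stored in attributes `z_hit`,
#'   `z_top1`.
#' @export
score_protein <- function(sequence, matrices, sequence_id = "seq1",
                          z_hit = Z_HIT_DEFAULT, z_top1 = Z_TOP1_DEFAULT,
                          on_nonstandard = c("error", "mask")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (inherits(matrices, "scoring_matrix")) matrices <- list(matrices)
  if (!length(matrices)) stop("at least one scoring matrix is required")
  for (m in matrices) {
    stopifnot_scoring_matrix(m)
    if (!is_calibrated(m))
      stop("matrix for allele '", m$allele, "' is not calibrated")
  }
  alleles <- vapply(matrices, function(m) m$allele, character(1))
  if (anyDuplicated(alleles))
    stop("duplicate allele labels among matrices: ",
         paste(unique(alleles[duplicated(alleles)]), collapse = ", "))

  frames <- parse_ninemers(sequence, validate = on_nonstandard == "error")
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
              frames$ninemer)
  per_allele <- lapply(matrices, function(m) {
    raw <- rep(NA_real_, nrow(frames))
    raw[ok] <- raw_score(frames$ninemer[ok], m)
    z <- z_score(raw, m)
    data.frame(sequence_id = sequence_id,
               start = frames$start,
               ninemer = frames$ninemer,
               allele = m$allele,
               raw = raw,
               z = z,
               hit = !is.na(z) & z >= z_hit,
               top1 = !is.na(z) & z >= z_top1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_allele)
  tab <- tab[order(tab$start, match(tab$allele, alleles)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            z_hit = z_hit, z_top1 = z_top1,
            alleles = alleles,
            class = c("frame_score_table", "data.frame"))
}

# Keep attributes through subsetting done inside the package.
fst_attrs <- function(table) {
  list(z_hit = attr(table, "z_hit") %||% Z_HIT_DEFAULT,
       z_top1 = attr(table, "z_top1") %||% Z_TOP1_DEFAULT,
       alleles = attr(table, "alleles") %||% unique(table$allele))
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning a named
#' character vector of sequences.
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a frame score table as TSV
#'
#' Emits the score table with `# key: value` metadata lines (thresholds and
#' package version) followed by the tab-separated columns.
#'
#' @param table A `frame_score_table` from [score_protein()].
#' @param path Output path.
#' @param metadata Optional named list of extra metadata to echo.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path, metadata = list()) {
  at <- fst_attrs(table)
  meta <- c(list(tool = paste0("epitopetools ", packageVersion("epitopetools")),
                 z_hit = at$z_hit, z_top1 = at$z_top1),
            metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, function(x) paste(format(x), collapse = ","),
                            character(1))), con)
  suppressWarnings(write.table(as.data.frame(table), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}
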