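#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline with the
#' standard defaults, validates them, and is echoed verbatim into every
#' output's metadata so that results are reproducible from the outputs
#' alone.
#'
#' @param z_hit,z_top1 Z-score hit thresholds (defaults 1.64 / 2.32, the
#'   0.95 / 0.99 standard-normal quantiles).
#' @param epibar_min Distinct alleles hit for an EpiBar (default 4).
#' @param positivity_sfc ELISpot positivity threshold in SFC per 10^6 over
#'   background (default 50).
#' @param affinity_high,affinity_weak IC50 class boundaries in uM
#'   (defaults 25 / 50).
#' @param min_len,max_len,gap_max,min_cluster_score Cluster-calling
#'   parameters (see [find_clusters()]).
#' @param seed Seed echoed to stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(z_hit = Z_HIT_DEFAULT, z_top1 = Z_TOP1_DEFAULT,
                            epibar_min = EPIBAR_MIN_DEFAULT,
                            positivity_sfc = POSITIVITY_SFC_DEFAULT,
                            affinity_high = AFFINITY_HIGH_MAX,
                            affinity_weak = AFFINITY_WEAK_MIN,
                            min_len = 12L, max_len = 25L, gap_max = 2L,
                            min_cluster_score = 5, seed = 1L) {
  cfg <- list(z_hit = z_hit, z_top1 = z_top1,
              epibar_min = as.integer(epibar_min),
              positivity_sfc = positivity_sfc,
              affinity_high = affinity_high, affinity_weak = affinity_weak,
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              gap_max = as.integer(gap_max),
              min_cluster_score = min_cluster_score,
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) <= 0))
    stop("all pipeline thresholds must be positive numbers")
  if (cfg$z_top1 < cfg$z_hit) stop("z_top1 must be >= z_hit")
  if (cfg$affinity_weak < cfg$affinity_high)
    stop("affinity_weak must be >= affinity_high")
  structure(cfg, class = "pipeline_config")
}

config_metadata <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(json, tmp); on.exit(unlink(tmp))
  list(tool = paste0("epitopetools ",
                     as.character(packageVersion("epitopetools"))),
       seed = config$seed,
       config = unclass(config),
       config_hash = unname(tools::md5sum(tmp)))
}

#' Run pipeline stages
#'
#' Executes the requested analysis stage on file inputs and writes TSV/JSON
#' results carrying the tool version, seed, and configuration (with hash)
#' in their metadata. Available stages:
#'
#' * `score`: FASTA + matrix files -> per-frame score table
#'   (`scores.tsv`).
#' * `cluster`: FASTA + matrix files -> epitope clusters (`clusters.tsv`,
#'   `clusters.bed`, `clusters.json` including EpiBar frames).
#' * `ic50`: competition TSV -> 4PL fits, IC50s, affinity classes
#'   (`ic50.tsv`).
#' * `elispot`: ELISpot TSV -> per-subject summary (`elispot_subjects.tsv`)
#'   and cohort report (`elispot_cohort.json`).
#' * `simulate`: writes a synthetic bundle via
#'   [write_simulation_bundle()].
#'
#' @param stage One of `"score"`, `"cluster"`, `"ic50"`, `"elispot"`,
#'   `"simulate"`.
#' @param inputs Named list of input paths: `fasta` and `matrices`
#'   (character vector) for score/cluster; `competition` for ic50;
#'   `elispot` for elispot.
#' @param outdir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named character vector of the files written.
#' @export
run_pipeline <- function(stage = c("score", "cluster", "ic50", "elispot",
                                   "simulate"),
                         inputs = list(), outdir,
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  if (!inherits(config, "pipeline_config"))
    stop("config must be a 'pipeline_config'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- config_metadata(config)
  need <- function(key) {
    if (is.null(inputs[[key]]))
      stop("stage '", stage, "' requires input '", key, "'")
    missing <- inputs[[key]][!file.exists(inputs[[key]])]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    inputs[[key]]
  }
  written <- character(0)

  score_tables <- function() {
    seqs <- read_fasta_sequences(need("fasta"))
    mats <- lapply(need("matrices"), read_scoring_matrix)
    bad <- names(seqs)[nchar(seqs) < NINEMER]
    if (length(bad))
      stop("sequence(s) shorter than 9 residues cannot be scored: ",
           paste(bad, collapse = ", "))
    tabs <- lapply(names(seqs), function(id)
      score_protein(seqs[[id]], mats, sequence_id = id,
                    z_hit = config$z_hit, z_top1 = config$z_top1))
    tab <- do.call(rbind, lapply(tabs, as.data.frame))
    structure(tab, z_hit = config$z_hit, z_top1 = config$z_top1,
              alleles = vapply(mats, function(m) m$allele, character(1)),
              class = c("frame_score_table", "data.frame"))
  }

  if (stage == "score") {
    tab <- score_tables()
    f <- file.path(outdir, "scores.tsv")
    write_score_table(tab, f, metadata = list(seed = meta$seed,
                                              config_hash = meta$config_hash))
    written <- c(scores = f)
  } else if (stage == "cluster") {
    tab <- score_tables()
    cl <- find_clusters(tab, min_len = config$min_len,
                        max_len = config$max_len, gap_max = config$gap_max,
                        epibar_min = config$epibar_min,
                        min_score = config$min_cluster_score)
    f_tsv <- file.path(outdir, "clusters.tsv")
    con <- file(f_tsv, "w")
    writeLines(sprintf("# %s: %s",
                       c("tool", "seed", "config_hash"),
                       c(meta$tool, meta$seed, meta$config_hash)), con)
    write.table(as.data.frame(cl), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    f_bed <- file.path(outdir, "clusters.bed")
    clusters_to_bed(cl, f_bed)
    f_json <- file.path(outdir, "clusters.json")
    jsonlite::write_json(
      c(meta, list(clusters = as.data.frame(cl))),
      f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(clusters = f_tsv, bed = f_bed, json = f_json)
  } else if (stage == "ic50") {
    series <- read_competition_series(need("competition"))
    rows <- lapply(series, function(s) {
      fit <- fit_4pl(s)
      if (!fit$converged)
        return(data.frame(peptide_id = s$peptide_id,
                          allele_id = s$allele_id, ic50 = "failed",
                          class = NA_character_, converged = FALSE))
      est <- ic50_from_fit(fit, s)
      data.frame(peptide_id = s$peptide_id, allele_id = s$allele_id,
                 ic50 = est$label,
                 class = classify_affinity(est,
                                           high_max = config$affinity_high,
                                           weak_min = config$affinity_weak),
                 converged = TRUE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows); rownames(out) <- NULL
    f <- file.path(outdir, "ic50.tsv")
    con <- file(f, "w")
    writeLines(sprintf("# %s: %s", c("tool", "seed", "config_hash"),
                       c(meta$tool, meta$seed, meta$config_hash)), con)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    written <- c(ic50 = f)
  } else if (stage == "elispot") {
    records <- read_elispot(need("elispot"))
    pairs <- elispot_pairs(records, sfc_min = config$positivity_sfc)
    summaries <- summarize_elispot(pairs)
    f_tsv <- file.path(outdir, "elispot_subjects.tsv")
    con <- file(f_tsv, "w")
    writeLines(sprintf("# %s: %s", c("tool", "seed", "config_hash"),
                       c(meta$tool, meta$seed, meta$config_hash)), con)
    write.table(summaries, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    f_json <- file.path(outdir, "elispot_cohort.json")
    jsonlite::write_json(c(meta, list(cohorts = summarize_cohort(summaries))),
                         f_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(subjects = f_tsv, cohort = f_json)
  } else if (stage == "simulate") {
    write_simulation_bundle(outdir, seed = config$seed)
    written <- c(manifest = file.path(outdir, "manifest.json"))
  }
  invisible(written)
}

#' Validate pipeline input files
#'
#' Checks each file against a named schema and reports per-file pass/fail
#' with line-level messages; inputs are never modified.
#'
#' @param paths Character vector of file paths.
#' @param schemas Character vector (recycled) naming the expected schema of
#'   each file: `"fasta"`, `"matrix"`, `"elispot"`, `"competition"`,
#'   `"genotype"`.
#' @return Data.frame with columns `file`, `schema`, `ok`, `messages`.
#' @export
validate_inputs <- function(paths, schemas) {
  schemas <- rep_len(schemas, length(paths))
  check_one <- function(path, schema) {
    if (!file.exists(path)) return("file does not exist")
    msgs <- character(0)
    tryCatch({
      if (schema == "fasta") {
        seqs <- read_fasta_sequences(path)
        short <- which(nchar(seqs) < NINEMER)
        if (length(short))
          msgs <- c(msgs, sprintf(
            "record %d ('%s'): %d aa is below the minimum length 9 for scoring",
            short, names(seqs)[short], nchar(seqs)[short]))
      } else if (schema == "matrix") {
        read_scoring_matrix(path)
      } else if (schema == "elispot") {
        tab <- read_elispot(path)
        if ("cells_per_well" %in% names(tab)) {
          bad <- which(!is.na(tab$cells_per_well) & tab$cells_per_well <= 0)
          if (length(bad))
            msgs <- c(msgs, sprintf("row %d: cells_per_well must be positive",
                                    bad))
        }
      } else if (schema == "competition") {
        tab <- read.delim(path, stringsAsFactors = FALSE)
        need <- c("peptide_id", "allele_id", "concentration_uM", "signal")
        miss <- setdiff(need, names(tab))
        if (length(miss))
          msgs <- c(msgs, paste("missing column(s):",
                                paste(miss, collapse = ", ")))
        else {
          bad <- which(tab$concentration_uM <= 0)
          if (length(bad))
            msgs <- c(msgs, sprintf("row %d: concentration must be positive",
                                    bad))
        }
      } else if (schema == "genotype") {
        read_genotypes(path)
      } else stop("unknown schema: ", schema)
      msgs
    }, error = function(e) c(msgs, conditionMessage(e)))
  }
  msgs <- mapply(check_one, paths, schemas, SIMPLIFY = FALSE)
  data.frame(file = paths, schema = schemas,
             ok = lengths(msgs) == 0,
             messages = vapply(msgs, paste, character(1), collapse = "; "),
             stringsAsFactors = FALSE, row.names = NULL)
}
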