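#' Find EpiBar frames
#'
#' An EpiBar is a single 9-mer frame predicted to bind at least
#' `epibar_min` (default 4) distinct HLA alleles, i.e. with a hit
#' (Z >= z_hit) for that many alleles. EpiBars mark promiscuously
#' immunogenic frames.
#'
#' @param table A `frame_score_table` from [score_protein()].
#' @param epibar_min Minimum number of distinct alleles hit (default 4).
#' @return Integer vector of frame start positions, in position order.
#' @export
find_epibars <- function(table, epibar_min = EPIBAR_MIN_DEFAULT) {
  at <- fst_attrs(table)
  if (!nrow(table)) return(integer(0))
  if (length(at$alleles) < epibar_min) {
    warning("only ", length(at$alleles), " allele(s) scored but epibar_min = ",
            epibar_min, "; no frame can be an EpiBar")
    return(integer(0))
  }
  hits <- table[table$hit, c("start", "allele")]
  if (!nrow(hits)) return(integer(0))
  counts <- tapply(hits$allele, hits$start, function(a) length(unique(a)))
  sort(as.integer(names(counts)[counts >= epibar_min]))
}

# Per-frame excess score: sum over alleles of max(z - z_hit, 0).
frame_excess <- function(table, z_hit) {
  ex <- pmax(table$z - z_hit, 0)
  ex[is.na(ex)] <- 0
  tapply(ex, table$start, sum)
}

#' Aggregate score of an epitope cluster
#'
#' The cluster score is the summed hit excess over all member frames and
#' alleles, penalized by the hit count expected under the null:
#' `sum over frames x alleles of max(z - z_hit, 0) - 0.05 * n_frames *
#' n_alleles`. Since 5% of random frames exceed `z_hit` by construction of
#' the Z-normalization, a region with only background-level hits scores
#' near or below zero; negative values are possible (and are printed for
#' some reference peptides).
#'
#' @param member_starts Frame start positions belonging to the cluster
#'   (usually the contiguous range spanned by its hit frames).
#' @param table A `frame_score_table` covering those frames.
#' @param z_hit Hit threshold; defaults to the table's own.
#' @return Single numeric score.
#' @export
cluster_score <- function(member_starts, table, z_hit = NULL) {
  at <- fst_attrs(table)
  if (is.null(z_hit)) z_hit <- at$z_hit
  member_starts <- sort(unique(as.integer(member_starts)))
  if (!length(member_starts)) stop("cluster has no member frames")
  rows <- table[table$start %in% member_starts, , drop = FALSE]
  if (!nrow(rows)) stop("member frames not present in score table")
  ex <- pmax(rows$z - z_hit, 0)
  ex[is.na(ex)] <- 0
  n_alleles <- length(at$alleles)
  sum(ex) - 0.05 * length(member_starts) * n_alleles
}

#' Detect epitope clusters in a scored protein
#'
#' Hit-bearing frames (any allele at Z >= z_hit) are merged into maximal
#' regions whenever at most `gap_max` hit-free frames intervene, trimmed to
#' hit-bearing boundaries, split at the lowest-scoring internal hit frame
#' while longer than `max_len`, and reported when they are at least
#' `min_len` residues long (regions shorter than `min_len` are kept only if
#' they contain an EpiBar, so a lone EpiBar frame is reported as a 9-residue
#' cluster). Non-EpiBar regions must additionally reach `min_score` on the
#' cluster score to be reported, which suppresses the background regions
#' that the 5% per-allele hit rate alone produces on random sequence.
#'
#' @param table A `frame_score_table` from [score_protein()].
#' @param min_len,max_len Cluster length bounds in residues (defaults 12
#'   and 25, the empirical size range of class II epitope clusters).
#' @param gap_max Maximum number of consecutive hit-free frames bridged
#'   within a region (default 2).
#' @param epibar_min Distinct-allele hit count defining an EpiBar.
#' @param min_score Minimum [cluster_score()] for reporting a cluster that
#'   contains no EpiBar (default 5).
#' @return A data.frame of class `epitope_clusters` with one row per
#'   cluster: `sequence_id`, `start`, `end` (1-based inclusive residue
#'   bounds; end = last hit-frame start + 8), `length`, `n_frames`,
#'   `n_motifs` (hit count over member frames x alleles), `n_epibars`,
#'   `epibar_starts` (comma-separated), `cluster_score`. Member frame
#'   starts are kept in the `member_frames` attribute (a list, one entry
#'   per cluster). Clusters are non-overlapping and position-ordered.
#' @export
find_clusters <- function(table, min_len = 12L, max_len = 25L, gap_max = 2L,
                          epibar_min = EPIBAR_MIN_DEFAULT, min_score = 5) {
  at <- fst_attrs(table)
  empty <- structure(
    data.frame(sequence_id = character(0), start = integer(0),
               end = integer(0), length = integer(0), n_frames = integer(0),
               n_motifs = integer(0), n_epibars = integer(0),
               epibar_starts = character(0), cluster_score = numeric(0),
               stringsAsFactors = FALSE),
    member_frames = list(), class = c("epitope_clusters", "data.frame"))
  if (!nrow(table)) return(empty)

  out <- lapply(split(seq_len(nrow(table)), table$sequence_id), function(i) {
    tab <- table[i, , drop = FALSE]
    attr(tab, "z_hit") <- at$z_hit
    attr(tab, "alleles") <- at$alleles
    find_clusters_one(tab, min_len, max_len, gap_max, epibar_min, min_score,
                      at)
  })
  rows <- do.call(rbind, lapply(out, `[[`, "rows"))
  members <- do.call(c, lapply(out, `[[`, "members"))
  if (is.null(rows) || !nrow(rows)) return(empty)
  ord <- order(rows$sequence_id, rows$start)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, member_frames = members[ord],
            class = c("epitope_clusters", "data.frame"))
}

find_clusters_one <- function(tab, min_len, max_len, gap_max, epibar_min,
                              min_score, at) {
  hit_starts <- sort(unique(tab$start[tab$hit]))
  if (!length(hit_starts)) return(list(rows = NULL, members = list()))
  epibars <- if (length(at$alleles) >= epibar_min)
    suppressWarnings(find_epibars(tab, epibar_min)) else integer(0)
  excess <- frame_excess(tab, at$z_hit)

  # maximal regions under the gap rule
  grp <- cumsum(c(1L, diff(hit_starts) > gap_max + 1L))
  groups <- split(hit_starts, grp)

  # recursive split of regions longer than max_len at the lowest-scoring
  # internal hit frame (ties -> leftmost); the split frame is dropped
  split_group <- function(s) {
    span <- s[length(s)] - s[1] + NINEMER
    if (span <= max_len || length(s) <= 2L) return(list(s))
    internal <- s[-c(1L, length(s))]
    sc <- excess[as.character(internal)]
    cut <- internal[which.min(sc)]
    c(split_group(s[s < cut]), split_group(s[s > cut]))
  }
  pieces <- do.call(c, lapply(groups, split_group))

  rows <- list(); members <- list()
  for (s in pieces) {
    first <- s[1]; last <- s[length(s)]
    span <- last - first + NINEMER
    member <- sort(unique(tab$start[tab$start >= first & tab$start <= last]))
    eb <- intersect(epibars, member)
    if (span < min_len && !length(eb)) next
    score <- cluster_score(member, tab, z_hit = at$z_hit)
    if (!length(eb) && score < min_score) next
    n_motifs <- sum(tab$hit[tab$start %in% member])
    rows[[length(rows) + 1L]] <- data.frame(
      sequence_id = tab$sequence_id[1],
      start = as.integer(first), end = as.integer(last + NINEMER - 1L),
      length = as.integer(span), n_frames = length(member),
      n_motifs = as.integer(n_motifs), n_epibars = length(eb),
      epibar_starts = paste(eb, collapse = ","),
      cluster_score = score, stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- member
  }
  list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
       members = members)
}

#' Write clusters as BED-like intervals
#'
#' Emits `sequence_id`, 0-based half-open start, end, a cluster name, and
#' the cluster score, suitable for genome-browser-style tooling.
#'
#' @param clusters An `epitope_clusters` data.frame from [find_clusters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
clusters_to_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$sequence_id,
                    start = clusters$start - 1L,
                    end = clusters$end,
                    name = sprintf("cluster_%d", seq_len(nrow(clusters))),
                    score = clusters$cluster_score)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
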