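# Shared test builders. All synthetic inputs are constructed in code.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# constant-coefficient matrix (degenerate: zero raw-score variance)
const_matrix <- function(value, allele = "CONST") {
  scoring_matrix(matrix(value, nrow = 9, ncol = 20,
                        dimnames = list(NULL, aa20)),
                 allele = allele)
}

# deterministic non-degenerate matrix for exact-arithmetic tests:
# coefficient(p, a) = (p * index(a)) / 50 - 1
grid_matrix <- function(allele = "GRID") {
  m <- outer(1:9, 1:20, function(p, a) p * a / 50 - 1)
  colnames(m) <- aa20
  scoring_matrix(m, allele = allele)
}

# matrix recognizing exactly one 9-mer (distinct key residue per position);
# every other frame scores 0 raw.
keyed_matrix <- function(allele = "KEY", value = 10) {
  m <- matrix(0, nrow = 9, ncol = 20, dimnames = list(NULL, aa20))
  for (p in 1:9) m[p, aa20[p]] <- value
  scoring_matrix(m, allele = allele)
}
keyed_ninemer <- paste(aa20[1:9], collapse = "")

random_ninemer <- function(alphabet = aa20) {
  paste(sample(alphabet, 9, replace = TRUE), collapse = "")
}

# build a frame_score_table directly from a frames x alleles z matrix
make_fst <- function(z, starts = seq_len(nrow(z)),
                     alleles = sprintf("AL%d", seq_len(ncol(z))),
                     sequence_id = "seq1",
                     z_hit = 1.64, z_top1 = 2.32) {
  stopifnot(length(starts) == nrow(z), length(alleles) == ncol(z))
  df <- data.frame(
    sequence_id = sequence_id,
    start = rep(starts, each = ncol(z)),
    ninemer = strrep("A", 9),
    allele = rep(alleles, times = nrow(z)),
    raw = as.vector(t(z)),
    z = as.vector(t(z)),
    stringsAsFactors = FALSE)
  df$hit <- !is.na(df$z) & df$z >= z_hit
  df$top1 <- !is.na(df$z) & df$z >= z_top1
  structure(df, z_hit = z_hit, z_top1 = z_top1, alleles = alleles,
            class = c("frame_score_table", "data.frame"))
}

# independent re-derivation of the cluster-calling rules, written as an
# iterative scan (vs the package's recursive grouping) for cross-checking
oracle_clusters <- function(table, min_len = 12, max_len = 25, gap_max = 2,
                            epibar_min = 4, min_score = 5, z_hit = 1.64) {
  hits <- sort(unique(table$start[table$hit]))
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0)))
  counts <- sapply(hits, function(s)
    length(unique(table$allele[table$start == s & table$hit])))
  epibars <- hits[counts >= epibar_min]
  fr_excess <- function(s) {
    rows <- table[table$start == s, ]
    sum(pmax(rows$z - z_hit, 0), na.rm = TRUE)
  }
  groups <- list(); cur <- hits[1]
  for (s in hits[-1]) {
    if (s - cur[length(cur)] > gap_max + 1) {
      groups[[length(groups) + 1]] <- cur; cur <- s
    } else cur <- c(cur, s)
  }
  groups[[length(groups) + 1]] <- cur
  # iterative splitting with an explicit worklist
  done <- list()
  while (length(groups)) {
    g <- groups[[1]]; groups <- groups[-1]
    span <- g[length(g)] - g[1] + 9
    if (span > max_len && length(g) > 2) {
      internal <- g[-c(1, length(g))]
      sc <- sapply(internal, fr_excess)
      cut <- internal[order(sc)[1]]
      groups <- c(groups, list(g[g < cut]), list(g[g > cut]))
    } else done[[length(done) + 1]] <- g
  }
  out <- list()
  for (g in done) {
    first <- g[1]; last <- g[length(g)]
    span <- last - first + 9
    member <- sort(unique(table$start[table$start >= first &
                                        table$start <= last]))
    eb <- intersect(epibars, member)
    if (span < min_len && !length(eb)) next
    n_alleles <- length(unique(table$allele))
    rows <- table[table$start %in% member, ]
    score <- sum(pmax(rows$z - z_hit, 0), na.rm = TRUE) -
      0.05 * length(member) * n_alleles
    if (!length(eb) && score < min_score) next
    out[[length(out) + 1]] <- data.frame(start = first, end = last + 8,
                                         score = score)
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
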