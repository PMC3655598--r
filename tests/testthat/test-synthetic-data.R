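test_that("generators are fully deterministic given the seed", {
  m1 <- gen_matrix(seed = 42, n_random = 2e4)
  m2 <- gen_matrix(seed = 42, n_random = 2e4)
  expect_identical(m1, m2)
  expect_false(identical(m1$coefficients,
                         gen_matrix(seed = 43, n_random = 2e4)$coefficients))

  mats <- gen_matrix_set(3, seed = 7, n_random = 2e4)
  p1 <- gen_protein(seed = 5, length = 120,
                    plants = list(list(start = 50, end = 70)),
                    matrices = mats)
  p2 <- gen_protein(seed = 5, length = 120,
                    plants = list(list(start = 50, end = 70)),
                    matrices = mats)
  expect_identical(p1$sequence, p2$sequence)

  s1 <- gen_competition_series(seed = 9, cv = 0.1)
  s2 <- gen_competition_series(seed = 9, cv = 0.1)
  expect_identical(s1$signals, s2$signals)

  e1 <- gen_elispot_dataset(seed = 11, n_diabetic = 2, n_control = 1,
                            n_peptides = 3)
  e2 <- gen_elispot_dataset(seed = 11, n_diabetic = 2, n_control = 1,
                            n_peptides = 3)
  expect_identical(e1, e2)
})

test_that("generated matrices calibrate with ~5% background hit rate", {
  m <- gen_matrix(seed = 31, n_random = 1e5)
  expect_gt(m$background_sd, 0)
  set.seed(63)
  z <- z_score(raw_score(replicate(2e4, random_ninemer()), m), m)
  expect_true(mean(z >= 1.64) >= 0.04 && mean(z >= 1.64) <= 0.06)
})

test_that("protein plants are validated and anchored windows score as epitopes", {
  mats <- gen_matrix_set(4, seed = 3, n_random = 2e4)
  expect_error(gen_protein(seed = 1, length = 100,
                           plants = list(list(start = 95, end = 110)),
                           matrices = mats), "within the protein")
  expect_error(gen_protein(seed = 1, length = 100,
                           plants = list(list(start = 10, end = 18)),
                           matrices = mats), "12-25")
  expect_error(gen_protein(seed = 1, length = 100,
                           plants = list(list(start = 10, end = 25),
                                         list(start = 20, end = 35)),
                           matrices = mats), "overlap")

  # matrices without the anchor cannot host a plant
  plain <- gen_matrix_set(2, seed = 3, n_anchored = 0, n_random = 2e4)
  expect_error(gen_protein(seed = 1, length = 100,
                           plants = list(list(start = 10, end = 25)),
                           matrices = plain), "infeasible plant")

  prot <- gen_protein(seed = 2, length = 150,
                      plants = list(list(start = 60, end = 80)),
                      matrices = mats)
  expect_equal(nchar(prot$sequence), 150)
  expect_equal(substr(prot$sequence, 60, 80), strrep("W", 21))
  # background carries no anchor residues
  expect_false(grepl("W", paste0(substr(prot$sequence, 1, 59),
                                 substr(prot$sequence, 81, 150))))
  # worked-example geometry: a plant at 450-470 of a 585-aa protein makes
  # frames 455, 456, and 459 EpiBars
  big <- gen_protein(seed = 4, length = 585,
                     plants = list(list(start = 450, end = 470)),
                     matrices = mats)
  tab <- score_protein(big$sequence, mats)
  eb <- find_epibars(tab)
  expect_true(all(c(455, 456, 459) %in% eb))
})

test_that("planted clusters are recalled and hit-free proteins stay empty", {
  mats <- gen_matrix_set(4, seed = 17, n_random = 2e4)
  recalled <- logical(100); clean <- logical(100); localized <- logical(100)
  for (s in 1:100) {
    plant <- list(start = 90, end = 110)
    prot <- gen_protein(seed = 2000 + s, length = 200,
                        plants = list(plant), matrices = mats)
    cl <- find_clusters(score_protein(prot$sequence, mats))
    recalled[s] <- any(cl$start <= plant$end & cl$end >= plant$start)
    localized[s] <- all(cl$start <= plant$end + 8 &
                          cl$end >= plant$start - 8)
    bare <- gen_protein(seed = 6000 + s, length = 200, matrices = mats)
    clean[s] <- nrow(find_clusters(score_protein(bare$sequence, mats))) == 0
  }
  expect_equal(mean(recalled), 1)
  expect_equal(mean(localized), 1)
  expect_gte(mean(clean), 0.95)
})

test_that("competition series carry their truth and censor as designed", {
  s <- gen_competition_series(seed = 1, cv = 0)
  expect_equal(attr(s, "truth")$midpoint, 10)
  fit <- fit_4pl(s)
  expect_equal(fit$midpoint, attr(s, "truth")$midpoint, tolerance = 1e-6)

  for (seed in 1:3) {
    s <- gen_competition_series(seed = seed, cv = 0,
                                truth = list(top = 100, bottom = 0,
                                             hill = 1, midpoint = 500),
                                conc_max = 100)
    expect_equal(ic50_from_fit(fit_4pl(s), s)$censor, "gt_max")
  }
})

test_that("synthetic ELISpot triplicates are nonnegative integers with truth attached", {
  recs <- gen_elispot_dataset(seed = 8, n_diabetic = 2, n_control = 2,
                              n_peptides = 4)
  reps <- unlist(recs[, c("rep1", "rep2", "rep3")])
  expect_true(all(reps >= 0))
  expect_true(all(reps == round(reps)))
  truth <- attr(recs, "truth")
  expect_equal(nrow(truth), 4 * 4)
  expect_true(all(truth$mean_sfc_with <= truth$mean_sfc_without))
  expect_error(gen_elispot_dataset(effect = 1.2), "\\[0, 1\\)")
})

test_that("suppression fraction tracks the planted effect size", {
  # null effect: suppression calls are coin flips
  frac0 <- vapply(1:20, function(s) {
    recs <- gen_elispot_dataset(seed = 100 + s, n_diabetic = 3,
                                n_control = 0, n_peptides = 8, effect = 0)
    pairs <- elispot_pairs(recs)
    mean(pairs$suppressed)
  }, numeric(1))
  expect_lt(abs(mean(frac0) - 0.5), 0.1)

  # the strong-suppression regime: fraction >= 75% in >= 90% of seeds
  high <- vapply(1:100, function(s) {
    recs <- gen_elispot_dataset(seed = 300 + s, n_diabetic = 6,
                                n_control = 0, n_peptides = 14,
                                effect = 0.6, cv = 0.2)
    mean(elispot_pairs(recs)$suppressed) >= 0.75
  }, logical(1))
  expect_gte(mean(high), 0.9)
})

test_that("packaged fixtures load and validate", {
  fx <- load_fixture("gad65_binding")
  expect_equal(nrow(fx), 14)
  expect_equal(fx$cluster_score[fx$peptide_id == "GAD65_450-470"], 33.90)

  peps <- load_fixture("peptides")
  expect_equal(nchar(peps$sequence[peps$peptide_id == "hTregitope-167"]), 26)
  expect_equal(peps$cluster_score[peps$peptide_id == "mPPI_20-35"], -2.82)

  eli <- load_fixture("elispot")
  expect_equal(eli$sfc_without[eli$subject_id == "D1100H" &
                                 eli$stimulus == "GAD65_550-570"], 199)
  expect_equal(length(unique(eli$subject_id)), 11)
  expect_error(load_fixture("nope"))
})

test_that("simulation bundles round-trip through the file formats", {
  dir <- withr::local_tempdir()
  manifest <- write_simulation_bundle(dir, seed = 5, n_alleles = 4,
                                      protein_length = 150,
                                      plants = list(list(start = 60,
                                                         end = 80)))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  seqs <- read_fasta_sequences(file.path(dir, "protein.fasta"))
  expect_equal(nchar(seqs[[1]]), 150)
  mats <- lapply(list.files(dir, pattern = "^matrix_", full.names = TRUE),
                 read_scoring_matrix)
  expect_length(mats, 4)
  series <- read_competition_series(file.path(dir, "competition.tsv"))
  expect_length(series, 1)
  expect_true(fit_4pl(series[[1]])$converged)
})
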