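test_that("simulated model RDMs are valid, structured and distinguishable", {
  st <- make_stimulus_set(6, 3)
  models <- simulate_model_rdms(st, n_models = 4, seed = 1)
  expect_length(models, 4)
  same_cat <- outer(st$category, st$category, `==`) & !diag(18)
  for (m in models) {
    mm <- as.matrix(m)
    expect_true(all(mm >= 0))
    expect_equal(mm, t(mm))
    expect_equal(unname(diag(mm)), rep(0, 18))
  }
  # category structure: within-category < between-category on average
  cat_m <- as.matrix(models$category1)
  expect_lt(mean(cat_m[same_cat]), mean(cat_m[!same_cat & !diag(18)]))
  # pairwise distinguishability bound holds
  vecs <- sapply(models, rdm_vec)
  cors <- abs(cor(vecs, method = "spearman"))
  diag(cors) <- 0
  expect_lte(max(cors), 0.8)
  # determinism
  again <- simulate_model_rdms(st, n_models = 4, seed = 1)
  expect_identical(models, again)
  # two identical (noise-free) category structures cannot satisfy the bound
  expect_error(
    simulate_model_rdms(st, structures = c("category", "category"),
                        rdm_noise = 0, retries = 5, seed = 2),
    "generation-failure")
})

test_that("simulated patterns follow the planted generative law", {
  st <- make_stimulus_set(18, 5)
  models <- simulate_model_rdms(st, n_models = 3, seed = 3)
  # noise attenuates cross-session correlations by 1/(1+sigma^2)
  for (sig in c(0, 1)) {
    gt <- ground_truth(models, c(1, 0, 0), noise_sd = sig, n_subjects = 1,
                       n_units = 30000, stimuli = st, seed = 5)
    subs <- simulate_subject_patterns(gt)
    S <- attr(subs, "target")
    expect_equal(unname(diag(S)), rep(1, 90))
    expect_true(all(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))
    M <- 1 - as.matrix(splitdata_rdm(subs[[1]]$session1,
                                     subs[[1]]$session2))
    err <- M - S / (1 + sig^2)
    # elementwise agreement up to sampling noise and the small bias that
    # per-unit z-scoring leaves on structured targets
    expect_lt(max(abs(err[lower.tri(err)])), 0.04)
    expect_lt(abs(mean(err[lower.tri(err)])), 0.002)
    # regression slope of observed on target ~ 1
    fitc <- coef(lm(M[lower.tri(M)] ~ I(S[lower.tri(S)] / (1 + sig^2))))
    expect_equal(unname(fitc[2]), 1, tolerance = 0.03)
  }
  # all weights zero: independent units, off-diagonal correlations near 0
  gt0 <- ground_truth(models, c(0, 0, 0), noise_sd = 0, n_subjects = 1,
                      n_units = 30000, stimuli = st, seed = 6)
  s0 <- simulate_subject_patterns(gt0)
  M0 <- 1 - as.matrix(splitdata_rdm(s0[[1]]$session1, s0[[1]]$session2))
  expect_lt(max(abs(M0[lower.tri(M0)])), 0.04)  # -1/(n-1) + noise
  # z-scored output and determinism
  expect_true(s0[[1]]$session1$zscored)
  s0b <- simulate_subject_patterns(gt0)
  expect_identical(s0[[1]]$session1$matrix, s0b[[1]]$session1$matrix)
  expect_error(simulate_subject_patterns(
    ground_truth(models, list(other = c(1, 0, 0)), stimuli = st),
    neighborhood = "nope"), "mixture weights")
})

test_that("arrangement simulation round-trips planted geometry when noiseless", {
  # a planted RDM that is exactly 2D-embeddable
  set.seed(11)
  pts <- matrix(rnorm(20 * 2, sd = 100), 20)
  ids <- sprintf("s%02d", 1:20)
  planted <- rdm(`dimnames<-`(as.matrix(dist(pts)), list(ids, ids)))
  subsets <- design_subsets(20, 3, 8, n_candidates = 5, seed = 12,
                            stimulus_ids = ids)
  recs <- simulate_arrangement_session(planted, subsets, jitter_sd = 0,
                                       seed = 13)
  expect_length(recs, 1 + 3)
  expect_equal(recs[[1]]$set_index, 0L)
  expect_equal(recs[[1]]$stimulus_ids, ids)
  agg <- aggregate_arrangements(recs)
  expect_equal(spearman_fit(agg, planted), 1, tolerance = 1e-10)
  # aggregated-vs-planted agreement decreases monotonically with jitter
  rho <- sapply(c(0, 30, 300), function(js) {
    rr <- simulate_arrangement_session(planted, subsets, jitter_sd = js,
                                       seed = 14)
    spearman_fit(aggregate_arrangements(rr), planted)
  })
  expect_true(all(diff(rho) < 0))
  # unknown stimulus in subsets
  bad <- subsets
  bad$subsets[[1]][1] <- "zzz"
  expect_error(simulate_arrangement_session(planted, bad, 0, seed = 1),
               "unknown stimulus")
})

test_that("simulated annotations respect word-count and noise contracts", {
  st <- make_stimulus_set(4, 3)
  ann <- simulate_annotations(st, dim = 20, seed = 21, annotator_noise = 0)
  a1 <- ann$annotator1
  expect_s3_class(a1, "annotation_table")
  counts <- table(a1$stimulus_id, a1$class)
  expect_true(all(counts[, "verb"] >= 2 & counts[, "verb"] <= 5))
  expect_true(all(counts[, "nonverb"] >= 3 & counts[, "nonverb"] <= 6))
  # zero annotator noise -> perfect agreement
  agree <- annotator_agreement(ann$annotator1, ann$annotator2)
  expect_equal(unname(agree$per_stimulus), rep(1, 12), tolerance = 1e-12)
  # nonzero noise -> high but imperfect agreement
  ann2 <- simulate_annotations(st, dim = 20, seed = 21,
                               annotator_noise = 0.3)
  agree2 <- annotator_agreement(ann2$annotator1, ann2$annotator2)
  expect_true(all(agree2$per_stimulus < 1))
  expect_gt(agree2$mean, 0.5)
  expect_error(simulate_annotations(st, dim = 1), "dim")
})

test_that("a written synthetic dataset reads back consistently", {
  st <- make_stimulus_set(3, 2)
  models <- simulate_model_rdms(st, n_models = 2, seed = 31)
  gt <- ground_truth(models, list(nb01 = c(0.7, 0.3)), noise_sd = 0.5,
                     n_subjects = 2, n_units = 30, stimuli = st, seed = 32)
  dir <- withr::local_tempdir()
  simulate_dataset(gt, dir, n_subsets = 2, subset_size = 3, n_blocks = 2)
  # patterns round-trip
  p <- read_patterns(file.path(dir, "nb01_sub001_ses-1.tsv"))
  subs <- simulate_subject_patterns(gt, "nb01")
  expect_identical(unname(p$matrix), unname(subs[[1]]$session1$matrix))
  expect_true(p$zscored)
  # model RDM round-trip
  m <- read_rdm(file.path(dir, "model_category1.tsv"))
  expect_identical(m$matrix, models$category1$matrix)
  # behavioral files parse
  expect_gt(length(read_arrangements(file.path(dir, "arrangements.csv"))), 0)
  expect_gt(length(read_gaze(file.path(dir, "gaze.csv"))), 0)
  ann <- read_annotations(file.path(dir, "annotations_a1.tsv"))
  expect_s3_class(ann, "annotation_table")
  side <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(side$seed, 32)
  expect_equal(side$noise_sd, 0.5)
})
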